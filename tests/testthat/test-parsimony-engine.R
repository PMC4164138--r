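ordered <- cost_model("ordered")
unordered <- cost_model("unordered")

test_that("tree_length scores elementary cases by hand", {
  # two taxa, one character 0 vs 5
  two <- ape::read.tree(text = "(a,b);")
  v2 <- make_view(matrix(c(0L, 5L), 2, 1, dimnames = list(c("a", "b"), "c1")))
  expect_equal(tree_length(two, v2, ordered), 5)
  expect_equal(tree_length(two, v2, unordered), 1)
  # constant character on any tree
  four <- ape::read.tree(text = "((A,B),(C,D));")
  vc <- make_view(matrix(2L, 4, 3, dimnames = list(LETTERS[1:4], paste0("c", 1:3))))
  expect_equal(tree_length(four, vc, ordered), 0)
  # 0,0,1,1 on the matching split: one Fitch step
  v4 <- make_view(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                         dimnames = list(LETTERS[1:4], "c1")))
  expect_equal(tree_length(four, v4, unordered), 1)
  expect_error(tree_length(four, make_view(matrix(c(0L, 0L, 1L, 40L), 4, 1,
                                                  dimnames = list(LETTERS[1:4], "c1"))),
                           ordered), "0, 31")
})

test_that("unrooted length is invariant under re-rooting", {
  set.seed(7)
  states <- rand_states(8, 12)
  tr <- rand_tx(8)
  phy <- gocensus:::tx_to_phylo(tr, rownames(states))
  v <- make_view(states)
  base <- tree_length(phy, v, ordered)
  for (tip in c("t2", "t5", "t8")) {
    rerooted <- ape::root(ape::unroot(phy), outgroup = tip,
                          resolve.root = TRUE)
    expect_equal(tree_length(rerooted, v, ordered), base)
  }
})

test_that("Sankoff agrees with Fitch, Wagner and phangorn on random instances", {
  set.seed(12)
  for (rep in 1:12) {
    n <- sample(4:9, 1)
    states <- rand_states(n, sample(3:10, 1))
    tr <- rand_tx(n)
    s_ord <- sum(gocensus:::sankoff_length_cpp(tr$parent, tr$tiprow, states,
                                               ordered$matrix))
    s_un <- sum(gocensus:::sankoff_length_cpp(tr$parent, tr$tiprow, states,
                                              unordered$matrix))
    expect_equal(s_ord, gocensus:::wagner_length_cpp(tr$parent, tr$tiprow, states))
    expect_equal(s_un, gocensus:::fitch_length_cpp(tr$parent, tr$tiprow, states))
    # independent implementations
    phy <- gocensus:::tx_to_phylo(tr, rownames(states))
    pd <- phangorn::phyDat(states, type = "USER", levels = 0:31)
    expect_equal(s_un, as.numeric(phangorn::parsimony(phy, pd, method = "fitch")))
    expect_equal(s_ord, as.numeric(phangorn::parsimony(phy, pd, method = "sankoff",
                                                       cost = ordered$matrix)))
  }
})

test_that("a clean 4-taxon split is recovered uniquely", {
  states <- matrix(c(0L, 0L, 4L, 4L), 4, 10,
                   dimnames = list(c("A", "B", "C", "D"), paste0("c", 1:10)))
  fit <- mp_search(make_view(states), ordered, n_starts = 4, seed = 5)
  expect_equal(fit$length, 40)          # 4 steps per character
  expect_length(fit$trees, 1)
  expect_false(fit$tied)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(fit$trees[[1]]), ape::unroot(want)), 0,
               ignore_attr = TRUE)
})

test_that("heuristic search attains the exhaustive minimum (<= 7 taxa)", {
  set.seed(20)
  n_cases <- 0
  for (rep in 1:50) {
    n <- if (rep <= 42) sample(5:6, 1) else 7
    states <- rand_states(n, sample(4:8, 1), max_state = 4)
    oracle <- exhaustive_mp_length(states, ordered$matrix)
    fit <- mp_search(make_view(states), ordered, n_starts = 5, seed = rep)
    expect_equal(fit$length, oracle, info = paste("case", rep))
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 50)
})

test_that("search is deterministic given the seed", {
  set.seed(77)
  states <- rand_states(9, 15)
  v <- make_view(states)
  f1 <- mp_search(v, ordered, n_starts = 4, seed = 123)
  f2 <- mp_search(v, ordered, n_starts = 4, seed = 123)
  expect_identical(lapply(f1$trees, ape::write.tree),
                   lapply(f2$trees, ape::write.tree))
  expect_identical(f1$length, f2$length)
})

test_that("Lundberg placement matches brute-force scoring on every branch", {
  set.seed(30)
  states <- rand_states(6, 9, max_state = 6)
  v <- make_view(states)
  fit <- mp_search(v, ordered, n_starts = 4, seed = 2)
  tr <- gocensus:::phylo_to_tx(fit$trees[[1]], rownames(states))
  for (anc in c(0L, 31L)) {
    aug <- rbind(states, rep(anc, ncol(states)))
    brute <- vapply(gocensus:::tx_edges(tr), function(e) {
      cand <- gocensus:::tx_insert(tr, e, 7L)
      sum(gocensus:::sankoff_length_cpp(cand$parent, cand$tiprow, aug,
                                        ordered$matrix))
    }, 0)
    rooted <- lundberg_root(fit$trees[[1]], v, ordered, anc)
    expect_equal(attr(rooted, "root_score"), min(brute))
    expect_equal(attr(rooted, "length"), fit$length)
    expect_true(ape::is.rooted(rooted))
    expect_setequal(rooted$tip.label, rownames(states))  # ancestor removed
  }
})

test_that("an all-ancestral taxon pulls the Lundberg root to its branch", {
  set.seed(31)
  states <- rand_states(5, 8, max_state = 6)
  states["t3", ] <- 0L
  v <- make_view(states)
  fit <- mp_search(v, ordered, n_starts = 4, seed = 9)
  rooted <- lundberg_root(fit$trees[[1]], v, ordered, 0L)
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  basal_tips <- rooted$tip.label[kids[kids <= length(rooted$tip.label)]]
  expect_true("t3" %in% basal_tips)
})

test_that("identical rows make every root placement tie, flagged as such", {
  states <- matrix(3L, 5, 6, dimnames = list(paste0("t", 1:5), paste0("c", 1:6)))
  v <- make_view(states)
  fit <- mp_search(v, ordered, n_starts = 2, seed = 1)
  rooted <- lundberg_root(fit$trees[[1]], v, ordered, 0L)
  expect_true(attr(rooted, "root_tie"))
})

test_that("single-character bootstraps are degenerate: support 0 or 100", {
  states <- matrix(c(0L, 0L, 3L, 3L, 3L), 5, 1,
                   dimnames = list(paste0("t", 1:5), "c1"))
  v <- make_view(states)
  fit <- mp_search(v, ordered, n_starts = 2, seed = 4)
  rooted <- lundberg_root(fit$trees[[1]], v, ordered, 0L)
  bs <- bootstrap_support(rooted, v, ordered, n_reps = 20, seed = 6)
  expect_true(all(bs$support[-1] %in% c(0, 100)))
  bs2 <- bootstrap_support(rooted, v, ordered, n_reps = 20, seed = 6)
  expect_identical(bs$support, bs2$support)     # seeded determinism
})

test_that("fit indices behave on congruent and homoplasious characters", {
  four <- ape::read.tree(text = "((A,B),(C,D));")
  congruent <- make_view(matrix(c(0L, 0L, 1L, 1L), 4, 2,
                                dimnames = list(LETTERS[1:4], c("c1", "c2"))))
  fi <- fit_indices(four, congruent, unordered)
  expect_equal(fi$CI, 1)
  expect_equal(fi$RI, 1)
  expect_equal(fi$RC, 1)
  # a character split against the tree: CI = 1/2
  against <- make_view(matrix(c(0L, 1L, 0L, 1L), 4, 1,
                              dimnames = list(LETTERS[1:4], "c1")))
  fa <- fit_indices(four, against, unordered)
  expect_equal(fa$CI, 0.5)
  # RC never exceeds CI or RI
  set.seed(40)
  for (rep in 1:5) {
    states <- rand_states(6, 8)
    tr <- rand_tx(6)
    phy <- gocensus:::tx_to_phylo(tr, rownames(states))
    f <- fit_indices(phy, make_view(states), ordered)
    expect_lte(f$RC, min(f$CI, f$RI) + 1e-12)
  }
  # invariant characters are reported
  inv <- make_view(matrix(c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L), 4, 2,
                          dimnames = list(LETTERS[1:4], c("c1", "c2"))))
  expect_message(fit_indices(four, inv, unordered), "1 invariant")
})

test_that("newick export round-trips and preserves polytomies", {
  tr <- ape::read.tree(text = "((A,B),C);")
  tr$node.label <- c("", "100")
  txt <- write_newick(tr)
  expect_match(txt, "\\(\\(A,B\\)100,C\\);")
  expect_identical(write_newick(ape::read.tree(text = txt)), txt)
  poly <- ape::read.tree(text = "(A,B,C,D);")
  expect_equal(ape::read.tree(text = write_newick(poly))$Nnode, 1)
  unlabeled <- tr
  unlabeled$tip.label[2] <- ""
  expect_error(write_newick(unlabeled), "unlabeled")
  # GO accessions are sanitised into legal unquoted labels
  go <- ape::read.tree(text = "((a,b),c);")
  go$tip.label <- c("GO:1", "GO:2", "GO:3")
  expect_match(write_newick(go), "GO_1")
})
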