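#' Character-change cost model
#'
#' Ordered (Wagner) characters cost `|i - j|` per change between states `i`
#' and `j`; unordered (Fitch) characters cost 1 for any change.  The
#' encoded abundance states are ordered by construction, so ordered is the
#' default throughout; unordered mode is provided for sensitivity checks.
#'
#' @param kind "ordered" or "unordered".
#' @param state_count Number of states (32 for the encoded census).
#' @return A `cost_model`: list with `kind`, `state_count` and the full
#'   cost `matrix`.
#' @export
cost_model <- function(kind = c("ordered", "unordered"), state_count = 32L) {
  kind <- match.arg(kind)
  s <- seq_len(state_count) - 1L
  m <- if (kind == "ordered") abs(outer(s, s, "-")) else
    1 - diag(state_count)
  structure(list(kind = kind, state_count = as.integer(state_count),
                 matrix = m + 0),
            class = "cost_model")
}

view_states <- function(view) {
  stopifnot(inherits(view, "go_charview"))
  s <- view$states
  if (any(s < 0L) || any(s > 31L)) stop_("states outside [0, 31]")
  storage.mode(s) <- "integer"
  s
}

#' Parsimony length of a tree
#'
#' Scores a tree against a character-matrix view by Sankoff dynamic
#' programming (generalised parsimony) under the given cost model.  The
#' score is rooting-invariant, so any rooting of the same unrooted topology
#' gives the same length.  Multifurcations are allowed.
#'
#' @param tree An ape `phylo` whose tips are the view's taxa.
#' @param view A `go_charview`.
#' @param cost A [cost_model()].
#' @param per_character Return the per-character step vector instead of the
#'   total?
#' @return Total parsimony steps (numeric, integer-valued), or a named
#'   per-character vector.
#' @export
tree_length <- function(tree, view, cost = cost_model("ordered"),
                        per_character = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(cost, "cost_model"))
  states <- view_states(view)
  if (!setequal(tree$tip.label, rownames(states))) {
    stop_("tree tips and view taxa differ")
  }
  tx <- phylo_to_tx(tree, rownames(states))
  steps <- sankoff_length_cpp(tx$parent, tx$tiprow, states, cost$matrix)
  names(steps) <- colnames(states)
  if (per_character) steps else sum(steps)
}

# fast scorer used inside the search; equals the Sankoff score for binary
# trees (asserted in the test suite)
fast_kind <- function(cost) cost$kind

#' Heuristic maximum-parsimony search
#'
#' Random-addition starting trees followed by first-improvement
#' hill-climbing: nearest-neighbour interchange (NNI) to a local optimum,
#' then subtree-prune-regraft (SPR) sweeps, returning to NNI after each
#' accepted SPR move.  All distinct unrooted topologies attaining the best
#' length found across starts are returned, in canonical order
#' (lexicographic canonical Newick), so results are reproducible and ties
#' are surfaced rather than silently broken.
#'
#' @param view A `go_charview` (taxa x characters).
#' @param cost A [cost_model()].
#' @param n_starts Random-addition replicates (default 10).
#' @param spr Run SPR sweeps after NNI (default TRUE; bootstrap replicates
#'   typically use NNI only).
#' @param seed Integer seed; identical input and seed give identical
#'   output.
#' @return An `mp_fit`: list with `trees` (ape `phylo` list, canonical
#'   order), `length` (best parsimony score), `tied` (more than one best
#'   topology?), `n_starts`, `cost`, `seed`.
#' @export
mp_search <- function(view, cost = cost_model("ordered"), n_starts = 10,
                      spr = TRUE, seed = 1) {
  states <- view_states(view)
  n <- nrow(states)
  if (n < 3L) stop_("maximum-parsimony search needs at least 3 taxa")
  labels <- rownames(states)
  kind <- fast_kind(cost)
  best_len <- Inf
  pool <- list()
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      tr <- tx_stepwise_addition(sample.int(n), states, kind)
      res <- tx_hillclimb(tr, states, kind, spr = spr)
      key <- tx_canonical_newick(res$tree, labels)
      if (res$length < best_len - 1e-9) {
        best_len <- res$length
        pool <- setNames(list(res$tree), key)
      } else if (abs(res$length - best_len) < 1e-9 &&
                 !key %in% names(pool)) {
        pool[[key]] <- res$tree
      }
    }
  })
  pool <- pool[order(names(pool))]
  trees <- lapply(pool, tx_to_phylo, labels = labels)
  names(trees) <- NULL
  structure(list(trees = trees, length = best_len,
                 tied = length(trees) > 1L, n_starts = n_starts,
                 cost = cost, seed = seed,
                 n_taxa = n, n_characters = ncol(states)),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat("mp_fit: maximum-parsimony search over", x$n_taxa, "taxa,",
      x$n_characters, "characters (", x$cost$kind, "states )\n")
  cat("  best length:", x$length, "steps;", length(x$trees),
      "best topolog", if (length(x$trees) == 1L) "y" else "ies (tie)", "\n")
  invisible(x)
}

#' @export
summary.mp_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

# enumerate unrooted edges in a deterministic canonical order: by the
# sorted tip-label set of the child-side clade
tx_edge_order <- function(tr, labels) {
  ch <- tx_children_vec(tr)
  edges <- tx_edges(tr)
  keys <- vapply(edges, function(e) {
    nodes <- tx_subtree_nodes(tr, e, ch)
    tips <- nodes[tr$tiprow[nodes] > 0L]
    paste(sort(labels[tr$tiprow[tips]]), collapse = "\r")
  }, "")
  edges[order(keys)]
}

#' Root a tree by the Lundberg criterion
#'
#' Attaches a hypothetical ancestor with every character fixed at
#' `ancestral_state` to each branch of the unrooted tree in turn and places
#' the root on a branch minimising the total parsimony length — rooting
#' without any outgroup taxon.  With the encoded census, ancestral state 31
#' ("V") polarises trees of functions (the most abundant function is
#' oldest) and ancestral state 0 polarises trees of life (the ancestral
#' genome is minimal).  Ties are broken by canonical branch order and
#' flagged on the result.
#'
#' @param tree An ape `phylo` (treated as unrooted; a basal trifurcation is
#'   resolved internally before scoring).
#' @param view A `go_charview`.
#' @param cost A [cost_model()].
#' @param ancestral_state 0 or 31.
#' @return A rooted ape `phylo` with attributes `length` (parsimony steps
#'   of the tree without the ancestor), `root_score` (steps including the
#'   ancestor at its best attachment), `root_tie` (TRUE if several branches
#'   tied) and `ancestral_state`.
#' @export
lundberg_root <- function(tree, view, cost = cost_model("ordered"),
                          ancestral_state = 0) {
  stopifnot(inherits(tree, "phylo"), ancestral_state %in% c(0L, 31L))
  states <- view_states(view)
  labels <- rownames(states)
  tx <- tx_binarize(phylo_to_tx(tree, labels))
  kind <- fast_kind(cost)
  anc_row <- nrow(states) + 1L
  aug <- rbind(states, rep(as.integer(ancestral_state), ncol(states)))
  edges <- tx_edge_order(tx, labels)
  scores <- vapply(edges, function(e) {
    tx_score(tx_insert(tx, e, anc_row), aug, kind)
  }, 0)
  best <- min(scores)
  chosen <- edges[which(scores == best)[1L]]
  # the child-side tip set of the chosen branch defines the outgroup
  ch <- tx_children_vec(tx)
  nodes <- tx_subtree_nodes(tx, chosen, ch)
  out_tips <- labels[tx$tiprow[nodes[tx$tiprow[nodes] > 0L]]]
  unrooted <- ape::unroot(tx_to_phylo(tx, labels))
  rooted <- if (length(out_tips) == length(unrooted$tip.label)) {
    # degenerate: the "child side" is the whole tree minus the root edge
    ape::root(unrooted, outgroup = setdiff(labels, out_tips),
              resolve.root = TRUE)
  } else {
    ape::root(unrooted, outgroup = out_tips, resolve.root = TRUE)
  }
  attr(rooted, "length") <- tx_score(tx, states, kind)
  attr(rooted, "root_score") <- best
  attr(rooted, "root_tie") <- sum(scores == best) > 1L
  attr(rooted, "ancestral_state") <- as.integer(ancestral_state)
  rooted
}

#' Bootstrap support for the clades of a rooted tree
#'
#' Resamples characters with replacement, reruns a reduced maximum-
#' parsimony search per replicate (fewer starts, NNI only by default), and
#' reports for every clade of `tree` the percentage of replicates whose
#' best tree contains it (as an unrooted bipartition).
#'
#' @param tree The full-data best tree (rooted ape `phylo`).
#' @param view The `go_charview` the tree was inferred from.
#' @param cost A [cost_model()].
#' @param n_reps Bootstrap replicates (the study convention is 1,000; tests
#'   use fewer).
#' @param seed Integer seed.
#' @param n_starts Random-addition starts per replicate (default 2).
#' @param spr SPR sweeps inside replicates (default FALSE: NNI only).
#' @return List with `support` (numeric vector, one percentage per internal
#'   node of `tree`, NA for the root), `clades` (tip sets as strings),
#'   `tree` (input tree with `node.label` set to the support values) and
#'   `n_reps`.
#' @export
bootstrap_support <- function(tree, view, cost = cost_model("ordered"),
                              n_reps = 1000, seed = 1, n_starts = 2,
                              spr = FALSE) {
  stopifnot(inherits(tree, "phylo"), n_reps >= 1)
  states <- view_states(view)
  C <- ncol(states)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(C, C, replace = TRUE)
      v <- structure(list(states = states[, cols, drop = FALSE],
                          taxa = rownames(states),
                          characters = colnames(states)[cols],
                          orientation = view$orientation),
                     class = "go_charview")
      # the replicate's search seed depends only on the resampled column
      # multiset, so identical replicate data always give the same tree
      rep_seed <- as.integer((sum(sort(cols) * seq_len(C)) + 131 * seed) %%
                               2147483587) + 1L
      fit <- mp_search(v, cost, n_starts = n_starts, spr = spr,
                       seed = rep_seed)
      fit$trees[[1L]]
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  support[1L] <- NA_real_   # the root clade is trivial
  clades <- vapply(seq_len(tree$Nnode), function(i) {
    tips <- ape::extract.clade(tree, ntip + i)$tip.label
    paste(sort(tips), collapse = ",")
  }, "")
  out_tree <- tree
  out_tree$node.label <- ifelse(is.na(support), "",
                                formatC(support, format = "fg"))
  list(support = support, clades = clades, tree = out_tree, n_reps = n_reps)
}

#' Homoplasy fit indices
#'
#' Ensemble consistency index (CI), retention index (RI) and rescaled
#' consistency index (RC = CI x RI) of a tree against a character matrix.
#' Per character, the minimum conceivable steps are the tip-state range
#' (ordered) or the number of observed states minus one (unordered); the
#' maximum steps are those on a completely unresolved tree.  Invariant
#' characters are excluded from the sums, with a message stating how many.
#'
#' @param tree An ape `phylo`.
#' @param view A `go_charview`.
#' @param cost A [cost_model()].
#' @return List with `CI`, `RI`, `RC`, `per_character` (data.frame with
#'   observed / min / max steps) and `n_invariant_excluded`.
#' @export
fit_indices <- function(tree, view, cost = cost_model("ordered")) {
  states <- view_states(view)
  obs <- tree_length(tree, view, cost, per_character = TRUE)
  ordered <- cost$kind == "ordered"
  mins <- apply(states, 2L, function(s) {
    if (ordered) max(s) - min(s) else length(unique(s)) - 1L
  })
  maxs <- apply(states, 2L, function(s) {
    if (ordered) {
      min(vapply(min(s):max(s), function(m) sum(abs(s - m)), 0))
    } else {
      length(s) - max(tabulate(s + 1L))
    }
  })
  invariant <- mins == 0 & maxs == 0
  if (any(invariant)) {
    message(sprintf("fit_indices: %d invariant character(s) excluded",
                    sum(invariant)))
  }
  keep <- !invariant
  CI <- sum(mins[keep]) / sum(obs[keep])
  denom <- sum(maxs[keep]) - sum(mins[keep])
  RI <- if (denom > 0) (sum(maxs[keep]) - sum(obs[keep])) / denom else NA_real_
  list(CI = CI, RI = RI, RC = CI * RI,
       per_character = data.frame(character = colnames(states),
                                  observed = as.numeric(obs),
                                  min_steps = as.numeric(mins),
                                  max_steps = as.numeric(maxs)),
       n_invariant_excluded = sum(invariant))
}

#' Write a tree as Newick with support labels
#'
#' Tip labels are sanitised for the unquoted Newick label syntax:
#' characters with structural meaning (colons, parentheses, commas,
#' semicolons, brackets, spaces) become underscores, so a GO accession
#' `GO:0000123` exports as `GO_0000123`.  Existing `node.label` values
#' (e.g. bootstrap supports) are preserved.
#'
#' @param tree A rooted or unrooted ape `phylo`.
#' @param path Output file, or NULL to return the string.
#' @param force Overwrite an existing file?
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, force = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop_("tree has unlabeled tips")
  }
  tree$tip.label <- gsub("[][ :;,()']", "_", tree$tip.label)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  writeLines(txt, path)
  invisible(txt)
}
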