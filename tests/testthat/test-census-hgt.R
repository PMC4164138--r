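test_that("census counts annotation records, not proteins", {
  ann <- list(g1 = annotation_set("g1", data.frame(
    protein_id = c("p1", "p2", "p1"), go_id = c("t1", "t1", "t2"),
    aspect = "F"), 5L))
  cen <- build_census(ann, c("t1", "t2", "t3"), "g1")
  expect_identical(cen$abundance["g1", ], c(t1 = 2L, t2 = 1L))
  expect_false("t3" %in% colnames(cen$abundance))   # absent term, no column
  expect_error(build_census(ann, c("t1", "t2"), character(0)), "retained")
})

test_that("census term count matches the ground-truth repertoire union", {
  corp <- small_corpus(seed = 31, hgt_term_count = 0)
  cen <- build_census(corp$sim$annotations, corp$terminal,
                      corp$sim$metadata$organism_id)
  union_terms <- sort(unique(unlist(lapply(corp$sim$annotations, function(a)
    a$records$go_id))))
  expect_identical(colnames(cen$abundance),
                   intersect(union_terms, corp$terminal))
})

test_that("column sums are preserved under genome reordering", {
  corp <- small_corpus(seed = 32)
  ids <- corp$sim$metadata$organism_id
  cen1 <- build_census(corp$sim$annotations, corp$terminal, ids)
  cen2 <- build_census(corp$sim$annotations, corp$terminal, rev(ids))
  expect_identical(colSums(cen1$abundance), colSums(cen2$abundance))
})

test_that("annotations to obsolete terms are dropped with a warning", {
  ann <- list(g1 = annotation_set("g1", data.frame(
    protein_id = c("p1", "p2"), go_id = c("t1", "dead"), aspect = "F"), 5L))
  expect_warning(
    cen <- build_census(ann, "t1", "g1", obsolete_terms = "dead"),
    "obsolete")
  expect_identical(colnames(cen$abundance), "t1")
})

test_that("hypergeometric upper tail matches closed-form and edge cases", {
  expect_equal(hypergeom_upper_tail(0, 5, 5, 10), 1.0)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_upper_tail(2, 3, 3, 6), 10 / 20)
  expect_error(hypergeom_upper_tail(6, 5, 5, 10), "bounds")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "bounds")
})

test_that("hypergeometric tail equals draw enumeration for N <= 12", {
  set.seed(1)
  for (rep in 1:25) {
    N <- sample(4:12, 1)
    n <- sample(1:N, 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 hyper_tail_enum(k, K, n, N),
                 tolerance = 1e-12,
                 info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
  }
})

test_that("a term carried only by HTPs is flagged; k = 0 never is", {
  # genome with 12 annotations; 3 of them (all of term tH) sit on HTPs
  ann <- list(g1 = annotation_set("g1", data.frame(
    protein_id = c(paste0("h", 1:3), paste0("p", 1:9)),
    go_id = c(rep("tH", 3), rep(paste0("t", 1:3), each = 3)),
    aspect = "F"), 20L))
  cen <- build_census(ann, c("tH", paste0("t", 1:3)), "g1")
  res <- flag_hgt_terms(cen, ann, list(g1 = paste0("h", 1:3)))
  res <- res[order(res$term), ]
  expect_true(res$flagged[res$term == "tH"])
  # hand enumeration: P(all 3 HTP draws hit the 3 tH records of 12)
  expect_equal(res$p_raw[res$term == "tH"], hyper_tail_enum(3, 3, 3, 12))
  expect_false(any(res$flagged[res$k == 0]))
})

test_that("empty HTP lists give all-unflagged results with p = 1", {
  corp <- small_corpus(seed = 33)
  cen <- build_census(corp$sim$annotations, corp$terminal,
                      corp$sim$metadata$organism_id)
  res <- flag_hgt_terms(cen, corp$sim$annotations, list())
  expect_true(all(res$p_raw == 1))
  expect_false(any(res$flagged))
})

test_that("planted high-copy HGT terms are recovered (power check)", {
  hits <- vapply(1:3, function(s) {
    corp <- small_corpus(seed = s, duplication_mean = 9, hgt_term_count = 5,
                         ancestral_repertoire_size = 40, n_terms_total = 80,
                         loss_rate_per_clade = 0.3)
    fl <- filter_organisms(corp$sim$metadata, corp$sim$annotations,
                           corp$terminal)
    cen <- build_census(corp$sim$annotations, corp$terminal, fl$retained)
    res <- flag_hgt_terms(cen, corp$sim$annotations, corp$sim$hgt_lists)
    sum(res$term[res$flagged] %in% corp$sim$truth$hgt_terms)
  }, 0)
  expect_true(all(hits >= 4))
})

test_that("type-I error is controlled when no transfer is planted", {
  # HTP lists are random proteins, so no term is truly enriched
  false_rates <- vapply(1:4, function(s) {
    corp <- small_corpus(seed = s, hgt_term_count = 0)
    cen <- build_census(corp$sim$annotations, corp$terminal,
                        corp$sim$metadata$organism_id)
    set.seed(s + 100)
    fake <- lapply(corp$sim$annotations[1:4], function(a) {
      prot <- unique(a$records$protein_id)
      sample(prot, min(5, length(prot)))
    })
    res <- flag_hgt_terms(cen, corp$sim$annotations, fake)
    mean(res$flagged)
  }, 0)
  expect_lte(mean(false_rates), 0.05)
})

test_that("exclude_terms removes exactly the flagged columns", {
  corp <- small_corpus(seed = 34)
  cen <- build_census(corp$sim$annotations, corp$terminal,
                      corp$sim$metadata$organism_id)
  expect_identical(exclude_terms(cen, character(0)), cen)
  drop2 <- colnames(cen$abundance)[1:2]
  cen2 <- exclude_terms(cen, c(drop2, "GO:not-a-column"))
  expect_equal(ncol(cen2$abundance), ncol(cen$abundance) - 2)
  expect_identical(rownames(cen2$abundance), rownames(cen$abundance))
  # flagging everything yields an empty matrix, rejected downstream
  all_gone <- exclude_terms(cen, colnames(cen$abundance))
  expect_equal(ncol(all_gone$abundance), 0)
  expect_error(encode_census(all_gone), "empty")
})

test_that("census TSV and MTX exports round-trip", {
  corp <- small_corpus(seed = 35)
  cen <- build_census(corp$sim$annotations, corp$terminal,
                      corp$sim$metadata$organism_id,
                      superkingdom = corp$sim$metadata)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_census(cen, tsv, force = TRUE)
  back <- read_census(tsv)
  expect_identical(back$abundance, cen$abundance)
  expect_identical(unname(back$superkingdom), unname(cen$superkingdom))
  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_census_mtx(cen, mtx, force = TRUE)
  m <- as.matrix(Matrix::readMM(mtx))
  expect_equal(unname(cen$abundance), unname(m), ignore_attr = TRUE)
})
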