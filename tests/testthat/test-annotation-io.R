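obo_lines <- function(...) c("format-version: 1.2", "", ...)

test_that("parse_obo loads terms, multiple parents and obsolete flags", {
  g <- parse_obo(obo_lines(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: mid", "namespace: molecular_function",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: leaf", "namespace: molecular_function",
    "is_a: GO:2", "is_a: GO:1", "",
    "[Term]", "id: GO:4", "name: gone", "namespace: molecular_function",
    "is_obsolete: true", "is_a: GO:1"))
  expect_equal(nrow(g$terms), 4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(sum(g$edges$child == "GO:3"), 2)   # two is_a parents
  expect_true(g$terms$obsolete[g$terms$id == "GO:4"])
})

test_that("malformed OBO stanzas are rejected with a line number", {
  expect_error(parse_obo(obo_lines("[Term]", "id: GO:1", "no colon here")),
               "line 5")
  expect_error(parse_obo(obo_lines("[Term]", "name: anonymous")),
               "missing id")
})

test_that("a generated ontology round-trips through OBO", {
  g <- generate_ontology(simulation_config(seed = 13))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, path, force = TRUE)
  back <- parse_obo(path)
  ord <- function(df) df[do.call(order, df), , drop = FALSE]
  expect_equal(ord(back$terms), ord(g$terms), ignore_attr = TRUE)
  expect_equal(ord(back$edges), ord(g$edges), ignore_attr = TRUE)
  expect_identical(terminal_mf_terms(back), terminal_mf_terms(g))
})

test_that("terminal_mf_terms returns exactly the molecular_function leaves", {
  chain <- parse_obo(obo_lines(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: a", "namespace: molecular_function",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: b", "namespace: molecular_function",
    "is_a: GO:2"))
  expect_identical(terminal_mf_terms(chain), "GO:3")

  diamond <- parse_obo(obo_lines(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: x", "namespace: molecular_function",
    "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: y", "namespace: molecular_function",
    "is_a: GO:1", "",
    "[Term]", "id: GO:4", "name: z", "namespace: molecular_function",
    "is_a: GO:2", "is_a: GO:3"))
  expect_identical(terminal_mf_terms(diamond), "GO:4")  # counted once

  with_bp <- parse_obo(obo_lines(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function", "",
    "[Term]", "id: GO:2", "name: mf leaf", "namespace: molecular_function",
    "is_a: GO:1", "",
    "[Term]", "id: GO:5", "name: bp leaf", "namespace: biological_process"))
  expect_identical(terminal_mf_terms(with_bp), "GO:2")

  bp_only <- parse_obo(obo_lines(
    "[Term]", "id: GO:5", "name: bp", "namespace: biological_process"))
  expect_error(terminal_mf_terms(bp_only), "molecular_function")
})

test_that("terminal set is the complement of the is_a parents (set identity)", {
  for (seed in 1:3) {
    g <- generate_ontology(simulation_config(seed = seed, n_terms_total = 90,
                                             ancestral_repertoire_size = 40))
    live <- g$terms[!g$terms$obsolete & g$terms$namespace == "molecular_function", ]
    parents <- unique(g$edges$parent[g$edges$child %in% live$id &
                                       g$edges$parent %in% live$id])
    expect_setequal(terminal_mf_terms(g), setdiff(live$id, parents))
  }
})

gaf_line <- function(protein, term, aspect = "F", qualifier = "") {
  paste(c("DB", protein, protein, qualifier, term, "REF:1", "IEA", "",
          aspect, "", "", "protein", "taxon:1", "20091101", "DB", "", ""),
        collapse = "\t")
}

test_that("parse_gaf filters aspects and NOT qualifiers, keeps duplicates", {
  lines <- c("!gaf-version: 2.1",
             gaf_line("p1", "GO:1"), gaf_line("p1", "GO:1"),  # duplicate kept
             gaf_line("p2", "GO:2"),
             gaf_line("p3", "GO:3", aspect = "P"),
             gaf_line("p4", "GO:4", aspect = "P"),
             gaf_line("p5", "GO:5", qualifier = "NOT"))
  a <- parse_gaf(lines, organism_id = "X")
  expect_equal(nrow(a$records), 3)
  expect_equal(sum(a$records$go_id == "GO:1"), 2)
  expect_false("GO:5" %in% a$records$go_id)
})

test_that("parse_gaf reports the offending line on a column-count error", {
  lines <- c("!header", gaf_line("p1", "GO:1"), "too\tfew\tcolumns")
  expect_error(parse_gaf(lines), "line 3.*3 columns|3 columns")
})

test_that("organism filters fire in order: strain, lifestyle, coverage", {
  ann <- list(
    good = annotation_set("good", data.frame(
      protein_id = paste0("p", 1:10), go_id = rep("GO:1", 10),
      aspect = "F"), 20L),                       # coverage 0.50, inclusive
    lowcov = annotation_set("lowcov", data.frame(
      protein_id = paste0("p", 1:49), go_id = rep("GO:1", 49),
      aspect = "F"), 100L),                      # coverage 0.49
    par = annotation_set("par", data.frame(
      protein_id = "p1", go_id = "GO:1", aspect = "F"), 1L),
    nottype = annotation_set("nottype", data.frame(
      protein_id = "p1", go_id = "GO:1", aspect = "F"), 1L))
  md <- data.frame(organism_id = c("good", "lowcov", "par", "nottype"),
                   superkingdom = "B",
                   lifestyle = c("free_living", "free_living",
                                 "facultative_parasite", "parasite"),
                   proteome_size = c(20L, 100L, 1L, 1L),
                   is_type_strain = c(TRUE, TRUE, TRUE, FALSE))
  f <- filter_organisms(md, ann, "GO:1")
  expect_identical(f$retained, "good")
  lg <- setNames(f$log$rule, f$log$organism_id)
  expect_identical(lg[["lowcov"]], "coverage")
  expect_identical(lg[["par"]], "lifestyle")
  expect_identical(lg[["nottype"]], "strain")    # strain precedes lifestyle
  expect_true(all(f$coverage >= 0 & f$coverage <= 1))
  # order independence
  f2 <- filter_organisms(md, rev(ann), "GO:1")
  expect_setequal(f2$retained, f$retained)
  # unknown organism
  expect_error(filter_organisms(md[-1, ], ann, "GO:1"), "missing")
})

test_that("coverage counts only proteins annotated to terminal MF terms", {
  ann <- list(x = annotation_set("x", data.frame(
    protein_id = paste0("p", 1:10),
    go_id = c(rep("GO:leaf", 4), rep("GO:inner", 6)),
    aspect = "F"), 10L))
  md <- data.frame(organism_id = "x", superkingdom = "A",
                   lifestyle = "free_living", proteome_size = 10L,
                   is_type_strain = TRUE)
  f <- filter_organisms(md, ann, "GO:leaf")
  expect_equal(unname(f$coverage["x"]), 0.4)
  expect_identical(f$log$rule, "coverage")
})

test_that("filters on the synthetic corpus retain exactly the clean genomes", {
  corp <- small_corpus(seed = 21)
  f <- filter_organisms(corp$sim$metadata, corp$sim$annotations,
                        corp$terminal)
  md <- corp$sim$metadata
  clean <- md$organism_id[md$lifestyle == "free_living" &
                            !md$organism_id %in% corp$sim$truth$low_coverage]
  expect_setequal(f$retained, clean)
})
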