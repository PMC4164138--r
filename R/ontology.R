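#' Gene Ontology graph objects
#'
#' A `go_graph` holds GO terms (id, name, namespace, obsolete flag) and the
#' directed `is_a` edges between them (child to parent).  Terms may carry
#' several parents, so the structure is a rooted directed acyclic graph, not
#' a tree.  Only `is_a` edges are represented: leafness of a term (and hence
#' membership in the terminal molecular-function set) is defined on the
#' `is_a` backbone alone.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`,
#'   `obsolete`.
#' @param edges data.frame with columns `child`, `parent` (GO accessions).
#' @return An object of class `go_graph`.
#' @export
go_graph <- function(terms, edges) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  need <- c("id", "name", "namespace", "obsolete")
  if (!all(need %in% names(terms))) {
    stop_("go_graph terms need columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(terms$id)) stop_("duplicated GO term ids")
  if (nrow(edges)) {
    if (!all(c("child", "parent") %in% names(edges))) {
      stop_("go_graph edges need columns child, parent")
    }
    unknown <- setdiff(c(edges$child, edges$parent), terms$id)
    if (length(unknown)) {
      stop_("edges reference unknown terms: %s",
            paste(head(unknown, 3), collapse = ", "))
    }
    assert_acyclic(edges)
  }
  structure(list(terms = terms, edges = edges), class = "go_graph")
}

# Kahn's algorithm on the child -> parent edges; stops on a directed cycle
assert_acyclic <- function(edges) {
  ids <- unique(c(edges$child, edges$parent))
  n <- length(ids)
  ci <- match(edges$child, ids)
  pi <- match(edges$parent, ids)
  indeg <- tabulate(pi, n)
  targets <- split(pi, ci)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[length(queue)]
    queue <- queue[-length(queue)]
    seen <- seen + 1L
    for (t in targets[[as.character(v)]]) {
      indeg[t] <- indeg[t] - 1L
      if (indeg[t] == 0L) queue <- c(queue, t)
    }
  }
  if (seen < n) stop_("GO graph contains a directed cycle")
  invisible(TRUE)
}

#' @export
print.go_graph <- function(x, ...) {
  ns <- table(x$terms$namespace[!x$terms$obsolete])
  cat("go_graph:", nrow(x$terms), "terms,", nrow(x$edges), "is_a edges\n")
  cat("  namespaces:",
      paste(sprintf("%s (%d)", names(ns), as.integer(ns)), collapse = ", "),
      "\n")
  cat("  obsolete terms:", sum(x$terms$obsolete), "\n")
  invisible(x)
}

#' Generate a synthetic GO-like ontology
#'
#' Builds a deterministic molecular-function DAG: one root, `ontology_depth
#' - 1` interior layers, and all remaining terms as leaves attached to the
#' deepest interior layer.  A fraction of leaves receive a second parent so
#' the multi-parent character of real GO is represented.  Two
#' biological_process terms and one obsolete molecular_function term are
#' appended as decoys for the namespace and obsolescence filters; they are
#' not counted in `n_terms_total`.
#'
#' With `w = max(2, ceiling(n_terms_total / 50))` interior terms per layer,
#' the leaf count is `n_terms_total - 1 - (ontology_depth - 1) * w`
#' (or `n_terms_total - 1` when `ontology_depth` is 1).
#'
#' @param config A [simulation_config()].
#' @return A [go_graph()] whose molecular_function leaves are the candidate
#'   GO-TMF terms.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_terms_total
  depth <- config$ontology_depth
  if (depth < 1) stop_("ontology_depth must be at least 1")
  if (n < 3) stop_("n_terms_total must be at least 3")
  w <- if (depth > 1L) max(2L, as.integer(ceiling(n / 50))) else 0L
  n_interior <- w * (depth - 1L)
  n_leaf <- n - 1L - n_interior
  if (n_leaf < 1) stop_("n_terms_total too small for the requested depth")

  id_of <- function(i) sprintf("GO:%07d", i)
  root <- id_of(1L)
  interior <- if (n_interior) id_of(1L + seq_len(n_interior)) else character(0)
  leaves <- id_of(1L + n_interior + seq_len(n_leaf))
  layer <- function(d) {
    if (d == 0L) root else interior[(d - 1L) * w + seq_len(w)]
  }

  with_seed(config$seed, {
    edges <- list()
    if (depth > 1L) {
      for (d in seq_len(depth - 1L)) {
        above <- layer(d - 1L)
        here <- layer(d)
        first <- above[1L + (seq_along(here) - 1L) %% length(above)]
        edges[[length(edges) + 1L]] <- data.frame(child = here, parent = first)
      }
    }
    pool <- layer(depth - 1L)
    first <- pool[1L + (seq_along(leaves) - 1L) %% length(pool)]
    edges[[length(edges) + 1L]] <- data.frame(child = leaves, parent = first)
    # second parents for ~15% of leaves, drawn from a different parent
    if (length(pool) > 1L) {
      extra <- leaves[runif(length(leaves)) < 0.15]
      if (length(extra)) {
        alt <- vapply(match(extra, leaves), function(i) {
          others <- setdiff(pool, first[i])
          others[sample.int(length(others), 1L)]
        }, "")
        edges[[length(edges) + 1L]] <- data.frame(child = extra, parent = alt)
      }
    }
    mf_ids <- c(root, interior, leaves)
    mf_names <- c("molecular_function",
                  sprintf("synthetic interior activity %d", seq_len(n_interior)),
                  sprintf("synthetic terminal activity %d", seq_len(n_leaf)))
    bp_root <- id_of(n + 1L)
    bp_leaf <- id_of(n + 2L)
    obs <- id_of(n + 3L)
    terms <- data.frame(
      id = c(mf_ids, bp_root, bp_leaf, obs),
      name = c(mf_names, "biological_process",
               "synthetic biological process", "obsolete synthetic activity"),
      namespace = c(rep("molecular_function", length(mf_ids)),
                    "biological_process", "biological_process",
                    "molecular_function"),
      obsolete = c(rep(FALSE, length(mf_ids)), FALSE, FALSE, TRUE))
    edges[[length(edges) + 1L]] <- data.frame(
      child = c(bp_leaf, obs), parent = c(bp_root, root))
    go_graph(terms, do.call(rbind, edges))
  })
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas, keeping id, name, namespace, `is_a` edges and the
#' `is_obsolete` flag.  Obsolete terms are retained but flagged.  Only
#' `is_a` relationships are loaded; `part_of` and other relationship types
#' are ignored by design, since terminality is defined on the `is_a`
#' backbone.
#'
#' @param path Path to an OBO 1.2 file, or a character vector of its lines.
#' @return A [go_graph()].
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  in_term <- FALSE
  cur <- NULL
  cur_line <- 0L
  terms <- list()
  edges <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop_("malformed OBO stanza starting at line %d: missing id", cur_line)
    }
    terms[[length(terms) + 1L]] <<- data.frame(
      id = cur$id, name = cur$name %||% cur$id,
      namespace = cur$namespace %||% "molecular_function",
      obsolete = isTRUE(cur$obsolete))
    for (p in cur$parents) {
      edges[[length(edges) + 1L]] <<- data.frame(child = cur$id, parent = p)
    }
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "[Term]") {
      flush()
      cur <- list(parents = character(0))
      cur_line <- i
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {         # some other stanza type
      flush()
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || line == "") next
    if (!grepl("^[A-Za-z_]+:", line)) {
      stop_("malformed OBO tag at line %d: '%s'", i, line)
    }
    tag <- sub(":.*$", "", line)
    val <- sub("^[A-Za-z_]+:\\s*", "", line)
    val <- sub("\\s*!.*$", "", val)    # trailing comments
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "namespace") cur$namespace <- val
    else if (tag == "is_a") cur$parents <- c(cur$parents, val)
    else if (tag == "is_obsolete") cur$obsolete <- identical(val, "true")
  }
  flush()
  if (!length(terms)) stop_("no [Term] stanzas found")
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(0), parent = character(0))
  # drop is_a edges pointing outside the parsed term set (external xrefs)
  edges <- edges[edges$parent %in% terms$id, , drop = FALSE]
  go_graph(terms, edges)
}

#' Write a go_graph as OBO 1.2
#'
#' @param graph A [go_graph()].
#' @param path Output file path.
#' @param force Overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_obo <- function(graph, path, force = FALSE) {
  stopifnot(inherits(graph, "go_graph"))
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  out <- c("format-version: 1.2", "ontology: synthetic-go", "")
  par <- split(graph$edges$parent, graph$edges$child)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    stanza <- c("[Term]",
                paste0("id: ", t$id),
                paste0("name: ", t$name),
                paste0("namespace: ", t$namespace))
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    for (p in par[[t$id]]) stanza <- c(stanza, paste0("is_a: ", p))
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Terminal molecular-function terms of a GO graph
#'
#' Returns the GO-TMF set: every non-obsolete molecular_function term that
#' no other non-obsolete molecular_function term names as an `is_a` parent,
#' i.e. the leaves of the molecular_function `is_a` backbone.
#'
#' @param graph A [go_graph()].
#' @return Sorted character vector of GO accessions.
#' @export
terminal_mf_terms <- function(graph) {
  stopifnot(inherits(graph, "go_graph"))
  live <- graph$terms[!graph$terms$obsolete, ]
  mf <- live$id[live$namespace == "molecular_function"]
  if (!length(mf)) stop_("no molecular_function namespace present")
  e <- graph$edges
  inner <- unique(e$parent[e$child %in% mf & e$parent %in% mf])
  sort(setdiff(mf, inner))
}
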