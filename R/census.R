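#' Build the genome-by-term abundance census
#'
#' Counts, for every retained genome, how many annotation records point at
#' each terminal molecular-function term.  A protein annotated twice to a
#' term counts twice (paralogous copies raise abundance); a protein
#' annotated to two terms contributes to both.  Annotations to terms
#' outside the terminal set are dropped (never propagated); annotations to
#' obsolete terms, when an obsolete set is supplied, are dropped with a
#' warning.  Columns that end up all-zero are removed, so every term in the
#' census is detected at least once.
#'
#' @param annotations Named list of [annotation_set()] objects.
#' @param terminal_terms GO-TMF accessions.
#' @param retained Organism ids to include (row order of the census).
#' @param superkingdom Named character vector organism -> "A"/"B"/"E", or a
#'   metadata data.frame to take it from.
#' @param obsolete_terms Optional accessions of obsolete terms, for the
#'   dropped-annotation warning.
#' @return A `go_census`: list with `abundance` (integer matrix, genomes x
#'   terms, lexicographic term order) and `superkingdom` (named vector).
#' @export
build_census <- function(annotations, terminal_terms, retained,
                         superkingdom = NULL, obsolete_terms = NULL) {
  if (!length(retained)) stop_("no retained organisms")
  missing <- setdiff(retained, names(annotations))
  if (length(missing)) {
    stop_("retained organisms without annotations: %s",
          paste(head(missing, 3), collapse = ", "))
  }
  if (is.data.frame(superkingdom)) {
    superkingdom <- setNames(superkingdom$superkingdom,
                             superkingdom$organism_id)
  }
  recs <- lapply(retained, function(o) {
    r <- annotations[[o]]$records
    if (length(obsolete_terms)) {
      n_obs <- sum(r$go_id %in% obsolete_terms)
      if (n_obs > 0L) {
        warning(sprintf("%s: dropped %d annotation(s) to obsolete terms",
                        o, n_obs))
      }
    }
    r$go_id[r$go_id %in% terminal_terms]
  })
  terms <- sort(unique(unlist(recs, use.names = FALSE)))
  if (!length(terms)) stop_("no terminal-term annotations in retained genomes")
  ab <- t(vapply(recs, function(g) {
    tabulate(match(g, terms), length(terms))
  }, integer(length(terms))))
  dimnames(ab) <- list(retained, terms)
  ab <- ab[, colSums(ab) > 0L, drop = FALSE]
  sk <- if (!is.null(superkingdom)) superkingdom[retained] else NULL
  structure(list(abundance = ab, superkingdom = sk), class = "go_census")
}

#' @export
print.go_census <- function(x, ...) {
  cat("go_census:", nrow(x$abundance), "genomes x", ncol(x$abundance),
      "GO-TMF terms\n")
  cat("  total annotations:", sum(x$abundance),
      "| max abundance:", max(x$abundance), "\n")
  if (!is.null(x$superkingdom)) {
    tb <- table(x$superkingdom)
    cat("  superkingdoms:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.go_census <- function(object, ...) {
  ab <- object$abundance
  out <- list(n_genomes = nrow(ab), n_terms = ncol(ab),
              total = sum(ab), g_max = max(ab),
              economy = rowSums(ab > 0L))
  class(out) <- "summary.go_census"
  out
}

#' @export
print.summary.go_census <- function(x, ...) {
  cat("census of", x$n_terms, "GO-TMF terms in", x$n_genomes, "genomes\n")
  cat("  g_max =", x$g_max, "; per-genome distinct terms:\n")
  print(summary(x$economy))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of observing at
#' least `k` annotations of a term in a draw of `n` records from a corpus
#' of `N` records of which `K` carry the term.  This is the enrichment
#' p-value used for the HGT screen.
#'
#' @param k Observed overlap count.
#' @param K Records carrying the focal term.
#' @param n Records drawn (HTP-borne records).
#' @param N All records.
#' @return Probability in [0, 1]; vectorised over its arguments.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | k > n | n > N | K > N | K < 0
  if (any(bad)) stop_("hypergeometric bounds violated (need 0 <= k <= n <= N, 0 <= K <= N)")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Flag GO-TMF terms enriched among horizontally transferred proteins
#'
#' Cross-lists the per-genome horizontally-transferred-protein (HTP) lists
#' with the annotation records of the census genomes, and tests every term
#' for enrichment of its annotations among HTP-borne records with the
#' upper-tail hypergeometric test.  The sampling frame is annotation
#' records: `N` all records in the census, `K` records of the focal term,
#' `n` HTP-borne records, `k` HTP-borne records of the term.
#' Benjamini-Hochberg correction is applied across all tested terms;
#' `flagged` is `p_adj < alpha`.
#'
#' @param census A `go_census`.
#' @param annotations The annotation sets the census was built from.
#' @param hgt_lists Named list (organism -> HTP protein ids).
#' @param alpha Significance level after correction (default 0.05).
#' @param p_adjust_method Correction method (default "BH").
#' @return data.frame with columns term, k, n_htp, K, N, p_raw, p_adj,
#'   flagged.
#' @export
flag_hgt_terms <- function(census, annotations, hgt_lists, alpha = 0.05,
                           p_adjust_method = "BH") {
  stopifnot(inherits(census, "go_census"), is_prob(alpha))
  ab <- census$abundance
  genomes <- rownames(ab)
  terms <- colnames(ab)
  unknown <- setdiff(names(hgt_lists), names(annotations))
  if (length(unknown)) {
    stop_("HTP lists reference organisms without annotations: %s",
          paste(head(unknown, 3), collapse = ", "))
  }
  N <- sum(ab)
  K <- colSums(ab)
  k <- setNames(integer(length(terms)), terms)
  n_htp <- 0L
  for (org in intersect(names(hgt_lists), genomes)) {
    r <- annotations[[org]]$records
    htp <- r$go_id[r$protein_id %in% hgt_lists[[org]] & r$go_id %in% terms]
    if (length(htp)) {
      tb <- table(htp)
      k[names(tb)] <- k[names(tb)] + as.integer(tb)
      n_htp <- n_htp + length(htp)
    }
  }
  if (n_htp == 0L) {
    p_raw <- rep(1, length(terms))
  } else {
    p_raw <- hypergeom_upper_tail(k, K, n_htp, N)
  }
  p_adj <- p.adjust(p_raw, method = p_adjust_method)
  data.frame(term = terms, k = as.integer(k), n_htp = n_htp,
             K = as.integer(K), N = N, p_raw = p_raw, p_adj = p_adj,
             flagged = p_adj < alpha & k > 0L, row.names = NULL)
}

#' Remove flagged terms from the census
#'
#' Drops the given term columns from every genome (dataset-level exclusion);
#' genome rows are untouched.  Flagging none returns an identical census;
#' flagging everything returns an empty matrix that downstream stages
#' reject.
#'
#' @param census A `go_census`.
#' @param flagged_terms Character vector of term accessions to remove.
#' @return The reduced `go_census`.
#' @export
exclude_terms <- function(census, flagged_terms) {
  stopifnot(inherits(census, "go_census"))
  keep <- !(colnames(census$abundance) %in% flagged_terms)
  census$abundance <- census$abundance[, keep, drop = FALSE]
  census
}

#' Census import/export
#'
#' TSV layout: genomes as rows (first column `organism_id`, second
#' `superkingdom`), terms as the remaining columns.
#'
#' @param census A `go_census`.
#' @param path File path.
#' @param force Overwrite an existing file?
#' @return `read_census`: a `go_census`.
#' @export
write_census <- function(census, path, force = FALSE) {
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  df <- data.frame(organism_id = rownames(census$abundance),
                   superkingdom = if (is.null(census$superkingdom)) NA
                   else unname(census$superkingdom),
                   census$abundance, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ab <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(ab) <- df$organism_id
  storage.mode(ab) <- "integer"
  sk <- df$superkingdom
  structure(list(abundance = ab,
                 superkingdom = if (all(is.na(sk))) NULL
                 else setNames(sk, df$organism_id)),
            class = "go_census")
}

#' @rdname write_census
#' @export
write_census_mtx <- function(census, path, force = FALSE) {
  if (file.exists(path) && !force) stop_("refusing to overwrite %s", path)
  m <- Matrix::Matrix(census$abundance, sparse = TRUE)
  Matrix::writeMM(m, path)
  invisible(path)
}
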