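#' Node distance (relative evolutionary age) of tree-of-function taxa
#'
#' For every tip of a rooted tree of functions, counts the internal nodes
#' strictly between the tip and the root; the count is then normalised to
#' [0, 1] so the most basal tip sits at nd = 0 (most ancient) and the most
#' nested tip at nd = 1 (most recent).  The default normalisation anchors
#' the basal-most tip at 0 and scales by the maximum tip-to-root node
#' count, the only variant under which the most ancient taxon sits at
#' exactly 0 and the most derived reaches exactly 1 on every rooted tree
#' (when a tip hangs directly off the root, as in a Lundberg-rooted tree
#' with a basal taxon, this equals plain division by the maximum count);
#' dividing the raw count by the total number of taxa is available as
#' `"n_taxa"` for comparison.
#'
#' @param tof A rooted ape `phylo` (taxa are GO-TMF terms).
#' @param normalize "max_depth" (default) or "n_taxa".
#' @return Named numeric vector of nd values, one per tip.
#' @export
node_distance <- function(tof, normalize = c("max_depth", "n_taxa")) {
  stopifnot(inherits(tof, "phylo"))
  normalize <- match.arg(normalize)
  if (!ape::is.rooted(tof)) stop_("node_distance needs a rooted tree")
  ntip <- length(tof$tip.label)
  if (ntip < 2L) stop_("need at least 2 tips")
  m <- ntip + tof$Nnode
  depth <- numeric(m)
  edge <- ape::reorder.phylo(tof, "cladewise")$edge
  for (i in seq_len(nrow(edge))) {
    depth[edge[i, 2L]] <- depth[edge[i, 1L]] + 1
  }
  raw <- depth[seq_len(ntip)] - 1          # internal nodes below the root
  rng <- max(raw) - min(raw)
  nd <- switch(normalize,
               max_depth = if (rng > 0) (raw - min(raw)) / rng else raw * 0,
               n_taxa = raw / ntip)
  names(nd) <- tof$tip.label
  nd
}

#' Distribution index f of GO-TMF terms
#'
#' Fraction of genomes (within the chosen subset) encoding each term:
#' f = 1 marks ubiquitous presence, f = 0 complete absence.
#'
#' @param census A `go_census`.
#' @param genomes Genome ids to consider (default: all in the census).
#' @return Named numeric vector of f values, one per census term.
#' @export
distribution_index <- function(census, genomes = rownames(census$abundance)) {
  stopifnot(inherits(census, "go_census"))
  if (!length(genomes)) stop_("empty genome subset")
  missing <- setdiff(genomes, rownames(census$abundance))
  if (length(missing)) {
    stop_("genomes not in census: %s", paste(head(missing, 3), collapse = ", "))
  }
  colMeans(census$abundance[genomes, , drop = FALSE] > 0L)
}

#' Venn taxonomic groups of GO-TMF terms
#'
#' Assigns every term the concatenation (in A, B, E order) of the
#' superkingdoms holding at least one genome that encodes it, yielding the
#' seven groups A, B, E, AB, AE, BE, ABE.
#'
#' @param census A `go_census` carrying superkingdom labels.
#' @return List with `groups` (named character vector term -> group),
#'   `sizes` (counts over the seven groups) and `kingdom_totals` (terms
#'   present in each superkingdom).
#' @export
venn_groups <- function(census) {
  stopifnot(inherits(census, "go_census"))
  sk <- census$superkingdom
  if (is.null(sk) || !all(sk %in% c("A", "B", "E"))) {
    stop_("census genomes must all be labeled A, B or E")
  }
  ab <- census$abundance
  pres <- vapply(c("A", "B", "E"), function(K) {
    rows <- which(sk == K)
    if (!length(rows)) rep(FALSE, ncol(ab)) else
      colSums(ab[rows, , drop = FALSE] > 0L) > 0L
  }, logical(ncol(ab)))
  pres <- matrix(pres, ncol = 3L,
                 dimnames = list(colnames(ab), c("A", "B", "E")))
  if (any(rowSums(pres) == 0L)) {
    stop_("term with no presence in any genome (should have been dropped)")
  }
  groups <- apply(pres, 1L, function(p) paste(c("A", "B", "E")[p], collapse = ""))
  names(groups) <- colnames(ab)
  lev <- c("A", "B", "E", "AB", "AE", "BE", "ABE")
  list(groups = groups,
       sizes = table(factor(groups, levels = lev)),
       kingdom_totals = colSums(pres))
}

#' Assemble per-term evolutionary records
#'
#' Joins node distance (from a rooted tree of functions), global and
#' per-superkingdom distribution indices, and Venn group into one table.
#'
#' @param census A `go_census` with superkingdom labels.
#' @param tof A rooted tree of functions whose tips are census terms.
#' @param normalize Node-distance normalisation (see [node_distance()]).
#' @return data.frame with columns term, nd, f_global, f_A, f_B, f_E,
#'   venn_group.
#' @export
term_evo_records <- function(census, tof, normalize = "max_depth") {
  nd <- node_distance(tof, normalize = normalize)
  terms <- intersect(colnames(census$abundance), names(nd))
  if (!length(terms)) stop_("tree tips and census terms do not overlap")
  f_global <- distribution_index(census)
  sk <- census$superkingdom
  f_k <- vapply(c("A", "B", "E"), function(K) {
    rows <- rownames(census$abundance)[sk == K]
    if (!length(rows)) rep(NA_real_, ncol(census$abundance)) else
      distribution_index(census, rows)
  }, numeric(ncol(census$abundance)))
  f_k <- matrix(f_k, ncol = 3L,
                dimnames = list(colnames(census$abundance), c("A", "B", "E")))
  vg <- venn_groups(census)$groups
  data.frame(term = terms,
             nd = unname(nd[terms]),
             f_global = unname(f_global[terms]),
             f_A = unname(f_k[terms, "A"]),
             f_B = unname(f_k[terms, "B"]),
             f_E = unname(f_k[terms, "E"]),
             venn_group = unname(vg[terms]),
             row.names = NULL)
}

#' Appearance order and boxplot summaries of Venn groups
#'
#' Per Venn group: the minimum nd (first appearance), quartiles of nd, and
#' Tukey 1.5 x IQR outliers.  The appearance order of groups is reported
#' both from raw minima and from minima after removing low outliers,
#' mirroring how an early lateral transfer can masquerade as an early group
#' appearance.
#'
#' @param records data.frame from [term_evo_records()] (needs columns term,
#'   nd, venn_group).
#' @return List with `summaries` (one row per non-empty group: n, min, Q1,
#'   median, Q3, max, min_excl_outliers, n_outliers), `outliers`
#'   (data.frame term, venn_group, nd, side), `order_raw` and
#'   `order_excl_outliers` (group labels sorted by first appearance).
#' @export
group_appearance <- function(records) {
  stopifnot(all(c("term", "nd", "venn_group") %in% names(records)))
  lev <- c("A", "B", "E", "AB", "AE", "BE", "ABE")
  present <- lev[lev %in% records$venn_group]
  dropped <- setdiff(unique(records$venn_group), lev)
  if (length(dropped)) stop_("unknown venn groups: %s", paste(dropped, collapse = ","))
  rows <- lapply(present, function(g) {
    nd <- records$nd[records$venn_group == g]
    q <- quantile(nd, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- q[1L] - 1.5 * iqr
    hi <- q[3L] + 1.5 * iqr
    out <- nd < lo | nd > hi
    kept <- nd[!out]
    data.frame(group = g, n = length(nd), min_nd = min(nd),
               q1 = q[1L], median = q[2L], q3 = q[3L], max_nd = max(nd),
               min_nd_excl_outliers = if (length(kept)) min(kept) else NA_real_,
               n_outliers = sum(out))
  })
  summaries <- do.call(rbind, rows)
  outliers <- do.call(rbind, lapply(present, function(g) {
    sel <- records$venn_group == g
    nd <- records$nd[sel]
    q <- quantile(nd, c(0.25, 0.75), names = FALSE)
    iqr <- q[2L] - q[1L]
    side <- ifelse(nd < q[1L] - 1.5 * iqr, "low",
                   ifelse(nd > q[2L] + 1.5 * iqr, "high", NA))
    data.frame(term = records$term[sel], venn_group = g, nd = nd,
               side = side)[!is.na(side), ]
  }))
  list(summaries = summaries,
       outliers = outliers,
       order_raw = summaries$group[order(summaries$min_nd)],
       order_excl_outliers =
         summaries$group[order(summaries$min_nd_excl_outliers)])
}

#' Persistence metrics of genomes
#'
#' Economy is the number of distinct GO-TMF terms a genome encodes;
#' flexibility is the total (redundant) annotation count; robustness is
#' flexibility divided by economy.  Genomes with zero economy get NA
#' robustness and are flagged.
#'
#' @param census A `go_census`.
#' @return data.frame with organism_id, superkingdom, economy, flexibility,
#'   robustness, flagged.
#' @export
persistence_metrics <- function(census) {
  stopifnot(inherits(census, "go_census"))
  ab <- census$abundance
  economy <- rowSums(ab > 0L)
  flexibility <- rowSums(ab)
  robustness <- ifelse(economy > 0L, flexibility / economy, NA_real_)
  data.frame(organism_id = rownames(ab),
             superkingdom = if (is.null(census$superkingdom)) NA_character_
             else unname(census$superkingdom),
             economy = as.integer(economy),
             flexibility = as.integer(flexibility),
             robustness = robustness,
             flagged = economy == 0L,
             row.names = NULL)
}

#' Export the scatter and boxplot tables
#'
#' Writes the figure-ready TSVs: nd-versus-f per term (global and per
#' superkingdom), the per-group boxplot summaries, the Venn group sizes,
#' and the 3D persistence table.  Rows are sorted deterministically so
#' reruns are byte-identical.
#'
#' @param records data.frame from [term_evo_records()].
#' @param appearance List from [group_appearance()].
#' @param persistence data.frame from [persistence_metrics()].
#' @param directory Output directory (created if missing).
#' @param force Overwrite existing files?
#' @return Named vector of file paths, invisibly.
#' @export
export_scatter_tables <- function(records, appearance, persistence,
                                  directory, force = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(nd_f = file.path(directory, "nd_f.tsv"),
             groups = file.path(directory, "groups.tsv"),
             venn = file.path(directory, "venn.tsv"),
             persistence = file.path(directory, "persistence.tsv"))
  for (p in paths) {
    if (file.exists(p) && !force) stop_("refusing to overwrite %s", p)
  }
  wt <- function(df, p) {
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(records[order(records$term), ], paths[["nd_f"]])
  wt(appearance$summaries, paths[["groups"]])
  venn <- as.data.frame(table(factor(records$venn_group,
                                     levels = c("A", "B", "E", "AB", "AE",
                                                "BE", "ABE"))))
  names(venn) <- c("group", "n_terms")
  wt(venn, paths[["venn"]])
  wt(persistence[order(persistence$organism_id), ], paths[["persistence"]])
  invisible(paths)
}
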