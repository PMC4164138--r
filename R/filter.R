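#' Apply the organism filters
#'
#' Reproduces the dataset-assembly filters: organisms are excluded when (in
#' this order of precedence) they are not the type strain of their species,
#' their lifestyle is parasitic or facultatively parasitic, or their GO-TMF
#' annotation coverage falls below the threshold.  Coverage is the number of
#' distinct proteins annotated to terminal molecular-function terms divided
#' by the proteome size; the threshold is inclusive (coverage of exactly
#' 0.5 is retained).
#'
#' @param metadata Metadata data.frame (see [read_metadata()]).
#' @param annotations Named list of [annotation_set()] objects.
#' @param terminal_terms GO-TMF accessions from [terminal_mf_terms()].
#' @param coverage_threshold Minimum fraction of the proteome annotated to
#'   terminal MF terms (default 0.5).
#' @return List with `retained` (organism ids in input order), `coverage`
#'   (named numeric, all organisms) and `log` (data.frame organism_id,
#'   rule, detail; rule is "retained" or the first exclusion rule fired:
#'   "strain", "lifestyle", "coverage").
#' @export
filter_organisms <- function(metadata, annotations, terminal_terms,
                             coverage_threshold = 0.5) {
  stopifnot(is_prob(coverage_threshold))
  orgs <- names(annotations)
  missing <- setdiff(orgs, metadata$organism_id)
  if (length(missing)) {
    stop_("organisms missing from metadata: %s",
          paste(head(missing, 3), collapse = ", "))
  }
  md <- metadata[match(orgs, metadata$organism_id), ]
  coverage <- vapply(orgs, function(o) {
    a <- annotations[[o]]
    ps <- md$proteome_size[md$organism_id == o]
    if (is.na(ps) || ps <= 0) return(NA_real_)
    covered <- unique(a$records$protein_id[a$records$go_id %in% terminal_terms])
    length(covered) / ps
  }, 0)
  rule <- rep("retained", length(orgs))
  detail <- rep("", length(orgs))
  for (i in seq_along(orgs)) {
    if (!isTRUE(md$is_type_strain[i])) {
      rule[i] <- "strain"
      detail[i] <- "not the type strain"
    } else if (md$lifestyle[i] %in% c("parasite", "facultative_parasite")) {
      rule[i] <- "lifestyle"
      detail[i] <- md$lifestyle[i]
    } else if (is.na(coverage[i]) || coverage[i] < coverage_threshold) {
      rule[i] <- "coverage"
      detail[i] <- sprintf("coverage %.3f < %.2f", coverage[i],
                           coverage_threshold)
    }
  }
  list(retained = orgs[rule == "retained"],
       coverage = coverage,
       log = data.frame(organism_id = orgs, rule = rule, detail = detail))
}
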