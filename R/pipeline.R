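#' Pipeline configuration
#'
#' One structure drives the whole analysis: either real input paths (OBO
#' ontology, GAF directory, metadata TSV, optional HTP-list directory) or a
#' [simulation_config()] for a synthetic corpus — exactly one of the two.
#'
#' @param synthetic A [simulation_config()], or NULL for real inputs.
#' @param obo,gaf_dir,metadata,hgt_dir Paths for real-input mode.
#' @param coverage_threshold Organism coverage threshold (default 0.5).
#' @param alpha HGT-enrichment significance level (default 0.05).
#' @param cost_kind "ordered" or "unordered" characters.
#' @param n_starts Random-addition starts of the tree searches.
#' @param n_bootstrap Bootstrap replicates on the tree of life.
#' @param nd_normalize Node-distance normalisation variant.
#' @param output_dir Directory for all artifacts.
#' @param seed Master seed: controls synthesis, searches and bootstrap.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, obo = NULL, gaf_dir = NULL,
                            metadata = NULL, hgt_dir = NULL,
                            coverage_threshold = 0.5, alpha = 0.05,
                            cost_kind = "ordered", n_starts = 5,
                            n_bootstrap = 100,
                            nd_normalize = "max_depth",
                            output_dir = "gocensus_out", seed = 1) {
  cfg <- structure(list(synthetic = synthetic, obo = obo, gaf_dir = gaf_dir,
                        metadata = metadata, hgt_dir = hgt_dir,
                        coverage_threshold = coverage_threshold,
                        alpha = alpha, cost_kind = cost_kind,
                        n_starts = n_starts, n_bootstrap = n_bootstrap,
                        nd_normalize = nd_normalize,
                        output_dir = output_dir, seed = seed),
                   class = "pipeline_config")
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problems; empty when the pipeline can run.
#' @export
validate_pipeline_config <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  synthetic <- !is.null(config$synthetic)
  real_paths <- c(config$obo, config$gaf_dir, config$metadata)
  if (synthetic && length(real_paths)) {
    add("both synthetic config and real input paths given; choose one")
  }
  if (!synthetic && length(real_paths) < 3L) {
    add("real-input mode needs obo, gaf_dir and metadata paths")
  }
  if (synthetic && !inherits(config$synthetic, "simulation_config")) {
    add("synthetic must be a simulation_config")
  }
  if (!is_prob(config$coverage_threshold)) {
    add("coverage_threshold must be in [0, 1]")
  }
  if (!is_prob(config$alpha)) add("alpha must be in [0, 1]")
  if (!config$cost_kind %in% c("ordered", "unordered")) {
    add("cost_kind must be 'ordered' or 'unordered'")
  }
  if (!config$nd_normalize %in% c("max_depth", "n_taxa")) {
    add("nd_normalize must be 'max_depth' or 'n_taxa'")
  }
  if (!is_count(config$n_starts) || config$n_starts < 1) {
    add("n_starts must be a positive count")
  }
  if (!is_count(config$n_bootstrap)) add("n_bootstrap must be a count")
  problems
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full census-to-trees-to-metrics pipeline
#'
#' Executes the stages in their canonical order — organism filtering,
#' census construction, HGT-term flagging and exclusion, state encoding,
#' maximum-parsimony reconstruction of the tree of functions (ancestral
#' state V) and tree of life (ancestral state 0) with Lundberg rooting,
#' bootstrap support on the tree of life, and the evolutionary metrics —
#' writing every intermediate artifact under `output_dir` so any stage can
#' be re-examined or re-loaded on its own.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `manifest` (deterministic run
#'   record including a config/outputs hash), `census`, `tof`, `tol`,
#'   `records`, `appearance`, `persistence`, `files`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_pipeline_config(config)
  if (length(problems)) {
    stop_("invalid pipeline config: %s", paste(problems, collapse = "; "))
  }
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  warnings_log <- character(0)

  inputs <- run_stage("inputs", {
    if (!is.null(config$synthetic)) {
      graph <- generate_ontology(config$synthetic)
      sim <- simulate_genomes(graph, config$synthetic)
      list(graph = graph, annotations = sim$annotations,
           metadata = sim$metadata, hgt_lists = sim$hgt_lists, sim = sim)
    } else {
      ann_files <- list.files(config$gaf_dir, pattern = "\\.gaf$",
                              full.names = TRUE)
      if (!length(ann_files)) stop_("no .gaf files in %s", config$gaf_dir)
      md <- read_metadata(config$metadata)
      annotations <- lapply(ann_files, function(f) {
        a <- parse_gaf(f)
        ps <- md$proteome_size[md$organism_id == a$organism_id]
        if (length(ps)) a$proteome_size <- as.integer(ps[1L])
        a
      })
      names(annotations) <- vapply(annotations, `[[`, "", "organism_id")
      hgt <- if (!is.null(config$hgt_dir)) read_hgt_lists(config$hgt_dir)
      else list()
      list(graph = parse_obo(config$obo), annotations = annotations,
           metadata = md, hgt_lists = hgt, sim = NULL)
    }
  })

  terminal <- run_stage("terminal_terms", terminal_mf_terms(inputs$graph))

  filt <- run_stage("filter_organisms", {
    filter_organisms(inputs$metadata, inputs$annotations, terminal,
                     config$coverage_threshold)
  })
  files["exclusions"] <- file.path(out, "exclusions.tsv")
  write.table(filt$log, files["exclusions"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  census <- run_stage("census", {
    obsolete <- inputs$graph$terms$id[inputs$graph$terms$obsolete]
    build_census(inputs$annotations, terminal, filt$retained,
                 superkingdom = inputs$metadata, obsolete_terms = obsolete)
  })
  n_detected <- ncol(census$abundance)

  hgt_res <- run_stage("hgt_flags", {
    flag_hgt_terms(census, inputs$annotations, inputs$hgt_lists,
                   alpha = config$alpha)
  })
  files["hgt_flags"] <- file.path(out, "hgt_flags.tsv")
  write.table(hgt_res, files["hgt_flags"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  census <- run_stage("exclude_terms", {
    exclude_terms(census, hgt_res$term[hgt_res$flagged])
  })
  files["census"] <- file.path(out, "census.tsv")
  write_census(census, files["census"], force = TRUE)

  encoded <- run_stage("encode", encode_census(census))
  tol_view <- character_view(encoded, "ToL")
  tof_view <- character_view(encoded, "ToF")
  files["nexus_tol"] <- file.path(out, "tol.nex")
  files["nexus_tof"] <- file.path(out, "tof.nex")
  write_nexus(tol_view, "min", files["nexus_tol"], force = TRUE)
  write_nexus(tof_view, "max", files["nexus_tof"], force = TRUE)

  cost <- cost_model(config$cost_kind)
  tol <- run_stage("tol_search", {
    fit <- mp_search(tol_view, cost, n_starts = config$n_starts,
                     seed = config$seed + 101L)
    rooted <- lundberg_root(fit$trees[[1L]], tol_view, cost,
                            ancestral_state = 0)
    list(fit = fit, rooted = rooted)
  })
  tof <- run_stage("tof_search", {
    fit <- mp_search(tof_view, cost, n_starts = config$n_starts,
                     seed = config$seed + 202L)
    rooted <- lundberg_root(fit$trees[[1L]], tof_view, cost,
                            ancestral_state = 31)
    list(fit = fit, rooted = rooted)
  })
  if (tol$fit$tied) warnings_log <- c(warnings_log, "ToL best-tree tie")
  if (tof$fit$tied) warnings_log <- c(warnings_log, "ToF best-tree tie")
  if (attr(tol$rooted, "root_tie")) {
    warnings_log <- c(warnings_log, "ToL Lundberg root tie")
  }
  if (attr(tof$rooted, "root_tie")) {
    warnings_log <- c(warnings_log, "ToF Lundberg root tie")
  }

  boot <- run_stage("bootstrap", {
    if (config$n_bootstrap > 0L) {
      bootstrap_support(tol$rooted, tol_view, cost,
                        n_reps = config$n_bootstrap,
                        seed = config$seed + 303L)
    } else NULL
  })
  tol_out <- if (is.null(boot)) tol$rooted else boot$tree
  files["tol_tree"] <- file.path(out, "tol.nwk")
  files["tof_tree"] <- file.path(out, "tof.nwk")
  write_newick(tol_out, files["tol_tree"], force = TRUE)
  write_newick(tof$rooted, files["tof_tree"], force = TRUE)

  metrics <- run_stage("metrics", {
    records <- term_evo_records(census, tof$rooted,
                                normalize = config$nd_normalize)
    appearance <- group_appearance(records)
    persistence <- persistence_metrics(census)
    tabs <- export_scatter_tables(records, appearance, persistence, out,
                                  force = TRUE)
    list(records = records, appearance = appearance,
         persistence = persistence, tabs = tabs)
  })
  files <- c(files, metrics$tabs)

  manifest <- list(
    package = as.character(utils::packageVersion("gocensus")),
    mode = if (is.null(config$synthetic)) "real" else "synthetic",
    seed = config$seed,
    n_organisms_input = nrow(inputs$metadata),
    n_retained = length(filt$retained),
    n_terms_detected = n_detected,
    n_terms_flagged = sum(hgt_res$flagged),
    n_terms_final = ncol(census$abundance),
    tol_length = as.numeric(attr(tol$rooted, "length")),
    tof_length = as.numeric(attr(tof$rooted, "length")),
    n_bootstrap = config$n_bootstrap,
    warnings = warnings_log,
    file_md5 = local({
      fl <- files[file.exists(files)]
      as.list(setNames(unname(tools::md5sum(unname(fl))), names(fl)))
    }))
  canon <- paste(deparse(manifest), collapse = "\n")
  tmp <- tempfile()
  writeLines(canon, tmp)
  manifest$manifest_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  files["manifest"] <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)

  structure(list(manifest = manifest, census = census, encoded = encoded,
                 tof = tof$rooted, tol = tol_out, tol_fit = tol$fit,
                 tof_fit = tof$fit, hgt = hgt_res,
                 records = metrics$records,
                 appearance = metrics$appearance,
                 persistence = metrics$persistence,
                 filter_log = filt$log, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("gocensus pipeline run (", m$mode, " mode, seed ", m$seed, ")\n",
      sep = "")
  cat("  genomes: ", m$n_organisms_input, " in -> ", m$n_retained,
      " retained\n", sep = "")
  cat("  terms: ", m$n_terms_detected, " detected -> ", m$n_terms_final,
      " after excluding ", m$n_terms_flagged, " HGT-flagged\n", sep = "")
  cat("  tree lengths: ToF", m$tof_length, "steps; ToL", m$tol_length,
      "steps\n")
  cat("  artifacts:", length(x$files), "files in",
      dirname(x$files[["manifest"]]), "\n")
  invisible(x)
}
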