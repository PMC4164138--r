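#' Configuration for the synthetic annotation corpus
#'
#' Bundles every knob of the synthetic-data generator.  The defaults are the
#' desk-scale study conditions used throughout the package's tests: three
#' superkingdom-like clades, a rich ancestral repertoire reduced along the
#' Archaea-like stem, eukaryal lineage-specific novelties, right-skewed
#' abundances from duplication, a small planted set of laterally transferred
#' terms, and deterministic quotas of parasitic and low-coverage genomes for
#' the organism filters to remove.
#'
#' @param n_terms_total Total molecular_function terms in the ontology
#'   (root + interior + leaves); see [generate_ontology()] for the layout.
#' @param ontology_depth Number of `is_a` levels below the root.
#' @param n_genomes_per_kingdom Integer triple: genomes in the Archaea-,
#'   Bacteria- and Eukarya-like clades (order A, B, E).
#' @param ancestral_repertoire_size Leaf terms in the ancestral repertoire
#'   shared by all genomes before loss.
#' @param loss_rate_per_clade Probability that an ancestral term is lost on
#'   the Archaea-like stem (one draw per term; the loss is clade-wide).
#' @param duplication_mean Mean extra copies per retained term; abundance is
#'   1 + Poisson(duplication_mean).
#' @param hgt_term_count Terms copied laterally from a Bacteria-like donor
#'   into an Archaea-like recipient and recorded in the HTP lists.
#' @param parasite_fraction Fraction of each clade labeled (facultative)
#'   parasite, assigned by deterministic quota to the clade's last tips.
#' @param low_coverage_fraction Fraction of each clade given a proteome size
#'   that pushes annotation coverage below 50%, likewise by quota.
#' @param seed Integer seed; identical configs give byte-identical corpora.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_terms_total = 60,
                              ontology_depth = 3,
                              n_genomes_per_kingdom = c(A = 6, B = 6, E = 6),
                              ancestral_repertoire_size = 30,
                              loss_rate_per_clade = 0.25,
                              duplication_mean = 0.8,
                              hgt_term_count = 2,
                              parasite_fraction = 0.1,
                              low_coverage_fraction = 0.1,
                              seed = 42) {
  stopifnot(is_count(n_terms_total), is_count(ontology_depth),
            is_count(ancestral_repertoire_size), is_count(hgt_term_count),
            is_prob(loss_rate_per_clade), is_prob(parasite_fraction),
            is_prob(low_coverage_fraction),
            length(n_genomes_per_kingdom) == 3L,
            all(n_genomes_per_kingdom >= 0),
            all(n_genomes_per_kingdom == floor(n_genomes_per_kingdom)),
            is.numeric(duplication_mean), duplication_mean >= 0,
            is_count(abs(seed)))
  if (ancestral_repertoire_size > n_terms_total) {
    stop_("ancestral_repertoire_size exceeds n_terms_total")
  }
  n_genomes_per_kingdom <- setNames(as.integer(n_genomes_per_kingdom),
                                    c("A", "B", "E"))
  structure(list(n_terms_total = as.integer(n_terms_total),
                 ontology_depth = as.integer(ontology_depth),
                 n_genomes_per_kingdom = n_genomes_per_kingdom,
                 ancestral_repertoire_size = as.integer(ancestral_repertoire_size),
                 loss_rate_per_clade = loss_rate_per_clade,
                 duplication_mean = duplication_mean,
                 hgt_term_count = as.integer(hgt_term_count),
                 parasite_fraction = parasite_fraction,
                 low_coverage_fraction = low_coverage_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

quota <- function(fraction, n) {
  setNames(as.integer(floor(fraction * n + 0.5)), names(n))
}

pectinate_newick <- function(tips) {
  if (length(tips) == 1L) return(tips)
  out <- tips[length(tips)]
  for (i in rev(seq_len(length(tips) - 1L))) {
    out <- paste0("(", tips[i], ",", out, ")")
  }
  out
}

#' Simulate genome annotation sets with known ground truth
#'
#' Evolves the leaf terms of a synthetic ontology over a fixed pectinate
#' species tree whose Archaea-like clade branches first:
#' \enumerate{
#'   \item the ancestral repertoire (first `ancestral_repertoire_size`
#'     leaves) is present in every genome;
#'   \item each ancestral term is lost clade-wide on the Archaea-like stem
#'     with probability `loss_rate_per_clade` (genome reduction);
#'   \item the remaining leaves are eukaryal novelties, assigned round-robin
#'     to the Eukarya-like tips (lineage-restricted gains);
#'   \item each present term gets abundance 1 + Poisson(`duplication_mean`),
#'     one annotated paralogous protein per copy;
#'   \item `hgt_term_count` terms lost from Archaea are copied from a
#'     free-living Bacteria-like donor into a free-living Archaea-like
#'     recipient, and the recipient's carrier proteins are written to its
#'     HTP list;
#'   \item parasite and low-coverage labels are assigned by deterministic
#'     per-clade quota (`floor(fraction * n + 0.5)` tips, taken from the end
#'     of each clade), so filter tests are exact rather than stochastic.
#' }
#'
#' @param graph A [go_graph()] from [generate_ontology()].
#' @param config A [simulation_config()].
#' @return A `go_census_sim`: list with `annotations` (named list of
#'   [annotation_set()]), `metadata` (data.frame), `hgt_lists` (named list
#'   of protein ids) and `truth` (species tree, true Venn groups, HGT terms,
#'   reduced clades, ancestral terms).
#' @export
simulate_genomes <- function(graph, config) {
  stopifnot(inherits(graph, "go_graph"), inherits(config, "simulation_config"))
  leaves <- terminal_mf_terms(graph)
  nk <- config$n_genomes_per_kingdom
  if (sum(nk) == 0L) stop_("all three kingdom genome counts are zero")
  if (length(leaves) < config$ancestral_repertoire_size) {
    stop_("ontology has %d leaves, fewer than ancestral_repertoire_size (%d)",
          length(leaves), config$ancestral_repertoire_size)
  }

  tips <- list(A = sprintf("A%03d", seq_len(nk[["A"]])),
               B = sprintf("B%03d", seq_len(nk[["B"]])),
               E = sprintf("E%03d", seq_len(nk[["E"]])))
  all_tips <- unlist(tips, use.names = FALSE)
  kingdom <- rep(c("A", "B", "E"), times = nk)
  names(kingdom) <- all_tips

  # deterministic quotas from the end of each clade: low-coverage tips, then
  # parasites last
  n_par <- quota(config$parasite_fraction, nk)
  n_lc <- quota(config$low_coverage_fraction, nk)
  if (any(n_par + n_lc > nk)) {
    stop_("parasite and low-coverage quotas exceed a clade size")
  }
  lifestyle <- rep("free_living", length(all_tips))
  low_cov <- rep(FALSE, length(all_tips))
  names(lifestyle) <- names(low_cov) <- all_tips
  for (K in c("A", "B", "E")) {
    tk <- tips[[K]]
    np <- n_par[[K]]; nl <- n_lc[[K]]; n <- length(tk)
    if (np > 0L) {
      par_tips <- tk[(n - np + 1L):n]
      lifestyle[par_tips] <- rep(c("parasite", "facultative_parasite"),
                                 length.out = np)
    }
    if (nl > 0L) low_cov[tk[(n - np - nl + 1L):(n - np)]] <- TRUE
  }

  anc <- leaves[seq_len(config$ancestral_repertoire_size)]
  novel <- leaves[-seq_len(config$ancestral_repertoire_size)]

  with_seed(config$seed + 1L, {
    lost <- anc[runif(length(anc)) < config$loss_rate_per_clade]
    kept_anc <- setdiff(anc, lost)

    # per-genome repertoires
    repertoire <- vector("list", length(all_tips))
    names(repertoire) <- all_tips
    for (t in tips$A) repertoire[[t]] <- kept_anc
    for (t in tips$B) repertoire[[t]] <- anc
    for (t in tips$E) repertoire[[t]] <- anc
    if (length(novel) && nk[["E"]] > 0L) {
      novel_tip <- tips$E[1L + (seq_along(novel) - 1L) %% nk[["E"]]]
      for (i in seq_along(novel)) {
        t <- novel_tip[i]
        repertoire[[t]] <- c(repertoire[[t]], novel[i])
      }
    }

    # abundances: 1 + Poisson(duplication_mean), genome by genome
    abundance <- lapply(all_tips, function(t) {
      terms <- sort(repertoire[[t]])
      ab <- 1L + rpois(length(terms), config$duplication_mean)
      names(ab) <- terms
      ab
    })
    names(abundance) <- all_tips

    # lateral transfer of Archaea-lost terms from B donors to A recipients,
    # cycling over free-living adequate-coverage tips on both sides
    eligible <- function(K) {
      tk <- tips[[K]]
      tk[lifestyle[tk] == "free_living" & !low_cov[tk]]
    }
    hgt_terms <- character(0)
    hgt_by_genome <- list()
    recip_of <- character(0)
    if (config$hgt_term_count > 0L) {
      donors <- eligible("B"); if (!length(donors)) donors <- tips$B
      recips <- eligible("A"); if (!length(recips)) recips <- tips$A
      pool <- sort(lost)
      if (length(donors) && length(recips)) {
        if (length(pool) < config$hgt_term_count) {
          warning(sprintf(
            "only %d Archaea-lost terms available for %d requested HGT events",
            length(pool), config$hgt_term_count))
        }
        hgt_terms <- pool[seq_len(min(length(pool), config$hgt_term_count))]
        for (j in seq_along(hgt_terms)) {
          donor <- donors[1L + (j - 1L) %% length(donors)]
          recip <- recips[1L + (j - 1L) %% length(recips)]
          abundance[[recip]][hgt_terms[j]] <- abundance[[donor]][[hgt_terms[j]]]
          recip_of[hgt_terms[j]] <- recip
        }
      } else if (config$hgt_term_count > 0L) {
        warning("no donor/recipient clade available; HGT events skipped")
      }
    }

    # annotation records: one protein per term copy, annotated once
    annotations <- vector("list", length(all_tips))
    names(annotations) <- all_tips
    proteome_size <- integer(length(all_tips))
    names(proteome_size) <- all_tips
    for (t in all_tips) {
      ab <- abundance[[t]]
      ab <- ab[sort(names(ab))]
      go <- rep(names(ab), times = ab)
      prot <- sprintf("%s_P%05d", t, seq_along(go))
      cover <- if (low_cov[t]) 0.4 else 0.6
      proteome_size[t] <- max(as.integer(ceiling(length(prot) / cover)),
                              length(prot))
      annotations[[t]] <- annotation_set(
        t, data.frame(protein_id = prot, go_id = go,
                      aspect = rep("F", length(go))),
        proteome_size[t])
      if (t %in% recip_of) {
        carried <- names(ab) %in% names(recip_of)[recip_of == t]
        hgt_by_genome[[t]] <- prot[rep(carried, times = ab)]
      }
    }

    metadata <- data.frame(organism_id = all_tips,
                           superkingdom = unname(kingdom),
                           lifestyle = unname(lifestyle),
                           proteome_size = unname(proteome_size),
                           is_type_strain = TRUE)

    # true Venn groups from the pre-HGT repertoires
    present_in <- function(term) {
      ks <- character(0)
      if (nk[["A"]] > 0L && !(term %in% lost) && term %in% anc) ks <- c(ks, "A")
      if (nk[["B"]] > 0L && term %in% anc) ks <- c(ks, "B")
      if (nk[["E"]] > 0L && (term %in% anc || term %in% novel)) ks <- c(ks, "E")
      paste(ks, collapse = "")
    }
    used <- sort(unique(c(anc, if (nk[["E"]] > 0L) novel else character(0))))
    true_group <- vapply(used, present_in, "")
    true_group <- true_group[nzchar(true_group)]

    nwk <- local({
      parts <- Filter(nzchar, c(
        A = if (nk[["A"]]) pectinate_newick(tips$A) else "",
        BE = {
          sub <- Filter(nzchar, c(
            if (nk[["B"]]) pectinate_newick(tips$B) else "",
            if (nk[["E"]]) pectinate_newick(tips$E) else ""))
          if (length(sub) == 2L) paste0("(", sub[1L], ",", sub[2L], ")")
          else if (length(sub) == 1L) sub else ""
        }))
      if (length(parts) == 2L) paste0("(", parts[1L], ",", parts[2L], ");")
      else paste0(parts[[1L]], ";")
    })
    species_tree <- if (sum(nk > 0L) >= 2L || sum(nk) >= 2L) {
      ape::read.tree(text = nwk)
    } else NULL

    structure(list(annotations = annotations,
                   metadata = metadata,
                   hgt_lists = hgt_by_genome,
                   truth = list(species_tree = species_tree,
                                true_venn_group = true_group,
                                hgt_terms = hgt_terms,
                                hgt_recipients = recip_of,
                                reduced_clades = list(A = sort(lost)),
                                ancestral_terms = anc,
                                novel_terms = if (nk[["E"]] > 0L) novel else character(0),
                                low_coverage = names(low_cov)[low_cov]),
                   config = config),
              class = "go_census_sim")
  })
}

#' @export
print.go_census_sim <- function(x, ...) {
  nk <- x$config$n_genomes_per_kingdom
  cat("go_census_sim:", sum(nk), "genomes (A:", nk[["A"]], "B:", nk[["B"]],
      "E:", nk[["E"]], ")\n")
  cat("  ancestral terms:", length(x$truth$ancestral_terms),
      "| lost on A stem:", length(x$truth$reduced_clades$A),
      "| planted HGT terms:", length(x$truth$hgt_terms), "\n")
  cat("  parasites:", sum(x$metadata$lifestyle != "free_living"),
      "| low-coverage genomes:", length(x$truth$low_coverage), "\n")
  invisible(x)
}

#' Synthetic corpus mirroring the 2009 proteome study design
#'
#' Constructs the generator configuration whose filtered census reproduces
#' the bookkeeping of the original free-living proteome dataset: 49 + 199 +
#' 23 genomes with 4% parasite and 4% low-coverage quotas leave 45 Archaea,
#' 183 Bacteria and 21 Eukarya (249 genomes) after organism filtering; 989
#' ancestral leaf terms plus 1,150 eukaryal novelties assigned round-robin
#' to the 23 Eukarya tips leave 2,039 distinct detected terms in the
#' retained census; and 115 planted laterally transferred terms leave 1,924
#' terms once the HGT-acquired set is excluded.
#'
#' @param seed Integer seed forwarded to the generator.
#' @return List with `graph` (the ontology), `sim` (the corpus) and
#'   `config`.
#' @export
simulate_reference_corpus <- function(seed = 2009) {
  config <- simulation_config(
    n_terms_total = 2230,          # 1 root + 2x45 interior + 2,139 leaves
    ontology_depth = 3,
    n_genomes_per_kingdom = c(A = 49, B = 199, E = 23),
    ancestral_repertoire_size = 989,
    loss_rate_per_clade = 0.3,
    duplication_mean = 0.8,
    hgt_term_count = 115,
    parasite_fraction = 0.04,
    low_coverage_fraction = 0.04,
    seed = seed)
  graph <- generate_ontology(config)
  sim <- simulate_genomes(graph, config)
  list(graph = graph, sim = sim, config = config)
}
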