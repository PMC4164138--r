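# fixture builders and independent oracles shared across the suite

make_census <- function(abundance, superkingdom = NULL) {
  structure(list(abundance = abundance, superkingdom = superkingdom),
            class = "go_census")
}

make_view <- function(states, orientation = "ToL") {
  structure(list(states = states, taxa = rownames(states),
                 characters = colnames(states), orientation = orientation),
            class = "go_charview")
}

rand_states <- function(n_taxa, n_chars, max_state = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:max_state, n_taxa * n_chars, replace = TRUE),
         n_taxa, n_chars,
         dimnames = list(paste0("t", seq_len(n_taxa)),
                         paste0("c", seq_len(n_chars))))
}

# random binary tree in the package's internal representation
rand_tx <- function(n) {
  tr <- gocensus:::tx_init3(1L, 2L, 3L)
  if (n > 3L) {
    for (k in 4:n) {
      ed <- gocensus:::tx_edges(tr)
      tr <- gocensus:::tx_insert(tr, ed[sample(length(ed), 1L)], k)
    }
  }
  tr
}

# oracle: every unrooted binary topology on n taxa by recursive addition
enumerate_topologies <- function(n) {
  out <- list()
  grow <- function(tr, k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- tr
      return(invisible())
    }
    for (e in gocensus:::tx_edges(tr)) grow(gocensus:::tx_insert(tr, e, k), k + 1L)
  }
  grow(gocensus:::tx_init3(1L, 2L, 3L), 4L)
  out
}

# oracle: minimum parsimony length by exhaustive enumeration, scored with
# the reference Sankoff dynamic program
exhaustive_mp_length <- function(states, cost_matrix) {
  min(vapply(enumerate_topologies(nrow(states)), function(tr) {
    sum(gocensus:::sankoff_length_cpp(tr$parent, tr$tiprow, states,
                                      cost_matrix))
  }, 0))
}

# oracle: hypergeometric upper tail by enumerating all C(N, n) draws
hyper_tail_enum <- function(k, K, n, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# small simulated corpus used by several files
small_corpus <- function(seed = 42, ...) {
  cfg <- simulation_config(seed = seed, ...)
  graph <- generate_ontology(cfg)
  sim <- simulate_genomes(graph, cfg)
  list(cfg = cfg, graph = graph, sim = sim,
       terminal = terminal_mf_terms(graph))
}
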