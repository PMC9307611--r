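# One small cohort shared across test files (built once per test run).

.cohort_cache <- new.env(parent = emptyenv())

tiny_sim_config <- function(seed = 11L, ...) {
  sim_config(
    genome_sizes = c(chrA = 3e5, chrB = 3e5),
    n_sv = 30L,
    cluster_spec = list(),
    n_cnv = 8L, n_indel = 8L, n_genes = 8L, n_panel = 4L, n_fragile = 2L,
    seed = seed, ...)
}

tiny_cohort <- function() {
  if (is.null(.cohort_cache$tiny)) {
    .cohort_cache$tiny <- simulate_cohort(tiny_sim_config())
  }
  .cohort_cache$tiny
}

truth_sv <- function(cohort, ...) {
  svdynamics:::truth_to_sv(cohort$truth, ...)
}
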