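# Simulation configuration. Defaults mirror the emulated study design:
# six developmental timepoints (10.5E, 16.5E, 1M, 4M, 8M, 12M) with two
# replicate animals each, ~45% genomic repeat content, a 54% breakpoint
# repeat bias, and two thirds of events inherited from the strain
# background rather than arising de novo.

#' Simulation configuration for a synthetic longitudinal cohort
#'
#' @param genome_sizes named integer vector of chromosome lengths (bp).
#' @param repeat_fraction target genomic repeat coverage in `[0, 1]`.
#' @param n_sv total SV events, including clustered ones.
#' @param mh_distribution data frame with columns `length` (0-50) and
#'   `prob` (sums to 1): the designed junction-microhomology distribution.
#'   The default is NHEJ-heavy with a small blunt fraction, echoing
#'   reported repair-pathway proportions in HR-deficient genomes.
#' @param repeat_bias probability a breakpoint is placed inside a repeat.
#' @param cluster_spec list of `list(chrom, start, end, n_events)` hotspot
#'   designs; their event counts must not exceed `n_sv`.
#' @param timepoints ordered timepoint labels.
#' @param replicates_per_timepoint replicate count per timepoint.
#' @param inherited_fraction fraction of events present in the baseline
#'   ("kidney") callset, assigned by exact quota.
#' @param dynamics_model list with `p_persistent` (probability an event is
#'   present at every timepoint) and `p_present` (per-timepoint presence
#'   probability for the rest). No quantitative appearance/disappearance
#'   model is reported for the emulated system; this two-parameter model
#'   is a documented free choice.
#' @param p_both_replicates probability a present event is called in both
#'   replicates (else exactly one).
#' @param noise_fraction fraction of extra quality-failing records added
#'   per emitted file, exercising the hard filters.
#' @param n_panel wildtype strain-background SV count (in every sample and
#'   in the panel file).
#' @param n_cnv,n_indel CNV and indel truth-event counts.
#' @param n_genes,n_fragile gene-model and fragile-site counts.
#' @param flank junction flank length (bp) the design guarantees
#'   microhomology within.
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of the configuration including the seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_sizes = c(chr1 = 5e6, chr2 = 5e6,
                                        chr3 = 5e6, chr4 = 5e6),
                       repeat_fraction = 0.45,
                       n_sv = 240L,
                       mh_distribution = default_mh_distribution(),
                       repeat_bias = 0.54,
                       cluster_spec = default_cluster_spec(),
                       timepoints = c("10.5E", "16.5E", "1M", "4M", "8M", "12M"),
                       replicates_per_timepoint = 2L,
                       inherited_fraction = 2 / 3,
                       dynamics_model = list(
                         p_persistent = 0.3,
                         p_present = c(0.35, 0.45, 0.5, 0.55, 0.65, 0.75)),
                       p_both_replicates = 0.7,
                       noise_fraction = 0.1,
                       n_panel = 30L,
                       n_cnv = 60L,
                       n_indel = 120L,
                       n_genes = 40L,
                       n_fragile = 5L,
                       flank = 50L,
                       seed = 1L) {
  stopifnot(length(genome_sizes) >= 1, !is.null(names(genome_sizes)))
  genome_sizes <- stats::setNames(as.integer(genome_sizes), names(genome_sizes))
  if (repeat_fraction < 0 || repeat_fraction > 1) {
    stop("repeat_fraction must lie in [0, 1]")
  }
  if (repeat_bias < 0 || repeat_bias > 1) stop("repeat_bias must lie in [0, 1]")
  if (inherited_fraction < 0 || inherited_fraction > 1) {
    stop("inherited_fraction must lie in [0, 1]")
  }
  if (abs(sum(mh_distribution$prob) - 1) > 1e-9) {
    stop("mh_distribution probabilities must sum to 1")
  }
  if (any(mh_distribution$length < 0 | mh_distribution$length > flank)) {
    stop("designed microhomology lengths must lie in [0, flank]")
  }
  n_clustered <- sum(vapply(cluster_spec, `[[`, 0, "n_events"))
  if (n_clustered > n_sv) stop("cluster event counts exceed n_sv")
  if (length(timepoints) < 1 || anyDuplicated(timepoints)) {
    stop("timepoints must be a non-empty duplicate-free ordered vector")
  }
  dp <- dynamics_model$p_present
  if (length(dp) == 1) dp <- rep(dp, length(timepoints))
  if (length(dp) != length(timepoints)) {
    stop("dynamics_model$p_present must have one probability per timepoint")
  }
  dynamics_model$p_present <- dp
  structure(list(
    genome_sizes = genome_sizes, repeat_fraction = repeat_fraction,
    n_sv = as.integer(n_sv), mh_distribution = mh_distribution,
    repeat_bias = repeat_bias, cluster_spec = cluster_spec,
    timepoints = timepoints,
    replicates_per_timepoint = as.integer(replicates_per_timepoint),
    inherited_fraction = inherited_fraction,
    dynamics_model = dynamics_model,
    p_both_replicates = p_both_replicates,
    noise_fraction = noise_fraction,
    n_panel = as.integer(n_panel), n_cnv = as.integer(n_cnv),
    n_indel = as.integer(n_indel), n_genes = as.integer(n_genes),
    n_fragile = as.integer(n_fragile), flank = as.integer(flank),
    seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_mh_distribution <- function() {
  data.frame(
    length = 0:50,
    prob = c(0.05,                 # blunt
             rep(0.82 / 5, 5),     # 1-5 bp
             rep(0.125 / 20, 20),  # 6-25 bp
             rep(0.005 / 25, 25))) # 26-50 bp
}

#' @rdname sim_config
#' @export
default_cluster_spec <- function() {
  list(
    list(chrom = "chr1", start = 1.0e6, end = 1.1e6, n_events = 10L),
    list(chrom = "chr1", start = 3.5e6, end = 3.6e6, n_events = 10L),
    list(chrom = "chr2", start = 2.0e6, end = 2.1e6, n_events = 10L),
    list(chrom = "chr3", start = 4.0e6, end = 4.1e6, n_events = 10L))
}
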