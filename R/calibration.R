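#' Null-model calibration experiment
#'
#' Validates the inferential machinery on data that truly satisfy the null:
#' generates independent CSR communities, applies the homogeneous Poisson
#' null to one target species in each, and records (i) whether the
#' goodness-of-fit rank test over a distance interval rejects, and (ii)
#' whether the observed ISAR lies inside the two-sided pointwise envelope
#' at a fixed radius. Across replicates the rejection fraction should sit
#' at the nominal level and the containment fraction at its complement:
#' both are exact consequences of the exchangeability of the observed
#' pattern with its own relocations.
#'
#' @param n_rep Number of independent replicate communities (default 200).
#' @param seed Master seed; every replicate derives its own substreams.
#' @param n_species,abundance,window Community layout (defaults: 10 species
#'   of 60 stems each on a 200 x 200 m window).
#' @param n_sim Simulations per ensemble (default 199).
#' @param grid Radius grid (default `1:25`).
#' @param interval GoF interval (default `c(1, 10)`).
#' @param alpha Significance level (default 0.05).
#' @param envelope_r Radius at which envelope containment is recorded
#'   (default 10 m).
#' @param envelope_k Envelope order-statistic rank (default 5).
#' @return Data frame with one row per replicate: `reject` (GoF rejection)
#'   and `inside` (envelope containment at `envelope_r`).
#' @export
null_calibration <- function(n_rep = 200, seed = 1, n_species = 10,
                             abundance = 60,
                             window = isar_window(0, 200, 0, 200),
                             n_sim = 199, grid = 1:25, interval = c(1, 10),
                             alpha = 0.05, envelope_r = 10,
                             envelope_k = 5) {
  reject <- logical(n_rep)
  inside <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    cfg <- scenario_config(n_species = n_species, abundance = abundance,
                           window = window,
                           seed = substream_seed(seed, 17L, k))
    com <- gen_csr_community(cfg)
    ens <- run_null_ensemble(com, cfg$species[1L], "homogeneous",
                             n_sim = n_sim,
                             seed = substream_seed(seed, 23L, k),
                             grid = grid)
    reject[k] <- gof_rank_test(ens, interval, alpha = alpha)$significant
    env <- pointwise_envelope(ens, k = envelope_k)
    inside[k] <- env$outside[env$r == envelope_r] == 0L
  }
  data.frame(reject = reject, inside = inside)
}
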