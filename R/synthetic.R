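#' Scenario configuration for synthetic communities
#'
#' Collects the parameters of a synthetic multispecies point pattern with
#' known structure, used to validate every inference stage against ground
#' truth. Defaults emulate a 25 ha mapped census: a 500 x 500 m window and
#' species abundances spanning tens to thousands of stems.
#'
#' @param window An [isar_window()] (default 500 x 500 m).
#' @param n_species Number of species (ignored when `abundance` is a named
#'   vector).
#' @param abundance Per-species abundance: a single number (recycled) or a
#'   vector, optionally named with species codes.
#' @param structure Spatial structure: `"csr"` (independent uniform
#'   placement) or `"habitat"` (log-linear response to a smooth covariate).
#' @param beta Habitat-response coefficients, recycled over species; 0 is
#'   no response (CSR).
#' @param habitat_scale Length scale (m) of the Gaussian covariate bumps
#'   (default 100, comfortably above the 50 m separation scale of the
#'   heterogeneous null).
#' @param n_bumps Number of Gaussian bumps in the covariate (default 3).
#' @param interaction `"none"`, `"accumulator"` or `"repeller"` overlay
#'   around the target species.
#' @param target Species code of the interaction target (default: the
#'   first species).
#' @param d_int Interaction distance in metres (must be > 0 when an
#'   interaction is requested).
#' @param strength Interaction strength: recruits per target individual for
#'   the accumulator overlay (>= 0); thinning probability in `[0, 1]` for
#'   the repeller overlay.
#' @param adult_fraction Expected share of stems with DBH > 10 cm
#'   (default 0.16, echoing the adult share of a typical large mapped
#'   census).
#' @param dbh_meanlog,dbh_sdlog Log-normal parameters of the adult DBH
#'   excess above 10 cm.
#' @param seed Master seed.
#' @return A list of class `"isar_scenario"`.
#' @export
scenario_config <- function(window = isar_window(0, 500, 0, 500),
                            n_species = 100,
                            abundance = 100,
                            structure = c("csr", "habitat"),
                            beta = 0,
                            habitat_scale = 100,
                            n_bumps = 3,
                            interaction = c("none", "accumulator", "repeller"),
                            target = NULL,
                            d_int = 10,
                            strength = 0,
                            adult_fraction = 0.16,
                            dbh_meanlog = 2, dbh_sdlog = 0.8,
                            seed = 1L) {
  structure_ <- match.arg(structure)
  interaction <- match.arg(interaction)
  if (length(abundance) > 1L) n_species <- length(abundance)
  abundance <- rep_len(abundance, n_species)
  if (any(abundance < 1)) stop("abundances must be >= 1")
  species <- if (!is.null(names(abundance)) && all(nzchar(names(abundance))))
    names(abundance) else sprintf("sp%02d", seq_len(n_species))
  if (interaction != "none" && d_int <= 0)
    stop("d_int must be > 0 when an interaction is requested")
  if (interaction == "repeller" && (strength < 0 || strength > 1))
    stop("repeller strength must be in [0, 1]")
  if (!(adult_fraction > 0 && adult_fraction < 1))
    stop("adult_fraction must be in (0, 1)")
  structure(list(window = window, species = species,
                 abundance = stats::setNames(as.integer(abundance), species),
                 structure = structure_, beta = rep_len(beta, n_species),
                 habitat_scale = habitat_scale, n_bumps = n_bumps,
                 interaction = interaction,
                 target = if (is.null(target)) species[1L] else target,
                 d_int = d_int, strength = strength,
                 adult_fraction = adult_fraction,
                 dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
                 seed = as.integer(seed)),
            class = "isar_scenario")
}

new_stem_table <- function(species, x, y) {
  data.frame(stem_id = sprintf("s%06d", seq_along(x)),
             species = species, x = x, y = y, dbh = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate a community under complete spatial randomness
#'
#' Each species' individuals are placed i.i.d. uniformly on the window,
#' independently across species, with exact per-species counts. DBH marks
#' are then assigned with [assign_dbh()] and the adult/sapling
#' stratification applied.
#'
#' @param config An `"isar_scenario"` (its `structure` is ignored here).
#' @return An `"isar_community"` with `size_class` set.
#' @export
gen_csr_community <- function(config) {
  w <- config$window
  set.seed(substream_seed(config$seed, 1L))
  n <- sum(config$abundance)
  stems <- new_stem_table(rep(config$species, config$abundance),
                          stats::runif(n, w$x_min, w$x_max),
                          stats::runif(n, w$y_min, w$y_max))
  com <- assign_dbh(community(stems, w, validate = FALSE), config)
  stratify_by_size(com)
}

#' Smooth habitat covariate surface
#'
#' A sum of Gaussian bumps with length scale `habitat_scale` (default 100
#' m), centred at seeded random positions in the window, standardised to
#' zero mean and unit variance over a probe grid. All structure lives at
#' scales well above the 50 m separation scale, so the separation-of-scales
#' assumption of the heterogeneous null holds by construction.
#'
#' @param config An `"isar_scenario"`.
#' @return A vectorised function `f(x, y)`.
#' @export
habitat_covariate <- function(config) {
  w <- config$window
  set.seed(substream_seed(config$seed, 2L))
  cx <- stats::runif(config$n_bumps, w$x_min, w$x_max)
  cy <- stats::runif(config$n_bumps, w$y_min, w$y_max)
  s2 <- config$habitat_scale^2
  raw <- function(x, y) {
    v <- 0
    for (b in seq_len(config$n_bumps))
      v <- v + exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * s2))
    v
  }
  gx <- seq(w$x_min, w$x_max, length.out = 41)
  gy <- seq(w$y_min, w$y_max, length.out = 41)
  probe <- raw(rep(gx, times = 41), rep(gy, each = 41))
  m <- mean(probe); s <- stats::sd(probe)
  if (s == 0) s <- 1
  function(x, y) (raw(x, y) - m) / s
}

#' Generate a community with habitat association
#'
#' Species s is drawn from the inhomogeneous intensity proportional to
#' `exp(beta_s * covariate(x, y))` by rejection sampling; `beta_s = 0`
#' reduces exactly to CSR. Species sharing a positive response co-occur in
#' the covariate's high patches, creating large-scale richness structure
#' with no individual interactions.
#'
#' @param config An `"isar_scenario"` with `structure = "habitat"`.
#' @param covariate_surface Optional covariate function `f(x, y)`; default
#'   [habitat_covariate()] of the config.
#' @return An `"isar_community"` with `size_class` set.
#' @export
gen_habitat_community <- function(config, covariate_surface = NULL) {
  w <- config$window
  if (is.null(covariate_surface)) covariate_surface <- habitat_covariate(config)
  set.seed(substream_seed(config$seed, 3L))
  parts <- vector("list", length(config$species))
  for (s in seq_along(config$species)) {
    n <- config$abundance[[s]]
    beta <- config$beta[s]
    if (beta == 0) {
      parts[[s]] <- data.frame(x = stats::runif(n, w$x_min, w$x_max),
                               y = stats::runif(n, w$y_min, w$y_max))
    } else {
      xs <- numeric(0); ys <- numeric(0)
      # rejection bound: covariate is standardised, |z| rarely exceeds ~4
      logM <- abs(beta) * 4.5
      while (length(xs) < n) {
        m <- max(2L * (n - length(xs)), 100L)
        px <- stats::runif(m, w$x_min, w$x_max)
        py <- stats::runif(m, w$y_min, w$y_max)
        keep <- log(stats::runif(m)) < beta * covariate_surface(px, py) - logM
        xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
      }
      parts[[s]] <- data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
    }
  }
  xy <- do.call(rbind, parts)
  stems <- new_stem_table(rep(config$species, config$abundance), xy$x, xy$y)
  com <- assign_dbh(community(stems, w, validate = FALSE), config)
  stratify_by_size(com)
}

#' Overlay a constructed species interaction on a community
#'
#' Builds ground-truth accumulator or repeller structure around the target
#' species at a known distance, for parameter-recovery tests.
#' Accumulator: heterospecific recruits are added uniformly within `d_int`
#' of randomly chosen target individuals (`round(strength * n_t)` recruits
#' in total, species drawn uniformly from the non-target species), raising
#' neighbourhood richness locally. Repeller: each heterospecific stem
#' within `d_int` of any target is deleted with probability `strength`.
#' `strength = 0` returns the community unchanged.
#'
#' @param com An `"isar_community"`.
#' @param t Target species code.
#' @param interaction `"accumulator"` or `"repeller"`.
#' @param d_int Interaction distance (m).
#' @param strength Recruits per target individual (accumulator, >= 0) or
#'   deletion probability (repeller, in `[0, 1]`).
#' @param seed Seed for the overlay draws.
#' @return The modified `"isar_community"`.
#' @export
gen_interaction_overlay <- function(com, t,
                                    interaction = c("accumulator", "repeller"),
                                    d_int = 10, strength = 1, seed = 1L) {
  interaction <- match.arg(interaction)
  stopifnot(inherits(com, "isar_community"))
  w <- attr(com, "window")
  df <- as.data.frame(com)
  targets <- df[df$species == t, , drop = FALSE]
  if (nrow(targets) == 0L) stop("target species not present: ", t)
  if (strength == 0) return(com)
  set.seed(substream_seed(seed, species_hash(t), 4L))
  if (interaction == "accumulator") {
    n_rec <- round(strength * nrow(targets))
    if (n_rec == 0) return(com)
    others <- setdiff(unique(df$species), t)
    if (!length(others)) stop("no heterospecific species to recruit from")
    anchors <- sample.int(nrow(targets), n_rec, replace = TRUE)
    xs <- numeric(n_rec); ys <- numeric(n_rec)
    for (i in seq_len(n_rec)) {
      repeat {   # uniform in the disc, clipped to the window by resampling
        rr <- d_int * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        px <- targets$x[anchors[i]] + rr * cos(th)
        py <- targets$y[anchors[i]] + rr * sin(th)
        if (in_window(px, py, w)) { xs[i] <- px; ys[i] <- py; break }
      }
    }
    recruits <- data.frame(
      stem_id = sprintf("rec%05d", seq_len(n_rec)),
      species = sample(others, n_rec, replace = TRUE),
      x = xs, y = ys,
      dbh = stats::runif(n_rec, 1, 10),   # recruits are saplings
      stringsAsFactors = FALSE)
    if ("size_class" %in% names(df)) recruits$size_class <- "sapling"
    out <- community(rbind(df, recruits), w, validate = FALSE)
  } else {
    if (strength < 0 || strength > 1)
      stop("repeller strength must be in [0, 1]")
    het <- which(df$species != t)
    M <- cpp_min_dist_by_group(df$x[het], df$y[het],
                               targets$x, targets$y,
                               rep(1L, nrow(targets)), 1L)
    near <- het[M[, 1L] <= d_int]
    drop <- near[stats::runif(length(near)) < strength]
    out <- community(df[setdiff(seq_len(nrow(df)), drop), , drop = FALSE],
                     w, validate = FALSE)
  }
  out
}

#' Assign DBH marks to a community
#'
#' Draws DBH (cm) as a two-part mixture: with probability `adult_fraction`
#' a stem is an adult with DBH `10 + X`, `X ~ lognormal(meanlog, sdlog)`;
#' otherwise a sapling with DBH uniform on `[1, 10]`. The expected adult
#' share (DBH > 10) therefore equals `adult_fraction` exactly, and every
#' mark is >= 1.
#'
#' @param points An `"isar_community"` (existing `dbh` is overwritten).
#' @param config An `"isar_scenario"` supplying `adult_fraction`,
#'   `dbh_meanlog`, `dbh_sdlog`; or `NULL` to use the explicit arguments.
#' @param adult_fraction,meanlog,sdlog Used when `config` is `NULL`.
#' @param seed Optional seed; `NULL` (default when `config` given uses the
#'   scenario substream) draws from the current RNG state.
#' @return The community with `dbh` set.
#' @export
assign_dbh <- function(points, config = NULL, adult_fraction = 0.16,
                       meanlog = 2, sdlog = 0.8, seed = NULL) {
  stopifnot(inherits(points, "isar_community"))
  if (!is.null(config)) {
    adult_fraction <- config$adult_fraction
    meanlog <- config$dbh_meanlog
    sdlog <- config$dbh_sdlog
    if (is.null(seed)) seed <- substream_seed(config$seed, 5L)
  }
  if (!(adult_fraction > 0 && adult_fraction < 1))
    stop("adult_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  adult <- stats::runif(n) < adult_fraction
  dbh <- numeric(n)
  dbh[adult] <- 10 + stats::rlnorm(sum(adult), meanlog, sdlog)
  dbh[!adult] <- stats::runif(sum(!adult), 1, 10)
  points$dbh <- dbh
  points
}

#' Generate a community from a scenario
#'
#' Dispatches on the scenario's `structure` and applies any interaction
#' overlay, giving one call that realises the full configured ground truth.
#'
#' @param config An `"isar_scenario"`.
#' @return An `"isar_community"` with `size_class` set.
#' @export
gen_community <- function(config) {
  stopifnot(inherits(config, "isar_scenario"))
  com <- switch(config$structure,
                csr = gen_csr_community(config),
                habitat = gen_habitat_community(config))
  if (config$interaction != "none")
    com <- gen_interaction_overlay(com, config$target, config$interaction,
                                   d_int = config$d_int,
                                   strength = config$strength,
                                   seed = config$seed)
  com
}
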