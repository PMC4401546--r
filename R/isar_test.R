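#' Test one target species' ISAR against a null model
#'
#' The central fitting function: computes the observed individual
#' species-area relationship of a target species, simulates the Monte Carlo
#' null ensemble, builds the pointwise envelope, runs the accumulated-
#' deviation goodness-of-fit rank test on each distance interval, and
#' classifies the species per interval.
#'
#' Under the homogeneous Poisson null (targets relocated uniformly over the
#' window, everything else fixed) a departure means the species sits in
#' locally richer or poorer neighbourhoods than the plot-average
#' species-area relationship predicts, whatever the cause. Under the
#' heterogeneous Poisson null the targets are relocated according to their
#' own kernel-estimated intensity surface, so habitat association at scales
#' above the bandwidth is kept and a remaining departure is attributed to
#' species interactions: the species is an accumulator (significantly
#' richer neighbourhoods), a repeller (poorer), or no-effect.
#'
#' @inheritParams run_null_ensemble
#' @param intervals List of `c(r_min, r_max)` distance intervals (default
#'   [default_intervals()]).
#' @param alpha Significance level of the rank test (default 0.05).
#' @param envelope_k Order-statistic rank of the pointwise envelope
#'   (default 5: the 5th-lowest/5th-highest of 199 simulations).
#' @return An object of class `"isar_test"`: list with the `ensemble`,
#'   `envelope`, `gof` (one `"isar_gof"` per interval), `classification`
#'   (data frame, one row per interval), and the call parameters.
#' @examples
#' com <- gen_csr_community(scenario_config(n_species = 8, abundance = 50,
#'   window = isar_window(0, 200, 0, 200), seed = 7))
#' fit <- isar_test(com, "sp01", model = "homogeneous", n_sim = 39,
#'                  grid = 1:20, intervals = list(c(1, 10), c(11, 20)),
#'                  seed = 7)
#' fit
#' summary(fit)
#' @export
isar_test <- function(com, t, model = c("homogeneous", "heterogeneous"),
                      n_sim = 199, seed = 1L, grid = 1:50,
                      intervals = default_intervals(),
                      alpha = 0.05, neighbors = "all", target_class = NULL,
                      bandwidth = 50, cell = 5, envelope_k = 5) {
  model <- match.arg(model)
  ens <- run_null_ensemble(com, t, model = model, n_sim = n_sim, seed = seed,
                           grid = grid, neighbors = neighbors,
                           target_class = target_class,
                           bandwidth = bandwidth, cell = cell)
  env <- pointwise_envelope(ens, k = envelope_k)
  gof <- lapply(intervals, function(iv) gof_rank_test(ens, iv, alpha = alpha))
  cls <- classify_species(gof, model = model, species = t)
  structure(list(ensemble = ens, envelope = env, gof = gof,
                 classification = cls, species = t, model = model,
                 n_sim = n_sim, alpha = alpha, seed = seed,
                 intervals = intervals),
            class = "isar_test")
}

#' @export
print.isar_test <- function(x, ...) {
  cat(sprintf("ISAR test: species %s vs %s Poisson null (%d simulations, alpha = %g)\n",
              x$species, x$model, x$n_sim, x$alpha))
  cat(sprintf("  n_t = %d target individuals, %d neighbour species\n",
              x$ensemble$n_t, x$ensemble$n_pool_species))
  cl <- x$classification
  cat("  per-interval classification:",
      paste(sprintf("%s m: %s", cl$interval, cl$label), collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.isar_test <- function(object, ...) {
  cl <- object$classification
  cl$critical_rank <- vapply(object$gof, function(g) g$critical_rank,
                             numeric(1))
  cl$summed_deviation <- vapply(object$gof, function(g) g$summed_deviation,
                                numeric(1))
  structure(list(species = object$species, model = object$model,
                 n_sim = object$n_sim, alpha = object$alpha,
                 n_t = object$ensemble$n_t, table = cl,
                 n_outside = sum(object$envelope$outside != 0L)),
            class = "summary.isar_test")
}

#' @export
print.summary.isar_test <- function(x, ...) {
  cat(sprintf("ISAR goodness-of-fit summary: species %s, %s Poisson null\n",
              x$species, x$model))
  cat(sprintf("  %d target individuals; %d simulations; alpha = %g; %d radii outside the pointwise envelope\n",
              x$n_t, x$n_sim, x$alpha, x$n_outside))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot an ISAR test: observed curve and simulation envelope
#'
#' @param x An `"isar_test"`.
#' @param shade Shade the envelope band? Default `TRUE`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.isar_test <- function(x, shade = TRUE, ...) {
  e <- x$envelope
  graphics::plot(e$r, e$observed, type = "n",
                 ylim = range(e$lower, e$upper, e$observed),
                 xlab = "neighbourhood radius r (m)",
                 ylab = expression(ISAR[t](r)),
                 main = sprintf("%s vs %s Poisson null", x$species, x$model),
                 ...)
  if (shade)
    graphics::polygon(c(e$r, rev(e$r)), c(e$lower, rev(e$upper)),
                      col = grDevices::grey(0.85), border = NA)
  graphics::lines(e$r, e$mean, lty = 2, col = "grey40")
  graphics::lines(e$r, e$observed, lwd = 2)
  out <- e$outside != 0L
  if (any(out))
    graphics::points(e$r[out], e$observed[out], pch = 16, col = 2)
  invisible(x)
}

#' @export
as.data.frame.isar_test <- function(x, ...) {
  cbind(species = x$species, model = x$model,
        as.data.frame(x$envelope)[c("r", "observed", "lower", "upper")])
}

#' Community-wide ISAR analysis
#'
#' Runs [isar_test()] for every target species (selected by adult
#' abundance, see [select_targets()]) under one null model, and assembles
#' the classification and summary tables. The size-stratified mode
#' `"large_small"` uses adult targets with heterospecific sapling
#' neighbours; the main mode `"large_large"` uses adults on both sides.
#'
#' @param com An `"isar_community"`; stratified automatically when
#'   `size_class` is absent.
#' @param targets Character vector of target species, or `NULL` to select
#'   species with more than `min_abundance` adults.
#' @param mode `"large_large"` or `"large_small"`.
#' @param min_abundance Strict adult-abundance threshold for automatic
#'   target selection (default 50).
#' @inheritParams isar_test
#' @param verbose Print one progress line per species?
#' @return An object of class `"isar_analysis"`: list with `fits` (named
#'   list of `"isar_test"`), `classification` (with abundance ranks),
#'   `summary` (list `by_type`, `by_species`), `targets`, and parameters.
#' @export
isar_analysis <- function(com, targets = NULL,
                          model = c("homogeneous", "heterogeneous"),
                          mode = c("large_large", "large_small"),
                          min_abundance = 50, n_sim = 199, seed = 1L,
                          grid = 1:50, intervals = default_intervals(),
                          alpha = 0.05, bandwidth = 50, cell = 5,
                          envelope_k = 5, verbose = FALSE) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (!"size_class" %in% names(com)) com <- stratify_by_size(com)
  tab <- select_targets(com, min_abundance = min_abundance)
  if (!is.null(targets)) {
    tab <- tab[tab$species %in% targets, , drop = FALSE]
    missing_t <- setdiff(targets, tab$species)
    if (length(missing_t))
      warning("dropping requested targets below the abundance threshold: ",
              paste(missing_t, collapse = ", "))
  }
  if (!nrow(tab)) stop("no target species above the abundance threshold")
  neighbors <- if (mode == "large_large") "adults" else "saplings"
  fits <- vector("list", nrow(tab))
  names(fits) <- tab$species
  for (i in seq_len(nrow(tab))) {
    sp <- tab$species[i]
    t0 <- proc.time()[["elapsed"]]
    fits[[i]] <- isar_test(com, sp, model = model, n_sim = n_sim,
                           seed = seed, grid = grid, intervals = intervals,
                           alpha = alpha, neighbors = neighbors,
                           target_class = "adult", bandwidth = bandwidth,
                           cell = cell, envelope_k = envelope_k)
    if (verbose)
      message(sprintf("%s  model=%s n_sim=%d elapsed=%.2fs", sp, model,
                      n_sim, proc.time()[["elapsed"]] - t0))
  }
  cls <- do.call(rbind, lapply(fits, function(f) f$classification))
  cls$abundance_rank <- tab$rank[match(cls$species, tab$species)]
  cls <- cls[order(cls$abundance_rank, cls$interval), ]
  rownames(cls) <- NULL
  structure(list(fits = fits, classification = cls,
                 summary = summarize_classifications(cls),
                 targets = tab, model = model, mode = mode, n_sim = n_sim,
                 seed = seed, alpha = alpha, bandwidth = bandwidth),
            class = "isar_analysis")
}

#' @export
print.isar_analysis <- function(x, ...) {
  cat(sprintf("ISAR analysis: %d target species, %s Poisson null, mode %s, %d simulations\n",
              nrow(x$targets), x$model, x$mode, x$n_sim))
  print(x$summary$by_type, row.names = FALSE)
  invisible(x)
}

#' @export
summary.isar_analysis <- function(object, ...) object$summary

#' Plot the proportion of species types against neighbourhood distance
#'
#' The distance-profile display: one line per label giving, for each
#' distance interval, the proportion of target species carrying that label.
#'
#' @param x An `"isar_analysis"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.isar_analysis <- function(x, ...) {
  bt <- x$summary$by_type
  labs <- unname(label_sets[[x$model]])
  ivs <- unique(bt$interval)
  ivs <- ivs[order(as.numeric(sub("-.*", "", ivs)))]
  m <- sapply(labs, function(l)
    bt$proportion[match(paste(ivs, l), paste(bt$interval, bt$label))])
  graphics::matplot(seq_along(ivs), m, type = "b", pch = 1:3, lty = 1:3,
                    col = 1, xaxt = "n", ylim = c(0, 1),
                    xlab = "neighbourhood distance class (m)",
                    ylab = "proportion of species", ...)
  graphics::axis(1, at = seq_along(ivs), labels = ivs)
  graphics::legend("topright", legend = labs, pch = 1:3, lty = 1:3,
                   bty = "n")
  invisible(x)
}
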