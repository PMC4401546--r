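#' Default goodness-of-fit distance intervals
#'
#' The five intervals 1-10, 11-20, 21-30, 31-40 and 41-50 m over which
#' accumulated deviations are pooled; pooling over intervals is the device
#' that keeps Type I error inflation from per-radius multiple testing in
#' check.
#'
#' @return A list of `c(r_min, r_max)` pairs (metres, inclusive).
#' @export
default_intervals <- function() {
  list(c(1, 10), c(11, 20), c(21, 30), c(31, 40), c(41, 50))
}

interval_label <- function(interval) {
  sprintf("%g-%g", interval[1], interval[2])
}

interval_cols <- function(ensemble, interval) {
  if (interval[1] > interval[2]) stop("invalid interval")
  cols <- which(ensemble$radii >= interval[1] & ensemble$radii <= interval[2])
  if (!any(ensemble$radii == interval[1]) || !any(ensemble$radii == interval[2]))
    stop("interval endpoints must lie on the radius grid")
  cols
}

#' Pointwise simulation envelope of an ISAR ensemble
#'
#' Two-sided pointwise band from order statistics of the simulated curves:
#' at each radius the lower bound is the `k`-th smallest and the upper bound
#' the `k`-th largest simulated value (k = 5 of 199 simulations gives the
#' conventional 95% quantile band). Radii where the observed curve exits the
#' band are flagged.
#'
#' @param ensemble An `"isar_ensemble"`.
#' @param k Order-statistic rank (default 5).
#' @return An object of class `"isar_envelope"`: data frame with columns
#'   `r`, `observed`, `lower`, `upper`, `mean` (simulation mean), and
#'   `outside` (-1 below, 0 inside, +1 above), plus attribute `k`.
#' @export
pointwise_envelope <- function(ensemble, k = 5) {
  stopifnot(inherits(ensemble, "isar_ensemble"))
  sims <- ensemble$curves[-1L, , drop = FALSE]
  if (nrow(sims) < 2 * k)
    stop("too few simulations for order-statistic rank k = ", k)
  lower <- apply(sims, 2L, function(v) sort(v)[k])
  upper <- apply(sims, 2L, function(v) sort(v, decreasing = TRUE)[k])
  obs <- ensemble$curves[1L, ]
  out <- data.frame(r = ensemble$radii, observed = obs, lower = lower,
                    upper = upper, mean = colMeans(sims),
                    outside = ifelse(obs > upper, 1L,
                                     ifelse(obs < lower, -1L, 0L)))
  structure(out, k = k, species = ensemble$species, model = ensemble$model,
            class = c("isar_envelope", "data.frame"))
}

#' Accumulated squared deviation of one ensemble curve
#'
#' The goodness-of-fit statistic u_i: the squared deviation of curve i from
#' the mean of all other curves (leave-one-out ensemble mean), summed over
#' the radii of a distance interval. Index 0 is the observed curve,
#' 1..n_sim the simulations.
#'
#' @param i Curve index in `0:n_sim`.
#' @param ensemble An `"isar_ensemble"`.
#' @param interval `c(r_min, r_max)` in metres, both on the radius grid.
#' @return The scalar u_i (>= 0).
#' @export
gof_statistic <- function(i, ensemble, interval) {
  stopifnot(inherits(ensemble, "isar_ensemble"))
  if (i < 0 || i > ensemble$n_sim) stop("curve index out of range")
  cols <- interval_cols(ensemble, interval)
  H <- ensemble$curves[, cols, drop = FALSE]
  Hi <- H[i + 1L, ]
  Hbar <- (colSums(H) - Hi) / ensemble$n_sim
  sum((Hi - Hbar)^2)
}

# all u_i at once: leave-one-out means via the column totals
gof_statistics_all <- function(ensemble, interval) {
  cols <- interval_cols(ensemble, interval)
  H <- ensemble$curves[, cols, drop = FALSE]
  tot <- colSums(H)
  dev <- H - rep(tot, each = nrow(H)) / (nrow(H) - 1L) +
    H / (nrow(H) - 1L)   # H_i - (tot - H_i)/n_sim
  rowSums(dev^2)
}

#' Goodness-of-fit rank test over a distance interval
#'
#' Ranks the observed statistic u_0 among all n_sim + 1 accumulated
#' deviations (ascending). The departure is significant at level `alpha`
#' when the rank exceeds the critical rank `(1 - alpha) * (n_sim + 1)`
#' (190 for alpha = 0.05 with 199 simulations). Ties give the observed
#' statistic the smallest rank in its tie group, which is conservative.
#' Because u is sign-blind, the direction of a departure is the sign of the
#' raw deviation of the observed curve from the simulation mean summed over
#' the interval.
#'
#' @param ensemble An `"isar_ensemble"`.
#' @param interval `c(r_min, r_max)` in metres.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `"isar_gof"`: list with `interval`, `u0`,
#'   `u_sim`, `rank`, `critical_rank`, `alpha`, `significant`, `direction`
#'   (`"positive"`/`"negative"`), and `summed_deviation`.
#' @export
gof_rank_test <- function(ensemble, interval, alpha = 0.05) {
  stopifnot(inherits(ensemble, "isar_ensemble"))
  u <- gof_statistics_all(ensemble, interval)
  u0 <- u[1L]
  rank0 <- sum(u < u0) + 1L            # smallest rank within a tie group
  critical <- (1 - alpha) * (ensemble$n_sim + 1L)
  cols <- interval_cols(ensemble, interval)
  sims <- ensemble$curves[-1L, cols, drop = FALSE]
  sdev <- sum(ensemble$curves[1L, cols] - colMeans(sims))
  structure(list(interval = interval, u0 = u0, u_sim = u[-1L],
                 rank = rank0, critical_rank = critical, alpha = alpha,
                 significant = rank0 > critical,
                 direction = if (sdev >= 0) "positive" else "negative",
                 summed_deviation = sdev),
            class = "isar_gof")
}

#' @export
print.isar_gof <- function(x, ...) {
  cat(sprintf(
    "GoF rank test, interval %s m: u0 = %.4g, rank %d/%d (critical %g) -> %s%s\n",
    interval_label(x$interval), x$u0, x$rank, length(x$u_sim) + 1L,
    x$critical_rank,
    if (x$significant) "significant " else "not significant",
    if (x$significant) x$direction else ""))
  invisible(x)
}

label_sets <- list(
  homogeneous = c(positive = "positive", negative = "negative",
                  none = "none"),
  heterogeneous = c(positive = "accumulator", negative = "repeller",
                    none = "no_effect"))

#' Classify a species per distance interval from its GoF results
#'
#' Maps each interval's goodness-of-fit outcome to a label. Under the
#' homogeneous model a significant positive/negative departure means the
#' species sits in richer/poorer neighbourhoods than the plot-random
#' species-area baseline (`"positive"`/`"negative"`/`"none"`); under the
#' heterogeneous model, which discounts habitat association, a significant
#' departure is attributed to species interactions and labelled
#' `"accumulator"`/`"repeller"`, otherwise `"no_effect"`.
#'
#' @param gof_results A list of `"isar_gof"` objects, one per interval.
#' @param model `"homogeneous"` or `"heterogeneous"`.
#' @param species Optional species code carried into the output.
#' @return Data frame with columns `species`, `model`, `interval`, `label`,
#'   `u0`, `rank`, `significant`.
#' @export
classify_species <- function(gof_results,
                             model = c("homogeneous", "heterogeneous"),
                             species = NA_character_) {
  model <- match.arg(model)
  labs <- label_sets[[model]]
  rows <- lapply(gof_results, function(g) {
    stopifnot(inherits(g, "isar_gof"))
    lab <- if (!g$significant) labs[["none"]]
    else {
      if (g$summed_deviation == 0)
        stop("degenerate classification: significant departure with zero summed deviation")
      labs[[g$direction]]
    }
    data.frame(species = species, model = model,
               interval = interval_label(g$interval), label = lab,
               u0 = g$u0, rank = g$rank, significant = g$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise classifications across species
#'
#' Builds the two standard report tables: per (model, interval, label) the
#' species count and the proportion of target species (every label of the
#' model's label set is reported, including zero counts), and per species
#' the abundance rank alongside its per-interval labels.
#'
#' @param classifications Data frame as returned by [classify_species()]
#'   (row-bound over species), optionally with an `abundance_rank` column.
#' @return List with data frames `by_type` (model, interval, label, count,
#'   proportion) and `by_species` (one row per species x model, one column
#'   per interval), the latter `NULL` when no `abundance_rank` is present.
#' @export
summarize_classifications <- function(classifications) {
  stopifnot(nrow(classifications) >= 1)
  cl <- classifications
  by_type <- do.call(rbind, lapply(split(cl, list(cl$model, cl$interval),
                                         drop = TRUE), function(d) {
    labs <- unname(label_sets[[d$model[1]]])
    n <- vapply(labs, function(l) sum(d$label == l), integer(1))
    data.frame(model = d$model[1], interval = d$interval[1], label = labs,
               count = n, proportion = n / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(by_type) <- NULL
  by_type <- by_type[order(by_type$model, by_type$interval), ]
  by_species <- NULL
  if ("abundance_rank" %in% names(cl)) {
    wide <- stats::reshape(
      cl[c("species", "abundance_rank", "model", "interval", "label")],
      idvar = c("species", "abundance_rank", "model"),
      timevar = "interval", direction = "wide")
    names(wide) <- sub("^label\\.", "interval_", names(wide))
    by_species <- wide[order(wide$model, wide$abundance_rank), ]
    rownames(by_species) <- NULL
  }
  list(by_type = by_type, by_species = by_species)
}
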