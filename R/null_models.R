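#' Deterministic substream seeds
#'
#' Mixes a master seed with arbitrary integer labels (species hash,
#' simulation index, ...) into a single seed below 2^31, so that every
#' (species, simulation) pair has its own reproducible random substream and
#' evaluation order cannot change results.
#'
#' @param master Master seed (integer).
#' @param ... Further integer labels.
#' @return A single integer seed.
#' @keywords internal
substream_seed <- function(master, ...) {
  ks <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 0
  for (k in ks) h <- (h * 1664525 + k + 1013904223) %% 2147483629
  as.integer(h)
}

species_hash <- function(code) {
  v <- utf8ToInt(as.character(code))
  as.integer(sum(v * seq_along(v)) %% 1000003L)
}

#' Relocate a target species uniformly over the window
#'
#' The homogeneous Poisson null model: the individuals of the target species
#' are redistributed i.i.d. uniformly over the entire window while every
#' other stem stays exactly where it is. The relocated pattern is the
#' reference of the classical species-area relationship.
#'
#' Uses the current R random number stream; seed management for ensembles is
#' done by [run_null_ensemble()].
#'
#' @param com An `"isar_community"`.
#' @param t Target species code.
#' @param rows Optional integer row indices to relocate (default: every stem
#'   of species `t`); used by size-stratified analyses where only the adult
#'   individuals of `t` are targets.
#' @return The community with the selected stems moved.
#' @export
simulate_homogeneous <- function(com, t, rows = NULL) {
  stopifnot(inherits(com, "isar_community"))
  w <- attr(com, "window")
  if (is.null(rows)) rows <- which(com$species == t)
  if (!length(rows)) stop("target species not present: ", t)
  n <- length(rows)
  com$x[rows] <- stats::runif(n, w$x_min, w$x_max)
  com$y[rows] <- stats::runif(n, w$y_min, w$y_max)
  com
}

#' Kernel estimate of a species' spatially varying intensity
#'
#' Non-parametric intensity surface for the heterogeneous Poisson null
#' model: an Epanechnikov kernel (a distance-weighted moving window,
#' `k_R(d) = max(0, 1 - (d/R)^2)`) of radius `bandwidth` is summed over the
#' individual locations at the centres of a regular cell grid, then
#' renormalised so the surface mass inside the window equals the number of
#' points (no mass is lost at the borders). The bandwidth doubles as the
#' maximum redistribution radius of the null model: structure at scales
#' larger than `bandwidth` (habitat association) is preserved, structure
#' below it is smoothed away.
#'
#' @param target_points Data frame with columns `x`, `y` (at least one row).
#' @param window An [isar_window()].
#' @param bandwidth Kernel radius R in metres (default 50).
#' @param cell Requested cell size in metres (default 5); the actual size is
#'   adjusted so cells tile the window exactly.
#' @return An object of class `"isar_intensity"`: list with cell-centre
#'   coordinates `x`, `y`, intensity matrix `lambda` (rows = x cells,
#'   columns = y cells, per m^2), `cell_x`, `cell_y`, `bandwidth`, `kernel`,
#'   `n_t` and the window.
#' @export
estimate_intensity <- function(target_points, window, bandwidth = 50,
                               cell = 5) {
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive")
  n_t <- nrow(target_points)
  if (is.null(n_t) || n_t < 1) stop("need at least one target point")
  nx <- max(1L, round(window$width / cell))
  ny <- max(1L, round(window$height / cell))
  cell_x <- window$width / nx
  cell_y <- window$height / ny
  cx <- window$x_min + (seq_len(nx) - 0.5) * cell_x
  cy <- window$y_min + (seq_len(ny) - 0.5) * cell_y
  centers <- expand.grid(x = cx, y = cy)
  lam <- cpp_kernel_sum(centers$x, centers$y,
                        target_points$x, target_points$y, bandwidth)
  mass <- sum(lam) * cell_x * cell_y
  if (mass <= 0)
    stop("intensity surface has zero mass: bandwidth too small for the cell grid")
  lam <- lam * n_t / mass
  structure(list(x = cx, y = cy,
                 lambda = matrix(lam, nrow = nx, ncol = ny),
                 cell_x = cell_x, cell_y = cell_y,
                 bandwidth = bandwidth, kernel = "epanechnikov",
                 n_t = n_t, window = window),
            class = "isar_intensity")
}

#' @export
print.isar_intensity <- function(x, ...) {
  cat(sprintf(
    "kernel intensity surface: %d x %d cells (%.3g x %.3g m), %s kernel, R = %g m, mass = %g\n",
    length(x$x), length(x$y), x$cell_x, x$cell_y, x$kernel, x$bandwidth,
    sum(x$lambda) * x$cell_x * x$cell_y))
  invisible(x)
}

#' @export
plot.isar_intensity <- function(x, ...) {
  graphics::image(x$x, x$y, x$lambda, xlab = "x (m)", ylab = "y (m)",
                  asp = 1, col = grDevices::hcl.colors(64, "YlOrRd",
                                                      rev = TRUE), ...)
  invisible(x)
}

#' @export
as.data.frame.isar_intensity <- function(x, ...) {
  g <- expand.grid(x_cell = x$x, y_cell = x$y)
  g$lambda <- as.vector(x$lambda)
  g
}

#' Flat (constant) intensity surface
#'
#' A uniform surface with total mass `n_t`, under which the heterogeneous
#' null model statistically reduces to the homogeneous one; the limiting
#' case of [estimate_intensity()] as the bandwidth grows beyond the window.
#'
#' @param window An [isar_window()].
#' @param n_t Target abundance carried as the surface mass.
#' @param cell Requested cell size in metres (default 5).
#' @return An `"isar_intensity"`.
#' @export
flat_intensity <- function(window, n_t, cell = 5) {
  nx <- max(1L, round(window$width / cell))
  ny <- max(1L, round(window$height / cell))
  cell_x <- window$width / nx
  cell_y <- window$height / ny
  structure(list(x = window$x_min + (seq_len(nx) - 0.5) * cell_x,
                 y = window$y_min + (seq_len(ny) - 0.5) * cell_y,
                 lambda = matrix(n_t / window$area, nx, ny),
                 cell_x = cell_x, cell_y = cell_y,
                 bandwidth = Inf, kernel = "flat", n_t = n_t,
                 window = window),
            class = "isar_intensity")
}

# draw n points from a normalized intensity surface: cells with probability
# proportional to their mass, uniform position within the cell
sample_intensity <- function(surface, n) {
  p <- as.vector(surface$lambda)
  if (all(p <= 0)) stop("all-zero intensity surface")
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  nx <- length(surface$x)
  ix <- (idx - 1L) %% nx + 1L
  iy <- (idx - 1L) %/% nx + 1L
  list(x = surface$x[ix] + stats::runif(n, -0.5, 0.5) * surface$cell_x,
       y = surface$y[iy] + stats::runif(n, -0.5, 0.5) * surface$cell_y)
}

#' Relocate a target species according to its intensity surface
#'
#' The heterogeneous Poisson null model: target individuals are redrawn
#' independently with cell probabilities proportional to the kernel
#' intensity surface (uniform within a cell), conditioned on the observed
#' abundance. Large-scale habitat association encoded in the surface is
#' preserved; small-scale structure is randomised. All other stems stay
#' fixed.
#'
#' @inheritParams simulate_homogeneous
#' @param surface An `"isar_intensity"` built from the same target species.
#' @return The community with the selected stems moved.
#' @export
simulate_heterogeneous <- function(com, t, surface, rows = NULL) {
  stopifnot(inherits(com, "isar_community"), inherits(surface, "isar_intensity"))
  if (is.null(rows)) rows <- which(com$species == t)
  if (!length(rows)) stop("target species not present: ", t)
  pts <- sample_intensity(surface, length(rows))
  w <- attr(com, "window")
  com$x[rows] <- pmin(pmax(pts$x, w$x_min), w$x_max)
  com$y[rows] <- pmin(pmax(pts$y, w$y_min), w$y_max)
  com
}

# ISAR values for explicit target coordinates against a fixed heterospecific
# pool (the fast path used inside ensembles: non-target stems never move)
isar_values <- function(targets, pool, grid) {
  if (nrow(pool) == 0L) return(numeric(length(grid)))
  M <- min_dist_matrix(targets, pool)
  vapply(grid, function(r) sum(M <= r) / nrow(targets), numeric(1))
}

#' Monte Carlo ISAR ensemble under a null model
#'
#' Computes the observed ISAR curve of a target species and `n_sim`
#' simulated curves, each obtained by relocating the target individuals
#' under the chosen null model and recomputing the curve against the fixed
#' heterospecific neighbour pool. Every simulation index draws from its own
#' seed substream, so ensembles are bit-reproducible for a fixed master
#' seed regardless of evaluation order.
#'
#' @param com An `"isar_community"`.
#' @param t Target species code.
#' @param model `"homogeneous"` or `"heterogeneous"`.
#' @param n_sim Number of Monte Carlo simulations (default 199).
#' @param seed Master seed (integer).
#' @param grid Radii in metres (default `1:50`).
#' @param neighbors Neighbour pool rule: `"all"`, `"adults"` or
#'   `"saplings"` (see [neighbor_pool()]).
#' @param target_class Restrict the target individuals to one size class
#'   (`"adult"` or `"sapling"`); `NULL` uses every stem of `t`.
#' @param bandwidth,cell Kernel parameters for the heterogeneous model
#'   (defaults 50 m and 5 m); ignored for the homogeneous model.
#' @param surface Optional `"isar_intensity"` to use instead of estimating
#'   one from the target points (heterogeneous model only), e.g. a flat
#'   surface to study the reduction to the homogeneous model.
#' @return An object of class `"isar_ensemble"`: list with `curves` (a
#'   `(n_sim + 1) x length(grid)` matrix, row 1 = observed curve, rows
#'   2..n_sim+1 = simulations), `radii`, `species`, `model`, `n_sim`,
#'   `seed`, `n_t` and `n_pool_species`.
#' @export
run_null_ensemble <- function(com, t, model = c("homogeneous", "heterogeneous"),
                              n_sim = 199, seed = 1L, grid = 1:50,
                              neighbors = "all", target_class = NULL,
                              bandwidth = 50, cell = 5, surface = NULL) {
  model <- match.arg(model)
  check_grid(grid)
  stopifnot(n_sim >= 1)
  df <- as.data.frame(com)
  w <- attr(com, "window")
  tmask <- df$species == t
  if (!is.null(target_class)) {
    if (!"size_class" %in% names(df))
      stop("size_class not assigned; call stratify_by_size() first")
    tmask <- tmask & df$size_class == target_class
  }
  targets <- df[tmask, , drop = FALSE]
  if (nrow(targets) == 0L) stop("target species not present: ", t)
  pool <- neighbor_pool(com, neighbors)
  pool <- pool[pool$species != t, , drop = FALSE]

  curves <- matrix(NA_real_, nrow = n_sim + 1L, ncol = length(grid))
  curves[1L, ] <- isar_values(targets, pool, grid)
  if (model == "heterogeneous" && is.null(surface))
    surface <- estimate_intensity(targets, w, bandwidth = bandwidth,
                                  cell = cell)
  sh <- species_hash(t)
  n_t <- nrow(targets)
  for (i in seq_len(n_sim)) {
    set.seed(substream_seed(seed, sh, i))
    sim_targets <- if (model == "homogeneous") {
      list(x = stats::runif(n_t, w$x_min, w$x_max),
           y = stats::runif(n_t, w$y_min, w$y_max))
    } else {
      pts <- sample_intensity(surface, n_t)
      list(x = pmin(pmax(pts$x, w$x_min), w$x_max),
           y = pmin(pmax(pts$y, w$y_min), w$y_max))
    }
    curves[i + 1L, ] <- isar_values(as.data.frame(sim_targets), pool, grid)
  }
  structure(list(curves = curves, radii = grid, species = t, model = model,
                 n_sim = n_sim, seed = seed, n_t = n_t,
                 n_pool_species = length(unique(pool$species)),
                 bandwidth = if (model == "heterogeneous") bandwidth else NA_real_),
            class = "isar_ensemble")
}

#' @export
print.isar_ensemble <- function(x, ...) {
  cat(sprintf(
    "ISAR null ensemble: %s, %s model, n_t = %d, %d simulations + observed, r in [%g, %g] m\n",
    x$species, x$model, x$n_t, x$n_sim, min(x$radii), max(x$radii)))
  invisible(x)
}

#' @export
as.data.frame.isar_ensemble <- function(x, ...) {
  data.frame(sim_index = rep(0:x$n_sim, each = length(x$radii)),
             r = rep(x$radii, x$n_sim + 1L),
             isar = as.vector(t(x$curves)))
}
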