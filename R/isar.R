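#' Nearest-neighbour distribution function between two species
#'
#' Computes D_tj(r): the proportion of individuals of the target species
#' that have their nearest individual of species j within distance r
#' (closed disc, Euclidean distance in the plane, no edge correction).
#' An empty neighbour set gives D identically zero.
#'
#' @param target_points Data frame (or community subset) with columns
#'   `x`, `y` for the target individuals; must be non-empty.
#' @param neighbor_points Data frame with columns `x`, `y` for species j.
#' @param grid Numeric vector of strictly increasing radii in metres
#'   (default `1:50`).
#' @return Numeric vector of D values on `grid`, in `[0, 1]`,
#'   non-decreasing in r.
#' @export
nn_distribution <- function(target_points, neighbor_points, grid = 1:50) {
  check_grid(grid)
  if (nrow(target_points) == 0L)
    stop("empty target set: the proportion is undefined")
  if (nrow(neighbor_points) == 0L)
    return(stats::setNames(numeric(length(grid)), grid))
  M <- cpp_min_dist_by_group(target_points$x, target_points$y,
                             neighbor_points$x, neighbor_points$y,
                             rep(1L, nrow(neighbor_points)), 1L)
  vapply(grid, function(r) mean(M[, 1L] <= r), numeric(1))
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) == 0L || any(grid <= 0) ||
      any(diff(grid) <= 0))
    stop("radius grid must be strictly increasing and positive")
  invisible(grid)
}

# n_t x S matrix of distances from each target individual to the nearest
# individual of each pool species (Inf where the species is absent from the
# pool). Species are the factor levels of pool$species.
min_dist_matrix <- function(targets, pool) {
  sp <- factor(pool$species)
  M <- cpp_min_dist_by_group(targets$x, targets$y, pool$x, pool$y,
                             as.integer(sp), nlevels(sp))
  colnames(M) <- levels(sp)
  M
}

#' Select the neighbour pool for an ISAR analysis
#'
#' In the main ("large-large") analysis both targets and neighbours are
#' adults; in the size-stratified ("large-small") analysis adult targets are
#' paired with sapling neighbours. Conspecifics are excluded later by the
#' ISAR definition itself, not here.
#'
#' @param com An `"isar_community"`.
#' @param neighbors `"all"` (every stem), `"adults"`, or `"saplings"`.
#' @return The matching subset of `com`, plain data frame.
#' @export
neighbor_pool <- function(com, neighbors = c("all", "adults", "saplings")) {
  neighbors <- match.arg(neighbors)
  df <- as.data.frame(com)
  if (neighbors == "all") return(df)
  if (!"size_class" %in% names(df))
    stop("size_class not assigned; call stratify_by_size() first")
  want <- if (neighbors == "adults") "adult" else "sapling"
  df[df$size_class == want, , drop = FALSE]
}

#' Individual species-area relationship curve
#'
#' ISAR_t(r) is the mean number of species found within radius r of the
#' individuals of target species t, computed as the sum over all other
#' species j of the nearest-neighbour distribution functions D_tj(r).
#' Conspecifics never contribute. No edge correction is applied: focal
#' individuals near the border are retained, and the small bias this causes
#' is shared by the null-model simulations it is compared against.
#'
#' @param com An `"isar_community"` (or any data frame with `species`,
#'   `x`, `y`).
#' @param t Target species code; must be present in `com`.
#' @param grid Radii in metres (default `1:50`).
#' @param pool Data frame of stems that count as neighbours (default: every
#'   stem in `com`); see [neighbor_pool()]. Individuals of species `t` in
#'   the pool are ignored.
#' @return An object of class `"isar_curve"`: numeric vector of ISAR values
#'   on `grid`, with attributes `species`, `n_t` (number of target
#'   individuals) and `radii`.
#' @examples
#' com <- gen_csr_community(scenario_config(n_species = 5,
#'   abundance = 40, window = isar_window(0, 100, 0, 100), seed = 1))
#' isar_curve(com, t = "sp01", grid = 1:20)
#' @export
isar_curve <- function(com, t, grid = 1:50, pool = NULL) {
  check_grid(grid)
  df <- as.data.frame(com)
  targets <- df[df$species == t, , drop = FALSE]
  if (nrow(targets) == 0L) stop("target species not present: ", t)
  if (is.null(pool)) pool <- df
  pool <- pool[pool$species != t, , drop = FALSE]
  vals <- if (nrow(pool) == 0L) {
    numeric(length(grid))
  } else {
    # mean over target individuals of the number of species within r;
    # identical to sum_j D_tj(r). Counts are summed as integers and divided
    # once, so the result is exact.
    M <- min_dist_matrix(targets, pool)
    vapply(grid, function(r) sum(M <= r) / nrow(targets), numeric(1))
  }
  structure(vals, species = t, n_t = nrow(targets), radii = grid,
            class = "isar_curve")
}

#' @export
print.isar_curve <- function(x, ...) {
  cat(sprintf("ISAR curve for %s (n_t = %d), r in [%g, %g] m\n",
              attr(x, "species"), attr(x, "n_t"),
              min(attr(x, "radii")), max(attr(x, "radii"))))
  print(stats::setNames(as.numeric(x), attr(x, "radii")))
  invisible(x)
}

#' @export
as.data.frame.isar_curve <- function(x, ...) {
  data.frame(species = attr(x, "species"), r = attr(x, "radii"),
             isar = as.numeric(x), stringsAsFactors = FALSE)
}
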