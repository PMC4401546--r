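# Small fixture builders and independent brute-force oracles. The oracles
# deliberately use naive per-point loops and base R only, so they share no
# code path with the package internals they check.

toy_window <- function(s = 100) isar_window(0, s, 0, s)

make_community <- function(species, x, y, dbh = 5, window = toy_window()) {
  community(data.frame(stem_id = sprintf("t%03d", seq_along(x)),
                       species = species, x = x, y = y, dbh = dbh,
                       stringsAsFactors = FALSE),
            window)
}

# random marked community built straight from base R draws (not via the
# package generators), for oracle-equivalence checks
random_community <- function(n_stems, n_species, window = toy_window(),
                             seed = 1) {
  set.seed(seed)
  make_community(
    species = sprintf("sp%02d", sample.int(n_species, n_stems, replace = TRUE)),
    x = runif(n_stems, window$x_min, window$x_max),
    y = runif(n_stems, window$y_min, window$y_max),
    dbh = runif(n_stems, 1, 40),
    window = window)
}

# exhaustive all-pairs nearest-neighbour distribution D_tj(r)
oracle_nn <- function(targets, neighbors, grid) {
  nn <- vapply(seq_len(nrow(targets)), function(i)
    min(sqrt((neighbors$x - targets$x[i])^2 +
               (neighbors$y - targets$y[i])^2)), numeric(1))
  vapply(grid, function(r) mean(nn <= r), numeric(1))
}

# exhaustive per-disc census: for each target individual count the distinct
# heterospecific species with at least one stem within r, then average.
# Integer counts are summed and divided once, matching exact arithmetic.
oracle_isar <- function(com, t, grid, pool = NULL) {
  df <- as.data.frame(com)
  targets <- df[df$species == t, , drop = FALSE]
  if (is.null(pool)) pool <- df
  pool <- pool[pool$species != t, , drop = FALSE]
  vapply(grid, function(r) {
    counts <- vapply(seq_len(nrow(targets)), function(i) {
      d <- sqrt((pool$x - targets$x[i])^2 + (pool$y - targets$y[i])^2)
      length(unique(pool$species[d <= r]))
    }, integer(1))
    sum(counts) / nrow(targets)
  }, numeric(1))
}

# hand-rolled ensemble container for inference unit tests
fake_ensemble <- function(curves, radii = seq_len(ncol(curves)),
                          model = "homogeneous") {
  structure(list(curves = curves, radii = radii, species = "spX",
                 model = model, n_sim = nrow(curves) - 1L,
                 seed = 0L, n_t = 1L, n_pool_species = 1L,
                 bandwidth = NA_real_),
            class = "isar_ensemble")
}
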