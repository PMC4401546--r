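test_that("homogeneous relocation conserves counts and fixes non-targets", {
  com <- random_community(200, 5, seed = 2)
  set.seed(99)
  sim <- simulate_homogeneous(com, "sp02")
  expect_identical(sum(sim$species == "sp02"), sum(com$species == "sp02"))
  keep <- com$species != "sp02"
  expect_identical(sim$x[keep], com$x[keep])
  expect_identical(sim$y[keep], com$y[keep])
  moved <- sim$species == "sp02"
  expect_true(all(sim$x[moved] >= 0 & sim$x[moved] <= 100 &
                    sim$y[moved] >= 0 & sim$y[moved] <= 100))
})

test_that("homogeneous relocation is uniform over the window", {
  com <- make_community(rep(c("T", "O"), each = 20),
                        x = rep(1, 40), y = rep(1, 40))
  set.seed(7)
  counts <- matrix(0, 5, 5)
  for (i in 1:2000) {
    sim <- simulate_homogeneous(com, "T")
    ix <- pmin(5L, 1L + floor(sim$x[sim$species == "T"] / 20))
    iy <- pmin(5L, 1L + floor(sim$y[sim$species == "T"] / 20))
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("kernel intensity surface matches the explicit kernel-sum formula", {
  w <- toy_window(100)
  set.seed(4)
  pts <- data.frame(x = runif(12, 0, 100), y = runif(12, 0, 100))
  surf <- estimate_intensity(pts, w, bandwidth = 30, cell = 5)
  # probe several cells with a direct loop over points
  raw_at <- function(cx, cy) {
    s <- 0
    for (i in seq_len(nrow(pts))) {
      d <- sqrt((pts$x[i] - cx)^2 + (pts$y[i] - cy)^2)
      s <- s + max(0, 1 - (d / 30)^2)
    }
    s
  }
  raw_grid <- outer(surf$x, surf$y, Vectorize(raw_at))
  norm <- nrow(pts) / (sum(raw_grid) * surf$cell_x * surf$cell_y)
  for (probe in list(c(1, 1), c(10, 20), c(20, 10), c(7, 13))) {
    expect_equal(surf$lambda[probe[1], probe[2]],
                 raw_grid[probe[1], probe[2]] * norm, tolerance = 1e-12)
  }
  expect_error(estimate_intensity(pts, w, bandwidth = 0), "positive")
})

test_that("intensity surfaces conserve mass and peak at a single point", {
  w <- toy_window(100)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(c(1, 10, 200), 1)
    pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
    surf <- estimate_intensity(pts, w, bandwidth = sample(c(20, 50, 80), 1))
    mass <- sum(surf$lambda) * surf$cell_x * surf$cell_y
    expect_equal(mass, n, tolerance = 1e-9)
    expect_true(all(surf$lambda >= 0))
  }
  one <- estimate_intensity(data.frame(x = 42, y = 57), w, bandwidth = 25)
  peak <- which(one$lambda == max(one$lambda), arr.ind = TRUE)[1, ]
  expect_lt(abs(one$x[peak[1]] - 42), one$cell_x)
  expect_lt(abs(one$y[peak[2]] - 57), one$cell_y)
  expect_equal(sum(one$lambda) * one$cell_x * one$cell_y, 1, tolerance = 1e-9)
})

test_that("dense uniform points yield a nearly flat surface", {
  w <- toy_window(200)
  set.seed(8)
  pts <- data.frame(x = runif(10000, 0, 200), y = runif(10000, 0, 200))
  surf <- estimate_intensity(pts, w, bandwidth = 50, cell = 5)
  # interior cells: at least one bandwidth from every border
  ix <- surf$x > 50 & surf$x < 150
  iy <- surf$y > 50 & surf$y < 150
  lam <- surf$lambda[ix, iy]
  expect_lt(stats::sd(lam) / mean(lam), 0.2)
})

test_that("the intensity surface is stable under halving the cell size", {
  w <- toy_window(100)
  set.seed(19)
  pts <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  coarse <- estimate_intensity(pts, w, bandwidth = 50, cell = 5)
  fine <- estimate_intensity(pts, w, bandwidth = 50, cell = 2.5)
  # block-average the fine surface onto the coarse grid
  agg <- 0.25 * (fine$lambda[seq(1, 39, 2), seq(1, 39, 2)] +
                   fine$lambda[seq(2, 40, 2), seq(1, 39, 2)] +
                   fine$lambda[seq(1, 39, 2), seq(2, 40, 2)] +
                   fine$lambda[seq(2, 40, 2), seq(2, 40, 2)])
  expect_lt(mean(abs(agg - coarse$lambda)) / mean(coarse$lambda), 0.05)
})

test_that("heterogeneous relocation respects the surface support", {
  w <- toy_window(100)
  com <- random_community(150, 4, seed = 3)
  # all mass concentrated in the lower-left corner
  pts <- data.frame(x = runif(30, 0, 15), y = runif(30, 0, 15))
  surf <- estimate_intensity(pts, w, bandwidth = 10, cell = 5)
  expect_true(any(surf$lambda == 0))
  set.seed(12)
  for (i in 1:20) {
    sim <- simulate_heterogeneous(com, "sp01", surf)
    moved <- sim[sim$species == "sp01", ]
    expect_identical(nrow(moved), sum(com$species == "sp01"))
    # no point may land farther than bandwidth + cell diagonal from a source
    d <- vapply(seq_len(nrow(moved)), function(k)
      min(sqrt((pts$x - moved$x[k])^2 + (pts$y - moved$y[k])^2)), numeric(1))
    expect_true(all(d <= 10 + sqrt(2) * 5 + 1e-9))
  }
  keep <- com$species != "sp01"
  expect_identical(sim$x[keep], com$x[keep])
})

test_that("flat-surface relocation is indistinguishable from homogeneous", {
  w <- toy_window(100)
  com <- make_community(rep(c("T", "O"), each = 10),
                        x = rep(50, 20), y = rep(50, 20))
  surf <- flat_intensity(w, 10, cell = 5)
  set.seed(31)
  het_x <- het_y <- hom_x <- hom_y <- numeric(0)
  for (i in 1:250) {
    s1 <- simulate_heterogeneous(com, "T", surf)
    s2 <- simulate_homogeneous(com, "T")
    het_x <- c(het_x, s1$x[s1$species == "T"])
    het_y <- c(het_y, s1$y[s1$species == "T"])
    hom_x <- c(hom_x, s2$x[s2$species == "T"])
    hom_y <- c(hom_y, s2$y[s2$species == "T"])
  }
  expect_gt(stats::ks.test(het_x, hom_x)$p.value, 0.01)
  expect_gt(stats::ks.test(het_y, hom_y)$p.value, 0.01)
})

test_that("null ensembles are seed-deterministic with observed curve first", {
  com <- random_community(250, 6, seed = 14)
  e1 <- run_null_ensemble(com, "sp03", "homogeneous", n_sim = 199,
                          seed = 77, grid = 1:20)
  e2 <- run_null_ensemble(com, "sp03", "homogeneous", n_sim = 199,
                          seed = 77, grid = 1:20)
  expect_identical(e1$curves, e2$curves)
  expect_identical(dim(e1$curves), c(200L, 20L))
  expect_identical(e1$curves[1, ],
                   as.numeric(isar_curve(com, "sp03", 1:20)))

  e3 <- run_null_ensemble(com, "sp03", "homogeneous", n_sim = 199,
                          seed = 78, grid = 1:20)
  expect_false(identical(e1$curves[-1, ], e3$curves[-1, ]))

  eh1 <- run_null_ensemble(com, "sp03", "heterogeneous", n_sim = 39,
                           seed = 5, grid = 1:20)
  eh2 <- run_null_ensemble(com, "sp03", "heterogeneous", n_sim = 39,
                           seed = 5, grid = 1:20)
  expect_identical(eh1$curves, eh2$curves)
})
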