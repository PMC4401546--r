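test_that("pointwise envelope reproduces order statistics of the simulations", {
  # at one radius the 199 simulated values are exactly 1..199
  curves <- cbind(c(100, 1:199), c(50, rep(2, 199)))
  ens <- fake_ensemble(curves)
  env <- pointwise_envelope(ens, k = 5)
  expect_equal(env$lower[1], 5)
  expect_equal(env$upper[1], 195)
  expect_equal(env$lower[2], 2)
  expect_equal(env$upper[2], 2)
  expect_identical(env$outside, c(0L, 1L))

  # all simulated curves identical: band collapses onto that curve
  same <- fake_ensemble(rbind(c(3, 4), matrix(c(3, 4), 50, 2, byrow = TRUE)))
  env2 <- pointwise_envelope(same, k = 5)
  expect_equal(env2$lower, env2$upper)
  expect_identical(env2$outside, c(0L, 0L))

  # observed equal to the simulation mean everywhere: zero exit radii
  sims <- matrix(rnorm(199 * 4), 199, 4)
  env3 <- pointwise_envelope(fake_ensemble(rbind(colMeans(sims), sims)))
  expect_identical(env3$outside, rep(0L, 4))

  expect_error(pointwise_envelope(fake_ensemble(curves[1:8, ]), k = 5),
               "too few")
})

test_that("accumulated deviation uses the leave-one-out ensemble mean", {
  # three curves on a 2-point interval: A=(1,1), B=(2,2), C=(3,3)
  ens <- fake_ensemble(rbind(c(1, 1), c(2, 2), c(3, 3)), radii = 1:2)
  expect_equal(gof_statistic(0, ens, c(1, 2)), 4.5)  # 2 * (1 - 2.5)^2
  expect_equal(gof_statistic(1, ens, c(1, 2)), 0)    # B equals mean(A, C)
  expect_equal(gof_statistic(2, ens, c(1, 2)), 4.5)

  expect_error(gof_statistic(3, ens, c(1, 2)), "out of range")
  expect_error(gof_statistic(0, ens, c(1, 5)), "grid")
})

test_that("u statistics scale quadratically and match the slow route", {
  set.seed(6)
  curves <- matrix(rnorm(40 * 10, mean = 5), 40, 10)
  ens <- fake_ensemble(curves, radii = 1:10)
  iv <- c(3, 8)
  u <- vapply(0:39, gof_statistic, numeric(1), ensemble = ens, interval = iv)
  ens_scaled <- fake_ensemble(curves * 3, radii = 1:10)
  u_scaled <- vapply(0:39, gof_statistic, numeric(1),
                     ensemble = ens_scaled, interval = iv)
  expect_equal(u_scaled, 9 * u, tolerance = 1e-12)

  # permuting the other curves leaves u_0 unchanged
  perm <- fake_ensemble(curves[c(1, 1 + sample(39)), ], radii = 1:10)
  expect_equal(gof_statistic(0, perm, iv), u[1], tolerance = 1e-12)

  # rank-test internals agree with the one-at-a-time statistic
  gr <- gof_rank_test(ens, iv)
  expect_equal(gr$u0, u[1], tolerance = 1e-12)
  expect_equal(gr$u_sim, u[-1], tolerance = 1e-12)
})

test_that("rank test: critical rank, extremes, and conservative ties", {
  # u_0 strictly largest of 200
  sims <- matrix(rep(1:199, 2), 199, 2)           # u spread
  obs <- c(500, 500)
  ens <- fake_ensemble(rbind(obs, sims), radii = 1:2)
  res <- gof_rank_test(ens, c(1, 2), alpha = 0.05)
  expect_equal(res$critical_rank, 190)
  expect_equal(res$rank, 200L)
  expect_true(res$significant)
  expect_identical(res$direction, "positive")

  # observed curve at the simulation mean: u_0 minimal, rank 1
  sims2 <- matrix(c(rep(0, 199), rep(10, 199)), 199, 2)
  ens2 <- fake_ensemble(rbind(colMeans(sims2), sims2), radii = 1:2)
  res2 <- gof_rank_test(ens2, c(1, 2))
  expect_equal(res2$rank, 1L)
  expect_false(res2$significant)

  # all u tied: observed takes the smallest rank in the tie group
  ens3 <- fake_ensemble(matrix(rep(c(1, 2), each = 200), 200, 2), radii = 1:2)
  expect_equal(gof_rank_test(ens3, c(1, 2))$rank, 1L)

  # closed form (1 - alpha)(n_sim + 1) at other alpha
  expect_equal(gof_rank_test(ens, c(1, 2), alpha = 0.01)$critical_rank, 198)
})

test_that("classification maps GoF outcomes onto the model's label set", {
  ens <- fake_ensemble(rbind(c(500, 500), matrix(rep(1:199, 2), 199, 2)),
                       radii = 1:2)
  g_sig <- gof_rank_test(ens, c(1, 2))
  sims2 <- matrix(stats::rnorm(199 * 2), 199, 2)
  g_ns <- gof_rank_test(fake_ensemble(rbind(colMeans(sims2), sims2),
                                      radii = 1:2), c(1, 2))

  het <- classify_species(list(g_sig, g_ns), "heterogeneous", species = "T")
  expect_identical(het$label, c("accumulator", "no_effect"))
  hom <- classify_species(list(g_sig, g_ns), "homogeneous", species = "T")
  expect_identical(hom$label, c("positive", "none"))

  neg <- g_sig
  neg$summed_deviation <- -1
  neg$direction <- "negative"
  expect_identical(classify_species(list(neg), "heterogeneous")$label,
                   "repeller")

  degen <- g_sig
  degen$summed_deviation <- 0
  expect_error(classify_species(list(degen), "heterogeneous"), "degenerate")
})

test_that("summary tables report counts and proportions that normalise", {
  # 34 species, 16 accumulators / 6 repellers / 12 no-effect in one interval
  cls <- data.frame(
    species = sprintf("s%02d", 1:34), model = "heterogeneous",
    interval = "1-10",
    label = rep(c("accumulator", "repeller", "no_effect"), c(16, 6, 12)),
    u0 = 1, rank = 1, significant = FALSE,
    abundance_rank = 1:34, stringsAsFactors = FALSE)
  s <- summarize_classifications(cls)
  bt <- s$by_type
  expect_equal(bt$count[bt$label == "accumulator"], 16)
  expect_equal(bt$proportion[bt$label == "accumulator"], 16 / 34)
  expect_equal(round(bt$proportion[bt$label == "accumulator"], 2), 0.47)
  expect_equal(sum(bt$proportion), 1)
  expect_identical(s$by_species$species, sprintf("s%02d", 1:34))

  # single species, single interval: proportion 1 for its label
  one <- cls[1, ]
  s1 <- summarize_classifications(one)
  expect_equal(s1$by_type$proportion[s1$by_type$label == "accumulator"], 1)
  expect_equal(sum(s1$by_type$proportion), 1)
})
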