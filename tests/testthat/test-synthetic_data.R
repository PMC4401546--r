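test_that("CSR generator hits exact counts and is seed-deterministic", {
  cfg <- scenario_config(n_species = 10, abundance = 100,
                         window = toy_window(200), seed = 5)
  com <- gen_csr_community(cfg)
  expect_equal(nrow(com), 1000L)
  expect_true(all(table(com$species) == 100))
  expect_true(all(com$dbh >= 1))
  expect_true(all(com$size_class %in% c("adult", "sapling")))
  expect_identical(as.data.frame(gen_csr_community(cfg)),
                   as.data.frame(com))
  # a different seed moves the stems
  cfg2 <- scenario_config(n_species = 10, abundance = 100,
                          window = toy_window(200), seed = 6)
  expect_false(identical(gen_csr_community(cfg2)$x, com$x))
})

test_that("CSR coordinates pass a quadrat uniformity screen", {
  rejections <- 0L
  for (seed in 1:40) {
    cfg <- scenario_config(n_species = 2, abundance = 400,
                           window = toy_window(100), seed = seed)
    com <- gen_csr_community(cfg)
    one <- com[com$species == "sp01", ]
    counts <- table(factor(pmin(4, floor(one$x / 25)), levels = 0:3),
                    factor(pmin(4, floor(one$y / 25)), levels = 0:3))
    if (stats::chisq.test(as.vector(counts))$p.value <= 0.01)
      rejections <- rejections + 1L
  }
  # nominal 1% level: seeing >4 of 40 rejections would be wildly off
  expect_lte(rejections, 4L)
})

test_that("habitat generator reduces to CSR at beta 0 and follows gradients", {
  w <- toy_window(200)
  cfg0 <- scenario_config(n_species = 3, abundance = 300, window = w,
                          structure = "habitat", beta = 0, seed = 2)
  com0 <- gen_habitat_community(cfg0)
  expect_gt(stats::ks.test(com0$x, "punif", 0, 200)$p.value, 0.01)
  expect_gt(stats::ks.test(com0$y, "punif", 0, 200)$p.value, 0.01)

  # strong response to a one-sided gradient concentrates the species
  grad <- function(x, y) (x - 100) / 50
  cfg1 <- scenario_config(n_species = 1, abundance = 500, window = w,
                          structure = "habitat", beta = 4, seed = 3)
  com1 <- gen_habitat_community(cfg1, covariate_surface = grad)
  expect_gt(mean(com1$x > 100), 0.9)
})

test_that("interaction overlays change exactly the intended neighbourhood", {
  cfg <- scenario_config(n_species = 8, abundance = 80,
                         window = toy_window(200), seed = 9)
  com <- gen_csr_community(cfg)

  expect_identical(
    as.data.frame(gen_interaction_overlay(com, "sp01", "accumulator",
                                          strength = 0)),
    as.data.frame(com))

  acc <- gen_interaction_overlay(com, "sp01", "accumulator", d_int = 10,
                                 strength = 2, seed = 4)
  added <- acc[!(acc$stem_id %in% com$stem_id), ]
  expect_equal(nrow(acc) - nrow(com), round(2 * 80))
  expect_true(all(added$species != "sp01"))
  targets <- com[com$species == "sp01", ]
  near_t <- vapply(seq_len(nrow(added)), function(i)
    min(sqrt((targets$x - added$x[i])^2 + (targets$y - added$y[i])^2)),
    numeric(1))
  expect_true(all(near_t <= 10))
  # original stems untouched
  expect_identical(as.data.frame(acc[acc$stem_id %in% com$stem_id,
                                     , drop = FALSE]),
                   as.data.frame(com))

  rep1 <- gen_interaction_overlay(com, "sp01", "repeller", d_int = 10,
                                  strength = 1, seed = 4)
  kept_het <- rep1[rep1$species != "sp01", ]
  d_min <- vapply(seq_len(nrow(kept_het)), function(i)
    min(sqrt((targets$x - kept_het$x[i])^2 + (targets$y - kept_het$y[i])^2)),
    numeric(1))
  expect_true(all(d_min > 10))        # complete thinning inside d_int
  expect_identical(sum(rep1$species == "sp01"), sum(com$species == "sp01"))
  # removed stems were all within d_int of a target
  gone <- com[!(com$stem_id %in% rep1$stem_id), ]
  d_gone <- vapply(seq_len(nrow(gone)), function(i)
    min(sqrt((targets$x - gone$x[i])^2 + (targets$y - gone$y[i])^2)),
    numeric(1))
  expect_true(all(d_gone <= 10))

  expect_error(gen_interaction_overlay(com, "sp01", "repeller",
                                       strength = 1.5), "\\[0, 1\\]")
})

test_that("DBH marks recover the requested adult share", {
  cfg <- scenario_config(n_species = 4, abundance = 2500,
                         window = toy_window(300), adult_fraction = 0.16,
                         seed = 13)
  com <- gen_csr_community(cfg)
  expect_equal(nrow(com), 10000L)
  share <- mean(com$dbh > 10)
  expect_lt(abs(share - 0.16), 0.02)
  expect_true(all(com$dbh >= 1))
  expect_identical(gen_csr_community(cfg)$dbh, com$dbh)
})
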