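test_that("design closure: sown seeds equal the closed-form product", {
  cfg1 <- design_config(1)
  expect_equal(n_seeds_sown(cfg1), 17280L)
  lay1 <- simulate_design(cfg1)
  expect_equal(nrow(lay1), 8640L)            # positions = seeds / 2
  expect_equal(nrow(lay1) * cfg1$seeds_per_position, 17280L)

  cfg2 <- design_config(2)
  lay2 <- simulate_design(cfg2)
  expect_equal(nrow(lay2) * 2L, n_seeds_sown(cfg2))
  expect_equal(n_seeds_sown(cfg2), 5760L)    # 3*8*5*3*2*4*2

  tiny <- design_config(1, n_blocks = 1L, n_families = 1L,
                        treatments = "no_drought")
  expect_equal(n_seeds_sown(tiny), 32L)      # 2 row-plots * 8 * 2 seeds
  expect_error(design_config(1, n_blocks = 0L), "at least one block")
})

test_that("every family appears in every block-by-treatment cell", {
  lay <- simulate_design(design_config(1, n_families = 4L))
  tab <- table(lay$family, lay$block, lay$treatment)
  expect_true(all(tab == 2 * 8))             # row_plots * plot_size
})

test_that("emergence matches the configured rate and window", {
  set.seed(601)
  lay <- simulate_design(design_config(1))
  s <- simulate_emergence(lay, trait_config(1))
  rate <- attr(s, "n_emerged") / attr(s, "n_sown")
  se <- sqrt(0.588 * 0.412 / 17280)
  expect_lt(abs(rate - 0.588), 4 * se)
  expect_true(all(s$emergence_day >= 100 & s$emergence_day < 140))
  # occupied positions never exceed one seedling (culling)
  expect_lte(nrow(s), nrow(lay))

  s0 <- simulate_emergence(lay, trait_config(1, emergence_rate = 0))
  expect_equal(nrow(s0), 0L)
  expect_error(simulate_traits(s0, trait_config(1)), "no seedlings")
})

test_that("trait simulation respects family structure and configured ranges", {
  set.seed(602)
  sim <- simulate_experiment(1, seed = 602)
  d <- sim$data
  expect_true(all(d$seed_density >= 5.6 & d$seed_density <= 12.4))
  within_fam_var <- tapply(d$seed_density, d$family, function(v)
    diff(range(v)))
  expect_true(all(within_fam_var == 0))      # constant within family
})

test_that("a diagonal trait correlation gives near-zero sample correlations", {
  set.seed(603)
  sim <- simulate_experiment(
    1, traits = list(trait_cor = diag(4)), seed = 603)
  d <- sim$data[sim$data$surv_2009 == 1, ]   # rates expressed
  expect_gt(nrow(d), 4000)
  r <- cor(d[c("seed_density", "emergence_day", "early_rate",
               "late_rate")])
  off <- r[upper.tri(r)]
  expect_true(all(abs(off) < 0.1))
})

test_that("non-positive-semidefinite trait correlations are rejected", {
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9; bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(trait_config(1, trait_cor = bad), "positive semi-definite")
})

test_that("generated data are always aster-consistent with the invisible fraction masked", {
  for (seed in c(604, 605)) {
    sim <- simulate_experiment(1, config = list(n_families = 8,
                                                plot_size = 2),
                               seed = seed)
    v <- validate_records(sim$data, lh_graph("c"))
    expect_equal(v$n_violations, 0L)
    dead_y1 <- sim$data$surv_2009 == 0
    expect_true(all(is.na(sim$data$early_rate[dead_y1])))
    expect_true(all(!is.na(sim$data$early_rate[!dead_y1])))
  }
})

test_that("exports are deterministic under a fixed seed and round-trip losslessly", {
  dir1 <- tempfile(); dir2 <- tempfile()
  s1 <- simulate_experiment(1, config = list(n_families = 4,
                                             plot_size = 2), seed = 606)
  s2 <- simulate_experiment(1, config = list(n_families = 4,
                                             plot_size = 2), seed = 606)
  p1 <- export_dataset(s1$data, dir1)
  p2 <- export_dataset(s2$data, dir2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  export_truth(s1$truth, file.path(dir1, "truth.json"))

  rt <- read_records(p1[["wide"]], "wide")
  expect_equal(validate_records(rt, lh_graph("c"))$n_violations, 0L)
  rl <- read_records(p1[["long"]], "long")
  expect_equal(rl[names(rt)], rt, ignore_attr = TRUE)
})

test_that("outcome calibration: mortality concentrates in the emergence year", {
  set.seed(607)
  sim <- simulate_experiment(1, seed = 607)
  d <- sim$data
  share <- sum(d$surv_2009 == 0) / sum(d$surv_2011 == 0)
  expect_gt(share, 0.90)
  expect_lt(share, 0.97)
  mort <- mean(d$surv_2011 == 0)
  expect_gt(mort, 0.30); expect_lt(mort, 0.42)
})

test_that("a null truth with sure survival gives pure normal heights", {
  set.seed(608)
  tru0 <- list(surv1 = list(intercept = 30, treatment = c(
    mid_late_drought = 0, late_drought = 0, no_drought = 0),
    beta_emergence = 0, gamma_emergence = 0, beta_density = 0,
    gamma_density = 0),
    surv_later = list(intercept = 30, beta_emergence = 0,
                      gamma_emergence = 0, beta_density = 0,
                      gamma_density = 0),
    random = list(sd_block = 0, sd_family = 0, sd_rowplot = 0))
  sim <- simulate_experiment(1, config = list(n_families = 10,
                                              plot_size = 2),
                             truth = tru0, seed = 608)
  d <- sim$data
  expect_true(all(d$surv_2011 == 1))
  expect_gt(shapiro.test(sample(d$height_2011,
                                min(300, nrow(d))))$p.value, 0.001)
})

test_that("fixed-effect truth is recovered by the fit (round trip)", {
  sim <- simulate_experiment(1, config = list(plot_size = 2), seed = 609)
  d <- add_truth_z(sim$data, sim$truth)
  # per-node coefficients so the year-1 node is compared to the year-1
  # truth directly
  fit <- asterchain(~ treatment + z_emergence_day +
                      I(z_emergence_day^2) + z_seed_density, d,
                    lh_graph("a"), by_node = TRUE)
  cf <- fit$coefficients$surv
  se <- fit$se$surv
  tru <- sim$truth$surv1
  for (pair in list(c("surv_2009:z_emergence_day", "beta_emergence"),
                    c("surv_2009:I(z_emergence_day^2)",
                      "gamma_emergence"),
                    c("surv_2009:z_seed_density", "beta_density"))) {
    # 3 SE plus slack for the unmodelled block/family random effects
    expect_lt(abs(cf[[pair[1]]] - tru[[pair[2]]]),
              3 * se[[pair[1]]] + 0.05)
  }
})
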