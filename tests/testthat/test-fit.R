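test_that("intercept-only fits reproduce the closed-form node MLEs", {
  g <- lh_graph("a")
  n <- 100
  d <- data.frame(surv_2009 = rep(c(1, 0), c(80, 20)))
  d$surv_2010 <- d$surv_2009 * rep(c(1, 0), c(72, 28))[seq_len(n)]
  d$surv_2011 <- d$surv_2010
  fit <- suppressWarnings(asterchain(~1, d, g))
  p <- plogis(fit$coefficients$surv)
  expect_equal(unname(p["surv_2009"]), 0.8, tolerance = 1e-7)
  expect_equal(unname(p["surv_2010"]), 72 / 80, tolerance = 1e-7)
  expect_equal(fit$df, 3L)

  gc <- lh_graph("c")
  set.seed(9)
  d$height_2011 <- ifelse(d$surv_2011 == 1, rnorm(n, 250, 40), 0)
  fitc <- suppressWarnings(asterchain(~1, d, gc))
  surv_h <- d$height_2011[d$surv_2011 == 1]
  expect_equal(unname(fitc$coefficients$height), mean(surv_h),
               tolerance = 1e-9)
  expect_equal(fitc$sigma2,
               mean((surv_h - mean(surv_h))^2), tolerance = 1e-9)
})

test_that("a single-node fit matches glm (independent IRLS oracle)", {
  set.seed(21)
  d <- sim_logistic(400, 0.3, -0.6, 0.2)
  fit <- asterchain(~ x + I(x^2), d, one_node_graph())
  ref <- glm(surv ~ x + I(x^2), binomial, d)
  expect_equal(unname(fit$coefficients$surv),
               unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se$surv),
               unname(coef(summary(ref))[, 2]), tolerance = 1e-5)
})

test_that("parameter recovery: synthetic logistic truth within 3 MC SEs at n = 2000", {
  set.seed(31)
  truth <- c(0.5, -0.4, -0.15)
  reps <- 30
  est <- replicate(reps, {
    d <- sim_logistic(2000, truth[1], truth[2], truth[3])
    asterchain(~ x + I(x^2), d, one_node_graph())$coefficients$surv
  })
  bias <- rowMeans(est) - truth
  mcse <- apply(est, 1, sd) / sqrt(reps)
  expect_true(all(abs(bias) <= 3 * mcse))
})

test_that("adding terms never decreases the maximized log-likelihood", {
  set.seed(41)
  g <- lh_graph("c")
  sim <- simulate_experiment(1, config = list(n_families = 8,
                                              plot_size = 2), seed = 41)
  d <- add_truth_z(sim$data, sim$truth)
  terms <- c("treatment", "z_emergence_day", "I(z_emergence_day^2)",
             "z_seed_density")
  prev <- asterchain(~1, d, g)
  for (k in seq_along(terms)) {
    f <- as.formula(paste("~", paste(terms[1:k], collapse = "+")))
    cur <- asterchain(f, d, g)
    expect_gte(cur$loglik, prev$loglik - 1e-6)
    prev <- cur
  }
})

test_that("saturated group fits reproduce empirical group means", {
  set.seed(51)
  g <- lh_graph("c")
  d <- random_toy_records(300, g)
  d$grp <- factor(sample(c("g1", "g2", "g3"), 300, TRUE))
  fit <- suppressWarnings(asterchain(~grp, d, g, by_node = TRUE))
  nd <- data.frame(grp = factor(c("g1", "g2", "g3")))
  # survival through the chain equals the empirical survivor fraction
  p_hat <- predict(fit, nd, type = "survival")
  emp_surv <- tapply(d$surv_2011, d$grp, mean)
  expect_equal(as.numeric(p_hat), as.numeric(emp_surv),
               tolerance = 1e-7)
  # unconditional height equals the group mean of height x survival
  uh <- predict(fit, nd, type = "uncond_height")
  emp_uh <- tapply(d$height_2011 * d$surv_2011, d$grp, mean)
  expect_equal(as.numeric(uh), as.numeric(emp_uh), tolerance = 1e-8)
})

test_that("aliased columns are dropped with a warning and df counts retained columns", {
  set.seed(61)
  d <- sim_logistic(200, 0, 0.5)
  d$x2 <- d$x  # exact copy: aliased
  expect_warning(fit <- asterchain(~ x + x2, d, one_node_graph()),
                 "aliased")
  expect_equal(fit$df, 2L)
  expect_true(is.na(fit$coefficients$surv[["x2"]]))
})

test_that("separation is flagged, not silent", {
  d <- data.frame(surv = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(-1, 20), rep(1, 20)))
  expect_warning(fit <- asterchain(~x, d, one_node_graph()),
                 "separation")
  expect_true(fit$flags$separation)
})

test_that("model df matches the per-node-intercepts plus shared-terms layout", {
  set.seed(71)
  sim <- simulate_experiment(1, config = list(n_families = 6,
                                              plot_size = 2), seed = 71)
  d <- add_truth_z(sim$data, sim$truth)
  # survival graph (3 nodes): 3 intercepts + 2 treatment + 1 + 1 = 7
  fit <- asterchain(~ treatment + z_emergence_day + z_seed_density, d,
                    lh_graph("a"))
  expect_equal(fit$df, 7L)
  expect_equal(asterchain(~1, d, lh_graph("a"))$df, 3L)
  expect_equal(asterchain(~1, subset_cohort(d, "from_2010"),
                          lh_graph("b"))$df, 2L)
})
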