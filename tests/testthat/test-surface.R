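test_that("surface grid values equal direct predict calls exactly", {
  set.seed(501)
  sim <- simulate_experiment(1, config = list(n_families = 8,
                                              plot_size = 2), seed = 501)
  d <- standardize_traits(sim$data, c("emergence_day", "seed_density"))
  fit <- asterchain(~ z_emergence_day + I(z_emergence_day^2) +
                      z_seed_density, d, lh_graph("c"))
  fs <- fitness_surface(fit, "emergence_day", "seed_density", data = d,
                        grid_size = 7)
  sc <- attr(d, "trait_scaling")
  ref <- asterchain:::reference_row(fit, d)
  for (i in c(1, 4, 7)) for (j in c(2, 5)) {
    nd <- ref
    nd$z_emergence_day <- (fs$x[i] - sc$center[1]) / sc$scale[1]
    nd$z_seed_density <- (fs$y[j] - sc$center[2]) / sc$scale[2]
    # matrix-product association differs between the 625-row grid and
    # a 1-row newdata, so equality holds to machine precision
    expect_equal(fs$z[i, j],
                 unname(predict(fit, nd, type = "uncond_height")),
                 tolerance = 1e-12)
  }
  expect_equal(range(fs$x), range(d$emergence_day))
  expect_true(all(fs$z >= 0))
  expect_true(all(fs$points$count >= 1))
})

test_that("requesting an absent trait errors unless a flat surface is allowed", {
  set.seed(502)
  d <- sim_logistic(150, 0.3, 0.4)
  d$other <- rnorm(150)
  fit <- asterchain(~x, d, one_node_graph())
  expect_error(fitness_surface(fit, "x", "other", data = d),
               "absent from the fitted model")
  fs <- fitness_surface(fit, "other", "x", data = d, grid_size = 5,
                        allow_flat = TRUE)
  # flat along the absent axis, and probabilities stay in [0,1]
  expect_equal(max(apply(fs$z, 2, function(col) diff(range(col)))), 0)
  expect_true(all(fs$z >= 0 & fs$z <= 1))
})

test_that("an intercept-only model yields a constant surface", {
  set.seed(503)
  d <- sim_logistic(100, 0.4, 0)
  d$y2 <- rnorm(100)
  fit <- asterchain(~1, d, one_node_graph())
  fs <- fitness_surface(fit, "x", "y2", data = d, grid_size = 5,
                        allow_flat = TRUE)
  expect_equal(diff(range(fs$z)), 0)
})

test_that("a linear-only model is monotone along its trait axis", {
  set.seed(504)
  d <- sim_logistic(800, 0.2, 0.8)
  d$noise <- rnorm(800)
  fit <- asterchain(~x, d, one_node_graph())
  fs <- fitness_surface(fit, "x", "noise", data = d, grid_size = 9,
                        allow_flat = TRUE)
  for (j in seq_along(fs$y)) {
    expect_true(all(diff(fs$z[, j]) > 0))
  }
})

test_that("classification follows the gradient-sign rules", {
  set.seed(505)
  # directional negative: strong negative beta, no curvature
  d1 <- sim_logistic(4000, 0.5, -0.8)
  d1 <- standardize_traits(transform(d1, t = x * 3 + 115), "t")
  sw1 <- forward_stepwise(d1, one_node_graph(), candidate_terms("t"))
  c1 <- classify_selection(sw1, "t", data = d1)
  expect_equal(c1$classification, "directional_negative")
  expect_true(is.na(c1$optimum))

  # stabilizing: negative quadratic with interior optimum (z* = -1)
  d2 <- sim_logistic(4000, 0.8, -0.6, -0.3)
  d2 <- standardize_traits(transform(d2, t = x * 3 + 115), "t")
  sw2 <- forward_stepwise(d2, one_node_graph(), candidate_terms("t"))
  c2 <- classify_selection(sw2, "t", data = d2)
  expect_equal(c2$classification, "stabilizing")
  # closed-form optimum -beta/(2c) in trait units, near z = -1
  expect_lt(abs(c2$optimum_z - (-1)), 0.35)
  expect_equal(c2$optimum, mean(d2$t) + sd(d2$t) * c2$optimum_z,
               tolerance = 1e-6)

  # disruptive: positive quadratic, interior minimum.  A pure-quadratic
  # truth has no linear signal for the marginality-respecting stepwise
  # to enter on, so classify a directly specified fit.
  d3 <- sim_logistic(4000, -0.3, 0, 0.5)
  d3 <- standardize_traits(transform(d3, t = x), "t")
  fit3 <- asterchain(~ z_t + I(z_t^2), d3, one_node_graph())
  c3 <- classify_selection(fit3, "t", data = d3)
  expect_equal(c3$classification, "disruptive")

  # none: no effect at all
  d4 <- sim_logistic(500, 0.3, 0)
  d4 <- standardize_traits(transform(d4, t = x), "t")
  sw4 <- forward_stepwise(d4, one_node_graph(), candidate_terms("t"))
  c4 <- classify_selection(sw4, "t", data = d4)
  expect_equal(c4$classification, "none")
})

test_that("selection gradients report the doubled quadratic convention", {
  set.seed(506)
  d <- sim_logistic(2000, 0.5, -0.4, -0.2)
  d$z_t <- d$x
  fit <- asterchain(~ z_t + I(z_t^2), d, one_node_graph())
  g <- selection_gradients(fit)
  quad <- g[g$type == "quadratic", ]
  expect_equal(quad$gradient, 2 * quad$estimate)
  lin <- g[g$type == "linear", ]
  expect_equal(lin$gradient, lin$estimate)
})
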