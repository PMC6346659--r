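test_that("two traits with no exclusions enumerate the full gradient term set", {
  cand <- candidate_terms(c("a", "b"))
  expect_setequal(cand$term,
                  c("z_a", "z_b", "I(z_a^2)", "I(z_b^2)", "z_a:z_b"))
  expect_equal(cand$requires[cand$term == "I(z_a^2)"], "z_a")
  expect_equal(cand$requires[cand$term == "z_a:z_b"],
               "I(z_a^2),I(z_b^2)")
  # mains come before quadratics before cross-products
  expect_lt(which(cand$term == "z_b"), which(cand$term == "I(z_a^2)"))
  expect_lt(which(cand$term == "I(z_b^2)"),
            which(cand$term == "z_a:z_b"))
})

test_that("screened-out pairs lose their cross-product and cannot co-enter", {
  d <- data.frame(surv_2011 = 1, a = 1:20, b = (1:20) * 2 + 0.001,
                  c = rnorm(20))
  s <- screen_traits(d, c("a", "b", "c"))
  cand <- candidate_terms(c("a", "b", "c"), screen = s)
  expect_false("z_a:z_b" %in% cand$term)
  expect_true("z_a:z_c" %in% cand$term)
  expect_equal(cand$conflicts[cand$term == "z_a"], "z_b")
  expect_equal(cand$conflicts[cand$term == "z_b"], "z_a")
})

test_that("a single candidate above alpha leaves the model unchanged", {
  set.seed(401)
  d <- sim_logistic(300, 0.3, 0)   # x unrelated to survival
  d$z_x <- as.numeric(scale(d$x))
  cand <- candidate_terms("x", quadratics = FALSE,
                          cross_products = FALSE)
  sw <- forward_stepwise(d, one_node_graph(), cand)
  expect_length(sw$retained, 0L)
  expect_equal(sw$ledger$action[1], "start")
  expect_true("not_retained" %in% sw$ledger$action)
})

test_that("stepwise retains planted effects and honors marginality", {
  set.seed(402)
  n <- 3000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 0.6 - 0.5 * x1 - 0.4 * x1^2 + 0.3 * x2
  d <- data.frame(surv = rbinom(n, 1, plogis(eta)),
                  t1 = x1 * 4 + 110, t2 = x2 * 2 + 9)
  d <- standardize_traits(d, c("t1", "t2"))
  names(d)[1] <- "surv"
  cand <- candidate_terms(c("t1", "t2"))
  sw <- forward_stepwise(d, one_node_graph(), cand)
  expect_true(all(c("z_t1", "I(z_t1^2)", "z_t2") %in% sw$retained))
  # marginality: the quadratic enters after its linear
  expect_lt(match("z_t1", sw$retained), match("I(z_t1^2)", sw$retained))
  # any retained cross-product would require both quadratics
  if ("z_t1:z_t2" %in% sw$retained) {
    expect_true(all(c("I(z_t1^2)", "I(z_t2^2)") %in% sw$retained))
  }
  # ledger rows are a coherent nested sequence
  added <- sw$ledger[sw$ledger$action == "added", ]
  expect_true(all(diff(added$model_deviance) < 0))
  expect_true(all(added$p_value < 0.05))
})

test_that("correlated-pair conflicts propagate into the retained model", {
  set.seed(403)
  n <- 1500
  a <- rnorm(n)
  b <- a + rnorm(n, 0, 0.05)   # rank correlation ~ 1
  eta <- 0.4 - 0.6 * a
  d <- data.frame(surv = rbinom(n, 1, plogis(eta)),
                  surv_2011 = NA, a = a, b = b, c = rnorm(n))
  d$surv_2011 <- d$surv
  d <- standardize_traits(d, c("a", "b", "c"))
  s <- screen_traits(d, c("a", "b", "c"))
  cand <- candidate_terms(c("a", "b", "c"), screen = s)
  sw <- forward_stepwise(d, one_node_graph(), cand)
  expect_false(all(c("z_a", "z_b") %in% sw$retained))
  expect_false("z_a:z_b" %in% sw$retained)
})

test_that("with no mortality, height-block stepwise equals ordinary least-squares selection", {
  set.seed(404)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(surv_2009 = 1, surv_2010 = 1, surv_2011 = 1,
                  height_2011 = 250 + 20 * x1 - 8 * x1^2 + rnorm(n, 0, 30),
                  t1 = x1, t2 = x2)
  d <- standardize_traits(d, c("t1", "t2"))
  cand <- candidate_terms(c("t1", "t2"))
  sw <- suppressWarnings(
    forward_stepwise(d, lh_graph("c"), cand, blocks = "height"))

  # independent oracle: the same forward selection with plain lm/ML
  current <- character(0)
  retained_lm <- character(0)
  ll <- function(terms) {
    f <- if (length(terms))
      as.formula(paste("height_2011 ~", paste(terms, collapse = "+")))
      else height_2011 ~ 1
    as.numeric(logLik(lm(f, d)))
  }
  repeat {
    avail <- cand$term[!cand$term %in% current]
    ps <- sapply(avail, function(tm) {
      req <- strsplit(cand$requires[cand$term == tm], ",")[[1]]
      req <- req[nzchar(req)]
      if (!all(req %in% current)) return(NA_real_)
      stat <- 2 * (ll(c(current, tm)) - ll(current))
      pchisq(max(stat, 0), 1, lower.tail = FALSE)
    })
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= 0.05) break
    pick <- avail[which.min(ps)]
    current <- c(current, pick)
  }
  expect_identical(sw$retained, current)
  # per-step statistics agree with the lm oracle
  added <- sw$ledger[sw$ledger$action == "added", ]
  for (k in seq_len(nrow(added))) {
    stat_lm <- 2 * (ll(current[1:k]) - ll(current[seq_len(k - 1)]))
    dev_drop <- -diff(sw$ledger$model_deviance[k:(k + 1)])
    expect_equal(dev_drop, stat_lm, tolerance = 1e-6)
  }
})

test_that("density selection shows in the from-2009 window, not from 2010", {
  sim <- simulate_experiment(1, config = list(plot_size = 2), seed = 405)
  d <- add_truth_z(sim$data, sim$truth)
  cand <- candidate_terms("seed_density")
  sw09 <- forward_stepwise(d, lh_graph("a"), cand, blocks = "surv")
  d10 <- subset_cohort(d, "from_2010")
  sw10 <- forward_stepwise(d10, lh_graph("b"), cand, blocks = "surv")
  expect_true("z_seed_density" %in% sw09$retained)
  expect_false("z_seed_density" %in% sw10$retained)
})

test_that("the factor-model ladder has the expected structure", {
  sim <- simulate_experiment(1, config = list(n_families = 6,
                                              plot_size = 2), seed = 406)
  d <- sim$data
  tab <- fit_factor_models(d, lh_graph("a"),
                           factors = c("treatment", "family"))
  expect_equal(tab$terms,
               c("treatment + family", "treatment", "family",
                 "treatment:family", "Null"))
  head_df <- tab$model_df[1]
  null_df <- tab$model_df[tab$terms == "Null"]
  # 2 treatment contrasts + 5 family contrasts added over the null
  expect_equal(head_df - null_df, 7L)
  expect_equal(tab$test_df[1], 7L)
  expect_true(all(na.omit(tab$p_value) >= 0 & na.omit(tab$p_value) <= 1))
  expect_warning(
    fit_factor_models(cbind(d, one = "x"), lh_graph("a"),
                      factors = c("treatment", "one"),
                      interaction = FALSE),
    "single-level")
})

test_that("a true treatment effect is detected by the ladder", {
  # full default design (~7000 seedlings) so the 2-df treatment test
  # has near-certain power at the generator's stated effect sizes
  sim <- simulate_experiment(1, seed = 407)
  tab <- fit_factor_models(sim$data, lh_graph("a"),
                           factors = c("treatment"), interaction = FALSE)
  expect_lt(tab$p_value[1], 0.05)   # head model vs null
})
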