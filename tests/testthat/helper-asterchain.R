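# shared fixtures and independent oracles, all built in code

# Brute-force per-record, per-node log-likelihood: an implementation
# independent of aster_loglik / the stacked fit (explicit loops,
# dbinom/dnorm), used as the oracle for likelihood equality.
oracle_loglik <- function(data, graph, pars) {
  total <- 0
  for (i in seq_len(nrow(data))) {
    for (j in seq_len(nrow(graph))) {
      id <- graph$id[j]
      pred <- graph$pred[j]
      if (!is.na(pred) && data[[pred]][i] == 0) next  # degenerate
      y <- data[[id]][i]
      pj <- pars[[id]]
      if (graph$family[j] == "bernoulli") {
        p <- rep_len(pj$p, nrow(data))[i]
        total <- total + dbinom(y, 1, p, log = TRUE)
      } else {
        mu <- rep_len(pj$mean, nrow(data))[i]
        total <- total + dnorm(y, mu, sqrt(pj$sigma2), log = TRUE)
      }
    }
  }
  total
}

# random aster-consistent toy dataset on a given graph preset
random_toy_records <- function(n, graph) {
  d <- data.frame(row.names = seq_len(n))
  alive <- rep(1L, n)
  for (j in seq_len(nrow(graph))) {
    id <- graph$id[j]
    if (graph$family[j] == "bernoulli") {
      y <- rbinom(n, 1L, runif(1, 0.3, 0.9)) * alive
      d[[id]] <- y
      alive <- y
    } else {
      d[[id]] <- ifelse(alive == 1, abs(rnorm(n, 200, 50)), 0)
    }
  }
  d
}

# random valid node parameters for a graph
random_node_pars <- function(n, graph) {
  pars <- list()
  for (j in seq_len(nrow(graph))) {
    id <- graph$id[j]
    pars[[id]] <- if (graph$family[j] == "bernoulli") {
      list(p = runif(n, 0.05, 0.95))
    } else {
      list(mean = rnorm(n, 200, 30), sigma2 = runif(1, 100, 5000))
    }
  }
  pars
}

# single-Bernoulli-node graph (a chain of length one)
one_node_graph <- function(id = "surv") {
  lh_graph(nodes = data.frame(id = id, family = "bernoulli", pred = NA))
}

# logistic data on the one-node graph with known coefficients
sim_logistic <- function(n, beta0, beta_x, gamma_x = 0) {
  x <- rnorm(n)
  eta <- beta0 + beta_x * x + gamma_x * x^2
  data.frame(surv = rbinom(n, 1L, plogis(eta)), x = x)
}

# truth-referenced standardized trait columns, so estimates are
# comparable to the generator's coefficients scale
add_truth_z <- function(data, truth) {
  for (t in c("emergence_day", "seed_density", "early_rate",
              "late_rate")) {
    if (t %in% names(data)) {
      r <- truth$ref[[t]]
      data[[paste0("z_", t)]] <- (data[[t]] - r[["center"]]) / r[["scale"]]
    }
  }
  data
}
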