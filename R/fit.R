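#' Fit an aster chain life-history model
#'
#' Maximum-likelihood fit of a chain aster model: annual survival
#' indicators as Bernoulli nodes conditioned on the previous year's
#' survival and (for graphs `"c"`/`"d"`) final height as a terminal
#' normal node conditioned on survival.  Linear predictors act on the
#' conditional canonical scale — logit for Bernoulli nodes, the mean for
#' the normal node.
#'
#' The model has a per-node intercept for every node.  Covariate terms in
#' `formula` receive one shared coefficient across all Bernoulli nodes
#' (so e.g. a treatment contrast shifts every year's conditional survival
#' logit equally), unless `by_node = TRUE`, in which case every Bernoulli
#' node gets its own coefficient for every term (the saturated-by-node
#' layout).  The normal height node has its own coefficient block, given
#' by `height_formula` (default: the same right-hand side), on the mm
#' scale; its dispersion `sigma2` is estimated by maximum likelihood.
#'
#' Under this conditional parameterization the joint likelihood separates
#' into a stacked Bernoulli regression over (node, at-risk individual)
#' pairs plus a normal regression over terminal survivors, so the MLE is
#' computed exactly by iteratively reweighted least squares; no general
#' optimizer is involved.  With `random` groupings a Laplace-approximate
#' integrated likelihood is maximized instead (see Details).
#'
#' @details
#' Random intercepts (`random`) are shared across all nodes of an
#' individual, entering each node's conditional canonical parameter with
#' loading 1.  The marginal likelihood is approximated by the Laplace
#' method: an inner Newton iteration finds the joint mode of the random
#' effects, and the outer optimization (BFGS) maximizes the Laplace
#' objective over fixed effects and the variance components (on the log
#' standard-deviation scale, so components are constrained non-negative).
#' A component estimated below `1e-3` on the standard-deviation scale is
#' flagged `boundary` and reported as negligible.  One-tailed p-values
#' for variance components come from drop-one refits and the 50:50
#' mixture of chi-square(0) and chi-square(1) reference appropriate at a
#' boundary.
#'
#' @param formula One-sided formula of fixed-effect terms for the
#'   survival nodes, e.g. `~ treatment + z_emergence_day +
#'   I(z_emergence_day^2)`.  A two-sided formula has its left-hand side
#'   ignored.
#' @param data Wide records, one row per individual, containing every
#'   graph node column and every model covariate.
#' @param graph An [lh_graph()] (default preset `"c"`).
#' @param height_formula Fixed-effect terms for the normal node; defaults
#'   to `formula`.
#' @param random Character vector of grouping column names (e.g.
#'   `c("block", "family")`) for random intercepts; `NULL` for a pure
#'   fixed-effects fit.
#' @param by_node Logical; give every Bernoulli node its own covariate
#'   coefficients (default `FALSE`: shared).
#' @param test_components Logical; compute boundary likelihood-ratio
#'   p-values for each variance component by drop-one refits (default
#'   `TRUE`; set `FALSE` to skip the extra fits in simulation loops).
#' @param control List of numerical controls: `reltol` (outer BFGS
#'   relative tolerance, default `1e-10`), `inner_tol` (inner Newton
#'   gradient tolerance, default `1e-9`), `maxit` (outer iterations,
#'   default `500`), `hessian` (set `FALSE` to skip the numerical
#'   observed-information matrix — no standard errors — in simulation
#'   loops).
#' @return An object of class `asterchain` with components including
#'   `coefficients` (list `surv`, `height`), `se`, `vcov`, `loglik`,
#'   `deviance` (`-2 * loglik`), `df`, `sigma2`, `random` (variance
#'   component table or `NULL`), `converged`, and `flags`.
#' @seealso [predict.asterchain()], [anova.asterchain()],
#'   [fitness_surface()], [forward_stepwise()]
#' @examples
#' sim <- simulate_experiment(config = list(n_blocks = 2, n_families = 6,
#'                                          plot_size = 2), seed = 1)
#' fit <- asterchain(~ treatment, sim$data, lh_graph("c"))
#' fit
#' predict(fit, sim$data[1:3, ], type = "uncond_height")
#' @export
asterchain <- function(formula, data, graph = lh_graph("c"),
                       height_formula = NULL, random = NULL,
                       by_node = FALSE, test_components = TRUE,
                       control = list()) {
  cl <- match.call()
  stopifnot(inherits(graph, "lh_graph"))
  assert_valid_records(data, graph)
  formula <- strip_lhs(formula)
  if (is.null(height_formula)) height_formula <- formula
  height_formula <- strip_lhs(height_formula)

  stk <- build_stacked(formula, data, graph, by_node)
  hgt <- build_height(height_formula, data, graph)

  ctl <- utils::modifyList(
    list(reltol = 1e-10, inner_tol = 1e-9, maxit = 500), control)

  if (is.null(random) || length(random) == 0L) {
    fit <- fit_fixed_parts(stk, hgt)
    fit$random <- NULL
  } else {
    fit <- fit_mixed_parts(stk, hgt, data, random, ctl, test_components)
  }

  fit$call <- cl
  fit$formula <- formula
  fit$height_formula <- height_formula
  fit$graph <- graph
  fit$by_node <- by_node
  fit$n <- nrow(data)
  fit$data <- data
  class(fit) <- "asterchain"
  fit
}

strip_lhs <- function(f) {
  stopifnot(inherits(f, "formula"))
  if (length(f) == 3L) f <- f[-2L]
  f
}

## Builds the stacked Bernoulli regression problem over (node, at-risk
## individual) pairs: per-node intercept columns plus covariate columns
## (shared or per node).
build_stacked <- function(formula, data, graph, by_node) {
  surv <- graph_surv_nodes(graph)
  n <- nrow(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  trm <- attr(mf, "terms")
  xlev <- stats::.getXlevels(trm, mf)
  C <- stats::model.matrix(trm, mf)
  C <- C[, colnames(C) != "(Intercept)", drop = FALSE]

  rows_node <- integer(0); rows_id <- integer(0); y <- numeric(0)
  at_risk <- vector("list", length(surv)); names(at_risk) <- surv
  for (j in seq_along(surv)) {
    id <- surv[j]
    pred <- graph$pred[graph$id == id]
    idx <- if (is.na(pred)) seq_len(n) else which(data[[pred]] == 1)
    at_risk[[j]] <- idx
    rows_node <- c(rows_node, rep.int(j, length(idx)))
    rows_id <- c(rows_id, idx)
    y <- c(y, data[[id]][idx])
  }
  N <- matrix(0, length(rows_id), length(surv),
              dimnames = list(NULL, surv))
  N[cbind(seq_along(rows_id), rows_node)] <- 1
  if (ncol(C) > 0L) {
    Crep <- C[rows_id, , drop = FALSE]
    if (anyNA(Crep)) {
      bad <- colnames(Crep)[colSums(is.na(Crep)) > 0]
      stop("missing covariate values among at-risk individuals in: ",
           paste(bad, collapse = ", "))
    }
    if (by_node && length(surv) > 1L) {
      blocks <- lapply(seq_along(surv), function(j) {
        B <- Crep * (rows_node == j)
        colnames(B) <- paste0(surv[j], ":", colnames(Crep))
        B
      })
      X <- cbind(N, do.call(cbind, blocks))
    } else {
      X <- cbind(N, Crep)
    }
  } else {
    X <- N
  }
  list(X = X, y = y, rows_id = rows_id, rows_node = rows_node,
       nodes = surv, at_risk = at_risk, terms = trm, xlevels = xlev,
       n_cov = ncol(C))
}

## Normal-node regression problem over terminal survivors (or NULL).
build_height <- function(height_formula, data, graph) {
  hid <- graph_height_node(graph)
  if (is.null(hid)) return(NULL)
  pred <- graph$pred[graph$id == hid]
  idx <- which(data[[pred]] == 1)
  mf <- stats::model.frame(height_formula, data, na.action = stats::na.pass)
  trm <- attr(mf, "terms")
  xlev <- stats::.getXlevels(trm, mf)
  X <- stats::model.matrix(trm, mf)[idx, , drop = FALSE]
  if (anyNA(X)) {
    stop("missing height-model covariates among terminal survivors")
  }
  colnames(X) <- paste0("h:", colnames(X))
  list(X = X, y = data[[hid]][idx], idx = idx, node = hid,
       terms = trm, xlevels = xlev)
}

## Exact fixed-effects MLE: IRLS on the stacked Bernoulli problem plus a
## closed-form least-squares fit (sigma2 by ML) on the height node.
fit_fixed_parts <- function(stk, hgt) {
  flags <- list(separation = FALSE, aliased = character(0))
  g <- suppressWarnings(
    stats::glm.fit(stk$X, stk$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 200)))
  cf <- g$coefficients
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    warning("dropping aliased column(s): ", paste(aliased, collapse = ", "))
    flags$aliased <- aliased
  }
  mu <- g$fitted.values
  if (any(mu < 1e-7 | mu > 1 - 1e-7)) {
    big <- names(cf)[!is.na(cf) & abs(cf) > 10]
    warning("possible separation on a Bernoulli node (fitted ",
            "probabilities at 0/1); affected terms: ",
            if (length(big)) paste(big, collapse = ", ") else "(none large)")
    flags$separation <- TRUE
  }
  keep <- !is.na(cf)
  Xk <- stk$X[, keep, drop = FALSE]
  W <- mu * (1 - mu)
  XtWX <- crossprod(Xk * W, Xk)
  Vs <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(Xk), ncol(Xk))
  })
  dimnames(Vs) <- list(colnames(Xk), colnames(Xk))
  se_s <- rep(NA_real_, length(cf)); names(se_s) <- names(cf)
  se_s[keep] <- sqrt(pmax(diag(Vs), 0))
  ll_s <- -g$deviance / 2          # Bernoulli: saturated loglik is 0
  rank_s <- g$rank

  if (!is.null(hgt)) {
    h <- stats::lm.fit(hgt$X, hgt$y)
    hcf <- h$coefficients
    h_alias <- names(hcf)[is.na(hcf)]
    if (length(h_alias)) {
      warning("dropping aliased height column(s): ",
              paste(h_alias, collapse = ", "))
      flags$aliased <- c(flags$aliased, h_alias)
    }
    nh <- length(hgt$y)
    rss <- sum(h$residuals^2)
    sigma2 <- rss / nh
    ll_h <- -nh / 2 * (log(2 * pi * sigma2) + 1)
    keep_h <- !is.na(hcf)
    Xh <- hgt$X[, keep_h, drop = FALSE]
    Vh <- sigma2 * tryCatch(solve(crossprod(Xh)), error = function(e) {
      matrix(NA_real_, ncol(Xh), ncol(Xh))
    })
    dimnames(Vh) <- list(colnames(Xh), colnames(Xh))
    se_h <- rep(NA_real_, length(hcf)); names(se_h) <- names(hcf)
    se_h[keep_h] <- sqrt(pmax(diag(Vh), 0))
    rank_h <- h$rank
  } else {
    hcf <- NULL; se_h <- NULL; Vh <- NULL
    sigma2 <- NA_real_; ll_h <- 0; rank_h <- 0L
  }

  ll <- ll_s + ll_h
  df <- rank_s + rank_h + if (!is.null(hgt)) 1L else 0L
  list(coefficients = list(surv = cf, height = hcf),
       se = list(surv = se_s, height = se_h),
       vcov = list(surv = Vs, height = Vh),
       sigma2 = sigma2, loglik = ll, deviance = -2 * ll, df = df,
       converged = g$converged, flags = flags,
       stacked = stk[c("nodes", "at_risk", "terms", "xlevels")],
       height_node = if (is.null(hgt)) NULL else
         list(node = hgt$node, terms = hgt$terms, xlevels = hgt$xlevels,
              n = length(hgt$y)))
}
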