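#' @export
print.asterchain <- function(x, digits = 4, ...) {
  cat("Aster chain model",
      if (!is.null(x$random)) "(mixed effects, Laplace)" else
        "(fixed effects)", "\n")
  cat("  graph: ", paste(x$graph$id, collapse = " -> "), "\n", sep = "")
  cat("  individuals: ", x$n, ";  log-likelihood: ",
      format(x$loglik, digits = digits), ";  df: ", x$df, "\n", sep = "")
  cat("Survival coefficients (conditional logit scale):\n")
  print(round(x$coefficients$surv, digits))
  if (!is.null(x$coefficients$height)) {
    cat("Height coefficients (mm):\n")
    print(round(x$coefficients$height, digits))
    cat("  sigma2 (mm^2): ", format(x$sigma2, digits = digits), "\n",
        sep = "")
  }
  if (!is.null(x$random)) {
    cat("Random effects (sqrt of variance components):\n")
    print(x$random, digits = digits, row.names = FALSE)
  }
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.asterchain <- function(object, ...) {
  mk <- function(cf, se) {
    z <- cf / se
    data.frame(Estimate = cf, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
               check.names = FALSE)
  }
  out <- list(call = object$call,
              surv = mk(object$coefficients$surv, object$se$surv),
              height = if (!is.null(object$coefficients$height))
                mk(object$coefficients$height, object$se$height),
              sigma2 = object$sigma2, loglik = object$loglik,
              deviance = object$deviance, df = object$df,
              random = object$random, converged = object$converged)
  class(out) <- "summary.asterchain"
  out
}

#' @export
print.summary.asterchain <- function(x, digits = 4, ...) {
  cat("Call: "); print(x$call)
  cat("\nSurvival nodes (conditional logit scale):\n")
  stats::printCoefmat(as.matrix(x$surv), digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$height)) {
    cat("\nHeight node (mm):\n")
    stats::printCoefmat(as.matrix(x$height), digits = digits,
                        P.values = TRUE, has.Pvalue = TRUE)
    cat("Dispersion sigma2:", format(x$sigma2, digits = digits), "\n")
  }
  if (!is.null(x$random)) {
    cat("\nRandom effects (sqrt of variance components, one-tailed p):\n")
    print(x$random, digits = digits, row.names = FALSE)
  }
  cat("\nlog-likelihood:", format(x$loglik, digits = digits),
      "  deviance:", format(x$deviance, digits = digits),
      "  df:", x$df, "\n")
  invisible(x)
}

#' @export
coef.asterchain <- function(object, ...) {
  c(object$coefficients$surv, object$coefficients$height)
}

#' @export
logLik.asterchain <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
deviance.asterchain <- function(object, ...) object$deviance

#' @export
nobs.asterchain <- function(object, ...) object$n

## Per-node conditional parameters at new covariate values (fixed
## effects only; random effects at their mode of zero).
node_linear_predictors <- function(object, newdata) {
  trm <- stats::delete.response(object$stacked$terms)
  mf <- tryCatch(
    stats::model.frame(trm, newdata, na.action = stats::na.pass,
                       xlev = object$stacked$xlevels),
    error = function(e) stop("newdata lack model terms: ",
                             conditionMessage(e), call. = FALSE))
  C <- stats::model.matrix(trm, mf)
  C <- C[, colnames(C) != "(Intercept)", drop = FALSE]
  nodes <- object$stacked$nodes
  cf <- object$coefficients$surv
  cf[is.na(cf)] <- 0
  eta <- matrix(0, nrow(C), length(nodes),
                dimnames = list(NULL, nodes))
  for (j in seq_along(nodes)) {
    eta[, j] <- cf[nodes[j]]
    if (ncol(C) > 0L) {
      cn <- if (object$by_node && length(nodes) > 1L)
        paste0(nodes[j], ":", colnames(C)) else colnames(C)
      miss <- setdiff(cn, names(cf))
      if (length(miss)) stop("model lacks coefficients for terms: ",
                             paste(miss, collapse = ", "))
      eta[, j] <- eta[, j] + drop(C %*% cf[cn])
    }
  }
  p <- stats::plogis(eta)
  mean_h <- NULL
  if (!is.null(object$height_node)) {
    htrm <- stats::delete.response(object$height_node$terms)
    hmf <- tryCatch(
      stats::model.frame(htrm, newdata, na.action = stats::na.pass,
                         xlev = object$height_node$xlevels),
      error = function(e) stop("newdata lack height-model terms: ",
                               conditionMessage(e), call. = FALSE))
    Xh <- stats::model.matrix(htrm, hmf)
    colnames(Xh) <- paste0("h:", colnames(Xh))
    cfh <- object$coefficients$height
    cfh[is.na(cfh)] <- 0
    mean_h <- drop(Xh %*% cfh[colnames(Xh)])
  }
  list(p = p, mean_h = mean_h, nodes = nodes)
}

#' Predict survival and fitness from an aster chain fit
#'
#' @param object An [asterchain()] fit.
#' @param newdata Data frame of covariate values (one row per
#'   prediction); defaults to the training data.
#' @param type `"survival"` (cumulative survival probability through
#'   `through_node`), `"cond_height"` (conditional expected height of a
#'   survivor, mm), or `"uncond_height"` (unconditional expected height,
#'   mm: the product of all chain survival probabilities and the
#'   conditional mean — the fitness measure that accounts for mortality).
#' @param through_node Bernoulli node at which to stop the survival
#'   product (default: the terminal survival node).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.asterchain <- function(object, newdata = object$data,
                               type = c("survival", "cond_height",
                                        "uncond_height"),
                               through_node = NULL, ...) {
  type <- match.arg(type)
  lp <- node_linear_predictors(object, newdata)
  if (type == "survival") {
    nodes <- lp$nodes
    if (is.null(through_node)) through_node <- nodes[length(nodes)]
    if (!through_node %in% nodes) {
      stop("through_node '", through_node,
           "' is not a survival node of this model")
    }
    upto <- seq_len(match(through_node, nodes))
    return(apply(lp$p[, upto, drop = FALSE], 1L, prod))
  }
  if (is.null(object$height_node)) {
    stop("graph has no height node; height prediction unsupported")
  }
  if (type == "cond_height") return(lp$mean_h)
  apply(lp$p, 1L, prod) * lp$mean_h
}

#' Simulate responses from a fitted aster chain
#'
#' Draws node responses down the chain: each survival indicator is
#' Bernoulli given its predecessor (structural zeros by construction)
#' and height is normal for terminal survivors, zero otherwise.
#'
#' @param object An [asterchain()] fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param newdata Covariate data frame (default: training data).
#' @param ... Unused.
#' @return A list of `nsim` data frames of node responses.
#' @export
simulate.asterchain <- function(object, nsim = 1, seed = NULL,
                                newdata = object$data, ...) {
  if (!is.null(seed)) set.seed(seed)
  lp <- node_linear_predictors(object, newdata)
  n <- nrow(lp$p)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    alive <- rep(1, n)
    d <- as.data.frame(matrix(0, n, length(lp$nodes),
                              dimnames = list(NULL, lp$nodes)))
    for (j in seq_along(lp$nodes)) {
      y <- stats::rbinom(n, 1L, lp$p[, j]) * alive
      d[[lp$nodes[j]]] <- y
      alive <- y
    }
    if (!is.null(object$height_node)) {
      h <- stats::rnorm(n, lp$mean_h, sqrt(object$sigma2))
      d[[object$height_node$node]] <- ifelse(alive == 1, pmax(h, 0), 0)
    }
    out[[s]] <- d
  }
  out
}

#' @export
residuals.asterchain <- function(object,
                                 type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  lp <- node_linear_predictors(object, object$data)
  nodes <- lp$nodes
  res <- matrix(NA_real_, object$n, length(nodes),
                dimnames = list(NULL, nodes))
  for (j in seq_along(nodes)) {
    idx <- object$stacked$at_risk[[j]]
    y <- object$data[[nodes[j]]][idx]
    p <- lp$p[idx, j]
    r <- y - p
    if (type == "pearson") r <- r / sqrt(p * (1 - p))
    res[idx, j] <- r
  }
  out <- list(surv = res)
  if (!is.null(object$height_node)) {
    alive <- object$data[[object$graph$pred[
      object$graph$id == object$height_node$node]]] == 1
    hr <- rep(NA_real_, object$n)
    hr[alive] <- object$data[[object$height_node$node]][alive] -
      lp$mean_h[alive]
    if (type == "pearson") hr <- hr / sqrt(object$sigma2)
    out$height <- hr
  }
  out
}

#' Likelihood-ratio test between nested aster chain fits
#'
#' The statistic is the deviance difference `deviance(null) -
#' deviance(full)` (deviance is `-2 *` log-likelihood), referred to a
#' chi-square distribution with df equal to the difference in free
#' parameters.
#'
#' @param null,full Nested [asterchain()] fits on the same data and
#'   graph (the null model's terms must be a subset of the full
#'   model's).
#' @param tol Negative statistics smaller than `-tol` trigger an error
#'   (a convergence failure); within tolerance they are clipped to 0.
#' @return List with `statistic`, `df` and `p_value` (class
#'   `aster_lrt`).
#' @export
aster_lrt <- function(null, full, tol = 1e-6) {
  stopifnot(inherits(null, "asterchain"), inherits(full, "asterchain"))
  if (null$n != full$n) stop("models were fitted to different data")
  if (!identical(null$graph$id, full$graph$id)) {
    stop("models use different graphs; tests require the same graph")
  }
  nn <- c(names(null$coefficients$surv), names(null$coefficients$height))
  fn <- c(names(full$coefficients$surv), names(full$coefficients$height))
  if (!all(nn %in% fn)) {
    stop("models are not nested: null has terms absent from full (",
         paste(setdiff(nn, fn), collapse = ", "), ")")
  }
  stat <- null$deviance - full$deviance
  if (stat < -tol * max(1, abs(full$deviance))) {
    stop("negative likelihood-ratio statistic (", format(stat),
         ") beyond tolerance; refit with a tighter convergence tolerance")
  }
  stat <- max(0, stat)
  df <- full$df - null$df
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p),
            class = "aster_lrt")
}

#' @export
print.aster_lrt <- function(x, ...) {
  cat("Aster LRT: statistic =", format(x$statistic, digits = 5),
      " df =", x$df, " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Compare a sequence of nested aster chain fits
#'
#' @param object,... Two or more nested [asterchain()] fits, smallest
#'   first.
#' @return An `anova`-classed data frame with model df, model deviance,
#'   test df, LRT statistic and p-value per step.
#' @export
anova.asterchain <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L) stop("need at least two fits to compare")
  out <- data.frame(
    `Model df` = vapply(fits, function(f) f$df, 0L),
    `Model deviance` = vapply(fits, function(f) f$deviance, 0),
    `Test df` = NA_integer_, LRT = NA_real_, `Pr(>Chi)` = NA_real_,
    check.names = FALSE)
  for (k in 2:length(fits)) {
    t <- aster_lrt(fits[[k - 1L]], fits[[k]])
    out$`Test df`[k] <- t$df
    out$LRT[k] <- t$statistic
    out$`Pr(>Chi)`[k] <- t$p_value
  }
  rownames(out) <- paste("Model", seq_along(fits))
  structure(out, heading = "Likelihood-ratio tests of nested aster chain models",
            class = c("anova", "data.frame"))
}
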