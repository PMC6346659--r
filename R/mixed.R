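## Laplace-approximate mixed-effects fit.
##
## Random intercepts are shared across all nodes of an individual and
## enter every node's conditional canonical parameter with loading 1
## (logit scale at Bernoulli nodes, mm at the normal node).  The inner
## problem (random-effect mode given parameters) is globally concave and
## solved by Newton iteration; the outer problem maximizes the Laplace
## objective over fixed effects and log standard deviations by L-BFGS-B.

fit_mixed_parts <- function(stk, hgt, data, random, ctl, test_components) {
  for (g in random) {
    if (!g %in% names(data)) stop("random grouping not in data: ", g)
    if (length(unique(data[[g]])) < 2L) {
      stop("random grouping '", g, "' has fewer than 2 levels")
    }
  }

  ## drop aliased fixed columns found by a plain fixed pre-fit
  pre <- suppressWarnings(fit_fixed_parts(stk, hgt))
  keep_s <- !is.na(pre$coefficients$surv)
  Xs <- stk$X[, keep_s, drop = FALSE]
  has_h <- !is.null(hgt)
  if (has_h) {
    keep_h <- !is.na(pre$coefficients$height)
    Xh <- hgt$X[, keep_h, drop = FALSE]
    yh <- hgt$y
  }

  ## random-effect design: one indicator block per grouping, rows are the
  ## stacked Bernoulli rows followed by the height rows
  ids <- c(stk$rows_id, if (has_h) hgt$idx)
  n_bern <- length(stk$rows_id)
  n_all <- length(ids)
  fac <- lapply(random, function(g) factor(data[[g]]))
  names(fac) <- random
  L <- vapply(fac, nlevels, 0L)
  Z <- matrix(0, n_all, sum(L))
  off <- 0L
  zcols <- character(sum(L))
  for (k in seq_along(fac)) {
    lev_idx <- as.integer(fac[[k]])[ids]
    Z[cbind(seq_len(n_all), off + lev_idx)] <- 1
    zcols[off + seq_len(L[k])] <- paste0(random[k], ":", levels(fac[[k]]))
    off <- off + L[k]
  }
  comp_of <- rep.int(seq_along(L), L)   # which grouping each b belongs to
  ys <- stk$y

  p_s <- ncol(Xs)
  p_h <- if (has_h) ncol(Xh) else 0L
  n_g <- length(random)
  q <- sum(L)

  b_warm <- numeric(q)

  ## Laplace log-likelihood at theta = (beta_s, beta_h, log sigma_e,
  ## log sigma_g...); also returns the mode when want_mode = TRUE.
  lap <- function(theta, want_mode = FALSE) {
    beta_s <- theta[seq_len(p_s)]
    beta_h <- if (p_h) theta[p_s + seq_len(p_h)] else numeric(0)
    i <- p_s + p_h
    sig_e2 <- if (has_h) exp(2 * theta[i + 1L]) else NA_real_
    sig_g <- exp(theta[i + (if (has_h) 1L else 0L) + seq_len(n_g)])
    dinv <- 1 / sig_g[comp_of]^2

    eta_fix_s <- drop(Xs %*% beta_s)
    eta_fix_h <- if (has_h) drop(Xh %*% beta_h) else numeric(0)
    eta_fix <- c(eta_fix_s, eta_fix_h)

    b <- b_warm
    ll_data <- NA_real_
    obj_pen <- function(b) {
      eta <- eta_fix + drop(Z %*% b)
      es <- eta[seq_len(n_bern)]
      lls <- sum(ys * es - log1p(exp(es)))
      llh <- if (has_h) {
        eh <- eta[n_bern + seq_len(n_all - n_bern)]
        -0.5 * sum((yh - eh)^2) / sig_e2 -
          0.5 * (n_all - n_bern) * log(2 * pi * sig_e2)
      } else 0
      list(ll = lls + llh, pen = -0.5 * sum(dinv * b^2))
    }
    cur <- obj_pen(b)
    for (it in seq_len(60L)) {
      eta <- eta_fix + drop(Z %*% b)
      es <- eta[seq_len(n_bern)]
      mu <- stats::plogis(es)
      u <- c(ys - mu,
             if (has_h) (yh - eta[n_bern + seq_len(n_all - n_bern)]) / sig_e2)
      w <- c(mu * (1 - mu), if (has_h) rep(1 / sig_e2, n_all - n_bern))
      grad <- drop(crossprod(Z, u)) - dinv * b
      if (max(abs(grad)) < ctl$inner_tol * max(1, max(abs(b)))) break
      H <- crossprod(Z * w, Z)
      diag(H) <- diag(H) + dinv
      step <- tryCatch(solve(H, grad), error = function(e) grad / diag(H))
      ## step-halving to guarantee ascent of the penalized objective
      s <- 1
      repeat {
        bn <- b + s * step
        new <- obj_pen(bn)
        if (new$ll + new$pen >= cur$ll + cur$pen - 1e-12 || s < 1e-4) break
        s <- s / 2
      }
      b <- bn; cur <- new
    }
    b_warm <<- b
    ## final Hessian at the mode
    eta <- eta_fix + drop(Z %*% b)
    mu <- stats::plogis(eta[seq_len(n_bern)])
    w <- c(mu * (1 - mu), if (has_h) rep(1 / sig_e2, n_all - n_bern))
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + dinv
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(if (want_mode) list(ll = -Inf, b = b) else -Inf)
    logdetH <- 2 * sum(log(diag(ch)))
    logdetD <- sum(2 * L * log(sig_g))
    ll <- cur$ll + cur$pen - 0.5 * logdetD - 0.5 * logdetH
    if (want_mode) list(ll = ll, b = b) else ll
  }

  ## start values: fixed-fit coefficients, residual sd, sd 0.25 per group
  th0 <- c(pre$coefficients$surv[keep_s],
           if (has_h) pre$coefficients$height[keep_h],
           if (has_h) 0.5 * log(pre$sigma2),
           rep(log(0.25), n_g))
  lower <- c(rep(-Inf, p_s + p_h), if (has_h) -Inf,
             rep(log(1e-6), n_g))
  opt <- stats::optim(th0, function(th) -lap(th), method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = ctl$maxit, factr = 1e4))
  theta <- opt$par
  final <- lap(theta, want_mode = TRUE)
  ll <- final$ll

  ## standard errors from the observed information of the Laplace
  ## objective (finite differences); log-sd components by delta method
  hess <- if (isFALSE(ctl$hessian)) NULL else tryCatch(
    stats::optimHess(theta, function(th) -lap(th)),
    error = function(e) NULL)
  vcv <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL

  i <- p_s + p_h
  sig_e2 <- if (has_h) exp(2 * theta[i + 1L]) else NA_real_
  sd_g <- exp(theta[i + (if (has_h) 1L else 0L) + seq_len(n_g)])
  se_all <- if (!is.null(vcv)) sqrt(pmax(diag(vcv), 0)) else
    rep(NA_real_, length(theta))
  se_sd_g <- sd_g * se_all[i + (if (has_h) 1L else 0L) + seq_len(n_g)]

  boundary <- sd_g < 1e-3
  rnd <- data.frame(grouping = random, sd = sd_g, se = se_sd_g,
                    p_value = NA_real_, boundary = boundary,
                    stringsAsFactors = FALSE)
  rnd$sd[boundary] <- 0
  rnd$se[boundary] <- NA_real_

  if (test_components && n_g >= 1L) {
    for (k in seq_along(random)) {
      red <- if (n_g == 1L) {
        suppressWarnings(fit_fixed_parts(stk, hgt))$loglik
      } else {
        fit_mixed_parts(stk, hgt, data, random[-k], ctl,
                        test_components = FALSE)$loglik
      }
      stat <- max(0, 2 * (ll - red))
      rnd$p_value[k] <- if (stat <= 0) 1 else
        0.5 * stats::pchisq(stat, 1L, lower.tail = FALSE)
    }
  }

  ## assemble coefficient vectors on the original (possibly aliased) layout
  cf_s <- pre$coefficients$surv
  cf_s[keep_s] <- theta[seq_len(p_s)]
  se_s <- rep(NA_real_, length(cf_s)); names(se_s) <- names(cf_s)
  se_s[keep_s] <- se_all[seq_len(p_s)]
  Vs <- if (!is.null(vcv)) vcv[seq_len(p_s), seq_len(p_s), drop = FALSE]
        else matrix(NA_real_, p_s, p_s)
  dimnames(Vs) <- list(colnames(Xs), colnames(Xs))
  if (has_h) {
    cf_h <- pre$coefficients$height
    cf_h[keep_h] <- theta[p_s + seq_len(p_h)]
    se_h <- rep(NA_real_, length(cf_h)); names(se_h) <- names(cf_h)
    se_h[keep_h] <- se_all[p_s + seq_len(p_h)]
    Vh <- if (!is.null(vcv))
      vcv[p_s + seq_len(p_h), p_s + seq_len(p_h), drop = FALSE]
      else matrix(NA_real_, p_h, p_h)
    dimnames(Vh) <- list(colnames(Xh), colnames(Xh))
  } else {
    cf_h <- NULL; se_h <- NULL; Vh <- NULL
  }

  df <- p_s + p_h + (if (has_h) 1L else 0L) + n_g
  flags <- pre$flags
  flags$boundary <- any(boundary)
  if (opt$convergence != 0) {
    warning("mixed-model outer optimization did not converge (code ",
            opt$convergence, "): ", opt$message)
  }
  list(coefficients = list(surv = cf_s, height = cf_h),
       se = list(surv = se_s, height = se_h),
       vcov = list(surv = Vs, height = Vh),
       sigma2 = sig_e2, loglik = ll, deviance = -2 * ll, df = df,
       converged = opt$convergence == 0, flags = flags,
       random = rnd,
       ranef = stats::setNames(final$b, zcols),
       stacked = stk[c("nodes", "at_risk", "terms", "xlevels")],
       height_node = if (!has_h) NULL else
         list(node = hgt$node, terms = hgt$terms, xlevels = hgt$xlevels,
              n = length(hgt$y)))
}
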