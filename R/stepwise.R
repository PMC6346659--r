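#' Candidate term set for selection-gradient models
#'
#' Enumerates model terms in forward-entry order: factor main effects,
#' then trait linears (`z_<trait>`), trait quadratics (`I(z_<trait>^2)`),
#' factor-by-trait interactions, and cross-products between trait pairs.
#' Marginality prerequisites are attached to every term (a quadratic
#' requires its linear; a cross-product requires both quadratics; an
#' interaction requires the factor and the linear), and pairs flagged by
#' a Spearman screen are marked mutually conflicting so they can never
#' co-occur downstream.
#'
#' @param traits Character vector of (raw) trait names; models use the
#'   standardized columns `z_<trait>` (see [standardize_traits()]).
#' @param factors Character vector of factor columns (e.g.
#'   `"treatment"`).
#' @param screen Optional [screen_traits()] result.
#' @param stratum Stratum name within `screen` (when it has several).
#' @param quadratics,interactions,cross_products Logicals switching the
#'   corresponding term families on or off.
#' @return Data frame of class `candidate_terms` with columns `term`,
#'   `type`, `requires`, `conflicts` (comma-separated term lists).
#' @export
candidate_terms <- function(traits, factors = character(0), screen = NULL,
                            stratum = NULL, quadratics = TRUE,
                            interactions = TRUE, cross_products = TRUE) {
  if (!length(traits)) stop("empty trait set")
  scr <- screen_stratum(screen, stratum)
  if (!is.null(scr)) traits <- setdiff(traits, scr$unusable)
  if (!length(traits)) stop("no usable traits after screening")
  z <- function(t) paste0("z_", t)
  q <- function(t) paste0("I(z_", t, "^2)")
  rows <- list()
  add <- function(term, type, requires = "", conflicts = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, type = type, requires = requires,
      conflicts = conflicts, stringsAsFactors = FALSE)
  }
  ## screened-out pairs: their linears may not co-enter
  pair_conflicts <- stats::setNames(
    vector("list", length(traits)), traits)
  if (!is.null(scr) && nrow(scr$excluded)) {
    for (k in seq_len(nrow(scr$excluded))) {
      t1 <- scr$excluded$trait1[k]; t2 <- scr$excluded$trait2[k]
      pair_conflicts[[t1]] <- c(pair_conflicts[[t1]], t2)
      pair_conflicts[[t2]] <- c(pair_conflicts[[t2]], t1)
    }
  }
  for (f in factors) add(f, "factor")
  for (t in traits) {
    confl <- paste(vapply(pair_conflicts[[t]] %||% character(0), z, ""),
                   collapse = ",")
    add(z(t), "linear", conflicts = confl)
  }
  if (quadratics) {
    for (t in traits) add(q(t), "quadratic", requires = z(t))
  }
  if (interactions) {
    for (f in factors) for (t in traits) {
      add(paste0(f, ":", z(t)), "interaction",
          requires = paste(f, z(t), sep = ","))
    }
  }
  if (cross_products && quadratics && length(traits) >= 2L) {
    cmb <- utils::combn(traits, 2L)
    for (k in seq_len(ncol(cmb))) {
      t1 <- cmb[1L, k]; t2 <- cmb[2L, k]
      if (t2 %in% (pair_conflicts[[t1]] %||% character(0))) next
      add(paste0(z(t1), ":", z(t2)), "cross_product",
          requires = paste(q(t1), q(t2), sep = ","))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("candidate_terms", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_terms <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else
    strsplit(s, ",", fixed = TRUE)[[1L]]
}

formula_from_terms <- function(terms) {
  if (!length(terms)) ~1 else
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

#' Forward-stepwise selection of gradient terms by likelihood-ratio test
#'
#' Starting from the intercepts-only model, repeatedly fits every
#' admissible candidate term (prerequisites in the model, conflicts not)
#' added to the current model, computes its LRT against the current
#' model, and adds the candidate with the smallest p-value if below
#' `alpha` (exact ties broken by candidate order: mains before
#' quadratics before interactions before cross-products).  Stops when no
#' candidate qualifies.  Candidate fits that fail to converge are
#' skipped with a warning.
#'
#' @param data Wide records containing the standardized `z_` trait
#'   columns (see [standardize_traits()]).
#' @param graph An [lh_graph()].
#' @param candidates A [candidate_terms()] table.
#' @param alpha Retention threshold on the per-term LRT p-value
#'   (default 0.05).
#' @param random Optional random groupings, passed to [asterchain()].
#' @param blocks Where candidate terms enter: `"both"` (default: the
#'   shared survival block and the height block), `"surv"` (survival
#'   block only; the height node, if present, stays intercept-only), or
#'   `"height"` (height block only).
#' @param ... Further arguments to [asterchain()].
#' @return Object of class `aster_stepwise`: list with `retained`
#'   (terms, in entry order), `fit` (final [asterchain()] fit),
#'   `ledger` (model-comparison table: step, term, action, model df,
#'   model deviance, test df, p), `alpha`, `scaling`.
#' @export
forward_stepwise <- function(data, graph, candidates, alpha = 0.05,
                             random = NULL,
                             blocks = c("both", "surv", "height"), ...) {
  stopifnot(inherits(candidates, "data.frame"))
  blocks <- match.arg(blocks)
  fit_terms <- function(terms, ...) {
    f <- formula_from_terms(terms)
    switch(blocks,
           both = asterchain(f, data, graph, random = random, ...),
           surv = asterchain(f, data, graph, height_formula = ~1,
                             random = random, ...),
           height = asterchain(~1, data, graph, height_formula = f,
                               random = random, ...))
  }
  current <- character(0)
  fit <- fit_terms(character(0), ...)
  ledger <- data.frame(step = 0L, term = "(null)", action = "start",
                       model_df = fit$df, model_deviance = fit$deviance,
                       test_df = NA_integer_, p_value = NA_real_,
                       stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    avail <- candidates[!candidates$term %in% current, , drop = FALSE]
    best <- NULL
    for (k in seq_len(nrow(avail))) {
      req <- split_terms(avail$requires[k])
      if (!all(req %in% current)) next
      confl <- split_terms(avail$conflicts[k])
      if (any(confl %in% current)) next
      cand_fit <- tryCatch(
        suppressWarnings(fit_terms(c(current, avail$term[k]),
                                   test_components = FALSE, ...)),
        error = function(e) NULL)
      if (is.null(cand_fit) || !cand_fit$converged) {
        warning("skipping non-convergent candidate: ", avail$term[k])
        next
      }
      t <- tryCatch(aster_lrt(fit, cand_fit), error = function(e) NULL)
      if (is.null(t)) next
      if (is.null(best) || t$p_value < best$p) {
        best <- list(term = avail$term[k], fit = cand_fit,
                     p = t$p_value, df = t$df)
      }
    }
    if (is.null(best) || best$p >= alpha) break
    current <- c(current, best$term)
    fit <- best$fit
    ledger <- rbind(ledger, data.frame(
      step = step, term = best$term, action = "added",
      model_df = fit$df, model_deviance = fit$deviance,
      test_df = best$df, p_value = best$p, stringsAsFactors = FALSE))
  }
  ## closing ledger rows: remaining admissible candidates vs final model
  avail <- candidates[!candidates$term %in% current, , drop = FALSE]
  for (k in seq_len(nrow(avail))) {
    req <- split_terms(avail$requires[k])
    confl <- split_terms(avail$conflicts[k])
    if (!all(req %in% current) || any(confl %in% current)) next
    cand_fit <- tryCatch(
      suppressWarnings(fit_terms(c(current, avail$term[k]),
                                 test_components = FALSE, ...)),
      error = function(e) NULL)
    if (is.null(cand_fit)) next
    t <- tryCatch(aster_lrt(fit, cand_fit), error = function(e) NULL)
    if (is.null(t)) next
    ledger <- rbind(ledger, data.frame(
      step = NA_integer_, term = avail$term[k], action = "not_retained",
      model_df = cand_fit$df, model_deviance = cand_fit$deviance,
      test_df = t$df, p_value = t$p_value, stringsAsFactors = FALSE))
  }
  ## refit with component tests if mixed
  if (!is.null(random)) {
    fit <- fit_terms(current, ...)
  }
  structure(list(retained = current, fit = fit, ledger = ledger,
                 alpha = alpha, candidates = candidates,
                 scaling = attr(data, "trait_scaling")),
            class = "aster_stepwise")
}

#' @export
print.aster_stepwise <- function(x, digits = 4, ...) {
  cat("Forward-stepwise aster model selection (alpha =", x$alpha, ")\n")
  cat("Retained terms:",
      if (length(x$retained)) paste(x$retained, collapse = " + ")
      else "(none)", "\n\n")
  lg <- x$ledger
  lg$model_deviance <- round(lg$model_deviance, 2)
  lg$p_value <- signif(lg$p_value, 3)
  print(lg, row.names = FALSE)
  invisible(x)
}

#' Selection gradients from a fitted model
#'
#' Extracts linear (`beta_i`), quadratic and cross-product gradients for
#' standardized traits from an aster chain fit.  Following the usual
#' convention the fitted quadratic-term coefficient is doubled to give
#' the Lande-Arnold `gamma_ii` (the second derivative of the fitness
#' surface in the standardized trait); cross-product coefficients are
#' `gamma_ij` directly.  When a trait scaling is supplied, raw-scale
#' coefficients (per trait unit) are reported alongside.
#'
#' @param object An [asterchain()] fit or [forward_stepwise()] result.
#' @param scaling Optional trait-scaling table (attribute of
#'   [standardize_traits()]); defaults to the stepwise scaling when
#'   `object` is a stepwise result.
#' @return Data frame with `block` (`surv`/`height`), `term`, `type`,
#'   `estimate`, `gradient` (doubled for quadratics) and, when scaling
#'   is available, `raw_estimate`.
#' @export
selection_gradients <- function(object, scaling = NULL) {
  if (inherits(object, "aster_stepwise")) {
    scaling <- scaling %||% object$scaling
    object <- object$fit
  }
  stopifnot(inherits(object, "asterchain"))
  all_cf <- c(object$coefficients$surv, object$coefficients$height)
  blocks <- c(rep("surv", length(object$coefficients$surv)),
              rep("height", length(object$coefficients$height)))
  rows <- list()
  for (i in seq_along(all_cf)) {
    nm <- sub("^h:", "", names(all_cf)[i])
    type <- if (grepl("^I\\(z_.*\\^2\\)$", nm)) "quadratic"
            else if (grepl("^z_[^:]+$", nm)) "linear"
            else if (grepl("^z_.*:z_.*$", nm)) "cross_product"
            else next
    est <- all_cf[i]
    grad <- if (type == "quadratic") 2 * est else est
    trait <- sub("^I\\(z_(.*)\\^2\\)$", "\\1", sub("^z_", "", nm))
    raw <- NA_real_
    if (!is.null(scaling) && type %in% c("linear", "quadratic")) {
      s <- scaling$scale[match(trait, scaling$trait)]
      if (!is.na(s)) raw <- if (type == "linear") est / s else est / s^2
    }
    rows[[length(rows) + 1L]] <- data.frame(
      block = blocks[i], term = names(all_cf)[i], type = type,
      estimate = unname(est), gradient = unname(grad),
      raw_estimate = unname(raw), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(block = character(0), term = character(0),
                      type = character(0), estimate = numeric(0),
                      gradient = numeric(0), raw_estimate = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Factor-model comparison ladder
#'
#' Fits the standard factor ladder for an experiment: the head model
#' with all listed factors, each factor tested by dropping it from the
#' head model, the pairwise interaction tested by adding it to the head
#' model, and the head model tested against the intercepts-only null.
#'
#' @param data Wide records.
#' @param graph An [lh_graph()].
#' @param factors Character vector of factor columns (e.g.
#'   `c("treatment", "family")`); factors with a single level are
#'   dropped with a warning.
#' @param interaction Logical; include the two-way interaction row
#'   (first two factors).
#' @param random Optional random groupings for [asterchain()].
#' @param ... Passed to [asterchain()].
#' @return Data frame with columns `terms`, `model_df`,
#'   `model_deviance`, `test_df`, `p_value` (head model tested against
#'   the null; other rows tested against the head model).
#' @export
fit_factor_models <- function(data, graph, factors = c("treatment",
                                                       "family"),
                              interaction = TRUE, random = NULL, ...) {
  keep <- vapply(factors, function(f) {
    ok <- length(unique(data[[f]])) >= 2L
    if (!ok) warning("dropping single-level factor: ", f)
    ok
  }, TRUE)
  factors <- factors[keep]
  if (!length(factors)) stop("no usable factors")
  fit_of <- function(terms) suppressWarnings(
    asterchain(formula_from_terms(terms), data, graph, random = random,
               test_components = FALSE, ...))
  null <- fit_of(character(0))
  head <- fit_of(factors)
  t_head <- aster_lrt(null, head)
  rows <- list(data.frame(
    terms = paste(factors, collapse = " + "), model_df = head$df,
    model_deviance = head$deviance, test_df = t_head$df,
    p_value = t_head$p_value, stringsAsFactors = FALSE))
  for (f in factors) {
    red <- fit_of(setdiff(factors, f))
    t <- aster_lrt(red, head)
    rows[[length(rows) + 1L]] <- data.frame(
      terms = f, model_df = red$df, model_deviance = red$deviance,
      test_df = t$df, p_value = t$p_value, stringsAsFactors = FALSE)
  }
  if (interaction && length(factors) >= 2L) {
    int <- paste(factors[1:2], collapse = ":")
    full <- fit_of(c(factors, int))
    t <- aster_lrt(head, full)
    rows[[length(rows) + 1L]] <- data.frame(
      terms = int, model_df = full$df, model_deviance = full$deviance,
      test_df = t$df, p_value = t$p_value, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    terms = "Null", model_df = null$df, model_deviance = null$deviance,
    test_df = NA_integer_, p_value = NA_real_, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
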