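## Reference newdata row for predictions: numeric covariates at their
## data mean (standardized traits therefore at 0), factors at their
## first level, with named overrides via `at`.
reference_row <- function(fit, data, at = list()) {
  vars <- unique(c(all.vars(fit$formula), all.vars(fit$height_formula)))
  row <- list()
  for (v in vars) {
    if (!v %in% names(data)) stop("model variable not in data: ", v)
    col <- data[[v]]
    row[[v]] <- if (is.numeric(col)) mean(col, na.rm = TRUE) else {
      lev <- if (is.factor(col)) levels(col) else sort(unique(col))
      lev[1L]
    }
  }
  for (v in names(at)) row[[v]] <- at[[v]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

## The data column through which a raw trait enters the model (its
## standardized z_ column when that is what the model uses), plus the
## scaling needed to map raw grid values onto it.
trait_binding <- function(fit, trait, scaling, allow_flat = FALSE) {
  cf_names <- c(names(fit$coefficients$surv),
                names(fit$coefficients$height))
  zcol <- paste0("z_", trait)
  uses <- function(col) any(grepl(col, cf_names, fixed = TRUE))
  if (uses(zcol)) {
    if (is.null(scaling) || !trait %in% scaling$trait) {
      stop("no trait scaling available for '", trait,
           "'; standardize_traits() records it")
    }
    k <- match(trait, scaling$trait)
    list(col = zcol, center = scaling$center[k], scale = scaling$scale[k])
  } else if (uses(trait)) {
    list(col = trait, center = 0, scale = 1)
  } else if (allow_flat) {
    list(col = trait, center = 0, scale = 1, flat = TRUE)
  } else {
    stop("trait '", trait, "' is absent from the fitted model; ",
         "set allow_flat = TRUE to request a flat surface explicitly")
  }
}

#' Fitness surface over two traits
#'
#' Evaluates the fitted fitness measure (cumulative survival probability
#' or unconditional expected height) on a grid spanning the observed
#' range of two traits, holding other numeric covariates at their data
#' means (standardized traits at 0), factors at their reference level
#' and random effects at their mode of zero.  Observed trait pairs are
#' returned with multiplicity counts for overlay plotting.
#'
#' @param object An [asterchain()] fit or [forward_stepwise()] result.
#' @param trait_x,trait_y Raw trait names (e.g. `"emergence_day"`).
#' @param data Data frame supplying observed trait ranges and overlay
#'   points (default: the training data).
#' @param grid_size Grid points per axis (default 50, inclusive
#'   endpoints).
#' @param measure `"auto"` (unconditional height when the graph has the
#'   height node, else survival), `"survival"`, or `"uncond_height"`.
#' @param at Named list of covariate overrides for the reference row
#'   (e.g. `list(treatment = "no_drought")`).
#' @param scaling Trait-scaling table; defaults to the stepwise scaling
#'   or the `trait_scaling` attribute of `data`.
#' @param allow_flat Logical; permit a trait absent from the model (the
#'   surface is then flat along that axis).  Default `FALSE`: asking for
#'   an absent trait is an error.
#' @return Object of class `fitness_surface`: list with `x`, `y` (grid
#'   vectors, original units), `z` (grid matrix of predictions),
#'   `points` (observed pairs with counts), `measure`, trait names.
#' @export
fitness_surface <- function(object, trait_x, trait_y,
                            data = NULL, grid_size = 50,
                            measure = c("auto", "survival",
                                        "uncond_height"),
                            at = list(), scaling = NULL,
                            allow_flat = FALSE) {
  measure <- match.arg(measure)
  if (inherits(object, "aster_stepwise")) {
    scaling <- scaling %||% object$scaling
    object <- object$fit
  }
  stopifnot(inherits(object, "asterchain"))
  if (is.null(data)) data <- object$data
  scaling <- scaling %||% attr(data, "trait_scaling")
  if (measure == "auto") {
    measure <- if (is.null(object$height_node)) "survival" else
      "uncond_height"
  }
  type <- if (measure == "survival") "survival" else "uncond_height"

  bx <- trait_binding(object, trait_x, scaling, allow_flat)
  by <- trait_binding(object, trait_y, scaling, allow_flat)
  rx <- range(data[[trait_x]], na.rm = TRUE)
  ry <- range(data[[trait_y]], na.rm = TRUE)
  gx <- seq(rx[1L], rx[2L], length.out = grid_size)
  gy <- seq(ry[1L], ry[2L], length.out = grid_size)

  ref <- reference_row(object, data, at)
  grid <- ref[rep(1L, grid_size^2), , drop = FALSE]
  xy <- expand.grid(x = gx, y = gy)
  grid[[bx$col]] <- (xy$x - bx$center) / bx$scale
  grid[[by$col]] <- (xy$y - by$center) / by$scale
  z <- matrix(predict(object, grid, type = type), grid_size, grid_size)

  obs <- data[!is.na(data[[trait_x]]) & !is.na(data[[trait_y]]),
              c(trait_x, trait_y)]
  pts <- stats::aggregate(list(count = rep(1L, nrow(obs))),
                          obs, FUN = sum)
  structure(list(trait_x = trait_x, trait_y = trait_y, x = gx, y = gy,
                 z = z, points = pts, measure = measure),
            class = "fitness_surface")
}

#' @export
print.fitness_surface <- function(x, ...) {
  cat("Fitness surface (", x$measure, "): ", x$trait_x, " x ",
      x$trait_y, ", ", length(x$x), "x", length(x$y), " grid, range [",
      format(min(x$z), digits = 4), ", ", format(max(x$z), digits = 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
plot.fitness_surface <- function(x, nlevels = 10, ...) {
  graphics::contour(x$x, x$y, x$z, nlevels = nlevels,
                    xlab = x$trait_x, ylab = x$trait_y,
                    main = paste("fitness:", x$measure), ...)
  shade <- grDevices::grey(
    1 - 0.2 - 0.8 * x$points$count / max(x$points$count))
  graphics::points(x$points[[x$trait_x]], x$points[[x$trait_y]],
                   pch = 16, col = shade, cex = 0.6)
  invisible(x)
}

#' Contour plot of the fitted fitness surface
#'
#' Convenience method: computes a [fitness_surface()] over the first two
#' traits found in the model and plots it.
#'
#' @param x An [asterchain()] fit.
#' @param trait_x,trait_y Raw trait names.
#' @param ... Passed to [fitness_surface()].
#' @export
plot.asterchain <- function(x, trait_x, trait_y, ...) {
  plot(fitness_surface(x, trait_x, trait_y, ...))
}

#' Classify the form of selection on a trait
#'
#' Profiles the fitted fitness measure along one trait over its observed
#' range (other covariates at reference values) and classifies the
#' selection regime: `stabilizing` when a retained quadratic yields an
#' interior fitness maximum, `disruptive` for an interior minimum,
#' `directional_positive`/`directional_negative` when fitness is
#' monotone over the range with a retained linear term, and `none` when
#' no trait term was retained.  For survival fitness with a retained
#' quadratic the interior optimum has the closed form `-beta / (2 c)` on
#' the standardized scale (`c` the fitted `z^2` coefficient; the logit
#' link is monotone so the optimum carries over), back-transformed to
#' trait units; otherwise the profile argmax is reported.
#'
#' @param object A [forward_stepwise()] result or an [asterchain()] fit.
#' @param trait Raw trait name.
#' @param data Data supplying the observed range (default: training
#'   data).
#' @param at Covariate overrides for the profile's reference row.
#' @param n_profile Number of profile points (default 201).
#' @return Object of class `selection_form`: list with
#'   `classification`, `optimum` (trait units, `NA` unless interior),
#'   `optimum_z`, `retained`, `profile`.
#' @export
classify_selection <- function(object, trait, data = NULL, at = list(),
                               n_profile = 201L) {
  scaling <- NULL
  retained <- NULL
  if (inherits(object, "aster_stepwise")) {
    scaling <- object$scaling
    retained <- object$retained
    fit <- object$fit
  } else {
    fit <- object
  }
  stopifnot(inherits(fit, "asterchain"))
  if (is.null(data)) data <- fit$data
  scaling <- scaling %||% attr(data, "trait_scaling")
  zl <- paste0("z_", trait)
  zq <- paste0("I(z_", trait, "^2)")
  if (is.null(retained)) {
    retained <- unique(sub("^h:", "",
                           c(names(fit$coefficients$surv),
                             names(fit$coefficients$height))))
  }
  has_lin <- zl %in% retained
  has_quad <- zq %in% retained
  if (!has_lin && !has_quad) {
    return(structure(list(trait = trait, classification = "none",
                          optimum = NA_real_, optimum_z = NA_real_,
                          retained = character(0), profile = NULL),
                     class = "selection_form"))
  }
  b <- trait_binding(fit, trait, scaling)
  rng <- range(data[[trait]], na.rm = TRUE)
  xg <- seq(rng[1L], rng[2L], length.out = n_profile)
  ref <- reference_row(fit, data, at)
  nd <- ref[rep(1L, n_profile), , drop = FALSE]
  nd[[b$col]] <- (xg - b$center) / b$scale
  type <- if (is.null(fit$height_node)) "survival" else "uncond_height"
  w <- predict(fit, nd, type = type)
  eps <- 1e-10 * max(abs(w), 1)
  imax <- which.max(w); imin <- which.min(w)
  interior_max <- imax > 1L && imax < n_profile &&
    w[imax] > w[1L] + eps && w[imax] > w[n_profile] + eps
  interior_min <- imin > 1L && imin < n_profile &&
    w[imin] < w[1L] - eps && w[imin] < w[n_profile] - eps
  opt <- NA_real_; opt_z <- NA_real_
  if (has_quad && interior_max) {
    cls <- "stabilizing"
    ## closed form for pure survival fitness (monotone link)
    if (is.null(fit$height_node) && zl %in% names(fit$coefficients$surv) &&
        zq %in% names(fit$coefficients$surv)) {
      beta <- fit$coefficients$surv[[zl]]
      cc <- fit$coefficients$surv[[zq]]
      opt_z <- -beta / (2 * cc)
    } else {
      opt_z <- (xg[imax] - b$center) / b$scale
    }
    opt <- b$center + b$scale * opt_z
  } else if (has_quad && interior_min) {
    cls <- "disruptive"
    opt_z <- (xg[imin] - b$center) / b$scale
    opt <- b$center + b$scale * opt_z
  } else {
    cls <- if (w[n_profile] >= w[1L]) "directional_positive" else
      "directional_negative"
  }
  structure(list(trait = trait, classification = cls, optimum = opt,
                 optimum_z = opt_z,
                 retained = intersect(retained, c(zl, zq)),
                 profile = data.frame(x = xg, fitness = w)),
            class = "selection_form")
}

#' @export
print.selection_form <- function(x, ...) {
  cat("Selection on ", x$trait, ": ", x$classification, sep = "")
  if (!is.na(x$optimum)) {
    cat("  (optimum at ", format(x$optimum, digits = 5), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
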