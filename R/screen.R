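#' Spearman multicollinearity screen among seedling traits
#'
#' Computes Spearman rank correlations (midranks for ties) between trait
#' pairs within each analysis stratum, using only individuals alive at
#' the terminal census, and flags pairs whose squared rank correlation
#' meets the exclusion threshold (default `r_s^2 >= 0.70`).  Flagged
#' pairs must never co-occur in one candidate selection model; a trait
#' constant within a stratum is flagged unusable there.
#'
#' @param data Wide records.
#' @param traits Character vector of trait columns.
#' @param strata Character vector of stratification columns (e.g.
#'   `"treatment"` or `c("treatment", "provenance")`), or `NULL` for a
#'   single stratum.
#' @param alive Column marking terminal survival (default
#'   `"surv_2011"`); only rows with value 1 enter the correlations.
#' @param r2_threshold Exclusion threshold on `r_s^2` (default 0.70).
#' @return Object of class `trait_screen`: list of per-stratum results
#'   (`r` matrix, `excluded` pair table, `unusable` traits).
#' @export
screen_traits <- function(data, traits, strata = NULL,
                          alive = "surv_2011", r2_threshold = 0.70) {
  if (!is.null(alive) && alive %in% names(data)) {
    data <- data[!is.na(data[[alive]]) & data[[alive]] == 1, , drop = FALSE]
  }
  key <- if (is.null(strata)) rep("all", nrow(data)) else
    interaction(data[strata], drop = TRUE, sep = ":")
  res <- lapply(split(data, key), function(d) {
    usable <- traits[vapply(traits, function(t) {
      v <- d[[t]]
      sum(!is.na(v)) >= 3 && stats::sd(v, na.rm = TRUE) > 0
    }, TRUE)]
    unusable <- setdiff(traits, usable)
    r <- matrix(NA_real_, length(traits), length(traits),
                dimnames = list(traits, traits))
    diag(r) <- 1
    if (length(usable) >= 2L) {
      r[usable, usable] <- stats::cor(d[usable], method = "spearman",
                                      use = "pairwise.complete.obs")
    }
    excl <- data.frame(trait1 = character(0), trait2 = character(0),
                       r_s = numeric(0), r2 = numeric(0))
    if (length(usable) >= 2L) {
      cmb <- utils::combn(usable, 2L)
      for (k in seq_len(ncol(cmb))) {
        rs <- r[cmb[1L, k], cmb[2L, k]]
        if (!is.na(rs) && rs^2 >= r2_threshold) {
          excl <- rbind(excl, data.frame(trait1 = cmb[1L, k],
                                         trait2 = cmb[2L, k],
                                         r_s = rs, r2 = rs^2))
        }
      }
    }
    list(r = r, excluded = excl, unusable = unusable,
         n = nrow(d))
  })
  structure(list(strata = res, traits = traits,
                 r2_threshold = r2_threshold),
            class = "trait_screen")
}

#' @export
print.trait_screen <- function(x, digits = 3, ...) {
  cat("Spearman trait screen (exclusion at r_s^2 >=", x$r2_threshold,
      ")\n")
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    cat("Stratum ", s, " (n = ", st$n, "):\n", sep = "")
    print(round(st$r, digits))
    if (nrow(st$excluded)) {
      cat("  excluded pairs:\n"); print(st$excluded, row.names = FALSE)
    }
    if (length(st$unusable)) {
      cat("  unusable traits:", paste(st$unusable, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

## Screen result for one stratum (or the single "all" stratum).
screen_stratum <- function(screen, stratum = NULL) {
  if (is.null(screen)) return(NULL)
  if (is.null(stratum)) {
    if (length(screen$strata) == 1L) return(screen$strata[[1L]])
    stop("screen has multiple strata; name one")
  }
  out <- screen$strata[[stratum]]
  if (is.null(out)) stop("no screen stratum named '", stratum, "'")
  out
}
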