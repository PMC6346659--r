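#' Validate life-history records against a graph
#'
#' Checks the aster-consistency of a wide table of individual records:
#' Bernoulli responses must be 0/1, heights non-negative, every graph node
#' present, and structural zeros respected (once a survival indicator is
#' 0, every downstream response must be 0; height may be positive only for
#' terminal survivors).  Model fitting refuses data with violations.
#'
#' @param data Data frame, one row per individual, containing one column
#'   per graph node.
#' @param graph An [lh_graph()].
#' @return An object of class `record_validation`: list with elements
#'   `n_violations` and `violations` (data frame with `row`, `node`,
#'   `type`, `message`).
#' @examples
#' g <- lh_graph("a")
#' d <- data.frame(surv_2009 = c(1, 0), surv_2010 = c(1, 1),
#'                 surv_2011 = c(0, 0))
#' validate_records(d, g)  # row 2 violates a structural zero
#' @export
validate_records <- function(data, graph) {
  stopifnot(inherits(graph, "lh_graph"))
  miss <- setdiff(graph$id, names(data))
  if (length(miss)) {
    stop("data lack node column(s): ", paste(miss, collapse = ", "))
  }
  viol <- list()
  add <- function(rows, node, type, msg) {
    if (length(rows)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows, node = node, type = type, message = msg,
        stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(nrow(graph))) {
    id <- graph$id[j]
    v <- data[[id]]
    add(which(is.na(v)), id, "missing", "missing node response")
    if (graph$family[j] == "bernoulli") {
      add(which(!is.na(v) & !v %in% c(0, 1)), id, "domain",
          "survival response not in {0,1}")
    } else {
      add(which(!is.na(v) & v < 0), id, "domain", "negative height")
    }
    if (!is.na(graph$pred[j])) {
      p <- data[[graph$pred[j]]]
      bad <- which(!is.na(v) & !is.na(p) & p == 0 & v != 0)
      add(bad, id, "structural_zero",
          paste0("nonzero response at ", id, " although ",
                 graph$pred[j], " = 0"))
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(0), node = character(0),
               type = character(0), message = character(0))
  structure(list(n_violations = nrow(viol), violations = viol),
            class = "record_validation")
}

#' @export
print.record_validation <- function(x, ...) {
  cat("Record validation:", x$n_violations, "violation(s)\n")
  if (x$n_violations > 0) print(utils::head(x$violations, 10L))
  invisible(x)
}

assert_valid_records <- function(data, graph) {
  v <- validate_records(data, graph)
  if (v$n_violations > 0) {
    stop("data fail aster-consistency checks (", v$n_violations,
         " violation(s)); first: row ", v$violations$row[1L], ", node ",
         v$violations$node[1L], " [", v$violations$type[1L], "]")
  }
  invisible(TRUE)
}

#' Read life-history records from CSV
#'
#' Wide format has one row per individual (design factors, trait
#' covariates and one column per graph node).  Long format has columns
#' `individual_id`, `node_id`, `value` plus optional per-individual
#' covariate columns, and is reshaped to wide on input.
#'
#' @param path CSV file path (comma-separated, UTF-8, `.` decimal;
#'   missing values as empty fields).
#' @param format `"wide"` or `"long"`.
#' @param graph Optional [lh_graph()]; when given, survival/height domains
#'   are checked and a parse error cites the offending row.
#' @return Data frame of records (wide).
#' @export
read_records <- function(path, format = c("wide", "long"), graph = NULL) {
  format <- match.arg(format)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") d <- records_long_to_wide(d)
  if (!is.null(graph)) {
    for (j in seq_len(nrow(graph))) {
      id <- graph$id[j]
      if (!id %in% names(d)) next
      v <- d[[id]]
      bad <- if (graph$family[j] == "bernoulli") {
        which(!is.na(v) & !v %in% c(0, 1))
      } else {
        which(!is.na(v) & v < 0)
      }
      if (length(bad)) {
        stop("parse error in ", basename(path), ": invalid value ",
             v[bad[1L]], " for node '", id, "' at row ", bad[1L])
      }
    }
  }
  d
}

#' Reshape records between wide and long layouts
#'
#' @param data Wide data frame of records.
#' @param node_ids Character vector of node columns to melt (defaults to
#'   the known preset node names present in `data`).
#' @return `records_wide_to_long()`: long data frame with
#'   `individual_id`, `node_id`, `value` and the remaining columns
#'   carried per individual. `records_long_to_wide()` inverts it.
#' @export
records_wide_to_long <- function(data, node_ids = NULL) {
  if (is.null(node_ids)) {
    node_ids <- intersect(
      c("surv_2009", "surv_2010", "surv_2011", "height_2011"), names(data))
  }
  if (!"individual_id" %in% names(data)) {
    data$individual_id <- seq_len(nrow(data))
  }
  keep <- setdiff(names(data), node_ids)
  out <- do.call(rbind, lapply(node_ids, function(id) {
    cbind(data[keep],
          data.frame(node_id = id, value = data[[id]],
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out[order(out$individual_id), , drop = FALSE]
}

#' @rdname records_wide_to_long
#' @export
records_long_to_wide <- function(data) {
  stopifnot(all(c("individual_id", "node_id", "value") %in% names(data)))
  node_ids <- unique(data$node_id)
  keep <- setdiff(names(data), c("node_id", "value"))
  base <- unique(data[keep])
  if (anyDuplicated(base$individual_id)) {
    stop("long records carry inconsistent covariates within individual")
  }
  wide <- base
  for (id in node_ids) {
    sub <- data[data$node_id == id, c("individual_id", "value")]
    wide[[id]] <- sub$value[match(wide$individual_id, sub$individual_id)]
  }
  rownames(wide) <- NULL
  wide[order(wide$individual_id), , drop = FALSE]
}

#' Restrict records to an analysis window
#'
#' The `from_2009` window keeps every emergent and uses the full survival
#' chain; the `from_2010` window keeps only individuals alive in spring
#' 2010 (those that survived the year of emergence), the cohort on which
#' second-year shoot-elongation traits are expressed.  Pair with graph
#' presets `"a"`/`"c"` and `"b"`/`"d"` respectively.
#'
#' @param data Wide records.
#' @param window `"from_2009"` or `"from_2010"`.
#' @return Filtered data frame.
#' @export
subset_cohort <- function(data, window = c("from_2009", "from_2010")) {
  window <- match.arg(window)
  out <- if (window == "from_2010") {
    if (!"surv_2009" %in% names(data)) {
      stop("from_2010 window needs a surv_2009 column")
    }
    data[!is.na(data$surv_2009) & data$surv_2009 == 1, , drop = FALSE]
  } else {
    data
  }
  if (nrow(out) == 0L) stop("empty cohort after window subset")
  out
}

#' Standardize traits for selection-gradient terms
#'
#' Centers and scales the given trait columns to mean 0, variance 1
#' (within the supplied data, i.e. the analysis stratum), adding columns
#' `z_<trait>`.  Centers and scales are stored in the
#' `"trait_scaling"` attribute so gradients can be reported back on the
#' raw trait scale.
#'
#' @param data Data frame.
#' @param traits Character vector of trait column names.
#' @return `data` with added `z_` columns and a `trait_scaling` attribute
#'   (data frame with `trait`, `center`, `scale`).
#' @export
standardize_traits <- function(data, traits) {
  sc <- data.frame(trait = traits, center = NA_real_, scale = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(traits)) {
    v <- data[[traits[k]]]
    if (is.null(v)) stop("trait column not found: ", traits[k])
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1  # constant trait: center only
    sc$center[k] <- m
    sc$scale[k] <- s
    data[[paste0("z_", traits[k])]] <- (v - m) / s
  }
  attr(data, "trait_scaling") <- sc
  data
}
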