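#' Life-history graphs for aster chain models
#'
#' An aster chain graph lists the fitness components measured on each
#' individual and how they condition on one another: each node is a
#' Bernoulli survival indicator or the terminal normal height, and each
#' non-root node has exactly one predecessor.  A response at a node is
#' forced to zero (a structural zero) whenever its predecessor's response
#' is zero.
#'
#' Four presets cover the common-garden analyses:
#' \describe{
#'   \item{`"a"`}{survival chain `surv_2009 -> surv_2010 -> surv_2011`
#'     (fitness = survival from emergence through year 3);}
#'   \item{`"b"`}{survival chain `surv_2010 -> surv_2011` for individuals
#'     alive in spring 2010;}
#'   \item{`"c"`}{preset `"a"` plus a terminal normal node `height_2011`
#'     (fitness = unconditional expected height at age 3);}
#'   \item{`"d"`}{preset `"b"` plus `height_2011`.}
#' }
#'
#' @param preset One of `"a"`, `"b"`, `"c"`, `"d"`, or `NULL` when a
#'   custom `nodes` table is supplied.
#' @param nodes Optional data frame with columns `id`, `family`
#'   (`"bernoulli"` or `"normal"`), `pred` (predecessor id, `NA` for the
#'   root) and optionally `label` and `year`.
#' @return An object of class `lh_graph`: a data frame of nodes (in
#'   topological order) with attributes `root` and `terminal`.
#' @examples
#' lh_graph("c")
#' @export
lh_graph <- function(preset = c("a", "b", "c", "d"), nodes = NULL) {
  if (is.null(nodes)) {
    preset <- match.arg(preset)
    surv09 <- data.frame(
      id = c("surv_2009", "surv_2010", "surv_2011"),
      label = c("survival 2009", "survival 2010", "survival 2011"),
      family = "bernoulli",
      pred = c(NA, "surv_2009", "surv_2010"),
      year = c(2009L, 2010L, 2011L),
      stringsAsFactors = FALSE
    )
    surv10 <- surv09[-1L, ]
    surv10$pred[1L] <- NA
    height <- data.frame(
      id = "height_2011", label = "final height 2011 (mm)",
      family = "normal", pred = "surv_2011", year = 2011L,
      stringsAsFactors = FALSE
    )
    nodes <- switch(preset,
      a = surv09,
      b = surv10,
      c = rbind(surv09, height),
      d = rbind(surv10, height)
    )
  }
  validate_lh_graph(nodes)
}

## Checks the structural invariants and returns the classed graph with
## nodes in topological (root-first) order.
validate_lh_graph <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("id", "family", "pred")
  if (!all(req %in% names(nodes))) {
    stop("graph nodes need columns: ", paste(req, collapse = ", "))
  }
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  if (!"year" %in% names(nodes)) nodes$year <- NA_integer_
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1L])
  }
  if (!all(nodes$family %in% c("bernoulli", "normal"))) {
    bad <- nodes$id[!nodes$family %in% c("bernoulli", "normal")][1L]
    stop("node '", bad, "' has unknown family (must be bernoulli or normal)")
  }
  roots <- nodes$id[is.na(nodes$pred)]
  if (length(roots) != 1L) {
    stop("graph must have exactly one root node, found ", length(roots))
  }
  missing_pred <- setdiff(stats::na.omit(nodes$pred), nodes$id)
  if (length(missing_pred)) {
    stop("predecessor not in graph: ", missing_pred[1L])
  }
  ## chain structure: each node is predecessor of at most one node
  succ_tab <- table(stats::na.omit(nodes$pred))
  if (any(succ_tab > 1L)) {
    stop("node '", names(succ_tab)[succ_tab > 1L][1L],
         "' has multiple successors; aster chain graphs are linear")
  }
  ## topological sort (detects cycles)
  order_ids <- character(0)
  placed <- roots
  repeat {
    order_ids <- c(order_ids, placed)
    nxt <- nodes$id[!is.na(nodes$pred) & nodes$pred %in% placed]
    nxt <- setdiff(nxt, order_ids)
    if (!length(nxt)) break
    placed <- nxt
  }
  if (length(order_ids) != nrow(nodes)) {
    off <- setdiff(nodes$id, order_ids)
    stop("cycle detected in graph involving node(s): ",
         paste(off, collapse = ", "))
  }
  nodes <- nodes[match(order_ids, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  normal_ids <- nodes$id[nodes$family == "normal"]
  if (length(normal_ids) > 1L) {
    stop("at most one normal node allowed, found: ",
         paste(normal_ids, collapse = ", "))
  }
  if (length(normal_ids) == 1L) {
    if (normal_ids %in% nodes$pred) {
      stop("normal node '", normal_ids,
           "' has a successor; the height node must be terminal")
    }
  }
  terminal <- nodes$id[!nodes$id %in% nodes$pred]
  structure(nodes,
            root = nodes$id[1L],
            terminal = terminal,
            class = c("lh_graph", "data.frame"))
}

#' @export
print.lh_graph <- function(x, ...) {
  cat("Life-history chain graph (", nrow(x), " nodes)\n", sep = "")
  arrows <- ifelse(is.na(x$pred), "[root]", paste0(x$pred, " ->"))
  cat(paste0("  ", format(arrows, width = max(nchar(arrows))), " ", x$id,
             "  (", x$family, ")"), sep = "\n")
  invisible(x)
}

## Bernoulli node ids, in chain order.
graph_surv_nodes <- function(graph) graph$id[graph$family == "bernoulli"]

## Normal node id or NULL.
graph_height_node <- function(graph) {
  id <- graph$id[graph$family == "normal"]
  if (length(id)) id else NULL
}

## Terminal Bernoulli node (last survival indicator).
graph_terminal_surv <- function(graph) {
  s <- graph_surv_nodes(graph)
  s[length(s)]
}
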