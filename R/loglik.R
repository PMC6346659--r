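#' Joint log-likelihood of an aster chain at given node parameters
#'
#' Evaluates the joint log density of the recorded responses under the
#' conditional factorization of the chain graph: each Bernoulli node
#' contributes `log p` or `log(1 - p)` for individuals whose predecessor
#' response is 1 (the root node for all individuals), the terminal normal
#' node contributes a normal log density for terminal survivors, and
#' every node whose predecessor response is 0 contributes exactly 0 (the
#' conditional distribution is degenerate at the structural zero).
#'
#' @param data Validated wide records (see [validate_records()]).
#' @param graph An [lh_graph()].
#' @param pars Named list keyed by node id.  For a Bernoulli node, a list
#'   with element `p` (success probability, scalar or per-individual
#'   vector).  For the normal node, a list with `mean` (mm) and `sigma2`
#'   (mm^2, scalar).
#' @return Log-likelihood in nats (a single number).
#' @examples
#' g <- lh_graph("a")
#' d <- data.frame(surv_2009 = 1, surv_2010 = 1, surv_2011 = 0)
#' aster_loglik(d, g, list(surv_2009 = list(p = 0.5),
#'                         surv_2010 = list(p = 0.5),
#'                         surv_2011 = list(p = 0.5)))
#' @export
aster_loglik <- function(data, graph, pars) {
  stopifnot(inherits(graph, "lh_graph"))
  assert_valid_records(data, graph)
  n <- nrow(data)
  ll <- 0
  for (j in seq_len(nrow(graph))) {
    id <- graph$id[j]
    at_risk <- if (is.na(graph$pred[j])) rep(TRUE, n) else
      data[[graph$pred[j]]] == 1
    if (!any(at_risk)) next
    y <- data[[id]][at_risk]
    pj <- pars[[id]]
    if (is.null(pj)) stop("no parameters supplied for node '", id, "'")
    if (graph$family[j] == "bernoulli") {
      p <- rep_len(pj$p, n)[at_risk]
      if (any(p <= 0 | p >= 1)) {
        stop("p outside (0,1) on contributing node '", id, "'")
      }
      ll <- ll + sum(y * log(p) + (1 - y) * log(1 - p))
    } else {
      if (is.null(pj$sigma2) || pj$sigma2 <= 0) {
        stop("sigma2 must be > 0 for node '", id, "'")
      }
      mu <- rep_len(pj$mean, n)[at_risk]
      ll <- ll + sum(stats::dnorm(y, mu, sqrt(pj$sigma2), log = TRUE))
    }
  }
  ll
}
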