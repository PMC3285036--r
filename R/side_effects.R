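#' Affected ratio of a single node
#'
#' For a node i receiving flow, `P_i = F_i / K_i`, where `K_i` is the
#' node's in-degree in the augmented network (the dummy source arc counts
#' for the candidate) and `F_i` is the number of those incoming arcs that
#' actually carry positive flow in the canonical solution. The ratio
#' measures what fraction of a node's upstream neighbourhood the
#' candidate's intervention touches.
#'
#' @param node Gene id; must receive positive inflow and not be a dummy.
#' @param fr The `flow_result` solved on `fn`.
#' @param fn The `flow_network` the result came from.
#' @return `P_i` in (0, 1\].
#' @export
affected_ratio <- function(node, fr, fn) {
  stopifnot(inherits(fr, "flow_result"), inherits(fn, "flow_network"))
  if (node %in% c("S", "T"))
    stop("affected ratio is undefined for dummy nodes", call. = FALSE)
  inc <- fr$arc_flows$to == node
  k <- sum(inc)
  f <- sum(inc & fr$arc_flows$flow > 1e-9)
  if (f == 0L)
    stop("node '", node, "' receives no flow", call. = FALSE)
  f / k
}

#' Affected-genes score of a candidate
#'
#' Sums the affected ratio over every non-dummy node with positive inflow
#' in the canonical max-flow solution. Larger totals mean the candidate's
#' flow spreads through more of the network — a proxy for off-target side
#' effects. Disease genes themselves are included; interpretation is left
#' to the user. Because per-arc flows are canonical but not unique (see
#' [max_flow_push_relabel()]), the score is reproducible for this solver
#' but could differ under another optimal flow decomposition.
#'
#' @param fr The `flow_result` solved on `fn`.
#' @param fn The `flow_network` the result came from.
#' @return An `affected_score`: list with `candidate`, `per_node` (named
#'   vector of `P_i`) and `total` (the AG score).
#' @export
affected_genes_total <- function(fr, fn) {
  stopifnot(inherits(fr, "flow_result"), inherits(fn, "flow_network"))
  af <- fr$arc_flows
  recv <- unique(af$to[af$flow > 1e-9])
  recv <- sort(setdiff(recv, c("S", "T")))
  per_node <- vapply(recv, affected_ratio, numeric(1), fr = fr, fn = fn)
  structure(list(candidate = fr$candidate,
                 per_node = per_node,
                 total = sum(per_node)),
            class = "affected_score")
}

#' @export
print.affected_score <- function(x, ...) {
  cat(sprintf("affected_score: candidate %s, AG = %.4g over %d node(s)\n",
              x$candidate, x$total, length(x$per_node)))
  invisible(x)
}
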