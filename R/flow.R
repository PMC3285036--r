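#' Augment the weighted network for one candidate's flow problem
#'
#' Adds a dummy source `S` with a single effectively-infinite arc to the
#' candidate, and a dummy sink `T` receiving an effectively-infinite arc
#' from every disease gene. A disease gene that is itself a candidate
#' protein is linked only from the source side and gets no arc to the sink
#' (it would otherwise absorb unbounded flow unfairly). "Infinite" is
#' realized as `big_m` = (sum of all finite capacities) + 1, which no
#' combination of base arcs can saturate.
#'
#' @param net A `weighted_network`.
#' @param candidate Candidate gene id to connect to the source.
#' @param disease_set Character vector of disease gene ids (nonempty).
#' @param candidate_set Full candidate protein set (used for the
#'   disease-overlap rule); defaults to `candidate` alone.
#' @return A `flow_network`: the base arcs plus dummy arcs, with fields
#'   `candidate`, `disease_set`, `candidate_set`, `big_m` and a
#'   `disconnected` flag set when the candidate is absent from the network.
#' @export
build_flow_network <- function(net, candidate, disease_set,
                               candidate_set = candidate) {
  stopifnot(inherits(net, "weighted_network"))
  if (length(disease_set) == 0L)
    stop("disease set is empty", call. = FALSE)
  if (!candidate %in% candidate_set)
    stop("candidate must belong to the candidate set", call. = FALSE)
  disease_set <- sort(unique(as.character(disease_set)))
  disconnected <- !candidate %in% net$nodes
  big_m <- sum(net$arcs$capacity) + 1

  sink_genes <- setdiff(disease_set, candidate_set)
  dummy <- rbind(
    data.frame(from = "S", to = candidate, capacity = big_m,
               origin = "dummy", stringsAsFactors = FALSE),
    if (length(sink_genes))
      data.frame(from = sink_genes, to = "T", capacity = big_m,
                 origin = "dummy", stringsAsFactors = FALSE))
  arcs <- rbind(net$arcs, dummy)
  rownames(arcs) <- NULL
  nodes <- c(sort(unique(c(net$nodes, candidate, disease_set))), "S", "T")
  structure(list(nodes = nodes, arcs = arcs, candidate = candidate,
                 disease_set = disease_set,
                 candidate_set = sort(unique(as.character(candidate_set))),
                 big_m = big_m, disconnected = disconnected),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("flow_network: candidate %s -> %d disease gene(s); %d nodes, %d arcs%s\n",
              x$candidate, length(x$disease_set), length(x$nodes),
              nrow(x$arcs),
              if (x$disconnected) " [disconnected candidate]" else ""))
  invisible(x)
}

# Solver-internal indexed form: residual arc arrays with paired reverse arcs.
# Forward arc i sits at position 2i-1, its zero-capacity reverse at 2i.
flow_index <- function(fn) {
  nodes <- fn$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  m <- nrow(fn$arcs)
  from <- idx[fn$arcs$from]
  to <- idx[fn$arcs$to]
  cap <- fn$arcs$capacity
  rfrom <- integer(2L * m); rto <- integer(2L * m); rcap <- numeric(2L * m)
  fwd <- seq(1L, 2L * m, by = 2L)
  rfrom[fwd] <- from;  rto[fwd] <- to;   rcap[fwd] <- cap
  rfrom[fwd + 1L] <- to; rto[fwd + 1L] <- from; rcap[fwd + 1L] <- 0
  adj <- split(seq_len(2L * m), factor(rfrom, levels = seq_len(n)))
  list(nodes = nodes, n = n, m = m, idx = idx,
       rfrom = rfrom, rto = rto, rcap = rcap, fwd = fwd,
       adj = adj, s = idx[["S"]], t = idx[["T"]])
}

# reverse-residual-arc id: partner of arc a in the paired layout
rev_arc <- function(a) a + 1L - 2L * ((a - 1L) %% 2L)

#' Initial node heights by breadth-first search toward the sink
#'
#' The height of a node is the number of arcs on the shortest directed path
#' from it to the dummy sink `T`; `T` itself has height 0. Nodes that
#' cannot reach the sink get the sentinel height `|V|`, which keeps the
#' solver from pushing flow toward dead ends.
#'
#' @param fn A `flow_network`.
#' @return Named integer vector of heights over all nodes.
#' @export
bfs_heights <- function(fn) {
  stopifnot(inherits(fn, "flow_network"))
  fi <- flow_index(fn)
  h <- bfs_dist_to(fi, fi$t, use_cap = FALSE)
  stats::setNames(as.integer(h), fi$nodes)
}

# BFS distance from every node to `target` following arc directions.
# use_cap = TRUE restricts to arcs with residual capacity > eps (for
# global checks on the residual graph); unreachable nodes get n.
bfs_dist_to <- function(fi, target, use_cap = FALSE, rcap = NULL,
                        eps = 1e-12) {
  n <- fi$n
  # incoming-arc adjacency on the forward arcs only
  keep <- if (use_cap) fi$fwd[rcap[fi$fwd] > eps] else fi$fwd
  inc <- split(fi$rfrom[keep], factor(fi$rto[keep], levels = seq_len(n)))
  dist <- rep.int(n, n)
  dist[target] <- 0L
  frontier <- target
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(inc[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] == n]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Maximum s-t flow by push-relabel with BFS height initialization
#'
#' Node heights start at their BFS distance to the dummy sink; the source
#' is pinned at height `|V|` and its arcs are saturated. Active nodes
#' (positive excess) are then discharged highest-label-first, FIFO among
#' equal heights, pushing excess along admissible arcs (positive residual
#' capacity, height exactly one above the receiver) and relabeling when no
#' admissible arc remains, until no active node is left. Iteration order
#' over nodes and arcs is fixed (lexicographic gene ids), so the returned
#' per-arc flows are bit-reproducible; note that while the flow *value* is
#' unique, the per-arc decomposition generally is not, and a different
#' solver could legitimately return different arc flows. Residual flow
#' circulating on the two arcs of a bidirectional PPI pair is cancelled
#' before reporting.
#'
#' @param fn A `flow_network`.
#' @return A `flow_result`: list with `candidate`, `value` (the maximum
#'   flow), `arc_flows` (data frame `from`, `to`, `flow`, `capacity`),
#'   `heights` (final labels), and `steps` (ordered push log with columns
#'   `step`, `push_node`, `flow`, `received_node`).
#' @export
max_flow_push_relabel <- function(fn) {
  stopifnot(inherits(fn, "flow_network"))
  fi <- flow_index(fn)
  eps <- 1e-12
  n <- fi$n; s <- fi$s; t <- fi$t
  rcap <- fi$rcap
  h <- bfs_dist_to(fi, t, use_cap = FALSE)
  h[s] <- n
  excess <- numeric(n)
  cur <- rep.int(1L, n)

  log_u <- character(0); log_amt <- numeric(0); log_v <- character(0)

  # saturate source arcs
  for (a in fi$adj[[s]]) {
    if (rcap[a] > eps) {
      d <- rcap[a]; v <- fi$rto[a]
      rcap[a] <- 0; rcap[rev_arc(a)] <- rcap[rev_arc(a)] + d
      excess[v] <- excess[v] + d
      log_u <- c(log_u, fi$nodes[s]); log_amt <- c(log_amt, d)
      log_v <- c(log_v, fi$nodes[v])
    }
  }
  active <- setdiff(which(excess > eps), c(s, t))

  while (length(active)) {
    u <- active[which.max(h[active])]   # highest label, FIFO tie-break
    arcs_u <- fi$adj[[u]]
    repeat {
      if (cur[u] > length(arcs_u)) {
        # relabel: one above the lowest residual neighbour
        res <- arcs_u[rcap[arcs_u] > eps]
        if (!length(res)) break        # excess is stranded (cannot occur)
        h[u] <- 1L + min(h[fi$rto[res]])
        cur[u] <- 1L
      } else {
        a <- arcs_u[cur[u]]
        v <- fi$rto[a]
        if (rcap[a] > eps && h[u] == h[v] + 1L) {
          d <- min(excess[u], rcap[a])
          rcap[a] <- rcap[a] - d
          rcap[rev_arc(a)] <- rcap[rev_arc(a)] + d
          excess[u] <- excess[u] - d
          excess[v] <- excess[v] + d
          log_u <- c(log_u, fi$nodes[u]); log_amt <- c(log_amt, d)
          log_v <- c(log_v, fi$nodes[v])
          if (v != s && v != t && !(v %in% active))
            active <- c(active, v)
          if (excess[u] <= eps) break
        } else {
          cur[u] <- cur[u] + 1L
        }
      }
    }
    active <- active[excess[active] > eps]
  }

  flow <- fi$rcap[fi$fwd] - rcap[fi$fwd]   # capacity minus residual
  flow[flow < 0] <- 0
  af <- data.frame(from = fn$arcs$from, to = fn$arcs$to,
                   flow = flow, capacity = fn$arcs$capacity,
                   stringsAsFactors = FALSE)
  af <- cancel_antiparallel(af)
  value <- sum(af$flow[af$to == "T"])
  steps <- data.frame(step = seq_along(log_u), push_node = log_u,
                      flow = log_amt, received_node = log_v,
                      stringsAsFactors = FALSE)
  structure(list(candidate = fn$candidate, value = value, arc_flows = af,
                 heights = stats::setNames(as.integer(h), fi$nodes),
                 steps = steps),
            class = "flow_result")
}

# A preflow push can route flow both ways along an antiparallel PPI arc
# pair; the net flow is what matters, so cancel the common part.
cancel_antiparallel <- function(af) {
  key <- paste0(af$from, "\r", af$to)
  rev_key <- paste0(af$to, "\r", af$from)
  j <- match(rev_key, key)
  has_rev <- !is.na(j)
  i <- which(has_rev & seq_along(key) < j)
  if (length(i)) {
    ji <- j[i]
    c0 <- pmin(af$flow[i], af$flow[ji])
    af$flow[i] <- af$flow[i] - c0
    af$flow[ji] <- af$flow[ji] - c0
  }
  af
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: candidate %s, maximum flow %.4g (%d arcs carry flow)\n",
              x$candidate, x$value, sum(x$arc_flows$flow > 1e-9)))
  invisible(x)
}

#' Flow on a single arc of the canonical solution
#'
#' @param fr A `flow_result`.
#' @param u,v Arc endpoints.
#' @return The flow carried by arc `(u, v)` in the canonical run. Per-arc
#'   flows are deterministic for this solver but not unique across solvers;
#'   see [max_flow_push_relabel()].
#' @export
arc_flow <- function(fr, u, v) {
  stopifnot(inherits(fr, "flow_result"))
  i <- which(fr$arc_flows$from == u & fr$arc_flows$to == v)
  if (!length(i))
    stop("no arc (", u, ", ", v, ") in the flow network", call. = FALSE)
  fr$arc_flows$flow[i[1L]]
}

#' Maximum flow by shortest augmenting paths (test oracle)
#'
#' Independent Edmonds-Karp implementation used to cross-check the
#' push-relabel solver; returns the flow value only.
#'
#' @param fn A `flow_network`.
#' @return Maximum flow value.
#' @export
edmonds_karp_oracle <- function(fn) {
  stopifnot(inherits(fn, "flow_network"))
  fi <- flow_index(fn)
  eps <- 1e-12
  rcap <- fi$rcap
  s <- fi$s; t <- fi$t
  total <- 0
  repeat {
    # BFS for a shortest residual path s -> t
    parent_arc <- integer(fi$n)
    seen <- logical(fi$n); seen[s] <- TRUE
    frontier <- s
    while (length(frontier) && !seen[t]) {
      nxt <- integer(0)
      for (u in frontier) {
        for (a in fi$adj[[u]]) {
          v <- fi$rto[a]
          if (!seen[v] && rcap[a] > eps) {
            seen[v] <- TRUE
            parent_arc[v] <- a
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
    if (!seen[t]) break
    # bottleneck along the path
    path <- integer(0)
    v <- t
    while (v != s) {
      a <- parent_arc[v]
      path <- c(path, a)
      v <- fi$rfrom[a]
    }
    d <- min(rcap[path])
    rcap[path] <- rcap[path] - d
    rcap[rev_arc(path)] <- rcap[rev_arc(path)] + d
    total <- total + d
  }
  total
}
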