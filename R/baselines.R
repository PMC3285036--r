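# Undirected view of the partially directed network: one link per PPI pair,
# one link per regulatory arc. This is the link count "degree" uses.
network_links <- function(net) {
  arcs <- net$arcs
  ppi <- arcs[arcs$origin == "ppi", , drop = FALSE]
  reg <- arcs[arcs$origin != "ppi", , drop = FALSE]
  if (nrow(ppi)) {
    key <- paste0(pmin(ppi$from, ppi$to), "\r", pmax(ppi$from, ppi$to))
    ppi <- ppi[!duplicated(key), , drop = FALSE]
  }
  rbind(ppi, reg)
}

node_degrees <- function(net) {
  links <- network_links(net)
  tab <- table(factor(c(links$from, links$to), levels = net$nodes))
  stats::setNames(as.integer(tab), net$nodes)
}

rank_frame <- function(candidates, score) {
  ord <- order(-score, candidates)
  data.frame(candidate = candidates[ord], score = score[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Rank candidates by degree centrality
#'
#' Degree is the number of links incident on the node: a bidirectional PPI
#' pair counts once, a directed regulatory arc counts once (in either
#' orientation). Candidates absent from the network get degree 0.
#'
#' @param net A `weighted_network`.
#' @param candidates Character vector of candidate gene ids.
#' @return Data frame `candidate`, `score`, `rank`, sorted by score
#'   descending, ties broken lexicographically.
#' @export
degree_rank <- function(net, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  deg <- node_degrees(net)
  score <- ifelse(candidates %in% names(deg), deg[candidates], 0L)
  rank_frame(candidates, as.numeric(score))
}

#' Rank candidates by neighbourhood degree entropy
#'
#' For node i, the degrees of its neighbours are normalized to a
#' probability distribution `p_j = deg(j) / sum(deg over N(i))` and the
#' score is its Shannon entropy `H_i = -sum p_j log2 p_j`. A node with one
#' neighbour scores 0; one with m equal-degree neighbours scores log2(m).
#' Neighbourhood and degree use the undirected link view of the network.
#'
#' @inheritParams degree_rank
#' @return Data frame `candidate`, `score`, `rank`.
#' @export
entropy_rank <- function(net, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  links <- network_links(net)
  deg <- node_degrees(net)
  nbrs <- function(v) {
    if (!v %in% net$nodes) return(character(0))
    unique(c(links$to[links$from == v], links$from[links$to == v]))
  }
  score <- vapply(candidates, function(v) {
    nb <- nbrs(v)
    if (length(nb) == 0L) return(0)
    p <- deg[nb] / sum(deg[nb])
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  rank_frame(candidates, score)
}

# igraph view with capacity-derived distances 1/w; zero-capacity arcs are
# unusable and dropped.
as_igraph_dist <- function(net) {
  arcs <- net$arcs[net$arcs$capacity > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    arcs[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = net$nodes))
  igraph::E(g)$weight <- 1 / arcs$capacity
  g
}

#' Rank candidates by weighted betweenness centrality
#'
#' Shortest paths are computed on the directed network with arc length
#' `1/capacity`, so strongly coupled edges are short; zero-capacity arcs
#' are excluded.
#'
#' @inheritParams degree_rank
#' @return Data frame `candidate`, `score`, `rank`.
#' @export
betweenness_rank <- function(net, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  g <- as_igraph_dist(net)
  btw <- igraph::betweenness(g, directed = TRUE)
  score <- ifelse(candidates %in% names(btw), btw[candidates], 0)
  rank_frame(candidates, as.numeric(score))
}

#' Rank candidates by weighted closeness centrality
#'
#' Closeness of node v is `(n_reachable - 1) / sum(d(v, u))` over the nodes
#' reachable from v, with distances `1/capacity` along arc directions;
#' isolated nodes (nothing reachable) score 0.
#'
#' @inheritParams degree_rank
#' @return Data frame `candidate`, `score`, `rank`.
#' @export
closeness_rank <- function(net, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  g <- as_igraph_dist(net)
  dm <- igraph::distances(g, mode = "out")
  clo <- apply(dm, 1L, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (!length(d)) 0 else length(d) / sum(d)
  })
  score <- ifelse(candidates %in% names(clo), clo[candidates], 0)
  rank_frame(candidates, as.numeric(score))
}

#' Rank candidates by random walk with restart
#'
#' A walker starts at the candidate, at each step either restarts there
#' (probability `alpha`) or moves along an out-arc chosen with probability
#' proportional to arc capacity; a node with no usable out-arc sends the
#' walker back to the restart node. The candidate's score is the stationary
#' probability mass on the disease genes.
#'
#' @inheritParams degree_rank
#' @param disease Character vector of disease gene ids.
#' @param alpha Restart probability in (0, 1), default 0.3.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter Iteration cap, default 10000.
#' @return Data frame `candidate`, `score`, `rank`.
#' @export
rwr_rank <- function(net, candidates, disease, alpha = 0.3,
                     tol = 1e-10, max_iter = 10000L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  candidates <- sort(unique(as.character(candidates)))
  nodes <- net$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  arcs <- net$arcs[net$arcs$capacity > 0, , drop = FALSE]
  out_sum <- tapply(arcs$capacity, factor(arcs$from, levels = nodes), sum)
  out_sum[is.na(out_sum)] <- 0
  ai <- idx[arcs$from]; aj <- idx[arcs$to]
  p_arc <- arcs$capacity / out_sum[arcs$from]
  dis <- intersect(disease, nodes)

  score <- vapply(candidates, function(cand) {
    if (!cand %in% nodes) return(0)
    e <- numeric(n); e[idx[cand]] <- 1
    p <- e
    for (it in seq_len(max_iter)) {
      moved <- numeric(n)
      flowed <- p[ai] * p_arc
      moved_tab <- tapply(flowed, factor(aj, levels = seq_len(n)), sum)
      moved_tab[is.na(moved_tab)] <- 0
      moved <- as.numeric(moved_tab)
      dangling <- sum(p[out_sum[nodes] == 0])
      p_new <- (1 - alpha) * (moved + dangling * e) + alpha * e
      if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
      p <- p_new
    }
    sum(p[idx[dis]])
  }, numeric(1))
  rank_frame(candidates, score)
}

#' Rank candidates by absolute differential-expression t statistic
#'
#' The pure expression baseline: candidates are ordered by the absolute
#' Welch t statistic of cancer vs normal, no network information used.
#' Candidates absent from the matrix score 0.
#'
#' @param em An [expression_matrix()].
#' @param candidates Character vector of candidate gene ids.
#' @return Data frame `candidate`, `score`, `rank`.
#' @export
ttest_rank <- function(em, candidates) {
  candidates <- sort(unique(as.character(candidates)))
  score <- vapply(candidates, function(g) {
    if (!g %in% gene_ids(em)) return(0)
    abs(ttest_statistic(em, g))
  }, numeric(1))
  rank_frame(candidates, score)
}

as_ranking <- function(ranking) {
  if (is.data.frame(ranking)) ranking$candidate
  else if (inherits(ranking, "ranking_table")) ranking$rows$candidate
  else as.character(ranking)
}

#' Precision-recall evaluation of a ranking
#'
#' Precision at a cutoff is the fraction of true targets among candidates
#' ranked at or above it; recall is the fraction of all true targets
#' retrieved. At each attained recall level the interpolated precision is
#' the maximum precision at that recall or beyond; the mean of these over
#' the attained levels is the mean average precision (mAP).
#'
#' @param ranking Ordered candidate ids (character vector, rank data frame
#'   or `ranking_table`), best first.
#' @param truth Nonempty set of true target ids, a subset of the ranking.
#' @return List with `pr_points` (data frame `recall`, `precision` of the
#'   interpolated curve) and `map_score`.
#' @export
precision_recall <- function(ranking, truth) {
  ids <- as_ranking(ranking)
  truth <- unique(as.character(truth))
  if (!length(truth)) stop("empty truth set", call. = FALSE)
  if (!all(truth %in% ids))
    stop("truth contains ids outside the ranking", call. = FALSE)
  rel <- ids %in% truth
  prec <- cumsum(rel) / seq_along(ids)
  rec <- cumsum(rel) / length(truth)
  levels <- rec[rel]                       # recall levels actually attained
  interp <- vapply(levels, function(r) max(prec[rec >= r]), numeric(1))
  list(pr_points = data.frame(recall = levels, precision = interp),
       map_score = mean(interp))
}

#' True targets found in the top k% of a ranking
#'
#' For each fraction, the window size is `round(fraction * n)` (at least
#' 1); reported are the number of true targets inside the window and their
#' average 1-based position (`NA` when none are found).
#'
#' @inheritParams precision_recall
#' @param fractions Window fractions in (0, 1\], default 1%, 3%, 15%.
#' @return Data frame `fraction`, `k`, `found`, `avg_position`.
#' @export
topk_average_position <- function(ranking, truth,
                                  fractions = c(0.01, 0.03, 0.15)) {
  ids <- as_ranking(ranking)
  truth <- unique(as.character(truth))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]", call. = FALSE)
  n <- length(ids)
  do.call(rbind, lapply(fractions, function(f) {
    k <- max(1L, round(f * n))
    pos <- which(ids[seq_len(k)] %in% truth)
    data.frame(fraction = f, k = k, found = length(pos),
               avg_position = if (length(pos)) mean(pos) else NA_real_)
  }))
}

#' Collapse bidirectional PPI edges to random directions
#'
#' Each antiparallel PPI arc pair is replaced by a single directed arc, the
#' direction chosen by a fair coin flip; regulatory arcs and capacities are
#' untouched. Turns the partially directed network into a fully directed
#' one so the two regimes can be compared.
#'
#' @param net A `weighted_network`.
#' @param seed Integer RNG seed; the same seed reproduces the same network.
#' @return A `weighted_network` with one arc per former PPI pair.
#' @export
randomize_directions <- function(net, seed) {
  stopifnot(inherits(net, "weighted_network"))
  arcs <- net$arcs
  ppi <- arcs[arcs$origin == "ppi", , drop = FALSE]
  reg <- arcs[arcs$origin != "ppi", , drop = FALSE]
  if (nrow(ppi) == 0L) return(net)
  key <- paste0(pmin(ppi$from, ppi$to), "\r", pmax(ppi$from, ppi$to))
  pairs <- ppi[!duplicated(key), , drop = FALSE]
  pairs <- pairs[order(pmin(pairs$from, pairs$to),
                       pmax(pairs$from, pairs$to)), , drop = FALSE]
  flips <- with_local_seed(seed, stats::runif(nrow(pairs)) < 0.5)
  directed <- data.frame(
    from = ifelse(flips, pairs$from, pairs$to),
    to = ifelse(flips, pairs$to, pairs$from),
    capacity = pairs$capacity, origin = "ppi",
    stringsAsFactors = FALSE)
  new_weighted_network(net$nodes, rbind(directed, reg))
}

#' Least-squares logarithmic trend fit
#'
#' Fits `y = a * ln(x) + b` to (rank, value) points by ordinary least
#' squares; used to summarize how maximum flow decays down the candidate
#' ranking.
#'
#' @param ranks Positive integer x values (>= 1).
#' @param values Numeric y values, same length.
#' @return Named vector `c(a = slope, b = intercept)`.
#' @export
log_trend_fit <- function(ranks, values) {
  if (length(ranks) != length(values))
    stop("ranks and values differ in length", call. = FALSE)
  if (length(ranks) < 2L)
    stop("need at least 2 points", call. = FALSE)
  if (any(ranks < 1))
    stop("ranks must be >= 1", call. = FALSE)
  fit <- stats::lm(values ~ log(ranks))
  c(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]))
}

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
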