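# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive (exhaustive sorts, direct summation,
# enumeration) and share no code with the functions they test.

quietly <- function(expr) suppressMessages(suppressWarnings(expr))

make_net <- function(from, to, capacity, origin = "regulatory") {
  arcs <- data.frame(from = from, to = to, capacity = capacity,
                     origin = origin, stringsAsFactors = FALSE)
  targetflow:::new_weighted_network(unique(c(from, to)), arcs)
}

rand_em <- function(n_genes, n_cancer, n_normal, seed, missing = 0) {
  set.seed(seed)
  samples <- c(sprintf("c%d", seq_len(n_cancer)),
               sprintf("n%d", seq_len(n_normal)))
  m <- matrix(rnorm(n_genes * length(samples)), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)), samples))
  if (missing > 0) m[runif(length(m)) < missing] <- NA
  expression_matrix(m, setNames(rep(c("cancer", "normal"),
                                    c(n_cancer, n_normal)), samples))
}

# exhaustive-sort KNN imputation: rms distance over mutually observed
# samples, inverse-distance weights, exact matches averaged
brute_knn_impute <- function(vals, k) {
  out <- vals
  for (g in seq_len(nrow(vals))) {
    for (s in which(is.na(vals[g, ]))) {
      ds <- rep(Inf, nrow(vals))
      for (h in seq_len(nrow(vals))) {
        if (h == g) next
        shared <- !is.na(vals[g, ]) & !is.na(vals[h, ])
        if (!any(shared)) next
        ds[h] <- sqrt(mean((vals[g, shared] - vals[h, shared])^2))
      }
      cand <- which(!is.na(vals[, s]) & is.finite(ds))
      ord <- cand[order(ds[cand], rownames(vals)[cand])]
      nb <- ord[seq_len(min(k, length(ord)))]
      if (any(ds[nb] < 1e-12)) {
        out[g, s] <- mean(vals[nb[ds[nb] < 1e-12], s])
      } else {
        w <- 1 / ds[nb]
        out[g, s] <- sum(w * vals[nb, s]) / sum(w)
      }
    }
  }
  out
}

welch_oracle <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# BFS distance of every node to `target` along arc directions, by plain
# frontier expansion over an edge list
brute_bfs_to <- function(nodes, from, to, target) {
  d <- setNames(rep(length(nodes), length(nodes)), nodes)
  d[target] <- 0L
  repeat {
    changed <- FALSE
    for (i in seq_along(from)) {
      if (d[from[i]] > d[to[i]] + 1L && d[to[i]] < length(nodes)) {
        d[from[i]] <- d[to[i]] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# minimum s-t cut by exhaustive enumeration of node subsets
enum_min_cut <- function(fn) {
  nodes <- fn$nodes
  mid <- setdiff(nodes, c("S", "T"))
  stopifnot(length(mid) <= 14)
  best <- Inf
  for (mask in 0:(2^length(mid) - 1)) {
    side_s <- c("S", mid[bitwAnd(mask, 2^(seq_along(mid) - 1)) > 0])
    cut <- sum(fn$arcs$capacity[fn$arcs$from %in% side_s &
                                !(fn$arcs$to %in% side_s)])
    best <- min(best, cut)
  }
  best
}

# all simple paths u -> v in a directed edge list (tiny graphs only)
all_simple_paths_df <- function(arcs, u, v) {
  res <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == v) { res[[length(res) + 1L]] <<- path; return() }
    nxt <- arcs$to[arcs$from == last]
    for (w in setdiff(nxt, path)) recurse(c(path, w))
  }
  recurse(u)
  res
}

# brute-force weighted betweenness (distance = 1/capacity) by enumerating
# all simple paths per ordered pair
brute_betweenness <- function(net) {
  arcs <- net$arcs[net$arcs$capacity > 0, ]
  arcs$w <- 1 / arcs$capacity
  nodes <- net$nodes
  btw <- setNames(numeric(length(nodes)), nodes)
  plen <- function(p) {
    sum(vapply(seq_len(length(p) - 1L), function(i) {
      arcs$w[arcs$from == p[i] & arcs$to == p[i + 1L]][1L]
    }, numeric(1)))
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_simple_paths_df(arcs, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, plen, numeric(1))
    short <- paths[abs(lens - min(lens)) < 1e-12]
    inner <- unlist(lapply(short, function(p) p[-c(1, length(p))]))
    for (v in unique(inner))
      btw[v] <- btw[v] + sum(inner == v) / length(short)
  }
  btw
}
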