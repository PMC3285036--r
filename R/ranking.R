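#' Upper-tail flow cutoff under a fitted normal
#'
#' The empirical maximum-flow distribution over candidates is summarized by
#' a normal fit (mean, sample standard deviation); the cutoff is the
#' one-sided upper-tail boundary `mean + z_(1-tail) * sd`, so with the
#' default `tail = 0.05` a candidate is selected when its flow falls in the
#' top-5% area of the fitted distribution (the lower limit of the 95th
#' percentile). Under a right-skewed empirical distribution more than 5% of
#' candidates can exceed it.
#'
#' @param flows Numeric vector of candidate flow values, length >= 2.
#' @param tail Upper-tail probability, default 0.05.
#' @return The threshold value.
#' @export
top_flow_threshold <- function(flows, tail = 0.05) {
  flows <- as.numeric(flows)
  if (length(flows) < 2L)
    stop("need at least 2 flow values to fit the threshold", call. = FALSE)
  if (tail <= 0 || tail >= 1)
    stop("tail must be in (0, 1)", call. = FALSE)
  mean(flows) + stats::qnorm(1 - tail) * stats::sd(flows)
}

#' Rank candidate proteins by maximum flow to the disease genes
#'
#' Runs one flow computation per candidate on a freshly augmented network
#' (the candidate set as a whole drives the disease-overlap rule), computes
#' the affected-genes score from the same canonical run, and sorts by flow
#' descending with lexicographic ids breaking ties. Candidates absent from
#' the network get flow 0 and are flagged.
#'
#' @param net A `weighted_network`.
#' @param candidates Character vector of candidate gene ids (nonempty).
#' @param disease Character vector of disease gene ids (nonempty).
#' @param tail Upper-tail probability for the selection threshold.
#' @return A `ranking_table`: list with `rows` (data frame `candidate`,
#'   `flow`, `affected`, `rank`, `disconnected`, `selected`), `threshold`,
#'   and `selected` (ids at or above the threshold).
#' @export
rank_candidates <- function(net, candidates, disease, tail = 0.05) {
  stopifnot(inherits(net, "weighted_network"))
  candidates <- sort(unique(as.character(candidates)))
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  if (!length(disease)) stop("no disease genes", call. = FALSE)

  flows <- numeric(length(candidates))
  ag <- numeric(length(candidates))
  disc <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    fn <- build_flow_network(net, candidates[i], disease,
                             candidate_set = candidates)
    fr <- max_flow_push_relabel(fn)
    flows[i] <- fr$value
    ag[i] <- affected_genes_total(fr, fn)$total
    disc[i] <- fn$disconnected
  }
  ord <- order(-flows, candidates)
  rows <- data.frame(candidate = candidates[ord], flow = flows[ord],
                     affected = ag[ord], rank = seq_along(ord),
                     disconnected = disc[ord], stringsAsFactors = FALSE)
  threshold <- if (length(candidates) >= 2L)
    top_flow_threshold(flows, tail) else NA_real_
  rows$selected <- !is.na(threshold) & rows$flow >= threshold
  structure(list(rows = rows, threshold = threshold,
                 selected = rows$candidate[rows$selected]),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("ranking_table: %d candidate(s), threshold %.4g, %d selected\n",
              nrow(x$rows), x$threshold, length(x$selected)))
  print(utils::head(x$rows, 10))
  invisible(x)
}
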