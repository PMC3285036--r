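#' Construct an expression matrix with condition labels
#'
#' Container for a genes x samples grid of log2 expression ratios. Missing
#' entries are `NA`. Every sample carries a condition label, either
#' `"cancer"` or `"normal"`; downstream edge weighting needs at least one
#' sample of each.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique; they are the gene and
#'   sample identifiers.
#' @param condition Named character vector mapping every sample id to
#'   `"cancer"` or `"normal"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `condition` (labels aligned to the matrix columns).
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expression_matrix(m, c(s1 = "cancer", s2 = "cancer", s3 = "normal"))
#' @export
expression_matrix <- function(values, condition) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  condition <- unlist(condition)
  missing_cond <- setdiff(colnames(values), names(condition))
  if (length(missing_cond))
    stop("samples without a condition label: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  condition <- condition[colnames(values)]
  if (!all(condition %in% c("cancer", "normal")))
    stop("conditions must be 'cancer' or 'normal'", call. = FALSE)
  structure(list(values = values, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d cancer, %d normal), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "cancer"), sum(x$condition == "normal"),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

condition_samples <- function(em, condition) {
  sample_ids(em)[em$condition == condition]
}

#' Remove genes with too many missing values
#'
#' Drops every gene whose fraction of missing entries across all samples
#' exceeds `max_missing_fraction`. A gene at exactly the threshold is kept:
#' the rule removes genes with *more than* the allowed fraction missing.
#' Sample set and gene order are preserved.
#'
#' @param em An [expression_matrix()].
#' @param max_missing_fraction Maximum tolerated missing fraction per gene,
#'   in \[0, 1\]. Default 0.2.
#' @return A filtered `expr_matrix`. If every gene is removed the result has
#'   zero rows and a warning is raised.
#' @export
filter_genes_by_missingness <- function(em, max_missing_fraction = 0.2) {
  stopifnot(inherits(em, "expr_matrix"))
  if (nrow(em$values) == 0L)
    stop("expression matrix has no genes", call. = FALSE)
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]", call. = FALSE)
  frac <- rowMeans(is.na(em$values))
  keep <- frac <= max_missing_fraction
  if (!any(keep))
    warning("all genes removed by the missingness filter", call. = FALSE)
  expression_matrix(em$values[keep, , drop = FALSE], em$condition)
}

#' Impute missing expression values by k nearest neighbours
#'
#' For each missing entry, the k genes nearest in root-mean-square distance
#' over mutually observed samples (among genes observed at the missing
#' sample) supply an inverse-distance-weighted mean. Neighbours at zero
#' distance dominate: if any neighbour has an identical profile on the
#' shared samples, the imputed value is the plain mean of those exact
#' matches. Observed entries are never altered.
#'
#' @param em An [expression_matrix()], normally already missingness-filtered.
#' @param k Number of neighbours, default 10. If fewer neighbours are
#'   available for some entry, all available ones are used with a warning.
#' @return An `expr_matrix` with no missing entries.
#' @export
knn_impute <- function(em, k = 10) {
  stopifnot(inherits(em, "expr_matrix"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  vals <- em$values
  if (!anyNA(vals)) return(em)
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing))
    stop("gene(s) missing in every sample (filter first): ",
         paste(rownames(vals)[all_missing], collapse = ", "), call. = FALSE)

  obs <- !is.na(vals)
  need <- which(rowSums(!obs) > 0L)
  short <- FALSE
  for (g in need) {
    # rms distance to every other gene over mutually observed samples
    diffs <- sweep(vals, 2L, vals[g, ])
    shared <- obs & rep(obs[g, ], each = nrow(vals))
    sq <- diffs^2
    sq[!shared] <- NA
    nshared <- rowSums(shared)
    d <- sqrt(rowMeans(sq, na.rm = TRUE))
    d[nshared == 0L] <- Inf
    d[g] <- Inf
    for (s in which(!obs[g, ])) {
      cand <- which(obs[, s] & is.finite(d))
      if (!length(cand))
        stop("no neighbour observed at sample '", colnames(vals)[s],
             "' to impute gene '", rownames(vals)[g], "'", call. = FALSE)
      if (length(cand) < k) short <- TRUE
      ord <- cand[order(d[cand], rownames(vals)[cand])]
      nb <- ord[seq_len(min(k, length(ord)))]
      dn <- d[nb]
      exact <- dn < 1e-12
      if (any(exact)) {
        vals[g, s] <- mean(em$values[nb[exact], s])
      } else {
        w <- 1 / dn
        vals[g, s] <- sum(w * em$values[nb, s]) / sum(w)
      }
    }
  }
  if (short)
    warning("fewer than k neighbours available for some entries; used all available",
            call. = FALSE)
  expression_matrix(vals, em$condition)
}

#' Per-gene mean expression within a condition
#'
#' @param em An [expression_matrix()].
#' @param gene Gene identifier.
#' @param condition `"cancer"` or `"normal"`.
#' @return Arithmetic mean of the gene's observed values over samples of the
#'   condition.
#' @export
condition_mean <- function(em, gene, condition) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!gene %in% gene_ids(em))
    stop("unknown gene: ", gene, call. = FALSE)
  cols <- em$condition == condition
  if (!any(cols))
    stop("no samples with condition '", condition, "'", call. = FALSE)
  x <- em$values[gene, cols]
  if (all(is.na(x)))
    stop("gene '", gene, "' unobserved in condition '", condition, "'",
         call. = FALSE)
  mean(x, na.rm = TRUE)
}

#' Pearson correlation of two genes over cancer samples
#'
#' Correlation is computed over the cancer samples only, since the edge
#' weighting models the network as it operates in the disease state. A gene
#' with zero variance across cancer samples yields 0 (an uninformative edge
#' through which no flow should pass).
#'
#' @param em An [expression_matrix()] (normally imputed).
#' @param gene_i,gene_j Distinct gene identifiers.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cancer <- function(em, gene_i, gene_j) {
  stopifnot(inherits(em, "expr_matrix"))
  for (g in c(gene_i, gene_j))
    if (!g %in% gene_ids(em)) stop("unknown gene: ", g, call. = FALSE)
  cols <- em$condition == "cancer"
  if (sum(cols) < 2L)
    stop("need at least 2 cancer samples for correlation", call. = FALSE)
  x <- em$values[gene_i, cols]
  y <- em$values[gene_j, cols]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L)
    stop("fewer than 2 mutually observed cancer samples", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Welch two-sample t statistic, cancer minus normal
#'
#' Unequal-variance form, suited to unbalanced cancer/normal designs. The
#' squared standard error is floored at machine epsilon so that groups with
#' zero within-group variance but different means give a large finite
#' statistic rather than infinity; identical groups give exactly 0.
#'
#' @param em An [expression_matrix()].
#' @param gene Gene identifier.
#' @return Signed t statistic (positive when the gene is higher in cancer).
#' @export
ttest_statistic <- function(em, gene) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!gene %in% gene_ids(em))
    stop("unknown gene: ", gene, call. = FALSE)
  xc <- em$values[gene, em$condition == "cancer"]
  xn <- em$values[gene, em$condition == "normal"]
  xc <- xc[!is.na(xc)]; xn <- xn[!is.na(xn)]
  if (length(xc) < 2L || length(xn) < 2L)
    stop("need >= 2 samples per condition for the t statistic", call. = FALSE)
  diff <- mean(xc) - mean(xn)
  se2 <- stats::var(xc) / length(xc) + stats::var(xn) / length(xn)
  if (se2 == 0 && diff == 0) return(0)
  diff / sqrt(max(se2, .Machine$double.eps))
}
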