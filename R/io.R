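#' Read an expression matrix and its condition map from TSV
#'
#' The matrix file has a header row (first field a gene-id column label,
#' then sample ids) and one row per gene; empty fields and `NA` both mean
#' missing. The condition file has two tab-separated columns, sample id
#' and `cancer`/`normal`, no header; `#` lines are skipped in both files.
#'
#' @param path Path to the expression TSV.
#' @param condition_path Path to the condition map TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition_path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  if (length(lines) < 2L)
    stop("expression file needs a header and at least one gene row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  n_col <- length(header)
  rows <- fields[-1L]
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop("malformed expression row at line ", bad[1L] + 1L,
         ": expected ", n_col, " fields, got ", lengths(rows)[bad[1L]],
         call. = FALSE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene id in expression file: ",
         genes[duplicated(genes)][1L], call. = FALSE)
  vals <- t(vapply(rows, function(r) {
    x <- r[-1L]
    x[x == "" | x == "NA"] <- NA
    as.numeric(x)
  }, numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(genes, samples)

  cm <- read_two_column(condition_path, "condition map")
  condition <- stats::setNames(tolower(cm[[2L]]), cm[[1L]])
  message(sprintf("read expression: %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  expression_matrix(vals, condition)
}

read_two_column <- function(path, what) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty ", what, " file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop(what, " rows need two tab-separated fields (", path, ")",
         call. = FALSE)
  data.frame(V1 = vapply(fields, `[[`, character(1), 1L),
             V2 = vapply(fields, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Write an expression matrix to TSV
#' @param em An [expression_matrix()].
#' @param path Matrix output path.
#' @param condition_path Optional condition-map output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, condition_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  df <- data.frame(gene = gene_ids(em), em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(condition_path))
    utils::write.table(
      data.frame(sample = sample_ids(em), condition = em$condition),
      condition_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an interaction edge list from TSV
#'
#' Expects a header `u v type` (optional fourth column `source`); `type`
#' is `ppi` or `regulatory`, case-insensitive. `#` lines are skipped.
#'
#' @param path Edge list path.
#' @return Interaction record data frame (see [interaction_records()]).
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("edge list needs columns u, v, type", call. = FALSE)
  type <- tolower(df[[3L]])
  bad <- setdiff(unique(type), c("ppi", "regulatory"))
  if (length(bad))
    stop("unknown edge type token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  interaction_records(df[[1L]], df[[2L]], directed = type == "regulatory",
                      source = if (ncol(df) >= 4L) df[[4L]]
                               else NA_character_)
}

#' Write interaction records to TSV
#' @param records Interaction record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(records, path) {
  utils::write.table(
    data.frame(u = records$a, v = records$b,
               type = ifelse(records$directed, "regulatory", "ppi"),
               source = records$source),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line)
#'
#' `#` lines and blanks are skipped; duplicates are removed with a
#' warning.
#'
#' @param path Gene list path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene list: ", path, call. = FALSE)
  if (anyDuplicated(lines)) {
    warning("duplicate entries in ", path, " removed", call. = FALSE)
    lines <- unique(lines)
  }
  lines
}

#' Read a gene-id synonym map (alias TAB canonical)
#' @param path Id map path.
#' @return Named character vector: names are aliases, values canonical ids.
#' @export
read_id_map <- function(path) {
  df <- read_two_column(path, "id map")
  stats::setNames(df$V2, df$V1)
}

#' Write / read a capacity-weighted network as TSV (one row per arc)
#' @param net A `weighted_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$arcs[, c("from", "to", "capacity", "origin")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @return For `read_network`, the `weighted_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("from", "to", "capacity", "origin")
  if (!all(need %in% names(df)))
    stop("network file needs columns from, to, capacity, origin",
         call. = FALSE)
  df$from <- as.character(df$from); df$to <- as.character(df$to)
  new_weighted_network(unique(c(df$from, df$to)), df[, need])
}

#' Write a flow result: per-arc flows plus the step log
#' @param fr A `flow_result`.
#' @param path Per-arc flow TSV path (columns u, v, flow, capacity plus a
#'   summary row).
#' @param steps_path Optional path for the push step log (columns step,
#'   push_node, flow, received_node).
#' @return `path`, invisibly.
#' @export
write_flow_result <- function(fr, path, steps_path = NULL) {
  df <- data.frame(u = fr$arc_flows$from, v = fr$arc_flows$to,
                   flow = fr$arc_flows$flow,
                   capacity = fr$arc_flows$capacity)
  df <- rbind(df, data.frame(u = "#total", v = fr$candidate,
                             flow = fr$value, capacity = NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(steps_path))
    utils::write.table(fr$steps, steps_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Write an affected-genes score table
#' @param score An `affected_score`.
#' @param path Output TSV path (node, P_i rows plus an AG summary line).
#' @return `path`, invisibly.
#' @export
write_affected_score <- function(score, path) {
  df <- data.frame(node = names(score$per_node), p = score$per_node)
  df <- rbind(df, data.frame(node = "#AG", p = score$total))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate ranking table
#' @param rt A `ranking_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(rt, path) {
  utils::write.table(rt$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Either `network` (a prebuilt weighted-network TSV) or the trio
#' `matrix`/`condition`/`edges` must be supplied. `truth` (known true
#' targets) switches on the baseline evaluation.
#'
#' @param candidates,disease Paths to the candidate and disease gene lists.
#' @param matrix,condition,edges Paths to the expression matrix, condition
#'   map and raw edge list.
#' @param network Path to a prebuilt weighted-network TSV (skips
#'   preprocessing and weighting).
#' @param id_map Optional synonym map path.
#' @param truth Optional true-target list path.
#' @param output_dir Output directory, created if needed.
#' @param knn_k Imputation neighbours, default 10.
#' @param missing_threshold Gene missingness cutoff, default 0.2.
#' @param tail Selection tail probability, default 0.05.
#' @param rwr_alpha Random-walk restart probability, default 0.3.
#' @param seed Integer seed for any randomized stage, default 1.
#' @return A `run_config` list.
#' @export
run_config <- function(candidates, disease, matrix = NULL, condition = NULL,
                       edges = NULL, network = NULL, id_map = NULL,
                       truth = NULL, output_dir = tempfile("targetflow_"),
                       knn_k = 10, missing_threshold = 0.2, tail = 0.05,
                       rwr_alpha = 0.3, seed = 1) {
  if (is.null(network) &&
      (is.null(matrix) || is.null(condition) || is.null(edges)))
    stop("supply either 'network' or all of 'matrix', 'condition', 'edges'",
         call. = FALSE)
  for (p in c(tail, rwr_alpha))
    if (p <= 0 || p >= 1) stop("proportions must be in (0, 1)", call. = FALSE)
  structure(list(candidates = candidates, disease = disease,
                 matrix = matrix, condition = condition, edges = edges,
                 network = network, id_map = id_map, truth = truth,
                 output_dir = output_dir, knn_k = knn_k,
                 missing_threshold = missing_threshold, tail = tail,
                 rwr_alpha = rwr_alpha, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full prioritization pipeline
#'
#' Preprocess (missingness filter, KNN imputation) -> map/deduplicate and
#' weight the network -> per-candidate maximum flow and affected-genes
#' score -> rank and threshold; when a truth list is supplied, all
#' baselines are run on the same inputs and a precision-recall / top-k
#' evaluation report is written. All outputs are deterministic functions
#' of the inputs, configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `ranking` (the `ranking_table`),
#'   `network`, and (when truth is given) `evaluation`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)

  em <- NULL
  if (!is.null(config$network)) {
    net <- stage("network", read_network(config$network))
  } else {
    em <- stage("read", read_expression(config$matrix, config$condition))
    n0 <- nrow(em$values)
    em <- stage("preprocess", {
      em <- filter_genes_by_missingness(em, config$missing_threshold)
      knn_impute(em, config$knn_k)
    })
    summary$genes_filtered <- n0 - nrow(em$values)
    records <- stage("edges", {
      r <- read_edges(config$edges)
      id_map <- if (!is.null(config$id_map)) read_id_map(config$id_map)
      map_and_deduplicate(r, id_map)
    })
    net <- stage("build", build_weighted_network(records, em))
    write_network(net, file.path(config$output_dir, "network.tsv"))
  }
  summary$nodes <- length(net$nodes)
  summary$arcs <- nrow(net$arcs)

  candidates <- read_gene_list(config$candidates)
  disease <- read_gene_list(config$disease)
  rt <- stage("rank",
              rank_candidates(net, candidates, disease, config$tail))
  write_ranking(rt, file.path(config$output_dir, "ranking.tsv"))
  summary$candidates <- length(candidates)
  summary$disconnected <- sum(rt$rows$disconnected)
  summary$threshold <- rt$threshold
  summary$selected <- length(rt$selected)

  evaluation <- NULL
  if (!is.null(config$truth)) {
    truth <- read_gene_list(config$truth)
    evaluation <- stage("evaluate", {
      rankings <- list(
        flow = rt$rows$candidate,
        degree = degree_rank(net, candidates)$candidate,
        entropy = entropy_rank(net, candidates)$candidate,
        betweenness = betweenness_rank(net, candidates)$candidate,
        closeness = closeness_rank(net, candidates)$candidate,
        rwr = rwr_rank(net, candidates, disease,
                       alpha = config$rwr_alpha)$candidate)
      if (!is.null(em))
        rankings$ttest <- ttest_rank(em, candidates)$candidate
      evaluate_rankings(rankings, truth)
    })
    utils::write.table(evaluation$map,
                       file.path(config$output_dir, "evaluation_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(evaluation$topk,
                       file.path(config$output_dir, "evaluation_topk.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$map <- stats::setNames(as.list(evaluation$map$map),
                                   evaluation$map$method)
  }
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ranking = rt, network = net, evaluation = evaluation))
}

#' Evaluate several rankings against a truth set
#'
#' @param rankings Named list of orderings (character vectors or rank data
#'   frames), best first, all over the same candidate universe.
#' @param truth True-target ids.
#' @param fractions Top-k window fractions, default 1%, 3%, 15%.
#' @return List with `map` (data frame `method`, `map`) and `topk` (long
#'   data frame of [topk_average_position()] rows per method).
#' @export
evaluate_rankings <- function(rankings, truth,
                              fractions = c(0.01, 0.03, 0.15)) {
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  map <- data.frame(
    method = names(rankings),
    map = vapply(rankings,
                 function(r) precision_recall(r, truth)$map_score,
                 numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  topk <- do.call(rbind, lapply(names(rankings), function(nm) {
    tk <- topk_average_position(rankings[[nm]], truth, fractions)
    cbind(method = nm, tk)
  }))
  list(map = map, topk = topk)
}

#' Write the worked-example fixture as a pipeline input bundle
#'
#' Emits the reconstructed seven-gene network (as a weighted-network TSV,
#' since its capacities are given directly), plus candidate and disease
#' gene lists, so `run_pipeline()` can reproduce the worked example
#' end-to-end. The candidate list holds G1, the candidate whose printed
#' values the reconstruction pins down.
#'
#' @param dir Output directory, created if needed.
#' @return Named vector of the written file paths.
#' @export
write_fixture_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- worked_example_fixture()
  paths <- c(network = file.path(dir, "network.tsv"),
             candidates = file.path(dir, "candidates.txt"),
             disease = file.path(dir, "disease.txt"))
  write_network(fx$network, paths[["network"]])
  writeLines("G1", paths[["candidates"]])
  writeLines(fx$disease, paths[["disease"]])
  paths
}

#' Write a simulated dataset as a pipeline input bundle
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory, created if needed.
#' @return Named vector of the written file paths.
#' @export
write_dataset_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             condition = file.path(dir, "condition.tsv"),
             edges = file.path(dir, "edges.tsv"),
             candidates = file.path(dir, "candidates.txt"),
             disease = file.path(dir, "disease.txt"),
             truth = file.path(dir, "truth.txt"))
  write_expression(ds$matrix, paths[["matrix"]], paths[["condition"]])
  write_edges(ds$records, paths[["edges"]])
  writeLines(ds$candidates, paths[["candidates"]])
  writeLines(ds$disease, paths[["disease"]])
  writeLines(ds$planted_targets, paths[["truth"]])
  paths
}
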