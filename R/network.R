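#' Build a table of interaction records
#'
#' @param a,b Endpoint gene identifiers. For directed (regulatory) records
#'   the orientation is `a -> b`.
#' @param directed Logical; `TRUE` for TF->gene regulation, `FALSE` for PPI.
#' @param source Optional provenance tag.
#' @return A data frame with columns `a`, `b`, `directed`, `source`.
#' @export
interaction_records <- function(a, b, directed, source = NA_character_) {
  df <- data.frame(a = as.character(a), b = as.character(b),
                   directed = as.logical(directed),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$a) | is.na(df$b) | is.na(df$directed)))
    stop("interaction records need complete endpoints and directedness",
         call. = FALSE)
  df
}

#' Canonicalize gene ids and remove duplicate interactions
#'
#' Endpoints are mapped through a synonym table (alias -> canonical id);
#' unmapped ids pass through unchanged with a warning. Self-loops arising
#' after mapping are dropped. Undirected (PPI) duplicates are removed
#' regardless of endpoint order; directed duplicates only when orientation
#' matches, so `TF1 -> G1` and `G1 -> TF1` are distinct. A directed and an
#' undirected record over the same pair are both kept: they contribute
#' different arcs to the network.
#'
#' @param records Interaction data frame as from [interaction_records()].
#' @param id_map Named character vector, `names` = aliases, values =
#'   canonical ids; `NULL` to skip mapping.
#' @return Deduplicated record data frame.
#' @export
map_and_deduplicate <- function(records, id_map = NULL) {
  stopifnot(is.data.frame(records),
            all(c("a", "b", "directed") %in% names(records)))
  rec <- records
  if (!is.null(id_map) && length(id_map)) {
    id_map <- unlist(id_map)
    used <- unique(c(rec$a, rec$b))
    unmapped <- setdiff(used, names(id_map))
    if (length(unmapped))
      warning(length(unmapped),
              " endpoint id(s) absent from the id map; passed through unchanged",
              call. = FALSE)
    full <- c(id_map, stats::setNames(unmapped, unmapped))
    rec$a <- unname(full[rec$a])
    rec$b <- unname(full[rec$b])
  }
  loops <- rec$a == rec$b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop record(s)")
    rec <- rec[!loops, , drop = FALSE]
  }
  key <- ifelse(rec$directed,
                paste0("d:", rec$a, "\t", rec$b),
                paste0("u:", pmin(rec$a, rec$b), "\t", pmax(rec$a, rec$b)))
  dup <- duplicated(key)
  if (any(dup))
    message("dropped ", sum(dup), " duplicate record(s)")
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Edge capacity from co-expression and differential expression
#'
#' The capacity of an interaction between genes i and j is
#' `|r_ij| * (|E_ci - E_ni| + |E_cj - E_nj|)`: the absolute Pearson
#' correlation of the two genes across cancer samples times the summed
#' absolute cancer-vs-normal mean expression change of the endpoints. A
#' zero correlation gives capacity 0 — uncorrelated proteins pass no flow —
#' and so does a pair with no differential expression on either side.
#'
#' @param r_ij Pearson correlation in \[-1, 1\] (vectorized).
#' @param e_ci,e_ni Mean cancer / normal expression of gene i.
#' @param e_cj,e_nj Mean cancer / normal expression of gene j.
#' @return Nonnegative capacity.
#' @export
edge_capacity <- function(r_ij, e_ci, e_ni, e_cj, e_nj) {
  args <- cbind(r_ij, e_ci, e_ni, e_cj, e_nj)
  if (any(!is.finite(args)))
    stop("edge_capacity inputs must be finite", call. = FALSE)
  if (any(r_ij < -1 | r_ij > 1))
    stop("correlation outside [-1, 1]", call. = FALSE)
  abs(r_ij) * (abs(e_ci - e_ni) + abs(e_cj - e_nj))
}

new_weighted_network <- function(nodes, arcs) {
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = sort(unique(nodes)), arcs = arcs),
            class = "weighted_network")
}

#' Assemble the capacity-weighted, partially directed network
#'
#' Every retained interaction gets its capacity from [edge_capacity()],
#' with correlations and condition means taken from the (imputed)
#' expression matrix. A PPI record expands into two antiparallel arcs of
#' equal capacity (origin `"ppi"`); a regulatory record yields a single
#' directed arc (origin `"regulatory"`). Records with an endpoint absent
#' from the matrix are dropped with a message. Zero-capacity arcs are kept:
#' they exist in the topology but can carry no flow.
#'
#' @param records Deduplicated interaction data frame
#'   (see [map_and_deduplicate()]).
#' @param em Imputed [expression_matrix()].
#' @return A `weighted_network`: list with `nodes` (sorted gene ids) and
#'   `arcs` (data frame `from`, `to`, `capacity`, `origin`).
#' @export
build_weighted_network <- function(records, em) {
  stopifnot(is.data.frame(records), inherits(em, "expr_matrix"))
  if (nrow(records) == 0L)
    stop("no interaction records", call. = FALSE)
  genes <- gene_ids(em)
  if (any(c("S", "T") %in% c(records$a, records$b)))
    stop("'S' and 'T' are reserved node names", call. = FALSE)
  present <- records$a %in% genes & records$b %in% genes
  if (any(!present))
    message("dropped ", sum(!present),
            " record(s) with endpoints lacking expression data")
  rec <- records[present, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no interaction record has expression for both endpoints",
         call. = FALSE)

  ec <- vapply(unique(c(rec$a, rec$b)), condition_mean, numeric(1),
               em = em, condition = "cancer")
  en <- vapply(unique(c(rec$a, rec$b)), condition_mean, numeric(1),
               em = em, condition = "normal")
  r <- mapply(function(a, b) pearson_cancer(em, a, b), rec$a, rec$b)
  cap <- edge_capacity(r, ec[rec$a], en[rec$a], ec[rec$b], en[rec$b])

  und <- !rec$directed
  arcs <- rbind(
    data.frame(from = rec$a[und], to = rec$b[und], capacity = cap[und],
               origin = rep("ppi", sum(und)), stringsAsFactors = FALSE),
    data.frame(from = rec$b[und], to = rec$a[und], capacity = cap[und],
               origin = rep("ppi", sum(und)), stringsAsFactors = FALSE),
    data.frame(from = rec$a[!und], to = rec$b[!und], capacity = cap[!und],
               origin = rep("regulatory", sum(!und)),
               stringsAsFactors = FALSE))
  # a pair that is both PPI and regulatory may duplicate a directed arc;
  # capacities are identical by construction, keep one
  arcs <- arcs[!duplicated(paste0(arcs$from, "\t", arcs$to)), , drop = FALSE]
  new_weighted_network(unique(c(rec$a, rec$b)), arcs)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d arcs (%d ppi, %d regulatory)\n",
              length(x$nodes), nrow(x$arcs),
              sum(x$arcs$origin == "ppi"),
              sum(x$arcs$origin == "regulatory")))
  invisible(x)
}
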