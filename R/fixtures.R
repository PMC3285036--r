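#' The seven-gene worked-example network
#'
#' A small directed, edge-weighted network over genes G1..G7 with
#' candidates {G1, G2} and disease genes {G6, G7}, reconstructed from the
#' published worked example: the arcs G1->G6 (1.83), G1->G3 (0.69) and
#' G3->G7 (0.90) carry the printed capacities, and four directed padding
#' arcs (G4->G1 0.50, G2->G3 1.00, G2->G6 1.20, G5->G7 0.80) give G1, G3,
#' G6 and G7 in-degree 2 in the augmented network without opening any
#' alternative source-to-sink path for candidate G1. The printed results
#' for G1 — maximum flow 2.52, affected ratio 0.5 at each flow-receiving
#' node, AG = 2, initial height 2 — are therefore forced.
#'
#' @return List with `network` (a `weighted_network`), `candidates`,
#'   `disease`, and `expected` (the reference values above).
#' @export
worked_example_fixture <- function() {
  arcs <- data.frame(
    from = c("G1", "G1", "G3", "G4", "G2", "G2", "G5"),
    to   = c("G6", "G3", "G7", "G1", "G3", "G6", "G7"),
    capacity = c(1.83, 0.69, 0.90, 0.50, 1.00, 1.20, 0.80),
    origin = "regulatory",
    stringsAsFactors = FALSE)
  list(network = new_weighted_network(paste0("G", 1:7), arcs),
       candidates = c("G1", "G2"),
       disease = c("G6", "G7"),
       expected = list(flow_G1 = 2.52, ag_G1 = 2, p_affected = 0.5,
                       height_G1 = 2L,
                       flow_G1_G6 = 1.83, flow_G3_G7 = 0.69))
}

#' Random flow instance for solver cross-checks
#'
#' Draws a random directed network with capacities uniform on (0, 2) —
#' roughly 40% of sampled gene pairs become bidirectional PPI pairs, the
#' rest single directed arcs — picks one candidate and 1-3 disease genes,
#' and augments it with the dummy source and sink. Pure function of the
#' seed.
#'
#' @param n_nodes Number of gene nodes (>= 2).
#' @param n_arcs Approximate number of arcs to sample (>= 1).
#' @param seed Integer RNG seed.
#' @return A `flow_network`.
#' @export
random_flow_instance <- function(n_nodes, n_arcs, seed) {
  if (n_nodes < 2L || n_arcs < 1L)
    stop("degenerate instance size", call. = FALSE)
  if (n_arcs > n_nodes * (n_nodes - 1L))
    stop("more arcs than ordered pairs", call. = FALSE)
  with_local_seed(seed, {
    nodes <- sprintf("N%03d", seq_len(n_nodes))
    pairs <- expand.grid(from = nodes, to = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample.int(nrow(pairs), n_arcs), ]
    is_ppi <- stats::runif(n_arcs) < 0.4
    cap <- stats::runif(n_arcs, 0, 2)
    arcs <- rbind(
      data.frame(from = pick$from, to = pick$to, capacity = cap,
                 origin = ifelse(is_ppi, "ppi", "regulatory"),
                 stringsAsFactors = FALSE),
      data.frame(from = pick$to[is_ppi], to = pick$from[is_ppi],
                 capacity = cap[is_ppi], origin = rep("ppi", sum(is_ppi)),
                 stringsAsFactors = FALSE))
    arcs <- arcs[!duplicated(paste0(arcs$from, "\r", arcs$to)), ]
    net <- new_weighted_network(nodes, arcs)
    cand <- sample(nodes, 1L)
    disease <- sample(setdiff(nodes, cand),
                      sample.int(min(3L, n_nodes - 1L), 1L))
    build_flow_network(net, cand, disease, candidate_set = cand)
  })
}

#' Simulate an expression + interactome bundle with planted drug targets
#'
#' Emulates the shape of a two-condition microarray study wired to a
#' partially directed interactome, at reduced scale. Genes are organized
#' into co-expression modules: module genes share a latent factor across
#' cancer samples (high within-module correlation) and carry a module-wide
#' differential-expression shift, while background genes are uncorrelated
#' and near-flat. Each module contains disease genes and one planted
#' target wired to them by direct PPI edges, so planted targets command
#' high-capacity paths to the disease set. Decoy candidates are background
#' hubs: many links to other background genes (high degree) but only a
#' weak, uncorrelated link toward a disease gene, so their flow is small by
#' construction. Missing entries are sprinkled uniformly at `missing_rate`.
#'
#' @param n_genes Total genes, default 200.
#' @param n_cancer,n_normal Sample counts per condition, default 20 and 15.
#' @param n_modules Number of planted co-expression modules, default 4.
#' @param missing_rate Fraction of entries set missing, in \[0, 0.5).
#' @param seed Integer RNG seed; everything is a pure function of it.
#' @param module_size Genes per module, default 15.
#' @param n_decoys Number of decoy hub candidates, default 6.
#' @return A `synthetic_dataset`: list with `matrix` (an
#'   [expression_matrix()] with missing values), `records` (interaction
#'   data frame), `candidates`, `disease`, `planted_targets`, `decoys`,
#'   `modules` (gene -> module id), and `seed`.
#' @export
simulate_dataset <- function(n_genes = 200, n_cancer = 20, n_normal = 15,
                             n_modules = 4, missing_rate = 0.05, seed = 1,
                             module_size = 15, n_decoys = 6) {
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("missing_rate must be in [0, 0.5)", call. = FALSE)
  if (n_genes < n_modules * module_size + n_decoys + 10L)
    stop("n_genes too small for the requested structure", call. = FALSE)
  stopifnot(n_cancer >= 2L, n_normal >= 2L, n_modules >= 1L)
  with_local_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(sprintf("c%02d", seq_len(n_cancer)),
                 sprintf("n%02d", seq_len(n_normal)))
    condition <- stats::setNames(
      rep(c("cancer", "normal"), c(n_cancer, n_normal)), samples)

    modules <- rep(0L, n_genes)                    # 0 = background
    modules[seq_len(n_modules * module_size)] <-
      rep(seq_len(n_modules), each = module_size)
    names(modules) <- genes

    noise_sd <- 0.35
    shift <- rep(c(1.5, -1.5), length.out = n_modules)  # module dE
    vals <- matrix(stats::rnorm(n_genes * length(samples), 0, 0.5),
                   n_genes, dimnames = list(genes, samples))
    cancer_cols <- seq_len(n_cancer)
    for (m in seq_len(n_modules)) {
      z <- stats::rnorm(n_cancer)                  # shared latent factor
      rows <- which(modules == m)
      vals[rows, cancer_cols] <-
        shift[m] + rep(z, each = length(rows)) +
        stats::rnorm(length(rows) * n_cancer, 0, noise_sd)
      vals[rows, -cancer_cols] <-
        stats::rnorm(length(rows) * n_normal, 0, noise_sd)
    }

    # disease genes and planted targets live inside modules
    disease <- character(0); planted <- character(0)
    rec <- list()
    for (m in seq_len(n_modules)) {
      mg <- genes[modules == m]
      disease_m <- mg[1:2]
      target_m <- mg[3]
      disease <- c(disease, disease_m)
      planted <- c(planted, target_m)
      rec[[length(rec) + 1L]] <- interaction_records(
        a = target_m, b = disease_m, directed = FALSE, source = "planted")
      # random within-module PPI mesh
      others <- mg[-(1:3)]
      partners <- unlist(lapply(others, function(o) sample(setdiff(mg, o), 2L)))
      rec[[length(rec) + 1L]] <- interaction_records(
        a = rep(others, each = 2L), b = partners,
        directed = FALSE, source = "module")
    }

    background <- genes[modules == 0L]
    decoys <- background[seq_len(n_decoys)]
    bg_pool <- setdiff(background, decoys)
    for (d in decoys) {
      hub_partners <- sample(bg_pool, 12L)
      rec[[length(rec) + 1L]] <- interaction_records(
        a = d, b = hub_partners, directed = FALSE, source = "decoy_hub")
      rec[[length(rec) + 1L]] <- interaction_records(
        a = d, b = sample(disease, 1L), directed = FALSE,
        source = "decoy_link")
    }
    # background mesh and a few regulatory arcs for partial directedness
    rec[[length(rec) + 1L]] <- interaction_records(
      a = sample(bg_pool, 100L, replace = TRUE),
      b = sample(bg_pool, 100L, replace = TRUE),
      directed = FALSE, source = "background")
    rec[[length(rec) + 1L]] <- interaction_records(
      a = sample(genes, 30L, replace = TRUE),
      b = sample(genes, 30L, replace = TRUE),
      directed = TRUE, source = "tf")
    records <- map_and_deduplicate(do.call(rbind, rec))

    if (missing_rate > 0) {
      holes <- stats::runif(length(vals)) < missing_rate
      vals[holes] <- NA_real_
    }
    structure(list(matrix = expression_matrix(vals, condition),
                   records = records,
                   candidates = sort(c(planted, decoys)),
                   disease = sort(disease),
                   planted_targets = sort(planted),
                   decoys = sort(decoys),
                   modules = modules, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset (seed %d): %d genes x %d samples, %d records, %d planted target(s), %d decoy(s), %d disease gene(s)\n",
    x$seed, nrow(x$matrix$values), ncol(x$matrix$values),
    nrow(x$records), length(x$planted_targets), length(x$decoys),
    length(x$disease)))
  invisible(x)
}
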