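#' Build the clustering matrix from gene-body levels
#'
#' Drops QC-failing cells, drops genes missing (no level) in more than
#' `max_missing` of the remaining cells, imputes leftover missing entries
#' with the gene mean, drops zero-variance genes, and standardises each
#' gene to zero mean and unit variance. The standardised matrix feeds the
#' reduction step only; raw (unimputed) levels are retained for marker
#' testing, where imputation would fabricate evidence.
#'
#' @param region_levels [region_level()] output (gene-body levels).
#' @param qc Optional `scm_cell_qc` tibble; failing cells are removed.
#' @param max_missing Maximum tolerated per-gene missing fraction
#'   (default 0.8).
#' @return List of class `scm_matrix`: `scaled` (cells x genes numeric
#'   matrix), `raw` (cells x genes matrix with `NA` for missing), `cells`,
#'   `genes`.
#' @export
build_matrix <- function(region_levels, qc = NULL, max_missing = 0.8) {
  lv <- region_levels
  if (!is.null(qc)) {
    keep_cells <- qc$cell[qc$pass]
    lv <- filter(lv, .data$cell %in% keep_cells)
  }
  wide <- tidyr::pivot_wider(lv, id_cols = "cell", names_from = "region_id",
                             values_from = "level")
  if (nrow(wide) < 2) abort("need at least 2 cells after QC")
  raw <- as.matrix(wide[, -1, drop = FALSE])
  rownames(raw) <- wide$cell

  miss_frac <- colMeans(is.na(raw))
  raw <- raw[, miss_frac <= max_missing, drop = FALSE]
  # gene-mean imputation for the reduction input only
  imp <- apply(raw, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  v <- apply(imp, 2, sd)
  keep <- is.finite(v) & v > 0
  imp <- imp[, keep, drop = FALSE]
  raw <- raw[, keep, drop = FALSE]
  scaled <- scale(imp)
  structure(list(scaled = scaled, raw = raw,
                 cells = rownames(raw), genes = colnames(raw)),
            class = "scm_matrix")
}

#' @export
print.scm_matrix <- function(x, ...) {
  cat(sprintf("<scm_matrix> %d cells x %d genes (%.1f%% missing raw levels)\n",
              length(x$cells), length(x$genes),
              100 * mean(is.na(x$raw))))
  invisible(x)
}

#' Reduce and cluster cells
#'
#' Principal-component reduction followed by either graph clustering
#' (k-nearest-neighbour / shared-nearest-neighbour graph with Jaccard
#' weights and Louvain modularity communities) or k-means. A deterministic
#' 2-D embedding (the first two principal components) is attached for
#' visualisation only; labels are never derived from it.
#'
#' @param mat `scm_matrix` from [build_matrix()].
#' @param n_pcs Number of principal components (default 20; clamped with a
#'   warning when it exceeds the data rank).
#' @param method `"graph"` (default) or `"kmeans"`.
#' @param k_or_resolution For `"graph"`, the Louvain resolution (default
#'   0.8); for `"kmeans"`, the number of clusters.
#' @param knn Neighbourhood size for the SNN graph (default 20, clamped to
#'   cells - 1).
#' @param seed Integer seed; the same seed gives identical labels and
#'   embedding.
#' @return Object of class `scm_cluster`: list with `labels` (tibble
#'   `cell`, `cluster`, `dim1`, `dim2`), `params`, `pcs`.
#' @export
reduce_and_cluster <- function(mat, n_pcs = 20, method = c("graph", "kmeans"),
                               k_or_resolution = NULL, knn = 20, seed = 1) {
  method <- match.arg(method)
  x <- mat$scaled
  max_pcs <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_pcs) {
    warn(sprintf("n_pcs clamped from %d to %d", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pcs <- prcomp(x, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                     drop = FALSE]
  labels <- with_seed(seed, {
    if (method == "graph") {
      res <- k_or_resolution %||% 0.8
      g <- snn_graph(pcs, k = min(knn, nrow(pcs) - 1L))
      memb <- igraph::cluster_louvain(g, resolution = res)$membership
      as.integer(memb)
    } else {
      k <- k_or_resolution %||% 2
      kmeans(pcs, centers = k, nstart = 10)$cluster
    }
  })
  structure(list(
    labels = tibble(cell = mat$cells, cluster = labels,
                    dim1 = pcs[, 1], dim2 = if (n_pcs >= 2) pcs[, 2] else 0),
    params = list(n_pcs = n_pcs, method = method,
                  k_or_resolution = k_or_resolution, knn = knn, seed = seed),
    pcs = pcs), class = "scm_cluster")
}

# Shared-nearest-neighbour graph with Jaccard edge weights.
snn_graph <- function(pcs, k) {
  d <- as.matrix(dist(pcs))
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) {
    c(i, order(d[i, ])[2:(k + 1)])  # self + k nearest
  })
  edges <- numeric(0); weights <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(nbr[[i]], nbr[[j]]))
      jac <- shared / length(union(nbr[[i]], nbr[[j]]))
      if (jac > 1 / 15) {   # prune weak edges, as SNN implementations do
        edges <- c(edges, i, j); weights <- c(weights, jac)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, edges, weight = weights)
  }
  g
}

#' @export
print.scm_cluster <- function(x, ...) {
  cat(sprintf("<scm_cluster> %d cells, %d cluster(s), method=%s, n_pcs=%d\n",
              nrow(x$labels), length(unique(x$labels$cluster)),
              x$params$method, x$params$n_pcs))
  invisible(x)
}

#' Marker genes by differential modification level
#'
#' For one cluster against all other cells: per gene, a two-sided Wilcoxon
#' rank-sum test of the non-missing gene-body levels in-cluster versus the
#' rest. `pct_in`/`pct_out` are the fractions of cells with a non-missing
#' level (the coverage-limited analogue of a detection fraction); genes
#' where both fall below `min_pct` are untested. p-values are
#' Benjamini-Hochberg adjusted over the tested genes and markers are the
#' rows with `p_adj < alpha`.
#'
#' @param mat `scm_matrix` (raw levels are used).
#' @param labels Tibble with `cell`, `cluster` (e.g.
#'   `result$labels`), or a vector of labels in `mat$cells` order.
#' @param cluster The cluster to test against the rest.
#' @param min_pct Minimum detection fraction (default 0.25).
#' @param alpha Adjusted-p threshold for selection (default 0.05).
#' @return Tibble of class `scm_markers`: `gene`, `cluster`, `mean_in`,
#'   `mean_out`, `delta`, `pct_in`, `pct_out`, `p_value`, `p_adj`,
#'   `selected`, sorted by `p_adj` then `|delta|` descending.
#' @export
find_markers <- function(mat, labels, cluster, min_pct = 0.25, alpha = 0.05) {
  lab <- if (is.data.frame(labels)) {
    labels$cluster[match(mat$cells, labels$cell)]
  } else {
    labels
  }
  stopifnot(length(lab) == length(mat$cells))
  inside <- lab == cluster
  if (sum(inside) < 3 || sum(!inside) < 3) {
    abort("need at least 3 cells on each side of the comparison")
  }
  raw <- mat$raw
  rows <- purrr::map(colnames(raw), function(g) {
    x <- raw[inside, g]; y <- raw[!inside, g]
    pct_in <- mean(!is.na(x)); pct_out <- mean(!is.na(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    tested <- max(pct_in, pct_out) >= min_pct &&
      length(x) >= 1 && length(y) >= 1
    p <- if (tested) {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    } else {
      NA_real_
    }
    tibble(gene = g, cluster = as.character(cluster),
           mean_in = if (length(x)) mean(x) else NA_real_,
           mean_out = if (length(y)) mean(y) else NA_real_,
           pct_in = pct_in, pct_out = pct_out, p_value = p)
  })
  out <- bind_rows(rows)
  tested_idx <- !is.na(out$p_value)
  out$p_adj <- NA_real_
  out$p_adj[tested_idx] <- p.adjust(out$p_value[tested_idx], method = "BH")
  out <- out |>
    mutate(delta = .data$mean_in - .data$mean_out,
           selected = !is.na(.data$p_adj) & .data$p_adj < alpha) |>
    arrange(.data$p_adj, dplyr::desc(abs(.data$delta))) |>
    select("gene", "cluster", "mean_in", "mean_out", "delta", "pct_in",
           "pct_out", "p_value", "p_adj", "selected")
  structure(out, class = c("scm_markers", class(out)))
}
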