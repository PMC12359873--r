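#' Simulate a two-population gene-body level matrix
#'
#' Generates the clustering module's study conditions directly at the
#' region-level: two cell populations whose gene-body 5hmC levels share a
#' common per-gene baseline except for a set of shifted genes that differ
#' by `delta` between populations. Baselines are Beta-distributed around
#' the mean of the two global-5hmC presets (neurons 22.04%,
#' oligodendrocyte-precursor-like non-neurons 9.29%), which sets the
#' realistic level scale; the shifted genes carry the population
#' difference. Observed levels are binomial: each gene-cell entry draws
#' `n_total ~ 1 + Poisson(mean_calls - 1)` calls and
#' `n_mod ~ Binomial(n_total, p)`. Entries with fewer than `min_calls`
#' total calls, plus a random `missing_rate` of entries, are missing —
#' emulating coverage-limited single-cell data.
#'
#' @param n_cells Length-2 vector of cells per population (default 48+48).
#' @param n_genes Total genes (default 200).
#' @param n_shifted Genes shifted between populations (default 30).
#' @param delta Level difference of shifted genes (default 0.15);
#'   population 1 gets `+delta/2`, population 2 `-delta/2` (clamped to
#'   [0.01, 0.99]).
#' @param global_levels The two populations' global 5hmC levels, used for
#'   the baseline scale (default `c(0.2204, 0.0929)`).
#' @param concentration Beta concentration of the per-gene baselines.
#' @param mean_calls Mean total calls per gene-cell entry (default 100).
#' @param min_calls Calls below which an entry is missing (default 5).
#' @param missing_rate Extra random missingness (default 0.05).
#' @param seed Integer seed.
#' @return List: `region_levels` (long tibble compatible with
#'   [build_matrix()]), `truth` (tibble `cell`, `population`), `shifted`
#'   (character vector of truly shifted gene ids).
#' @export
simulate_region_matrix <- function(n_cells = c(48L, 48L), n_genes = 200L,
                                   n_shifted = 30L, delta = 0.15,
                                   global_levels = c(0.2204, 0.0929),
                                   concentration = 30, mean_calls = 100,
                                   min_calls = 5, missing_rate = 0.05,
                                   seed = 1) {
  stopifnot(n_shifted <= n_genes, length(n_cells) == 2)
  with_seed(seed, {
    m <- mean(global_levels)
    base <- stats::rbeta(n_genes, m * concentration,
                         (1 - m) * concentration)
    genes <- sprintf("gene%04d", seq_len(n_genes))
    shifted <- genes[seq_len(n_shifted)]
    p_pop <- rbind(base, base)  # populations x genes
    p_pop[1, seq_len(n_shifted)] <- base[seq_len(n_shifted)] + delta / 2
    p_pop[2, seq_len(n_shifted)] <- base[seq_len(n_shifted)] - delta / 2
    p_pop <- pmin(pmax(p_pop, 0.01), 0.99)

    cells <- sprintf("cell%03d", seq_len(sum(n_cells)))
    pop <- rep(1:2, n_cells)
    grid <- tidyr::expand_grid(cell_i = seq_along(cells),
                               gene_i = seq_len(n_genes))
    p <- p_pop[cbind(pop[grid$cell_i], grid$gene_i)]
    n_total <- 1L + rpois(nrow(grid), mean_calls - 1)
    n_mod <- rbinom(nrow(grid), n_total, p)
    lv <- tibble(region_id = genes[grid$gene_i],
                 cell = cells[grid$cell_i],
                 n_mod = n_mod, n_total = n_total,
                 level = if_else(n_total >= min_calls,
                                 n_mod / n_total, NA_real_))
    drop <- runif(nrow(lv)) < missing_rate
    lv$level[drop] <- NA_real_
    list(region_levels = structure(lv,
                                   class = c("scm_region_levels", class(lv)),
                                   min_calls = min_calls),
         truth = tibble(cell = cells, population = pop),
         shifted = shifted)
  })
}
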