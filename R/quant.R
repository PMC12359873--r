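#' Aggregate site calls over regions
#'
#' Computes the modification level of each region (gene body, chromatin
#' state, any BED-like interval set) per cell by summing modified calls and
#' dividing by total C-or-T calls over the sites falling in
#' `[start0, end0)`. Regions supported by fewer than `min_calls` total
#' calls get `level = NA` (the published gene filter excludes genes with
#' fewer than 5 total calls).
#'
#' @param calls Strand-merged CpG `scm_calls` table.
#' @param regions Tibble with `region_id` (or `gene_id`), `contig`,
#'   `start0`, `end0` and optionally `strand`.
#' @param min_calls Minimum total calls for a level (default 5).
#' @param group_by `"cell"` (default) or `"pooled"`.
#' @return Tibble of class `scm_region_levels` with `region_id`, `cell`,
#'   `n_mod`, `n_total`, `level`. Regions a cell never covers are absent;
#'   covered regions below `min_calls` have `level = NA`.
#' @export
region_level <- function(calls, regions, min_calls = 5,
                         group_by = c("cell", "pooled")) {
  group_by <- match.arg(group_by)
  regions <- normalise_regions(regions)
  df <- calls
  if (group_by == "pooled") df$cell <- "pooled"
  hits <- overlap_join(df, regions)
  out <- hits |>
    group_by(.data$region_id, .data$cell) |>
    summarise(n_total = sum(.data$n_mod + .data$n_unmod),
              n_mod = sum(.data$n_mod),
              .groups = "drop") |>
    select("region_id", "cell", "n_mod", "n_total") |>
    mutate(level = if_else(.data$n_total >= min_calls,
                           .data$n_mod / .data$n_total, NA_real_)) |>
    arrange(.data$region_id, .data$cell)
  structure(out, class = c("scm_region_levels", class(out)),
            min_calls = min_calls)
}

normalise_regions <- function(regions) {
  if (!"region_id" %in% names(regions)) {
    if ("gene_id" %in% names(regions)) {
      regions <- rename(regions, region_id = "gene_id")
    } else {
      regions <- mutate(regions, region_id = paste0("region", row_number()))
    }
  }
  if (!"strand" %in% names(regions)) regions$strand <- "+"
  bad <- regions$start0 >= regions$end0
  if (any(bad)) abort("regions must satisfy start0 < end0")
  regions
}

# Sites (pos0) overlapping regions [start0, end0), per contig via IRanges.
overlap_join <- function(calls, regions) {
  common <- intersect(unique(calls$contig), unique(regions$contig))
  skipped <- setdiff(unique(regions$contig), common)
  if (length(skipped) > 0) {
    warn(sprintf("skipping region(s) on contig(s) absent from the call table: %s",
                 paste(skipped, collapse = ", ")))
  }
  keep_cols <- intersect(c("cell", "contig", "pos0", "strand", "context",
                           "n_mod", "n_unmod", "n_other", "level"),
                         names(calls))
  parts <- lapply(common, function(ct) {
    cs <- calls[calls$contig == ct, keep_cols]
    rg <- regions[regions$contig == ct, ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(cs$pos0 + 1L, cs$pos0 + 1L),
      IRanges::IRanges(rg$start0 + 1L, rg$end0))
    bind_cols(cs[S4Vectors::queryHits(ov), ],
              rg[S4Vectors::subjectHits(ov), c("region_id", "start0", "end0",
                                               "strand")] |>
                rename(r_strand = "strand"))
  })
  bind_rows(parts)
}

#' Genome-wide binned modification track
#'
#' Tiles each contig with fixed-size bins `[k*b, (k+1)*b)` and aggregates
#' calls per bin with the same rule as [region_level()]; `min_calls`
#' defaults to 1 for browser-style tracks.
#'
#' @param calls Strand-merged CpG `scm_calls` table.
#' @param bin_size Bin width (bp), > 0.
#' @param min_calls Minimum total calls (default 1).
#' @param group_by `"cell"` or `"pooled"`.
#' @return Tibble with `cell`, `contig`, `bin`, `start0`, `end0`, `n_mod`,
#'   `n_total`, `level`.
#' @export
bin_levels <- function(calls, bin_size, min_calls = 1,
                       group_by = c("cell", "pooled")) {
  group_by <- match.arg(group_by)
  if (bin_size <= 0) abort("`bin_size` must be positive")
  df <- calls
  if (group_by == "pooled") df$cell <- "pooled"
  df |>
    mutate(bin = .data$pos0 %/% as.integer(bin_size)) |>
    group_by(.data$cell, .data$contig, .data$bin) |>
    summarise(n_total = sum(.data$n_mod + .data$n_unmod),
              n_mod = sum(.data$n_mod),
              .groups = "drop") |>
    mutate(start0 = .data$bin * as.integer(bin_size),
           end0 = .data$start0 + as.integer(bin_size),
           level = if_else(.data$n_total >= min_calls,
                           .data$n_mod / .data$n_total, NA_real_)) |>
    select("cell", "contig", "bin", "start0", "end0", "n_mod", "n_total",
           "level") |>
    arrange(.data$contig, .data$bin, .data$cell)
}

#' Metagene profile around gene bodies
#'
#' Scale-regions semantics: the upstream flank is kept in real coordinates,
#' the gene body is linearly rescaled to `body_length`, the downstream
#' flank is real again; minus-strand genes are mirrored so bin 0 is always
#' the 5' end. The profile is the pooled mean of site levels per bin across
#' genes (each covered site contributes its level once per overlapping
#' gene). Defaults follow the standard computeMatrix parameters: 5 kb
#' flanks, 5 kb body, 10 bp bins, i.e. 1500 bins.
#'
#' @param calls Strand-merged CpG `scm_calls` table (cells pooled).
#' @param genes Gene tibble (`contig`, `strand`, `start0`, `end0`).
#' @param flank Upstream/downstream flank length (bp).
#' @param body_length Rescaled gene-body length (bp).
#' @param bin_size Bin width (bp); `flank` and `body_length` must be
#'   multiples of it.
#' @return Tibble with `bin` (0-based), `segment`
#'   (`upstream`/`body`/`downstream`), `rel_pos` (bp from TSS, body
#'   rescaled), `mean_level`, `n_sites`. Bins with no calls are absent.
#' @export
metagene <- function(calls, genes, flank = 5000L, body_length = 5000L,
                     bin_size = 10L) {
  flank <- as.integer(flank); body_length <- as.integer(body_length)
  bin_size <- as.integer(bin_size)
  if (flank %% bin_size != 0 || body_length %% bin_size != 0) {
    abort("`flank` and `body_length` must be divisible by `bin_size`")
  }
  nf <- flank %/% bin_size; nb <- body_length %/% bin_size
  windows <- genes |>
    mutate(region_id = paste0("mg", row_number()),
           w_start = .data$start0 - flank, w_end = .data$end0 + flank)
  hits <- overlap_join(
    calls |> filter(!is.na(.data$level)),
    windows |> select("region_id", "contig",
                      start0 = "w_start", end0 = "w_end", "strand"))
  if (nrow(hits) == 0) {
    return(tibble(bin = integer(), segment = character(),
                  rel_pos = numeric(), mean_level = numeric(),
                  n_sites = integer()))
  }
  gmeta <- windows |> select("region_id", g_start = "start0", g_end = "end0")
  hits <- left_join(hits, gmeta, by = "region_id") |>
    mutate(glen = .data$g_end - .data$g_start,
           # mirror minus-strand genes inside their own interval
           p = if_else(.data$r_strand == "-",
                       .data$g_start + .data$g_end - 1L - .data$pos0,
                       .data$pos0),
           bin = dplyr::case_when(
             .data$p < .data$g_start ~
               (.data$p - (.data$g_start - flank)) %/% bin_size,
             .data$p >= .data$g_end ~
               nf + nb + (.data$p - .data$g_end) %/% bin_size,
             # body: rescale the site centre (x + 0.5) so that strand
             # mirroring maps bin b to bin nb-1-b (exact whenever nb is odd)
             TRUE ~ nf + pmin(
               as.integer(floor((.data$p - .data$g_start + 0.5) /
                                  .data$glen * nb)),
               nb - 1L)
           ))
  hits |>
    group_by(.data$bin) |>
    summarise(mean_level = mean(.data$level), n_sites = n(),
              .groups = "drop") |>
    mutate(segment = dplyr::case_when(
      .data$bin < nf ~ "upstream",
      .data$bin < nf + nb ~ "body",
      TRUE ~ "downstream"),
      rel_pos = (.data$bin - nf) * bin_size + bin_size / 2) |>
    select("bin", "segment", "rel_pos", "mean_level", "n_sites") |>
    arrange(.data$bin)
}

#' Number of metagene bins implied by the parameters
#' @inheritParams metagene
#' @return Integer bin count (default parameters give 1500).
#' @export
metagene_n_bins <- function(flank = 5000L, body_length = 5000L,
                            bin_size = 10L) {
  as.integer((2L * flank + body_length) %/% bin_size)
}

#' Pearson correlation of two level tables
#'
#' Joins two level tables (binned tracks, region matrices, ...) on their
#' shared keys and computes the Pearson correlation of the paired
#' non-missing levels — the bulk-versus-merged-single-cell comparison.
#'
#' @param levels_a,levels_b Tibbles containing a `level` column.
#' @param by Join keys (default: all shared columns except the value
#'   columns).
#' @param value Name of the value column (default `"level"`).
#' @return Tibble with `r` and `n` (pairs used).
#' @export
correlate_levels <- function(levels_a, levels_b, by = NULL, value = "level") {
  by <- by %||% setdiff(intersect(names(levels_a), names(levels_b)),
                        c(value, "n_mod", "n_total", "n_unmod", "n_other",
                          "cell"))
  joined <- inner_join(
    levels_a |> select(dplyr::all_of(c(by, value))) |> rename(a = dplyr::all_of(value)),
    levels_b |> select(dplyr::all_of(c(by, value))) |> rename(b = dplyr::all_of(value)),
    by = by) |>
    filter(!is.na(.data$a), !is.na(.data$b))
  if (nrow(joined) < 3) {
    abort(sprintf("need at least 3 paired observations, got %d", nrow(joined)))
  }
  tibble(r = cor(joined$a, joined$b), n = nrow(joined))
}

#' Pivot a region-level table to a regions x cells matrix tibble
#'
#' @param region_levels Output of [region_level()].
#' @return Wide tibble, one row per region, one column per cell.
#' @export
region_matrix <- function(region_levels) {
  tidyr::pivot_wider(region_levels, id_cols = "region_id",
                     names_from = "cell", values_from = "level")
}
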