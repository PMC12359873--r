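#' Estimate conversion and false-positive rates from spike-in controls
#'
#' Pools calls over the truth-eligible sites of each control class and
#' reports the modified fraction with a Wilson 95% confidence interval:
#'
#' * `mC_spikein` — CpG cytosines of the fully methylated control: the 5mC
#'   conversion rate under TAPS chemistry, or the 5mC false-positive rate
#'   under CAPS+ (which should leave 5mC unconverted).
#' * `hmC_spikein` — the declared 5hmC positions of the oligo control: the
#'   5hmC conversion rate.
#' * `uC_spikein` — every cytosine of the unmodified control: the
#'   false-positive rate.
#'
#' @param calls Unmerged (per-strand) `scm_calls` table covering the
#'   spike-in contigs; cells are pooled. Call with
#'   `contexts = c("CG", "CH")` so the unmodified-C class pools every
#'   cytosine, not just CpGs.
#' @param ref The `scm_reference` with spike-in contigs.
#' @param truth Truth tibble declaring the hmC spike-in positions.
#' @return Tibble of class `scm_spikein_report` with `class`, `rate`,
#'   `n_calls`, `conf_low`, `conf_high`. Classes with zero eligible calls
#'   are absent.
#' @export
spikein_rates <- function(calls, ref, truth) {
  spikes <- names(ref$spikein_class)[ref$spikein_class != "genomic"]
  if (length(spikes) == 0) abort("reference has no spike-in contigs")
  if (!any(calls$contig %in% spikes)) {
    abort(sprintf("call table covers no spike-in contig; expected any of: %s",
                  paste(spikes, collapse = ", ")))
  }
  if (isTRUE(attr(calls, "merged"))) {
    abort("spikein_rates needs the unmerged per-strand call table")
  }

  mC_ct <- SPIKEIN_CONTIGS[["mC_spikein"]]
  uC_ct <- SPIKEIN_CONTIGS[["uC_spikein"]]
  hmC_ct <- SPIKEIN_CONTIGS[["hmC_spikein"]]

  eligible <- list(
    mC_spikein = ref$cpg_index |>
      filter(.data$contig == mC_ct) |>
      select("contig", "pos0", "strand"),
    hmC_spikein = truth |>
      filter(.data$contig == hmC_ct, .data$state == "hmC") |>
      select("contig", "pos0", "strand"),
    uC_spikein = all_cytosines(ref$contigs[[uC_ct]], uC_ct)
  )

  rows <- purrr::imap(eligible, function(sites, cls) {
    sub <- inner_join(calls, sites, by = c("contig", "pos0", "strand"))
    n_mod <- sum(sub$n_mod); n_tot <- n_mod + sum(sub$n_unmod)
    if (n_tot == 0) return(NULL)
    ci <- suppressWarnings(
      prop.test(n_mod, n_tot, correct = FALSE)$conf.int)  # Wilson score
    tibble(class = cls, rate = n_mod / n_tot, n_calls = n_tot,
           conf_low = ci[1], conf_high = ci[2])
  })
  out <- bind_rows(rows)
  structure(out, class = c("scm_spikein_report", class(out)))
}

# Every cytosine of a contig, both strands (C on +, G on -).
all_cytosines <- function(seq, contig) {
  ch <- seq_chars(seq)
  tibble(contig = contig,
         pos0 = c(which(ch == "C"), which(ch == "G")) - 1L,
         strand = rep(c("+", "-"), c(sum(ch == "C"), sum(ch == "G"))))
}

#' Per-cell alignment statistics for quality gating
#'
#' Computes each cell's properly mapped read count under the QC definition:
#' reads surviving MAPQ > 1 and duplicate removal. Note this is a separate,
#' looser mapping-quality cut than the caller's MAPQ >= 10 filter.
#'
#' @param reads `scm_reads` tibble with duplicate flags set.
#' @param calls Optional merged CpG `scm_calls` table used to count CpGs
#'   covered per cell.
#' @return Tibble with `cell`, `properly_mapped_reads`, `cpgs_covered`.
#' @export
alignment_cell_stats <- function(reads, calls = NULL) {
  stats <- reads |>
    filter(!.data$dup, .data$mapq > 1) |>
    count(.data$cell, name = "properly_mapped_reads")
  cov <- if (!is.null(calls)) {
    calls |>
      filter(.data$n_mod + .data$n_unmod > 0) |>
      distinct(.data$cell, .data$contig, .data$pos0) |>
      count(.data$cell, name = "cpgs_covered")
  } else {
    tibble(cell = character(), cpgs_covered = integer())
  }
  left_join(stats, cov, by = "cell") |>
    mutate(cpgs_covered = dplyr::coalesce(.data$cpgs_covered, 0L))
}

#' Gate cells on properly mapped read counts
#'
#' Cells with fewer than `min_reads` or more than `max_reads` properly
#' mapped reads (MAPQ > 1, post-deduplication) are excluded from downstream
#' analysis; the published window is 500,000 to 3,000,000.
#'
#' @param stats Tibble with `cell` and `properly_mapped_reads` (see
#'   [alignment_cell_stats()]).
#' @param min_reads,max_reads QC window bounds (inclusive).
#' @return Tibble of class `scm_cell_qc` with `cell`,
#'   `properly_mapped_reads`, `cpgs_covered` (if supplied), `pass`,
#'   `reason` (`""`, `"low"` or `"high"`).
#' @export
cell_qc <- function(stats, min_reads = 5e5, max_reads = 3e6) {
  out <- stats |>
    mutate(reason = dplyr::case_when(
      .data$properly_mapped_reads < min_reads ~ "low",
      .data$properly_mapped_reads > max_reads ~ "high",
      TRUE ~ ""),
      pass = .data$reason == "")
  n_fail <- sum(!out$pass)
  if (n_fail > 0) {
    inform(sprintf("cell_qc: %d of %d cell(s) excluded (%d low, %d high)",
                   n_fail, nrow(out), sum(out$reason == "low"),
                   sum(out$reason == "high")))
  }
  structure(out, class = c("scm_cell_qc", class(out)))
}

#' CpG coverage saturation curve
#'
#' Subsamples read pairs at nested fractions (each smaller sample is a
#' subset of every larger one, so the curve is monotone by construction)
#' and counts the distinct CpG dinucleotides covered at each depth.
#'
#' @param reads `scm_reads` tibble.
#' @param ref The `scm_reference`.
#' @param fractions Ascending subsampling fractions in (0, 1].
#' @param seed Integer seed for the subsampling permutation.
#' @param min_mapq,end_trim Caller filters applied when deciding coverage.
#' @return Tibble with `fraction`, `n_pairs`, `cpgs_covered`.
#' @export
saturation <- function(reads, ref, fractions = seq(0.1, 1, by = 0.1),
                       seed = 1, min_mapq = 10, end_trim = 10) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must lie in (0, 1]")
  }
  if (is.unsorted(fractions)) abort("`fractions` must be ascending")
  obs <- site_observations(reads, ref, min_mapq, end_trim) |>
    filter(.data$context == "CG", .data$class %in% c("mod", "unmod")) |>
    mutate(cpg = paste0(.data$contig, ":",
                        if_else(.data$strand == "-", .data$pos0 - 1L,
                                .data$pos0)))
  all_pairs <- unique(reads$qname)
  perm <- with_seed(seed, sample(all_pairs))
  ord <- order(match(obs$qname, perm))
  obs <- obs[ord, ]
  first_cover <- !duplicated(obs$cpg)
  # cumulative distinct CpGs after each pair in permutation order
  pair_rank <- match(obs$qname, perm)
  cum_new <- cumsum(first_cover)
  purrr::map_dfr(fractions, function(f) {
    k <- floor(f * length(perm))
    idx <- which(pair_rank <= k)
    covered <- if (length(idx) == 0) 0L else cum_new[max(idx)]
    tibble(fraction = f, n_pairs = k, cpgs_covered = as.integer(covered))
  })
}

#' CpG coverage summary
#'
#' @param calls Merged CpG `scm_calls` table.
#' @param ref The `scm_reference`; the CpG universe is the merged
#'   dinucleotides of the genomic contigs (spike-ins excluded).
#' @return Tibble with `cpgs_covered`, `total_cpgs`,
#'   `fraction_of_total_cpgs`.
#' @export
coverage_stats <- function(calls, ref) {
  genomic <- names(ref$spikein_class)[ref$spikein_class == "genomic"]
  total <- ref$cpg_index |>
    filter(.data$contig %in% genomic, .data$strand == "+") |>
    nrow()
  covered <- calls |>
    filter(.data$contig %in% genomic, .data$n_mod + .data$n_unmod > 0) |>
    distinct(.data$contig, .data$pos0) |>
    nrow()
  tibble(cpgs_covered = covered, total_cpgs = total,
         fraction_of_total_cpgs = if (total > 0) covered / total else 0)
}
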