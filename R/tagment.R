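#' Simulate barcoded Tn5 tagmentation
#'
#' Draws per-cell genomic fragments: fragment starts are uniform over
#' eligible positions, insert lengths uniform over `insert_range` (clamped
#' to the contig), and the sequenced template strand is a fair coin. A
#' fraction of fragments is drawn from the spike-in contigs instead of the
#' genome; the real libraries add ~0.1% spike-in DNA, and test fixtures
#' raise the fraction for statistical power.
#'
#' @param ref An `scm_reference`.
#' @param cells Barcode tibble (see [default_barcodes()]); one row per cell.
#' @param frags_per_cell Fragments per cell.
#' @param insert_range Length-2 vector, min/max insert length (bp).
#' @param spikein_fraction Probability that a fragment comes from a
#'   spike-in contig (default 0.001).
#' @param seed Integer seed.
#' @return Tibble of class `scm_fragments` with `frag_id`, `cell`, `i5`,
#'   `i7`, `contig`, `start0`, `end0`, `template` (`top`/`bottom`).
#' @export
tagment <- function(ref, cells, frags_per_cell, insert_range = c(200L, 700L),
                    spikein_fraction = 0.001, seed = 1) {
  stopifnot(inherits(ref, "scm_reference"))
  if (nrow(cells) == 0) abort("`cells` must contain at least one barcode")
  if (!(spikein_fraction >= 0 && spikein_fraction < 1)) {
    abort("`spikein_fraction` must lie in [0, 1)")
  }
  insert_range <- as.integer(insert_range)
  if (insert_range[1] < 30 || insert_range[1] > insert_range[2]) {
    abort("`insert_range` must satisfy 30 <= min <= max")
  }
  genomic <- names(ref$spikein_class)[ref$spikein_class == "genomic"]
  spikes <- names(ref$spikein_class)[ref$spikein_class != "genomic"]
  if (spikein_fraction > 0 && length(spikes) == 0) {
    abort("spikein_fraction > 0 but the reference has no spike-in contigs")
  }
  n <- frags_per_cell * nrow(cells)

  with_seed(seed, {
    is_spike <- runif(n) < spikein_fraction
    pick <- function(pool, k) {
      if (k == 0) return(character(0))
      w <- as.numeric(nchar(ref$contigs[pool]))
      sample(pool, k, replace = TRUE, prob = w)
    }
    contig <- character(n)
    contig[!is_spike] <- pick(genomic, sum(!is_spike))
    contig[is_spike] <- pick(spikes, sum(is_spike))
    clen <- nchar(ref$contigs)[contig]
    insert <- pmin(as.integer(floor(runif(n, insert_range[1],
                                          insert_range[2] + 1))), clen)
    start0 <- as.integer(floor(runif(n, 0, clen - insert + 1)))
    cell_idx <- rep(seq_len(nrow(cells)), each = frags_per_cell)
    tibble(
      frag_id = sprintf("f%07d", seq_len(n)),
      cell = cells$well[cell_idx],
      i5 = cells$i5[cell_idx],
      i7 = cells$i7[cell_idx],
      contig = contig,
      start0 = start0,
      end0 = start0 + insert,
      template = sample(c("top", "bottom"), n, replace = TRUE)
    )
  })
}
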