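#' Built-in methylome profiles
#'
#' Global modification rates used when simulating genomic methylomes. The
#' `neuron` and `nonneuron` profiles carry the hippocampal global 5hmC
#' levels of NeuN+ neurons (22.04%) and NeuN- non-neurons, dominated by
#' oligodendrocyte precursors (9.29%); `somatic` is a generic high-5mC
#' profile for 5mC-focused simulations.
#'
#' @param name One of `"neuron"`, `"nonneuron"`, `"somatic"`.
#' @return A named list with `global_mC`, `global_hmC`, `tss_dip_width` (bp)
#'   and `tss_dip_depth`, suitable for [assign_methylome()].
#' @export
methylome_profile <- function(name = c("neuron", "nonneuron", "somatic")) {
  name <- match.arg(name)
  base <- switch(name,
    neuron    = list(global_mC = 0.60, global_hmC = 0.2204),
    nonneuron = list(global_mC = 0.60, global_hmC = 0.0929),
    somatic   = list(global_mC = 0.80, global_hmC = 0.05)
  )
  c(base, list(tss_dip_width = 2000L, tss_dip_depth = 0.8))
}

#' Assign a ground-truth methylome to the genomic CpGs
#'
#' Each CpG dinucleotide independently receives a state (`uC`, `mC`, `hmC`)
#' at the profile's global rates, attenuated near transcription start sites
#' by a triangular dip (factor `1 - depth * max(0, 1 - d/width)` at distance
#' `d` from the nearest TSS) so that both marks drop around promoters. By
#' default the two strands of a CpG share one state (symmetric CpG
#' methylation); non-CpG cytosines stay unmodified.
#'
#' @param ref An `scm_reference`.
#' @param profile List with `global_mC`, `global_hmC`, `tss_dip_width`,
#'   `tss_dip_depth` (see [methylome_profile()]); `global_mC + global_hmC`
#'   must not exceed 1.
#' @param genes Optional gene tibble providing TSS positions for the dip;
#'   `NULL` disables the dip.
#' @param seed Integer seed.
#' @param symmetric Draw one state per dinucleotide shared by both strands
#'   (default) or independent states per strand.
#' @param spikein_truth Optional spike-in truth tibble (from
#'   [add_spikeins()]) appended to the result.
#' @return Truth tibble (`contig`, `pos0`, `strand`, `state`) listing the
#'   modified cytosines; unmodified positions are implicit.
#' @export
assign_methylome <- function(ref, profile = methylome_profile("somatic"),
                             genes = NULL, seed = 1, symmetric = TRUE,
                             spikein_truth = NULL) {
  stopifnot(inherits(ref, "scm_reference"))
  pm <- profile$global_mC
  ph <- profile$global_hmC
  assert_unit_interval(pm, "global_mC")
  assert_unit_interval(ph, "global_hmC")
  if (pm + ph > 1) abort("global_mC + global_hmC must be <= 1")
  width <- profile$tss_dip_width %||% 2000L
  depth <- profile$tss_dip_depth %||% 0.8

  genomic <- names(ref$spikein_class)[ref$spikein_class == "genomic"]
  idx <- ref$cpg_index |> filter(.data$contig %in% genomic)
  # One row per dinucleotide: the top-strand C anchors the pair.
  top <- idx |> filter(.data$strand == "+")

  dip <- rep(1, nrow(top))
  if (!is.null(genes) && nrow(genes) > 0 && depth > 0 && width > 0) {
    tss <- genes |>
      mutate(tss = if_else(.data$strand == "+", .data$start0, .data$end0 - 1L)) |>
      select("contig", "tss")
    d <- nearest_distance(top$contig, top$pos0, tss$contig, tss$tss)
    dip <- 1 - depth * pmax(0, 1 - d / width)
  }

  states <- with_seed(seed, {
    draw_states <- function(n, f) {
      u <- runif(n)
      ifelse(u < pm * f, "mC", ifelse(u < (pm + ph) * f, "hmC", "uC"))
    }
    if (symmetric) {
      s <- draw_states(nrow(top), dip)
      tibble(contig = rep(top$contig, 2),
             pos0 = c(top$pos0, top$pos0 + 1L),
             strand = rep(c("+", "-"), each = nrow(top)),
             state = rep(s, 2))
    } else {
      bot <- idx |> filter(.data$strand == "-")
      dip_bot <- dip[match(bot$pos0 - 1L, top$pos0)]
      bind_rows(
        top |> mutate(state = draw_states(nrow(top), dip)),
        bot |> mutate(state = draw_states(nrow(bot), dip_bot))
      )
    }
  })
  out <- states |>
    filter(.data$state != "uC") |>
    arrange(.data$contig, .data$pos0, .data$strand)
  if (!is.null(spikein_truth)) out <- bind_rows(out, spikein_truth)
  out
}

# Distance from each query position to the nearest anchor on the same contig
# (Inf when the contig has no anchor).
nearest_distance <- function(q_contig, q_pos, a_contig, a_pos) {
  out <- rep(Inf, length(q_pos))
  for (ct in unique(q_contig)) {
    a <- sort(a_pos[a_contig == ct])
    if (length(a) == 0) next
    qi <- which(q_contig == ct)
    j <- findInterval(q_pos[qi], a)
    lo <- ifelse(j >= 1, abs(q_pos[qi] - a[pmax(j, 1)]), Inf)
    hi <- ifelse(j < length(a), abs(a[pmin(j + 1, length(a))] - q_pos[qi]), Inf)
    out[qi] <- pmin(lo, hi)
  }
  out
}

#' Write / read a truth table
#'
#' Plain TSV with columns `contig`, `pos0`, `strand`, `state`.
#'
#' @param truth Truth tibble.
#' @param path File path.
#' @return `path` (writer) or the truth tibble (reader).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "integer",
                                             "character", "character")))
}
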