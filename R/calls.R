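#' Infer the sequenced template strand of each read
#'
#' The libraries are directional: R1 always reports the converted template.
#' A read therefore comes from the top strand iff it is (R1 and forward)
#' or (R2 and reverse), and from the bottom strand otherwise. Top-strand
#' reads are scored at reference C positions (C read as T when converted),
#' bottom-strand reads at reference G positions (G read as A). This rule is
#' the single point to change for non-directional data.
#'
#' @param reads `scm_reads` tibble.
#' @return The tibble with a `template` column (`top`/`bottom`) added.
#' @export
infer_template_strand <- function(reads) {
  mutate(reads, template = if_else(
    (.data$mate == "R1") == (.data$orientation == "forward"),
    "top", "bottom"))
}

#' Mark PCR duplicates per cell
#'
#' Read pairs sharing cell, contig, fragment start, fragment end and
#' fragment orientation are duplicates of one original molecule; all but a
#' deterministic keeper (first read name in sort order) are flagged.
#' Fragments from different cells are biologically distinct molecules, so
#' duplicates are marked within cells.
#'
#' @param reads `scm_reads` tibble (both mates present per pair).
#' @return The tibble with the `dup` flag set on duplicate pairs.
#' @export
mark_duplicates <- function(reads) {
  rlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  frag <- reads |>
    mutate(.end = .data$pos0 + rlen) |>
    group_by(.data$qname) |>
    summarise(cell = first(.data$cell), contig = first(.data$contig),
              fstart = min(.data$pos0), fend = max(.data$.end),
              forient = .data$orientation[.data$mate == "R1"][1],
              .groups = "drop") |>
    arrange(.data$qname) |>
    group_by(.data$cell, .data$contig, .data$fstart, .data$fend,
             .data$forient) |>
    mutate(.isdup = row_number() > 1) |>
    ungroup()
  dup_names <- frag$qname[frag$.isdup]
  mutate(reads, dup = .data$qname %in% dup_names)
}

#' Call methylation at cytosine sites
#'
#' The direct-conversion caller: duplicate-flagged reads and reads below
#' `min_mapq` are excluded; per read, query positions within `end_trim`
#' bases of either read end are ignored; at every retained reference C
#' (top-strand template) or G (bottom-strand template) in a requested
#' context, a read base of T (resp. A) counts as a modified call, C
#' (resp. G) as unmodified, anything else as other. Bases where mates of
#' one pair overlap are counted once (R1 preferred). Defaults mirror the
#' published pre-processing: MAPQ >= 10 and 10 bp trimmed from each read
#' end.
#'
#' @param reads `scm_reads` tibble (or path readable by
#'   [read_alignments()]).
#' @param ref The `scm_reference`.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param end_trim Bases ignored at each read end (default 10).
#' @param contexts `"CG"` (default) or `c("CG", "CH")`.
#' @param group_by `"cell"` (default) or `"pooled"`.
#' @return Tibble of class `scm_calls`: one row per (cell, site, strand)
#'   with `cell`, `contig`, `pos0`, `strand`, `context`, `n_mod`,
#'   `n_unmod`, `n_other`, `level` (`n_mod / (n_mod + n_unmod)`, `NA` when
#'   uncovered), sorted by position. Carries attribute `merged = FALSE`.
#' @export
call_sites <- function(reads, ref, min_mapq = 10, end_trim = 10,
                       contexts = "CG", group_by = c("cell", "pooled")) {
  group_by <- match.arg(group_by)
  obs <- site_observations(reads, ref, min_mapq, end_trim)
  obs <- filter(obs, .data$context %in% contexts)
  if (group_by == "pooled") obs$cell <- "pooled"
  out <- obs |>
    group_by(.data$cell, .data$contig, .data$pos0, .data$strand,
             .data$context) |>
    summarise(n_mod = sum(.data$class == "mod"),
              n_unmod = sum(.data$class == "unmod"),
              n_other = sum(.data$class == "other"), .groups = "drop") |>
    mutate(level = if_else(.data$n_mod + .data$n_unmod > 0,
                           .data$n_mod / (.data$n_mod + .data$n_unmod),
                           NA_real_)) |>
    arrange(.data$contig, .data$pos0, .data$strand, .data$cell)
  new_calls(out, merged = FALSE)
}

new_calls <- function(df, merged) {
  structure(df, class = unique(c("scm_calls", class(df))), merged = merged)
}

# One row per retained (read pair, reference position) observation at a
# cytosine of the template strand. The engine behind call_sites() and
# saturation().
site_observations <- function(reads, ref, min_mapq = 10, end_trim = 10) {
  if (is.character(reads)) reads <- read_alignments(reads)
  reads <- reads |>
    filter(!.data$dup, .data$mapq >= min_mapq, !is.na(.data$cigar))
  bad <- grepl("[^0-9MIDSX=]", reads$cigar)
  if (any(bad)) {
    warn(sprintf("%d read(s) with unsupported CIGAR ops skipped", sum(bad)))
    reads <- reads[!bad, ]
  }
  reads <- infer_template_strand(reads)
  if (nrow(reads) == 0) {
    return(tibble(qname = character(), mate = character(), cell = character(),
                  contig = character(), pos0 = integer(), strand = character(),
                  context = character(), class = character()))
  }

  # Aligned (query, reference) position pairs from the CIGAR.
  ops <- c("M", "=", "X")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar, ops = ops)
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(reads$cigar,
                                                          pos = reads$pos0 + 1L,
                                                          ops = ops)
  widths <- unlist(IRanges::width(qr), use.names = FALSE)
  ridx <- rep(seq_len(nrow(reads)),
              S4Vectors::elementNROWS(qr))[rep(seq_along(widths),
                                               widths)] # nolint
  off <- sequence(widths) - 1L
  qpos <- rep(unlist(IRanges::start(qr), use.names = FALSE), widths) + off
  rpos1 <- rep(unlist(IRanges::start(rr), use.names = FALSE), widths) + off

  # End trim: drop query positions within end_trim of either read end
  # (symmetric, so stored reference-forward coordinates are fine).
  qlen <- nchar(reads$seq)[ridx]
  keep <- qpos > end_trim & qpos <= qlen - end_trim
  ridx <- ridx[keep]; qpos <- qpos[keep]; rpos1 <- rpos1[keep]

  refchars <- lapply(ref$contigs, seq_chars)
  refbase <- character(length(ridx))
  nextbase <- prevbase <- rep(NA_character_, length(ridx))
  ct_of <- reads$contig[ridx]
  for (ct in unique(ct_of)) {
    rc <- refchars[[ct]]
    if (is.null(rc)) abort(sprintf("aligned contig '%s' absent from reference", ct))
    sel <- ct_of == ct
    refbase[sel] <- rc[rpos1[sel]]
    nb <- rpos1[sel] + 1L
    pb <- rpos1[sel] - 1L
    nextbase[sel] <- ifelse(nb <= length(rc), rc[nb], NA)
    prevbase[sel] <- ifelse(pb >= 1L, rc[pmax(pb, 1L)], NA)
  }

  top <- reads$template[ridx] == "top"
  is_site <- (top & refbase == "C") | (!top & refbase == "G")
  ridx <- ridx[is_site]; qpos <- qpos[is_site]; rpos1 <- rpos1[is_site]
  top <- top[is_site]
  context <- if_else(top,
                     if_else(!is.na(nextbase[is_site]) & nextbase[is_site] == "G",
                             "CG", "CH"),
                     if_else(!is.na(prevbase[is_site]) & prevbase[is_site] == "C",
                             "CG", "CH"))
  base <- substr(reads$seq[ridx], qpos, qpos)
  class <- if_else(top,
                   if_else(base == "T", "mod",
                           if_else(base == "C", "unmod", "other")),
                   if_else(base == "A", "mod",
                           if_else(base == "G", "unmod", "other")))

  obs <- tibble(qname = reads$qname[ridx],
                mate = reads$mate[ridx],
                cell = reads$cell[ridx],
                contig = reads$contig[ridx],
                pos0 = rpos1 - 1L,
                strand = if_else(top, "+", "-"),
                context = context,
                class = class)
  # Overlapping mates: count the overlapped template position once,
  # preferring R1.
  obs |>
    arrange(.data$mate) |>
    distinct(.data$qname, .data$contig, .data$pos0, .keep_all = TRUE)
}

#' Merge symmetric CpG strand calls
#'
#' Sums the counts of the top-strand C and the paired bottom-strand call
#' (the reference G one base downstream) of each CpG dinucleotide. The
#' merged site is reported at the C's top-strand position with strand
#' `"+"`. Total calls are conserved.
#'
#' @param calls `scm_calls` tibble with context `CG`.
#' @return Merged `scm_calls` tibble (attribute `merged = TRUE`).
#' @export
merge_cpg_strands <- function(calls) {
  stopifnot(all(calls$context == "CG"))
  out <- calls |>
    mutate(cpg_pos = if_else(.data$strand == "-", .data$pos0 - 1L,
                             .data$pos0)) |>
    group_by(.data$cell, .data$contig, .data$cpg_pos) |>
    summarise(n_mod = sum(.data$n_mod), n_unmod = sum(.data$n_unmod),
              n_other = sum(.data$n_other), .groups = "drop") |>
    mutate(pos0 = .data$cpg_pos, strand = "+", context = "CG",
           level = if_else(.data$n_mod + .data$n_unmod > 0,
                           .data$n_mod / (.data$n_mod + .data$n_unmod),
                           NA_real_)) |>
    select("cell", "contig", "pos0", "strand", "context",
           "n_mod", "n_unmod", "n_other", "level") |>
    arrange(.data$contig, .data$pos0, .data$cell)
  new_calls(out, merged = TRUE)
}

#' Write a site-call table as bedMethyl-like TSV
#'
#' Columns: contig, pos0, pos0+1, strand, context, cell, n_mod, n_unmod,
#' level — in bit-stable position order.
#'
#' @param calls `scm_calls` tibble.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  df <- calls |>
    arrange(.data$contig, .data$pos0, .data$strand, .data$cell) |>
    mutate(end0 = .data$pos0 + 1L) |>
    select("contig", "pos0", "end0", "strand", "context", "cell",
           "n_mod", "n_unmod", "level")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
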