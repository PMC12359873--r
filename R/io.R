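#' Write simulated reads as paired FASTQ
#'
#' Emits standard 4-line phred+33 FASTQ (constant quality `I`). Reads with
#' reverse orientation are reverse-complemented from their stored
#' reference-forward sequence back to as-sequenced orientation.
#'
#' @param reads `scm_reads` tibble from [convert_and_sequence()].
#' @param r1_path,r2_path Output paths for the two mates.
#' @param inline_barcode Prepend `<i5><i7>` to each read sequence (for
#'   in-read demultiplexing tests); default `FALSE`, barcodes live in the
#'   read names.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path, inline_barcode = FALSE) {
  write_one <- function(df, path) {
    df <- arrange(df, .data$qname)
    sq <- if_else(df$orientation == "reverse", revcomp(df$seq), df$seq)
    if (inline_barcode) sq <- paste0(df$i5, df$i7, sq)
    lines <- as.vector(rbind(paste0("@", df$qname), sq, "+",
                             strrep("I", nchar(sq))))
    writeLines(lines, path)
  }
  write_one(filter(reads, .data$mate == "R1"), r1_path)
  write_one(filter(reads, .data$mate == "R2"), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ pair into a tibble
#'
#' @param r1_path,r2_path FASTQ paths (matching read order).
#' @return Tibble with `qname`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) {
    abort(sprintf("R1/R2 record counts differ (%d vs %d)",
                  length(r1), length(r2)))
  }
  n1 <- sub("\\s.*$", "", names(r1))
  n2 <- sub("\\s.*$", "", names(r2))
  mism <- which(n1 != n2)
  if (length(mism) > 0) {
    abort(sprintf("R1/R2 name mismatch at record %d: '%s' vs '%s'",
                  mism[1], n1[mism[1]], n2[mism[1]]))
  }
  tibble(qname = n1, seq1 = as.character(r1), seq2 = as.character(r2))
}

# SAM flag bits
FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_REV <- 16L; FLAG_MREV <- 32L
FLAG_R1 <- 64L; FLAG_R2 <- 128L; FLAG_SECONDARY <- 256L; FLAG_DUP <- 1024L
FLAG_UNMAPPED <- 4L; FLAG_SUPPL <- 2048L

#' Write reads as a SAM file with truth positions
#'
#' Emits coordinate-correct alignments (all-match CIGAR, MAPQ 60,
#' proper-pair flags, `CB` cell-barcode tag) so the caller can be exercised
#' without an external aligner.
#'
#' @param reads `scm_reads` tibble.
#' @param ref The `scm_reference` (for `@SQ` header lines).
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                      nchar(ref$contigs)))
  df <- arrange(reads, .data$qname, .data$mate)
  mate_of <- df |>
    mutate(idx = row_number()) |>
    group_by(.data$qname) |>
    mutate(mpos = rev(.data$pos0), morient = rev(.data$orientation)) |>
    ungroup()
  rlen <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  frag_start <- pmin(df$pos0, mate_of$mpos)
  frag_end <- pmax(df$pos0 + rlen, mate_of$mpos + rlen)  # equal-length mates
  tlen <- if_else(df$pos0 <= mate_of$mpos,
                  frag_end - frag_start, -(frag_end - frag_start))
  flag <- FLAG_PAIRED +
    if_else(df$proper, FLAG_PROPER, 0L) +
    if_else(df$orientation == "reverse", FLAG_REV, 0L) +
    if_else(mate_of$morient == "reverse", FLAG_MREV, 0L) +
    if_else(df$mate == "R1", FLAG_R1, FLAG_R2) +
    if_else(df$dup, FLAG_DUP, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s\tCB:Z:%s",
                   df$qname, flag, df$contig, df$pos0 + 1L, df$mapq,
                   df$cigar, mate_of$mpos + 1L, tlen, df$seq,
                   strrep("I", nchar(df$seq)), df$cell)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read alignments from SAM/BAM into an `scm_reads` tibble
#'
#' SAM text is converted with [Rsamtools::asBam()] and read back via
#' [Rsamtools::scanBam()]. Unmapped, secondary and supplementary records
#' are dropped. The cell id is taken from the `CB` tag when present,
#' otherwise from the third `|`-separated read-name field (the simulator's
#' encoding), otherwise `"pooled"`.
#'
#' @param path `.sam` or `.bam` path.
#' @return `scm_reads` tibble (without `true_template`).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "CB")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  keep <- bitwAnd(flag, FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPL) == 0L
  cb <- b$tag$CB
  if (is.null(cb)) cb <- rep(NA_character_, length(flag))
  qn <- b$qname
  cell <- cb
  from_name <- is.na(cell) & stringr::str_count(qn, stringr::fixed("|")) >= 2
  cell[from_name] <- purrr::map_chr(strsplit(qn[from_name], "|", fixed = TRUE),
                                    3)
  cell[is.na(cell)] <- "pooled"
  out <- tibble(
    qname = qn,
    mate = if_else(bitwAnd(flag, FLAG_R1) > 0L, "R1", "R2"),
    cell = cell,
    i5 = NA_character_,
    i7 = NA_character_,
    contig = as.character(b$rname),
    pos0 = b$pos - 1L,
    mapq = as.integer(b$mapq),
    cigar = b$cigar,
    orientation = if_else(bitwAnd(flag, FLAG_REV) > 0L, "reverse", "forward"),
    proper = bitwAnd(flag, FLAG_PROPER) > 0L,
    dup = bitwAnd(flag, FLAG_DUP) > 0L,
    seq = as.character(b$seq)
  )[keep, ]
  structure(out, class = c("scm_reads", class(out)))
}
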