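#' Demultiplex read pairs by i5/i7 barcode
#'
#' Replicates the name-based demultiplexing stage: each pair is assigned to
#' the unique well whose i5 AND i7 tags are each within `max_mismatch`
#' substitutions of the observed tags. Pairs matching no well are
#' `unassigned`; pairs matching more than one (possible only when the tag
#' set's Hamming guarantees are violated by the chosen tolerance) are
#' `ambiguous` and never assigned. The default tolerance is 0, matching
#' exact name-based demultiplexing; `max_mismatch = 1` enables error
#' correction, which the distance-3 tag sets support unambiguously.
#'
#' @param reads Either an `scm_reads`/pairs tibble with a `qname` column
#'   encoding `<i5>+<i7>` in its second `|`-separated field (the
#'   simulator's name mode), or a length-2 character vector of R1/R2 FASTQ
#'   paths. For `mode = "inline"` the observed tags are taken from the
#'   first bases of each read sequence instead (i5 from R1, i7 from R1
#'   after the i5).
#' @param barcodes Barcode tibble (`well`, `i5`, `i7`).
#' @param max_mismatch Per-tag substitution tolerance (default 0).
#' @param mode `"name"` (default) or `"inline"`.
#' @param outdir If non-`NULL` and `reads` are FASTQ paths, per-well FASTQ
#'   pairs are written here.
#' @return A list of class `scm_demux` with `assignments` (tibble `qname`,
#'   `well`, `status`) and `report` (tibble `well`, `n_pairs`, including
#'   `unassigned` and `ambiguous` pseudo-wells). Counts are conserved:
#'   assigned + unassigned + ambiguous equals the number of input pairs.
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 0,
                        mode = c("name", "inline"), outdir = NULL) {
  mode <- match.arg(mode)
  from_files <- is.character(reads)
  pairs <- if (from_files) {
    read_fastq_pair(reads[1], reads[2])
  } else {
    reads |> filter(.data$mate == "R1") |> distinct(.data$qname, .keep_all = TRUE)
  }

  tag_len_i5 <- nchar(barcodes$i5[1])
  tag_len_i7 <- nchar(barcodes$i7[1])
  if (mode == "name") {
    field <- purrr::map_chr(strsplit(pairs$qname, "|", fixed = TRUE), function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    })
    obs <- stringr::str_split_fixed(field, stringr::fixed("+"), 2)
    obs_i5 <- obs[, 1]; obs_i7 <- obs[, 2]
  } else {
    sq <- if (from_files) pairs$seq1 else pairs$seq
    obs_i5 <- substr(sq, 1, tag_len_i5)
    obs_i7 <- substr(sq, tag_len_i5 + 1, tag_len_i5 + tag_len_i7)
  }

  i5_set <- unique(barcodes$i5)
  i7_set <- unique(barcodes$i7)
  m5 <- match_tags(obs_i5, i5_set, max_mismatch)
  m7 <- match_tags(obs_i7, i7_set, max_mismatch)

  status <- rep("assigned", nrow(pairs))
  status[m5$n == 0 | m7$n == 0] <- "unassigned"
  status[m5$n > 1 | m7$n > 1] <- "ambiguous"
  well <- rep(NA_character_, nrow(pairs))
  ok <- status == "assigned"
  key <- paste(i5_set[m5$which[ok]], i7_set[m7$which[ok]])
  well[ok] <- barcodes$well[match(key, paste(barcodes$i5, barcodes$i7))]
  # (i5, i7) combinations absent from the plate layout are unassigned
  status[ok][is.na(well[ok])] <- "unassigned"
  well[status != "assigned"] <- NA_character_

  assignments <- tibble(qname = pairs$qname, well = well, status = status)
  report <- assignments |>
    count(well = dplyr::coalesce(.data$well, .data$status), name = "n_pairs") |>
    arrange(.data$well)

  if (!is.null(outdir) && from_files) {
    write_demux_fastq(reads, assignments, outdir)
  }
  structure(list(assignments = assignments, report = report),
            class = "scm_demux")
}

# For each observed tag: number of set tags within max_mismatch and the
# index of the (unique) best one.
match_tags <- function(obs, set, max_mismatch) {
  L <- nchar(set[1])
  setm <- do.call(rbind, strsplit(set, ""))
  n <- integer(length(obs)); which_one <- integer(length(obs))
  uo <- unique(obs)
  for (tag in uo) {
    d <- if (is.na(tag) || nchar(tag) != L) {
      rep(L, length(set))
    } else {
      colSums(t(setm) != strsplit(tag, "")[[1]])
    }
    hits <- which(d <= max_mismatch)
    sel <- obs == tag & !is.na(obs)
    n[sel] <- length(hits)
    which_one[sel] <- if (length(hits) >= 1) hits[1] else NA_integer_
  }
  list(n = n, which = which_one)
}

write_demux_fastq <- function(fastq_paths, assignments, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pr <- read_fastq_pair(fastq_paths[1], fastq_paths[2])
  pr <- left_join(pr, assignments, by = "qname")
  for (w in unique(stats::na.omit(pr$well))) {
    sub <- filter(pr, .data$well == w)
    for (m in c(1, 2)) {
      sq <- if (m == 1) sub$seq1 else sub$seq2
      lines <- as.vector(rbind(paste0("@", sub$qname), sq, "+",
                               strrep("I", nchar(sq))))
      writeLines(lines, file.path(outdir, sprintf("%s_R%d.fastq", w, m)))
    }
  }
  invisible(outdir)
}

#' @export
print.scm_demux <- function(x, ...) {
  total <- sum(x$report$n_pairs)
  unas <- sum(x$report$n_pairs[x$report$well %in% c("unassigned", "ambiguous")])
  cat(sprintf("<scm_demux> %d pairs, %d assigned (%.1f%%)\n",
              total, total - unas, 100 * (total - unas) / max(total, 1)))
  invisible(x)
}
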