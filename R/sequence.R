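#' Apply conversion chemistry and sequence paired-end reads
#'
#' For each fragment the sequenced template strand is taken from the
#' fragment record. Every cytosine on that template is replaced by T with
#' the preset's per-state probability (direct conversion: the modified base
#' is the one that changes). On a bottom-strand template this manifests as
#' G read as A in reference-forward orientation. Conversion happens once
#' per fragment (before amplification); a configurable fraction of
#' fragments is then re-emitted to simulate PCR duplicates, and an
#' independent per-base substitution error is applied to every read copy.
#' Reads follow standard FR orientation: R1 reports the converted template
#' strand, R2 its complement.
#'
#' Read names encode the truth so the pipeline is testable without an
#' aligner: `<frag>.<copy>|<i5>+<i7>|<well>|<contig>:<start0>-<end0>:<template>`.
#'
#' @param frags Fragment tibble from [tagment()].
#' @param ref The `scm_reference` the fragments refer to.
#' @param truth Truth tibble (`contig`, `pos0`, `strand`, `state`);
#'   positions absent from it are unmodified.
#' @param preset An `scm_preset` (see [load_preset()]).
#' @param read_len Read length (default 120 bp); fragments shorter than
#'   this yield truncated reads.
#' @param dup_frac Fraction of fragments re-emitted once as PCR duplicates
#'   (default 0).
#' @param seed Integer seed.
#' @return Tibble of class `scm_reads`, one row per read, with `qname`,
#'   `mate` (`R1`/`R2`), `cell`, `i5`, `i7`, `contig`, `pos0`, `mapq`,
#'   `cigar`, `orientation` (`forward`/`reverse`), `proper`, `dup`
#'   (all `FALSE`; flags are set by [mark_duplicates()]), `seq`
#'   (reference-forward orientation, as in SAM), and `true_template`.
#' @export
convert_and_sequence <- function(frags, ref, truth, preset, read_len = 120L,
                                 dup_frac = 0, seed = 1) {
  stopifnot(inherits(ref, "scm_reference"), inherits(preset, "scm_preset"))
  assert_unit_interval(dup_frac, "dup_frac", open_right = TRUE)
  read_len <- as.integer(read_len)
  state_maps <- truth_state_maps(ref, truth)

  with_seed(seed, {
    n <- nrow(frags)
    converted <- character(n)
    n_short <- 0L
    for (i in seq_len(n)) {
      fr <- frags[i, ]
      sq <- substr(ref$contigs[[fr$contig]], fr$start0 + 1, fr$end0)
      ch <- seq_chars(sq)
      if (fr$template == "top") {
        idx <- which(ch == "C"); sm <- state_maps[[fr$contig]]$plus; to <- "T"
      } else {
        idx <- which(ch == "G"); sm <- state_maps[[fr$contig]]$minus; to <- "A"
      }
      if (length(idx) > 0) {
        st <- sm[fr$start0 + idx]          # state code at each template cytosine
        conv <- runif(length(idx)) < preset_prob(preset, st)
        ch[idx[conv]] <- to
      }
      converted[i] <- paste(ch, collapse = "")
      if (nchar(sq) < read_len) n_short <- n_short + 1L
    }
    if (n_short > 0) {
      inform(sprintf("%d fragment(s) shorter than read_len; reads truncated to insert", n_short))
    }

    # PCR duplication: re-emit a fraction of converted fragments once more.
    copies <- rep(1L, n)
    if (dup_frac > 0) copies <- copies + (runif(n) < dup_frac)
    src <- rep(seq_len(n), copies)
    copy_no <- unlist(lapply(copies, seq_len), use.names = FALSE)

    L <- nchar(converted)[src]
    len1 <- pmin(read_len, L)
    head_seq <- substr(converted[src], 1, len1)
    tail_seq <- substr(converted[src], L - len1 + 1, L)
    is_top <- frags$template[src] == "top"

    qname <- sprintf("%s.%d|%s+%s|%s|%s:%d-%d:%s",
                     frags$frag_id[src], copy_no, frags$i5[src],
                     frags$i7[src], frags$cell[src], frags$contig[src],
                     frags$start0[src], frags$end0[src], frags$template[src])

    reads <- tibble(
      qname = rep(qname, 2),
      mate = rep(c("R1", "R2"), each = length(src)),
      cell = rep(frags$cell[src], 2),
      i5 = rep(frags$i5[src], 2),
      i7 = rep(frags$i7[src], 2),
      contig = rep(frags$contig[src], 2),
      pos0 = c(if_else(is_top, frags$start0[src], frags$end0[src] - len1),
               if_else(is_top, frags$end0[src] - len1, frags$start0[src])),
      mapq = 60L,
      cigar = rep(paste0(len1, "M"), 2),
      orientation = c(if_else(is_top, "forward", "reverse"),
                      if_else(is_top, "reverse", "forward")),
      proper = TRUE,
      dup = FALSE,
      seq = c(if_else(is_top, head_seq, tail_seq),
              if_else(is_top, tail_seq, head_seq)),
      true_template = rep(frags$template[src], 2)
    )
    if (preset$seq_error > 0) {
      reads$seq <- add_seq_errors(reads$seq, preset$seq_error)
    }
    structure(arrange(reads, .data$qname, .data$mate), class = c("scm_reads", class(reads)))
  })
}

# Integer state codes (0 uC, 1 mC, 2 hmC) per contig position and strand;
# cytosines absent from the truth are unmodified.
truth_state_maps <- function(ref, truth) {
  code <- c(uC = 0L, mC = 1L, hmC = 2L)
  maps <- lapply(ref$contigs, function(s) {
    L <- nchar(s)
    list(plus = integer(L), minus = integer(L))
  })
  if (!is.null(truth) && nrow(truth) > 0) {
    bad <- setdiff(unique(truth$contig), names(maps))
    if (length(bad) > 0) {
      abort(sprintf("truth references unknown contig(s): %s",
                    paste(bad, collapse = ", ")))
    }
    for (ct in unique(truth$contig)) {
      tt <- truth[truth$contig == ct, ]
      plus <- tt$strand == "+"
      maps[[ct]]$plus[tt$pos0[plus] + 1L] <- code[tt$state[plus]]
      maps[[ct]]$minus[tt$pos0[!plus] + 1L] <- code[tt$state[!plus]]
    }
  }
  maps
}

# Uniform substitution error over the three alternative bases.
add_seq_errors <- function(seqs, rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(runif(total) < rate)
  if (length(hit) == 0) return(seqs)
  read_of <- findInterval(hit - 1L, cumsum(c(0, lens)), rightmost.closed = FALSE)
  offset <- hit - cumsum(c(0, lens))[read_of]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hit)) {
    i <- read_of[k]; j <- offset[k]
    old <- substr(seqs[i], j, j)
    alt <- setdiff(bases, old)
    substr(seqs[i], j, j) <- sample(alt, 1)
  }
  seqs
}
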