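#' Simulate a multi-contig reference genome
#'
#' Draws each base independently with the requested GC content and indexes
#' every cytosine in CpG context on both strands. The returned object is the
#' coordinate frame for the whole pipeline: the simulator, the caller and the
#' quantification steps all interpret positions against it. Coordinates are
#' 0-based half-open throughout; the strand of a CpG entry is the strand of
#' the cytosine (the top-strand C at `pos0` is paired with the bottom-strand
#' C at the reference G at `pos0 + 1`).
#'
#' @param n_contigs Number of genomic contigs.
#' @param lengths Integer vector of contig lengths (recycled to `n_contigs`).
#' @param gc_fraction Target GC content in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same reference.
#' @param contig_names Optional contig names (default `chr1`, `chr2`, ...).
#' @return An object of class `scm_reference`: a list with `contigs` (named
#'   character vector of uppercase sequences), `spikein_class` (named factor
#'   of `genomic`/`mC_spikein`/`uC_spikein`/`hmC_spikein`) and `cpg_index`
#'   (tibble with columns `contig`, `pos0`, `strand`).
#' @examples
#' ref <- make_reference(1, 1000, 0.5, seed = 7)
#' head(ref$cpg_index)
#' @export
make_reference <- function(n_contigs, lengths, gc_fraction = 0.5, seed = 1,
                           contig_names = NULL) {
  stopifnot(n_contigs >= 1)
  lengths <- rep_len(as.integer(lengths), n_contigs)
  if (any(lengths <= 0)) abort("contig lengths must be positive")
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    abort("`gc_fraction` must lie strictly between 0 and 1")
  }
  contig_names <- contig_names %||% paste0("chr", seq_len(n_contigs))
  if (anyDuplicated(contig_names)) abort("contig names must be unique")

  contigs <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(contigs) <- contig_names

  new_reference(contigs, setNames(rep("genomic", n_contigs), contig_names))
}

# Constructor shared by make_reference() and add_spikeins().
new_reference <- function(contigs, spikein_class) {
  structure(
    list(contigs = contigs,
         spikein_class = spikein_class,
         cpg_index = cpg_index(contigs)),
    class = "scm_reference"
  )
}

#' @export
print.scm_reference <- function(x, ...) {
  cat(sprintf("<scm_reference> %d contig(s), %s bp, %d CpG cytosines\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              nrow(x$cpg_index)))
  cls <- table(x$spikein_class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Index all CpG cytosines of a set of contigs
#'
#' Finds every CG dinucleotide with [Biostrings::vmatchPattern()] and reports
#' both cytosines: the top-strand C at the match start and the bottom-strand
#' C (a reference G) at the following position.
#'
#' @param contigs Named character vector of sequences.
#' @return Tibble with `contig`, `pos0` (0-based position of the cytosine on
#'   the reference top strand), `strand` (`+` or `-`), sorted by position.
#' @export
cpg_index <- function(contigs) {
  hits <- Biostrings::vmatchPattern("CG", Biostrings::DNAStringSet(contigs))
  per_contig <- purrr::map2(names(contigs), as.list(hits), function(nm, ir) {
    s <- IRanges::start(ir)          # 1-based start of each CG
    tibble(contig = rep(nm, 2 * length(s)),
           pos0 = c(s - 1L, s),
           strand = rep(c("+", "-"), each = length(s)))
  })
  bind_rows(per_contig) |> arrange(.data$contig, .data$pos0, .data$strand)
}

# Names used for the three control contigs.
SPIKEIN_CONTIGS <- c(mC_spikein = "spike_mC", uC_spikein = "spike_uC",
                     hmC_spikein = "spike_hmC")

#' Append spike-in control contigs and their truth states
#'
#' Adds the three control contigs the chemistry estimators rely on: a fully
#' CpG-methylated 2-kb contig (lambda-like in role: every CpG cytosine is
#' 5mC), a fully unmodified 2-kb contig, and a short oligo-like contig
#' carrying 5hmC at declared cytosine positions only. The controls are
#' random sequence; only their known modification states matter.
#'
#' @param ref An `scm_reference`.
#' @param hmC_positions 0-based positions of 5hmC cytosines on the hmC
#'   contig. Positions at a reference C are taken on the top strand, at a
#'   reference G on the bottom strand; anything else is an error. `NULL`
#'   (default) marks every CpG cytosine of the contig; `integer(0)` declares
#'   none.
#' @param lengths Lengths of the mC, uC and hmC contigs.
#' @param gc_fraction GC content of the generated controls.
#' @param seed Integer seed for the control sequences.
#' @return A list with `ref` (the extended `scm_reference`) and `truth`
#'   (tibble `contig`, `pos0`, `strand`, `state` holding the spike-in truth;
#'   unmodified cytosines are implicit).
#' @export
add_spikeins <- function(ref, hmC_positions = NULL,
                         lengths = c(mC = 2000L, uC = 2000L, hmC = 200L),
                         gc_fraction = 0.5, seed = 99) {
  stopifnot(inherits(ref, "scm_reference"))
  if (any(SPIKEIN_CONTIGS %in% names(ref$contigs))) {
    abort("reference already contains spike-in contigs")
  }
  if (lengths[["hmC"]] < 100) abort("hmC spike-in contig must be >= 100 bp")
  spikes <- with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    vapply(as.integer(lengths[c("mC", "uC", "hmC")]), function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(spikes) <- unname(SPIKEIN_CONTIGS)

  contigs <- c(ref$contigs, spikes)
  classes <- c(ref$spikein_class,
               setNames(names(SPIKEIN_CONTIGS), unname(SPIKEIN_CONTIGS)))
  out <- new_reference(contigs, classes)

  # mC control: every CpG cytosine on both strands carries 5mC.
  mC_truth <- out$cpg_index |>
    filter(.data$contig == SPIKEIN_CONTIGS[["mC_spikein"]]) |>
    mutate(state = "mC")

  hmC_truth <- hmc_spikein_truth(spikes[[SPIKEIN_CONTIGS[["hmC_spikein"]]]],
                                 out, hmC_positions)
  list(ref = out, truth = bind_rows(mC_truth, hmC_truth))
}

hmc_spikein_truth <- function(seq, ref, hmC_positions) {
  contig <- SPIKEIN_CONTIGS[["hmC_spikein"]]
  if (is.null(hmC_positions)) {
    return(ref$cpg_index |>
             filter(.data$contig == !!contig) |>
             mutate(state = "hmC"))
  }
  hmC_positions <- as.integer(hmC_positions)
  if (length(hmC_positions) == 0) {
    return(tibble(contig = character(), pos0 = integer(),
                  strand = character(), state = character()))
  }
  if (any(hmC_positions < 0 | hmC_positions >= nchar(seq))) {
    abort("hmC positions fall outside the hmC spike-in contig")
  }
  base <- substring(seq, hmC_positions + 1, hmC_positions + 1)
  if (any(!base %in% c("C", "G"))) {
    abort(sprintf("hmC positions must be cytosines (C or G in the reference); offending pos0: %s",
                  paste(hmC_positions[!base %in% c("C", "G")], collapse = ", ")))
  }
  tibble(contig = contig, pos0 = hmC_positions,
         strand = if_else(base == "C", "+", "-"), state = "hmC")
}

#' Write reference contigs as FASTA
#'
#' @param ref An `scm_reference`.
#' @param path Output FASTA path (60-column wrapped).
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file as an `scm_reference`
#'
#' Contigs named like the shipped spike-in controls are classified as such;
#' everything else is genomic.
#'
#' @param path FASTA path.
#' @return An `scm_reference`.
#' @export
read_ref_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  contigs <- setNames(toupper(as.character(ss)),
                      sub("\\s.*$", "", names(ss)))
  cls <- setNames(rep("genomic", length(contigs)), names(contigs))
  for (k in names(SPIKEIN_CONTIGS)) {
    cls[names(cls) == SPIKEIN_CONTIGS[[k]]] <- k
  }
  new_reference(contigs, cls)
}
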