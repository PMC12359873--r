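# Shared simulated fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# A mid-sized end-to-end simulation reused by caller/qc/quant tests.
sim_fixture <- function() {
  if (!is.null(.fx$sim)) return(.fx$sim)
  ref0 <- make_reference(2, c(60000, 40000), 0.5, seed = 7)
  sp <- add_spikeins(ref0, seed = 11)
  ref <- sp$ref
  genes <- make_genes(ref, 10, c(3000, 8000), seed = 3)
  truth <- assign_methylome(ref, methylome_profile("somatic"), genes,
                            seed = 5, spikein_truth = sp$truth)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:6, ], 500, c(150, 400),
                   spikein_fraction = 0.15, seed = 9)
  reads <- convert_and_sequence(frags, ref, truth, load_preset("sctaps"),
                                seed = 13)
  reads <- mark_duplicates(reads)
  calls <- call_sites(reads, ref)
  .fx$sim <- list(ref = ref, genes = genes, truth = truth, bc = bc,
                  frags = frags, reads = reads, calls = calls,
                  merged = merge_cpg_strands(calls))
  .fx$sim
}

# Independent brute-force pileup: walks every read string against the
# reference with plain per-read loops and base-R aggregation. Supports the
# all-match CIGARs the simulator emits.
brute_force_calls <- function(reads, ref, min_mapq = 10, end_trim = 10,
                              contexts = "CG", group_by = "cell") {
  reads <- reads[!reads$dup & reads$mapq >= min_mapq, ]
  stopifnot(all(grepl("^[0-9]+M$", reads$cigar)))
  refchars <- lapply(ref$contigs, function(s) strsplit(s, "")[[1]])
  # template rule restated from first principles
  template <- ifelse((reads$mate == "R1") == (reads$orientation == "forward"),
                     "top", "bottom")
  rows <- list()
  for (qn in unique(reads$qname)) {
    pair <- reads[reads$qname == qn, ]
    seen <- character(0)   # positions already taken by R1
    for (m in c("R1", "R2")) {
      rd <- pair[pair$mate == m, ]
      if (nrow(rd) == 0) next
      L <- nchar(rd$seq)
      qidx <- seq_len(L)
      qidx <- qidx[qidx > end_trim & qidx <= L - end_trim]
      rc <- refchars[[rd$contig]]
      for (q in qidx) {
        rpos1 <- rd$pos0 + q
        key <- as.character(rpos1)
        if (key %in% seen) next
        seen <- c(seen, key)
        rb <- rc[rpos1]
        tpl <- template[reads$qname == qn & reads$mate == m][1]
        if (tpl == "top" && rb == "C") {
          strand <- "+"
          ctx <- if (rpos1 < length(rc) && rc[rpos1 + 1] == "G") "CG" else "CH"
          b <- substr(rd$seq, q, q)
          cls <- if (b == "T") "mod" else if (b == "C") "unmod" else "other"
        } else if (tpl == "bottom" && rb == "G") {
          strand <- "-"
          ctx <- if (rpos1 > 1 && rc[rpos1 - 1] == "C") "CG" else "CH"
          b <- substr(rd$seq, q, q)
          cls <- if (b == "A") "mod" else if (b == "G") "unmod" else "other"
        } else {
          next
        }
        if (!ctx %in% contexts) next
        cell <- if (group_by == "pooled") "pooled" else rd$cell
        rows[[length(rows) + 1]] <- data.frame(
          cell = cell, contig = rd$contig, pos0 = rpos1 - 1L,
          strand = strand, context = ctx, class = cls)
      }
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(df))) ~
                            cell + contig + pos0 + strand + context + class,
                          data = df, FUN = sum)
  wide <- stats::reshape(agg, idvar = c("cell", "contig", "pos0", "strand",
                                        "context"),
                         timevar = "class", direction = "wide")
  for (col in c("n.mod", "n.unmod", "n.other")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
    wide[[col]][is.na(wide[[col]])] <- 0
  }
  out <- tibble::tibble(
    cell = wide$cell, contig = wide$contig, pos0 = as.integer(wide$pos0),
    strand = wide$strand, context = wide$context,
    n_mod = as.integer(wide$n.mod), n_unmod = as.integer(wide$n.unmod),
    n_other = as.integer(wide$n.other))
  out$level <- ifelse(out$n_mod + out$n_unmod > 0,
                      out$n_mod / (out$n_mod + out$n_unmod), NA_real_)
  out[order(out$contig, out$pos0, out$strand, out$cell), ]
}

# Naive CpG scan: character-by-character, independent of cpg_index().
naive_cpg_scan <- function(contigs) {
  out <- list()
  for (nm in names(contigs)) {
    ch <- strsplit(contigs[[nm]], "")[[1]]
    for (i in seq_len(length(ch) - 1)) {
      if (ch[i] == "C" && ch[i + 1] == "G") {
        out[[length(out) + 1]] <- data.frame(contig = nm, pos0 = i - 1L,
                                             strand = "+")
        out[[length(out) + 1]] <- data.frame(contig = nm, pos0 = i,
                                             strand = "-")
      }
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$pos0, df$strand), ]
  rownames(df) <- NULL
  df
}

# Exhaustive nearest-barcode assignment used as the demux oracle.
brute_force_demux <- function(obs_i5, obs_i7, barcodes, max_mismatch) {
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  i5 <- unique(barcodes$i5); i7 <- unique(barcodes$i7)
  vapply(seq_along(obs_i5), function(k) {
    d5 <- vapply(i5, ham, integer(1), a = obs_i5[k])
    d7 <- vapply(i7, ham, integer(1), a = obs_i7[k])
    h5 <- which(d5 <= max_mismatch); h7 <- which(d7 <= max_mismatch)
    if (length(h5) == 1 && length(h7) == 1) {
      barcodes$well[barcodes$i5 == i5[h5] & barcodes$i7 == i7[h7]][1]
    } else if (length(h5) == 0 || length(h7) == 0) {
      "unassigned"
    } else {
      "ambiguous"
    }
  }, character(1))
}

# Hand-built aligned reads for filter-fidelity tests.
manual_read <- function(qname, contig, pos0, seq, mate = "R1",
                        orientation = "forward", mapq = 60L, cell = "A01",
                        dup = FALSE, cigar = NULL) {
  tibble::tibble(qname = qname, mate = mate, cell = cell,
                 i5 = "AAAAAAAA", i7 = "CCCCCCCC", contig = contig,
                 pos0 = as.integer(pos0), mapq = mapq,
                 cigar = cigar %||% paste0(nchar(seq), "M"),
                 orientation = orientation, proper = TRUE, dup = dup,
                 seq = seq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
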