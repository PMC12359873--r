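test_that("presets carry the published chemistry rates and validate input", {
  taps <- load_preset("sctaps")
  expect_equal(taps$p_read_T_given_mC, 0.966)
  expect_equal(taps$p_read_T_given_hmC, 0.850)
  expect_equal(taps$p_read_T_given_uC, 0.0019)
  caps <- load_preset("sccaps")
  expect_equal(caps$p_read_T_given_mC, 0.0025)
  expect_equal(caps$p_read_T_given_hmC, 0.930)
  expect_equal(caps$p_read_T_given_uC, 0.0038)
  # aliases resolve to the same presets
  expect_equal(load_preset("sctaps-paper")$p_read_T_given_hmC, 0.850)
  expect_error(load_preset("nope"), "available")
  expect_error(chemistry_preset("x", 1.2, 0.5, 0.1), "unit interval")
  # config file round trip, including validation
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("p_read_T_given_mC = 0.9", "p_read_T_given_hmC = 0.8",
               "p_read_T_given_uC = 0.001"), path)
  expect_equal(load_preset(path)$p_read_T_given_mC, 0.9)
  writeLines(c("p_read_T_given_mC = 1.2", "p_read_T_given_hmC = 0.8",
               "p_read_T_given_uC = 0.001"), path)
  expect_error(load_preset(path), "unit interval")
})

test_that("the plate layout gives 96 wells with distance-3 tag sets", {
  bc <- default_barcodes()
  expect_equal(nrow(bc), 96)
  expect_equal(anyDuplicated(paste(bc$i5, bc$i7)), 0)
  i5 <- unique(bc$i5); i7 <- unique(bc$i7)
  expect_equal(length(i5), 8)
  expect_equal(length(i7), 12)
  for (set in list(i5, i7)) {
    for (i in seq_along(set)[-1]) {
      expect_true(all(hamming(set[i], set[seq_len(i - 1)]) >= 3))
    }
  }
})

test_that("tagmentation counts, wells and spike-in fractions behave", {
  ref0 <- make_reference(1, 50000, 0.5, seed = 2)
  sp <- add_spikeins(ref0, seed = 3)
  bc <- default_barcodes()
  frags <- tagment(sp$ref, bc, 100, c(150, 400), spikein_fraction = 0,
                   seed = 5)
  expect_equal(nrow(frags), 9600)
  expect_true(all(frags$cell %in% bc$well))
  expect_true(all(!startsWith(frags$contig, "spike_")))
  expect_true(all(frags$end0 - frags$start0 >= 150 |
                    frags$end0 - frags$start0 ==
                      nchar(sp$ref$contigs)[frags$contig]))

  # binomial oracle on the spike-in share
  frags2 <- tagment(sp$ref, bc, 200, c(150, 400), spikein_fraction = 0.2,
                    seed = 6)
  n <- nrow(frags2)
  share <- mean(startsWith(frags2$contig, "spike_"))
  expect_lt(abs(share - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_error(tagment(sp$ref, bc[0, ], 10, seed = 1), "barcode")
  expect_error(tagment(ref0, bc, 10, spikein_fraction = 0.5, seed = 1),
               "no spike-in")
})

test_that("identity chemistry reproduces the reference verbatim", {
  ref <- make_reference(1, 5000, 0.5, seed = 31)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:2, ], 50, c(150, 300), spikein_fraction = 0,
                   seed = 32)
  empty_truth <- tibble::tibble(contig = character(), pos0 = integer(),
                                strand = character(), state = character())
  preset <- chemistry_preset("identity", 0, 0, 0, seq_error = 0)
  reads <- convert_and_sequence(frags, ref, empty_truth, preset, seed = 33)
  ok <- mapply(function(ct, p, sq) {
    substr(ref$contigs[[ct]], p + 1, p + nchar(sq)) == sq
  }, reads$contig, reads$pos0, reads$seq)
  expect_true(all(ok))
})

test_that("forced conversion turns every template CpG cytosine into T", {
  ref0 <- make_reference(1, 500, 0.5, seed = 41)
  sp <- add_spikeins(ref0, seed = 42)
  bc <- default_barcodes()
  frags <- tagment(sp$ref, bc[1:2, ], 100, c(150, 300),
                   spikein_fraction = 0.9, seed = 43)
  frags <- frags[frags$contig == "spike_mC", ]
  preset <- chemistry_preset("force", 1, 0, 0, seq_error = 0)
  reads <- convert_and_sequence(frags, sp$ref, sp$truth, preset, seed = 44)
  top <- reads[reads$true_template == "top", ]
  mC_pos <- sp$truth$pos0[sp$truth$contig == "spike_mC" &
                            sp$truth$strand == "+"]
  for (i in seq_len(min(nrow(top), 50))) {
    rd <- top[i, ]
    inside <- mC_pos[mC_pos >= rd$pos0 & mC_pos < rd$pos0 + nchar(rd$seq)]
    bases <- substring(rd$seq, inside - rd$pos0 + 1, inside - rd$pos0 + 1)
    expect_true(all(bases == "T"))
  }
})

test_that("observed conversion follows the preset binomially and independently", {
  ref0 <- make_reference(1, 500, 0.5, seed = 51)
  sp <- add_spikeins(ref0, seed = 52)
  bc <- default_barcodes()
  frags <- tagment(sp$ref, bc, 40, c(200, 500), spikein_fraction = 0.95,
                   seed = 53)
  preset <- load_preset("sctaps", seq_error = 0)
  reads <- convert_and_sequence(frags, sp$ref, sp$truth, preset, seed = 54)
  calls <- call_sites(reads, sp$ref, group_by = "pooled")
  mC_sites <- calls[calls$contig == "spike_mC", ]
  n <- sum(mC_sites$n_mod + mC_sites$n_unmod)
  expect_gt(n, 20000)
  p_hat <- sum(mC_sites$n_mod) / n
  p <- preset$p_read_T_given_mC
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))

  # independence across adjacent sites: conversion indicators uncorrelated
  reads_top <- reads[reads$true_template == "top" &
                       reads$contig == "spike_mC", ]
  pos <- sort(sp$truth$pos0[sp$truth$contig == "spike_mC" &
                              sp$truth$strand == "+"])
  pairs <- cbind(pos[-length(pos)], pos[-1])
  a <- c(); b <- c()
  for (i in seq_len(nrow(reads_top))) {
    rd <- reads_top[i, ]
    inside <- pairs[, 1] >= rd$pos0 + 10 &
      pairs[, 2] < rd$pos0 + nchar(rd$seq) - 10
    for (j in which(inside)) {
      a <- c(a, substr(rd$seq, pairs[j, 1] - rd$pos0 + 1,
                       pairs[j, 1] - rd$pos0 + 1) == "T")
      b <- c(b, substr(rd$seq, pairs[j, 2] - rd$pos0 + 1,
                       pairs[j, 2] - rd$pos0 + 1) == "T")
    }
    if (length(a) > 10000) break
  }
  expect_gt(length(a), 1000)
  expect_lt(abs(cor(a, b)), 0.05)
})

test_that("chemistry only touches template-strand cytosines", {
  ref <- make_reference(1, 4000, 0.5, seed = 61)
  genes <- make_genes(ref, 2, c(500, 1000), seed = 62)
  truth <- assign_methylome(ref, methylome_profile("somatic"), genes,
                            seed = 63)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:2, ], 80, c(150, 300), spikein_fraction = 0,
                   seed = 64)
  preset <- load_preset("sctaps", seq_error = 0)
  reads <- convert_and_sequence(frags, ref, truth, preset, seed = 65)
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    refseg <- substr(ref$contigs[[rd$contig]], rd$pos0 + 1,
                     rd$pos0 + nchar(rd$seq))
    rc <- strsplit(refseg, "")[[1]]
    oc <- strsplit(rd$seq, "")[[1]]
    diffs <- which(rc != oc)
    if (rd$true_template == "top") {
      expect_true(all(rc[diffs] == "C" & oc[diffs] == "T"))
    } else {
      expect_true(all(rc[diffs] == "G" & oc[diffs] == "A"))
    }
  }
})

test_that("FASTQ and SAM round trips preserve reads", {
  fx <- sim_fixture()
  sub <- fx$reads[fx$reads$qname %in% unique(fx$reads$qname)[1:200], ]
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sub, r1, r2)
  pairs <- read_fastq_pair(r1, r2)
  expect_equal(nrow(pairs), 200)
  expect_setequal(pairs$qname, unique(sub$qname))

  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sub, fx$ref, sam)
  back <- read_alignments(sam)
  expect_equal(nrow(back), nrow(sub))
  key <- function(df) paste(df$qname, df$mate)
  m <- match(key(sub), key(back))
  expect_false(anyNA(m))
  expect_equal(back$pos0[m], sub$pos0)
  expect_equal(back$seq[m], sub$seq)
  expect_equal(back$orientation[m], sub$orientation)
  expect_equal(back$cell[m], sub$cell)
  expect_true(all(back$proper))
})
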