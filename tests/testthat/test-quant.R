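test_that("region levels sum calls and apply the minimum-call filter", {
  calls <- tibble::tibble(
    cell = "A01", contig = "chr1", pos0 = c(10L, 20L, 200L),
    strand = "+", context = "CG",
    n_mod = c(2L, 1L, 1L), n_unmod = c(1L, 1L, 2L), n_other = 0L,
    level = c(2 / 3, 1 / 2, 1 / 3))
  regions <- tibble::tibble(region_id = c("rA", "rB"), contig = "chr1",
                            start0 = c(0L, 150L), end0 = c(100L, 300L))
  rl <- region_level(calls, regions, min_calls = 5)
  # (2 mod / 3 total) + (1 mod / 2 total) -> 3/5
  expect_equal(rl$level[rl$region_id == "rA"], 0.6)
  # rB has n_total = 3 < 5: present but missing level
  expect_equal(rl$n_total[rl$region_id == "rB"], 3L)
  expect_true(is.na(rl$level[rl$region_id == "rB"]))
  # n_total = 4 at min_calls = 5 is excluded; passes at min_calls = 4
  calls4 <- dplyr::mutate(calls, n_mod = c(2L, 1L, 1L),
                          n_unmod = c(1L, 0L, 2L))
  rl4 <- region_level(calls4, regions[1, ], min_calls = 5)
  expect_true(is.na(rl4$level))
  expect_false(is.na(region_level(calls4, regions[1, ], min_calls = 4)$level))
})

test_that("region levels equal a brute-force per-site interval scan", {
  fx <- sim_fixture()
  regions <- withr::with_seed(31, tibble::tibble(
    region_id = sprintf("r%03d", 1:100),
    contig = sample(c("chr1", "chr2"), 100, replace = TRUE),
    start0 = sample.int(30000, 100)))
  regions$end0 <- regions$start0 + sample.int(5000, 100) + 100L
  rl <- region_level(fx$merged, regions, min_calls = 1)
  # brute force: explicit loop over regions and sites
  for (i in withr::with_seed(32, sample.int(100, 15))) {
    rg <- regions[i, ]
    sub <- fx$merged[fx$merged$contig == rg$contig &
                       fx$merged$pos0 >= rg$start0 &
                       fx$merged$pos0 < rg$end0, ]
    for (cl in unique(sub$cell)) {
      ss <- sub[sub$cell == cl, ]
      got <- rl[rl$region_id == rg$region_id & rl$cell == cl, ]
      expect_equal(got$n_mod, sum(ss$n_mod))
      expect_equal(got$n_total, sum(ss$n_mod) + sum(ss$n_unmod))
    }
  }
})

test_that("pooling cells before or after aggregation is equivalent", {
  fx <- sim_fixture()
  regions <- tibble::tibble(region_id = "all", contig = "chr1",
                            start0 = 0L, end0 = 60000L)
  per_cell <- region_level(fx$merged, regions, min_calls = 1)
  pooled <- region_level(fx$merged, regions, min_calls = 1,
                         group_by = "pooled")
  expect_equal(sum(per_cell$n_mod), pooled$n_mod)
  expect_equal(sum(per_cell$n_total), pooled$n_total)
  # whole-contig region at min_calls 1 equals the global level
  chr1 <- fx$merged[fx$merged$contig == "chr1", ]
  expect_equal(pooled$level,
               sum(chr1$n_mod) / sum(chr1$n_mod + chr1$n_unmod))
})

test_that("binned tracks conserve counts and degenerate to global levels", {
  fx <- sim_fixture()
  bl <- bin_levels(fx$merged, 5000)
  expect_equal(sum(bl$n_mod), sum(fx$merged$n_mod))
  expect_equal(sum(bl$n_total), sum(fx$merged$n_mod + fx$merged$n_unmod))
  # one covered site per bin reproduces the site level
  one <- fx$merged[fx$merged$cell == fx$merged$cell[1], ][1, ]
  bl1 <- bin_levels(one, 1)
  expect_equal(bl1$level, one$level)
  # bin spanning the contig reproduces the global level
  chr1 <- fx$merged[fx$merged$contig == "chr1", ]
  blg <- bin_levels(chr1, 60000, group_by = "pooled")
  expect_equal(blg$level[blg$contig == "chr1"],
               sum(chr1$n_mod) / sum(chr1$n_mod + chr1$n_unmod))
  expect_error(bin_levels(fx$merged, 0), "positive")
})

test_that("metagene geometry, flat profiles and strand flips behave", {
  expect_equal(metagene_n_bins(), 1500L)
  expect_error(metagene(sim_fixture()$merged, sim_fixture()$genes,
                        flank = 1005, bin_size = 10), "divisible")

  # flat methylome: profile flat within sampling error
  ref <- make_reference(1, 120000, 0.5, seed = 141)
  genes <- make_genes(ref, 12, c(3000, 6000), seed = 142)
  truth <- assign_methylome(ref, list(global_mC = 0.5, global_hmC = 0,
                                      tss_dip_width = 0, tss_dip_depth = 0),
                            genes, seed = 143)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:4, ], 2000, c(150, 400), spikein_fraction = 0,
                   seed = 144)
  reads <- convert_and_sequence(frags, ref, truth,
                                chemistry_preset("half", 1, 1, 0, 0),
                                seed = 145)
  merged <- merge_cpg_strands(call_sites(reads, ref, group_by = "pooled"))
  # odd body-bin count: site centres never land on a bin boundary, so the
  # strand-flip reversal below is exact
  prof <- metagene(merged, genes, flank = 2000, body_length = 2200,
                   bin_size = 200)
  expect_true(stats::sd(prof$mean_level) < 0.1)
  expect_lt(abs(mean(prof$mean_level) - 0.5), 0.05)

  # strand flip: reversing every gene reverses the profile
  genes_flip <- dplyr::mutate(genes,
                              strand = ifelse(strand == "+", "-", "+"))
  prof_flip <- metagene(merged, genes_flip, flank = 2000,
                        body_length = 2200, bin_size = 200)
  expect_equal(prof$mean_level, rev(prof_flip$mean_level))
})

test_that("a simulated TSS dip places the profile minimum near the TSS", {
  ref <- make_reference(1, 150000, 0.5, seed = 151)
  genes <- make_genes(ref, 15, c(4000, 7000), seed = 152)
  truth <- assign_methylome(ref, list(global_mC = 0.7, global_hmC = 0,
                                      tss_dip_width = 2000,
                                      tss_dip_depth = 0.8),
                            genes, seed = 153)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:4, ], 2500, c(150, 400), spikein_fraction = 0,
                   seed = 154)
  reads <- convert_and_sequence(frags, ref, truth,
                                chemistry_preset("bin", 1, 1, 0, 0),
                                seed = 155)
  merged <- merge_cpg_strands(call_sites(reads, ref, group_by = "pooled"))
  prof <- metagene(merged, genes, flank = 4000, body_length = 4000,
                   bin_size = 100)
  min_pos <- prof$rel_pos[which.min(prof$mean_level)]
  expect_gte(min_pos, -2000)
  expect_lte(min_pos, 2000)
})

test_that("level correlation behaves at its fixed points", {
  a <- tibble::tibble(contig = "chr1", bin = 1:20,
                      level = seq(0.1, 0.9, length.out = 20))
  expect_equal(correlate_levels(a, a)$r, 1.0)
  b <- dplyr::mutate(a, level = mean(level) - (level - mean(level)))
  expect_equal(correlate_levels(a, b)$r, -1.0)
  expect_error(correlate_levels(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("merged single cells correlate with their pooled bulk run", {
  ref <- make_reference(1, 200000, 0.5, seed = 161)
  genes <- make_genes(ref, 10, c(4000, 8000), seed = 162)
  truth <- assign_methylome(ref, methylome_profile("somatic"), genes,
                            seed = 163)
  bc <- default_barcodes()
  frags <- tagment(ref, bc[1:12, ], 2000, c(150, 400),
                   spikein_fraction = 0, seed = 164)
  reads <- convert_and_sequence(frags, ref, truth,
                                load_preset("sctaps", seq_error = 0),
                                seed = 165)
  calls <- call_sites(reads, ref)
  merged <- merge_cpg_strands(calls)
  # "bulk": same counts pooled across cells; "merged single cells": the
  # per-cell tables aggregated into bins then averaged via pooling counts
  bulk_bins <- bin_levels(merged, 10000, min_calls = 20,
                          group_by = "pooled")
  cell_bins <- bin_levels(merged, 10000, min_calls = 5) |>
    dplyr::group_by(contig, bin, start0, end0) |>
    dplyr::summarise(level = mean(level, na.rm = TRUE), .groups = "drop")
  r <- correlate_levels(bulk_bins, cell_bins, by = c("contig", "bin"))
  expect_gt(r$r, 0.9)
})
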