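#' Place synthetic gene models on the genomic contigs
#'
#' Genes are uniformly placed intervals with random strand; overlap is
#' allowed. Intervals are 0-based half-open; for a `+` gene the TSS is
#' `start0` and the TES is `end0`, for a `-` gene the reverse.
#'
#' @param ref An `scm_reference`; genes are placed on `genomic` contigs only.
#' @param n_genes Number of genes.
#' @param length_range Length-2 integer vector of min/max gene length (bp).
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `contig`, `strand`, `start0`, `end0`.
#' @export
make_genes <- function(ref, n_genes, length_range = c(5000L, 20000L), seed = 1) {
  stopifnot(inherits(ref, "scm_reference"), n_genes >= 0)
  length_range <- as.integer(length_range)
  genomic <- names(ref$spikein_class)[ref$spikein_class == "genomic"]
  if (n_genes == 0) {
    return(tibble(gene_id = character(), contig = character(),
                  strand = character(), start0 = integer(), end0 = integer()))
  }
  if (length(genomic) == 0) abort("reference has no genomic contigs")
  clen <- nchar(ref$contigs[genomic])
  if (length_range[2] > max(clen)) {
    abort("`length_range` exceeds the longest genomic contig")
  }
  with_seed(seed, {
    contig <- sample(genomic, n_genes, replace = TRUE,
                     prob = as.numeric(clen))
    len <- pmin(sample(length_range[1]:length_range[2], n_genes,
                       replace = TRUE),
                nchar(ref$contigs[contig]))
    start0 <- vapply(seq_len(n_genes), function(i) {
      max_start <- nchar(ref$contigs[[contig[i]]]) - len[i]
      as.integer(floor(runif(1, 0, max_start + 1)))
    }, integer(1))
    tibble(gene_id = sprintf("gene%04d", seq_len(n_genes)),
           contig = contig,
           strand = sample(c("+", "-"), n_genes, replace = TRUE),
           start0 = start0,
           end0 = start0 + len)
  })
}

#' Write gene models as GTF
#'
#' Emits one `gene` feature line per model (1-based inclusive coordinates,
#' as GTF requires) with a `gene_id` attribute.
#'
#' @param genes Tibble as returned by [make_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  header <- "##gff-version 2"
  lines <- if (nrow(genes) == 0) character() else {
    sprintf('%s\tscmethpipe\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
            genes$contig, genes$start0 + 1L, genes$end0, genes$strand,
            genes$gene_id)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read gene models from GTF/GFF
#'
#' Imports via [rtracklayer::import()] and converts `gene` features (all
#' features when no `type` column is present) back to the package's 0-based
#' half-open tibble representation.
#'
#' @param path GTF or GFF path.
#' @return Tibble with `gene_id`, `contig`, `strand`, `start0`, `end0`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  empty_tbl <- tibble(gene_id = character(), contig = character(),
                      strand = character(), start0 = integer(),
                      end0 = integer())
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) return(empty_tbl)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), contig = character(),
                  strand = character(), start0 = integer(), end0 = integer()))
  }
  md <- as.data.frame(S4Vectors::mcols(gr))
  keep <- if ("type" %in% names(md)) as.character(md$type) == "gene" else TRUE
  gr <- gr[keep]
  md <- md[keep, , drop = FALSE]
  tibble(
    gene_id = as.character(md$gene_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr)
  ) |> arrange(.data$gene_id)
}
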