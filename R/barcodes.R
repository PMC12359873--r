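#' The 96-well Tn5 barcode layout
#'
#' Eight i5 tags (rows A-H) crossed with twelve i7 tags (columns 1-12) give
#' the 96 per-cell barcode combinations of one plate. Tags are 8-mers with
#' pairwise Hamming distance of at least 3 within each set, so one
#' substitution is always correctable and two substitutions never convert
#' one valid tag into another.
#'
#' @param n_i5,n_i7 Number of row/column tags (defaults 8 x 12).
#' @param tag_length Tag length in bases.
#' @param min_dist Minimum pairwise Hamming distance within each tag set.
#' @return Tibble with `well` (e.g. `"A01"`), `row`, `col`, `i5`, `i7`.
#' @examples
#' default_barcodes()
#' @export
default_barcodes <- function(n_i5 = 8, n_i7 = 12, tag_length = 8,
                             min_dist = 3) {
  i5 <- generate_tags(n_i5, tag_length, min_dist, seed = 1201)
  i7 <- generate_tags(n_i7, tag_length, min_dist, seed = 7077)
  grid <- expand.grid(row = seq_len(n_i5), col = seq_len(n_i7))
  tibble(
    well = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    row = grid$row, col = grid$col,
    i5 = i5[grid$row], i7 = i7[grid$col]
  ) |> arrange(.data$well)
}

# Greedy accumulation of random tags at the required minimum distance;
# deterministic for a given internal seed.
generate_tags <- function(n, len, min_dist, seed) {
  with_seed(seed, {
    tags <- character(0)
    tries <- 0
    while (length(tags) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
      if (all(hamming(cand, tags) >= min_dist)) tags <- c(tags, cand)
      tries <- tries + 1
      if (tries > 10000) abort("could not generate a tag set; relax constraints")
    }
    tags
  })
}

#' Hamming distance between a query and a set of equal-length strings
#'
#' @param x Single string.
#' @param set Character vector of strings of the same length as `x`.
#' @return Integer vector of distances.
#' @export
hamming <- function(x, set) {
  if (length(set) == 0) return(integer(0))
  xm <- strsplit(x, "")[[1]]
  vapply(strsplit(set, ""), function(s) sum(s != xm), integer(1))
}

#' Write / read a barcode table
#'
#' TSV with columns `well`, `i5`, `i7` (plus `row`/`col` if present).
#'
#' @param barcodes Barcode tibble.
#' @param path File path.
#' @export
write_barcodes <- function(barcodes, path) {
  utils::write.table(barcodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcodes
#' @export
read_barcodes <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
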