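#' Conversion chemistry presets
#'
#' A chemistry preset gives, for each cytosine state, the probability that
#' the base is read as T after conversion (on the bottom strand this shows
#' up as G read as A against the reference top strand). The two shipped
#' presets carry the measured single-cell conversion and false-positive
#' rates of the two direct-conversion chemistries:
#'
#' * `"sctaps"` — TET-assisted pyridine borane (single-cell TAPS): 5mCG
#'   96.6%, 5hmCG 85.0% converted; unmodified C false positives 0.19%.
#' * `"sccaps"` — chemical-assisted pyridine borane (single-cell CAPS+):
#'   5hmCG 93.0% converted; 5mCG 0.25% and unmodified C 0.38% false
#'   positives.
#'
#' @param name Preset name, or a YAML/TSV-free plain `key=value` config file
#'   path (one of `p_read_T_given_mC`, `p_read_T_given_hmC`,
#'   `p_read_T_given_uC`, `seq_error` per line).
#' @param seq_error Per-base substitution sequencing-error probability
#'   applied after conversion (overrides the preset/file value).
#' @return An object of class `scm_preset`.
#' @examples
#' load_preset("sctaps")$p_read_T_given_hmC  # 0.85
#' @export
load_preset <- function(name, seq_error = NULL) {
  known <- list(
    sctaps = chemistry_preset("sctaps", 0.966, 0.850, 0.0019, 0.001),
    sccaps = chemistry_preset("sccaps", 0.0025, 0.930, 0.0038, 0.001)
  )
  aliases <- c("sctaps-paper" = "sctaps", "sccaps-paper" = "sccaps")
  if (name %in% names(aliases)) name <- aliases[[name]]
  if (name %in% names(known)) {
    p <- known[[name]]
  } else if (file.exists(name)) {
    p <- read_preset_file(name)
  } else {
    abort(sprintf("unknown preset '%s'; available: %s (or a config file path)",
                  name, paste(names(known), collapse = ", ")))
  }
  if (!is.null(seq_error)) {
    assert_unit_interval(seq_error, "seq_error")
    p$seq_error <- seq_error
  }
  p
}

#' @rdname load_preset
#' @param p_read_T_given_mC,p_read_T_given_hmC,p_read_T_given_uC Per-state
#'   probabilities that the cytosine is read as converted.
#' @export
chemistry_preset <- function(name, p_read_T_given_mC, p_read_T_given_hmC,
                             p_read_T_given_uC, seq_error = 0.001) {
  for (nm in c("p_read_T_given_mC", "p_read_T_given_hmC",
               "p_read_T_given_uC", "seq_error")) {
    assert_unit_interval(get(nm), nm)
  }
  structure(list(name = name,
                 p_read_T_given_mC = p_read_T_given_mC,
                 p_read_T_given_hmC = p_read_T_given_hmC,
                 p_read_T_given_uC = p_read_T_given_uC,
                 seq_error = seq_error),
            class = "scm_preset")
}

read_preset_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- setNames(as.numeric(trimws(vapply(kv, `[`, "", 2))),
                   trimws(vapply(kv, `[`, "", 1)))
  chemistry_preset(
    name = tools::file_path_sans_ext(basename(path)),
    p_read_T_given_mC = vals[["p_read_T_given_mC"]],
    p_read_T_given_hmC = vals[["p_read_T_given_hmC"]],
    p_read_T_given_uC = vals[["p_read_T_given_uC"]],
    seq_error = if ("seq_error" %in% names(vals)) vals[["seq_error"]] else 0.001
  )
}

#' @export
print.scm_preset <- function(x, ...) {
  cat(sprintf("<scm_preset '%s'> P(T|mC)=%.4f P(T|hmC)=%.4f P(T|uC)=%.4f err=%.4g\n",
              x$name, x$p_read_T_given_mC, x$p_read_T_given_hmC,
              x$p_read_T_given_uC, x$seq_error))
  invisible(x)
}

# Conversion probability per truth state (uC/mC/hmC as integer codes 0/1/2).
preset_prob <- function(preset, state_code) {
  c(preset$p_read_T_given_uC, preset$p_read_T_given_mC,
    preset$p_read_T_given_hmC)[state_code + 1L]
}
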