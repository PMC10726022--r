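# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' @keywords internal
#' @noRd
.read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    check.names = FALSE, strip.white = TRUE)
}

# Missing-parent codes accepted in pedigree and data files.
#' @keywords internal
#' @noRd
.is_missing_id <- function(x) {
  is.na(x) | x == "" | x == "0" | toupper(x) == "NA"
}

#' Significance stars
#'
#' Two-tier/three-tier star convention used in the rendered tables:
#' `***` P<0.001, `**` P<0.01, `*` P<0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
sig_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

# clamp to [-1, 1], reporting whether clamping occurred
#' @keywords internal
#' @noRd
.clamp_cor <- function(r) {
  if (is.na(r)) return(r)
  if (r > 1 || r < -1) {
    message(sprintf("correlation %.6f clamped to [-1, 1]", r))
    r <- max(-1, min(1, r))
  }
  r
}
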