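#' Integer percent, rounding half away from zero
#'
#' Report `count / total` as an integer percentage using round-half-away-
#' from-zero (so 55.5 reports as 56), the convention used for the summary
#' tables written by [category_summary()].
#'
#' @param count Numerator count.
#' @param total Denominator count; must be positive.
#' @return Integer percent.
#' @examples
#' percent_round(998, 1786)  # 56
#' @export
percent_round <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# 20-letter amino-acid alphabet used throughout
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

assert_aa <- function(sequences, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequences)
  if (any(bad)) {
    stop(sprintf(
      "%s contains characters outside the 20-letter amino-acid alphabet: %s",
      what, paste(utils::head(sequences[bad], 3), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
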