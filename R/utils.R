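#' @keywords internal
"_PACKAGE"

# Call categories, in cascade order. Used as factor levels everywhere.
CALL_LEVELS <- c("COPY_NUMBER_LOSS", "NO_SNV_DATA", "NOT_EXPRESSED",
                 "BIALLELIC", "MONOALLELIC", "UNRESOLVED")

FEATURE_LEVELS <- c("GENE", "ISOFORM", "EXON")

AUTOSOMES <- paste0("chr", 1:22)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; summary percentages follow the
#' conventional half-away-from-zero rule so that e.g. 11.345 prints as 11.35.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, rounded to two decimals
#'
#' The formatting rule used for all percent-monoallelic style statistics:
#' \code{100 * n / total} rounded half away from zero to two decimal places.
#' Returns \code{NA} when \code{total} is zero (undefined proportion).
#'
#' @param n numerator count(s)
#' @param total denominator count(s)
#' @return numeric vector of percentages (2 dp), NA where total == 0
#' @export
pct_of <- function(n, total) {
  out <- ifelse(total > 0, round_half_away(100 * n / total, 2), NA_real_)
  as.numeric(out)
}

#' Write an internal table as TSV
#'
#' All pipeline outputs are tab-delimited with a header row, UTF-8, and '.'
#' for missing values, so that writing and re-reading round-trips exactly.
#'
#' @param x data.frame
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_mae_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by \code{write_mae_table}
#'
#' @param path input path
#' @return data.frame
#' @export
read_mae_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a tag.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 65521L)
}

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
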