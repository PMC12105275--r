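#' Read a gene-level copy-number table
#'
#' The DepMap-style input is a TSV with a \code{gene_id} column and one column
#' per sample. Two input scales are supported:
#' \describe{
#'   \item{\code{LOG2_PSEUDO1_RELATIVE}}{values \code{v = log2(cn/2 + 1)}
#'     relative to a diploid baseline; back-transformed as
#'     \code{cn_linear = 2 * (2^v - 1)}, so \code{v = 1} maps to 2 copies.
#'     This convention keeps the 1.5-copy loss threshold meaningful.}
#'   \item{\code{LINEAR_ABSOLUTE}}{values are already absolute copy numbers
#'     and pass through unchanged.}
#' }
#' Negative linear values after the transform are clamped to 0 with a
#' warning. \code{cn_discrete} is the nearest integer, rounding half away
#' from zero; the copy-loss rule in the classifier uses \code{cn_linear},
#' not the rounded value, so the 1.5 cutoff stays sharp.
#'
#' @param cn_path path to the TSV (column \code{gene_id}, then samples)
#' @param input_scale \code{"LOG2_PSEUDO1_RELATIVE"} (default) or
#'   \code{"LINEAR_ABSOLUTE"}
#' @return long data.frame: \code{gene_id}, \code{sample_id},
#'   \code{cn_linear}, \code{cn_discrete}
#' @export
read_copy_number <- function(cn_path,
                             input_scale = c("LOG2_PSEUDO1_RELATIVE",
                                             "LINEAR_ABSOLUTE")) {
  input_scale <- match.arg(input_scale)
  tab <- read_mae_table(cn_path)
  if (!"gene_id" %in% colnames(tab))
    stop("copy-number table must have a gene_id column: ", cn_path)
  samples <- setdiff(colnames(tab), "gene_id")
  if (!length(samples)) stop("copy-number table has no sample columns")
  long <- data.frame(
    gene_id = rep(tab$gene_id, times = length(samples)),
    sample_id = rep(samples, each = nrow(tab)),
    v = as.numeric(unlist(tab[samples], use.names = FALSE)),
    stringsAsFactors = FALSE)
  cn <- if (input_scale == "LOG2_PSEUDO1_RELATIVE") 2 * (2^long$v - 1)
        else long$v
  if (any(cn < 0, na.rm = TRUE)) {
    warning(sum(cn < 0, na.rm = TRUE),
            " negative copy-number value(s) clamped to 0")
    cn[cn < 0] <- 0
  }
  data.frame(gene_id = long$gene_id, sample_id = long$sample_id,
             cn_linear = cn,
             cn_discrete = as.integer(round_half_away(cn)),
             stringsAsFactors = FALSE)
}
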