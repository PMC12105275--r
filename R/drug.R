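#' Read a drug-response table onto the log10(IC50) scale
#'
#' Accepts a CSV or TSV with columns \code{agent}, \code{sample} and either
#' \code{ic50} (linear scale, transformed here) or \code{log_ic50} (already
#' log10). Each table carries a dataset label (\code{PRISM}, \code{GDSC1} or
#' \code{GDSC2}); agents screened in several datasets are always analysed
#' separately per dataset, never pooled. GDSC1 contains duplicate
#' (agent, sample) experiments; those rows are replaced by the mean of their
#' log10(IC50) values, so (agent, dataset, sample) is unique on output.
#' Duplicates in other datasets are an input error.
#'
#' @param path path to the table (delimiter sniffed from the extension:
#'   \code{.csv} comma, otherwise tab)
#' @param dataset one of \code{"PRISM"}, \code{"GDSC1"}, \code{"GDSC2"}
#' @return data.frame: \code{agent_id}, \code{dataset}, \code{sample_id},
#'   \code{log_ic50}
#' @export
read_drug_response <- function(path, dataset = c("PRISM", "GDSC1", "GDSC2")) {
  dataset <- match.arg(dataset)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("agent", "sample") %in% names(tab)))
    stop("drug table needs 'agent' and 'sample' columns: ", path)
  if ("log_ic50" %in% names(tab)) {
    lic <- as.numeric(tab$log_ic50)
  } else if ("ic50" %in% names(tab)) {
    ic <- as.numeric(tab$ic50)
    if (any(ic <= 0, na.rm = TRUE))
      stop("IC50 values on the linear scale must be positive: ", path)
    lic <- log10(ic)
  } else stop("drug table needs an 'ic50' or 'log_ic50' column: ", path)

  out <- data.frame(agent_id = as.character(tab$agent), dataset = dataset,
                    sample_id = as.character(tab$sample), log_ic50 = lic,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$log_ic50), , drop = FALSE]
  key <- paste(out$agent_id, out$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (dataset != "GDSC1")
      stop("duplicate (agent, sample) rows in ", dataset, " table: ", path)
    agg <- tapply(out$log_ic50, key, mean)
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out$log_ic50 <- as.numeric(agg[key[first]])
  }
  rownames(out) <- NULL
  out
}
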