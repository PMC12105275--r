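#' Read an htseq-count style exon count table
#'
#' One file per sample and assay: two tab-separated columns (exon_id, count),
#' no header. Counts are joined to the catalog's exons; exon ids absent from
#' the catalog are reported with a warning and skipped; catalog exons missing
#' from the file are imputed as count 0, so the result always covers every
#' catalog exon exactly once. htseq-count's trailing \code{__no_feature} style
#' summary rows (ids starting with "__") are ignored silently.
#'
#' @param counts_path path to the two-column table
#' @param catalog a \code{feature_catalog}
#' @return data.frame with columns \code{exon_id}, \code{count}
#' @export
read_exon_counts <- function(counts_path, catalog) {
  exon_ids <- names(catalog$exon_ranges)
  raw <- tryCatch(
    utils::read.table(counts_path, sep = "\t", header = FALSE,
                      col.names = c("exon_id", "count"),
                      colClasses = c("character", "numeric"),
                      quote = "", comment.char = ""),
    error = function(e) {
      # an empty file is a valid degenerate input: all exons count 0
      if (file.size(counts_path) == 0)
        data.frame(exon_id = character(), count = numeric())
      else stop("cannot parse counts file ", counts_path, ": ",
                conditionMessage(e))
    })
  raw <- raw[!startsWith(raw$exon_id, "__"), , drop = FALSE]
  if (any(raw$count < 0))
    stop("negative count in ", counts_path)
  if (any(raw$count != floor(raw$count)))
    stop("non-integer count in ", counts_path)
  if (anyDuplicated(raw$exon_id))
    stop("duplicate exon_id in ", counts_path, ": ",
         raw$exon_id[duplicated(raw$exon_id)][1])
  unknown <- setdiff(raw$exon_id, exon_ids)
  if (length(unknown)) {
    warning(length(unknown), " exon id(s) not in catalog skipped (e.g. ",
            unknown[1], ")")
    raw <- raw[raw$exon_id %in% exon_ids, , drop = FALSE]
  }
  count <- rep(0, length(exon_ids))
  names(count) <- exon_ids
  count[raw$exon_id] <- raw$count
  data.frame(exon_id = exon_ids, count = as.numeric(count),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate exon counts to log10 length-normalised feature expression
#'
#' For each feature at the requested level, expression is
#' \code{log10(sum of its exon counts / exonic_length)} with length in bp.
#' A gene or isoform sums each of its distinct exons once (shared exons are
#' not double-counted) and divides by the merged-union exonic length. A zero
#' count sum yields \code{-Inf}, a sentinel that is below any finite cutoff,
#' so zero-count features always fall on the "not expressed" side.
#'
#' @param exon_counts data.frame from \code{\link{read_exon_counts}}
#' @param catalog a \code{feature_catalog}
#' @param level one of \code{"GENE"}, \code{"ISOFORM"}, \code{"EXON"}
#' @return data.frame with columns \code{feature_id}, \code{expr}
#' @export
aggregate_expression <- function(exon_counts, catalog, level) {
  level <- match.arg(level, FEATURE_LEVELS)
  cnt <- stats::setNames(exon_counts$count, exon_counts$exon_id)
  feats <- catalog_features(catalog, level)
  em <- catalog$exon_map
  sums <- if (level == "EXON") {
    as.numeric(cnt[feats$feature_id])
  } else {
    key <- if (level == "GENE") em$gene_id else em$transcript_id
    pairs <- unique(data.frame(key = key, exon_id = em$exon_id,
                               stringsAsFactors = FALSE))
    agg <- tapply(cnt[pairs$exon_id], pairs$key, sum)
    as.numeric(agg[feats$feature_id])
  }
  sums[is.na(sums)] <- 0
  expr <- ifelse(sums > 0, log10(sums / feats$exonic_length), -Inf)
  data.frame(feature_id = feats$feature_id, expr = expr,
             stringsAsFactors = FALSE)
}
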