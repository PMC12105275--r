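#' Thresholds for the allelic-pattern classifier
#'
#' @param cn_loss_threshold copy-number loss rule: linear copies below this
#'   value mean at least one allelic copy is lost (default 1.5)
#' @param expr_cutoff log10 length-normalised RNA count at or above which a
#'   feature counts as expressed (default -0.5, the inflection point of the
#'   zero-het-SNV proportion curve; see
#'   \code{\link{expression_cutoff_curve}})
#' @param wes_cov_cutoff same scale applied to WES coverage; required both
#'   for a monoallelic call and for the RNA/WES discrepancy QC flag
#'   (default -0.5)
#' @return object of class \code{classifier_thresholds}
#' @export
classifier_thresholds <- function(cn_loss_threshold = 1.5,
                                  expr_cutoff = -0.5,
                                  wes_cov_cutoff = -0.5) {
  stopifnot(is.finite(cn_loss_threshold), is.finite(expr_cutoff),
            is.finite(wes_cov_cutoff))
  structure(list(cn_loss_threshold = cn_loss_threshold,
                 expr_cutoff = expr_cutoff,
                 wes_cov_cutoff = wes_cov_cutoff),
            class = "classifier_thresholds")
}

#' Classify allelic expression for feature x sample evidence
#'
#' The decision cascade, applied independently to every row (first matching
#' rule wins):
#' \enumerate{
#'   \item \code{cn_linear < cn_loss_threshold} — \code{COPY_NUMBER_LOSS}
#'     (gene-level copy number; loss of at least one allelic copy makes
#'     mono/biallelic inference meaningless);
#'   \item no heterozygous SNVs in either assay — \code{NO_SNV_DATA};
#'   \item \code{rna_expr < expr_cutoff} — \code{NOT_EXPRESSED};
#'   \item het SNVs present in both WES and RNA — \code{BIALLELIC} (more
#'     than one allele observed in the transcript);
#'   \item het SNVs in WES, none in RNA, and WES coverage at or above
#'     \code{wes_cov_cutoff} — \code{MONOALLELIC} (the genome is
#'     heterozygous but only one allele is seen expressed);
#'   \item otherwise — \code{UNRESOLVED}.
#' }
#' A missing (\code{NA}) copy number never triggers rule 1. Independently of
#' the cascade, \code{qc_discrepancy_flag} marks the suspicious pattern of
#' het SNVs present in RNA but absent in WES while both assays have adequate
#' coverage (possible sequencing error or RNA editing); such rows always
#' fall through to \code{UNRESOLVED}.
#'
#' @param evidence data.frame from \code{\link{build_evidence}} (columns
#'   rna_het_snv_count, wes_het_snv_count, rna_expr, wes_cov, cn_linear;
#'   \code{-Inf} sentinels allowed in the expression columns)
#' @param thresholds a \code{\link{classifier_thresholds}} object
#' @return the evidence rows' classifications: data.frame with
#'   \code{call} (factor over the six categories) and
#'   \code{qc_discrepancy_flag}
#' @export
classify_feature <- function(evidence, thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  cn <- evidence$cn_linear
  rh <- evidence$rna_het_snv_count
  wh <- evidence$wes_het_snv_count
  re <- evidence$rna_expr
  wc <- evidence$wes_cov

  call <- rep("UNRESOLVED", nrow(evidence))
  open <- rep(TRUE, nrow(evidence))

  take <- function(cond, label) {
    hit <- open & !is.na(cond) & cond
    call[hit] <<- label
    open[hit] <<- FALSE
  }
  take(cn < thresholds$cn_loss_threshold, "COPY_NUMBER_LOSS")
  take(wh == 0L & rh == 0L, "NO_SNV_DATA")
  take(re < thresholds$expr_cutoff, "NOT_EXPRESSED")
  take(wh > 0L & rh > 0L, "BIALLELIC")
  take(wh > 0L & rh == 0L & wc >= thresholds$wes_cov_cutoff, "MONOALLELIC")

  # set independently of the cascade; outside copy-loss such rows always
  # fall through to UNRESOLVED
  qc <- rh > 0L & wh == 0L & re >= thresholds$expr_cutoff &
    wc >= thresholds$wes_cov_cutoff

  data.frame(call = factor(call, levels = CALL_LEVELS),
             qc_discrepancy_flag = qc)
}

#' Build the full allelic-call matrix for a cohort
#'
#' Applies \code{\link{classify_feature}} to every feature x sample pair at
#' one level. Classification is strictly per-sample: no information crosses
#' samples, so permuting or subsetting samples never changes any call.
#' Pairs with no evidence row are called \code{UNRESOLVED} with a warning.
#' The catalog's multi-chromosome flag is copied onto every call of the
#' affected features.
#'
#' @param evidence data.frame from \code{\link{build_evidence}}
#' @param catalog a \code{feature_catalog}
#' @param thresholds a \code{\link{classifier_thresholds}} object
#' @param level \code{"GENE"}, \code{"ISOFORM"} or \code{"EXON"}
#' @param samples sample ids to cover; default: those present in
#'   \code{evidence}
#' @return object of class \code{allelic_calls}: a data.frame with
#'   feature_id, level, sample_id, call, qc_discrepancy_flag,
#'   multi_chromosome_flag
#' @export
classify_matrix <- function(evidence, catalog,
                            thresholds = classifier_thresholds(),
                            level = c("GENE", "ISOFORM", "EXON"),
                            samples = unique(evidence$sample_id)) {
  level <- match.arg(level)
  feats <- catalog_features(catalog, level)
  want <- expand.grid(feature_id = feats$feature_id, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_w <- paste(want$feature_id, want$sample_id, sep = "\r")
  key_e <- paste(evidence$feature_id, evidence$sample_id, sep = "\r")
  m <- match(key_w, key_e)
  if (anyNA(m))
    warning(sum(is.na(m)),
            " feature x sample pair(s) without evidence called UNRESOLVED")
  ev <- evidence[ifelse(is.na(m), 1L, m), , drop = FALSE]
  cls <- classify_feature(ev, thresholds)
  cls$call[is.na(m)] <- "UNRESOLVED"
  cls$qc_discrepancy_flag[is.na(m)] <- FALSE

  out <- data.frame(
    feature_id = want$feature_id,
    level = level,
    sample_id = want$sample_id,
    call = cls$call,
    qc_discrepancy_flag = cls$qc_discrepancy_flag,
    multi_chromosome_flag = feats$multi_chromosome[
      match(want$feature_id, feats$feature_id)],
    stringsAsFactors = FALSE)
  structure(out, class = c("allelic_calls", "data.frame"),
            level = level, thresholds = thresholds)
}

#' @export
print.allelic_calls <- function(x, ...) {
  cat("allelic_calls:", length(unique(x$feature_id)), attr(x, "level"),
      "feature(s) x", length(unique(x$sample_id)), "sample(s)\n")
  print(table(x$call))
  invisible(x)
}

#' @export
summary.allelic_calls <- function(object, ...) {
  tab <- table(object$call)
  info <- sum(tab[c("MONOALLELIC", "BIALLELIC")])
  cat("Calls by category:\n")
  print(tab)
  cat("QC discrepancy flags:", sum(object$qc_discrepancy_flag), "\n")
  cat("Multi-chromosome feature calls:", sum(object$multi_chromosome_flag),
      "\n")
  if (info > 0)
    cat("% monoallelic among informative calls:",
        pct_of(tab[["MONOALLELIC"]], info), "\n")
  invisible(tab)
}

#' Diagnostic curve behind the expression cutoff
#'
#' Bins features by finite log10 length-normalised expression and computes,
#' per bin, the proportion of feature x sample observations with zero
#' detected heterozygous SNVs, plus a LOESS smooth of that proportion
#' against the bin midpoint. The inflection of this curve is what motivates
#' the default expression cutoff of -0.5; the cutoff itself stays a
#' configuration choice. Rows with \code{-Inf} expression (zero counts)
#' carry no information about SNV detectability and are excluded.
#'
#' @param evidence data.frame from \code{\link{build_evidence}}
#' @param bin_width width of the expression bins (default 0.25)
#' @param span LOESS span (default 0.75)
#' @return data.frame: bin_mid, n, prop_zero_het, smoothed (NA when fewer
#'   than two bins have data, in which case raw proportions are returned
#'   unsmoothed)
#' @export
expression_cutoff_curve <- function(evidence, bin_width = 0.25, span = 0.75) {
  ok <- is.finite(evidence$rna_expr)
  e <- evidence$rna_expr[ok]
  z <- evidence$rna_het_snv_count[ok] == 0L
  if (!length(e)) stop("no finite expression values to bin")
  bin <- floor(e / bin_width)
  mid <- (as.numeric(names(table(bin))) + 0.5) * bin_width
  n <- as.integer(table(bin))
  prop <- as.numeric(tapply(z, bin, mean))
  out <- data.frame(bin_mid = mid, n = n, prop_zero_het = prop)
  out <- out[order(out$bin_mid), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) >= 2) {
    fit <- try(stats::loess(prop_zero_het ~ bin_mid, data = out, span = span,
                            weights = out$n), silent = TRUE)
    out$smoothed <- if (inherits(fit, "try-error")) NA_real_
                    else as.numeric(stats::predict(fit, out$bin_mid))
  } else {
    out$smoothed <- NA_real_
  }
  out
}
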