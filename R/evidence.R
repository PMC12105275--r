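#' Assemble per-feature, per-sample evidence for the classifier
#'
#' Joins the five evidence variables the decision cascade needs — RNA and WES
#' heterozygous-SNV counts, RNA expression, WES coverage (both on the log10
#' length-normalised scale) and the gene-level linear copy number — into one
#' long table with a row per feature x sample at the requested level. Copy
#' number is a gene-level quantity: isoforms and exons inherit the value of
#' their parent gene, so a copy-loss gene forces copy loss for all of its
#' features. A feature/sample missing from the copy-number table gets
#' \code{NA}, which the classifier treats as "no evidence of loss".
#'
#' @param catalog a \code{feature_catalog}
#' @param level \code{"GENE"}, \code{"ISOFORM"} or \code{"EXON"}
#' @param samples character vector of sample ids (defines row order)
#' @param rna_het,wes_het named lists (by sample) of \code{$het_counts}
#'   tables from \code{\link{read_het_snvs}}
#' @param rna_expr,wes_expr named lists (by sample) of expression tables from
#'   \code{\link{aggregate_expression}} at this level (WES coverage uses the
#'   same normalisation applied to WES read counts)
#' @param cn long copy-number table from \code{\link{read_copy_number}}
#' @return data.frame: feature_id, sample_id, rna_het_snv_count,
#'   wes_het_snv_count, rna_expr, wes_cov, cn_linear, cn_discrete
#' @export
build_evidence <- function(catalog, level, samples,
                           rna_het, wes_het, rna_expr, wes_expr, cn) {
  level <- match.arg(level, FEATURE_LEVELS)
  feats <- catalog_features(catalog, level)
  gene_of <- if (level == "GENE") feats$feature_id else feats$parent_id

  one <- function(s) {
    rh <- rna_het[[s]]; wh <- wes_het[[s]]
    rh <- rh[rh$level == level, ]
    wh <- wh[wh$level == level, ]
    cns <- cn[cn$sample_id == s, ]
    data.frame(
      feature_id = feats$feature_id,
      sample_id = s,
      rna_het_snv_count = int_lookup(rh$het_snv_count, rh$feature_id,
                                     feats$feature_id, 0L),
      wes_het_snv_count = int_lookup(wh$het_snv_count, wh$feature_id,
                                     feats$feature_id, 0L),
      rna_expr = num_lookup(rna_expr[[s]]$expr, rna_expr[[s]]$feature_id,
                            feats$feature_id, -Inf),
      wes_cov = num_lookup(wes_expr[[s]]$expr, wes_expr[[s]]$feature_id,
                           feats$feature_id, -Inf),
      cn_linear = num_lookup(cns$cn_linear, cns$gene_id, gene_of, NA_real_),
      cn_discrete = int_lookup(cns$cn_discrete, cns$gene_id, gene_of,
                               NA_integer_),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(samples, one))
  rownames(out) <- NULL
  out
}

int_lookup <- function(values, keys, want, default) {
  m <- match(want, keys)
  out <- values[m]
  out[is.na(m)] <- default
  as.integer(out)
}

num_lookup <- function(values, keys, want, default) {
  m <- match(want, keys)
  out <- values[m]
  out[is.na(m)] <- default
  as.numeric(out)
}
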