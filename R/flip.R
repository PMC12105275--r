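#' Combine per-sample SNV site records into one table
#'
#' @param sites_list named list (by sample id) of \code{$sites} tables from
#'   \code{\link{read_het_snvs}}; RNA and WES tables may be concatenated by
#'   calling this once per assay and rbinding, or by passing both per sample
#' @return data.frame with a \code{sample_id} column prepended
#' @export
bind_snv_sites <- function(sites_list) {
  out <- do.call(rbind, lapply(names(sites_list), function(s) {
    d <- sites_list[[s]]
    if (nrow(d) == 0) return(NULL)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), d)
  }))
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      het = logical(), assay = character())
  rownames(out) <- NULL
  out
}

# map SNV rows to the gene(s) whose exons they fall in; returns the input
# rows replicated per overlapping gene with a gene_id column
sites_to_genes <- function(site_df, catalog) {
  if (nrow(site_df) == 0)
    return(cbind(site_df, data.frame(gene_id = character())))
  gr <- GenomicRanges::GRanges(site_df$chrom,
                               IRanges::IRanges(site_df$pos, site_df$pos))
  ov <- GenomicRanges::findOverlaps(gr, catalog$exon_ranges)
  hit <- site_df[S4Vectors::queryHits(ov), , drop = FALSE]
  hit$exon_id <- names(catalog$exon_ranges)[S4Vectors::subjectHits(ov)]
  em <- unique(catalog$exon_map[, c("exon_id", "gene_id")])
  out <- merge(hit, em, by = "exon_id")
  out$exon_id <- NULL
  unique(out)
}

#' Extract per-SNV monoallelic base counts (the base-preference chain)
#'
#' Implements the four-step extraction behind the flip test:
#' \enumerate{
#'   \item capture, per sample, RNA-seq SNV calls expressing a single base
#'     (homozygous-looking RNA genotypes; the expressed base is the
#'     alternative base) and WES heterozygous SNV calls;
#'   \item keep only sites inside features called \code{MONOALLELIC} in that
#'     sample (gene-level calls by default);
#'   \item infer reference-base expression for a sample when WES shows a
#'     heterozygous SNV at the site but RNA recorded no alternative
#'     single-base call there (a monoallelic feature expressing the
#'     reference allele produces no RNA variant record);
#'   \item drop sites with no supporting WES heterozygous call in any
#'     sample — this removes RNA calls at sites that are homozygous
#'     everywhere, which express a single base biallelically.
#' }
#' At multi-allelic sites the most frequent alternative base across WES het
#' calls is taken as the site's alt base; samples expressing a different
#' alternative are tallied in \code{n_other} and not counted in
#' \code{n_ref}/\code{n_alt}.
#'
#' @param snv_table combined site table from \code{\link{bind_snv_sites}}
#'   containing both assays (column \code{assay} in \code{"RNA"},
#'   \code{"WES"})
#' @param calls an \code{allelic_calls} object (gene level)
#' @param catalog a \code{feature_catalog}
#' @param gene_set gene ids to analyse (e.g. imprinted + top-monoallelic
#'   lists); ids absent from the catalog are skipped with a warning
#' @return data.frame: snv_id (chrom:pos:ref:alt), gene_id, n_ref, n_alt,
#'   n_other; n_ref + n_alt is the number of informative samples
#' @export
extract_monoallelic_snvs <- function(snv_table, calls, catalog, gene_set) {
  known <- catalog$features$feature_id[catalog$features$level == "GENE"]
  absent <- setdiff(gene_set, known)
  if (length(absent))
    warning(length(absent), " gene id(s) not in catalog skipped (e.g. ",
            absent[1], ")")
  gene_set <- intersect(gene_set, known)

  mapped <- sites_to_genes(snv_table, catalog)
  mapped <- mapped[mapped$gene_id %in% gene_set, , drop = FALSE]

  # samples in which each gene is monoallelic
  mono <- calls[as.character(calls$call) == "MONOALLELIC", , drop = FALSE]
  mono_key <- paste(mono$feature_id, mono$sample_id, sep = "\r")
  mapped <- mapped[paste(mapped$gene_id, mapped$sample_id, sep = "\r") %in%
                     mono_key, , drop = FALSE]

  empty <- data.frame(snv_id = character(), gene_id = character(),
                      n_ref = integer(), n_alt = integer(),
                      n_other = integer())
  if (nrow(mapped) == 0) return(empty)

  wes_het <- mapped[mapped$assay == "WES" & mapped$het, , drop = FALSE]
  rna_hom <- mapped[mapped$assay == "RNA" & !mapped$het, , drop = FALSE]
  if (nrow(wes_het) == 0) return(empty)  # nothing has WES het support

  loc <- function(d) paste(d$chrom, d$pos, d$gene_id, sep = "\r")
  wes_het$loc <- loc(wes_het)
  rna_hom$loc <- loc(rna_hom)
  # step (d): site must have >= 1 WES het call across all samples
  rna_hom <- rna_hom[rna_hom$loc %in% wes_het$loc, , drop = FALSE]

  res <- lapply(split(wes_het, wes_het$loc), function(w) {
    l <- w$loc[1]
    ref <- w$ref[1]
    alt_site <- names(sort(table(w$alt), decreasing = TRUE))[1]
    r <- rna_hom[rna_hom$loc == l, , drop = FALSE]
    n_alt <- length(unique(r$sample_id[r$alt == alt_site]))
    n_other <- length(unique(r$sample_id[r$alt != alt_site]))
    # inferred reference expression: WES het, no RNA single-base alt call
    inf_ref <- setdiff(unique(w$sample_id), unique(r$sample_id))
    data.frame(snv_id = paste(w$chrom[1], w$pos[1], ref, alt_site, sep = ":"),
               gene_id = w$gene_id[1],
               n_ref = length(inf_ref), n_alt = n_alt, n_other = n_other,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$gene_id, out$snv_id), , drop = FALSE]
}

#' Exact two-sided binomial flip test
#'
#' Tests whether monoallelic expression across samples prefers the
#' reference or the alternative base, under the null that either allele is
#' expressed with probability 0.5. The two-sided p-value doubles the
#' smaller tail and is capped at 1; with a symmetric null this coincides
#' with the minimum-likelihood definition. Vectorised.
#'
#' @param n_ref,n_alt nonnegative integer counts of samples monoallelically
#'   expressing the reference / alternative base
#' @return p-value(s); \code{NA} where \code{n_ref + n_alt == 0}
#' @export
flip_test <- function(n_ref, n_alt) {
  stopifnot(all(n_ref >= 0), all(n_alt >= 0),
            all(n_ref == floor(n_ref)), all(n_alt == floor(n_alt)))
  n <- n_ref + n_alt
  k <- pmin(n_ref, n_alt)
  p <- ifelse(n == 0, NA_real_, pmin(1, 2 * stats::pbinom(k, n, 0.5)))
  # when both tails meet in the middle (n_ref == n_alt) everything is as
  # extreme as observed
  as.numeric(ifelse(n > 0 & n_ref == n_alt, 1, p))
}

#' Run flip tests over extracted SNV records
#'
#' SNVs monoallelically expressed in fewer than \code{min_cells} samples are
#' labelled untested (never significant) rather than dropped: below 6
#' informative samples even a fully one-sided split cannot reach p < 0.05
#' (p = 0.0625 at n = 5, 0.03125 at n = 6).
#'
#' @param records data.frame from \code{\link{extract_monoallelic_snvs}}
#' @param min_cells minimum informative samples to test (default 6)
#' @param alpha significance level on the raw p-value (default 0.05; no
#'   multiplicity correction is applied, matching how such SNV screens are
#'   conventionally reported)
#' @return records with \code{n}, \code{p_binomial}, \code{tested},
#'   \code{significant} columns appended
#' @export
run_flip_tests <- function(records, min_cells = 6, alpha = 0.05) {
  n <- records$n_ref + records$n_alt
  p <- flip_test(records$n_ref, records$n_alt)
  tested <- n >= min_cells
  out <- records
  out$n <- n
  out$p_binomial <- p
  out$tested <- tested
  out$significant <- tested & !is.na(p) & p < alpha
  out
}

#' Gene- and set-level summary of flip-test results
#'
#' Counts significant versus non-significant tested SNVs per gene, then
#' forms the 2 x 2 set-level table (gene set x significance) and tests
#' independence with both the Pearson chi-square (no continuity correction)
#' and Fisher's exact test. Genes without any tested SNV are excluded from
#' the set totals.
#'
#' @param results data.frame from \code{\link{run_flip_tests}}
#' @param gene_sets named character vector: gene_id -> set label (e.g.
#'   \code{"IMPRINTED"} or \code{"OTHER_MONOALLELIC"})
#' @return list: \code{$per_gene} (gene_id, set, n_tested, n_significant,
#'   n_nonsignificant), \code{$table} (2 x 2), \code{$chisq_p},
#'   \code{$fisher_p}
#' @export
gene_level_flip_summary <- function(results, gene_sets) {
  tested <- results[results$tested, , drop = FALSE]
  per_gene <- do.call(rbind, lapply(split(tested, tested$gene_id),
                                    function(d) {
    data.frame(gene_id = d$gene_id[1],
               set = unname(gene_sets[d$gene_id[1]]),
               n_tested = nrow(d),
               n_significant = sum(d$significant),
               n_nonsignificant = sum(!d$significant),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene))
    per_gene <- data.frame(gene_id = character(), set = character(),
                           n_tested = integer(), n_significant = integer(),
                           n_nonsignificant = integer())
  rownames(per_gene) <- NULL
  sets <- sort(unique(stats::na.omit(per_gene$set)))
  tab <- t(vapply(sets, function(s) {
    d <- per_gene[!is.na(per_gene$set) & per_gene$set == s, ]
    c(significant = sum(d$n_significant),
      nonsignificant = sum(d$n_nonsignificant))
  }, c(significant = 0, nonsignificant = 0)))
  chisq_p <- fisher_p <- NA_real_
  if (nrow(tab) == 2 && all(rowSums(tab) > 0)) {
    chisq_p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
    fisher_p <- stats::fisher.test(tab)$p.value
  }
  list(per_gene = per_gene, table = tab, chisq_p = chisq_p,
       fisher_p = fisher_p)
}
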