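#' Read per-sample SNV calls and count heterozygous exonic sites per feature
#'
#' Reads a single-sample VCF (one file per sample and assay, RNA-seq or WES)
#' and produces, for every catalog feature at every level, the number of
#' distinct heterozygous SNV sites falling inside its exons. Intronic sites
#' (inside a gene span but outside all exons) are never counted; a site
#' inside an exon shared by several isoforms is counted once for each isoform
#' and once for the gene. Only single-base substitutions are considered:
#' indels and multi-base records are ignored, and multi-allelic records
#' contribute their primary (first) single-base alternative. Sites on
#' non-autosomal contigs are skipped.
#'
#' Alongside the counts, the per-site record table needed by the
#' base-preference analysis is returned: chromosome, position, reference and
#' primary alternative base, and het/hom status of the genotype call.
#'
#' @param vcf_path path to a coordinate-sorted VCF 4.x with one sample column
#' @param assay \code{"RNA"} or \code{"WES"}; carried through to the output
#' @param catalog a \code{feature_catalog}
#' @return list with \code{$het_counts} (feature_id, level, het_snv_count for
#'   every catalog feature) and \code{$sites} (chrom, pos, ref, alt, het,
#'   assay; one row per retained SNV genotype call)
#' @export
read_het_snvs <- function(vcf_path, assay = c("RNA", "WES"), catalog) {
  assay <- match.arg(assay)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  feats <- catalog$features

  if (nrow(fix) == 0) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        het = logical(), assay = character())
    return(list(het_counts = zero_het_counts(feats), sites = sites))
  }

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  # sortedness: positions non-decreasing within contiguous chromosome blocks
  blocks <- rle(chrom)$values
  within_unsorted <- any(vapply(split(pos, factor(chrom, levels = unique(chrom))),
                                is.unsorted, logical(1)))
  if (anyDuplicated(blocks) || within_unsorted)
    stop("unsorted VCF: ", vcf_path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) < 1)
    stop("VCF has no genotype column: ", vcf_path)
  gt <- gt[, 1]

  ref <- as.character(fix[, "REF"])
  alt1 <- vapply(strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE),
                 function(a) if (length(a)) a[1] else NA_character_,
                 character(1))

  al <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)
  het <- vapply(al, function(a) {
    a <- a[a != "."]
    length(unique(a)) > 1L
  }, logical(1))
  called <- vapply(al, function(a) any(a != "." & !is.na(a)), logical(1))

  keep <- called & !is.na(ref) & !is.na(alt1) &
    nchar(ref) == 1L & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    chrom %in% AUTOSOMES
  sites <- data.frame(chrom = chrom[keep], pos = pos[keep],
                      ref = ref[keep], alt = alt1[keep], het = het[keep],
                      assay = assay, stringsAsFactors = FALSE)
  sites <- unique(sites)

  hs <- sites[sites$het, , drop = FALSE]
  counts <- count_sites_per_feature(hs, catalog)
  list(het_counts = counts, sites = sites)
}

zero_het_counts <- function(feats) {
  data.frame(feature_id = feats$feature_id, level = feats$level,
             het_snv_count = 0L, stringsAsFactors = FALSE)
}

# Count distinct (chrom, pos) sites per feature at all three levels via
# exon overlap; exonic restriction is implicit in the overlap with exons.
count_sites_per_feature <- function(site_df, catalog) {
  feats <- catalog$features
  out <- zero_het_counts(feats)
  if (nrow(site_df) == 0) return(out)
  site_key <- paste(site_df$chrom, site_df$pos, sep = ":")
  gr <- GenomicRanges::GRanges(site_df$chrom,
                               IRanges::IRanges(site_df$pos, site_df$pos))
  ov <- GenomicRanges::findOverlaps(gr, catalog$exon_ranges)
  if (length(ov) == 0) return(out)
  hit <- data.frame(
    site = site_key[S4Vectors::queryHits(ov)],
    exon_id = names(catalog$exon_ranges)[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE)
  em <- catalog$exon_map
  # expand over all transcripts carrying each exon
  expand <- merge(hit, em, by = "exon_id")
  tally <- function(pairs) {
    t <- table(unique(pairs)$feature_id)
    stats::setNames(as.integer(t), names(t))
  }
  cnt <- list(
    EXON    = tally(data.frame(feature_id = expand$exon_id,
                               site = expand$site)),
    ISOFORM = tally(data.frame(feature_id = expand$transcript_id,
                               site = expand$site)),
    GENE    = tally(data.frame(feature_id = expand$gene_id,
                               site = expand$site)))
  for (lv in names(cnt)) {
    sel <- out$level == lv
    m <- match(out$feature_id[sel], names(cnt[[lv]]))
    out$het_snv_count[sel] <- ifelse(is.na(m), 0L, as.integer(cnt[[lv]][m]))
  }
  out
}
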