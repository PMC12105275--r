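#' Read a GTF annotation into a feature catalog
#'
#' Builds the gene / isoform / exon hierarchy used by every downstream step.
#' Exon records are read from a GENCODE-style GTF (1-based, inclusive),
#' restricted to autosomes, and rolled up into three feature levels:
#' \describe{
#'   \item{GENE}{exonic length = length of the merged union of all exon
#'     intervals of the gene, so exons shared between isoforms are never
#'     double-counted;}
#'   \item{ISOFORM}{merged union of the transcript's exons;}
#'   \item{EXON}{its own length.}
#' }
#' Features whose exons map to more than one (autosomal) chromosome are kept
#' but flagged (\code{multi_chromosome}), since copy-number and allelic
#' inference is unreliable for them. Features entirely outside
#' \code{autosome_names} are dropped.
#'
#' @param gtf_path path to a GTF file with \code{gene_id}, \code{transcript_id}
#'   and \code{exon_id} attributes on exon records
#' @param autosome_names chromosomes retained (default \code{chr1}..\code{chr22})
#' @return an object of class \code{feature_catalog}: a list with
#'   \code{$features} (one row per feature: \code{feature_id}, \code{level},
#'   \code{parent_id}, \code{chromosomes} (comma-separated set), \code{start},
#'   \code{end}, \code{exonic_length}, \code{multi_chromosome}),
#'   \code{$exon_map} (exon_id / transcript_id / gene_id triples) and
#'   \code{$exon_ranges} (a \code{GRanges} of unique exons, names = exon_id)
#' @export
read_annotation <- function(gtf_path, autosome_names = AUTOSOMES) {
  if (!file.exists(gtf_path)) stop("annotation file not found: ", gtf_path)
  check_gtf_wellformed(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon records: ", gtf_path)

  md <- S4Vectors::mcols(ex)
  need <- c("gene_id", "transcript_id", "exon_id")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("GTF exon records lack required attribute(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(md$transcript_id) || any(md$transcript_id == ""))
    stop("exon record without a transcript parent in ", gtf_path)
  if (anyNA(md$gene_id) || anyNA(md$exon_id))
    stop("exon record with missing gene_id or exon_id in ", gtf_path)

  keep <- as.character(GenomicRanges::seqnames(ex)) %in% autosome_names
  ex <- ex[keep]
  if (length(ex) == 0L)
    stop("no exon records remain after restricting to autosomes")

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end   = GenomicRanges::end(ex),
    exon_id = as.character(ex$exon_id),
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    stringsAsFactors = FALSE)

  exon_map <- unique(df[, c("exon_id", "transcript_id", "gene_id")])

  exon_tbl <- unique(df[, c("exon_id", "chrom", "start", "end", "gene_id")])
  if (anyDuplicated(exon_tbl$exon_id)) {
    dup <- unique(exon_tbl$exon_id[duplicated(exon_tbl$exon_id)])
    stop("exon_id with conflicting coordinates or gene assignment: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }

  exon_ranges <- GenomicRanges::GRanges(
    seqnames = exon_tbl$chrom,
    ranges = IRanges::IRanges(exon_tbl$start, exon_tbl$end))
  names(exon_ranges) <- exon_tbl$exon_id

  roll <- function(ids, key) {
    # ids: grouping vector parallel to df rows; returns per-group summary
    sp <- split(seq_len(nrow(df)), ids)
    out <- lapply(names(sp), function(id) {
      i <- sp[[id]]
      chs <- sort(unique(df$chrom[i]))
      # union of the group's distinct exon intervals, per chromosome
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        seqnames = df$chrom[i],
        ranges = IRanges::IRanges(df$start[i], df$end[i])))
      data.frame(feature_id = id,
                 chromosomes = paste(chs, collapse = ","),
                 start = min(df$start[i]), end = max(df$end[i]),
                 exonic_length = sum(GenomicRanges::width(gr)),
                 multi_chromosome = length(chs) > 1L,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }

  genes <- roll(df$gene_id)
  genes$level <- "GENE"
  genes$parent_id <- ""

  isos <- roll(df$transcript_id)
  isos$level <- "ISOFORM"
  tx2gene <- unique(df[, c("transcript_id", "gene_id")])
  if (anyDuplicated(tx2gene$transcript_id))
    stop("transcript assigned to more than one gene")
  isos$parent_id <- tx2gene$gene_id[match(isos$feature_id,
                                          tx2gene$transcript_id)]

  exons <- data.frame(
    feature_id = exon_tbl$exon_id,
    chromosomes = exon_tbl$chrom,
    start = exon_tbl$start, end = exon_tbl$end,
    exonic_length = exon_tbl$end - exon_tbl$start + 1L,
    multi_chromosome = FALSE,
    level = "EXON",
    parent_id = exon_tbl$gene_id,
    stringsAsFactors = FALSE)

  cols <- c("feature_id", "level", "parent_id", "chromosomes", "start", "end",
            "exonic_length", "multi_chromosome")
  features <- rbind(genes[, cols], isos[, cols], exons[, cols])
  rownames(features) <- NULL
  stopifnot(all(features$exonic_length > 0))

  structure(list(features = features, exon_map = exon_map,
                 exon_ranges = exon_ranges),
            class = "feature_catalog")
}

# Pre-scan a GTF for structurally broken lines so the error can name the line.
check_gtf_wellformed <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(nf < 9L)
  if (length(bad))
    stop("malformed GTF line ", which(body)[bad[1]], " in ", gtf_path,
         " (expected 9 tab-separated fields, found ", nf[bad[1]], ")")
  invisible(TRUE)
}

#' @export
print.feature_catalog <- function(x, ...) {
  tab <- table(factor(x$features$level, levels = FEATURE_LEVELS))
  cat("feature_catalog:", tab["GENE"], "genes,", tab["ISOFORM"], "isoforms,",
      tab["EXON"], "exons on",
      length(unique(unlist(strsplit(x$features$chromosomes, ",")))),
      "chromosome(s)\n")
  nmc <- sum(x$features$multi_chromosome)
  if (nmc) cat("  ", nmc, "multi-chromosome feature(s) flagged\n")
  invisible(x)
}

# Convenience accessors used throughout the package.
catalog_features <- function(catalog, level) {
  catalog$features[catalog$features$level == level, , drop = FALSE]
}

# exon ids belonging to one feature at any level
feature_exons <- function(catalog, feature_id, level) {
  em <- catalog$exon_map
  switch(level,
         GENE    = unique(em$exon_id[em$gene_id == feature_id]),
         ISOFORM = unique(em$exon_id[em$transcript_id == feature_id]),
         EXON    = feature_id)
}
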