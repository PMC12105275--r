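#' Ingest a complete cohort bundle
#'
#' Reads every input of a cohort directory laid out like the output of
#' \code{\link{generate_cohort}} (a \code{manifest.json} naming the
#' annotation, per-sample count and VCF files, copy-number table, drug
#' tables, gene list and sample table) into the internal data model.
#'
#' @param dir cohort directory containing \code{manifest.json}
#' @return list: \code{$catalog}, \code{$samples} (data.frame),
#'   \code{$rna_counts}/\code{$wes_counts} (per-sample exon count tables),
#'   \code{$rna_snv}/\code{$wes_snv} (per-sample \code{read_het_snvs}
#'   results), \code{$cn}, \code{$drugs} (combined PRISM + GDSC1 table),
#'   \code{$gene_list}
#' @export
ingest_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json under ", dir)
  man <- jsonlite::read_json(manifest_path)
  fp <- function(x) file.path(dir, unlist(x))

  catalog <- read_annotation(fp(man$files$annotation))
  samples <- read_mae_table(fp(man$files$samples))
  sample_ids <- samples$sample_id

  named_list <- function(paths, reader) {
    out <- lapply(fp(paths), reader)
    names(out) <- names(paths)
    out[sample_ids]
  }
  rna_counts <- named_list(man$files$rna_counts,
                           function(p) read_exon_counts(p, catalog))
  wes_counts <- named_list(man$files$wes_counts,
                           function(p) read_exon_counts(p, catalog))
  rna_snv <- named_list(man$files$rna_vcf,
                        function(p) read_het_snvs(p, "RNA", catalog))
  wes_snv <- named_list(man$files$wes_vcf,
                        function(p) read_het_snvs(p, "WES", catalog))
  cn <- read_copy_number(fp(man$files$copy_number))
  drugs <- rbind(read_drug_response(fp(man$files$drug_prism), "PRISM"),
                 read_drug_response(fp(man$files$drug_gdsc1), "GDSC1"))
  gene_list <- readLines(fp(man$files$gene_list))

  list(catalog = catalog, samples = samples, rna_counts = rna_counts,
       wes_counts = wes_counts, rna_snv = rna_snv, wes_snv = wes_snv,
       cn = cn, drugs = drugs, gene_list = gene_list)
}

#' Build classifier evidence from an ingested cohort at one level
#'
#' @param ingested result of \code{\link{ingest_cohort}}
#' @param level \code{"GENE"}, \code{"ISOFORM"} or \code{"EXON"}
#' @return evidence data.frame (see \code{\link{build_evidence}})
#' @export
cohort_evidence <- function(ingested, level = c("GENE", "ISOFORM", "EXON")) {
  level <- match.arg(level)
  sample_ids <- ingested$samples$sample_id
  rna_expr <- lapply(ingested$rna_counts, aggregate_expression,
                     catalog = ingested$catalog, level = level)
  wes_expr <- lapply(ingested$wes_counts, aggregate_expression,
                     catalog = ingested$catalog, level = level)
  build_evidence(ingested$catalog, level, sample_ids,
                 rna_het = lapply(ingested$rna_snv, `[[`, "het_counts"),
                 wes_het = lapply(ingested$wes_snv, `[[`, "het_counts"),
                 rna_expr = rna_expr, wes_expr = wes_expr,
                 cn = ingested$cn)
}

#' Classify a whole cohort at one level
#'
#' Convenience wrapper: ingested bundle to \code{allelic_calls}.
#'
#' @inheritParams cohort_evidence
#' @param thresholds a \code{\link{classifier_thresholds}} object
#' @return an \code{allelic_calls} object
#' @export
classify_cohort <- function(ingested, level = c("GENE", "ISOFORM", "EXON"),
                            thresholds = classifier_thresholds()) {
  level <- match.arg(level)
  ev <- cohort_evidence(ingested, level)
  classify_matrix(ev, ingested$catalog, thresholds, level,
                  samples = ingested$samples$sample_id)
}

#' Combined SNV site table of an ingested cohort (both assays)
#'
#' @param ingested result of \code{\link{ingest_cohort}}
#' @return data.frame suitable for
#'   \code{\link{extract_monoallelic_snvs}}
#' @export
cohort_snv_table <- function(ingested) {
  rbind(bind_snv_sites(lapply(ingested$rna_snv, `[[`, "sites")),
        bind_snv_sites(lapply(ingested$wes_snv, `[[`, "sites")))
}
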