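# Fixtures are built in code at test time; nothing is stored on disk.

# A small two-gene annotation used across the ingest and flip tests:
#   GA on chr1: isoforms GA.T1 = {E1, E2}, GA.T2 = {E2, E3} (E2 shared)
#     E1 100-199 (100 bp), E2 300-449 (150 bp), E3 600-699 (100 bp)
#     gene union length = 350 bp
#   GB on chr2: single isoform GB.T1 = {E4}, E4 100-299 (200 bp)
toy_gtf_lines <- function() {
  a <- function(g, t, e) sprintf('gene_id "%s"; transcript_id "%s"; exon_id "%s";',
                                 g, t, e)
  c(sprintf("chr1\ttoy\texon\t100\t199\t.\t+\t.\t%s", a("GA", "GA.T1", "E1")),
    sprintf("chr1\ttoy\texon\t300\t449\t.\t+\t.\t%s", a("GA", "GA.T1", "E2")),
    sprintf("chr1\ttoy\texon\t300\t449\t.\t+\t.\t%s", a("GA", "GA.T2", "E2")),
    sprintf("chr1\ttoy\texon\t600\t699\t.\t+\t.\t%s", a("GA", "GA.T2", "E3")),
    sprintf("chr2\ttoy\texon\t100\t299\t.\t+\t.\t%s", a("GB", "GB.T1", "E4")))
}

toy_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- tempfile(fileext = ".gtf")
      writeLines(toy_gtf_lines(), p)
      cache <<- read_annotation(p)
    }
    cache
  }
})

write_gtf <- function(lines) {
  p <- tempfile(fileext = ".gtf")
  writeLines(lines, p)
  p
}

write_test_vcf <- function(rows, sample_id = "S1") {
  p <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  body <- if (nrow(rows)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                                  rows$chrom, rows$pos, rows$ref, rows$alt,
                                  rows$gt)
          else character(0)
  writeLines(c(hdr, body), p)
  p
}

vcf_rows <- function(chrom, pos, ref, alt, gt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             stringsAsFactors = FALSE)
}

# evidence row shorthand for classifier tests
ev_row <- function(rna_het, wes_het, rna_expr, wes_cov, cn,
                   feature_id = "F", sample_id = "S") {
  data.frame(feature_id = feature_id, sample_id = sample_id,
             rna_het_snv_count = rna_het, wes_het_snv_count = wes_het,
             rna_expr = rna_expr, wes_cov = wes_cov, cn_linear = cn,
             cn_discrete = NA_integer_, stringsAsFactors = FALSE)
}

# hand-built calls table (summarize/associate tests construct these directly)
make_calls <- function(feature_id, sample_id, call, qc = FALSE,
                       multichrom = FALSE, level = "GENE") {
  data.frame(feature_id = feature_id, level = level, sample_id = sample_id,
             call = factor(call, levels = maecall:::CALL_LEVELS),
             qc_discrepancy_flag = qc, multi_chromosome_flag = multichrom,
             stringsAsFactors = FALSE)
}
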