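test_that("annotation roll-up builds the gene/isoform/exon hierarchy with merged lengths", {
  cat <- toy_catalog()
  f <- cat$features
  expect_equal(sum(f$level == "GENE"), 2)
  expect_equal(sum(f$level == "ISOFORM"), 3)
  expect_equal(sum(f$level == "EXON"), 4)
  # shared exon E2 appears once; gene length is the interval union
  expect_equal(f$exonic_length[f$feature_id == "GA"], 100 + 150 + 100)
  expect_equal(f$exonic_length[f$feature_id == "GA.T1"], 250)
  expect_equal(f$exonic_length[f$feature_id == "GA.T2"], 250)
  expect_equal(f$exonic_length[f$feature_id == "E2"], 150)
  expect_equal(f$parent_id[f$feature_id == "GA.T2"], "GA")
  expect_true(all(f$exonic_length > 0))
})

test_that("non-autosomal features are dropped and multi-chromosome features flagged", {
  a <- function(g, t, e) sprintf('gene_id "%s"; transcript_id "%s"; exon_id "%s";',
                                 g, t, e)
  lines <- c(
    sprintf("chr1\tt\texon\t100\t199\t.\t+\t.\t%s", a("GM", "GM.T1", "EM1")),
    sprintf("chr5\tt\texon\t100\t199\t.\t+\t.\t%s", a("GM", "GM.T2", "EM2")),
    sprintf("chrX\tt\texon\t100\t199\t.\t+\t.\t%s", a("GX", "GX.T1", "EX1")))
  cat <- read_annotation(write_gtf(lines))
  f <- cat$features
  expect_true(f$multi_chromosome[f$feature_id == "GM"])
  expect_equal(f$chromosomes[f$feature_id == "GM"], "chr1,chr5")
  expect_false("GX" %in% f$feature_id)
  expect_false("GX.T1" %in% f$feature_id)
})

test_that("broken annotation inputs fail loudly", {
  bad <- c(toy_gtf_lines(), "chr1\ttoy\texon\t1\t2")
  expect_error(read_annotation(write_gtf(bad)), "line 6")
  no_tx <- 'chr1\tt\texon\t100\t199\t.\t+\t.\tgene_id "G"; exon_id "E";'
  expect_error(read_annotation(write_gtf(no_tx)), "transcript")
})

test_that("exon counts are validated, joined and zero-imputed", {
  cat <- toy_catalog()
  p <- tempfile()
  writeLines(c("E1\t10", "E2\t0"), p)
  tab <- read_exon_counts(p, cat)
  expect_setequal(tab$exon_id, c("E1", "E2", "E3", "E4"))
  expect_equal(tab$count[tab$exon_id == "E1"], 10)
  expect_equal(tab$count[tab$exon_id == "E3"], 0)  # imputed

  writeLines(c("E1\t10", "EZZ\t5"), p)
  expect_warning(tab2 <- read_exon_counts(p, cat), "not in catalog")
  expect_false("EZZ" %in% tab2$exon_id)

  file.create(p2 <- tempfile())
  empty <- read_exon_counts(p2, cat)
  expect_true(all(empty$count == 0))

  writeLines("E1\t-3", p)
  expect_error(read_exon_counts(p, cat), "negative")
  writeLines(c("E1\t1", "E1\t2"), p)
  expect_error(read_exon_counts(p, cat), "duplicate")
})

test_that("expression aggregation is log10(count sum / merged length) with -Inf for silence", {
  cat <- toy_catalog()
  p <- tempfile()
  # GB: single 200 bp exon
  writeLines(c("E4\t100"), p)
  tab <- read_exon_counts(p, cat)
  ge <- aggregate_expression(tab, cat, "GENE")
  expect_equal(ge$expr[ge$feature_id == "GB"], log10(100 / 200))
  expect_identical(ge$expr[ge$feature_id == "GA"], -Inf)
  # hand-summed isoform oracle: GA.T1 exons (E1 5, E2 15) / 250
  writeLines(c("E1\t5", "E2\t15", "E3\t10"), p)
  ie <- aggregate_expression(read_exon_counts(p, cat), cat, "ISOFORM")
  expect_equal(ie$expr[ie$feature_id == "GA.T1"], log10(20 / 250))
  expect_equal(ie$expr[ie$feature_id == "GA.T2"], log10(25 / 250))
})

test_that("gene expression never double-counts exons shared between isoforms", {
  cat <- toy_catalog()
  p <- tempfile()
  writeLines(c("E1\t10", "E2\t20", "E3\t30", "E4\t0"), p)
  tab <- read_exon_counts(p, cat)
  ge <- aggregate_expression(tab, cat, "GENE")
  # brute-force oracle: each distinct exon once over the union length
  expect_equal(ge$expr[ge$feature_id == "GA"], log10((10 + 20 + 30) / 350))
})

test_that("copy-number back-transform and rounding follow the diploid convention", {
  p <- tempfile()
  write_mae_table(data.frame(gene_id = c("G1", "G2", "G3"),
                             S1 = c(1.0, 0, log2(1.5))), p)
  cn <- read_copy_number(p)
  expect_equal(cn$cn_linear, c(2, 0, 1), tolerance = 1e-12)
  expect_equal(cn$cn_discrete, c(2L, 0L, 1L))
  expect_lt(cn$cn_linear[3], 1.5)  # below the loss threshold
  # linear pass-through
  write_mae_table(data.frame(gene_id = "G1", S1 = 2.5), p)
  expect_equal(read_copy_number(p, "LINEAR_ABSOLUTE")$cn_linear, 2.5)
})

test_that("het SNV counting is exonic, per-feature, once per level", {
  cat <- toy_catalog()
  # two het exonic (E1, shared E2), one hom exonic, one het intronic (250),
  # one het on chrX, one indel
  p <- write_test_vcf(vcf_rows(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chrX"),
    pos = c(150, 160, 170, 250, 350, 100),
    ref = c("A", "G", "AT", "A", "C", "A"),
    alt = c("G", "A", "A", "C", "T", "G"),
    gt = c("0/1", "1/1", "0/1", "0/1", "0|1", "0/1")))
  res <- read_het_snvs(p, "RNA", cat)
  hc <- stats::setNames(res$het_counts$het_snv_count, res$het_counts$feature_id)
  expect_equal(hc[["GA"]], 2L)       # intronic + hom + indel + chrX excluded
  expect_equal(hc[["GA.T1"]], 2L)    # E1 + shared E2
  expect_equal(hc[["GA.T2"]], 1L)    # shared E2 only
  expect_equal(hc[["E2"]], 1L)
  expect_equal(hc[["GB"]], 0L)
  # hom site still present in the site records, flagged non-het
  expect_true(any(res$sites$pos == 160 & !res$sites$het))
  expect_false(any(res$sites$chrom == "chrX"))
})

test_that("a hom-only VCF yields zero het counts everywhere", {
  cat <- toy_catalog()
  p <- write_test_vcf(vcf_rows("chr1", c(150, 350), c("A", "C"),
                               c("G", "T"), c("1/1", "1/1")))
  res <- read_het_snvs(p, "WES", cat)
  expect_true(all(res$het_counts$het_snv_count == 0))
})

test_that("unsorted VCFs are rejected", {
  cat <- toy_catalog()
  p <- write_test_vcf(vcf_rows("chr1", c(350, 150), c("A", "C"),
                               c("G", "T"), c("0/1", "0/1")))
  expect_error(read_het_snvs(p, "RNA", cat), "unsorted")
})

test_that("drug response lands on log10(IC50) with GDSC1 duplicate averaging", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("agent,sample,ic50", "d1,S1,10", "d1,S2,1"), p)
  pr <- read_drug_response(p, "PRISM")
  expect_equal(pr$log_ic50, c(1, 0))

  p2 <- tempfile()
  write_mae_table(data.frame(agent = c("d1", "d1", "d1"),
                             sample = c("S1", "S1", "S2"),
                             log_ic50 = c(0.2, 0.4, 1)), p2)
  g1 <- read_drug_response(p2, "GDSC1")
  expect_equal(nrow(g1), 2)
  expect_equal(g1$log_ic50[g1$sample_id == "S1"], 0.3)
  # duplicates are an error outside GDSC1
  expect_error(read_drug_response(p2, "GDSC2"), "duplicate")

  writeLines(c("agent,sample,ic50", "d1,S1,-1"), p)
  expect_error(read_drug_response(p, "PRISM"), "positive")

  # same agent in two datasets stays two records
  both <- rbind(pr, read_drug_response(p2, "GDSC1"))
  expect_equal(sort(unique(both$dataset)), c("GDSC1", "PRISM"))
})

test_that("table writing round-trips bit-exactly including missing markers", {
  x <- data.frame(id = c("a", "b"), val = c(1.25, NA),
                  flag = c(TRUE, FALSE), stringsAsFactors = FALSE)
  p <- tempfile()
  write_mae_table(x, p)
  expect_true(any(grepl("\\.", readLines(p)[3])))
  y <- read_mae_table(p)
  expect_identical(x, y)
  # and a second write of the re-read table is byte-identical
  p2 <- tempfile()
  write_mae_table(y, p2)
  expect_identical(readLines(p), readLines(p2))
})
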