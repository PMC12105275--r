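test_that("the decision cascade assigns each worked case correctly", {
  th <- classifier_thresholds()
  cl <- function(rna_het, wes_het, rna_expr, wes_cov, cn)
    classify_feature(ev_row(rna_het, wes_het, rna_expr, wes_cov, cn), th)

  # copy loss wins regardless of other evidence
  r <- cl(2, 2, 0.3, 0.1, 1.2)
  expect_equal(as.character(r$call), "COPY_NUMBER_LOSS")
  r <- cl(0, 3, -1.2, 0.1, 2)
  expect_equal(as.character(r$call), "NOT_EXPRESSED")
  r <- cl(2, 2, 0.3, 0.1, 2)
  expect_equal(as.character(r$call), "BIALLELIC")
  r <- cl(0, 2, 0.3, 0.1, 2)
  expect_equal(as.character(r$call), "MONOALLELIC")
  # RNA het with no WES het and good coverage: unresolved + QC discrepancy
  r <- cl(1, 0, 0.3, 0.0, 2)
  expect_equal(as.character(r$call), "UNRESOLVED")
  expect_true(r$qc_discrepancy_flag)
  # no SNVs in either assay
  r <- cl(0, 0, 0.3, 0.1, 2)
  expect_equal(as.character(r$call), "NO_SNV_DATA")
  # WES het, no RNA het, but WES under-covered: unresolved, no flag
  r <- cl(0, 2, 0.3, -1.0, 2)
  expect_equal(as.character(r$call), "UNRESOLVED")
  expect_false(r$qc_discrepancy_flag)
})

test_that("the cascade agrees with an exhaustive truth-table oracle", {
  # independent re-derivation as literal nested conditionals
  oracle <- function(rna_het, wes_het, rna_expr, wes_cov, cn) {
    if (!is.na(cn) && cn < 1.5) return("COPY_NUMBER_LOSS")
    if (wes_het == 0 && rna_het == 0) return("NO_SNV_DATA")
    if (rna_expr < -0.5) return("NOT_EXPRESSED")
    if (wes_het > 0 && rna_het > 0) return("BIALLELIC")
    if (wes_het > 0 && rna_het == 0 && wes_cov >= -0.5) return("MONOALLELIC")
    "UNRESOLVED"
  }
  grid <- expand.grid(rna_het = c(0L, 2L), wes_het = c(0L, 2L),
                      rna_expr = c(-Inf, -1.2, -0.5, 0.3),
                      wes_cov = c(-Inf, -1.0, -0.5, 0.1),
                      cn = c(NA, 1.2, 1.5, 2.0))
  got <- classify_feature(
    ev_row(grid$rna_het, grid$wes_het, grid$rna_expr, grid$wes_cov, grid$cn,
           feature_id = sprintf("F%03d", seq_len(nrow(grid))),
           sample_id = "S"))
  want <- mapply(oracle, grid$rna_het, grid$wes_het, grid$rna_expr,
                 grid$wes_cov, grid$cn)
  expect_equal(as.character(got$call), unname(want))
})

test_that("threshold shifts move calls monotonically", {
  set.seed(1)
  n <- 500
  ev <- ev_row(rna_het = rbinom(n, 3, 0.4), wes_het = rbinom(n, 3, 0.5),
               rna_expr = rnorm(n, -0.5, 1), wes_cov = rnorm(n, 0, 1),
               cn = runif(n, 0, 3),
               feature_id = sprintf("F%03d", 1:n), sample_id = "S")
  n_cnl <- function(thr) sum(classify_feature(
    ev, classifier_thresholds(cn_loss_threshold = thr))$call == "COPY_NUMBER_LOSS")
  n_ne <- function(cut) sum(classify_feature(
    ev, classifier_thresholds(expr_cutoff = cut))$call == "NOT_EXPRESSED")
  thr_seq <- c(2, 1.5, 1, 0.5, 0)
  expect_true(all(diff(vapply(thr_seq, n_cnl, 0L)) <= 0))
  cut_seq <- c(-2, -1, -0.5, 0, 1)
  expect_true(all(diff(vapply(cut_seq, n_ne, 0L)) >= 0))
})

test_that("classify_matrix covers all pairs, is per-sample, and warns on gaps", {
  cat <- toy_catalog()
  samples <- c("S1", "S2", "S3")
  ev <- do.call(rbind, lapply(samples, function(s)
    ev_row(rna_het = c(1L, 0L), wes_het = c(1L, 2L), rna_expr = 0.2,
           wes_cov = 0.2, cn = 2, feature_id = c("GA", "GB"), sample_id = s)))
  calls <- classify_matrix(ev, cat, level = "GENE", samples = samples)
  expect_equal(nrow(calls), 6)
  expect_true(all(as.character(calls$call[calls$feature_id == "GA"]) ==
                    "BIALLELIC"))
  # permuting samples leaves every call unchanged
  calls_perm <- classify_matrix(ev[sample(nrow(ev)), ], cat, level = "GENE",
                                samples = rev(samples))
  key <- function(x) x[order(x$feature_id, x$sample_id),
                       c("feature_id", "sample_id", "call")]
  expect_equal(key(as.data.frame(calls)), key(as.data.frame(calls_perm)),
               ignore_attr = TRUE)
  # missing pair: UNRESOLVED with warning
  expect_warning(
    calls_gap <- classify_matrix(ev[ev$sample_id != "S3" |
                                      ev$feature_id != "GB", ],
                                 cat, level = "GENE", samples = samples),
    "without evidence")
  expect_equal(as.character(
    calls_gap$call[calls_gap$feature_id == "GB" &
                     calls_gap$sample_id == "S3"]), "UNRESOLVED")
})

test_that("a copy-loss gene forces copy loss for its isoforms and exons", {
  nf <- noise_free_cohort()
  gcalls <- classify_cohort(nf$ingested, "GENE")
  icalls <- classify_cohort(nf$ingested, "ISOFORM")
  ecalls <- classify_cohort(nf$ingested, "EXON")
  feats <- nf$ingested$catalog$features
  loss <- gcalls[as.character(gcalls$call) == "COPY_NUMBER_LOSS", ]
  expect_gt(nrow(loss), 0)
  for (child in list(icalls, ecalls)) {
    parent <- feats$parent_id[match(child$feature_id, feats$feature_id)]
    # exon parents are genes; isoform parents are genes too
    hit <- paste(parent, child$sample_id) %in%
      paste(loss$feature_id, loss$sample_id)
    expect_true(all(as.character(child$call[hit]) == "COPY_NUMBER_LOSS"))
  }
})

test_that("expression cutoff curve tracks zero-het proportion and smooths", {
  # logistic dropout: P(zero het) falls with expression
  set.seed(9)
  n <- 3000
  expr <- runif(n, -2, 2)
  zero <- rbinom(n, 1, plogis(-3 * expr)) == 1
  ev <- ev_row(rna_het = ifelse(zero, 0L, 1L), wes_het = 1L,
               rna_expr = expr, wes_cov = 0, cn = 2,
               feature_id = sprintf("F%05d", 1:n), sample_id = "S")
  cur <- expression_cutoff_curve(ev, bin_width = 0.25)
  expect_true(all(diff(cur$bin_mid) > 0))
  sm <- cur$smoothed[!is.na(cur$smoothed)]
  expect_true(all(diff(sm) < 0.05))  # essentially monotone decreasing
  # all features with >= 1 het SNV: proportion 0 everywhere
  ev2 <- ev; ev2$rna_het_snv_count <- 1L
  expect_true(all(expression_cutoff_curve(ev2)$prop_zero_het == 0))
  # single bin: raw proportion only
  ev3 <- ev[abs(ev$rna_expr - 0.1) < 0.05, ]
  cur3 <- expression_cutoff_curve(ev3, bin_width = 10)
  expect_equal(nrow(cur3), 1)
  expect_true(is.na(cur3$smoothed))
})
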