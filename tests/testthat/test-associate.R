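# construct a minimal groups object without running the classifier
make_groups <- function(pattern_list, gene_id = "G1") {
  # pattern_list: named list group_id -> named character vector sample -> call
  pattern <- do.call(rbind, lapply(names(pattern_list), function(g)
    data.frame(group_id = g, sample_id = names(pattern_list[[g]]),
               call = unname(pattern_list[[g]]), qc_discrepancy_flag = FALSE,
               stringsAsFactors = FALSE)))
  groups <- data.frame(
    group_id = names(pattern_list), gene_id = gene_id,
    members = names(pattern_list), n_members = 1L,
    n_mono = vapply(pattern_list, function(p) sum(p == "MONOALLELIC"), 0L),
    n_bi = vapply(pattern_list, function(p) sum(p == "BIALLELIC"), 0L),
    stringsAsFactors = FALSE)
  list(groups = groups, pattern = pattern)
}

drug_rows <- function(agent, sample, lic, dataset = "PRISM") {
  data.frame(agent_id = agent, dataset = dataset, sample_id = sample,
             log_ic50 = lic, stringsAsFactors = FALSE)
}

test_that("isoforms group by identical full pattern vectors within a gene", {
  cat <- toy_catalog()
  samples <- c("S1", "S2")
  calls <- make_calls(
    feature_id = rep(c("GA.T1", "GA.T2", "GB.T1"), each = 2),
    sample_id = rep(samples, 3),
    call = c("MONOALLELIC", "BIALLELIC",
             "MONOALLELIC", "BIALLELIC",
             "MONOALLELIC", "BIALLELIC"),
    level = "ISOFORM")
  g <- build_isoform_groups(calls, cat)
  # identical vectors, same gene -> one group; same vector, other gene -> own
  expect_equal(nrow(g$groups), 2)
  expect_equal(sort(g$groups$gene_id), c("GA", "GB"))
  expect_equal(g$groups$n_members[g$groups$gene_id == "GA"], 2L)
  # one differing sample splits the group
  calls2 <- calls
  calls2$call[calls2$feature_id == "GA.T2" & calls2$sample_id == "S2"] <-
    "UNRESOLVED"
  g2 <- build_isoform_groups(calls2, cat)
  expect_equal(sum(g2$groups$gene_id == "GA"), 2)
  # deterministic ids
  g3 <- build_isoform_groups(calls[sample(nrow(calls)), ], cat)
  expect_identical(g$groups$group_id, g3$groups$group_id)
})

test_that("allelic vs response t-tests respect arms, edges and eligibility", {
  pat <- c(S1 = "MONOALLELIC", S2 = "MONOALLELIC", S3 = "MONOALLELIC",
           S4 = "BIALLELIC", S5 = "BIALLELIC", S6 = "BIALLELIC")
  g <- make_groups(list(grp1 = pat))
  # identical constant arms: t = 0, p = 1, degenerate flag
  d <- drug_rows("a1", names(pat), rep(1, 6))
  r <- test_allelic_vs_response(g, d)
  expect_equal(r$p0, 1)
  expect_equal(r$statistic, 0)
  expect_true(r$degenerate)
  # arm sizes (2, 8) are skipped
  pat2 <- c(S1 = "MONOALLELIC", S2 = "MONOALLELIC",
            stats::setNames(rep("BIALLELIC", 8), sprintf("S%d", 3:10)))
  g2 <- make_groups(list(grp1 = pat2))
  d2 <- drug_rows("a1", names(pat2), rnorm(10))
  expect_equal(nrow(test_allelic_vs_response(g2, d2)), 0)
  # direction: monoallelic arm with lower IC50 is "more sensitive"
  d3 <- drug_rows("a1", names(pat), c(0, 0.1, -0.1, 5, 5.1, 4.9))
  r3 <- test_allelic_vs_response(g, d3)
  expect_equal(r3$direction, "monoallelic_more_sensitive")
  expect_lt(r3$p0, 0.01)
})

test_that("t statistics match the pooled-variance oracle to 1e-10", {
  pat <- stats::setNames(rep(c("MONOALLELIC", "BIALLELIC"), c(5, 7)),
                         sprintf("S%02d", 1:12))
  g <- make_groups(list(grp1 = pat))
  set.seed(8)
  for (i in 1:100) {
    lic <- rnorm(12)
    r <- test_allelic_vs_response(g, drug_rows("a1", names(pat), lic))
    or <- t.test(lic[1:5], lic[6:12], var.equal = TRUE)
    expect_equal(r$statistic, unname(or$statistic), tolerance = 1e-10)
    expect_equal(r$p0, or$p.value, tolerance = 1e-10)
  }
})

test_that("expression-response Spearman handles monotone, short and tied inputs", {
  pat <- stats::setNames(rep("BIALLELIC", 10), sprintf("S%02d", 1:10))
  g <- make_groups(list(grp1 = pat))
  g$groups$members <- "iso1"
  ex <- data.frame(feature_id = "iso1", sample_id = names(pat),
                   expr = seq(0.1, 1, 0.1))
  d_up <- drug_rows("a1", names(pat), 1:10)
  r <- test_expression_vs_response(g, ex, d_up)
  expect_equal(r$statistic, 1)
  expect_equal(r$direction, "positive")
  r2 <- test_expression_vs_response(g, ex, drug_rows("a1", names(pat), 10:1))
  expect_equal(r2$statistic, -1)
  # n = 9 available: skipped
  expect_equal(nrow(test_expression_vs_response(
    g, ex, drug_rows("a1", names(pat)[1:9], 1:9))), 0)
  # constant expression: undefined rho, skipped
  ex2 <- ex; ex2$expr <- 1
  expect_equal(nrow(test_expression_vs_response(g, ex2, d_up)), 0)
  # tie-corrected t-approximation oracle
  set.seed(14)
  for (i in 1:100) {
    e <- sample(1:5, 10, replace = TRUE) / 2
    lic <- rnorm(10)
    ex$expr <- e
    if (length(unique(e)) == 1) next
    r <- test_expression_vs_response(g, ex, drug_rows("a1", names(pat), lic))
    or <- suppressWarnings(cor.test(e, lic, method = "spearman",
                                    exact = FALSE))
    expect_equal(r$statistic, unname(or$estimate), tolerance = 1e-10)
    expect_equal(r$p0, or$p.value, tolerance = 1e-10)
  }
})

test_that("allelic vs expression tests the dosage contrast at minimal arms", {
  pat <- c(S1 = "MONOALLELIC", S2 = "MONOALLELIC", S3 = "MONOALLELIC",
           S4 = "BIALLELIC", S5 = "BIALLELIC", S6 = "BIALLELIC")
  g <- make_groups(list(grp1 = pat))
  g$groups$members <- "iso1"
  ex <- data.frame(feature_id = "iso1", sample_id = names(pat),
                   expr = c(1, 1, 1, 1, 1, 1))
  r <- test_allelic_vs_expression(g, ex)
  expect_equal(nrow(r), 1)  # (3, 3) minimal arms are eligible
  expect_equal(r$p0, 1)
  # halving dosage: monoallelic arm lower by log10(2)
  ex$expr <- c(1, 1.01, 0.99, 1.3, 1.31, 1.29)
  r2 <- test_allelic_vs_expression(g, ex)
  expect_equal(r2$direction, "monoallelic_lower_expression")
  expect_lt(r2$p0, 0.01)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "within")
  expect_error(bh_fdr(c(0.5, NA)), "within")
  # independent step-up oracle on random vectors
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    adj <- pmin(adj, 1)
    want <- numeric(m); want[o] <- adj
    expect_equal(bh_fdr(p), want, tolerance = 1e-12)
  }
})

test_that("significance filtering is strict and sorted by raw p", {
  res <- data.frame(group_id = sprintf("g%d", 1:20), p0 = (1:20) / 100,
                    p_fdr = c(rep(0.01, 5), 0.05, rep(0.5, 14)))
  out <- filter_significant(res[sample(nrow(res)), ], 0.05)
  expect_equal(nrow(out), 5)           # p_fdr exactly at level excluded
  expect_true(!is.unsorted(out$p0))
  expect_equal(nrow(filter_significant(res[0, ], 0.05)), 0)
})

test_that("FDR families are isolated and sized after eligibility filtering", {
  pat_ok <- stats::setNames(rep(c("MONOALLELIC", "BIALLELIC"), each = 4),
                            sprintf("S%d", 1:8))
  pat_small <- stats::setNames(
    c(rep("MONOALLELIC", 2), rep("BIALLELIC", 6)), sprintf("S%d", 1:8))
  g_both <- make_groups(list(grpA = pat_ok, grpB = pat_small))
  g_only <- make_groups(list(grpA = pat_ok))
  set.seed(5)
  d <- drug_rows(rep(sprintf("a%d", 1:4), each = 8),
                 rep(sprintf("S%d", 1:8), 4), rnorm(32))
  rA <- test_allelic_vs_response(g_both, d)
  rB <- test_allelic_vs_response(g_only, d)
  # the ineligible group contributes nothing to the family
  expect_equal(nrow(rA), nrow(rB))
  expect_equal(rA$p_fdr, rB$p_fdr)
  # perturbing another family's inputs cannot change this one (families are
  # adjusted independently within each test function)
  ex <- data.frame(feature_id = "grpA", sample_id = sprintf("S%d", 1:8),
                   expr = rnorm(8))
  g_only$groups$members <- "grpA"
  r_expr <- test_allelic_vs_expression(g_only, ex)
  expect_equal(rB$p_fdr, test_allelic_vs_response(g_only, d)$p_fdr)
  expect_true(all(r_expr$p_fdr >= r_expr$p0))
})
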