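#' Group isoforms of a gene by identical allelic-pattern vectors
#'
#' Isoforms of the same gene whose full per-sample categorical pattern
#' (call category plus QC flag, over all samples) is identical are combined
#' into one isoform group, the unit of the association analyses — each
#' pattern is tested once instead of once per redundant isoform. Isoforms of
#' different genes never share a group, even with identical patterns.
#' Group ids are deterministic: \code{gene_id#k} with k assigned in sorted
#' pattern order.
#'
#' @param calls isoform-level \code{allelic_calls}
#' @param catalog a \code{feature_catalog}
#' @return list with \code{$groups} (group_id, gene_id, members
#'   (comma-separated isoform ids), n_members, n_mono, n_bi) and
#'   \code{$pattern} (long: group_id, sample_id, call,
#'   qc_discrepancy_flag)
#' @export
build_isoform_groups <- function(calls, catalog) {
  iso <- catalog_features(catalog, "ISOFORM")
  samples <- sort(unique(calls$sample_id))
  d <- calls[order(calls$feature_id, calls$sample_id), , drop = FALSE]
  pat <- vapply(split(paste(as.character(d$call), d$qc_discrepancy_flag),
                      d$feature_id),
                paste, "", collapse = "|")
  gene <- iso$parent_id[match(names(pat), iso$feature_id)]

  key <- paste(gene, pat, sep = "\r")
  groups_l <- split(names(pat), key)
  ord <- order(names(groups_l))
  groups_l <- groups_l[ord]
  gkey <- names(groups_l)
  ggene <- vapply(strsplit(gkey, "\r", fixed = TRUE), `[`, "", 1)
  idx <- stats::ave(seq_along(ggene), ggene, FUN = seq_along)
  gid <- paste0(ggene, "#", idx)

  pattern <- do.call(rbind, lapply(seq_along(groups_l), function(i) {
    iso1 <- groups_l[[i]][1]
    sub <- d[d$feature_id == iso1, , drop = FALSE]
    data.frame(group_id = gid[i], sample_id = sub$sample_id,
               call = as.character(sub$call),
               qc_discrepancy_flag = sub$qc_discrepancy_flag,
               stringsAsFactors = FALSE)
  }))
  groups <- data.frame(
    group_id = gid, gene_id = ggene,
    members = vapply(groups_l, function(m) paste(sort(m), collapse = ","), ""),
    n_members = lengths(groups_l),
    n_mono = vapply(seq_along(gid), function(i)
      sum(pattern$call[pattern$group_id == gid[i]] == "MONOALLELIC"), 0L),
    n_bi = vapply(seq_along(gid), function(i)
      sum(pattern$call[pattern$group_id == gid[i]] == "BIALLELIC"), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(groups = groups, pattern = pattern)
}

# informative arms of one group: samples excluded if the call is
# non-informative or carries a QC discrepancy flag
group_arms <- function(pattern, group_id) {
  p <- pattern[pattern$group_id == group_id & !pattern$qc_discrepancy_flag, ]
  list(mono = p$sample_id[p$call == "MONOALLELIC"],
       bi = p$sample_id[p$call == "BIALLELIC"])
}

# pooled-variance (Student) two-sample t-test; returns t, df, p, means and a
# degenerate flag for the zero-variance corner
student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- (sum((x - m1)^2) + sum((y - m2)^2)) / df
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, m1 = m1, m2 = m2,
                              degenerate = TRUE))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0, m1 = m1, m2 = m2,
                degenerate = TRUE))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), m1 = m1, m2 = m2,
       degenerate = FALSE)
}

# Spearman correlation with tie-corrected ranks and two-sided p from the
# t-approximation (the convention when n is moderate and ties are present)
spearman_t <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

assoc_row <- function(group_id, agent_id, dataset, family, statistic,
                      direction, n_mono, n_bi, n_total, p0, degenerate) {
  data.frame(group_id = group_id, agent_id = agent_id, dataset = dataset,
             family = family, statistic = statistic, direction = direction,
             n_mono = n_mono, n_bi = n_bi, n_total = n_total, p0 = p0,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

empty_assoc <- function() {
  assoc_row(character(), character(), character(), character(), numeric(),
            character(), integer(), integer(), integer(), numeric(),
            logical())
}

#' Allelic pattern versus drug response (Student's t)
#'
#' For every isoform group and every (agent, dataset) pair, compares
#' log10(IC50) between samples with monoallelic and with biallelic calls
#' using the pooled-variance Student's t-test. Pairs with fewer than
#' \code{min_per_arm} samples in either arm are skipped before FDR
#' adjustment, so ineligible pairs never inflate the family. Datasets are
#' never pooled: the same agent screened in two datasets yields two tests.
#'
#' @param groups result of \code{\link{build_isoform_groups}}
#' @param drug_table data.frame from \code{\link{read_drug_response}}
#'   (several datasets may be rbinded)
#' @param min_per_arm minimum samples per arm (default 3)
#' @return AssociationResult data.frame (family
#'   \code{ALLELIC_VS_RESPONSE}) with BH-adjusted \code{p_fdr}; direction is
#'   \code{"monoallelic_more_sensitive"} when the monoallelic arm has the
#'   lower mean log10(IC50)
#' @export
test_allelic_vs_response <- function(groups, drug_table, min_per_arm = 3) {
  by_ad <- split(drug_table, paste(drug_table$agent_id, drug_table$dataset,
                                   sep = "\r"))
  rows <- list()
  for (g in groups$groups$group_id) {
    arms <- group_arms(groups$pattern, g)
    if (length(arms$mono) < min_per_arm || length(arms$bi) < min_per_arm)
      next
    for (ad in by_ad) {
      lic <- stats::setNames(ad$log_ic50, ad$sample_id)
      x <- lic[intersect(arms$mono, ad$sample_id)]
      y <- lic[intersect(arms$bi, ad$sample_id)]
      if (length(x) < min_per_arm || length(y) < min_per_arm) next
      st <- student_t(x, y)
      dir <- if (st$m1 < st$m2) "monoallelic_more_sensitive"
             else if (st$m1 > st$m2) "biallelic_more_sensitive" else "none"
      rows[[length(rows) + 1L]] <-
        assoc_row(g, ad$agent_id[1], ad$dataset[1], "ALLELIC_VS_RESPONSE",
                  st$t, dir, length(x), length(y), length(x) + length(y),
                  st$p, st$degenerate)
    }
  }
  finish_family(rows)
}

#' Isoform-group expression versus drug response (Spearman)
#'
#' Correlates the mean log10 length-normalised expression of each isoform
#' group (mean over member isoforms, per sample) with log10(IC50), for
#' pairs with at least \code{min_n} samples having both measurements.
#' Groups whose expression vector is constant over the available samples
#' are skipped (rho undefined).
#'
#' @param groups result of \code{\link{build_isoform_groups}}
#' @param expression long data.frame (feature_id, sample_id, expr) of
#'   isoform-level expression
#' @param drug_table data.frame from \code{\link{read_drug_response}}
#' @param min_n minimum paired samples (default 10)
#' @return AssociationResult data.frame (family \code{EXPR_VS_RESPONSE});
#'   direction is the sign of rho (\code{"positive"} = higher expression,
#'   higher IC50, i.e. more resistant)
#' @export
test_expression_vs_response <- function(groups, expression, drug_table,
                                        min_n = 10) {
  gx <- group_expression(groups, expression)
  by_ad <- split(drug_table, paste(drug_table$agent_id, drug_table$dataset,
                                   sep = "\r"))
  rows <- list()
  for (g in names(gx)) {
    ex <- gx[[g]]
    for (ad in by_ad) {
      lic <- stats::setNames(ad$log_ic50, ad$sample_id)
      common <- intersect(names(ex)[is.finite(ex)], names(lic))
      if (length(common) < min_n) next
      sp <- spearman_t(ex[common], lic[common])
      if (is.na(sp$rho)) next  # constant expression: undefined
      dir <- if (sp$rho > 0) "positive" else if (sp$rho < 0) "negative"
             else "none"
      rows[[length(rows) + 1L]] <-
        assoc_row(g, ad$agent_id[1], ad$dataset[1], "EXPR_VS_RESPONSE",
                  sp$rho, dir, NA_integer_, NA_integer_, length(common),
                  sp$p, FALSE)
    }
  }
  finish_family(rows)
}

#' Allelic pattern versus isoform-group expression (Student's t)
#'
#' Compares the mean expression of each isoform group between samples with
#' monoallelic and with biallelic calls — the dosage question: does losing
#' one expressed allele halve output? Same eligibility rule as the drug
#' response t-test.
#'
#' @inheritParams test_expression_vs_response
#' @param min_per_arm minimum samples per arm (default 3)
#' @return AssociationResult data.frame (family \code{ALLELIC_VS_EXPR});
#'   agent_id and dataset are \code{NA}
#' @export
test_allelic_vs_expression <- function(groups, expression, min_per_arm = 3) {
  gx <- group_expression(groups, expression)
  rows <- list()
  for (g in names(gx)) {
    arms <- group_arms(groups$pattern, g)
    ex <- gx[[g]]
    x <- ex[intersect(arms$mono, names(ex)[is.finite(ex)])]
    y <- ex[intersect(arms$bi, names(ex)[is.finite(ex)])]
    if (length(x) < min_per_arm || length(y) < min_per_arm) next
    st <- student_t(x, y)
    dir <- if (st$m1 < st$m2) "monoallelic_lower_expression"
           else if (st$m1 > st$m2) "monoallelic_higher_expression" else "none"
    rows[[length(rows) + 1L]] <-
      assoc_row(g, NA_character_, NA_character_, "ALLELIC_VS_EXPR",
                st$t, dir, length(x), length(y), length(x) + length(y),
                st$p, st$degenerate)
  }
  finish_family(rows)
}

# per-sample mean expression of each group's member isoforms
group_expression <- function(groups, expression) {
  out <- list()
  for (i in seq_len(nrow(groups$groups))) {
    mem <- strsplit(groups$groups$members[i], ",", fixed = TRUE)[[1]]
    sub <- expression[expression$feature_id %in% mem, , drop = FALSE]
    if (!nrow(sub)) next
    out[[groups$groups$group_id[i]]] <-
      tapply(sub$expr, sub$sample_id, mean)
  }
  out
}

finish_family <- function(rows) {
  if (!length(rows)) {
    out <- empty_assoc()
    out$p_fdr <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p0)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment within one analysis family. Families are adjusted
#' separately (each \code{test_*} function adjusts only its own p-values);
#' skipped ineligible tests are never part of the family.
#'
#' @param p vector of p-values in [0, 1]
#' @return adjusted p-values, same order as the input
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter association results at an FDR level
#'
#' @param results AssociationResult data.frame
#' @param level strict upper bound on \code{p_fdr} (conventional choices:
#'   0.05 stringent, 0.125 relaxed)
#' @return rows with \code{p_fdr < level}, sorted by \code{p0}
#' @export
filter_significant <- function(results, level = 0.05) {
  out <- results[!is.na(results$p_fdr) & results$p_fdr < level, ,
                 drop = FALSE]
  out <- out[order(out$p0), , drop = FALSE]
  rownames(out) <- NULL
  out
}
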