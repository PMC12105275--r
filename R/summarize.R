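#' Summarise allelic calls per feature and sample group
#'
#' Counts, for every feature and every sample group (plus the pooled
#' "pancancer" group), how many samples fall in each call category, and the
#' percent-monoallelic statistic: \code{100 * monoallelic / (monoallelic +
#' biallelic)}, rounded half away from zero to two decimals, undefined
#' (\code{NA}) when a feature has no informative (monoallelic or biallelic)
#' call in the group.
#'
#' @param calls an \code{allelic_calls} object (or equivalent data.frame)
#' @param grouping named character vector mapping every sample id to one
#'   group label (e.g. tumor histology); \code{NULL} for pancancer only
#' @param pancancer include the pooled all-samples group (default TRUE)
#' @return data.frame with one row per feature x group: feature_id, group,
#'   n_samples, copy_number_loss, no_snv_data, not_expressed, biallelic,
#'   monoallelic, unresolved, total_informative, pct_monoallelic
#' @export
summarize_calls <- function(calls, grouping = NULL, pancancer = TRUE) {
  samples <- unique(calls$sample_id)
  if (!is.null(grouping)) {
    unknown <- setdiff(samples, names(grouping))
    if (length(unknown))
      stop("sample(s) missing from grouping: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  groups <- list()
  if (!is.null(grouping))
    groups <- split(names(grouping), unname(grouping))
  if (pancancer || is.null(grouping))
    groups$pancancer <- samples

  out <- lapply(names(groups), function(g) {
    sub <- calls[calls$sample_id %in% groups[[g]], , drop = FALSE]
    tab <- table(sub$feature_id,
                 factor(as.character(sub$call), levels = CALL_LEVELS))
    df <- as.data.frame.matrix(tab)
    names(df) <- tolower(CALL_LEVELS)
    data.frame(feature_id = rownames(tab), group = g,
               n_samples = length(unique(sub$sample_id)),
               df, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$total_informative <- out$monoallelic + out$biallelic
  out$pct_monoallelic <- pct_of(out$monoallelic, out$total_informative)
  out
}

#' Compare call-category proportions between two gene sets
#'
#' Aggregates a \code{\link{summarize_calls}} table over two disjoint id
#' sets (typically a curated imprinted-gene list versus all remaining genes)
#' and reports, per group, the proportion of calls in each category and the
#' percent monoallelic among informative calls for each set.
#'
#' @param summary data.frame from \code{\link{summarize_calls}}
#' @param set_A_ids,set_B_ids disjoint character vectors of feature ids
#' @param labels length-2 labels for the sets
#' @return data.frame with one row per group x set: group, set, total call
#'   counts per category, prop_* columns, pct_monoallelic
#' @export
compare_gene_sets <- function(summary, set_A_ids, set_B_ids,
                              labels = c("set_A", "set_B")) {
  if (length(intersect(set_A_ids, set_B_ids)))
    stop("gene sets overlap")
  cats <- tolower(CALL_LEVELS)
  one <- function(ids, lab) {
    sub <- summary[summary$feature_id %in% ids, , drop = FALSE]
    res <- lapply(split(sub, sub$group), function(d) {
      tot <- colSums(d[, cats, drop = FALSE])
      all_calls <- sum(tot)
      info <- tot[["monoallelic"]] + tot[["biallelic"]]
      props <- if (all_calls > 0) tot / all_calls else rep(NA_real_, 6)
      cbind(data.frame(group = d$group[1], set = lab,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(tot)),
            stats::setNames(as.data.frame(as.list(as.numeric(props))),
                            paste0("prop_", cats)),
            data.frame(pct_monoallelic = pct_of(tot[["monoallelic"]], info)))
    })
    do.call(rbind, res)
  }
  # groups with no rows in one set still get a row with missing proportions
  all_groups <- unique(summary$group)
  out <- rbind(one(set_A_ids, labels[1]), one(set_B_ids, labels[2]))
  missing <- setdiff(as.vector(outer(all_groups, labels, paste, sep = "\r")),
                     paste(out$group, out$set, sep = "\r"))
  if (length(missing)) {
    parts <- strsplit(missing, "\r", fixed = TRUE)
    pad <- out[rep(1, length(missing)), , drop = FALSE]
    pad$group <- vapply(parts, `[`, "", 1)
    pad$set <- vapply(parts, `[`, "", 2)
    pad[, setdiff(names(pad), c("group", "set"))] <- NA
    out <- rbind(out, pad)
  }
  rownames(out) <- NULL
  out[order(out$group, out$set), , drop = FALSE]
}

#' Null distribution of category proportions by gene subsampling
#'
#' Draws \code{n_reps} replicates of \code{n_genes} genes without
#' replacement from a background id set and, for each replicate, computes
#' the proportion of calls in each category per sample group (stratified
#' summarisation: one global gene draw per replicate, proportions reported
#' within each group). Used to place a reference set (e.g. 94 imprinted
#' genes) against a size-matched background distribution. Deterministic
#' given \code{seed}.
#'
#' @param calls an \code{allelic_calls} object
#' @param background_ids character vector to draw from
#' @param n_genes genes per replicate (must not exceed the background size)
#' @param n_reps number of replicates (default 1000)
#' @param seed integer seed (mandatory)
#' @param grouping optional named sample-to-group map (pancancer always
#'   included)
#' @return list with \code{$replicates} (one row per replicate x group:
#'   proportions per category and pct_monoallelic) and \code{$summary}
#'   (mean and SD per group and statistic)
#' @export
subsample_comparison <- function(calls, background_ids, n_genes,
                                 n_reps = 1000, seed, grouping = NULL) {
  if (n_genes > length(background_ids))
    stop("n_genes exceeds the background set size")
  if (missing(seed)) stop("seed is required")
  cats <- tolower(CALL_LEVELS)

  samples <- unique(calls$sample_id)
  groups <- list()
  if (!is.null(grouping)) groups <- split(names(grouping), unname(grouping))
  groups$pancancer <- samples

  # precompute per-feature x group category counts once; replicates then
  # just sum rows, which keeps 1000 replicates fast
  summ <- summarize_calls(calls, grouping = grouping)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      draw <- sample(background_ids, n_genes, replace = FALSE)
      sub <- summ[summ$feature_id %in% draw, , drop = FALSE]
      res <- lapply(split(sub, sub$group), function(d) {
        tot <- colSums(d[, cats, drop = FALSE])
        info <- tot[["monoallelic"]] + tot[["biallelic"]]
        cbind(data.frame(replicate = r, group = d$group[1],
                         stringsAsFactors = FALSE),
              stats::setNames(as.data.frame(as.list(tot / sum(tot))),
                              paste0("prop_", cats)),
              data.frame(pct_monoallelic = pct_of(tot[["monoallelic"]],
                                                  info)))
      })
      do.call(rbind, res)
    })
  })
  reps <- do.call(rbind, reps)
  rownames(reps) <- NULL
  stat_cols <- c(paste0("prop_", cats), "pct_monoallelic")
  summary <- do.call(rbind, lapply(split(reps, reps$group), function(d) {
    data.frame(group = d$group[1],
               statistic = stat_cols,
               mean = vapply(stat_cols,
                             function(cc) mean(d[[cc]], na.rm = TRUE), 0),
               sd = vapply(stat_cols,
                           function(cc) stats::sd(d[[cc]], na.rm = TRUE), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(replicates = reps, summary = summary)
}

#' Chi-square test for tissue-specific isoform allelic patterns
#'
#' Pearson chi-square test of independence, without continuity correction,
#' on a G x 2 table of (monoallelic, biallelic) isoform counts per tumor
#' histology. Histologies with zero informative isoforms are dropped before
#' testing; at least two must remain.
#'
#' @param counts matrix or data.frame with one row per group and two columns
#'   (monoallelic, biallelic counts); row names are group labels
#' @return list: statistic, df, p_value, observed table used
#' @export
histology_pattern_test <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2) stop("counts must have exactly two columns")
  if (any(m < 0) || any(m != floor(m))) stop("counts must be nonnegative integers")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) stop("insufficient groups: need >= 2 with informative isoforms")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, observed = m)
}

#' Count isoforms with pure allelic patterns per group for one gene
#'
#' An isoform contributes to a histology's monoallelic (or biallelic) count
#' only when all of its informative calls within that histology are
#' monoallelic (respectively biallelic); isoforms mixed within the group, or
#' with no informative call there, are excluded. The resulting G x 2 table
#' feeds \code{\link{histology_pattern_test}}.
#'
#' @param calls isoform-level \code{allelic_calls}
#' @param grouping named sample-to-group map
#' @param isoform_ids restrict to these isoforms (e.g. one gene's); default
#'   all
#' @return integer matrix, rows = groups, columns = c("monoallelic",
#'   "biallelic")
#' @export
count_pure_isoforms <- function(calls, grouping, isoform_ids = NULL) {
  sub <- calls[calls$sample_id %in% names(grouping), , drop = FALSE]
  if (!is.null(isoform_ids))
    sub <- sub[sub$feature_id %in% isoform_ids, , drop = FALSE]
  sub$group <- unname(grouping[sub$sample_id])
  sub <- sub[as.character(sub$call) %in% c("MONOALLELIC", "BIALLELIC"), ,
             drop = FALSE]
  groups <- sort(unique(unname(grouping)))
  m <- matrix(0L, nrow = length(groups), ncol = 2,
              dimnames = list(groups, c("monoallelic", "biallelic")))
  if (nrow(sub)) {
    key <- paste(sub$group, sub$feature_id, sep = "\r")
    calls_by <- split(as.character(sub$call), key)
    for (k in names(calls_by)) {
      cs <- unique(calls_by[[k]])
      if (length(cs) != 1L) next  # mixed within group: excluded
      g <- strsplit(k, "\r", fixed = TRUE)[[1]][1]
      col <- if (cs == "MONOALLELIC") 1L else 2L
      m[g, col] <- m[g, col] + 1L
    }
  }
  m
}
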