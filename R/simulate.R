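#' Configuration for a synthetic cohort
#'
#' Defines the generative conditions for a complete, internally consistent
#' input bundle with known truth. The defaults emulate the cohort structure
#' of a 108-cell-line pancancer panel spread over 9 tumor histologies, with
#' a curated "imprinted" gene list whose members are predominantly
#' monoallelic (with occasional loss of imprinting), a background of mostly
#' biallelic genes, a small set of base-biased predominantly monoallelic
#' genes, sporadic copy loss and silent features, and realistic
#' negative-binomial count noise.
#'
#' @param n_samples number of cell lines (default 108)
#' @param histology_weights named numeric vector of histology proportions
#'   (defaults mirror a 9-histology pancancer panel); samples are assigned
#'   round-robin proportionally
#' @param n_genes number of genes (default 200)
#' @param isoforms_per_gene,exons_per_isoform integer ranges c(min, max)
#' @param fraction_imprinted fraction of genes on the imprinted list
#' @param fraction_base_biased fraction of genes that are predominantly
#'   monoallelic through a base-biased mechanism (RNA-editing-like)
#' @param fraction_loi probability an imprinted gene is biallelic (loss of
#'   imprinting) in a given sample
#' @param biased_mono_rate probability a base-biased gene is monoallelic in
#'   a given sample
#' @param background_mono_rate probability a background gene is monoallelic
#'   in a given sample (default 0.135)
#' @param fraction_copy_loss probability of copy-number loss per gene x
#'   sample
#' @param fraction_silent probability a gene is not expressed in a sample
#' @param het_snv_rate candidate SNV sites per exonic kb of each gene
#' @param p_site_het probability a candidate site is heterozygous in a
#'   given sample
#' @param p_site_hom_alt probability a candidate site is homozygous-alt
#'   instead (exercises the hom filter of the base-preference chain)
#' @param base_bias_probability probability a base-biased monoallelic site
#'   expresses the alternative base
#' @param expr_rate_range,wes_rate_range reads per bp for RNA expression and
#'   WES coverage (uniform per gene x sample / per sample)
#' @param count_dispersion negative-binomial size parameter for exon counts;
#'   0 means deterministic counts (no noise)
#' @param cn_noise_sd SD of linear copy number around 2 for non-loss genes
#'   (truncated so noise never crosses the 1.5 loss line)
#' @param rna_dropout probability a would-be RNA variant record is missed
#'   (creates RNA/WES discordance)
#' @param n_agents agents per drug dataset
#' @param drug_noise_sd SD of log10(IC50) around each agent's baseline
#' @param gdsc1_duplicate_fraction fraction of GDSC1 (agent, sample) pairs
#'   emitted twice (exercises duplicate averaging)
#' @param seed integer seed (mandatory; the whole bundle is a pure function
#'   of the config)
#' @return object of class \code{cohort_config}
#' @export
cohort_config <- function(n_samples = 108,
                          histology_weights = c(AML = 17, bladder = 10,
                            breast = 6, colorectal = 13, head_and_neck = 16,
                            neuroblastoma = 4, ovarian = 14, PDAC = 16,
                            SCLC = 12),
                          n_genes = 200,
                          isoforms_per_gene = c(1, 3),
                          exons_per_isoform = c(2, 6),
                          fraction_imprinted = 0.15,
                          fraction_base_biased = 0.10,
                          fraction_loi = 0.25,
                          biased_mono_rate = 0.80,
                          background_mono_rate = 0.135,
                          fraction_copy_loss = 0.05,
                          fraction_silent = 0.10,
                          het_snv_rate = 2,
                          p_site_het = 0.5,
                          p_site_hom_alt = 0.05,
                          base_bias_probability = 0.9,
                          expr_rate_range = c(1, 5),
                          wes_rate_range = c(1, 5),
                          count_dispersion = 10,
                          cn_noise_sd = 0.1,
                          rna_dropout = 0,
                          n_agents = 20,
                          drug_noise_sd = 0.5,
                          gdsc1_duplicate_fraction = 0.1,
                          seed) {
  if (missing(seed)) stop("seed is required")
  cfg <- as.list(environment())
  fr <- c(fraction_imprinted, fraction_base_biased, fraction_loi,
          background_mono_rate, fraction_copy_loss, fraction_silent,
          p_site_het, p_site_hom_alt, base_bias_probability, rna_dropout,
          biased_mono_rate, gdsc1_duplicate_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (fraction_imprinted + fraction_base_biased > 1)
    stop("infeasible config: fraction_imprinted + fraction_base_biased > 1")
  if (p_site_het + p_site_hom_alt > 1)
    stop("infeasible config: p_site_het + p_site_hom_alt > 1")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort bundle with known truth
#'
#' Emits, under \code{dir}: a GTF annotation; per-sample RNA and WES VCFs;
#' per-sample exon-count tables for both assays; a gene-level copy-number
#' table on the log2(cn/2 + 1) scale; PRISM (linear IC50, CSV) and GDSC1
#' (log10 IC50 with planted duplicate rows, TSV) drug-response tables; the
#' imprinted-gene list; a sample-to-histology table; and a JSON manifest.
#' Alongside the files it returns truth labels: the generative call
#' category for every feature x sample (with SNV availability folded in:
#' features without a heterozygous WES site in a sample are NO_SNV_DATA)
#' and the mechanism of every SNV site (IMPRINT_LIKE in imprinted genes,
#' BASE_BIASED in base-biased genes, BIALLELIC elsewhere).
#'
#' Monoallelic expression is simulated feature-wise: all sites of a
#' monoallelic gene in a sample express the same haplotype. For imprinted
#' genes the expressed haplotype is the simulated parental origin (so each
#' site expresses reference or alternative with probability 0.5 across
#' samples); for base-biased genes the alternative base is expressed with
#' probability \code{base_bias_probability}. The same seed always yields a
#' byte-identical bundle.
#'
#' @param config a \code{\link{cohort_config}}
#' @param dir output directory (created; default a fresh tempdir)
#' @return object of class \code{synthetic_cohort}: list with \code{$dir},
#'   \code{$files} (named paths), \code{$config}, \code{$samples}
#'   (sample_id, histology), \code{$truth} (list: \code{$categories} long
#'   data.frame over all three levels, \code{$snv_mechanism})
#' @export
generate_cohort <- function(config, dir = tempfile("cohort")) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  with_seed(config$seed, generate_cohort_impl(config, dir))
}

generate_cohort_impl <- function(cfg, dir) {
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  w <- cfg$histology_weights / sum(cfg$histology_weights)
  histology <- rep(names(w), times = round_quota(w, n))
  samples_df <- data.frame(sample_id = samples, histology = histology,
                           stringsAsFactors = FALSE)

  ## ---- gene models -------------------------------------------------------
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  chrom <- AUTOSOMES[(seq_len(cfg$n_genes) - 1L) %% 22L + 1L]
  class_draw <- rep("BACKGROUND", cfg$n_genes)
  n_imp <- round(cfg$fraction_imprinted * cfg$n_genes)
  n_bb <- round(cfg$fraction_base_biased * cfg$n_genes)
  cls_idx <- sample(cfg$n_genes)
  class_draw[cls_idx[seq_len(n_imp)]] <- "IMPRINTED"
  if (n_bb > 0)
    class_draw[cls_idx[n_imp + seq_len(n_bb)]] <- "BASE_BIASED"

  models <- vector("list", cfg$n_genes)
  gtf <- character(0)
  offset_on <- stats::setNames(rep(10000L, 22), AUTOSOMES)
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i]; ch <- chrom[i]
    pool <- sample(cfg$exons_per_isoform[1]:cfg$exons_per_isoform[2], 1L)
    ex_len <- sample(150:300, pool, replace = TRUE)
    ex_start <- offset_on[ch] + cumsum(c(0L, utils::head(ex_len, -1) + 200L))
    ex_end <- ex_start + ex_len - 1L
    offset_on[ch] <- ex_end[pool] + 5000L
    n_iso <- sample(cfg$isoforms_per_gene[1]:cfg$isoforms_per_gene[2], 1L)
    iso_ex <- vector("list", n_iso)
    iso_ex[[1]] <- seq_len(pool)  # first isoform covers the pool
    if (n_iso > 1) for (j in 2:n_iso) {
      len <- sample(seq_len(pool), 1L)
      st <- sample(seq_len(pool - len + 1L), 1L)
      iso_ex[[j]] <- st:(st + len - 1L)
    }
    ex_id <- sprintf("%s:E%02d", g, seq_len(pool))
    iso_id <- sprintf("%s.T%02d", g, seq_len(n_iso))
    attr_s <- function(gid, tid, eid = NULL) {
      a <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      if (!is.null(eid)) a <- paste0(a, sprintf(' exon_id "%s";', eid))
      a
    }
    gtf <- c(gtf, sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\t%s",
                          ch, ex_start[1], ex_end[pool],
                          sprintf('gene_id "%s";', g)))
    for (j in seq_len(n_iso)) {
      e <- iso_ex[[j]]
      gtf <- c(gtf, sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                            ch, ex_start[e[1]], ex_end[e[length(e)]],
                            attr_s(g, iso_id[j])))
      gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\t%s",
                            ch, ex_start[e], ex_end[e],
                            attr_s(g, iso_id[j], ex_id[e])))
    }
    exonic_len <- sum(ex_len)
    n_sites <- max(1L, stats::rpois(1, cfg$het_snv_rate * exonic_len / 1000))
    site_ex <- sample(seq_len(pool), n_sites, replace = TRUE)
    site_pos <- ex_start[site_ex] +
      vapply(site_ex, function(e) sample.int(ex_len[e], 1L) - 1L, 0L)
    dup <- duplicated(site_pos)
    site_pos <- site_pos[!dup]; site_ex <- site_ex[!dup]
    o <- order(site_pos)
    site_pos <- site_pos[o]; site_ex <- site_ex[o]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(site_pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    models[[i]] <- list(gene = g, chrom = ch, ex_id = ex_id,
                        ex_start = ex_start, ex_end = ex_end, ex_len = ex_len,
                        iso_id = iso_id, iso_ex = iso_ex, class = class_draw[i],
                        site_pos = site_pos, site_ex = site_ex,
                        ref = ref, alt = unname(alt))
  }
  writeLines(gtf, file.path(dir, "annotation.gtf"))

  ## ---- per-gene x sample generative state -------------------------------
  # category before SNV availability: CNL / NOT_EXPRESSED / MONO / BI
  state <- matrix("BIALLELIC", cfg$n_genes, n,
                  dimnames = list(genes, samples))
  cn_lin <- matrix(2, cfg$n_genes, n, dimnames = list(genes, samples))
  for (i in seq_len(cfg$n_genes)) {
    loss <- stats::runif(n) < cfg$fraction_copy_loss
    silent <- stats::runif(n) < cfg$fraction_silent
    p_mono <- switch(models[[i]]$class,
                     IMPRINTED = 1 - cfg$fraction_loi,
                     BASE_BIASED = cfg$biased_mono_rate,
                     BACKGROUND = cfg$background_mono_rate)
    mono <- stats::runif(n) < p_mono
    state[i, ] <- ifelse(loss, "COPY_NUMBER_LOSS",
                  ifelse(silent, "NOT_EXPRESSED",
                  ifelse(mono, "MONOALLELIC", "BIALLELIC")))
    base_cn <- 2 + stats::rnorm(n, 0, cfg$cn_noise_sd)
    base_cn <- pmax(base_cn, 1.55)  # noise never fakes a loss
    cn_lin[i, ] <- ifelse(loss, stats::runif(n, 0.4, 1.3), base_cn)
  }

  ## ---- per-site zygosity and expressed base ------------------------------
  # zygosity: 0 = hom ref (absent from WES VCF), 1 = het, 2 = hom alt
  site_zyg <- list(); site_expr_alt <- list()
  for (i in seq_len(cfg$n_genes)) {
    m <- models[[i]]
    ns <- length(m$site_pos)
    u <- matrix(stats::runif(ns * n), ns, n)
    zyg <- matrix(0L, ns, n)
    zyg[u < cfg$p_site_het] <- 1L
    zyg[u >= cfg$p_site_het &
          u < cfg$p_site_het + cfg$p_site_hom_alt] <- 2L
    # expressed base at het sites when the gene is monoallelically expressed
    expr_alt <- matrix(FALSE, ns, n)
    for (s in seq_len(n)) {
      st <- state[i, s]
      if (st == "NOT_EXPRESSED") next
      if (m$class == "BASE_BIASED" && st == "MONOALLELIC") {
        expr_alt[, s] <- stats::runif(ns) < cfg$base_bias_probability
      } else {
        # imprint-like / copy loss: expressed haplotype by parental origin;
        # phase of the alt allele is random per site, so P(alt) = 0.5
        expr_alt[, s] <- stats::runif(ns) < 0.5
      }
    }
    site_zyg[[i]] <- zyg; site_expr_alt[[i]] <- expr_alt
  }

  ## ---- expression rates and counts ---------------------------------------
  rna_rate <- matrix(stats::runif(cfg$n_genes * n, cfg$expr_rate_range[1],
                                  cfg$expr_rate_range[2]),
                     cfg$n_genes, n)
  wes_rate <- stats::runif(n, cfg$wes_rate_range[1], cfg$wes_rate_range[2])

  draw_counts <- function(mu) {
    if (cfg$count_dispersion <= 0) round(mu)
    else stats::rnbinom(length(mu), mu = mu, size = cfg$count_dispersion)
  }

  all_ex_id <- unlist(lapply(models, `[[`, "ex_id"))
  files <- list(annotation = file.path(dir, "annotation.gtf"))
  rna_counts_files <- wes_counts_files <- character(0)
  rna_vcf_files <- wes_vcf_files <- character(0)

  for (s in seq_len(n)) {
    sm <- samples[s]
    rna_cnt <- integer(0); wes_cnt <- integer(0)
    rna_rec <- list(); wes_rec <- list()
    for (i in seq_len(cfg$n_genes)) {
      m <- models[[i]]
      st <- state[i, s]
      expressed <- st != "NOT_EXPRESSED"
      mu_r <- if (expressed) rna_rate[i, s] * m$ex_len else rep(0, length(m$ex_len))
      rna_cnt <- c(rna_cnt, draw_counts(mu_r))
      wes_cnt <- c(wes_cnt, draw_counts(wes_rate[s] * m$ex_len))

      zyg <- site_zyg[[i]][, s]
      ns <- length(m$site_pos)
      if (ns) {
        het <- zyg == 1L
        if (any(het | zyg == 2L))
          wes_rec[[length(wes_rec) + 1L]] <- data.frame(
            chrom = m$chrom, pos = m$site_pos[het | zyg == 2L],
            ref = m$ref[het | zyg == 2L], alt = m$alt[het | zyg == 2L],
            gt = ifelse(het[het | zyg == 2L], "0/1", "1/1"),
            stringsAsFactors = FALSE)
        if (expressed) {
          keep <- stats::runif(ns) >= cfg$rna_dropout
          show_het <- het & keep & st == "BIALLELIC"
          mono_like <- st %in% c("MONOALLELIC", "COPY_NUMBER_LOSS")
          show_alt <- (het & keep & mono_like & site_expr_alt[[i]][, s]) |
            (zyg == 2L & keep)
          if (any(show_het | show_alt))
            rna_rec[[length(rna_rec) + 1L]] <- data.frame(
              chrom = m$chrom, pos = m$site_pos[show_het | show_alt],
              ref = m$ref[show_het | show_alt],
              alt = m$alt[show_het | show_alt],
              gt = ifelse(show_het[show_het | show_alt], "0/1", "1/1"),
              stringsAsFactors = FALSE)
        }
      }
    }
    rc <- file.path(dir, "counts", paste0(sm, ".rna.tsv"))
    wc <- file.path(dir, "counts", paste0(sm, ".wes.tsv"))
    utils::write.table(data.frame(all_ex_id, rna_cnt), rc, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(all_ex_id, wes_cnt), wc, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    rv <- file.path(dir, "vcf", paste0(sm, ".rna.vcf"))
    wv <- file.path(dir, "vcf", paste0(sm, ".wes.vcf"))
    write_sim_vcf(do.call(rbind, rna_rec), sm, rv)
    write_sim_vcf(do.call(rbind, wes_rec), sm, wv)
    rna_counts_files[sm] <- rc; wes_counts_files[sm] <- wc
    rna_vcf_files[sm] <- rv; wes_vcf_files[sm] <- wv
  }

  ## ---- copy number table (log2(cn/2 + 1) scale) --------------------------
  cn_tab <- data.frame(gene_id = genes,
                       round(log2(cn_lin / 2 + 1), 6), check.names = FALSE)
  colnames(cn_tab) <- c("gene_id", samples)
  cn_path <- file.path(dir, "copy_number.tsv")
  write_mae_table(cn_tab, cn_path)

  ## ---- drug response -----------------------------------------------------
  agents <- sprintf("agent%02d", seq_len(cfg$n_agents))
  make_drug <- function() {
    base <- stats::rnorm(cfg$n_agents, 0, 1)
    data.frame(agent = rep(agents, each = n),
               sample = rep(samples, times = cfg$n_agents),
               log_ic50 = rep(base, each = n) +
                 stats::rnorm(cfg$n_agents * n, 0, cfg$drug_noise_sd),
               stringsAsFactors = FALSE)
  }
  prism <- make_drug()
  gdsc1 <- make_drug()
  dup <- which(stats::runif(nrow(gdsc1)) < cfg$gdsc1_duplicate_fraction)
  if (length(dup)) {
    extra <- gdsc1[dup, , drop = FALSE]
    extra$log_ic50 <- extra$log_ic50 + stats::rnorm(length(dup), 0, 0.1)
    gdsc1 <- rbind(gdsc1, extra)
    gdsc1 <- gdsc1[order(gdsc1$agent, gdsc1$sample), , drop = FALSE]
  }
  prism_out <- data.frame(agent = prism$agent, sample = prism$sample,
                          ic50 = round(10^prism$log_ic50, 8))
  prism_path <- file.path(dir, "drug_prism.csv")
  utils::write.csv(prism_out, prism_path, row.names = FALSE, quote = FALSE)
  gdsc1$log_ic50 <- round(gdsc1$log_ic50, 8)
  gdsc1_path <- file.path(dir, "drug_gdsc1.tsv")
  write_mae_table(gdsc1, gdsc1_path)

  ## ---- gene list, samples, manifest --------------------------------------
  imprinted <- genes[class_draw == "IMPRINTED"]
  genelist_path <- file.path(dir, "imprinted_genes.txt")
  writeLines(imprinted, genelist_path)
  samples_path <- file.path(dir, "samples.tsv")
  write_mae_table(samples_df, samples_path)

  truth <- build_truth(models, state, site_zyg, samples)

  files <- c(files, list(
    copy_number = cn_path, drug_prism = prism_path, drug_gdsc1 = gdsc1_path,
    gene_list = genelist_path, samples = samples_path,
    rna_counts = rna_counts_files, wes_counts = wes_counts_files,
    rna_vcf = rna_vcf_files, wes_vcf = wes_vcf_files))

  manifest <- list(config = cfg[setdiff(names(cfg), "histology_weights")],
                   histology_weights = as.list(cfg$histology_weights),
                   files = lapply(files, function(f)
                     as.list(sub(paste0(dir, "/"), "", f, fixed = TRUE))))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files$manifest <- manifest_path

  structure(list(dir = dir, files = files, config = cfg,
                 samples = samples_df, gene_classes =
                   stats::setNames(class_draw, genes),
                 truth = truth),
            class = "synthetic_cohort")
}

# proportional integer allocation that always sums to n
round_quota <- function(w, n) {
  q <- floor(w * n)
  rem <- n - sum(q)
  if (rem > 0) {
    o <- order(w * n - q, decreasing = TRUE)
    q[o[seq_len(rem)]] <- q[o[seq_len(rem)]] + 1L
  }
  q
}

write_sim_vcf <- function(rec, sample_id, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", AUTOSOMES),
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  body <- character(0)
  if (!is.null(rec) && nrow(rec)) {
    o <- order(match(rec$chrom, AUTOSOMES), rec$pos)
    rec <- rec[o, , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                    rec$chrom, rec$pos, rec$ref, rec$alt, rec$gt)
  }
  writeLines(c(hdr, body), path)
}

# truth categories per feature x sample at all three levels: the generative
# state, downgraded to NO_SNV_DATA where the feature contains no WES het
# site in that sample (rule order: copy loss still wins)
build_truth <- function(models, state, site_zyg, samples) {
  n <- length(samples)
  rows <- list()
  mech_rows <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    zyg <- site_zyg[[i]]
    feats <- c(list(gene = list(id = m$gene, level = "GENE",
                                ex = seq_along(m$ex_id))),
               lapply(seq_along(m$iso_id), function(j)
                 list(id = m$iso_id[j], level = "ISOFORM", ex = m$iso_ex[[j]])),
               lapply(seq_along(m$ex_id), function(e)
                 list(id = m$ex_id[e], level = "EXON", ex = e)))
    for (f in feats) {
      in_f <- m$site_ex %in% f$ex
      het_in_f <- if (any(in_f))
        colSums(zyg[in_f, , drop = FALSE] == 1L) else rep(0L, n)
      cat <- state[i, ]
      cat[cat != "COPY_NUMBER_LOSS" & het_in_f == 0L] <- "NO_SNV_DATA"
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f$id, level = f$level, sample_id = samples,
        true_call = unname(cat), stringsAsFactors = FALSE)
    }
    if (length(m$site_pos))
      mech_rows[[length(mech_rows) + 1L]] <- data.frame(
        snv_id = paste(m$chrom, m$site_pos, m$ref, m$alt, sep = ":"),
        gene_id = m$gene,
        mechanism = switch(m$class, IMPRINTED = "IMPRINT_LIKE",
                           BASE_BIASED = "BASE_BIASED", "BIALLELIC"),
        stringsAsFactors = FALSE)
  }
  list(categories = do.call(rbind, rows),
       snv_mechanism = do.call(rbind, mech_rows))
}

#' Plant a drug-response effect for one gene's monoallelic samples
#'
#' Shifts log10(IC50) of the samples in which \code{gene_id} is truly
#' monoallelic, for one agent in one dataset, by \code{shift} (negative =
#' monoallelic arm more sensitive). Operates on a drug table already on the
#' log10 scale and records the planted truth in the returned attributes.
#'
#' @param drug_table data.frame from \code{\link{read_drug_response}}
#' @param cohort a \code{synthetic_cohort} (source of truth labels)
#' @param gene_id gene whose monoallelic samples form the affected arm
#' @param agent_id,dataset which measurements to shift
#' @param shift added to log10(IC50) of the monoallelic arm
#' @param min_per_arm error if either arm has fewer samples (default 3)
#' @return the modified drug table, with attribute \code{planted_effect}
#' @export
plant_drug_effect <- function(drug_table, cohort, gene_id, agent_id,
                              dataset, shift, min_per_arm = 3) {
  tc <- cohort$truth$categories
  g <- tc[tc$feature_id == gene_id & tc$level == "GENE", ]
  mono <- g$sample_id[g$true_call == "MONOALLELIC"]
  bi <- g$sample_id[g$true_call == "BIALLELIC"]
  if (length(mono) < min_per_arm || length(bi) < min_per_arm)
    stop("arm too small: ", length(mono), " monoallelic / ", length(bi),
         " biallelic samples for ", gene_id)
  hit <- drug_table$agent_id == agent_id & drug_table$dataset == dataset &
    drug_table$sample_id %in% mono
  drug_table$log_ic50[hit] <- drug_table$log_ic50[hit] + shift
  attr(drug_table, "planted_effect") <-
    list(gene_id = gene_id, agent_id = agent_id, dataset = dataset,
         shift = shift, mono_samples = mono)
  drug_table
}

#' Simulate flip-test counts directly from the SNV mechanisms
#'
#' Bypasses file emission to produce per-SNV (n_ref, n_alt) counts under
#' the generator's allele-expression mechanisms, for calibration checks at
#' large SNV numbers: under \code{IMPRINT_LIKE} the expressed allele is the
#' simulated parental origin (alternative base with probability 0.5), under
#' \code{BASE_BIASED} the alternative base is expressed with probability
#' \code{base_bias_probability}.
#'
#' @param n_snvs number of SNVs
#' @param n_samples samples per SNV
#' @param mechanism \code{"IMPRINT_LIKE"} or \code{"BASE_BIASED"}
#' @param base_bias_probability see \code{\link{cohort_config}}
#' @param p_informative probability a sample is informative (het and
#'   monoallelic) for a site (default 0.5)
#' @param seed integer seed
#' @return data.frame: snv_id, gene_id, n_ref, n_alt, n_other
#' @export
simulate_flip_records <- function(n_snvs, n_samples,
                                  mechanism = c("IMPRINT_LIKE",
                                                "BASE_BIASED"),
                                  base_bias_probability = 0.9,
                                  p_informative = 0.5, seed) {
  mechanism <- match.arg(mechanism)
  if (missing(seed)) stop("seed is required")
  p_alt <- if (mechanism == "IMPRINT_LIKE") 0.5 else base_bias_probability
  with_seed(seed, {
    m <- stats::rbinom(n_snvs, n_samples, p_informative)
    n_alt <- stats::rbinom(n_snvs, m, p_alt)
    data.frame(snv_id = sprintf("snv%06d", seq_len(n_snvs)),
               gene_id = sprintf("G%06d", seq_len(n_snvs)),
               n_ref = m - n_alt, n_alt = n_alt, n_other = 0L,
               stringsAsFactors = FALSE)
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_genes, "genes x",
      x$config$n_samples, "samples in", x$dir, "\n")
  print(table(x$gene_classes))
  invisible(x)
}
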