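# Shared synthetic cohorts, generated once per test run and memoised.

# noise-free cohort: deterministic counts, no CN noise, no hom-alt sites —
# the classifier must recover the generative truth exactly
noise_free_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_samples = 12, n_genes = 30, seed = 4242,
                           count_dispersion = 0, cn_noise_sd = 0,
                           p_site_hom_alt = 0)
      co <- generate_cohort(cfg, dir = file.path(tempdir(), "co_nf"))
      cache <<- list(cohort = co, ingested = ingest_cohort(co$dir))
    }
    cache
  }
})

# larger clean cohort for flip / association tests: every gene informative
flip_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_samples = 30, n_genes = 40, seed = 77,
                           count_dispersion = 0, cn_noise_sd = 0,
                           p_site_hom_alt = 0, fraction_copy_loss = 0,
                           fraction_silent = 0)
      co <- generate_cohort(cfg, dir = file.path(tempdir(), "co_flip"))
      ing <- ingest_cohort(co$dir)
      cache <<- list(cohort = co, ingested = ing,
                     gene_calls = classify_cohort(ing, "GENE"),
                     iso_calls = classify_cohort(ing, "ISOFORM"))
    }
    cache
  }
})

isoform_expression <- function(ing) {
  do.call(rbind, lapply(names(ing$rna_counts), function(s)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          aggregate_expression(ing$rna_counts[[s]], ing$catalog, "ISOFORM"))))
}

# null drug table: independent normal log10(IC50), no association with
# anything in the cohort
null_drug_table <- function(samples, n_agents, seed, dataset = "PRISM") {
  with_seed <- maecall:::with_seed
  with_seed(seed, {
    data.frame(agent_id = rep(sprintf("a%03d", seq_len(n_agents)),
                              each = length(samples)),
               dataset = dataset,
               sample_id = rep(samples, times = n_agents),
               log_ic50 = stats::rnorm(n_agents * length(samples)),
               stringsAsFactors = FALSE)
  })
}
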