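# Shared fixture builders; everything is generated in code under fixed seeds.

# small mosaic locus with paired diploids
toy_locus <- function(n_samples = 200, n_sites = 60, seed = 1L, ...) {
  cfg <- scenario_config(n_samples = n_samples, n_sites = n_sites,
                         seed = seed, ...)
  panel <- suppressMessages(build_panel_mosaic(cfg))
  data <- pair_into_diploids(panel, n_samples, seed = seed + 1000L)
  list(panel = panel, data = data, config = cfg)
}

# dataset built directly from a dosage matrix (positions = 1000, 2000, ...)
manual_dataset <- function(dosages, ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(ids)) ids <- colnames(dosages)
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  geno_dataset(dosages,
               sample_ids = paste0("ind", seq_len(nrow(dosages))),
               site_ids = ids, positions = seq_len(m) * 1000)
}

# truth locus + single causal + phenotype, for credible-set tests
causal_locus <- function(n_samples = 400, n_sites = 80, h2 = 0.2,
                         seed = 1L) {
  tl <- toy_locus(n_samples, n_sites, seed = seed)
  causal <- choose_causal_site(tl$data, seed = seed + 1L)
  pheno <- simulate_phenotype(tl$data, causal, h2, seed = seed + 2L)
  c(tl, list(causal = causal, pheno = pheno))
}
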