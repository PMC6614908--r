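#' Coverage and set-size summary of credible sets
#'
#' Scores a collection of credible sets against the simulation truth:
#' coverage is the fraction of sets containing their causal site, and the
#' set-size summaries mirror the usual reporting (mean, median, and the 95%
#' quantile by the nearest-rank convention). A causal id absent from a set's
#' analyzed site list (e.g. removed by imputation QC) simply counts as
#' non-covered.
#'
#' @param sets list of [credible_set()] objects (one per locus/replicate).
#' @param causal_ids character vector of true causal site ids, parallel to
#'   `sets`.
#' @param causal_positions,top_positions optional parallel numeric vectors of
#'   base-pair positions of the causal site and each set's top site; when both
#'   are given the mean top-SNP distance is reported.
#' @param label optional label for the dataset arm.
#' @return a one-row `coverage_report` data frame: `arm`, `method`, `n_loci`,
#'   `coverage`, `mean_set_size`, `median_set_size`, `q95_set_size`,
#'   `mean_top_snp_distance_bp`.
#' @export
coverage <- function(sets, causal_ids, causal_positions = NULL,
                     top_positions = NULL, label = NA_character_) {
  if (length(sets) != length(causal_ids)) {
    stop("coverage: every set must be paired with a truth record")
  }
  hit <- mapply(function(s, causal) causal %in% s$members, sets, causal_ids)
  sizes <- vapply(sets, function(s) length(s$members), numeric(1))
  methods <- unique(vapply(sets, function(s) s$method, character(1)))
  dist <- NA_real_
  if (!is.null(causal_positions) && !is.null(top_positions)) {
    dist <- mean(abs(top_positions - causal_positions), na.rm = TRUE)
  }
  out <- data.frame(
    arm = label,
    method = paste(methods, collapse = "+"),
    n_loci = length(sets),
    coverage = mean(hit),
    mean_set_size = mean(sizes),
    median_set_size = stats::median(sizes),
    q95_set_size = nearest_rank_quantile(sizes, 0.95),
    mean_top_snp_distance_bp = dist,
    stringsAsFactors = FALSE)
  class(out) <- c("coverage_report", "data.frame")
  out
}

# nearest-rank empirical quantile: the ceil(q*n)-th order statistic
nearest_rank_quantile <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

#' Coverage stratified by causal-site provenance
#'
#' Splits the loci by whether the causal site was directly genotyped or
#' imputed and reports coverage within each stratum. An empty stratum yields
#' a row with `n_loci = 0` and `NA` coverage.
#'
#' @param sets list of [credible_set()] objects.
#' @param causal_ids parallel character vector of causal site ids.
#' @param genotyped parallel logical vector: `TRUE` where the causal site was
#'   genotyped on the array.
#' @param label optional arm label.
#' @return a two-row `coverage_report` data frame (strata `genotyped`,
#'   `imputed` recorded in a `stratum` column).
#' @export
stratify_by_provenance <- function(sets, causal_ids, genotyped,
                                   label = NA_character_) {
  if (length(sets) != length(causal_ids) ||
      length(sets) != length(genotyped)) {
    stop("stratify_by_provenance: inputs must be parallel")
  }
  one <- function(keep, name) {
    if (!any(keep)) {
      row <- data.frame(arm = label, method = NA_character_, n_loci = 0L,
                        coverage = NA_real_, mean_set_size = NA_real_,
                        median_set_size = NA_real_, q95_set_size = NA_real_,
                        mean_top_snp_distance_bp = NA_real_,
                        stringsAsFactors = FALSE)
    } else {
      row <- coverage(sets[keep], causal_ids[keep], label = label)
    }
    row$stratum <- name
    row
  }
  out <- rbind(one(genotyped, "genotyped"), one(!genotyped, "imputed"))
  class(out) <- c("coverage_report", "data.frame")
  out
}

#' Variance explained by the causal site across dataset arms
#'
#' Regresses the phenotype on the causal site's dosages within each arm and
#' reports the regression r-squared -- dosage error attenuates this roughly
#' by the squared correlation between imputed and true dosage, so imputed
#' arms fall below the sequence arm.
#'
#' @param arms named list of [geno_dataset()] objects.
#' @param y phenotype (`pheno_sim` or numeric).
#' @param causal_id the causal site id.
#' @return named numeric vector of per-arm r-squared (NA, with a warning,
#'   where the causal site is absent from an arm).
#' @export
variance_explained_comparison <- function(arms, y, causal_id) {
  y <- as_pheno_values(y)
  vapply(arms, function(arm) {
    if (!causal_id %in% arm$sites$id) {
      warning("variance_explained_comparison: causal site ", causal_id,
              " missing from an arm (QC casualty)")
      return(NA_real_)
    }
    x <- site_dosage(arm, causal_id)
    if (stats::sd(x) <= 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
}
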