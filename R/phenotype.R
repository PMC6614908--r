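#' Simulate an additive quantitative phenotype
#'
#' Generates a methylation-like trait under the standard additive model
#' `y = sum_c X_c beta_c + e`, with per-causal effect sizes drawn from N(0, 1)
#' (unless supplied) and environmental noise `e ~ N(0, sigma_e^2)` scaled so
#' that the population-level fraction of variance attributable to the genetic
#' values equals `h2_target`. The genetic variance is computed from the
#' empirical covariance of the causal dosage columns, so causal sites in LD
#' are handled exactly. With a single causal variant the narrow-sense
#' heritability equals the variance explained by that variant.
#'
#' @param truth a [geno_dataset()] holding the generating (true) genotypes.
#' @param causal_ids site ids of the causal variants.
#' @param h2_target narrow-sense heritability in [0, 1). `h2_target = 0`
#'   yields pure N(0, 1) noise.
#' @param seed integer seed.
#' @param betas optional fixed effect sizes (default: N(0, 1) draws).
#' @param causal_maf_min minimum minor-allele frequency required of each
#'   causal site (default 0.05).
#' @return An object of class `pheno_sim`: list with `values` (length-N trait
#'   vector), `causal_ids`, `true_betas`, `h2_target`, `seed`.
#' @export
simulate_phenotype <- function(truth, causal_ids, h2_target, seed = 1L,
                               betas = NULL, causal_maf_min = 0.05) {
  if (h2_target < 0 || h2_target >= 1) {
    stop("simulate_phenotype: h2_target must lie in [0, 1)")
  }
  n <- nrow(truth$dosages)
  set.seed(seed)
  if (h2_target > 0 && !length(causal_ids)) {
    stop("simulate_phenotype: h2_target > 0 requires causal sites")
  }
  if (length(causal_ids)) {
    j <- site_index(truth, causal_ids)
    maf <- truth$sites$maf[j]
    if (any(maf < causal_maf_min)) {
      stop("simulate_phenotype: causal site(s) below causal_maf_min: ",
           paste(causal_ids[maf < causal_maf_min], collapse = ", "))
    }
    if (is.null(betas)) betas <- stats::rnorm(length(j))
    if (length(betas) != length(j)) {
      stop("simulate_phenotype: one beta per causal site")
    }
  } else {
    betas <- numeric(0)
  }

  if (h2_target == 0) {
    y <- stats::rnorm(n)
  } else {
    xc <- truth$dosages[, site_index(truth, causal_ids), drop = FALSE]
    g <- drop(xc %*% betas)
    # population-level genetic variance: beta' Sigma beta with Sigma the
    # empirical covariance of the causal dosages (exact under LD)
    sigma <- stats::cov(xc) * (n - 1) / n
    var_g <- drop(t(betas) %*% sigma %*% betas)
    if (var_g <= 0) {
      stop("simulate_phenotype: degenerate causal configuration (zero ",
           "genetic variance)")
    }
    sigma_e <- sqrt(var_g * (1 - h2_target) / h2_target)
    y <- g + stats::rnorm(n, 0, sigma_e)
  }

  structure(list(values = y,
                 causal_ids = as.character(causal_ids),
                 true_betas = betas,
                 h2_target = h2_target,
                 seed = as.integer(seed)),
            class = "pheno_sim")
}

#' @export
print.pheno_sim <- function(x, ...) {
  cat(sprintf("<pheno_sim> n = %d, h2 = %g, causal: %s\n",
              length(x$values), x$h2_target,
              paste(x$causal_ids, collapse = ", ")))
  invisible(x)
}

as_pheno_values <- function(y) {
  if (inherits(y, "pheno_sim")) y$values else as.numeric(y)
}

#' Build a two-causal masking locus
#'
#' Constructs the haplotype configuration under which a non-causal-candidate
#' "top SNP" masks the causal CpG-SNP: three two-locus haplotypes
#' (top-major/cpg-major, top-minor/cpg-major, top-minor/cpg-minor), so every
#' CpG minor allele rides on a top-SNP minor haplotype (D' = 1, r-squared
#' < 1) and the top SNP, at higher frequency and with an additional
#' trait-lowering effect of its own, explains more phenotypic variance than
#' the CpG-SNP. A few unlinked neutral sites pad the locus.
#'
#' @param n_samples number of diploid samples.
#' @param maf_cpg minor-allele frequency of the CpG-SNP.
#' @param maf_top minor-allele frequency of the top SNP (must exceed
#'   `maf_cpg`).
#' @param effect_cpg,effect_top effect-size magnitudes; both are applied with
#'   a negative (methylation-lowering) sign.
#' @param h2_target total heritability of the two-causal trait.
#' @param n_neutral number of unlinked neutral padding sites.
#' @param seed integer seed.
#' @return list with elements `data` (a [geno_dataset()]; sites `top_snp` and
#'   `cpg_snp` plus neutral sites), `pheno` (a `pheno_sim`), `panel`.
#' @export
build_masking_scenario <- function(n_samples = 1366, maf_cpg = 0.15,
                                   maf_top = 0.30, effect_cpg = 0.5,
                                   effect_top = 1.0, h2_target = 0.2,
                                   n_neutral = 8, seed = 1L) {
  if (maf_top <= maf_cpg) {
    stop("build_masking_scenario: maf_top must exceed maf_cpg ",
         "(masking impossible otherwise)")
  }
  if (sign(effect_cpg) * sign(effect_top) < 0) {
    stop("build_masking_scenario: effects must have the same sign")
  }
  set.seed(seed)
  h <- 2L * n_samples
  # columns: top SNP, CpG-SNP; the {top-major, cpg-minor} haplotype is absent
  pair_haps <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  pair_freqs <- c(1 - maf_top, maf_top - maf_cpg, maf_cpg)
  pair_panel <- build_panel_from_haplotype_table(
    pair_haps, pair_freqs, h, mode = "exact", seed = seed + 1L)

  neutral <- matrix(stats::rbinom(h * n_neutral, 1L,
                                  rep(stats::runif(n_neutral, 0.1, 0.4),
                                      each = h)),
                    nrow = h)
  af <- colMeans(neutral)
  neutral[, af <= 0] <- sample(c(0L, 1L), h, replace = TRUE)  # degenerate guard
  half <- ceiling(n_neutral / 2)
  alleles <- cbind(neutral[, seq_len(half), drop = FALSE],
                   pair_panel$alleles,
                   neutral[, setdiff(seq_len(n_neutral), seq_len(half)),
                           drop = FALSE])
  m <- ncol(alleles)
  ids <- character(m)
  ids[half + 1] <- "top_snp"
  ids[half + 2] <- "cpg_snp"
  ids[ids == ""] <- paste0("neutral", seq_len(m - 2))
  panel <- hap_panel(alleles, seq_len(m) * 1000, ids)

  data <- pair_into_diploids(panel, n_samples, seed = seed + 2L)
  pheno <- simulate_phenotype(
    data, causal_ids = c("cpg_snp", "top_snp"), h2_target = h2_target,
    seed = seed + 3L,
    betas = c(-abs(effect_cpg), -abs(effect_top)),
    causal_maf_min = 0)
  list(data = data, pheno = pheno, panel = panel)
}
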