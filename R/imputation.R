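#' Restrict a dataset to the sites present on a genotyping array
#'
#' Emulates array genotyping of a sequenced population: only the listed sites
#' are retained, all flagged as directly genotyped. The phased haplotypes of
#' the samples (when carried by the dataset) are restricted alongside, which
#' is what the imputation emulator consumes.
#'
#' @param truth a [geno_dataset()] holding the full (true) site set.
#' @param array_site_ids character vector of site ids on the array; must be a
#'   non-empty subset of `truth`'s site ids.
#' @return a [geno_dataset()] over the array sites only.
#' @export
mask_to_array <- function(truth, array_site_ids) {
  if (!length(array_site_ids)) {
    stop("mask_to_array: empty array site set -- nothing to impute from")
  }
  unknown <- setdiff(array_site_ids, truth$sites$id)
  if (length(unknown)) {
    stop("mask_to_array: unknown site id(s): ",
         paste(unknown, collapse = ", "))
  }
  out <- subset_sites(truth, array_site_ids)
  out$sites$genotyped <- TRUE
  out$sites$info <- 1
  out
}

#' Impute masked sites by Li-Stephens haplotype copying
#'
#' Runs a haplotype-copying hidden Markov model for each target haplotype over
#' the reference panel: the hidden state is the reference haplotype being
#' copied, transitions switch to a uniformly chosen reference haplotype with
#' probability `1 - exp(-switch_rate * distance)` between adjacent sites, and
#' the observed array-site alleles are emitted with error `mismatch_rate`.
#' Posterior-mean alleles from the forward-backward recursion are summed over
#' a sample's two haplotypes to give dosages on all reference sites. Array
#' sites keep their hard dosages (info = 1); imputed sites carry the
#' IMPUTE-style [info_score()]. The target's true phase is used directly
#' (phasing error is deliberately excluded so reference-panel quality is the
#' only imputation knob).
#'
#' @param array_data a [geno_dataset()] produced by [mask_to_array()] (must
#'   carry the phased-haplotype attribute).
#' @param reference a [hap_panel()] with >= 4 haplotypes covering all array
#'   sites (imputation output spans all reference sites).
#' @param mismatch_rate allele-copying error probability at observed sites.
#' @param switch_rate copying-switch rate per base pair.
#' @return a [geno_dataset()] over all reference sites. Deterministic.
#' @export
impute_li_stephens <- function(array_data, reference,
                               mismatch_rate = 0.01, switch_rate = 1e-5) {
  haps <- attr(array_data, "haplotypes")
  if (is.null(haps)) {
    stop("impute_li_stephens: array_data does not carry phased haplotypes")
  }
  if (nrow(reference$alleles) < 4) {
    stop("impute_li_stephens: reference must hold at least 4 haplotypes")
  }
  array_idx <- match(array_data$sites$id, reference$site_ids)
  if (anyNA(array_idx)) {
    stop("impute_li_stephens: array site(s) absent from the reference: ",
         paste(array_data$sites$id[is.na(array_idx)], collapse = ", "))
  }
  m <- ncol(reference$alleles)
  rho <- 1 - exp(-switch_rate * diff(reference$positions))
  post <- ls_posterior_allele(reference$alleles, haps,
                              as.integer(array_idx), rho, mismatch_rate)
  n <- nrow(array_data$dosages)
  odd <- seq(1, 2 * n, by = 2)
  dosages <- post[odd, , drop = FALSE] + post[odd + 1, , drop = FALSE]

  genotyped <- rep(FALSE, m)
  genotyped[array_idx] <- TRUE
  dosages[, array_idx] <- array_data$dosages

  info <- vapply(seq_len(m), function(j) {
    if (genotyped[j]) return(1)
    p <- mean(dosages[, j]) / 2
    if (p <= 0 || p >= 1) return(NA_real_)
    info_score(dosages[, j], p)
  }, numeric(1))

  geno_dataset(pmin(pmax(dosages, 0), 2),
               array_data$sample_ids,
               reference$site_ids, reference$positions,
               genotyped = genotyped, info = info)
}

#' IMPUTE-style imputation info score
#'
#' Ratio of the observed dosage variance at a site (maximum-likelihood
#' variance, i.e. with denominator n) to the variance expected under
#' Hardy-Weinberg equilibrium, `2p(1-p)`, clipped to [0, 1]. Hard genotypes
#' at HWE give a score near 1; dosages collapsed to the prior mean `2p`
#' give 0.
#'
#' @param dosages numeric vector of dosages in [0, 2] at one site.
#' @param allele_freq the site's alternate-allele frequency, in (0, 1).
#' @return a score in [0, 1], or `NA` for a monomorphic site (treated as a QC
#'   failure downstream).
#' @export
info_score <- function(dosages, allele_freq) {
  if (is.na(allele_freq) || allele_freq <= 0 || allele_freq >= 1) {
    return(NA_real_)
  }
  d <- dosages[!is.na(dosages)]
  v_obs <- mean((d - mean(d))^2)
  v_exp <- 2 * allele_freq * (1 - allele_freq)
  min(max(v_obs / v_exp, 0), 1)
}

#' Hardy-Weinberg exact test
#'
#' Exact (Wigginton-style) two-sided test on genotype counts: the p-value is
#' the total probability of heterozygote counts no more likely than the
#' observed one, conditional on the allele counts.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  if (n == 0) return(1)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # unnormalized probabilities via the standard recurrence
  logp <- numeric(length(hets))
  mid <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n - 1)))
  logp[mid] <- 0
  if (mid < length(hets)) {
    for (i in (mid + 1):length(hets)) {
      h <- hets[i - 1]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h+2) = P(h) * 4 * hom_r * hom_c / ((h+2)*(h+1))
      logp[i] <- logp[i - 1] +
        log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in (mid - 1):1) {
      h <- hets[i + 1]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h-2) = P(h) * h*(h-1) / (4*(hom_r+1)*(hom_c+1))
      logp[i] <- logp[i + 1] +
        log(h * (h - 1)) - log(4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  if (!length(obs)) return(1)  # inconsistent counts
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Quality-control thresholds
#'
#' The standard post-imputation filters: minimum minor-allele frequency,
#' Hardy-Weinberg exact-test floor, maximum per-site missingness, and minimum
#' imputation info score (the stringent 0.8 default, with 0.3 as the common
#' lenient alternative).
#'
#' @param maf_min minimum minor-allele frequency (sites below are removed).
#' @param hwe_p_min minimum HWE exact-test p-value.
#' @param max_missing maximum per-site missing fraction (0.05 array
#'   convention; 0.10 for sequence data).
#' @param info_min minimum imputation info score.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, hwe_p_min = 1e-6,
                      max_missing = 0.05, info_min = 0.8) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            hwe_p_min >= 0, hwe_p_min <= 1,
            max_missing >= 0, max_missing <= 1,
            info_min >= 0, info_min <= 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 max_missing = max_missing, info_min = info_min),
            class = "qc_config")
}

#' Apply quality-control filters to a genotype dataset
#'
#' Removes sites failing any of the [qc_config()] thresholds. HWE is tested
#' by the exact test on hard-called genotypes (dosages rounded to the nearest
#' integer); undefined info scores (monomorphic sites) fail the info filter.
#' The surviving set is independent of the order in which filters are applied.
#' A removal log (per-filter counts and site ids) is attached as attribute
#' `"qc_log"` and retrievable with [qc_log()].
#'
#' @param data a [geno_dataset()].
#' @param qc a [qc_config()].
#' @return the filtered [geno_dataset()]; errors if no site survives.
#' @export
apply_qc <- function(data, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  g <- round(data$dosages)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j][!is.na(g[, j])]
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  data$sites$hwe_p <- hwe_p

  fail_maf <- data$sites$maf < qc$maf_min | is.na(data$sites$maf)
  fail_hwe <- hwe_p < qc$hwe_p_min
  fail_missing <- data$sites$missing_rate > qc$max_missing
  fail_info <- is.na(data$sites$info) | data$sites$info < qc$info_min
  fail <- fail_maf | fail_hwe | fail_missing | fail_info
  if (all(fail)) {
    stop("apply_qc: all sites removed -- fine-mapping impossible")
  }
  log <- data.frame(
    filter = c("maf", "hwe", "missing", "info"),
    threshold = c(qc$maf_min, qc$hwe_p_min, qc$max_missing, qc$info_min),
    n_removed = c(sum(fail_maf), sum(fail_hwe), sum(fail_missing),
                  sum(fail_info)),
    stringsAsFactors = FALSE)
  out <- subset_sites(data, which(!fail))
  out$sites$hwe_p <- hwe_p[!fail]
  attr(out, "qc_log") <- list(summary = log,
                              removed = data$sites$id[fail])
  out
}

#' @rdname apply_qc
#' @export
qc_log <- function(data) attr(data, "qc_log")

#' Restrict datasets to their shared sites
#'
#' The fair-comparison step: all dataset arms are cut down to the intersection
#' of their surviving site lists, keeping each arm's own dosages.
#'
#' @param ... two or more [geno_dataset()] objects (or a single list of them).
#' @return a list of [geno_dataset()]s with identical site lists.
#' @export
intersect_datasets <- function(...) {
  arms <- list(...)
  if (length(arms) == 1 && is.list(arms[[1]]) &&
      !inherits(arms[[1]], "geno_dataset")) {
    arms <- arms[[1]]
  }
  if (length(arms) < 2) stop("intersect_datasets: need at least 2 datasets")
  shared <- Reduce(intersect, lapply(arms, function(a) a$sites$id))
  if (!length(shared)) stop("intersect_datasets: empty site intersection")
  lapply(arms, subset_sites, sites = shared)
}
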