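#' Single-SNP association scan
#'
#' Ordinary least-squares regression of the phenotype on each site's dosage in
#' turn (`y = mu + X_j b_j + e`). Sites are ranked by strength of association:
#' ascending p-value, ties broken by descending |t| and then by position.
#' Zero-variance sites are flagged `excluded` and left out of the ranking.
#'
#' @param data a [geno_dataset()].
#' @param y a `pheno_sim` or numeric phenotype vector (length = samples).
#' @return An `assoc_result` data frame with columns `site`, `position`,
#'   `beta`, `se`, `t_stat`, `p_value`, `r2`, `mu`, `n_used`, `excluded`;
#'   attribute `"ranking"` holds the ordered site ids.
#' @export
assoc_scan <- function(data, y) {
  y <- as_pheno_values(y)
  x <- data$dosages
  n <- nrow(x)
  if (length(y) != n) stop("assoc_scan: phenotype length != sample count")
  if (n < 3) stop("assoc_scan: need at least 3 samples")

  yc <- y - mean(y)
  syy <- sum(yc^2)
  xm <- colMeans(x)
  sxx <- colSums(x^2) - n * xm^2
  sxy <- drop(crossprod(x, yc))

  excluded <- sxx <= 1e-12
  beta <- ifelse(excluded, NA_real_, sxy / sxx)
  sse <- pmax(syy - beta * sxy, 0)
  df <- n - 2
  se <- sqrt(sse / (df * sxx))
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  r2 <- ifelse(excluded | syy <= 0, NA_real_, (sxy^2) / (sxx * syy))
  mu <- mean(y) - beta * xm

  res <- data.frame(site = data$sites$id,
                    position = data$sites$position,
                    beta = beta, se = se, t_stat = t_stat, p_value = p,
                    r2 = r2, mu = mu, n_used = n,
                    excluded = excluded,
                    stringsAsFactors = FALSE)
  ord <- order(res$p_value, -abs(res$t_stat), res$position)
  ord <- ord[!res$excluded[ord]]
  attr(res, "ranking") <- res$site[ord]
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Conditional association scan
#'
#' For each site not in the conditioned set, fits the multiple regression of
#' the phenotype on that site plus all conditioned sites and reports the
#' site's conditional test. Implemented by residualizing the phenotype and
#' the candidate dosages on the conditioned design (equivalent to the joint
#' fit, with the correct residual degrees of freedom). With an empty
#' conditioned set this reduces exactly to [assoc_scan()].
#'
#' @param data a [geno_dataset()].
#' @param y phenotype (`pheno_sim` or numeric).
#' @param condition_ids site ids to condition on (may be empty).
#' @param collinearity_cap maximum pairwise r-squared tolerated within the
#'   conditioned set (default 0.9); an offending pair raises an error naming
#'   it.
#' @return an `assoc_result` data frame over the unconditioned sites;
#'   attribute `"conditioned"` holds `condition_ids`.
#' @export
conditional_regression <- function(data, y, condition_ids = character(0),
                                   collinearity_cap = 0.9) {
  if (!length(condition_ids)) return(assoc_scan(data, y))
  y <- as_pheno_values(y)
  jc <- site_index(data, condition_ids)
  xc <- data$dosages[, jc, drop = FALSE]
  if (length(jc) > 1) {
    cc <- stats::cor(xc)^2
    diag(cc) <- 0
    if (any(cc >= collinearity_cap, na.rm = TRUE)) {
      w <- which(cc >= collinearity_cap, arr.ind = TRUE)[1, ]
      stop("conditional_regression: conditioned sites are collinear: ",
           condition_ids[w[1]], " ~ ", condition_ids[w[2]])
    }
  }
  n <- nrow(data$dosages)
  qrc <- qr(cbind(1, xc))
  ry <- qr.resid(qrc, y)
  keep <- setdiff(seq_len(ncol(data$dosages)), jc)
  rx <- qr.resid(qrc, data$dosages[, keep, drop = FALSE])

  syy <- sum(ry^2)
  sxx <- colSums(rx^2)
  sxy <- drop(crossprod(rx, ry))
  df <- n - 2 - length(jc)
  excluded <- sxx <= 1e-10
  beta <- ifelse(excluded, NA_real_, sxy / sxx)
  sse <- pmax(syy - beta * sxy, 0)
  se <- sqrt(sse / (df * sxx))
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  r2 <- ifelse(excluded | syy <= 0, NA_real_, (sxy^2) / (sxx * syy))

  res <- data.frame(site = data$sites$id[keep],
                    position = data$sites$position[keep],
                    beta = beta, se = se, t_stat = t_stat, p_value = p,
                    r2 = r2, mu = NA_real_, n_used = n,
                    excluded = excluded,
                    stringsAsFactors = FALSE)
  ord <- order(res$p_value, -abs(res$t_stat), res$position)
  ord <- ord[!res$excluded[ord]]
  attr(res, "ranking") <- res$site[ord]
  attr(res, "conditioned") <- as.character(condition_ids)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Two-locus linkage disequilibrium metrics
#'
#' Computes the raw coefficient `D = p_AB - p_A p_B`, the normalized
#' `D' = |D| / D_max`, and the squared correlation
#' `r^2 = D^2 / (p_A q_A p_B q_B)`. From a phased [hap_panel()] the two-locus
#' haplotype frequencies are counted directly; from a [geno_dataset()] they
#' are estimated by the usual EM algorithm on hard-called (rounded) genotypes,
#' started at linkage equilibrium and run to convergence (delta < 1e-12) or
#' 100 iterations. `D' = 1` with `r^2 < 1` flags a missing haplotype class
#' with unequal allele frequencies -- the masking configuration.
#'
#' @param x a [hap_panel()] or [geno_dataset()].
#' @param site_a,site_b site ids (or indices).
#' @return An `ld_stats` list: `d`, `d_prime`, `r2`, `hap_freqs` (named
#'   `AB`, `Ab`, `aB`, `ab`, where `A`/`B` denote the alternate alleles).
#' @export
ld_metrics <- function(x, site_a, site_b) {
  if (inherits(x, "hap_panel")) {
    ja <- if (is.character(site_a)) match(site_a, x$site_ids) else site_a
    jb <- if (is.character(site_b)) match(site_b, x$site_ids) else site_b
    if (is.na(ja) || is.na(jb)) stop("ld_metrics: unknown site id")
    a <- x$alleles[, ja]; b <- x$alleles[, jb]
    if (length(unique(a)) < 2 || length(unique(b)) < 2) {
      stop("ld_metrics: monomorphic site")
    }
    hf <- c(AB = mean(a == 1 & b == 1), Ab = mean(a == 1 & b == 0),
            aB = mean(a == 0 & b == 1), ab = mean(a == 0 & b == 0))
  } else {
    ga <- round(site_dosage(x, site_a))
    gb <- round(site_dosage(x, site_b))
    ok <- !is.na(ga) & !is.na(gb)
    ga <- ga[ok]; gb <- gb[ok]
    if (stats::var(ga) <= 0 || stats::var(gb) <= 0) {
      stop("ld_metrics: monomorphic site")
    }
    hf <- em_hap_freqs(ga, gb)
  }
  ld_from_hap_freqs(hf)
}

ld_from_hap_freqs <- function(hf) {
  pa <- hf[["AB"]] + hf[["Ab"]]
  pb <- hf[["AB"]] + hf[["aB"]]
  d <- hf[["AB"]] - pa * pb
  d_max <- if (d >= 0) {
    min(pa * (1 - pb), (1 - pa) * pb)
  } else {
    min(pa * pb, (1 - pa) * (1 - pb))
  }
  d_prime <- if (d_max <= 0) 0 else min(abs(d) / d_max, 1)
  denom <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- if (denom <= 0) NA_real_ else min(d^2 / denom, 1)
  structure(list(d = d, d_prime = d_prime, r2 = r2, hap_freqs = hf),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("<ld_stats> D = %.4f, D' = %.3f, r2 = %.3f\n",
              x$d, x$d_prime, x$r2))
  invisible(x)
}

# EM estimation of two-locus haplotype frequencies from unphased genotypes
em_hap_freqs <- function(ga, gb, max_iter = 100, tol = 1e-12) {
  n <- length(ga)
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  # start at linkage equilibrium
  f <- c(AB = pa * pb, Ab = pa * (1 - pb), aB = (1 - pa) * pb,
         ab = (1 - pa) * (1 - pb))
  dh <- ga == 1 & gb == 1  # double heterozygotes: ambiguous phase
  n_dh <- sum(dh)
  # fixed haplotype counts from unambiguous genotypes (per individual: 2 haps)
  base <- c(
    AB = sum(ga[!dh] * gb[!dh]) / 2,
    Ab = sum(ga[!dh] * (2 - gb[!dh])) / 2,
    aB = sum((2 - ga[!dh]) * gb[!dh]) / 2,
    ab = sum((2 - ga[!dh]) * (2 - gb[!dh])) / 2)
  for (it in seq_len(max_iter)) {
    num <- f[["AB"]] * f[["ab"]]
    den <- num + f[["Ab"]] * f[["aB"]]
    w <- if (den > 0) num / den else 0.5  # P(coupling | double het)
    cnt <- base + n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    f_new <- cnt / (2 * n)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  f
}

#' Group sites in complete linkage disequilibrium
#'
#' Complete LD is read as squared dosage correlation r^2 = 1 (within 1e-9) on
#' the analyzed dataset, which includes allele-flipped perfect proxies. Used
#' by the credible-set constructors: only one member of each group is tested
#' or sampled, and group members share the representative's fate/counts.
#'
#' @param data a [geno_dataset()].
#' @return integer vector of group ids (one per site); attribute
#'   `"representative"` marks the member of lowest position chosen to stand
#'   for each group; zero-variance sites get group id `NA`.
#' @export
complete_ld_groups <- function(data) {
  x <- data$dosages
  m <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  ok <- which(sds > 0)
  grp <- rep(NA_integer_, m)
  if (length(ok)) {
    cc <- suppressWarnings(stats::cor(x[, ok, drop = FALSE]))
    cc[is.na(cc)] <- 0
    dup <- abs(cc) >= 1 - 1e-9
    assigned <- rep(FALSE, length(ok))
    g <- 0L
    for (i in seq_along(ok)) {
      if (assigned[i]) next
      g <- g + 1L
      members <- which(dup[i, ] & !assigned)
      grp[ok[members]] <- g
      assigned[members] <- TRUE
    }
  }
  rep_flag <- rep(FALSE, m)
  for (g in unique(grp[!is.na(grp)])) {
    members <- which(grp == g)
    rep_flag[members[which.min(data$sites$position[members])]] <- TRUE
  }
  attr(grp, "representative") <- rep_flag
  grp
}
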