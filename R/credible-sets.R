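#' Credible set container
#'
#' A method-tagged minimal set of sites constructed to contain the causal
#' variant with the nominal probability. `evidence` stores the per-member
#' scalar the method ranks by: the marginal p-value for the J-test, the
#' posterior probability of association for the Bayes-factor method, and the
#' MCMC top-variant count for the sampler-based method.
#'
#' @param method one of `"jtest"`, `"ppa"`, `"mcmc_count"`.
#' @param level nominal probability (default 0.95).
#' @param members ordered character vector of site ids (non-empty).
#' @param evidence numeric vector parallel to `members`.
#' @param top_site the most associated site (always a member).
#' @return An object of class `credible_set`.
#' @export
credible_set <- function(method, level, members, evidence, top_site = NULL) {
  method <- match.arg(method, c("jtest", "ppa", "mcmc_count"))
  if (!length(members)) stop("credible_set: members must be non-empty")
  if (length(evidence) != length(members)) {
    stop("credible_set: evidence must parallel members")
  }
  structure(list(method = method, level = level,
                 members = as.character(members),
                 evidence = stats::setNames(as.numeric(evidence),
                                            as.character(members)),
                 top_site = top_site),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("<credible_set:%s> level %.2f, %d member(s): %s\n",
              x$method, x$level, length(x$members),
              paste(utils::head(x$members, 8), collapse = ", ")))
  invisible(x)
}

#' @export
length.credible_set <- function(x) length(x$members)

#' J-test confidence set
#'
#' Builds a confidence set by testing whether the top SNP explains
#' significantly more phenotypic variance than each lower-ranked rival.
#' Sites are ranked by strength of association; the top SNP enters the set
#' and is regressed on the phenotype; then for N = 2, 3, ... the phenotype is
#' regressed on the Nth-ranked SNP with the top-SNP fitted values as a
#' covariate. If the fitted-values coefficient `lambda_N` is significant at
#' the Bonferroni-corrected level `alpha / (N - 1)`, iteration stops (SNP N
#' and all worse-ranked SNPs are excluded); otherwise SNP N joins the set.
#' Sites in complete LD are represented by one member: a single test is
#' performed and all partners share its outcome.
#'
#' @param data a [geno_dataset()].
#' @param y phenotype (`pheno_sim` or numeric).
#' @param alpha nominal test size (default 0.05, i.e. a 95% set).
#' @return a [credible_set()] with `method = "jtest"`; evidence = marginal
#'   p-values.
#' @export
jtest_credible_set <- function(data, y, alpha = 0.05) {
  y <- as_pheno_values(y)
  scan <- assoc_scan(data, y)
  ranking <- attr(scan, "ranking")
  if (!length(ranking)) stop("jtest_credible_set: no polymorphic sites")
  grp <- complete_ld_groups(data)
  names(grp) <- data$sites$id
  is_rep <- stats::setNames(attr(grp, "representative"), data$sites$id)
  reps <- ranking[is_rep[ranking]]

  marg_p <- stats::setNames(scan$p_value, scan$site)
  group_members <- function(id) {
    g <- grp[[id]]
    names(grp)[!is.na(grp) & grp == g]
  }
  members <- group_members(reps[1])

  if (length(reps) > 1) {
    x1 <- site_dosage(data, reps[1])
    fit1 <- stats::lm.fit(cbind(1, x1), y)
    f <- fit1$fitted.values
    for (nn in 2:length(reps)) {
      xn <- site_dosage(data, reps[nn])
      fit <- stats::lm(y ~ xn + f)
      coefs <- summary(fit)$coefficients
      if (!"f" %in% rownames(coefs)) {
        # lambda inestimable (collinear with the rival): cannot distinguish
        members <- c(members, group_members(reps[nn]))
        next
      }
      p_lambda <- coefs["f", 4]
      if (is.finite(p_lambda) && p_lambda < alpha / (nn - 1)) break
      members <- c(members, group_members(reps[nn]))
    }
  }
  members <- members[order(marg_p[members],
                           data$sites$position[match(members,
                                                     data$sites$id)])]
  credible_set("jtest", 1 - alpha, members, marg_p[members],
               top_site = ranking[1])
}

#' Per-site Bayes factors for a single causal variant
#'
#' For each site, the Bayes factor of the one-SNP linear model against the
#' null (intercept-only) model. The default is Wakefield's approximate Bayes
#' factor computed from the OLS estimate and its standard error,
#' `ABF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` with `V = se^2`,
#' `z = beta / se`, and prior variance `W` on the effect. The exact
#' conjugate-prior alternative (`model = "conjugate_exact"`) integrates the
#' normal linear model with prior `beta ~ N(0, W sigma^2)` and reference
#' priors on intercept and variance. The phenotype is standardized
#' internally, so `W` is on the standardized-trait scale; the default
#' `W = 0.5` accommodates the large effects typical of methylation QTL.
#'
#' @param data a [geno_dataset()].
#' @param y phenotype (`pheno_sim` or numeric).
#' @param W prior variance of the effect on the standardized-phenotype scale.
#' @param model `"wakefield_abf"` (default) or `"conjugate_exact"`.
#' @return a `bf_set` data frame with columns `site`, `position`, `log10_bf`;
#'   attributes `W` and `model`. Zero-variance sites get `log10_bf = 0` with
#'   a warning.
#' @export
compute_bayes_factors <- function(data, y, W = 0.5,
                                  model = c("wakefield_abf",
                                            "conjugate_exact")) {
  model <- match.arg(model)
  if (W <= 0) stop("compute_bayes_factors: W must be positive")
  y <- as_pheno_values(y)
  sdy <- stats::sd(y)
  if (sdy <= 0) stop("compute_bayes_factors: constant phenotype")
  ys <- (y - mean(y)) / sdy

  if (model == "wakefield_abf") {
    scan <- assoc_scan(data, ys)
    v <- scan$se^2
    z <- scan$t_stat
    log_bf <- 0.5 * log(v / (v + W)) + z^2 * W / (2 * (v + W))
    log10_bf <- log_bf / log(10)
  } else {
    x <- data$dosages
    n <- nrow(x)
    yc <- ys - mean(ys)
    syy <- sum(yc^2)
    xm <- colMeans(x)
    sxx <- colSums(x^2) - n * xm^2
    sxy <- drop(crossprod(x, yc))
    # BF = (1 + W Sxx)^(-1/2) * ((Syy - Sxy^2/(Sxx + 1/W)) / Syy)^(-(n-1)/2)
    rss1 <- syy - sxy^2 / (sxx + 1 / W)
    log_bf <- -0.5 * log1p(W * sxx) - (n - 1) / 2 * (log(rss1) - log(syy))
    log10_bf <- log_bf / log(10)
    log10_bf[sxx <= 1e-12] <- NA_real_
  }
  zero_var <- !is.finite(log10_bf)
  if (any(zero_var)) {
    warning("compute_bayes_factors: ", sum(zero_var),
            " zero-variance site(s) assigned BF = 1")
    log10_bf[zero_var] <- 0
  }
  res <- data.frame(site = data$sites$id, position = data$sites$position,
                    log10_bf = log10_bf, stringsAsFactors = FALSE)
  attr(res, "W") <- W
  attr(res, "model") <- model
  class(res) <- c("bf_set", "data.frame")
  res
}

#' Credible set from posterior probabilities of association
#'
#' Under a single-causal-variant assumption, each site's posterior probability
#' of association is its Bayes factor normalized by the locus-wide sum,
#' `PPA_i = BF_i / sum_j BF_j` (computed in log space with max subtraction).
#' Sites are added in descending PPA (ties broken by position) until the
#' cumulative PPA reaches `level`; the set is minimal by construction.
#'
#' @param bfs a `bf_set` from [compute_bayes_factors()].
#' @param level nominal probability (default 0.95).
#' @return a [credible_set()] with `method = "ppa"`; evidence = PPA.
#' @export
ppa_credible_set <- function(bfs, level = 0.95) {
  lbf <- bfs$log10_bf * log(10)
  w <- exp(lbf - max(lbf))
  ppa <- w / sum(w)
  ord <- order(-ppa, bfs$position)
  cum <- cumsum(ppa[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  pick <- ord[seq_len(k)]
  credible_set("ppa", level, bfs$site[pick], ppa[pick],
               top_site = bfs$site[ord[1]])
}

#' Spike-and-slab Gibbs sampler with top-variant counting
#'
#' Samples a sparse Bayesian linear model (per-site inclusion indicators with
#' a Beta(1, M) prior on the inclusion probability, a normal slab whose
#' variance carries an inverse-gamma hyperprior, and conjugate updates for
#' the effects and the residual variance) on standardized genotypes and
#' phenotype. At every `thin`-th post-burn-in iteration the included site
#' with the largest |effect| is counted as the predicted causal variant; all
#' sites in complete LD with it are counted at the same time. The counts feed
#' [count_credible_set()].
#'
#' @param data a [geno_dataset()].
#' @param y phenotype (`pheno_sim` or numeric).
#' @param n_iter total MCMC iterations (default 11000).
#' @param burn_in discarded initial iterations (default 1000).
#' @param thin counting stride (default 10: every 10th kept iteration).
#' @param seed integer seed (drives R's RNG; runs are reproducible).
#' @return named integer vector of per-site counts (attribute `"n_counted"`
#'   gives the number of counted iterations; attribute `"degenerate"` flags
#'   an all-zero count vector).
#' @export
spike_slab_sampler <- function(data, y, n_iter = 11000, burn_in = 1000,
                               thin = 10, seed = 1L) {
  if (n_iter < thin) stop("spike_slab_sampler: n_iter must be >= thin")
  if (burn_in >= n_iter) stop("spike_slab_sampler: burn_in must be < n_iter")
  y <- as_pheno_values(y)
  grp <- complete_ld_groups(data)
  is_rep <- attr(grp, "representative")
  reps <- which(is_rep)
  x <- scale(data$dosages[, reps, drop = FALSE])
  ys <- drop(scale(y))
  n <- length(ys)
  xtx <- crossprod(x)
  xty <- drop(crossprod(x, ys))
  yty <- sum(ys^2)
  m_rep <- length(reps)

  set.seed(seed)
  fit <- spike_slab_gibbs(xtx, xty, yty, n, as.integer(n_iter),
                          as.integer(burn_in), as.integer(thin),
                          1, m_rep, 1, 1)
  rep_counts <- fit$counts

  counts <- stats::setNames(integer(ncol(data$dosages)), data$sites$id)
  for (i in seq_along(reps)) {
    g <- grp[reps[i]]
    members <- which(!is.na(grp) & grp == g)
    counts[members] <- rep_counts[i]
  }
  attr(counts, "n_counted") <- fit$n_counted
  attr(counts, "degenerate") <- all(counts == 0)
  if (all(counts == 0)) {
    warning("spike_slab_sampler: degenerate run -- no site was ever included")
  }
  counts
}

#' Credible set from MCMC top-variant counts
#'
#' Adds sites in order of decreasing count (ties broken by position) until
#' the included counts reach `level` of the total.
#'
#' @param counts named per-site counts (from [spike_slab_sampler()]).
#' @param level nominal probability (default 0.95).
#' @param positions optional per-site positions for tie-breaking (defaults to
#'   input order).
#' @return a [credible_set()] with `method = "mcmc_count"`; evidence =
#'   counts.
#' @export
count_credible_set <- function(counts, level = 0.95, positions = NULL) {
  total <- sum(counts)
  if (total <= 0) stop("count_credible_set: zero total count")
  if (is.null(positions)) positions <- seq_along(counts)
  ids <- names(counts)
  if (is.null(ids)) ids <- paste0("site", seq_along(counts))
  ord <- order(-counts, positions)
  cum <- cumsum(counts[ord]) / total
  k <- which(cum >= level - 1e-12)[1]
  pick <- ord[seq_len(k)]
  credible_set("mcmc_count", level, ids[pick], counts[pick],
               top_site = ids[ord[1]])
}

#' One-call MCMC credible set
#'
#' Convenience wrapper: [spike_slab_sampler()] followed by
#' [count_credible_set()] with the dataset's positions for tie-breaking.
#'
#' @inheritParams spike_slab_sampler
#' @param level nominal probability (default 0.95).
#' @return a [credible_set()] with `method = "mcmc_count"`.
#' @export
mcmc_credible_set <- function(data, y, level = 0.95, n_iter = 11000,
                              burn_in = 1000, thin = 10, seed = 1L) {
  counts <- spike_slab_sampler(data, y, n_iter = n_iter, burn_in = burn_in,
                               thin = thin, seed = seed)
  count_credible_set(counts, level = level, positions = data$sites$position)
}
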