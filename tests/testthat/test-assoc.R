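test_that("association scan matches lm and a normal-equations oracle", {
  # 3-sample perfect-fit fixture: dosages {0,1,2}, y {0,1,2}
  d <- manual_dataset(cbind(a = c(0, 1, 2)))
  res <- assoc_scan(d, c(0, 1, 2))
  expect_equal(res$beta, 1, tolerance = 1e-12)
  expect_equal(res$mu, 0, tolerance = 1e-12)
  expect_equal(res$r2, 1, tolerance = 1e-12)

  # random fixtures: beta/se/t agree with lm to 1e-10, and with explicit
  # normal equations
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    x <- matrix(rbinom(n * 6, 2, runif(6, 0.2, 0.5)), nrow = n)
    y <- rnorm(n) + 0.5 * x[, 2]
    dd <- manual_dataset(x)
    res <- assoc_scan(dd, y)
    for (j in 1:6) {
      fit <- summary(lm(y ~ x[, j]))$coefficients
      expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-10)
      expect_equal(res$se[j], fit[2, 2], tolerance = 1e-10)
      expect_equal(res$p_value[j], fit[2, 4], tolerance = 1e-10)
      # normal equations by hand
      xc <- x[, j] - mean(x[, j]); yc <- y - mean(y)
      expect_equal(res$beta[j], sum(xc * yc) / sum(xc^2), tolerance = 1e-10)
    }
  }
})

test_that("null association scan is calibrated", {
  frac <- vapply(1:30, function(s) {
    set.seed(s)
    x <- matrix(rbinom(60 * 100, 2, 0.3), nrow = 60)
    y <- rnorm(60)
    res <- assoc_scan(manual_dataset(x), y)
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.015)
})

test_that("zero-variance sites are flagged and excluded from the ranking", {
  d <- manual_dataset(cbind(a = c(0, 1, 2, 1), b = c(1, 1, 1, 1)))
  res <- assoc_scan(d, c(0.1, 0.9, 2.1, 1.2))
  expect_true(res$excluded[2])
  expect_false("b" %in% attr(res, "ranking"))
})

test_that("ld_metrics reproduces hand-computed D, D', r2", {
  # identity: duplicated site
  pan <- hap_panel(cbind(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L)),
                   c(1, 2), c("a", "b"))
  ld <- ld_metrics(pan, "a", "b")
  expect_equal(ld$d_prime, 1)
  expect_equal(ld$r2, 1)

  # haplotype freqs {AB: .5, Ab: 0, aB: .25, ab: .25}:
  # D = .125, D' = 1, r2 = 1/3 (the high-D'/low-r2 masking signature)
  hap <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 1L), c(0L, 0L))
  pan2 <- hap_panel(hap, c(10, 20), c("x", "y"))
  ld2 <- ld_metrics(pan2, "x", "y")
  expect_equal(ld2$d, 0.125, tolerance = 1e-12)
  expect_equal(ld2$d_prime, 1, tolerance = 1e-12)
  expect_equal(ld2$r2, 1 / 3, tolerance = 1e-12)
  expect_equal(sum(ld2$hap_freqs), 1)

  # independence limit
  set.seed(2)
  big <- hap_panel(cbind(p = rbinom(4000, 1, 0.5), q = rbinom(4000, 1, 0.3)),
                   c(1, 2), c("p", "q"))
  expect_equal(ld_metrics(big, "p", "q")$d, 0, tolerance = 0.02)

  expect_error(
    ld_metrics(hap_panel(cbind(c(0L, 1L), c(1L, 1L)), c(1, 2), c("m", "n"),
                         require_polymorphic = FALSE), "m", "n"),
    "monomorphic")
})

test_that("EM haplotype frequencies from genotypes agree with phased truth", {
  # phased truth = the realized haplotypes behind the diploids, so EM error
  # is isolated from haplotype-sampling noise
  for (s in 1:4) {
    cfg <- scenario_config(n_samples = 600, n_sites = 30, seed = s)
    panel <- suppressMessages(build_panel_mosaic(cfg))
    data <- pair_into_diploids(panel, 600, seed = s + 50)
    realized <- hap_panel(attr(data, "haplotypes"), panel$positions,
                          panel$site_ids, require_polymorphic = FALSE)
    ld_hap <- tryCatch(ld_metrics(realized, 5, 6), error = function(e) NULL)
    ld_em <- tryCatch(ld_metrics(data, 5, 6), error = function(e) NULL)
    if (is.null(ld_em) || is.null(ld_hap)) next
    expect_lt(abs(ld_em$r2 - ld_hap$r2), 0.02)
    expect_lt(max(abs(ld_em$hap_freqs - ld_hap$hap_freqs)), 0.02)
  }
})

test_that("conditional regression reduces to the scan and matches lm", {
  lc <- causal_locus(n_samples = 300, n_sites = 40, seed = 9)
  plain <- assoc_scan(lc$data, lc$pheno)
  cond0 <- conditional_regression(lc$data, lc$pheno, character(0))
  expect_equal(cond0$p_value, plain$p_value)

  # conditioning on one site matches the joint lm t-test
  cond <- conditional_regression(lc$data, lc$pheno, lc$causal)
  y <- lc$pheno$values
  xc <- site_dosage(lc$data, lc$causal)
  j <- which(cond$site == cond$site[3])
  x3 <- site_dosage(lc$data, cond$site[3])
  fit <- summary(lm(y ~ x3 + xc))$coefficients
  expect_equal(cond$beta[j], fit[2, 1], tolerance = 1e-10)
  expect_equal(cond$p_value[j], fit[2, 4], tolerance = 1e-10)
})

test_that("conditioning on the sole causal site leaves no signal", {
  pvals <- unlist(lapply(1:10, function(s) {
    lc <- causal_locus(n_samples = 300, n_sites = 40, h2 = 0.3,
                       seed = 100 + s)
    cond <- conditional_regression(lc$data, lc$pheno, lc$causal)
    min(cond$p_value[!cond$excluded], na.rm = TRUE)
  }))
  expect_true(all(pvals > 5e-8))
})

test_that("a second independent causal survives conditioning on the first", {
  set.seed(3)
  n <- 1000
  x1 <- rbinom(n, 2, 0.3)
  x2 <- rbinom(n, 2, 0.4)
  noise <- matrix(rbinom(n * 5, 2, 0.25), nrow = n)
  d <- manual_dataset(cbind(x1, x2, noise),
                      ids = c("c1", "c2", paste0("n", 1:5)))
  y <- x1 + x2 + rnorm(n)
  cond <- conditional_regression(d, y, "c1")
  expect_lt(cond$p_value[cond$site == "c2"], 5e-8)

  # collinear conditioned pair errors, naming the pair
  d2 <- manual_dataset(cbind(a = x1, b = x1, c = x2))
  expect_error(conditional_regression(d2, y, c("a", "b")),
               "collinear.*(a ~ b|b ~ a)")
})
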