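test_that("J-test set handles trivial and complete-LD loci", {
  # single polymorphic site
  d <- manual_dataset(cbind(a = c(0, 1, 2, 1, 0, 2, 1, 1)))
  set.seed(1)
  cs <- jtest_credible_set(d, rnorm(8) + c(0, 1, 2, 1, 0, 2, 1, 1))
  expect_equal(cs$members, "a")

  # a perfect copy of the top site joins without a second test
  set.seed(2)
  x <- rbinom(300, 2, 0.3)
  noise <- matrix(rbinom(300 * 4, 2, 0.25), nrow = 300)
  d2 <- manual_dataset(cbind(x, x, noise),
                       ids = c("c1", "c1copy", paste0("n", 1:4)))
  y <- x + rnorm(300, 0, 0.5)
  cs2 <- jtest_credible_set(d2, y)
  expect_true(all(c("c1", "c1copy") %in% cs2$members))
})

test_that("J-test excludes a clearly inferior rival", {
  # two orthogonal sites, one strongly causal: rival rejected >= 95% of seeds
  wins <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 1000
    x1 <- rbinom(n, 2, 0.4)
    x2 <- rbinom(n, 2, 0.4)
    g <- x1 * 1
    y <- g + rnorm(n, 0, sd = sqrt(var(g)))  # h2 ~ 0.5
    d <- manual_dataset(cbind(x1, x2), ids = c("causal", "null"))
    cs <- jtest_credible_set(d, y)
    identical(cs$members, "causal")
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("J-test sets never grow when alpha grows", {
  # a larger alpha makes the stopping test easier to pass, so sets shrink
  for (s in 1:10) {
    lc <- causal_locus(n_samples = 300, n_sites = 40, seed = 300 + s)
    s_strict <- jtest_credible_set(lc$data, lc$pheno, alpha = 0.01)
    s_mid <- jtest_credible_set(lc$data, lc$pheno, alpha = 0.05)
    s_loose <- jtest_credible_set(lc$data, lc$pheno, alpha = 0.2)
    expect_gte(length(s_strict), length(s_mid))
    expect_gte(length(s_mid), length(s_loose))
  }
})

test_that("Wakefield ABF matches its closed form; exact BF matches quadrature", {
  # z = 5, V = 0.01, W = 0.1 hand evaluation
  set.seed(7)
  n <- 500
  x <- rbinom(n, 2, 0.3)
  y <- 0.2 * x + rnorm(n)
  d <- manual_dataset(cbind(x = x))
  bf <- compute_bayes_factors(d, y, W = 0.1)
  sc <- assoc_scan(d, scale(y)[, 1])
  z <- sc$t_stat; v <- sc$se^2; W <- 0.1
  expect_equal(bf$log10_bf,
               log10(sqrt(v / (v + W)) * exp(z^2 * W / (2 * (v + W)))),
               tolerance = 1e-9)

  # beta-hat = 0 exactly: log10 BF = 0.5*log10(V/(V+W)) < 0
  x0 <- c(0, 0, 1, 1, 2, 2)
  y0 <- c(1, -1, 1, -1, 1, -1)  # orthogonal to x0
  bf0 <- compute_bayes_factors(manual_dataset(cbind(x0)), y0, W = 0.5)
  sc0 <- assoc_scan(manual_dataset(cbind(x0)), scale(y0)[, 1])
  expect_equal(bf0$log10_bf, 0.5 * log10(sc0$se^2 / (sc0$se^2 + 0.5)),
               tolerance = 1e-9)
  expect_lt(bf0$log10_bf, 0)

  # identical (beta, se) -> identical BFs
  d2 <- manual_dataset(cbind(a = x, b = x))
  bf2 <- compute_bayes_factors(d2, y)
  expect_equal(bf2$log10_bf[1], bf2$log10_bf[2])

  # exact conjugate BF against 2D numerical integration
  set.seed(9)
  n <- 12
  xs <- rbinom(n, 2, 0.4)
  ys <- 0.5 + 0.8 * xs + rnorm(n)
  W <- 0.5
  bfe <- compute_bayes_factors(manual_dataset(cbind(xs)), ys, W = W,
                               model = "conjugate_exact")
  yy <- ys / sd(ys)
  marg <- function(with_b) {
    f <- function(ls2) {
      s2 <- exp(ls2)
      inner <- function(b) {
        r <- yy - b * xs
        rc <- r - mean(r)
        exp(-sum(rc^2) / (2 * s2)) * sqrt(2 * pi * s2 / n) *
          (2 * pi * s2)^(-n / 2) *
          if (with_b) dnorm(b, 0, sqrt(W * s2)) else 1
      }
      if (with_b) {
        integrate(Vectorize(inner), -10, 10, rel.tol = 1e-10)$value
      } else inner(0)
    }
    log(integrate(Vectorize(f), -12, 10, rel.tol = 1e-10)$value)
  }
  lbf_num <- (marg(TRUE) - marg(FALSE)) / log(10)
  expect_equal(bfe$log10_bf, lbf_num, tolerance = 1e-5)
})

test_that("PPA normalization and credible-set accumulation follow the rules", {
  mk_bfs <- function(log10_bf, ids = paste0("s", seq_along(log10_bf))) {
    res <- data.frame(site = ids, position = seq_along(log10_bf) * 1000,
                      log10_bf = log10_bf, stringsAsFactors = FALSE)
    class(res) <- c("bf_set", "data.frame")
    res
  }
  # single site
  cs1 <- ppa_credible_set(mk_bfs(2))
  expect_equal(cs1$members, "s1")
  expect_equal(unname(cs1$evidence), 1)
  # equal BFs: PPA 0.5 each, both needed at level 0.95
  cs2 <- ppa_credible_set(mk_bfs(c(1, 1)))
  expect_equal(unname(cs2$evidence), c(0.5, 0.5))
  expect_equal(length(cs2), 2)
  # BFs {8, 1, 1}: PPAs {0.8, 0.1, 0.1}; cumulative 0.9 < 0.95 -> all three
  cs3 <- ppa_credible_set(mk_bfs(log10(c(8, 1, 1))))
  expect_equal(unname(cs3$evidence), c(0.8, 0.1, 0.1), tolerance = 1e-12)
  expect_equal(length(cs3), 3)
})

test_that("PPA sets match an exhaustive-normalization oracle on random fixtures", {
  for (s in 1:20) {
    set.seed(s)
    m <- sample(3:20, 1)
    lbf <- rnorm(m, 0, 3)
    res <- data.frame(site = paste0("s", 1:m), position = (1:m) * 1000,
                      log10_bf = lbf, stringsAsFactors = FALSE)
    class(res) <- c("bf_set", "data.frame")
    cs <- ppa_credible_set(res)
    # oracle: direct normalization + greedy accumulation
    bfs <- 10^lbf
    ppa <- bfs / sum(bfs)
    expect_equal(sum(ppa), 1, tolerance = 1e-12)
    ord <- order(-ppa)
    k <- which(cumsum(ppa[ord]) >= 0.95 - 1e-12)[1]
    expect_setequal(cs$members, paste0("s", ord[seq_len(k)]))
    # minimality: dropping the last member breaks the bound
    if (length(cs) > 1) {
      expect_lt(sum(cs$evidence) - cs$evidence[length(cs)], 0.95)
    }
    expect_gte(sum(cs$evidence), 0.95 - 1e-12)
  }
})

test_that("spike-and-slab counts are reproducible and find a strong causal", {
  lc <- causal_locus(n_samples = 400, n_sites = 50, h2 = 0.5, seed = 77)
  c1 <- spike_slab_sampler(lc$data, lc$pheno, n_iter = 3000, burn_in = 500,
                           seed = 5)
  c2 <- spike_slab_sampler(lc$data, lc$pheno, n_iter = 3000, burn_in = 500,
                           seed = 5)
  expect_identical(c1, c2)
  # the causal site should dominate the counts
  expect_gt(c1[[lc$causal]], 0.5 * attr(c1, "n_counted"))
})

test_that("complete-LD partners receive identical counts", {
  set.seed(12)
  n <- 300
  x <- rbinom(n, 2, 0.3)
  noise <- matrix(rbinom(n * 3, 2, 0.25), nrow = n)
  d <- manual_dataset(cbind(x, x, noise),
                      ids = c("c1", "c1copy", paste0("n", 1:3)))
  y <- x + rnorm(n, 0, 1)
  counts <- spike_slab_sampler(d, y, n_iter = 2000, burn_in = 200, seed = 3)
  expect_equal(counts[["c1"]], counts[["c1copy"]])
  expect_gt(counts[["c1"]], 0)
})

test_that("count-based credible sets follow the cumulative rule", {
  # boundary: 950/1000 = 0.95 exactly -> singleton
  cs <- count_credible_set(c(a = 950, b = 30, c = 20))
  expect_equal(cs$members, "a")
  # cumulative 0.5, 0.9, 1.0 -> all three
  cs2 <- count_credible_set(c(a = 500, b = 400, c = 100))
  expect_equal(length(cs2), 3)
  # all counts on one site
  cs3 <- count_credible_set(c(a = 0, b = 100, c = 0))
  expect_equal(cs3$members, "b")
  expect_error(count_credible_set(c(a = 0, b = 0)), "zero total")
})
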