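test_that("mask_to_array subsets exactly and validates its inputs", {
  tl <- toy_locus(n_samples = 50, n_sites = 100, seed = 2)
  d <- tl$data
  # identity
  all_ids <- d$sites$id
  expect_equal(mask_to_array(d, all_ids)$dosages, d$dosages)
  # cardinality
  sub <- mask_to_array(d, all_ids[seq(1, 100, by = 5)])
  expect_equal(ncol(sub$dosages), 20)
  expect_true(all(sub$sites$genotyped))
  # errors
  expect_error(mask_to_array(d, character(0)), "empty")
  expect_error(mask_to_array(d, c(all_ids[1], "nope")), "nope")
})

test_that("Li-Stephens imputation recovers truth in identifiable limits", {
  # reference of 2 identical haplotypes -> dosage = 2 x that haplotype
  ref_hap <- c(0L, 1L, 0L, 1L, 1L)
  ref <- hap_panel(matrix(rep(ref_hap, 4), nrow = 4, byrow = TRUE),
                   (1:5) * 1000, paste0("s", 1:5),
                   require_polymorphic = FALSE)
  tgt_panel <- hap_panel(rbind(c(0L, 1L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L, 1L)),
                         (1:5) * 1000, paste0("s", 1:5),
                         require_polymorphic = FALSE)
  truth <- pair_into_diploids(tgt_panel, 1, seed = 1)
  arr <- mask_to_array(truth, c("s1", "s3"))
  imp <- impute_li_stephens(arr, ref)
  expect_equal(unname(imp$dosages[1, ]), 2 * ref_hap, tolerance = 1e-6)

  # perfect-panel limit: target haplotypes present verbatim, distinct from
  # all others at the array sites, mismatch -> 0
  haps <- rbind(c(1L, 1L, 1L, 1L, 1L, 0L),
                c(0L, 0L, 0L, 0L, 0L, 1L),
                c(1L, 0L, 1L, 0L, 1L, 1L),
                c(0L, 1L, 0L, 1L, 0L, 0L))
  pan <- hap_panel(haps, (1:6) * 500, paste0("v", 1:6),
                   require_polymorphic = FALSE)
  truth2 <- pair_into_diploids(pan, 2, seed = 3)
  arr2 <- mask_to_array(truth2, c("v1", "v2", "v4"))
  imp2 <- impute_li_stephens(arr2, pan, mismatch_rate = 1e-9)
  expect_lt(max(abs(imp2$dosages - truth2$dosages)), 0.05)

  # errors
  expect_error(impute_li_stephens(arr2, subset_panel(pan, haps = 1:3,
                                  require_polymorphic = FALSE)),
               "at least 4")
  ref_short <- subset_panel(pan, sites = c("v1", "v3"),
                            require_polymorphic = FALSE)
  expect_error(impute_li_stephens(arr2, ref_short), "absent")
})

test_that("imputation error shrinks as the reference panel grows", {
  sizes <- c(40, 160, 640)
  errs <- matrix(NA_real_, nrow = 8, ncol = length(sizes))
  for (s in 1:8) {
    cfg <- scenario_config(n_samples = 60, n_sites = 60,
                           n_haplotypes = 120 + max(sizes), seed = s)
    pool <- suppressMessages(build_panel_mosaic(cfg))
    tgt <- subset_panel(pool, haps = 1:120, require_polymorphic = FALSE)
    truth <- pair_into_diploids(tgt, 60, seed = s + 500)
    arr <- mask_to_array(truth, truth$sites$id[seq(2, 60, by = 3)])
    for (i in seq_along(sizes)) {
      ref <- subset_panel(pool, haps = 120 + seq_len(sizes[i]),
                          require_polymorphic = FALSE)
      imp <- impute_li_stephens(arr, ref)
      errs[s, i] <- mean(abs(imp$dosages - truth$dosages))
    }
  }
  m <- colMeans(errs)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("info score matches its defining ratio and limits", {
  # hand computation: dosages {0,1,1,2}, p = 0.5 -> observed (ML) variance
  # 0.5, expected 2p(1-p) = 0.5 -> score exactly 1
  d <- c(0, 1, 1, 2)
  expect_equal(mean((d - mean(d))^2), 0.5)
  expect_equal(info_score(d, 0.5), 1.0)
  # pure-prior dosages -> 0
  expect_equal(info_score(rep(2 * 0.3, 50), 0.3), 0)
  # hard dosages at HWE proportions -> ~1
  set.seed(4)
  g <- rbinom(2000, 2, 0.25)
  expect_equal(info_score(g, mean(g) / 2), 1, tolerance = 0.05)
  # monomorphic -> NA sentinel
  expect_true(is.na(info_score(rep(0, 10), 0)))
})

test_that("HWE exact test matches an enumeration oracle and equilibrium data", {
  # independent oracle: enumerate all heterozygote counts with log-choose
  hwe_oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    nr <- 2 * min(n_aa, n_bb) + n_ab
    hets <- seq(nr %% 2, nr, by = 2)
    logp <- vapply(hets, function(h) {
      hr <- (nr - h) / 2
      hc <- n - h - hr
      lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
        h * log(2) - (lfactorial(2 * n) - lfactorial(nr) -
                        lfactorial(2 * n - nr))
    }, numeric(1))
    p <- exp(logp - max(logp)); p <- p / sum(p)
    sum(p[p <= p[hets == n_ab] * (1 + 1e-12)])
  }
  cases <- list(c(20, 10, 5), c(50, 25, 1), c(7, 1, 7), c(100, 40, 4),
                c(0, 10, 0), c(3, 0, 3))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-9,
                 info = paste(cs, collapse = ","))
  }
  expect_equal(hwe_exact_test(30, 0, 0), 1)
})

test_that("QC filters remove exactly the engineered failures, in any order", {
  set.seed(8)
  n <- 400
  good <- function(p) rbinom(n, 2, p)
  doses <- cbind(
    a_ok = good(0.3),
    b_lowmaf = rbinom(n, 2, 0.004),
    c_ok = good(0.45),
    d_hwe = c(rep(0, 200), rep(2, 200)),        # no hets: HWE blows up
    e_ok = good(0.2),
    f_ok = good(0.35))
  d <- manual_dataset(doses, ids = colnames(doses))
  d$sites$genotyped[2] <- FALSE; d$sites$info[2] <- 0.95
  clean <- apply_qc(d, qc_config())
  expect_setequal(clean$sites$id, c("a_ok", "c_ok", "e_ok", "f_ok"))
  log <- qc_log(clean)
  expect_true("b_lowmaf" %in% log$removed)
  expect_true("d_hwe" %in% log$removed)
  expect_equal(nrow(clean$sites), 4)

  # info thresholds: 0.79 removed at 0.8, retained at 0.3
  d2 <- manual_dataset(cbind(x = good(0.3), y = good(0.4)))
  d2$sites$genotyped[2] <- FALSE
  d2$sites$info[2] <- 0.79
  strict <- apply_qc(d2, qc_config(info_min = 0.8))
  lenient <- apply_qc(d2, qc_config(info_min = 0.3))
  expect_false("y" %in% strict$sites$id)
  expect_true("y" %in% lenient$sites$id)

  # order independence: same survivors if we filter sequentially by hand
  surv_joint <- clean$sites$id
  d_tmp <- d
  for (qc1 in list(qc_config(hwe_p_min = 0, info_min = 0, max_missing = 1),
                   qc_config(maf_min = 0, info_min = 0, max_missing = 1),
                   qc_config(maf_min = 0, hwe_p_min = 0, max_missing = 1))) {
    d_tmp <- apply_qc(d_tmp, qc1)
  }
  expect_setequal(d_tmp$sites$id, surv_joint)

  expect_error(apply_qc(manual_dataset(cbind(z = rbinom(n, 2, 0.001)))),
               "all sites removed")
})

test_that("dataset intersection keeps shared sites with original dosages", {
  tl <- toy_locus(n_samples = 30, n_sites = 20, seed = 6)
  d <- tl$data
  a <- subset_sites(d, d$sites$id[1:15])
  b <- subset_sites(d, d$sites$id[6:20])
  out <- intersect_datasets(a, b)
  expect_equal(out[[1]]$sites$id, d$sites$id[6:15])
  expect_equal(out[[2]]$sites$id, d$sites$id[6:15])
  expect_equal(out[[1]]$dosages, out[[2]]$dosages)
  # identity
  same <- intersect_datasets(d, d)
  expect_equal(same[[1]]$dosages, d$dosages)
  # errors
  expect_error(intersect_datasets(a), "at least 2")
  c_ds <- subset_sites(d, d$sites$id[16:20])
  expect_error(intersect_datasets(a, c_ds), "empty")
})
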