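#' Deterministic per-locus child seed
#'
#' Pure function of the master seed and locus index, so any locus can be
#' re-run in isolation and reproduce its in-pipeline result. Values stay
#' below 2^31.
#'
#' @param master_seed integer master seed.
#' @param locus_index 1-based locus index.
#' @return an integer seed.
#' @export
child_seed <- function(master_seed, locus_index) {
  as.integer((as.numeric(master_seed) * 7919 +
                as.numeric(locus_index) * 104729) %% 2147483629)
}

#' Experiment configuration
#'
#' Encodes the full simulation design: the per-locus scenario, the dataset
#' arms (the truth arm plus imputed arms differing in reference-panel size),
#' the fine-mapping methods to run, and replication/seeding.
#'
#' Each imputed arm is a list with fields `ref_size` (reference haplotypes),
#' and optionally `mismatch_rate`, `switch_rate`, `array_fraction` (share of
#' sites on the emulated array), `causal_on_array` (default `FALSE`: the
#' causal site is imputed), and `qc` (a [qc_config()]; `NULL` skips QC).
#'
#' @param scenario a [scenario_config()] describing one locus.
#' @param arms named list of arm definitions; the entry `list(type =
#'   "truth")` is the sequence arm, others must have `type = "imputed"`.
#' @param methods subset of `c("jtest", "ppa", "mcmc_count")`.
#' @param level nominal credible-set probability.
#' @param h2 simulated heritability.
#' @param n_loci number of simulated loci.
#' @param master_seed integer master seed (spawns child seeds via
#'   [child_seed()]).
#' @param run_conditional run [forward_selection()] and
#'   [stepwise_joint_selection()] per locus (default `FALSE`).
#' @param mcmc_iter,mcmc_burn_in MCMC budget for the sampler-based method.
#' @param intersect restrict all arms to their shared post-QC sites
#'   (default `TRUE` when >1 arm).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = scenario_config(),
                              arms = list(truth = list(type = "truth")),
                              methods = c("jtest", "ppa", "mcmc_count"),
                              level = 0.95, h2 = 0.2, n_loci = 10,
                              master_seed = 1L, run_conditional = FALSE,
                              mcmc_iter = 11000, mcmc_burn_in = 1000,
                              intersect = TRUE) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (anyDuplicated(names(arms)) || is.null(names(arms))) {
    stop("experiment_config: arms must be uniquely named")
  }
  methods <- match.arg(methods, c("jtest", "ppa", "mcmc_count"),
                       several.ok = TRUE)
  structure(list(scenario = scenario, arms = arms, methods = methods,
                 level = level, h2 = h2, n_loci = as.integer(n_loci),
                 master_seed = as.integer(master_seed),
                 run_conditional = run_conditional,
                 mcmc_iter = mcmc_iter, mcmc_burn_in = mcmc_burn_in,
                 intersect = intersect),
            class = "experiment_config")
}

#' Write / read an experiment configuration as JSON
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `read_experiment_config` returns an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- raw$scenario
  scenario <- scenario_config(
    n_samples = sc$n_samples, n_sites = sc$n_sites,
    n_haplotypes = sc$n_haplotypes, n_founders = sc$n_founders,
    recomb_rate = sc$recomb_rate, mutation_rate = sc$mutation_rate,
    site_spacing = sc$site_spacing, causal_maf_min = sc$causal_maf_min,
    causal_id = sc$causal_id, seed = sc$seed)
  arms <- lapply(raw$arms, function(a) {
    if (!is.null(a$qc)) a$qc <- do.call(qc_config, a$qc)
    a
  })
  experiment_config(scenario = scenario, arms = arms,
                    methods = raw$methods, level = raw$level, h2 = raw$h2,
                    n_loci = raw$n_loci, master_seed = raw$master_seed,
                    run_conditional = isTRUE(raw$run_conditional),
                    mcmc_iter = raw$mcmc_iter,
                    mcmc_burn_in = raw$mcmc_burn_in,
                    intersect = isTRUE(raw$intersect))
}

# simulate one locus and derive all arms; internal
simulate_locus_arms <- function(config, locus_seed) {
  sc <- config$scenario
  imputed_arms <- Filter(function(a) identical(a$type, "imputed"),
                         config$arms)
  max_ref <- if (length(imputed_arms)) {
    max(vapply(imputed_arms, function(a) a$ref_size, numeric(1)))
  } else 0
  pool <- scenario_config(
    n_samples = sc$n_samples, n_sites = sc$n_sites,
    n_haplotypes = 2L * sc$n_samples + as.integer(max_ref),
    n_founders = sc$n_founders, recomb_rate = sc$recomb_rate,
    mutation_rate = sc$mutation_rate, site_spacing = sc$site_spacing,
    causal_maf_min = sc$causal_maf_min, seed = locus_seed)
  panel <- suppressMessages(build_panel_mosaic(pool))
  target_rows <- seq_len(2L * sc$n_samples)
  ref_rows <- setdiff(seq_len(nrow(panel$alleles)), target_rows)
  target_panel <- subset_panel(panel, haps = target_rows,
                               require_polymorphic = FALSE)

  truth <- pair_into_diploids(target_panel, sc$n_samples,
                              seed = child_seed(locus_seed, 1))
  causal <- choose_causal_site(truth, maf_min = sc$causal_maf_min,
                               seed = child_seed(locus_seed, 2))
  pheno <- simulate_phenotype(truth, causal, config$h2,
                              seed = child_seed(locus_seed, 3))

  arms_out <- list()
  for (arm_name in names(config$arms)) {
    arm <- config$arms[[arm_name]]
    if (identical(arm$type, "truth")) {
      ds <- truth
    } else if (identical(arm$type, "imputed")) {
      af <- if (is.null(arm$array_fraction)) 0.3 else arm$array_fraction
      m <- ncol(truth$dosages)
      array_idx <- unique(round(seq(1, m, length.out = max(2, round(af * m)))))
      causal_j <- site_index(truth, causal)
      if (isTRUE(arm$causal_on_array)) {
        array_idx <- sort(unique(c(array_idx, causal_j)))
      } else {
        array_idx <- setdiff(array_idx, causal_j)
      }
      array_data <- mask_to_array(truth, truth$sites$id[array_idx])
      ref <- subset_panel(panel, haps = ref_rows[seq_len(arm$ref_size)],
                          require_polymorphic = FALSE)
      mr <- if (is.null(arm$mismatch_rate)) 0.01 else arm$mismatch_rate
      sr <- if (is.null(arm$switch_rate)) 1e-5 else arm$switch_rate
      ds <- impute_li_stephens(array_data, ref, mismatch_rate = mr,
                               switch_rate = sr)
      if (!is.null(arm$qc)) ds <- apply_qc(ds, arm$qc)
    } else {
      stop("run_experiment: unknown arm type for arm ", arm_name)
    }
    arms_out[[arm_name]] <- ds
  }
  if (config$intersect && length(arms_out) > 1) {
    arms_out <- intersect_datasets(arms_out)
  }
  list(arms = arms_out, causal = causal, pheno = pheno, panel = panel)
}

#' Run the full fine-mapping experiment
#'
#' For each locus: simulate a truth population and phenotype, derive the
#' dataset arms (array masking, Li-Stephens imputation, QC, intersection),
#' build the requested credible sets per arm, optionally run both
#' conditional analyses, and aggregate coverage per method and arm. Fully
#' reproducible from the configuration and master seed; a locus failing any
#' stage is quarantined with a logged reason, and the run fails only if more
#' than half the loci are quarantined.
#'
#' @param config an [experiment_config()].
#' @param progress print a progress message every 50 loci.
#' @return A list: `report` (a `coverage_report` data frame, one row per
#'   method x arm), `per_locus` (data frame of per-locus outcomes),
#'   `conditional` (per-locus signal counts, when requested),
#'   `quarantined` (data frame of locus index and reason).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  arm_names <- names(config$arms)
  sets <- list()
  per_locus <- list()
  conditional <- list()
  quarantined <- list()

  for (i in seq_len(config$n_loci)) {
    locus_seed <- child_seed(config$master_seed, i)
    out <- tryCatch({
      sim <- simulate_locus_arms(config, locus_seed)
      rows <- list()
      for (arm_name in arm_names) {
        ds <- sim$arms[[arm_name]]
        for (method in config$methods) {
          cs <- switch(method,
            jtest = jtest_credible_set(ds, sim$pheno,
                                       alpha = 1 - config$level),
            ppa = ppa_credible_set(compute_bayes_factors(ds, sim$pheno),
                                   level = config$level),
            mcmc_count = mcmc_credible_set(
              ds, sim$pheno, level = config$level,
              n_iter = config$mcmc_iter, burn_in = config$mcmc_burn_in,
              seed = child_seed(locus_seed, 7)))
          key <- paste(arm_name, method, sep = ".")
          sets[[key]] <- c(sets[[key]], list(cs))
          rows[[key]] <- data.frame(
            locus = i, arm = arm_name, method = method,
            causal = sim$causal,
            covered = sim$causal %in% cs$members,
            set_size = length(cs$members),
            causal_present = sim$causal %in% ds$sites$id,
            stringsAsFactors = FALSE)
        }
      }
      cond_row <- NULL
      if (config$run_conditional) {
        truth_arm <- sim$arms[[which(vapply(config$arms, function(a)
          identical(a$type, "truth"), logical(1)))[1]]]
        fwd <- forward_selection(truth_arm, sim$pheno)
        stp <- stepwise_joint_selection(truth_arm, sim$pheno)
        cond_row <- data.frame(locus = i,
                               n_forward = length(fwd$signals),
                               n_stepwise = length(stp$signals),
                               agree = length(fwd$signals) ==
                                 length(stp$signals),
                               stringsAsFactors = FALSE)
      }
      list(rows = rows, cond = cond_row, causal = sim$causal)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      quarantined[[length(quarantined) + 1]] <-
        data.frame(locus = i, reason = conditionMessage(out),
                   stringsAsFactors = FALSE)
      next
    }
    per_locus[[i]] <- do.call(rbind, out$rows)
    if (!is.null(out$cond)) conditional[[i]] <- out$cond
    if (progress && i %% 50 == 0) message("locus ", i, "/", config$n_loci)
  }

  quarantined <- if (length(quarantined)) do.call(rbind, quarantined) else
    data.frame(locus = integer(0), reason = character(0))
  if (nrow(quarantined) > config$n_loci / 2) {
    stop("run_experiment: more than half the loci were quarantined; ",
         "first reason: ", quarantined$reason[1])
  }
  per_locus <- do.call(rbind, per_locus)

  report <- do.call(rbind, lapply(names(sets), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    keep <- per_locus$arm == parts[1] & per_locus$method == parts[2]
    coverage(sets[[key]], per_locus$causal[keep], label = parts[1])
  }))
  class(report) <- c("coverage_report", "data.frame")

  list(report = report,
       per_locus = per_locus,
       conditional = if (length(conditional)) do.call(rbind, conditional)
         else NULL,
       quarantined = quarantined,
       sets = sets)
}
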