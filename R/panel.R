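#' Haplotype panel
#'
#' A `hap_panel` stores a phased collection of binary haplotypes over a set of
#' biallelic sites: the ground-truth population from which diploid samples are
#' drawn, and the reference panels used for imputation. Alleles are coded
#' 0 (major/reference) and 1 (minor/alternate); coordinates are 1-based and
#' strictly increasing, matching VCF convention.
#'
#' @param alleles H x M integer matrix with values in \{0, 1\} (H haplotypes,
#'   M sites).
#' @param positions length-M vector of strictly increasing base-pair positions.
#' @param site_ids length-M character vector of unique site identifiers.
#' @param require_polymorphic if `TRUE` (default) every site must have an
#'   allele frequency strictly inside (0, 1).
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(alleles, positions, site_ids,
                      require_polymorphic = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    stop("hap_panel: alleles must be binary (0/1)")
  }
  m <- ncol(alleles)
  if (length(positions) != m || length(site_ids) != m) {
    stop("hap_panel: positions and site_ids must match the number of sites")
  }
  if (m > 1 && any(diff(positions) <= 0)) {
    stop("hap_panel: positions must be strictly increasing")
  }
  if (anyDuplicated(site_ids)) stop("hap_panel: site_ids must be unique")
  if (require_polymorphic) {
    af <- colMeans(alleles)
    if (any(af <= 0 | af >= 1)) {
      stop("hap_panel: monomorphic site(s) violate the frequency invariant: ",
           paste(site_ids[af <= 0 | af >= 1], collapse = ", "))
    }
  }
  structure(
    list(alleles = alleles,
         positions = as.numeric(positions),
         site_ids = as.character(site_ids)),
    class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d sites, span %s-%s bp\n",
              nrow(x$alleles), ncol(x$alleles),
              format(min(x$positions)), format(max(x$positions))))
  invisible(x)
}

#' Number of haplotypes / sites in a panel
#' @param panel a [hap_panel()].
#' @return integer count.
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(panel) ncol(panel$alleles)

#' Allele frequencies of a panel
#' @param panel a [hap_panel()].
#' @return named numeric vector of alternate-allele frequencies.
#' @export
panel_allele_freq <- function(panel) {
  stats::setNames(colMeans(panel$alleles), panel$site_ids)
}

#' Subset a haplotype panel
#'
#' @param panel a [hap_panel()].
#' @param haps row (haplotype) indices to keep; `NULL` keeps all.
#' @param sites site indices or site ids to keep; `NULL` keeps all.
#' @param require_polymorphic passed to [hap_panel()]; subsetting haplotypes
#'   can make a site monomorphic, which is allowed for reference panels when
#'   this is `FALSE`.
#' @return a [hap_panel()].
#' @export
subset_panel <- function(panel, haps = NULL, sites = NULL,
                         require_polymorphic = FALSE) {
  if (is.null(haps)) haps <- seq_len(nrow(panel$alleles))
  if (is.null(sites)) {
    sites <- seq_len(ncol(panel$alleles))
  } else if (is.character(sites)) {
    sites <- match(sites, panel$site_ids)
    if (anyNA(sites)) stop("subset_panel: unknown site id(s)")
  }
  hap_panel(panel$alleles[haps, sites, drop = FALSE],
            panel$positions[sites], panel$site_ids[sites],
            require_polymorphic = require_polymorphic)
}

#' Scenario configuration for the mosaic haplotype simulator
#'
#' Bundles the knobs of a simulated locus: the population size, the number of
#' polymorphic sites, the founder-mosaic parameters controlling linkage
#' disequilibrium, and the causal-variant frequency floor. The mosaic model
#' builds each haplotype by copying stretches of a small set of founder
#' haplotypes, switching founders at rate `recomb_rate` per base pair, which
#' yields block-like LD that decays with distance -- the property the
#' downstream fine-mapping analysis depends on.
#'
#' @param n_samples number of diploid samples the locus is intended for.
#' @param n_sites number of polymorphic sites to deliver after frequency
#'   filtering.
#' @param n_haplotypes size of the haplotype pool (default `2 * n_samples`).
#' @param n_founders number of founder haplotypes (>= 2).
#' @param recomb_rate founder-switch probability per base pair.
#' @param mutation_rate per-allele flip probability, adding site-private noise
#'   that breaks complete LD between nearby sites.
#' @param site_spacing mean inter-site distance in base pairs.
#' @param causal_maf_min minimum minor-allele frequency allowed for a causal
#'   site (must lie in (0, 0.5]).
#' @param causal_id optional site id nominating the causal variant.
#' @param haplotype_spec optional explicit haplotype table for small loci (see
#'   [build_panel_from_haplotype_table()]).
#' @param seed integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 1366, n_sites = 150,
                            n_haplotypes = 2L * n_samples,
                            n_founders = 24, recomb_rate = 4e-5,
                            mutation_rate = 1e-3, site_spacing = 500,
                            causal_maf_min = 0.05, causal_id = NULL,
                            haplotype_spec = NULL, seed = 1L) {
  if (n_sites < 2) stop("scenario_config: n_sites must be >= 2")
  if (n_founders < 2) stop("scenario_config: n_founders must be >= 2")
  if (causal_maf_min <= 0 || causal_maf_min > 0.5) {
    stop("scenario_config: causal_maf_min must lie in (0, 0.5]")
  }
  if (recomb_rate < 0 || mutation_rate < 0) {
    stop("scenario_config: rates must be non-negative")
  }
  if (!is.null(haplotype_spec)) {
    s <- sum(haplotype_spec$freq)
    if (abs(s - 1) > 1e-9) {
      stop("scenario_config: explicit haplotype frequencies must sum to 1")
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
         n_haplotypes = as.integer(n_haplotypes),
         n_founders = as.integer(n_founders),
         recomb_rate = recomb_rate, mutation_rate = mutation_rate,
         site_spacing = site_spacing, causal_maf_min = causal_maf_min,
         causal_id = causal_id, haplotype_spec = haplotype_spec,
         seed = as.integer(seed)),
    class = "scenario_config")
}

#' Build a haplotype panel with a founder-mosaic model
#'
#' Each haplotype copies one of `n_founders` founder haplotypes, switching to
#' a uniformly chosen founder between adjacent sites with probability
#' `1 - exp(-recomb_rate * distance)`. The founders themselves are drawn from
#' a single random genealogy under the infinite-sites model, so founder-level
#' carrier sets are nested or disjoint (|D'| = 1 with variable r-squared, the
#' configuration real loci show) and site frequencies follow a neutral-like
#' spectrum; a small per-allele mutation rate then adds haplotype-private
#' variation that imperfect tagging and imputation have to contend with.
#' Monomorphic sites are dropped (with a message) and the first `n_sites`
#' surviving sites are returned. Pairwise LD is near-complete at adjacent
#' sites and decays with distance as recombination decouples founder choice.
#'
#' @param config a [scenario_config()].
#' @return a [hap_panel()] with `config$n_haplotypes` haplotypes and
#'   `config$n_sites` polymorphic sites. Deterministic given `config$seed`.
#' @export
build_panel_mosaic <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  h <- config$n_haplotypes
  k <- config$n_founders
  m_raw <- ceiling(1.4 * config$n_sites) + 8L

  gaps <- pmax(1, round(stats::rexp(m_raw, rate = 1 / config$site_spacing)))
  positions <- cumsum(gaps)

  founders <- founder_alleles_coalescent(k, m_raw)
  if (all(apply(founders, 2, function(col) length(unique(col)) == 1))) {
    stop("build_panel_mosaic: degenerate config -- all founders identical; ",
         "increase n_founders")
  }

  rho <- 1 - exp(-config$recomb_rate * diff(positions))
  fid <- matrix(0L, nrow = h, ncol = m_raw)
  fid[, 1] <- sample.int(k, h, replace = TRUE)
  for (j in 2:m_raw) {
    sw <- stats::runif(h) < rho[j - 1]
    fid[, j] <- ifelse(sw, sample.int(k, h, replace = TRUE), fid[, j - 1])
  }
  alleles <- matrix(founders[cbind(as.vector(fid),
                                   rep(seq_len(m_raw), each = h))],
                    nrow = h)
  if (config$mutation_rate > 0) {
    flip <- matrix(stats::runif(h * m_raw) < config$mutation_rate, nrow = h)
    alleles[flip] <- 1L - alleles[flip]
  }

  af <- colMeans(alleles)
  keep <- which(af > 0 & af < 1)
  n_dropped <- m_raw - length(keep)
  if (n_dropped > 0) {
    message(sprintf("build_panel_mosaic: dropped %d monomorphic site(s)",
                    n_dropped))
  }
  if (length(keep) < config$n_sites) {
    stop("build_panel_mosaic: fewer than n_sites polymorphic sites survived; ",
         "increase n_haplotypes or loosen frequencies")
  }
  keep <- keep[seq_len(config$n_sites)]
  hap_panel(alleles[, keep, drop = FALSE], positions[keep],
            sprintf("snp%05d", seq_along(keep)))
}

# Founder haplotypes drawn from a single random genealogy under the
# infinite-sites model: a Kingman coalescent topology over the k founders is
# simulated, and each site's derived allele is assigned to the founders below
# a branch chosen with probability proportional to branch length. Sites
# therefore carry nested/disjoint carrier sets (|D'| = 1 at the founder
# level, variable r^2) and a neutral-like frequency spectrum -- the local-LD
# features the locus simulator needs. Recombination in the mosaic layer
# decays this LD with distance.
founder_alleles_coalescent <- function(k, m) {
  sets <- vector("list", 2 * k - 2)
  lens <- numeric(2 * k - 2)
  active_sets <- as.list(seq_len(k))
  active_len <- numeric(k)
  nb <- 0L
  while (length(active_sets) > 1) {
    na <- length(active_sets)
    dt <- stats::rexp(1, rate = choose(na, 2))
    active_len <- active_len + dt
    pair <- sample.int(na, 2)
    for (i in pair) {
      nb <- nb + 1L
      sets[[nb]] <- active_sets[[i]]
      lens[nb] <- active_len[i]
    }
    merged <- c(active_sets[[pair[1]]], active_sets[[pair[2]]])
    active_sets[pair] <- NULL
    active_len <- active_len[-pair]
    active_sets[[length(active_sets) + 1]] <- merged
    active_len <- c(active_len, 0)
  }
  branch <- sample.int(nb, m, replace = TRUE, prob = lens[seq_len(nb)])
  founders <- matrix(0L, nrow = k, ncol = m)
  for (j in seq_len(m)) founders[sets[[branch[j]]], j] <- 1L
  founders
}

#' Build a haplotype panel from an explicit haplotype-frequency table
#'
#' Used for exact small-locus constructions, e.g. the three-haplotype system in
#' which the top SNP's minor allele carries every causal minor allele (D' = 1,
#' r-squared < 1). In `"exact"` mode realized counts are obtained by
#' largest-remainder rounding of `freqs * n_haplotypes`; in `"sample"` mode
#' they are a multinomial draw.
#'
#' @param haplotypes K x M binary matrix, one row per distinct haplotype.
#' @param freqs length-K non-negative frequencies summing to 1 (tol 1e-9).
#' @param n_haplotypes number of haplotype copies to realize.
#' @param mode `"sample"` (multinomial) or `"exact"` (largest remainder).
#' @param positions,site_ids optional site coordinates/ids (defaults: 1..M
#'   spaced 1000 bp, ids `snp1..snpM`).
#' @param seed integer seed (used in `"sample"` mode and to shuffle rows).
#' @return a [hap_panel()].
#' @export
build_panel_from_haplotype_table <- function(haplotypes, freqs, n_haplotypes,
                                             mode = c("sample", "exact"),
                                             positions = NULL, site_ids = NULL,
                                             seed = 1L) {
  mode <- match.arg(mode)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (any(freqs < 0)) stop("build_panel_from_haplotype_table: negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("build_panel_from_haplotype_table: frequencies must sum to 1")
  }
  if (nrow(haplotypes) != length(freqs)) {
    stop("build_panel_from_haplotype_table: one frequency per haplotype row")
  }
  set.seed(seed)
  if (mode == "exact") {
    target <- freqs * n_haplotypes
    counts <- floor(target)
    short <- n_haplotypes - sum(counts)
    if (short > 0) {
      counts[order(target - counts, decreasing = TRUE)[seq_len(short)]] <-
        counts[order(target - counts, decreasing = TRUE)[seq_len(short)]] + 1
    }
  } else {
    counts <- as.vector(stats::rmultinom(1, n_haplotypes, freqs))
  }
  rows <- rep(seq_along(freqs), counts)
  rows <- sample(rows)  # shuffle copy order
  alleles <- haplotypes[rows, , drop = FALSE]
  m <- ncol(alleles)
  if (is.null(positions)) positions <- seq_len(m) * 1000
  if (is.null(site_ids)) site_ids <- paste0("snp", seq_len(m))
  hap_panel(alleles, positions, site_ids)
}

#' Pair panel haplotypes into diploid samples
#'
#' Draws `2 * n_samples` haplotypes (with replacement) from the panel and sums
#' consecutive pairs into dosages in \{0, 1, 2\}. All sites are flagged as
#' genotyped with info score 1; the constituent haplotypes are retained (as an
#' attribute) so that downstream imputation can operate on the true phase.
#'
#' @param panel a [hap_panel()] with at least `2 * n_samples` haplotypes.
#' @param n_samples number of diploid samples.
#' @param seed integer seed.
#' @return a [geno_dataset()].
#' @export
pair_into_diploids <- function(panel, n_samples, seed = 1L) {
  h <- nrow(panel$alleles)
  if (h < 2 * n_samples) {
    stop("pair_into_diploids: panel must hold at least 2 * n_samples haplotypes")
  }
  set.seed(seed)
  idx <- sample.int(h, 2 * n_samples, replace = TRUE)
  haps <- panel$alleles[idx, , drop = FALSE]
  odd <- seq(1, 2 * n_samples, by = 2)
  dosages <- haps[odd, , drop = FALSE] + haps[odd + 1, , drop = FALSE]
  ds <- geno_dataset(dosages,
                     sample_ids = sprintf("sample%05d", seq_len(n_samples)),
                     site_ids = panel$site_ids,
                     positions = panel$positions,
                     genotyped = rep(TRUE, ncol(dosages)),
                     info = rep(1, ncol(dosages)))
  attr(ds, "haplotypes") <- haps
  ds
}

#' Choose a causal site from a panel or dataset
#'
#' Picks one site uniformly among those whose minor-allele frequency is at
#' least `maf_min`, optionally restricted to the central portion of the locus
#' (so the causal variant has flanking LD partners on both sides).
#'
#' @param x a [hap_panel()] or [geno_dataset()].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param central fraction of the site list (centred) to draw from.
#' @param seed integer seed.
#' @return a site id.
#' @export
choose_causal_site <- function(x, maf_min = 0.05, central = 0.5, seed = 1L) {
  if (inherits(x, "hap_panel")) {
    af <- colMeans(x$alleles)
    ids <- x$site_ids
  } else {
    af <- x$sites$maf
    ids <- x$sites$id
  }
  maf <- pmin(af, 1 - af)
  m <- length(ids)
  lo <- floor(m * (1 - central) / 2) + 1
  hi <- m - lo + 1
  eligible <- which(maf >= maf_min & seq_len(m) >= lo & seq_len(m) <= hi)
  if (!length(eligible)) eligible <- which(maf >= maf_min)
  if (!length(eligible)) {
    stop("choose_causal_site: no site reaches maf_min = ", maf_min)
  }
  set.seed(seed)
  ids[eligible[sample.int(length(eligible), 1)]]
}
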