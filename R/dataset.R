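#' Genotype dataset
#'
#' The fine-mapping input: an N x M matrix of allele dosages in [0, 2]
#' (hard genotypes for sequenced/array sites, posterior-mean dosages for
#' imputed sites) plus per-site metadata. The `genotyped` flag and `info`
#' score record each site's provenance; genotyped sites always carry
#' info = 1. Minor-allele frequency is recomputed from the dosages.
#'
#' @param dosages N x M numeric matrix with values in [0, 2] (NA = missing).
#' @param sample_ids length-N character vector.
#' @param site_ids length-M unique character vector.
#' @param positions length-M strictly increasing base-pair positions.
#' @param genotyped length-M logical; `TRUE` for directly observed sites.
#' @param info length-M numeric imputation info scores in [0, 1] (NA allowed
#'   for undefined scores at monomorphic sites).
#' @param hwe_p optional length-M Hardy-Weinberg exact-test p-values.
#' @return An object of class `geno_dataset`.
#' @export
geno_dataset <- function(dosages, sample_ids, site_ids, positions,
                         genotyped = rep(TRUE, ncol(dosages)),
                         info = rep(1, ncol(dosages)),
                         hwe_p = rep(NA_real_, ncol(dosages))) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (length(sample_ids) != n) stop("geno_dataset: sample_ids length mismatch")
  if (length(site_ids) != m || length(positions) != m ||
      length(genotyped) != m || length(info) != m) {
    stop("geno_dataset: per-site metadata length mismatch")
  }
  if (anyDuplicated(site_ids)) stop("geno_dataset: site_ids must be unique")
  if (m > 1 && any(diff(positions) <= 0)) {
    stop("geno_dataset: positions must be strictly increasing")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
    stop("geno_dataset: dosages must lie in [0, 2]")
  }
  if (any(genotyped & !is.na(info) & abs(info - 1) > 1e-9)) {
    stop("geno_dataset: genotyped sites must have info = 1")
  }
  p <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  missing_rate <- colMeans(is.na(dosages))
  sites <- data.frame(id = as.character(site_ids),
                      position = as.numeric(positions),
                      maf = maf,
                      genotyped = as.logical(genotyped),
                      info = as.numeric(info),
                      hwe_p = as.numeric(hwe_p),
                      missing_rate = missing_rate,
                      stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  colnames(dosages) <- sites$id
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 sites = sites),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf(
    "<geno_dataset> %d samples x %d sites (%d genotyped, %d imputed)\n",
    nrow(x$dosages), ncol(x$dosages),
    sum(x$sites$genotyped), sum(!x$sites$genotyped)))
  invisible(x)
}

#' Number of samples / sites in a dataset
#' @param data a [geno_dataset()].
#' @return integer count.
#' @export
n_samples <- function(data) nrow(data$dosages)

#' Dosage vector for one site
#' @param data a [geno_dataset()].
#' @param site a site id or column index.
#' @return numeric vector of length `n_samples(data)`.
#' @export
site_dosage <- function(data, site) {
  j <- site_index(data, site)
  data$dosages[, j]
}

site_index <- function(data, site) {
  if (is.character(site)) {
    j <- match(site, data$sites$id)
    if (anyNA(j)) {
      stop("unknown site id(s): ", paste(site[is.na(j)], collapse = ", "))
    }
    j
  } else {
    as.integer(site)
  }
}

#' Subset a genotype dataset by site
#'
#' Keeps per-site metadata, and (when present) the phased-haplotype attribute
#' so that imputation can still run on the restricted site set.
#'
#' @param data a [geno_dataset()].
#' @param sites site ids or column indices to keep (original position order is
#'   preserved).
#' @return a [geno_dataset()].
#' @export
subset_sites <- function(data, sites) {
  j <- sort(unique(site_index(data, sites)))
  out <- geno_dataset(data$dosages[, j, drop = FALSE],
                      data$sample_ids,
                      data$sites$id[j], data$sites$position[j],
                      genotyped = data$sites$genotyped[j],
                      info = data$sites$info[j],
                      hwe_p = data$sites$hwe_p[j])
  haps <- attr(data, "haplotypes")
  if (!is.null(haps)) attr(out, "haplotypes") <- haps[, j, drop = FALSE]
  out
}
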