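#' Write a genotype dataset as VCF
#'
#' Emits a minimal VCF 4.2 file: hard genotypes in the `GT` field (dosages
#' rounded), real-valued dosages in a `DS` field, the imputation info score
#' as the `II` INFO key, and a `TYPED` INFO flag on genotyped sites. All
#' records are biallelic (`A`/`G` placeholder alleles) on chromosome 1.
#'
#' @param data a [geno_dataset()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=finemapsim",
    "##INFO=<ID=II,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Directly genotyped\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", data$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(data$dosages))) {
    ds <- data$dosages[, j]
    hard <- pmin(pmax(round(ds), 0), 2)
    gt <- ifelse(is.na(ds), "./.", gt_codes[hard + 1])
    dss <- ifelse(is.na(ds), ".", formatC(ds, digits = 3, format = "f"))
    info <- if (is.na(data$sites$info[j])) "II=." else
      sprintf("II=%s", formatC(data$sites$info[j], digits = 4, format = "f"))
    if (data$sites$genotyped[j]) info <- paste0(info, ";TYPED")
    writeLines(paste(c("1", format(data$sites$position[j], scientific = FALSE),
                       data$sites$id[j], "A", "G", ".", "PASS", info,
                       "GT:DS", paste(gt, dss, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype dataset from VCF
#'
#' Parses a VCF (via `vcfR`) into a [geno_dataset()]. When a `DS` FORMAT
#' field is present its dosage is preferred over the hard `GT` genotype;
#' otherwise dosages are the GT allele counts. The `II` INFO key populates
#' the info score and a `TYPED` flag marks genotyped sites (defaults: info 1,
#' genotyped, when absent). Multiallelic records are rejected with their
#' record number.
#'
#' @param path VCF file path.
#' @return a [geno_dataset()]; round-trips with [write_genotypes_vcf()] to 3
#'   decimals on dosages.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("read_genotypes_vcf: multiallelic record(s) at record number(s): ",
         paste(which(multi), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- apply(gt, 2, function(col) {
    sapply(strsplit(col, "[/|]"), function(a) {
      a <- suppressWarnings(as.numeric(a))
      if (anyNA(a)) NA_real_ else sum(a)
    })
  })
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = nrow(gt))
  dosages <- t(alleles)  # extract.gt is variants x samples; we want N x M

  fmt <- v@gt[, 1]
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dosages_ds <- t(ds)
    dosages[!is.na(dosages_ds)] <- dosages_ds[!is.na(dosages_ds)]
  }

  info_str <- fix[, "INFO"]
  ii <- suppressWarnings(as.numeric(sub(".*II=([0-9.eE+-]+).*", "\\1",
                                        info_str)))
  ii[!grepl("II=", info_str)] <- NA_real_
  typed <- grepl("(^|;)TYPED($|;)", info_str)
  if (!any(grepl("II=", info_str))) ii <- rep(1, length(info_str))
  if (!any(grepl("TYPED|II=", info_str))) typed <- rep(TRUE, length(info_str))
  ii[typed] <- 1

  geno_dataset(dosages,
               sample_ids = colnames(gt),
               site_ids = fix[, "ID"],
               positions = as.numeric(fix[, "POS"]),
               genotyped = typed,
               info = ii)
}
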