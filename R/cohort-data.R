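#' Assemble a cohort dataset
#'
#' A `cohort_dataset` bundles one cohort's genotype matrix with its SNP
#' annotation and phenotype/covariate table; it is the unit on which all
#' per-cohort QC and model fitting operates.
#'
#' @param cohort_name Character scalar naming the cohort.
#' @param genotypes Numeric sample-by-SNP matrix of additive minor-allele
#'   counts (`0`, `1`, `2`, `NA` for missing). Row names are sample ids,
#'   column names SNP ids; if absent they are taken from `samples`/`snps`.
#' @param snps Data frame with one row per SNP: `snp_id`, `chromosome`,
#'   `position` (1-based), `effect_allele` (the minor allele whose carriage is
#'   modelled), `other_allele`, and optionally `maf`, `hwe_p`, `missing_rate`,
#'   `imputation_quality`. MAF and missing rate are (re)computed from the
#'   genotypes when absent.
#' @param samples Data frame with one row per sample: `sample_id`,
#'   `ad_status` (1 = case), `age` (years), `sex` (binary code), `e2_carrier`,
#'   `e4_carrier`, and optionally `family_id`.
#' @param has_family_structure Logical; when `NULL` it is inferred from
#'   duplicated non-missing `family_id` values. Cohorts with family structure
#'   get a family random intercept in the logistic fits.
#'
#' @return An object of class `cohort_dataset`.
#' @seealso [read_cohort()], [apply_qc()], [subset_cohort()]
#' @export
cohort_dataset <- function(cohort_name, genotypes, snps, samples,
                           has_family_structure = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  check_genotype_values(genotypes)

  req_snp <- c("snp_id", "chromosome", "position", "effect_allele", "other_allele")
  missing_cols <- setdiff(req_snp, names(snps))
  if (length(missing_cols)) {
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  req_smp <- c("sample_id", "ad_status", "age", "sex", "e2_carrier", "e4_carrier")
  missing_cols <- setdiff(req_smp, names(samples))
  if (length(missing_cols)) {
    stop("samples table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"family_id" %in% names(samples)) samples$family_id <- NA_character_
  samples$family_id <- as.character(samples$family_id)

  if (nrow(genotypes) != nrow(samples)) {
    stop("genotype rows (", nrow(genotypes), ") do not match samples (", nrow(samples), ")",
         call. = FALSE)
  }
  if (ncol(genotypes) != nrow(snps)) {
    stop("genotype columns (", ncol(genotypes), ") do not match snps (", nrow(snps), ")",
         call. = FALSE)
  }
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id in snps table", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id in samples table", call. = FALSE)
  rownames(genotypes) <- as.character(samples$sample_id)
  colnames(genotypes) <- as.character(snps$snp_id)

  if (!is_binary01(samples$ad_status)) stop("ad_status must be 0/1", call. = FALSE)
  if (any(!is.na(samples$age) & samples$age <= 0)) stop("age must be positive", call. = FALSE)
  for (v in c("e2_carrier", "e4_carrier")) {
    if (!is_binary01(samples[[v]])) stop(v, " must be 0/1", call. = FALSE)
  }

  if (is.null(snps$maf) || anyNA(snps$maf)) {
    snps$maf <- apply(genotypes, 2, function(g) {
      if (all(is.na(g))) NA_real_ else compute_maf(g)
    })
  }
  if (is.null(snps$missing_rate)) snps$missing_rate <- colMeans(is.na(genotypes))
  if (is.null(snps$hwe_p)) snps$hwe_p <- NA_real_
  if (is.null(snps$imputation_quality)) snps$imputation_quality <- NA_real_

  if (is.null(has_family_structure)) {
    fam <- samples$family_id[!is.na(samples$family_id) & samples$family_id != ""]
    has_family_structure <- anyDuplicated(fam) > 0L
  }

  structure(
    list(cohort_name = as.character(cohort_name),
         genotypes = genotypes,
         snps = snps,
         samples = samples,
         has_family_structure = isTRUE(has_family_structure)),
    class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", x$cohort_name, "\n", sep = "")
  cat("  samples: ", nrow(x$samples),
      " (", sum(x$samples$ad_status == 1, na.rm = TRUE), " cases / ",
      sum(x$samples$ad_status == 0, na.rm = TRUE), " controls)\n", sep = "")
  cat("  SNPs:    ", nrow(x$snps), "\n", sep = "")
  if (x$has_family_structure) cat("  family structure: yes\n")
  log <- attr(x, "exclusion_log")
  if (!is.null(log)) cat("  QC exclusions: ", nrow(log), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$genotypes)

#' Subset a cohort dataset by SNPs and/or samples
#'
#' MAF and missing rate of the retained SNPs are recomputed on the retained
#' samples; stored HWE p-values are cleared (they are recomputed by
#' [apply_qc()]).
#'
#' @param x A [cohort_dataset()].
#' @param snp_ids Character vector of SNP ids to keep (default: all).
#' @param sample_ids Character vector of sample ids (or logical mask) to keep.
#' @return A `cohort_dataset`.
#' @export
subset_cohort <- function(x, snp_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(x, "cohort_dataset"))
  keep_snp <- if (is.null(snp_ids)) x$snps$snp_id else snp_ids
  if (!all(keep_snp %in% x$snps$snp_id)) {
    stop("unknown snp_id: ", paste(setdiff(keep_snp, x$snps$snp_id), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    keep_smp <- x$samples$sample_id
  } else if (is.logical(sample_ids)) {
    keep_smp <- x$samples$sample_id[sample_ids]
  } else {
    keep_smp <- sample_ids
  }
  snps <- x$snps[match(keep_snp, x$snps$snp_id), , drop = FALSE]
  smp <- x$samples[match(keep_smp, x$samples$sample_id), , drop = FALSE]
  g <- x$genotypes[as.character(keep_smp), as.character(keep_snp), drop = FALSE]
  snps$maf <- apply(g, 2, function(col) if (all(is.na(col))) NA_real_ else compute_maf(col))
  snps$missing_rate <- colMeans(is.na(g))
  snps$hwe_p <- NA_real_
  rownames(snps) <- NULL
  rownames(smp) <- NULL
  cohort_dataset(x$cohort_name, g, snps, smp,
                 has_family_structure = x$has_family_structure)
}
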