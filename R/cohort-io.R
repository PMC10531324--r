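#' Read one cohort's genotype and phenotype files
#'
#' Reads genotypes from a VCF (v4.x, `GT` field, biallelic sites only; phased
#' and unphased genotypes are both accepted and phase is discarded) or from a
#' dosage TSV (`sample_id` column followed by one additive-count column per
#' SNP), joins them to a phenotype TSV, restricts to samples present in both
#' files, and orients every SNP so that the counted (effect) allele is the
#' minor allele in this cohort.
#'
#' The phenotype TSV is tab-separated with columns `sample_id`, `family_id`,
#' `ad_status`, `age`, `sex`, `e2_carrier`, `e4_carrier` (`NA` for missing).
#' For dosage input an optional SNP-info sidecar (`snp_info_path`; columns
#' `snp_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' optionally `imputation_quality`) supplies coordinates and alleles; without
#' it, positions default to column order and alleles are unknown.
#'
#' @param genotype_path Path to the VCF or dosage TSV.
#' @param phenotype_path Path to the phenotype TSV.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @param cohort_name Cohort label; defaults to the genotype file stem.
#' @param snp_info_path Optional SNP annotation TSV (dosage format only).
#' @param has_family_structure Passed to [cohort_dataset()]; `NULL` infers it.
#' @return A [cohort_dataset()] whose `effect_allele` is the cohort minor
#'   allele (MAF <= 0.5).
#' @export
read_cohort <- function(genotype_path, phenotype_path,
                        format = c("auto", "vcf", "dosage"),
                        cohort_name = NULL, snp_info_path = NULL,
                        has_family_structure = NULL) {
  format <- match.arg(format)
  for (p in c(genotype_path, phenotype_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", genotype_path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (is.null(cohort_name)) {
    cohort_name <- sub("\\.(vcf|tsv|txt)(\\.gz)?$", "", basename(genotype_path),
                       ignore.case = TRUE)
  }

  geno <- if (format == "vcf") read_genotypes_vcf(genotype_path)
          else read_genotypes_dosage(genotype_path, snp_info_path)
  pheno <- read_phenotypes(phenotype_path)

  shared <- intersect(rownames(geno$matrix), pheno$sample_id)
  if (length(shared) == 0L) {
    stop("no overlapping sample ids between genotype and phenotype files", call. = FALSE)
  }
  g <- geno$matrix[shared, , drop = FALSE]
  smp <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  rownames(smp) <- NULL
  snps <- geno$snps

  # orient so the effect allele is the cohort minor allele
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    nm <- sum(!is.na(col))
    if (nm == 0L) next
    f <- sum(col, na.rm = TRUE) / (2 * nm)
    if (f > 0.5) {
      g[, j] <- 2 - col
      ea <- snps$effect_allele[j]
      snps$effect_allele[j] <- snps$other_allele[j]
      snps$other_allele[j] <- ea
    }
  }
  snps$maf <- NULL
  snps$missing_rate <- NULL

  cohort_dataset(cohort_name, g, snps, smp, has_family_structure = has_family_structure)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "ID", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- which(grepl(",", fix$ALT, fixed = TRUE))[1]
    stop("multi-allelic site not supported (variant line ", bad, ": ",
         fix$CHROM[bad], ":", fix$POS[bad], ")", call. = FALSE)
  }
  ids <- fix$ID
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix$CHROM[blank], ":", fix$POS[blank])
  if (anyDuplicated(ids)) stop("duplicated variant ids in VCF", call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "./." = NA, "." = NA, "./0" = NA, "0/." = NA, "./1" = NA, "1/." = NA)
  known <- is.na(gt) | gt %in% names(lut)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("unparseable GT '", gt[!known][1], "' at variant line ", bad[1], call. = FALSE)
  }
  counts <- matrix(lut[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  counts <- t(counts)  # samples x SNPs
  colnames(counts) <- ids

  snps <- data.frame(snp_id = ids,
                     chromosome = as.character(fix$CHROM),
                     position = as.integer(fix$POS),
                     effect_allele = as.character(fix$ALT),
                     other_allele = as.character(fix$REF),
                     stringsAsFactors = FALSE)
  list(matrix = counts, snps = snps)
}

read_genotypes_dosage <- function(path, snp_info_path = NULL) {
  d <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "sample_id") {
    stop("dosage TSV must start with a 'sample_id' column (", path, ", line 1)", call. = FALSE)
  }
  ids <- as.character(d$sample_id)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  check_genotype_values(m, what = paste0("dosage (", path, ")"))
  rownames(m) <- ids

  if (!is.null(snp_info_path)) {
    info <- read.delim(snp_info_path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(colnames(m) %in% info$snp_id)) {
      stop("snp info file lacks entries for: ",
           paste(setdiff(colnames(m), info$snp_id), collapse = ", "), call. = FALSE)
    }
    info <- info[match(colnames(m), info$snp_id), , drop = FALSE]
    snps <- data.frame(snp_id = colnames(m),
                       chromosome = as.character(info$chromosome),
                       position = as.integer(info$position),
                       effect_allele = as.character(info$effect_allele),
                       other_allele = as.character(info$other_allele),
                       stringsAsFactors = FALSE)
    if (!is.null(info$imputation_quality)) snps$imputation_quality <- info$imputation_quality
  } else {
    snps <- data.frame(snp_id = colnames(m),
                       chromosome = NA_character_,
                       position = seq_len(ncol(m)),
                       effect_allele = NA_character_,
                       other_allele = NA_character_,
                       stringsAsFactors = FALSE)
  }
  list(matrix = m, snps = snps)
}

read_phenotypes <- function(path) {
  p <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("sample_id", "ad_status", "age", "sex", "e2_carrier", "e4_carrier")
  miss <- setdiff(req, names(p))
  if (length(miss)) {
    stop("phenotype file ", path, " lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p$sample_id <- as.character(p$sample_id)
  p
}

#' Minor allele frequency of one genotype column
#'
#' Allele-count frequency of the minor allele among non-missing genotypes;
#' always at most 0.5 regardless of which allele the column counts.
#'
#' @param genotype_column Additive counts in `{0, 1, 2, NA}`.
#' @return Fraction in `[0, 0.5]`.
#' @export
compute_maf <- function(genotype_column) {
  check_genotype_values(genotype_column)
  n <- sum(!is.na(genotype_column))
  if (n == 0L) stop("all genotypes missing; MAF undefined", call. = FALSE)
  f <- sum(genotype_column, na.rm = TRUE) / (2 * n)
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of the observed heterozygote count given the allele
#' counts (the conditional-enumeration test of Wigginton et al. type): all
#' heterozygote counts compatible with the allele counts are enumerated and
#' the probabilities of outcomes no more likely than the observed one are
#' summed.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (either homozygote may be the minor
#'   one; the test is symmetric).
#' @return Exact two-sided p-value. Monomorphic input returns 1 with a warning.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0L) stop("no genotypes", call. = FALSE)
  n_rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_rare == 0L) {
    warning("monomorphic column; HWE p-value set to 1")
    return(1)
  }
  # heterozygote counts share the parity of the rare-allele count
  h <- seq(n_rare %% 2, n_rare, by = 2)
  hom_rare <- (n_rare - h) / 2
  hom_common <- n - h - hom_rare
  keep <- hom_common >= 0
  h <- h[keep]; hom_rare <- hom_rare[keep]; hom_common <- hom_common[keep]
  lp <- lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) - lfactorial(hom_common) +
    h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' QC threshold configuration
#'
#' Defaults follow standard imputed-array practice: MAF at least 5%, exact
#' HWE p at least 1e-6, SNP and sample missingness at most 5%, and imputation
#' quality r^2 at least 0.9 where an imputation-quality column is present.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum exact HWE p-value.
#' @param snp_missing_max,sample_missing_max Maximum missing-data fractions.
#' @param imputation_r2_min Minimum imputation quality (applied only to SNPs
#'   carrying a non-missing `imputation_quality` value).
#' @param hwe_sample_set `"controls"` (default; avoids association-driven HWE
#'   departures in cases) or `"all"`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-6,
                          snp_missing_max = 0.05, sample_missing_max = 0.05,
                          imputation_r2_min = 0.9,
                          hwe_sample_set = c("controls", "all")) {
  hwe_sample_set <- match.arg(hwe_sample_set)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 snp_missing_max = snp_missing_max,
                 sample_missing_max = sample_missing_max,
                 imputation_r2_min = imputation_r2_min,
                 hwe_sample_set = hwe_sample_set),
            class = "qc_thresholds")
}

#' Apply per-cohort quality control
#'
#' Samples failing the missingness threshold are removed first; SNP metrics
#' (MAF, missing rate, exact HWE p on the configured sample set) are then
#' recomputed on the retained samples and SNPs failing any rule are removed.
#' Every removal is recorded in the exclusion log attached to the result as
#' attribute `"exclusion_log"` (columns `item`, `type`, `rule`, `value`,
#' `threshold`); see [write_exclusion_log()].
#'
#' @param dataset A [cohort_dataset()].
#' @param thresholds A [qc_thresholds()] configuration.
#' @return The filtered `cohort_dataset` with updated SNP metrics.
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(thresholds, "qc_thresholds"))
  g <- dataset$genotypes
  log <- list()

  smp_miss <- rowMeans(is.na(g))
  bad_smp <- smp_miss > thresholds$sample_missing_max
  if (any(bad_smp)) {
    log[[length(log) + 1L]] <- data.frame(
      item = rownames(g)[bad_smp], type = "sample", rule = "missingness",
      value = smp_miss[bad_smp], threshold = thresholds$sample_missing_max,
      stringsAsFactors = FALSE)
  }
  keep_smp <- dataset$samples$sample_id[!bad_smp]
  if (length(keep_smp) == 0L) stop("no samples pass QC", call. = FALSE)
  g <- g[as.character(keep_smp), , drop = FALSE]
  smp <- dataset$samples[match(keep_smp, dataset$samples$sample_id), , drop = FALSE]

  is_ctrl <- !is.na(smp$ad_status) & smp$ad_status == 0
  hwe_rows <- if (thresholds$hwe_sample_set == "controls" && any(is_ctrl)) is_ctrl
              else rep(TRUE, nrow(smp))

  snps <- dataset$snps
  m <- nrow(snps)
  maf <- miss <- hwe <- numeric(m)
  for (j in seq_len(m)) {
    col <- g[, j]
    miss[j] <- mean(is.na(col))
    maf[j] <- if (all(is.na(col))) 0 else compute_maf(col)
    hcol <- col[hwe_rows]
    hwe[j] <- suppressWarnings(
      if (all(is.na(hcol))) 1
      else hwe_exact_test(sum(hcol == 0, na.rm = TRUE),
                          sum(hcol == 1, na.rm = TRUE),
                          sum(hcol == 2, na.rm = TRUE)))
  }
  snps$maf <- maf
  snps$missing_rate <- miss
  snps$hwe_p <- hwe

  rule <- rep(NA_character_, m)
  value <- thr <- rep(NA_real_, m)
  mark <- function(idx, r, v, t) {
    sel <- idx & is.na(rule)
    rule[sel] <<- r; value[sel] <<- v[sel]; thr[sel] <<- t
  }
  mark(miss > thresholds$snp_missing_max, "missingness", miss, thresholds$snp_missing_max)
  mark(maf < thresholds$maf_min, "maf", maf, thresholds$maf_min)
  mark(hwe < thresholds$hwe_p_min, "hwe", hwe, thresholds$hwe_p_min)
  iq <- snps$imputation_quality
  has_iq <- !is.na(iq)
  mark(has_iq & iq < thresholds$imputation_r2_min, "imputation_quality",
       ifelse(has_iq, iq, NA_real_), thresholds$imputation_r2_min)

  bad_snp <- !is.na(rule)
  if (any(bad_snp)) {
    log[[length(log) + 1L]] <- data.frame(
      item = snps$snp_id[bad_snp], type = "snp", rule = rule[bad_snp],
      value = value[bad_snp], threshold = thr[bad_snp], stringsAsFactors = FALSE)
  }
  if (all(bad_snp)) stop("no SNPs pass QC: empty panel", call. = FALSE)

  keep <- snps[!bad_snp, , drop = FALSE]
  rownames(keep) <- NULL
  out <- cohort_dataset(dataset$cohort_name,
                        g[, !bad_snp, drop = FALSE],
                        keep,
                        smp,
                        has_family_structure = dataset$has_family_structure)
  exclusions <- if (length(log)) do.call(rbind, log) else
    data.frame(item = character(), type = character(), rule = character(),
               value = numeric(), threshold = numeric(), stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  attr(out, "exclusion_log") <- exclusions
  out
}

#' Write a QC exclusion log as TSV
#'
#' @param dataset A QC'd [cohort_dataset()] (output of [apply_qc()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(dataset, path) {
  log <- attr(dataset, "exclusion_log")
  if (is.null(log)) stop("dataset carries no exclusion log; run apply_qc() first", call. = FALSE)
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD pruning of a SNP panel
#'
#' SNPs are visited in ascending position order (ties broken by SNP id) and a
#' SNP is retained only if its genotypic (composite) r^2 with every
#' previously retained SNP is at most `r2_max`; the later-positioned SNP of an
#' offending pair is always the one dropped. Deterministic for fixed input.
#'
#' @param dataset A [cohort_dataset()].
#' @param r2_max Maximum allowed pairwise r^2 among retained SNPs (in (0, 1]).
#' @return Character vector of retained SNP ids, in position order.
#' @export
ld_prune <- function(dataset, r2_max = 0.7) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (!(r2_max > 0 && r2_max <= 1)) stop("r2_max must be in (0, 1]", call. = FALSE)
  snps <- dataset$snps
  ord <- order(snps$position, snps$snp_id)
  ids <- snps$snp_id[ord]
  g <- dataset$genotypes[, ids, drop = FALSE]
  kept <- character(0)
  for (id in ids) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(cor(g[, id], g[, k], use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Dominant (carrier) coding of additive genotypes
#'
#' Heterozygotes and minor-allele homozygotes share one effect: additive
#' counts 1 and 2 both map to carrier status 1; missing stays missing.
#'
#' @param genotype_column Additive counts in `{0, 1, 2, NA}`.
#' @return Binary carrier vector (`NA` preserved).
#' @export
dominant_code <- function(genotype_column) {
  check_genotype_values(genotype_column)
  pmin(genotype_column, 1)
}

#' Harmonize several cohorts to a shared, consistently oriented SNP panel
#'
#' Restricts all cohorts to the SNP ids common to every cohort (kept in the
#' first cohort's position order) and re-orients later cohorts to the first
#' cohort's effect allele, flipping additive counts where the minor allele
#' differs between cohorts. Cohorts whose alleles are incompatible with the
#' first cohort's (neither matching nor swapped) raise an error naming the
#' offending SNPs. Cohorts with unknown alleles (plain dosage input) are
#' assumed to already count the same allele.
#'
#' @param cohorts List of [cohort_dataset()] objects.
#' @return List of harmonized `cohort_dataset` objects.
#' @export
harmonize_cohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1, all(vapply(cohorts, inherits, TRUE, "cohort_dataset")))
  shared <- Reduce(intersect, lapply(cohorts, function(d) d$snps$snp_id))
  if (length(shared) == 0L) stop("no SNP ids shared by all cohorts", call. = FALSE)
  ref <- cohorts[[1]]$snps
  ref <- ref[ref$snp_id %in% shared, , drop = FALSE]
  shared <- ref$snp_id[order(ref$position, ref$snp_id)]
  ref <- ref[match(shared, ref$snp_id), , drop = FALSE]

  out <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    d <- subset_cohort(cohorts[[i]], snp_ids = shared)
    if (i > 1L) {
      ea <- d$snps$effect_allele; oa <- d$snps$other_allele
      known <- !is.na(ea) & !is.na(ref$effect_allele)
      same <- known & ea == ref$effect_allele & oa == ref$other_allele
      swapped <- known & ea == ref$other_allele & oa == ref$effect_allele
      bad <- known & !same & !swapped
      if (any(bad)) {
        stop("allele mismatch with cohort '", cohorts[[1]]$cohort_name, "' for: ",
             paste(d$snps$snp_id[bad], collapse = ", "), call. = FALSE)
      }
      if (any(swapped)) {
        g <- d$genotypes
        g[, swapped] <- 2 - g[, swapped]
        snps <- d$snps
        snps$effect_allele[swapped] <- ref$effect_allele[swapped]
        snps$other_allele[swapped] <- ref$other_allele[swapped]
        d <- cohort_dataset(d$cohort_name, g, snps, d$samples,
                            has_family_structure = d$has_family_structure)
      }
    }
    out[[i]] <- d
  }
  out
}
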