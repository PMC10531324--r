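# Latent-Gaussian haplotype simulator. Each SNP's minor allele on one
# haplotype is an indicator that a standard normal falls below qnorm(maf);
# pairwise latent correlations are calibrated (tetrachoric inversion) so the
# *allelic* correlation of the binary haplotypes matches the requested LD.

#' Simulation configuration for multi-cohort case-control data
#'
#' Defaults describe a four-cohort AD-style case-control design: cohort sizes
#' in the proportions of large consortium, sequencing, family-based and
#' biobank collections; a common-variant panel; logistic disease risk with
#' dominant SNP effects, optional compound-genotype cell effects, and
#' age/sex/APOE-carrier covariates; 40% cases.
#'
#' @param n_snps Number of SNPs in the shared panel.
#' @param maf Vector of minor allele frequencies (recycled to `n_snps`).
#' @param ld_target Symmetric positive semi-definite matrix of target
#'   *allelic* (haplotype-level) correlations, unit diagonal.
#' @param n_per_cohort Cohort sizes; its length sets the number of cohorts.
#' @param cohort_names Cohort labels, fixed order (direction strings follow it).
#' @param main_effects Per-SNP dominant log-odds effects (recycled).
#' @param compg_effects Optional list of compound-genotype cell effects, each
#'   element `list(pair = c(i, j), beta = c(Mm = , mM = , mm = ))` with `i`,
#'   `j` panel indices (i < j); effects of multiple pairs add on the log-odds
#'   scale.
#' @param covariate_effects Named log-odds effects `age` (per decade of age),
#'   `sex`, `e2`, `e4`.
#' @param covariate_freqs Named frequencies of `sex`, `e2` and `e4` being 1.
#' @param age_mean,age_sd Age distribution (years).
#' @param min_control_age Controls younger than this are age-resampled from
#'   the truncated distribution (the biobank age-matching rule); `NULL`
#'   disables.
#' @param target_case_fraction Realized by tuning the intercept.
#' @param family_structure `NULL`, or `list(fraction = , size = , sd = )`:
#'   the fraction of samples grouped into families of the given size sharing
#'   a normal random intercept with that standard deviation.
#' @param family_cohorts Indices of cohorts with family structure (defaults
#'   to the third cohort when `family_structure` is given).
#' @param missing_rate MCAR genotype missingness.
#' @param seed Master seed; per-cohort seeds derive from it deterministically.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10,
                       maf = 0.25,
                       ld_target = NULL,
                       n_per_cohort = c(15000, 10000, 4000, 30000),
                       cohort_names = NULL,
                       main_effects = 0,
                       compg_effects = list(),
                       covariate_effects = c(age = 0.5, sex = 0.2, e2 = -0.5, e4 = 1.2),
                       covariate_freqs = c(sex = 0.5, e2 = 0.15, e4 = 0.30),
                       age_mean = 75, age_sd = 6, min_control_age = 65,
                       target_case_fraction = 0.4,
                       family_structure = NULL,
                       family_cohorts = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  maf <- rep_len(maf, n_snps)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (is.null(ld_target)) ld_target <- diag(n_snps)
  ld_target <- as.matrix(ld_target)
  if (!isTRUE(all.equal(ld_target, t(ld_target))) ||
      !isTRUE(all.equal(diag(ld_target), rep(1, n_snps)))) {
    stop("ld_target must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(ld_target, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("ld_target must be positive semi-definite", call. = FALSE)
  }
  if (!(target_case_fraction > 0 && target_case_fraction < 1)) {
    stop("target_case_fraction must be in (0, 1)", call. = FALSE)
  }
  main_effects <- rep_len(main_effects, n_snps)
  for (ce in compg_effects) {
    stopifnot(length(ce$pair) == 2, all(ce$pair %in% seq_len(n_snps)),
              ce$pair[1] < ce$pair[2],
              all(c("Mm", "mM", "mm") %in% names(ce$beta)))
  }
  if (is.null(cohort_names)) {
    cohort_names <- paste0("cohort", seq_along(n_per_cohort))
  }
  if (!is.null(family_structure)) {
    stopifnot(all(c("fraction", "size", "sd") %in% names(family_structure)))
    if (is.null(family_cohorts)) family_cohorts <- min(3L, length(n_per_cohort))
  } else {
    family_cohorts <- integer(0)
  }
  structure(list(n_snps = n_snps, maf = maf, ld_target = ld_target,
                 n_per_cohort = n_per_cohort, cohort_names = cohort_names,
                 main_effects = main_effects, compg_effects = compg_effects,
                 covariate_effects = covariate_effects,
                 covariate_freqs = covariate_freqs,
                 age_mean = age_mean, age_sd = age_sd,
                 min_control_age = min_control_age,
                 target_case_fraction = target_case_fraction,
                 family_structure = family_structure,
                 family_cohorts = family_cohorts,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by 1-D Gaussian quadrature over the first coordinate.
pnorm2 <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(pnorm(t1) * pnorm(t2))
  if (rho >= 1 - 1e-12) return(pnorm(min(t1, t2)))
  if (rho <= -1 + 1e-12) return(max(0, pnorm(t1) + pnorm(t2) - 1))
  s <- sqrt(1 - rho^2)
  integrate(function(x) pnorm((t2 - rho * x) / s) * dnorm(x),
            lower = -9, upper = t1, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

allelic_r_from_latent <- function(rho, maf1, maf2) {
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  p11 <- pnorm2(t1, t2, rho)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Calibrate the latent correlation for a target allelic LD
#'
#' Numerically inverts the tetrachoric relation: finds the latent bivariate
#' normal correlation such that thresholded haplotype indicators with the
#' given minor allele frequencies have the requested allelic correlation r.
#' Targets outside the Frechet-bound feasible interval raise an error
#' reporting that interval.
#'
#' @param target_allelic_r Desired haplotype-level correlation.
#' @param maf1,maf2 Minor allele frequencies of the two SNPs.
#' @return Latent correlation in `[-1, 1]`.
#' @export
calibrate_latent_correlation <- function(target_allelic_r, maf1, maf2) {
  stopifnot(maf1 > 0, maf1 < 1, maf2 > 0, maf2 < 1)
  if (abs(target_allelic_r) < 1e-12) return(0)
  denom <- sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  r_max <- (min(maf1, maf2) - maf1 * maf2) / denom
  r_min <- (max(0, maf1 + maf2 - 1) - maf1 * maf2) / denom
  if (target_allelic_r > r_max + 1e-10 || target_allelic_r < r_min - 1e-10) {
    stop(sprintf("target allelic r = %.4g infeasible for MAFs (%.3g, %.3g); feasible interval [%.4g, %.4g]",
                 target_allelic_r, maf1, maf2, r_min, r_max), call. = FALSE)
  }
  if (target_allelic_r >= r_max - 1e-10) return(1)
  if (target_allelic_r <= r_min + 1e-10) return(-1)
  uniroot(function(rho) allelic_r_from_latent(rho, maf1, maf2) - target_allelic_r,
          lower = -1 + 1e-9, upper = 1 - 1e-9, tol = 1e-10)$root
}

latent_sigma <- function(config) {
  m <- config$n_snps
  S <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      S[i, j] <- S[j, i] <- calibrate_latent_correlation(
        config$ld_target[i, j], config$maf[i], config$maf[j])
    }
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    # nearest-PD adjustment: clip eigenvalues, restore unit diagonal
    v <- pmax(ev$values, 1e-8)
    S <- ev$vectors %*% (v * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
  }
  S
}

snp_panel_table <- function(config) {
  m <- config$n_snps
  data.frame(snp_id = sprintf("snp%02d", seq_len(m)),
             chromosome = "1",
             position = 1000000L + (seq_len(m) - 1L) * 5000L,
             effect_allele = "A",
             other_allele = "G",
             stringsAsFactors = FALSE)
}

#' Simulate one cohort's genotype matrix
#'
#' Two independent haplotypes per individual are drawn from the calibrated
#' latent-Gaussian model and summed; deterministic given the configuration
#' seed and cohort index.
#'
#' @param config A [sim_config()].
#' @param cohort_index Which cohort to generate.
#' @return Sample-by-SNP matrix of additive counts (with MCAR missingness if
#'   configured).
#' @export
simulate_genotypes <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"),
            cohort_index >= 1, cohort_index <= length(config$n_per_cohort))
  set.seed(derive_seed(config$seed, cohort_index, 1L))
  n <- config$n_per_cohort[cohort_index]
  m <- config$n_snps
  L <- chol(latent_sigma(config))
  thr <- qnorm(config$maf)
  Z <- matrix(rnorm(2 * n * m), ncol = m) %*% L
  hap <- sweep(Z, 2, thr, "<") + 0
  g <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
  if (config$missing_rate > 0) {
    g[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_real_
  }
  panel <- snp_panel_table(config)
  dimnames(g) <- list(sprintf("%s_S%05d", config$cohort_names[cohort_index], seq_len(n)),
                      panel$snp_id)
  g
}

#' Simulate phenotypes and covariates for a genotype matrix
#'
#' Draws age, sex and APOE epsilon-2/epsilon-4 carrier covariates, assembles
#' the logistic linear predictor (dominant main effects, compound-genotype
#' cell effects of configured pairs, covariate effects, optional family
#' random intercept), tunes the intercept so the expected case fraction
#' matches the target, and draws case status.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param cohort_index Cohort being generated.
#' @return List: `samples` (phenotype data frame) and `truth` (realized
#'   intercept, case fraction and generating effects).
#' @export
simulate_phenotypes <- function(genotypes, config, cohort_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, cohort_index, 2L))
  n <- nrow(genotypes)
  cf <- config$covariate_freqs
  ce <- config$covariate_effects
  age <- rnorm(n, config$age_mean, config$age_sd)
  age[age < 40] <- 40
  sex <- rbinom(n, 1, cf[["sex"]])
  e2 <- rbinom(n, 1, cf[["e2"]])
  e4 <- rbinom(n, 1, cf[["e4"]])

  carriers <- pmin(genotypes, 1)
  carriers[is.na(carriers)] <- 0  # masked genotypes enter the risk model as non-carriers
  lp <- as.vector(carriers %*% config$main_effects)
  for (cep in config$compg_effects) {
    cg <- build_compound_genotype(carriers[, cep$pair[1]], carriers[, cep$pair[2]])
    add <- c(MM = 0, cep$beta[c("Mm", "mM", "mm")])
    lp <- lp + add[as.integer(cg)]
  }
  lp <- lp + ce[["age"]] * (age - config$age_mean) / 10 +
    ce[["sex"]] * sex + ce[["e2"]] * e2 + ce[["e4"]] * e4

  family_id <- rep(NA_character_, n)
  if (cohort_index %in% config$family_cohorts) {
    fs <- config$family_structure
    n_clustered <- floor(n * fs$fraction / fs$size) * fs$size
    if (n_clustered > 0) {
      fam <- rep(seq_len(n_clustered / fs$size), each = fs$size)
      family_id[seq_len(n_clustered)] <- sprintf("F%04d", fam)
      if (fs$sd > 0) {  # sd = 0 must reproduce the unclustered stream exactly
        u <- rnorm(max(fam), 0, fs$sd)
        lp[seq_len(n_clustered)] <- lp[seq_len(n_clustered)] + u[fam]
      }
    }
  }

  b0 <- tryCatch(
    uniroot(function(b) mean(plogis(lp + b)) - config$target_case_fraction,
            lower = -30, upper = 30, tol = 1e-10)$root,
    error = function(e) stop("intercept calibration failed: ", conditionMessage(e),
                             call. = FALSE))
  status <- rbinom(n, 1, plogis(lp + b0))

  if (!is.null(config$min_control_age)) {
    young_ctrl <- status == 0 & age < config$min_control_age
    if (any(young_ctrl)) {
      lo <- pnorm(config$min_control_age, config$age_mean, config$age_sd)
      u <- runif(sum(young_ctrl), lo, 1)
      age[young_ctrl] <- qnorm(u, config$age_mean, config$age_sd)
    }
  }

  samples <- data.frame(sample_id = rownames(genotypes),
                        family_id = family_id,
                        ad_status = status,
                        age = age, sex = sex,
                        e2_carrier = e2, e4_carrier = e4,
                        stringsAsFactors = FALSE)
  truth <- list(cohort = config$cohort_names[cohort_index],
                intercept = b0,
                case_fraction = mean(status),
                main_effects = config$main_effects,
                compg_effects = config$compg_effects,
                covariate_effects = as.list(config$covariate_effects),
                seed = config$seed)
  list(samples = samples, truth = truth)
}

#' Generate all configured cohorts
#'
#' @param config A [sim_config()].
#' @return List of `sim_cohort` objects, each holding `dataset`
#'   (a [cohort_dataset()]) and `truth` (the realized generating parameters).
#' @export
generate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- snp_panel_table(config)
  lapply(seq_along(config$n_per_cohort), function(i) {
    g <- simulate_genotypes(config, i)
    ph <- simulate_phenotypes(g, config, i)
    ds <- cohort_dataset(config$cohort_names[i], g, panel, ph$samples,
                         has_family_structure = i %in% config$family_cohorts)
    structure(list(dataset = ds, truth = ph$truth), class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  print(x$dataset)
  invisible(x)
}

#' Write a cohort to disk in the dialects read_cohort() reads
#'
#' Writes the genotype file (dosage TSV or minimal VCFv4.2), the phenotype
#' TSV, a SNP-info sidecar TSV, and — for simulated cohorts — a `truth` JSON
#' sidecar.
#'
#' @param x A [cohort_dataset()] or `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"dosage"` or `"vcf"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(x, dir, format = c("dosage", "vcf")) {
  format <- match.arg(format)
  truth <- NULL
  if (inherits(x, "sim_cohort")) { truth <- x$truth; x <- x$dataset }
  stopifnot(inherits(x, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, x$cohort_name)
  paths <- c()

  if (format == "dosage") {
    gp <- paste0(stem, ".dosage.tsv")
    d <- data.frame(sample_id = rownames(x$genotypes), x$genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
    write.table(d, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gp <- paste0(stem, ".vcf")
    write_minimal_vcf(x, gp)
  }
  paths["genotypes"] <- gp

  pp <- paste0(stem, ".pheno.tsv")
  write.table(x$samples[, c("sample_id", "family_id", "ad_status", "age", "sex",
                            "e2_carrier", "e4_carrier")],
              pp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["phenotypes"] <- pp

  ip <- paste0(stem, ".snpinfo.tsv")
  info_cols <- c("snp_id", "chromosome", "position", "effect_allele", "other_allele")
  if (any(!is.na(x$snps$imputation_quality))) info_cols <- c(info_cols, "imputation_quality")
  write.table(x$snps[, info_cols], ip, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["snp_info"] <- ip

  if (!is.null(truth)) {
    tp <- paste0(stem, ".truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["truth"] <- tp
  }
  invisible(paths)
}

write_minimal_vcf <- function(x, path) {
  ea <- ifelse(is.na(x$snps$effect_allele), "A", x$snps$effect_allele)
  oa <- ifelse(is.na(x$snps$other_allele), "G", x$snps$other_allele)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(x$genotypes)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(x$snps))) {
    g <- x$genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    writeLines(paste(c(ifelse(is.na(x$snps$chromosome[j]), "1", x$snps$chromosome[j]),
                       x$snps$position[j],
                       x$snps$snp_id[j], oa[j], ea[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
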