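#' Build the compound genotype of a SNP pair
#'
#' Two dominant-coded SNPs define a four-level factor: `MM` (carrier of
#' neither minor allele), `Mm` (carrier at SNP2 only), `mM` (carrier at SNP1
#' only), `mm` (carrier at both). A missing carrier state at either SNP gives
#' a missing compound genotype.
#'
#' @param carrier1,carrier2 Binary carrier vectors for SNP1 and SNP2
#'   (outputs of [dominant_code()]; additive counts are also accepted and
#'   dominant-coded on the fly).
#' @return Factor with levels `MM`, `Mm`, `mM`, `mm`.
#' @export
build_compound_genotype <- function(carrier1, carrier2) {
  c1 <- dominant_code(carrier1)
  c2 <- dominant_code(carrier2)
  if (length(c1) != length(c2)) stop("carrier vectors differ in length", call. = FALSE)
  lv <- c("MM", "Mm", "mM", "mm")
  idx <- 1L + 2L * c1 + c2
  factor(lv[idx], levels = lv)
}

COMPG_LEVELS <- c("Mm", "mM", "mm")
COVARIATE_TERMS <- c("age", "sex", "e2_carrier", "e4_carrier")

# Shared complete-case model frame for one or two SNPs.
# Age is centered at 70 and scaled by 10 internally for conditioning; the
# reported age effect is rescaled back to the per-year scale.
build_model_frame <- function(dataset, snp_ids, use_covariates = TRUE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  missing_snp <- setdiff(snp_ids, dataset$snps$snp_id)
  if (length(missing_snp)) {
    stop("SNP not in panel: ", paste(missing_snp, collapse = ", "), call. = FALSE)
  }
  smp <- dataset$samples
  carriers <- lapply(snp_ids, function(s) dominant_code(dataset$genotypes[, s]))
  names(carriers) <- snp_ids
  cov <- NULL
  if (use_covariates) {
    cov <- cbind(age = (smp$age - 70) / 10, sex = smp$sex,
                 e2_carrier = smp$e2_carrier, e4_carrier = smp$e4_carrier)
  }
  ok <- !is.na(smp$ad_status)
  for (cc in carriers) ok <- ok & !is.na(cc)
  if (!is.null(cov)) ok <- ok & complete.cases(cov)
  cluster <- NULL
  if (dataset$has_family_structure) {
    fam <- smp$family_id
    fam[is.na(fam) | fam == ""] <- paste0(".solo", seq_len(nrow(smp)))[is.na(fam) | fam == ""]
    cluster <- fam
  }
  list(y = smp$ad_status[ok],
       carriers = lapply(carriers, function(cc) cc[ok]),
       cov = if (is.null(cov)) NULL else cov[ok, , drop = FALSE],
       cluster = if (is.null(cluster)) NULL else cluster[ok],
       n = sum(ok))
}

rescale_age_term <- function(terms) {
  i <- which(terms$term == "age")
  if (length(i)) {
    terms$beta[i] <- terms$beta[i] / 10
    terms$se[i] <- terms$se[i] / 10
  }
  terms
}

new_compg_fit <- function(dataset, model_kind, snp1, snp2, fit, cell_counts = NULL) {
  structure(list(cohort_name = dataset$cohort_name,
                 model_kind = model_kind,
                 snp1 = snp1, snp2 = snp2,
                 terms = fit$terms,
                 cell_counts = cell_counts,
                 log_likelihood = fit$log_likelihood,
                 converged = fit$converged,
                 n_effective = fit$n_effective),
            class = "compg_fit")
}

#' Single-SNP dominant-model logistic fit
#'
#' Logistic regression of case status on the dominant carrier indicator of
#' one SNP, adjusted for age, sex and the APOE epsilon-2/epsilon-4 carrier
#' indicators, with a family random intercept when the cohort is flagged as
#' family structured. The SNP term is labelled `carrier`.
#'
#' @param dataset A [cohort_dataset()].
#' @param snp SNP id.
#' @param use_covariates Include the age/sex/APOE covariate set (default).
#' @param family_method How family clustering is handled when present; see
#'   [fit_logistic()].
#' @return A `compg_fit` object.
#' @export
fit_single_snp_model <- function(dataset, snp, use_covariates = TRUE,
                                 family_method = c("random_intercept", "cluster_robust")) {
  family_method <- match.arg(family_method)
  mf <- build_model_frame(dataset, snp, use_covariates)
  X <- cbind(carrier = mf$carriers[[1]], mf$cov)
  fit <- fit_logistic(mf$y, X, cluster = mf$cluster, method = family_method)
  fit$terms <- rescale_age_term(fit$terms)
  counts <- data.frame(level = c("non-carrier", "carrier"),
                       n_cases = c(sum(mf$y == 1 & mf$carriers[[1]] == 0),
                                   sum(mf$y == 1 & mf$carriers[[1]] == 1)),
                       n_controls = c(sum(mf$y == 0 & mf$carriers[[1]] == 0),
                                      sum(mf$y == 0 & mf$carriers[[1]] == 1)))
  new_compg_fit(dataset, "single", snp, NA_character_, fit, counts)
}

#' Compound-genotype logistic fit for a SNP pair
#'
#' Logistic regression of case status on the three compound-genotype
#' indicators `Mm`, `mM`, `mm` (the double non-carrier level `MM` is the
#' reference), plus the covariate set. A level with no observations among the
#' complete cases yields a not-estimable term; the others are returned.
#' Per-level case/control counts are attached.
#'
#' @inheritParams fit_single_snp_model
#' @param snp1,snp2 Distinct SNP ids; `snp1` is the first-position SNP whose
#'   minor allele defines the `mM` level.
#' @return A `compg_fit` object with terms `Mm`, `mM`, `mm` and covariates.
#' @export
fit_compg_model <- function(dataset, snp1, snp2, use_covariates = TRUE,
                            family_method = c("random_intercept", "cluster_robust")) {
  family_method <- match.arg(family_method)
  if (identical(snp1, snp2)) stop("snp1 and snp2 must differ", call. = FALSE)
  mf <- build_model_frame(dataset, c(snp1, snp2), use_covariates)
  cg <- build_compound_genotype(mf$carriers[[1]], mf$carriers[[2]])
  X <- cbind(Mm = as.numeric(cg == "Mm"),
             mM = as.numeric(cg == "mM"),
             mm = as.numeric(cg == "mm"))
  X <- cbind(X, mf$cov)
  fit <- fit_logistic(mf$y, X, cluster = mf$cluster, method = family_method)
  fit$terms <- rescale_age_term(fit$terms)
  counts <- data.frame(level = levels(cg),
                       n_cases = as.integer(table(cg[mf$y == 1])),
                       n_controls = as.integer(table(cg[mf$y == 0])))
  new_compg_fit(dataset, "compg", snp1, snp2, fit, counts)
}

#' Multiplicative interaction logistic fit for a SNP pair
#'
#' The classical two-SNP interaction model: case status on `carrier1`,
#' `carrier2` and their product, plus the covariate set. Complete cases are
#' identical to those of [fit_compg_model()] for the same pair, and the two
#' models span the same column space, so their maximized log-likelihoods
#' coincide.
#'
#' @inheritParams fit_compg_model
#' @return A `compg_fit` object with terms `snp1`, `snp2`, `product` and
#'   covariates.
#' @export
fit_interaction_model <- function(dataset, snp1, snp2, use_covariates = TRUE,
                                  family_method = c("random_intercept", "cluster_robust")) {
  family_method <- match.arg(family_method)
  if (identical(snp1, snp2)) stop("snp1 and snp2 must differ", call. = FALSE)
  mf <- build_model_frame(dataset, c(snp1, snp2), use_covariates)
  c1 <- mf$carriers[[1]]; c2 <- mf$carriers[[2]]
  X <- cbind(snp1 = c1, snp2 = c2, product = c1 * c2)
  X <- cbind(X, mf$cov)
  fit <- fit_logistic(mf$y, X, cluster = mf$cluster, method = family_method)
  fit$terms <- rescale_age_term(fit$terms)
  new_compg_fit(dataset, "interaction", snp1, snp2, fit, NULL)
}

#' @export
print.compg_fit <- function(x, ...) {
  pair <- if (is.na(x$snp2)) x$snp1 else paste0(x$snp1, "-", x$snp2)
  cat("<compg_fit> ", x$model_kind, " model, ", pair,
      " [", x$cohort_name, "], n = ", x$n_effective,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  t <- x$terms
  t$beta <- signif(t$beta, 4); t$se <- signif(t$se, 4); t$p <- signif(t$p, 3)
  print(t, row.names = FALSE)
  invisible(x)
}

#' @export
coef.compg_fit <- function(object, ...) {
  setNames(object$terms$beta, object$terms$term)
}

#' @export
logLik.compg_fit <- function(object, ...) {
  structure(object$log_likelihood, df = sum(object$terms$estimable) + 1L,
            class = "logLik")
}

#' @export
summary.compg_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$cell_counts)) {
    cat("cell counts:\n")
    print(object$cell_counts, row.names = FALSE)
  }
  invisible(object)
}
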