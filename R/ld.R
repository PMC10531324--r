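#' Genotypic (composite) correlation between two SNPs
#'
#' Pearson correlation of additive genotype counts over complete pairs — the
#' composite LD measure computable from unphased data. Its square is the
#' r^2 used for pruning.
#'
#' @param col1,col2 Additive count vectors in `{0, 1, 2, NA}`.
#' @return Correlation in `[-1, 1]`.
#' @export
genotypic_r <- function(col1, col2) {
  check_genotype_values(col1); check_genotype_values(col2)
  ok <- !is.na(col1) & !is.na(col2)
  if (sum(ok) < 4L) stop("need at least 4 complete genotype pairs", call. = FALSE)
  x <- col1[ok]; y <- col2[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("monomorphic SNP in subset; LD undefined", call. = FALSE)
  }
  cor(x, y)
}

#' Case/control LD for one SNP pair
#'
#' Computes the genotypic correlation separately within cases and controls.
#'
#' @param dataset A [cohort_dataset()] (or a pooled one).
#' @param snp1,snp2 SNP ids.
#' @return List of class `ld_estimate`: `snp1`, `snp2`, `r_cases`,
#'   `r_controls`, `n_cases`, `n_controls` (complete-pair counts). Feed into
#'   [ld_difference_test()] for the case/control comparison.
#' @export
ld_by_group <- function(dataset, snp1, snp2) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  g1 <- dataset$genotypes[, snp1]
  g2 <- dataset$genotypes[, snp2]
  y <- dataset$samples$ad_status
  case <- !is.na(y) & y == 1
  ctrl <- !is.na(y) & y == 0
  n_cases <- sum(case & !is.na(g1) & !is.na(g2))
  n_controls <- sum(ctrl & !is.na(g1) & !is.na(g2))
  structure(list(snp1 = snp1, snp2 = snp2,
                 r_cases = genotypic_r(g1[case], g2[case]),
                 r_controls = genotypic_r(g1[ctrl], g2[ctrl]),
                 n_cases = n_cases, n_controls = n_controls),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("<ld_estimate> %s-%s: r = %.3f (cases, n=%d) vs %.3f (controls, n=%d)\n",
              x$snp1, x$snp2, x$r_cases, x$n_cases, x$r_controls, x$n_controls))
  invisible(x)
}

#' Chi-square test for a case/control LD difference
#'
#' Fisher z-transforms each correlation and refers the squared standardized
#' difference, `(z1 - z2)^2 / (1/(n1-3) + 1/(n2-3))`, to the 1-df chi-square
#' distribution — the standard two-sample correlation comparison in
#' chi-square form.
#'
#' @param r1,n1 Correlation and sample size in the first group (cases).
#' @param r2,n2 Correlation and sample size in the second group (controls).
#' @return List with `chisq` and `p`.
#' @export
ld_difference_test <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need at least 4 observations per group", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1 for the Fisher z transform",
                                         call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  chisq <- (z1 - z2)^2 / (1 / (n1 - 3) + 1 / (n2 - 3))
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Bonferroni per-test threshold for a family of LD tests
#'
#' @param n_tests Number of pair tests in the family.
#' @param alpha Family-wise level.
#' @return `alpha / n_tests`.
#' @export
ld_bonferroni <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1", call. = FALSE)
  alpha / n_tests
}
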