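#' One-degree-of-freedom chi-square contrast between two coefficients
#'
#' Tests whether two (assumed independent) log-odds estimates differ:
#' `chisq = (b1 - b2)^2 / (se1^2 + se2^2)`, referred to the upper tail of the
#' 1-df chi-square distribution. Equivalent to the squared two-sample z test.
#' Note the independence assumption is retained even when the two estimates
#' come from the same data (compound-genotype level vs the single-SNP main
#' effect); the covariance between them is ignored.
#'
#' @param b1,se1 First estimate and its standard error.
#' @param b2,se2 Second estimate and its standard error.
#' @param contrast Optional label carried through to the result.
#' @return List of class `comparison_result`: `contrast`, `chisq`, `p`,
#'   `q` (`NA` until FDR adjustment).
#' @export
beta_diff_chisq <- function(b1, se1, b2, se2, contrast = NA_character_) {
  if (any(c(se1, se2) <= 0) || anyNA(c(se1, se2))) {
    stop("standard errors must be positive", call. = FALSE)
  }
  chisq <- (b1 - b2)^2 / (se1^2 + se2^2)
  structure(list(contrast = contrast, chisq = chisq,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE),
                 q = NA_real_),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result>%s chisq(1) = %.4g, p = %.3g%s\n",
              if (!is.na(x$contrast)) paste0(" ", x$contrast, ":") else "",
              x$chisq, x$p,
              if (!is.na(x$q)) sprintf(", q = %.3g", x$q) else ""))
  invisible(x)
}

#' Contrast the three compound-genotype levels of one pair
#'
#' Applies [beta_diff_chisq()] to the `mM-Mm`, `mM-mm` and `Mm-mm` level
#' differences of one SNP pair's pooled estimates. Contrasts involving a
#' non-estimable level are returned with `NA` statistics. FDR adjustment is
#' applied by the caller across the declared contrast family (all pairs of
#' one gene panel).
#'
#' @param meta_mM,meta_Mm,meta_mm [meta_fixed_effects()] results for the
#'   three levels (or `NULL` where a level was not estimable).
#' @return Data frame with columns `contrast`, `chisq`, `p`.
#' @export
compare_compg_levels <- function(meta_mM, meta_Mm, meta_mm) {
  est <- list(mM = meta_mM, Mm = meta_Mm, mm = meta_mm)
  specs <- list(c("mM", "Mm"), c("mM", "mm"), c("Mm", "mm"))
  rows <- lapply(specs, function(s) {
    a <- est[[s[1]]]; b <- est[[s[2]]]
    lab <- paste0(s[1], "-", s[2])
    if (is.null(a) || is.null(b)) {
      return(data.frame(contrast = lab, chisq = NA_real_, p = NA_real_))
    }
    r <- beta_diff_chisq(a$beta, a$se, b$beta, b$se, contrast = lab)
    data.frame(contrast = lab, chisq = r$chisq, p = r$p)
  })
  do.call(rbind, rows)
}

#' Contrast a compound-genotype level with a single-SNP main effect
#'
#' Compares the pooled level estimate with the pooled single-SNP carrier
#' estimate via [beta_diff_chisq()]. Used to decide whether a significant
#' level merely restates a main effect.
#'
#' @param meta_level,meta_main [meta_fixed_effects()] results.
#' @param contrast Optional label.
#' @return A `comparison_result`.
#' @export
compare_compg_to_main <- function(meta_level, meta_main, contrast = "level-vs-main") {
  beta_diff_chisq(meta_level$beta, meta_level$se,
                  meta_main$beta, meta_main$se, contrast = contrast)
}

#' Detect a partial interaction from the compound-heterozygote contrast
#'
#' A pair shows partial interaction when the `mM-Mm` difference is
#' FDR-significant and more extreme (smaller p) than the difference of the
#' two comprising SNPs' main effects — the minor allele of one SNP acts more
#' strongly in the absence of the other's minor allele.
#'
#' @param p_mM_Mm Raw p-value of the `mM-Mm` level contrast.
#' @param p_main_diff Raw p-value of the main-effect difference contrast
#'   (`NA` when a main effect was not estimable; the flag is then `FALSE`).
#' @param q_mM_Mm FDR-adjusted `mM-Mm` p-value.
#' @param alpha Significance threshold on the q-value.
#' @return Logical flag.
#' @export
detect_partial_interaction <- function(p_mM_Mm, p_main_diff, q_mM_Mm, alpha = 0.05) {
  if (anyNA(c(p_mM_Mm, q_mM_Mm)) || is.na(p_main_diff)) return(FALSE)
  isTRUE(q_mM_Mm < alpha && p_mM_Mm < p_main_diff)
}

#' Classify a SNP pair from its meta-analysis results
#'
#' Deterministic decision logic:
#' * `pair_significant`: any compound-genotype level has `q < alpha`.
#' * `novel-compg`: the pair is significant while neither comprising SNP is
#'   individually significant.
#' * `partial-interaction`: the pair is significant, at least one comprising
#'   SNP is significant, and [detect_partial_interaction()] fires.
#' * `main-effect-explained`: the pair is significant, at least one
#'   comprising SNP is significant, and no partial interaction is detected.
#' * `null`: no significant level. Pairs with a significant `mM-Mm` contrast
#'   but no significant level keep category `null` and are flagged
#'   `contrast_only` (they are retained in reports).
#'
#' A novel pair that also satisfies the partial-interaction condition keeps
#' category `novel-compg`; the condition is reported in the separate
#' `partial_interaction` field.
#'
#' @param level_q Named numeric (`Mm`, `mM`, `mm`) of level q-values
#'   (`NA` for non-estimable levels).
#' @param snp_q Length-2 numeric of the comprising SNPs' single-SNP q-values.
#' @param p_mM_Mm,q_mM_Mm Raw and FDR-adjusted p of the `mM-Mm` contrast.
#' @param p_main_diff Raw p of the main1-main2 effect contrast.
#' @param alpha Significance threshold.
#' @return List of class `pair_classification`: `category`,
#'   `pair_significant`, `snp_significant` (length 2), `significant_levels`,
#'   `partial_interaction`, `contrast_only`.
#' @export
classify_pair <- function(level_q, snp_q, p_mM_Mm = NA_real_, q_mM_Mm = NA_real_,
                          p_main_diff = NA_real_, alpha = 0.05) {
  lev <- setNames(rep(NA_real_, 3), c("Mm", "mM", "mm"))
  lev[names(level_q)] <- level_q
  sig_lev <- names(lev)[!is.na(lev) & lev < alpha]
  pair_sig <- length(sig_lev) > 0L
  snp_sig <- !is.na(snp_q) & snp_q < alpha
  partial <- detect_partial_interaction(p_mM_Mm, p_main_diff, q_mM_Mm, alpha)
  contrast_only <- !pair_sig && isTRUE(!is.na(q_mM_Mm) && q_mM_Mm < alpha)

  category <- if (!pair_sig) {
    "null"
  } else if (!any(snp_sig)) {
    "novel-compg"
  } else if (partial) {
    "partial-interaction"
  } else {
    "main-effect-explained"
  }
  structure(list(category = category,
                 pair_significant = pair_sig,
                 snp_significant = snp_sig,
                 significant_levels = sig_lev,
                 partial_interaction = partial,
                 contrast_only = contrast_only),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat("<pair_classification> ", x$category,
      if (x$partial_interaction) " [partial interaction]",
      if (x$contrast_only) " [contrast-only]", "\n", sep = "")
  cat("  significant levels: ",
      if (length(x$significant_levels)) paste(x$significant_levels, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}
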