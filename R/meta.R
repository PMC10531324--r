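#' Fixed-effects inverse-variance meta-analysis of one term
#'
#' Pools per-cohort estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w*b)/sum(w)`, `se = 1/sqrt(sum(w))`, two-sided normal p from
#' `z = beta/se`. Cohorts in which the term was not estimable are simply not
#' supplied.
#'
#' @param beta Numeric vector of per-cohort log-odds estimates.
#' @param se Matching vector of standard errors (all positive).
#' @param cohorts Optional cohort names, used for the direction string.
#' @return Object of class `meta_estimate`: `beta`, `se`, `z`, `p`, `k`
#'   (number of cohorts pooled), `directions` (per-cohort sign string, see
#'   [direction_string()]), `q` (`NA` until FDR adjustment).
#' @export
meta_fixed_effects <- function(beta, se, cohorts = NULL) {
  if (length(beta) == 0L) stop("no estimates to pool", call. = FALSE)
  if (length(beta) != length(se)) stop("beta and se differ in length", call. = FALSE)
  if (anyNA(beta) || anyNA(se)) stop("beta/se must be non-missing (drop absent cohorts)",
                                     call. = FALSE)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  structure(list(beta = b, se = s, z = z, p = 2 * pnorm(-abs(z)),
                 q = NA_real_, k = length(beta),
                 directions = direction_string(beta),
                 cohorts = cohorts,
                 cohort_beta = beta, cohort_se = se),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("<meta_estimate> beta = %.4g (se %.4g), z = %.3f, p = %.3g%s, k = %d [%s]\n",
              x$beta, x$se, x$z, x$p,
              if (!is.na(x$q)) sprintf(", q = %.3g", x$q) else "",
              x$k, x$directions))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment, optionally within families
#'
#' Step-up BH q-values, order-preserving with the input. When `family` is
#' given, the adjustment is applied separately within each family (e.g. all
#' single-SNP p-values of one gene panel form one family and all
#' compound-genotype level p-values another).
#'
#' @param p_values Vector of p-values in (0, 1]. `NA`s propagate.
#' @param family Optional grouping vector of the same length.
#' @return Vector of q-values aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, family = NULL) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] <= 0 | p_values[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(family)) return(p.adjust(p_values, method = "BH"))
  if (length(family) != length(p_values)) stop("family length mismatch", call. = FALSE)
  q <- rep(NA_real_, length(p_values))
  for (f in unique(family)) {
    idx <- which(family == f)
    q[idx] <- p.adjust(p_values[idx], method = "BH")
  }
  q
}

#' Per-cohort effect-direction string
#'
#' One character per cohort in the declared cohort order: `"+"` for a
#' positive (adverse) log-odds estimate, `"-"` for a negative (protective)
#' one. An exact zero is written `"+"` (documented tie rule; has probability
#' zero in continuous fits).
#'
#' @param per_cohort_betas Ordered numeric vector of per-cohort estimates.
#' @return Single string, one `+`/`-` per cohort.
#' @export
direction_string <- function(per_cohort_betas) {
  paste(ifelse(per_cohort_betas >= 0, "+", "-"), collapse = "")
}
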