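# Core logistic engine. The fast path wraps stats::glm.fit on an explicit
# design matrix; the clustered paths go through lme4::glmer (family random
# intercept) or stats::glm + sandwich::vcovCL (cluster-robust SEs).

SEPARATION_BETA <- 15  # |beta| beyond this is treated as (quasi-)separation

logistic_irls <- function(X, y, epsilon = 1e-10, maxit = 100L) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = epsilon, maxit = maxit)))
  p <- ncol(X)
  beta <- fit$coefficients
  se <- rep(NA_real_, p)
  r <- fit$rank
  if (r > 0) {
    Qr <- fit$qr
    piv <- Qr$pivot[seq_len(r)]
    covm <- chol2inv(Qr$qr[seq_len(r), seq_len(r), drop = FALSE])
    se[piv] <- sqrt(diag(covm))
  }
  names(se) <- colnames(X)
  list(beta = beta, se = se,
       log_likelihood = -fit$deviance / 2,
       converged = fit$converged, rank = r, n = length(y))
}

#' Fit a covariate-adjusted logistic model and return per-term estimates
#'
#' Maximum-likelihood logistic regression of a binary outcome on an explicit
#' design matrix (an intercept column is added internally), with Wald standard
#' errors and two-sided normal p-values per term. Rows with any missing value
#' are dropped. Constant (degenerate) columns and terms whose estimates
#' diverge (|beta| > 15, indicating separation or an empty cell) are flagged
#' not estimable rather than penalized.
#'
#' When `cluster` is supplied, `method = "random_intercept"` adds a per-cluster
#' random intercept (Laplace approximation via [lme4::glmer()]); with all
#' singleton clusters this degenerates to the plain fit.
#' `method = "cluster_robust"` keeps the plain ML point estimates and replaces
#' the standard errors by CR0 cluster-robust (sandwich) ones.
#'
#' @param outcome Binary 0/1 vector.
#' @param design Numeric matrix of predictors with column names (no intercept).
#' @param cluster Optional cluster/family id vector (same length as `outcome`).
#' @param method Clustered-data handling; ignored when `cluster` is `NULL`.
#' @param epsilon,maxit IRLS convergence tolerance on the deviance and
#'   iteration cap.
#' @return List with elements `terms` (data frame: `term`, `beta`, `se`, `p`,
#'   `estimable`), `log_likelihood`, `converged`, `n_effective`.
#' @export
fit_logistic <- function(outcome, design, cluster = NULL,
                         method = c("random_intercept", "cluster_robust"),
                         epsilon = 1e-10, maxit = 100L) {
  method <- match.arg(method)
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (!is_binary01(outcome)) stop("outcome must be 0/1", call. = FALSE)
  ok <- !is.na(outcome) & complete.cases(design)
  if (!is.null(cluster)) ok <- ok & !is.na(cluster)
  y <- outcome[ok]
  X <- design[ok, , drop = FALSE]
  if (length(y) == 0L) stop("no complete cases", call. = FALSE)

  term_names <- colnames(design)
  constant <- apply(X, 2, function(v) length(unique(v)) < 2L)
  Xu <- X[, !constant, drop = FALSE]

  if (is.null(cluster)) {
    fit <- logistic_irls(cbind(`(Intercept)` = 1, Xu), y,
                         epsilon = epsilon, maxit = maxit)
    beta <- fit$beta[-1]; se <- fit$se[-1]
    if (anyNA(beta)) {
      stop("design is rank deficient; aliased columns: ",
           paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
    }
    ll <- fit$log_likelihood; conv <- fit$converged
  } else if (method == "random_intercept") {
    df <- data.frame(.y = y, Xu, check.names = FALSE)
    df$.cluster <- factor(cluster[ok])
    form <- as.formula(paste(".y ~",
                             paste0("`", colnames(Xu), "`", collapse = " + "),
                             "+ (1 | .cluster)"))
    gf <- suppressMessages(suppressWarnings(
      lme4::glmer(form, data = df, family = binomial(), nAGQ = 1L,
                  control = lme4::glmerControl(
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE))))
    fe <- lme4::fixef(gf)[-1]
    vc <- as.matrix(vcov(gf))[-1, -1, drop = FALSE]
    beta <- setNames(as.numeric(fe), colnames(Xu))
    se <- setNames(sqrt(diag(vc)), colnames(Xu))
    ll <- as.numeric(logLik(gf))
    conv <- length(gf@optinfo$conv$lme4) == 0L
  } else {
    df <- data.frame(.y = y, Xu, check.names = FALSE)
    form <- as.formula(paste(".y ~", paste0("`", colnames(Xu), "`", collapse = " + ")))
    gf <- suppressWarnings(glm(form, data = df, family = binomial(),
                               control = glm.control(epsilon = epsilon, maxit = maxit)))
    vc <- sandwich::vcovCL(gf, cluster = factor(cluster[ok]), type = "HC0")
    beta <- setNames(coef(gf)[-1], colnames(Xu))
    se <- setNames(sqrt(diag(vc))[-1], colnames(Xu))
    ll <- as.numeric(logLik(gf))
    conv <- gf$converged
  }

  full_beta <- full_se <- setNames(rep(NA_real_, length(term_names)), term_names)
  full_beta[colnames(Xu)] <- beta
  full_se[colnames(Xu)] <- se
  estimable <- !is.na(full_beta) & !is.na(full_se) & is.finite(full_se) &
    full_se > 0 & abs(full_beta) <= SEPARATION_BETA
  full_beta[!estimable] <- NA_real_
  full_se[!estimable] <- NA_real_
  p <- 2 * pnorm(-abs(full_beta / full_se))

  list(terms = data.frame(term = term_names, beta = unname(full_beta),
                          se = unname(full_se), p = unname(p),
                          estimable = unname(estimable), stringsAsFactors = FALSE),
       log_likelihood = ll, converged = conv, n_effective = length(y))
}
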