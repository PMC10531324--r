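# Small in-code fixtures shared across test files.

# Minimal cohort built directly from matrices (no simulator involved).
toy_cohort <- function(genotypes, ad_status, name = "toy", age = NULL,
                       sex = NULL, e2 = NULL, e4 = NULL, family_id = NULL,
                       positions = NULL, imputation_quality = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  snps <- data.frame(snp_id = colnames(genotypes) %||%
                       sprintf("s%02d", seq_len(m)),
                     chromosome = "1",
                     position = positions %||% seq_len(m) * 1000L,
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  if (!is.null(imputation_quality)) snps$imputation_quality <- imputation_quality
  colnames(genotypes) <- snps$snp_id
  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        family_id = family_id %||% NA_character_,
                        ad_status = ad_status,
                        age = age %||% rep(75, n),
                        sex = sex %||% rep(0, n),
                        e2_carrier = e2 %||% rep(0, n),
                        e4_carrier = e4 %||% rep(0, n),
                        stringsAsFactors = FALSE)
  cohort_dataset(name, genotypes, snps, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random two-SNP case-control data with known cell effects, covariate-free.
sim_pair_data <- function(n, p1, p2, b_Mm = 0, b_mM = 0, b_mm = 0, b0 = -0.4,
                          seed = 1) {
  set.seed(seed)
  c1 <- rbinom(n, 1, 1 - (1 - p1)^2)
  c2 <- rbinom(n, 1, 1 - (1 - p2)^2)
  lp <- b0 + b_Mm * (c1 == 0 & c2 == 1) + b_mM * (c1 == 1 & c2 == 0) +
    b_mm * (c1 == 1 & c2 == 1)
  y <- rbinom(n, 1, plogis(lp))
  list(y = y, c1 = c1, c2 = c2)
}
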