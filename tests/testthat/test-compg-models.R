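test_that("compound genotype coding follows the two-SNP dominant table", {
  expect_equal(as.character(build_compound_genotype(0, 0)), "MM")
  expect_equal(as.character(build_compound_genotype(0, 1)), "Mm")
  expect_equal(as.character(build_compound_genotype(1, 0)), "mM")
  expect_equal(as.character(build_compound_genotype(1, 1)), "mm")
  # additive counts are dominant-coded on the fly; missing propagates
  expect_equal(as.character(build_compound_genotype(c(2, 2, NA), c(0, 2, 1))),
               c("mM", "mm", NA))
  expect_equal(levels(build_compound_genotype(0, 0)), c("MM", "Mm", "mM", "mm"))
})

test_that("covariate-free logistic fit reproduces the 2x2 closed form", {
  # cases: 30 carriers / 20 non; controls: 20 carriers / 30 non
  y <- c(rep(1, 50), rep(0, 50))
  x <- c(rep(1, 30), rep(0, 20), rep(1, 20), rep(0, 30))
  f <- fit_logistic(y, cbind(carrier = x))
  b <- f$terms$beta[f$terms$term == "carrier"]
  s <- f$terms$se[f$terms$term == "carrier"]
  expect_equal(b, log(2.25), tolerance = 1e-6)
  expect_equal(s, sqrt(1/30 + 1/20 + 1/20 + 1/30), tolerance = 1e-6)
  # Wald p is exactly the two-sided normal tail of beta/se
  expect_equal(f$terms$p[f$terms$term == "carrier"], 2 * pnorm(-abs(b / s)),
               tolerance = 1e-12)
})

test_that("degenerate predictors and separation are flagged, collinearity errors", {
  set.seed(3)
  y <- rbinom(200, 1, 0.4)
  x <- rbinom(200, 1, 0.3)
  f <- fit_logistic(y, cbind(a = x, b = rep(0, 200)))
  expect_false(f$terms$estimable[f$terms$term == "b"])
  expect_true(f$terms$estimable[f$terms$term == "a"])

  # perfect separation blows up the estimate and is declared not estimable
  fs <- fit_logistic(x, cbind(a = x))
  expect_false(fs$terms$estimable[1])

  expect_error(fit_logistic(y, cbind(a = x, b = x)), "rank deficient.*b")
})

test_that("all-singleton families give the same estimates as the plain fit", {
  set.seed(4)
  n <- 600
  x <- cbind(carrier = rbinom(n, 1, 0.3), age = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * x[, 1]))
  plain <- fit_logistic(y, x)
  clustered <- fit_logistic(y, x, cluster = paste0("fam", seq_len(n)),
                            method = "random_intercept")
  expect_equal(clustered$terms$beta, plain$terms$beta, tolerance = 1e-4)
  expect_equal(clustered$terms$se, plain$terms$se, tolerance = 1e-4)

  robust <- fit_logistic(y, x, cluster = rep(1:60, each = 10),
                         method = "cluster_robust")
  expect_equal(robust$terms$beta, plain$terms$beta, tolerance = 1e-8)
  expect_true(all(robust$terms$se > 0))
})

test_that("CompG and interaction fits are reparameterizations of each other", {
  cfg_base <- list(n = 800, p1 = 0.3, p2 = 0.35)
  for (seed in 1:5) {
    dd <- sim_pair_data(cfg_base$n, cfg_base$p1, cfg_base$p2,
                        b_Mm = 0.2, b_mM = -0.1, b_mm = 0.4, seed = seed)
    g <- cbind(s1 = dd$c1 * (1 + rbinom(cfg_base$n, 1, 0.4)),  # mix of het/hom carriers
               s2 = dd$c2 * (1 + rbinom(cfg_base$n, 1, 0.4)))
    d <- toy_cohort(g, ad_status = dd$y,
                    age = rnorm(cfg_base$n, 75, 6), sex = rbinom(cfg_base$n, 1, 0.5))
    fc <- fit_compg_model(d, "s1", "s2")
    fi <- fit_interaction_model(d, "s1", "s2")
    expect_equal(fc$n_effective, fi$n_effective)
    expect_lt(abs(fc$log_likelihood - fi$log_likelihood), 1e-6)
    bc <- coef(fc); bi <- coef(fi)
    expect_equal(unname(bc["mM"]), unname(bi["snp1"]), tolerance = 1e-5)
    expect_equal(unname(bc["Mm"]), unname(bi["snp2"]), tolerance = 1e-5)
    expect_equal(unname(bc["mm"]),
                 unname(bi["snp1"] + bi["snp2"] + bi["product"]), tolerance = 1e-5)
  }
})

test_that("empty CompG cells and all-zero products are not estimable", {
  set.seed(6)
  n <- 400
  c1 <- rbinom(n, 1, 0.3)
  c2 <- ifelse(c1 == 1, 0, rbinom(n, 1, 0.4))  # carriers never co-occur
  y <- rbinom(n, 1, 0.4)
  d <- toy_cohort(cbind(s1 = c1, s2 = c2), ad_status = y)
  fc <- fit_compg_model(d, "s1", "s2", use_covariates = FALSE)
  expect_false(fc$terms$estimable[fc$terms$term == "mm"])
  expect_true(all(fc$terms$estimable[fc$terms$term %in% c("Mm", "mM")]))
  expect_equal(fc$cell_counts$n_cases[fc$cell_counts$level == "mm"], 0L)
  # cell counts cover every complete case
  expect_equal(sum(fc$cell_counts$n_cases + fc$cell_counts$n_controls),
               fc$n_effective)

  fi <- fit_interaction_model(d, "s1", "s2", use_covariates = FALSE)
  expect_false(fi$terms$estimable[fi$terms$term == "product"])
})

test_that("complete cases match across model kinds for the same pair", {
  set.seed(7)
  n <- 500
  g <- cbind(s1 = sample(c(0, 1, 2, NA), n, TRUE, prob = c(5, 3, 1, 1)),
             s2 = sample(c(0, 1, 2, NA), n, TRUE, prob = c(5, 3, 1, 1)))
  d <- toy_cohort(g, ad_status = rbinom(n, 1, 0.4))
  fc <- fit_compg_model(d, "s1", "s2", use_covariates = FALSE)
  fi <- fit_interaction_model(d, "s1", "s2", use_covariates = FALSE)
  expect_equal(fc$n_effective, fi$n_effective)
  expect_equal(fc$n_effective, sum(!is.na(g[, 1]) & !is.na(g[, 2])))
})

test_that("single-SNP fit recovers an injected dominant effect", {
  cfg <- sim_config(n_snps = 2, maf = c(0.3, 0.25), n_per_cohort = 20000,
                    main_effects = c(0.2, 0), seed = 31)
  sc <- generate_multi_cohort(cfg)[[1]]
  f <- fit_single_snp_model(sc$dataset, "snp01")
  b <- coef(f)["carrier"]
  expect_true(f$converged)
  expect_lt(abs(b - 0.2), 0.06)
  # direction bookkeeping: positive estimate prints as "+"
  expect_equal(direction_string(b), "+")
})

test_that("the age effect is reported per year of age", {
  cfg <- sim_config(n_snps = 2, maf = 0.3, n_per_cohort = 12000,
                    covariate_effects = c(age = 0.5, sex = 0, e2 = 0, e4 = 0),
                    min_control_age = NULL,  # truncation would attenuate the age slope
                    seed = 32)
  sc <- generate_multi_cohort(cfg)[[1]]
  f <- fit_single_snp_model(sc$dataset, "snp01")
  # generating effect: 0.5 per decade = 0.05 per year
  expect_lt(abs(coef(f)["age"] - 0.05), 0.012)
})

test_that("null single-SNP p-values are uniform", {
  set.seed(33)
  n <- 400
  ps <- replicate(300, {
    y <- rbinom(n, 1, 0.4)
    x <- rbinom(n, 1, 0.3)
    f <- fit_logistic(y, cbind(carrier = x))
    f$terms$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("family random intercepts keep estimates valid in clustered cohorts", {
  cfg <- sim_config(n_snps = 2, maf = 0.3, n_per_cohort = c(2000, 2000),
                    main_effects = c(0.3, 0),
                    family_structure = list(fraction = 0.6, size = 4, sd = 1),
                    family_cohorts = 2, seed = 34)
  sims <- generate_multi_cohort(cfg)
  expect_false(sims[[1]]$dataset$has_family_structure)
  expect_true(sims[[2]]$dataset$has_family_structure)
  f <- fit_single_snp_model(sims[[2]]$dataset, "snp01")
  expect_true(f$converged)
  expect_true(f$terms$estimable[f$terms$term == "carrier"])
  expect_lt(abs(coef(f)["carrier"] - 0.3), 0.35)
})
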