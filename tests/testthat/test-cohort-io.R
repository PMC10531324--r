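test_that("MAF is the minor-allele frequency regardless of counted allele", {
  expect_equal(compute_maf(c(1, 1, 1, 1)), 0.5)
  expect_equal(compute_maf(c(0, 0, 1, 2)), 3 / 8)
  # column counting the major allele still reports the minor frequency
  expect_equal(compute_maf(c(2, 2, 1, 0)), 3 / 8)
  expect_equal(compute_maf(c(0, 1, NA, NA)), 0.25)
  expect_error(compute_maf(c(NA, NA)), "missing")
  expect_error(compute_maf(c(0, 3)), "must be 0, 1, 2")
})

test_that("exact HWE test matches full enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)
  expect_warning(p <- hwe_exact_test(10, 0, 0), "monomorphic")
  expect_equal(p, 1)

  # independent enumeration oracle via exact factorials (valid for total <= 50)
  enum_hwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    na <- min(2 * nAA + nAa, 2 * naa + nAa)
    hs <- seq(na %% 2, na, by = 2)
    pr <- vapply(hs, function(h) {
      hr <- (na - h) / 2; hc <- n - h - hr
      if (hc < 0) return(0)
      factorial(n) / (factorial(h) * factorial(hr) * factorial(hc)) *
        2^h * factorial(na) * factorial(2 * n - na) / factorial(2 * n)
    }, 0)
    pr <- pr / sum(pr)
    obs <- pr[hs == nAa]
    sum(pr[pr <= obs * (1 + 1e-9)])
  }
  expect_equal(hwe_exact_test(10, 10, 10), enum_hwe(10, 10, 10), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:16, 3, replace = TRUE)  # totals <= 48
    expect_equal(hwe_exact_test(n[1], n[2], n[3]), enum_hwe(n[1], n[2], n[3]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("apply_qc removes exactly the SNPs violating each rule", {
  set.seed(11)
  n <- 400
  good <- function() rbinom(n, 2, 0.3)
  # enough clean filler SNPs that one missing genotype keeps samples below
  # the 5% sample-missingness threshold
  filler <- sapply(1:21, function(i) good())
  colnames(filler) <- sprintf("clean%02d", 1:21)
  g <- cbind(low_maf = rbinom(n, 2, 0.03),
             bad_hwe = sample(c(0, 2), n, replace = TRUE),  # no heterozygotes
             high_miss = {x <- good(); x[seq_len(0.06 * n)] <- NA; x},
             low_imp = good(),
             filler)
  d <- toy_cohort(g, ad_status = rep(c(0, 1), n / 2),
                  imputation_quality = c(0.99, 0.99, 0.99, 0.85, rep(0.99, 21)))
  out <- apply_qc(d)
  log <- attr(out, "exclusion_log")
  expect_equal(nrow(log), 4)
  expect_setequal(log$item, c("low_maf", "bad_hwe", "high_miss", "low_imp"))
  expect_equal(log$rule[match(c("low_maf", "bad_hwe", "high_miss", "low_imp"), log$item)],
               c("maf", "hwe", "missingness", "imputation_quality"))
  expect_setequal(out$snps$snp_id, colnames(filler))

  # HWE filter catches p below 1e-6, not above
  expect_lt(hwe_exact_test(sum(g[, "bad_hwe"] == 0), 0, sum(g[, "bad_hwe"] == 2)), 1e-6)
})

test_that("apply_qc is idempotent and leaves passing data unchanged", {
  set.seed(12)
  # pristine data comes back unchanged
  g0 <- matrix(rbinom(300 * 6, 2, 0.3), 300, 6)
  d0 <- toy_cohort(g0, ad_status = rep(c(0, 1), 150))
  once0 <- apply_qc(d0)
  expect_equal(nrow(attr(once0, "exclusion_log")), 0)
  expect_equal(once0$genotypes, d0$genotypes)

  # with MCAR missingness, a second pass changes nothing
  g <- matrix(rbinom(300 * 25, 2, 0.3), 300, 25)
  g[matrix(runif(length(g)) < 0.01, nrow(g), ncol(g))] <- NA
  d <- toy_cohort(g, ad_status = rep(c(0, 1), 150))
  once <- apply_qc(d)
  twice <- apply_qc(once)
  expect_equal(twice$genotypes, once$genotypes)
  expect_equal(twice$snps, once$snps)
  expect_equal(twice$samples, once$samples)
})

test_that("apply_qc removes high-missingness samples before SNP metrics", {
  set.seed(13)
  g <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3)
  g[1, ] <- NA  # one sample fully missing
  d <- toy_cohort(g, ad_status = rep(c(0, 1), 100))
  out <- apply_qc(d)
  log <- attr(out, "exclusion_log")
  expect_true("S0001" %in% log$item[log$type == "sample"])
  expect_equal(nrow(out$samples), 199)
  expect_error(apply_qc(toy_cohort(matrix(rbinom(100, 2, 0.01), 50, 2),
                                   ad_status = rep(c(0, 1), 25))),
               "empty panel")
})

test_that("greedy LD pruning respects the r2 cap and drops later SNPs", {
  set.seed(14)
  base <- rbinom(500, 2, 0.4)
  g <- cbind(a = base, b = base, c = rbinom(500, 2, 0.4))
  d <- toy_cohort(g, ad_status = rep(c(0, 1), 250))
  kept <- ld_prune(d, 0.7)
  expect_equal(kept, c("a", "c"))  # duplicate dropped, later position loses

  # independent SNPs are all retained
  g2 <- sapply(1:5, function(i) rbinom(400, 2, 0.3))
  colnames(g2) <- paste0("s", 1:5)
  d2 <- toy_cohort(g2, ad_status = rep(c(0, 1), 200))
  expect_equal(ld_prune(d2, 0.7), paste0("s", 1:5))
})

test_that("LD pruning matches a brute-force greedy oracle on random panels", {
  brute_greedy <- function(g, ord, r2max) {
    kept <- integer(0)
    for (j in ord) {
      ok <- all(vapply(kept, function(k)
        cor(g[, j], g[, k], use = "pairwise.complete.obs")^2 <= r2max, TRUE))
      if (ok) kept <- c(kept, j)
    }
    kept
  }
  for (seed in 1:8) {
    set.seed(seed)
    n <- 300; m <- 6
    base <- matrix(rbinom(n * 3, 2, 0.35), n, 3)
    extra <- sapply(1:3, function(i) {
      x <- base[, i]
      flip <- runif(n) < 0.15
      x[flip] <- rbinom(sum(flip), 2, 0.35)
      x
    })
    g <- cbind(base, extra)
    colnames(g) <- sprintf("s%02d", 1:m)
    d <- toy_cohort(g, ad_status = rep(c(0, 1), n / 2))
    kept <- ld_prune(d, 0.5)
    expect_equal(kept, colnames(g)[brute_greedy(g, 1:m, 0.5)])
    # invariant: every retained pair has r^2 <= cap
    if (length(kept) > 1) {
      rr <- cor(g[, kept], use = "pairwise.complete.obs")^2
      expect_lte(max(rr[upper.tri(rr)]), 0.5)
    }
  }
})

test_that("dominant coding is min(count, 1) with missingness preserved", {
  expect_equal(dominant_code(c(0, 1, 2, NA)), c(0, 1, 1, NA))
  expect_error(dominant_code(c(0, 3)), "must be 0, 1, 2")
  set.seed(15)
  g <- sample(c(0, 1, 2, NA), 200, replace = TRUE)
  expect_equal(dominant_code(g), pmin(g, 1))
})

test_that("dosage TSV round-trips through write_cohort and read_cohort", {
  cfg <- sim_config(n_snps = 3, maf = c(0.2, 0.3, 0.4), n_per_cohort = 120,
                    missing_rate = 0.05, seed = 21)
  sc <- generate_multi_cohort(cfg)[[1]]
  dir <- tempfile()
  paths <- write_cohort(sc, dir, format = "dosage")
  back <- read_cohort(paths[["genotypes"]], paths[["phenotypes"]],
                      format = "dosage", snp_info_path = paths[["snp_info"]])
  expect_equal(back$genotypes, sc$dataset$genotypes)
  expect_equal(back$samples$ad_status, sc$dataset$samples$ad_status)
  expect_equal(back$snps$position, sc$dataset$snps$position)
  # truth sidecar round-trips through JSON
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$intercept, sc$truth$intercept)
  expect_equal(truth$case_fraction, sc$truth$case_fraction)
})

test_that("VCF input parses GT codes, phase and missingness", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4",
    "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/1\t0|0\t1|1\t./.",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0\t1/0"), vcf)
  ph <- file.path(dir, "ph.tsv")
  write.table(data.frame(sample_id = paste0("S", 1:4), family_id = NA,
                         ad_status = c(1, 0, 1, 0), age = 75, sex = 0,
                         e2_carrier = 0, e4_carrier = 0),
              ph, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_cohort(vcf, ph, format = "vcf")
  # rsA ALT frequency 3/6 -> no flip; "0/1"->1, "0|0"->0, "1|1"->2, "./."->NA
  expect_equal(unname(d$genotypes[, "rsA"]), c(1, 0, 2, NA))
  expect_equal(unname(d$genotypes[, "rsB"]), c(0, 1, 0, 1))
  expect_equal(d$snps$effect_allele, c("A", "T"))

  # multi-allelic sites are refused
  vcf2 <- file.path(dir, "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trsA\tG\tA,C\t.\tPASS\t.\tGT\t0/1"), vcf2)
  expect_error(read_cohort(vcf2, ph, format = "vcf"), "multi-allelic")

  # zero overlapping samples is an input error
  ph2 <- file.path(dir, "ph2.tsv")
  write.table(data.frame(sample_id = paste0("X", 1:4), family_id = NA,
                         ad_status = 0, age = 75, sex = 0,
                         e2_carrier = 0, e4_carrier = 0),
              ph2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(vcf, ph2, format = "vcf"), "overlapping")
})

test_that("read_cohort orients the effect allele to the cohort minor allele", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "flip.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"), vcf)
  ph <- file.path(dir, "ph.tsv")
  write.table(data.frame(sample_id = paste0("S", 1:3), family_id = NA,
                         ad_status = c(1, 0, 1), age = 75, sex = 0,
                         e2_carrier = 0, e4_carrier = 0),
              ph, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_cohort(vcf, ph, format = "vcf")
  # ALT A has frequency 5/6 -> flipped so G (REF) is counted
  expect_equal(d$snps$effect_allele, "G")
  expect_equal(d$snps$other_allele, "A")
  expect_equal(unname(d$genotypes[, "rsA"]), c(0, 0, 1))
  expect_lte(d$snps$maf, 0.5)
})

test_that("harmonize_cohorts aligns panels and flips swapped alleles", {
  g1 <- matrix(c(0, 1, 2, 0, 1, 1, 2, 0), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  d1 <- toy_cohort(g1, ad_status = c(0, 1, 0, 1), name = "c1")
  # second cohort counts the opposite allele at SNP a
  g2 <- matrix(c(2, 1, 0, 2, 1, 1, 0, 2), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  d2 <- toy_cohort(g2, ad_status = c(0, 1, 0, 1), name = "c2")
  d2$snps$effect_allele <- c("G", "A")
  d2$snps$other_allele <- c("A", "G")
  h <- harmonize_cohorts(list(d1, d2))
  expect_equal(unname(h[[2]]$genotypes[, "a"]), c(0, 1, 2, 0))
  expect_equal(h[[2]]$snps$effect_allele, h[[1]]$snps$effect_allele)

  d3 <- d2
  d3$snps$effect_allele <- c("T", "A")  # incompatible alleles
  expect_error(harmonize_cohorts(list(d1, d3)), "allele mismatch")
})
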