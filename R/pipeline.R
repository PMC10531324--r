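#' Enumerate all SNP pairs of a panel
#'
#' All unordered pairs, ordered by `(position1, position2)`; SNP1 is always
#' the lower-positioned SNP, which fixes the `mM`/`Mm` orientation of the
#' compound genotype.
#'
#' @param panel A [cohort_dataset()] or a SNP annotation data frame with
#'   `snp_id` and `position` columns.
#' @return Data frame with columns `snp1`, `snp2`.
#' @export
pair_enumeration <- function(panel) {
  snps <- if (inherits(panel, "cohort_dataset")) panel$snps else panel
  if (nrow(snps) < 2L) stop("need at least 2 SNPs to enumerate pairs", call. = FALSE)
  ord <- order(snps$position, snps$snp_id)
  ids <- snps$snp_id[ord]
  m <- length(ids)
  i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) (k + 1L):m))
  data.frame(snp1 = ids[i], snp2 = ids[j], stringsAsFactors = FALSE)
}

#' Plot-ready volcano records
#'
#' One record per tested item with the effect size on the x axis and
#' `-log10(q)` on the y axis; the conventional significance cutoff line sits
#' at `-log10(0.05) ~ 1.3`.
#'
#' @param item Character vector of item ids (SNP, or `pair:level`).
#' @param beta Effect sizes.
#' @param q FDR-adjusted p-values.
#' @param group Optional group labels (e.g. `novel` / `main-effect` / `ns`).
#' @return Data frame `item`, `beta`, `neg_log10_q`, `group`.
#' @export
emit_volcano_data <- function(item, beta, q, group = NULL) {
  data.frame(item = item, beta = beta,
             neg_log10_q = -log10(q),
             group = group %||% rep(NA_character_, length(item)),
             stringsAsFactors = FALSE)
}

# Pool harmonized cohorts into one dataset (for LD pruning and case/control
# LD contrasts); sample ids are prefixed by cohort to stay unique.
pool_cohorts <- function(cohorts) {
  g <- do.call(rbind, lapply(cohorts, function(d) {
    x <- d$genotypes
    rownames(x) <- paste(d$cohort_name, rownames(x), sep = ":")
    x
  }))
  smp <- do.call(rbind, lapply(cohorts, function(d) {
    s <- d$samples
    s$sample_id <- paste(d$cohort_name, s$sample_id, sep = ":")
    s
  }))
  rownames(smp) <- NULL
  cohort_dataset("pooled", g, cohorts[[1]]$snps, smp, has_family_structure = FALSE)
}

meta_or_null <- function(fits, term) {
  b <- s <- numeric(0); nm <- character(0)
  for (f in fits) {
    if (is.null(f) || !f$converged) next
    row <- f$terms[f$terms$term == term, ]
    if (nrow(row) == 1L && isTRUE(row$estimable)) {
      b <- c(b, row$beta); s <- c(s, row$se); nm <- c(nm, f$cohort_name)
    }
  }
  if (length(b) == 0L) return(NULL)
  meta_fixed_effects(b, s, cohorts = nm)
}

#' Run the full compound-genotype interaction analysis
#'
#' Orchestrates every stage over a list of cohorts: per-cohort QC, panel
#' harmonization, LD pruning on the pooled genotypes, single-SNP fits, all
#' pairwise compound-genotype and multiplicative-interaction fits,
#' fixed-effects meta-analysis, FDR adjustment within families (single-SNP
#' effects; compound-genotype levels; interaction terms; level contrasts;
#' level-vs-main comparisons — each across the whole panel), level and
#' level-vs-main chi-square contrasts, partial-interaction detection,
#' pair classification, case/control LD tests with a Bonferroni family
#' threshold, and plot-ready volcano tables.
#'
#' @param cohorts List of [cohort_dataset()] (or `sim_cohort`) objects, in
#'   the declared cohort order (direction strings follow it).
#' @param qc [qc_thresholds()] applied to every cohort.
#' @param r2_max LD-pruning threshold on pairwise r^2.
#' @param alpha Significance threshold on q-values.
#' @param gene_label Panel label carried into outputs.
#' @param use_covariates Adjust for age/sex/APOE covariates.
#' @param family_method Clustered-cohort handling, see [fit_logistic()].
#' @param run_qc Set `FALSE` when the cohorts are already QC'd.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a JSON run manifest.
#' @return Object of class `compg_analysis` with components `single_snp`,
#'   `pair_levels`, `interactions`, `contrasts`, `level_vs_main`,
#'   `classification`, `ld`, `volcano_single`, `volcano_pairs`,
#'   `retained_snps`, `exclusions`, `manifest`.
#' @export
run_full_analysis <- function(cohorts, qc = qc_thresholds(), r2_max = 0.7,
                              alpha = 0.05, gene_label = "panel",
                              use_covariates = TRUE,
                              family_method = c("random_intercept", "cluster_robust"),
                              run_qc = TRUE, out_dir = NULL) {
  family_method <- match.arg(family_method)
  cohorts <- lapply(cohorts, function(x) if (inherits(x, "sim_cohort")) x$dataset else x)
  stopifnot(length(cohorts) >= 1, all(vapply(cohorts, inherits, TRUE, "cohort_dataset")))

  exclusions <- list()
  if (run_qc) {
    cohorts <- lapply(cohorts, function(d) {
      out <- apply_qc(d, qc)
      exclusions[[d$cohort_name]] <<- attr(out, "exclusion_log")
      out
    })
  }
  cohorts <- harmonize_cohorts(cohorts)
  pooled <- pool_cohorts(cohorts)
  retained <- ld_prune(pooled, r2_max)
  cohorts <- lapply(cohorts, subset_cohort, snp_ids = retained)
  pooled <- subset_cohort(pooled, snp_ids = retained)
  panel <- cohorts[[1]]$snps

  # --- single-SNP models ---------------------------------------------------
  single_fits <- lapply(panel$snp_id, function(s) {
    lapply(cohorts, function(d) {
      tryCatch(fit_single_snp_model(d, s, use_covariates, family_method),
               error = function(e) NULL)
    })
  })
  names(single_fits) <- panel$snp_id
  single_meta <- lapply(single_fits, meta_or_null, term = "carrier")
  keep <- !vapply(single_meta, is.null, TRUE)
  single_snp <- data.frame(
    chromosome = panel$chromosome[keep],
    position = panel$position[keep],
    snp = panel$snp_id[keep],
    allele = panel$effect_allele[keep],
    beta = vapply(single_meta[keep], `[[`, 0, "beta"),
    se = vapply(single_meta[keep], `[[`, 0, "se"),
    p = vapply(single_meta[keep], `[[`, 0, "p"),
    effects = vapply(single_meta[keep], `[[`, "", "directions"),
    k = vapply(single_meta[keep], `[[`, 0L, "k"),
    stringsAsFactors = FALSE)
  single_snp$q <- bh_fdr(single_snp$p)
  single_snp <- single_snp[, c("chromosome", "position", "snp", "allele",
                               "beta", "se", "p", "q", "effects", "k")]
  rownames(single_snp) <- NULL
  snp_q <- setNames(single_snp$q, single_snp$snp)

  # --- pair models ---------------------------------------------------------
  pairs <- pair_enumeration(panel)
  n_pairs <- nrow(pairs)
  level_rows <- list(); inter_rows <- list()
  level_meta <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    s1 <- pairs$snp1[k]; s2 <- pairs$snp2[k]
    cfits <- lapply(cohorts, function(d) {
      tryCatch(fit_compg_model(d, s1, s2, use_covariates, family_method),
               error = function(e) NULL)
    })
    ifits <- lapply(cohorts, function(d) {
      tryCatch(fit_interaction_model(d, s1, s2, use_covariates, family_method),
               error = function(e) NULL)
    })
    lm3 <- lapply(setNames(COMPG_LEVELS, COMPG_LEVELS),
                  function(lev) meta_or_null(cfits, lev))
    level_meta[[k]] <- lm3
    for (lev in COMPG_LEVELS) {
      m <- lm3[[lev]]
      if (is.null(m)) next
      level_rows[[length(level_rows) + 1L]] <- data.frame(
        snp1 = s1, snp2 = s2, level = lev, beta = m$beta, se = m$se,
        p = m$p, effects = m$directions, k = m$k, stringsAsFactors = FALSE)
    }
    mprod <- meta_or_null(ifits, "product")
    if (!is.null(mprod)) {
      inter_rows[[length(inter_rows) + 1L]] <- data.frame(
        snp1 = s1, snp2 = s2, beta = mprod$beta, se = mprod$se,
        p = mprod$p, effects = mprod$directions, k = mprod$k,
        stringsAsFactors = FALSE)
    }
  }
  pair_levels <- if (length(level_rows)) do.call(rbind, level_rows) else
    data.frame(snp1 = character(), snp2 = character(), level = character(),
               beta = numeric(), se = numeric(), p = numeric(),
               effects = character(), k = integer())
  pair_levels$q <- bh_fdr(pair_levels$p)
  interactions <- if (length(inter_rows)) do.call(rbind, inter_rows) else
    data.frame(snp1 = character(), snp2 = character(), beta = numeric(),
               se = numeric(), p = numeric(), effects = character(), k = integer())
  interactions$q <- bh_fdr(interactions$p)

  # --- level contrasts and level-vs-main comparisons -----------------------
  contrast_rows <- list(); lvm_rows <- list(); main_diff_p <- rep(NA_real_, n_pairs)
  for (k in seq_len(n_pairs)) {
    s1 <- pairs$snp1[k]; s2 <- pairs$snp2[k]
    lm3 <- level_meta[[k]]
    cc <- compare_compg_levels(lm3$mM, lm3$Mm, lm3$mm)
    cc <- cbind(snp1 = s1, snp2 = s2, cc, stringsAsFactors = FALSE)
    contrast_rows[[k]] <- cc
    m1 <- single_meta[[s1]]; m2 <- single_meta[[s2]]
    if (!is.null(m1) && !is.null(m2)) {
      main_diff_p[k] <- beta_diff_chisq(m1$beta, m1$se, m2$beta, m2$se)$p
    }
    lvm_map <- list(c("mM", s1), c("Mm", s2), c("mm", s1), c("mm", s2))
    for (sp in lvm_map) {
      lev <- sp[1]; sid <- sp[2]
      mlev <- lm3[[lev]]; mmain <- single_meta[[sid]]
      if (is.null(mlev) || is.null(mmain)) next
      r <- compare_compg_to_main(mlev, mmain)
      lvm_rows[[length(lvm_rows) + 1L]] <- data.frame(
        snp1 = s1, snp2 = s2, level = lev, snp = sid,
        chisq = r$chisq, p = r$p, stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, contrast_rows)
  contrasts$q <- bh_fdr(contrasts$p)
  level_vs_main <- if (length(lvm_rows)) do.call(rbind, lvm_rows) else
    data.frame(snp1 = character(), snp2 = character(), level = character(),
               snp = character(), chisq = numeric(), p = numeric())
  level_vs_main$q <- bh_fdr(level_vs_main$p)

  # --- classification ------------------------------------------------------
  class_rows <- list()
  for (k in seq_len(n_pairs)) {
    s1 <- pairs$snp1[k]; s2 <- pairs$snp2[k]
    lq <- setNames(rep(NA_real_, 3), COMPG_LEVELS)
    sel <- pair_levels$snp1 == s1 & pair_levels$snp2 == s2
    lq[pair_levels$level[sel]] <- pair_levels$q[sel]
    csel <- contrasts$snp1 == s1 & contrasts$snp2 == s2 & contrasts$contrast == "mM-Mm"
    pmm <- if (any(csel)) contrasts$p[csel][1] else NA_real_
    qmm <- if (any(csel)) contrasts$q[csel][1] else NA_real_
    cl <- classify_pair(lq, c(snp_q[s1], snp_q[s2]),
                        p_mM_Mm = pmm, q_mM_Mm = qmm,
                        p_main_diff = main_diff_p[k], alpha = alpha)
    class_rows[[k]] <- data.frame(
      snp1 = s1, snp2 = s2, category = cl$category,
      pair_significant = cl$pair_significant,
      snp1_significant = unname(cl$snp_significant[1]),
      snp2_significant = unname(cl$snp_significant[2]),
      significant_levels = paste(cl$significant_levels, collapse = ","),
      partial_interaction = cl$partial_interaction,
      contrast_only = cl$contrast_only, stringsAsFactors = FALSE)
  }
  classification <- do.call(rbind, class_rows)

  # --- case/control LD -----------------------------------------------------
  ld_rows <- list()
  for (k in seq_len(n_pairs)) {
    s1 <- pairs$snp1[k]; s2 <- pairs$snp2[k]
    est <- tryCatch(ld_by_group(pooled, s1, s2), error = function(e) NULL)
    if (is.null(est)) next
    tst <- ld_difference_test(est$r_cases, est$n_cases, est$r_controls, est$n_controls)
    ld_rows[[length(ld_rows) + 1L]] <- data.frame(
      snp1 = s1, snp2 = s2, r_cases = est$r_cases, r_controls = est$r_controls,
      n_cases = est$n_cases, n_controls = est$n_controls,
      chisq = tst$chisq, p = tst$p, stringsAsFactors = FALSE)
  }
  ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else
    data.frame(snp1 = character(), snp2 = character(), r_cases = numeric(),
               r_controls = numeric(), n_cases = integer(), n_controls = integer(),
               chisq = numeric(), p = numeric())
  if (nrow(ld)) {
    ld$bonferroni_alpha <- ld_bonferroni(nrow(ld), alpha)
    ld$significant <- ld$p < ld$bonferroni_alpha
  }

  # --- volcano tables ------------------------------------------------------
  volcano_single <- emit_volcano_data(
    single_snp$snp, single_snp$beta, single_snp$q,
    ifelse(single_snp$q < alpha, "significant", "ns"))
  if (nrow(pair_levels)) {
    pkey <- paste(pair_levels$snp1, pair_levels$snp2)
    ckey <- paste(classification$snp1, classification$snp2)
    cat_of <- classification$category[match(pkey, ckey)]
    grp <- ifelse(pair_levels$q >= alpha, "ns",
                  ifelse(cat_of == "novel-compg", "novel", "main-effect"))
    volcano_pairs <- emit_volcano_data(
      paste0(pair_levels$snp1, "-", pair_levels$snp2, ":", pair_levels$level),
      pair_levels$beta, pair_levels$q, grp)
  } else {
    volcano_pairs <- emit_volcano_data(character(), numeric(), numeric())
  }

  manifest <- list(
    package = "compg", version = as.character(packageVersion("compg")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    gene_label = gene_label, alpha = alpha, r2_max = r2_max,
    cohorts = vapply(cohorts, function(d) d$cohort_name, ""),
    n_samples = vapply(cohorts, function(d) nrow(d$samples), 0L),
    n_snps_retained = length(retained), n_pairs = n_pairs,
    family_method = family_method, use_covariates = use_covariates,
    fdr_families = "per analysis type across the whole panel (single-SNP; CompG levels; interaction terms; level contrasts; level-vs-main)",
    qc = unclass(qc))

  res <- structure(list(single_snp = single_snp, pair_levels = pair_levels,
                        interactions = interactions, contrasts = contrasts,
                        level_vs_main = level_vs_main,
                        classification = classification, ld = ld,
                        volcano_single = volcano_single,
                        volcano_pairs = volcano_pairs,
                        retained_snps = retained, exclusions = exclusions,
                        alpha = alpha, manifest = manifest),
                   class = "compg_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' Write all result tables of an analysis to a directory
#'
#' @param x A `compg_analysis` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  stopifnot(inherits(x, "compg_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("single_snp", "pair_levels", "interactions", "contrasts",
            "level_vs_main", "classification", "ld",
            "volcano_single", "volcano_pairs")
  for (t in tabs) {
    write.table(x[[t]], file.path(dir, paste0(t, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(x$exclusions)) {
    write.table(x$exclusions[[nm]],
                file.path(dir, paste0("exclusions_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.compg_analysis <- function(x, ...) {
  cat("<compg_analysis> ", x$manifest$gene_label, "\n", sep = "")
  cat("  cohorts: ", paste(x$manifest$cohorts, collapse = ", "), "\n", sep = "")
  cat("  SNPs retained: ", x$manifest$n_snps_retained,
      "; pairs: ", x$manifest$n_pairs, "\n", sep = "")
  cat("  significant single SNPs (q < ", x$alpha, "): ",
      sum(x$single_snp$q < x$alpha, na.rm = TRUE), "\n", sep = "")
  cat("  significant pairs: ", sum(x$classification$pair_significant),
      " (novel-compg: ", sum(x$classification$category == "novel-compg"),
      ", partial interaction: ", sum(x$classification$partial_interaction), ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.compg_analysis <- function(object, ...) {
  print(object)
  cat("\nclassification counts:\n")
  print(table(object$classification$category))
  if (nrow(object$ld)) {
    cat("\nLD case/control differences significant at Bonferroni ",
        signif(object$ld$bonferroni_alpha[1], 3), ": ",
        sum(object$ld$significant), " of ", nrow(object$ld), " pairs\n", sep = "")
  }
  invisible(object)
}
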