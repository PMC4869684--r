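# End-to-end simulation experiments: type-I error, power against the
# single-variant min-P / burden / SKAT comparators, and estimator bias.

# Stage-1 analysis of one simulated cohort: EM -> dosages -> rare-haplotype
# collapsing -> kinship LMM. Returns a cohort_summary.
analyze_cohort_hap <- function(cohort, panel, cohort_id = "cohort",
                               collapse_threshold = 0.001) {
  G <- cohort$genotypes
  freqs <- hap_em(G)
  # haplotypes with fewer than half an expected copy carry no information
  # and would contribute a numerically void regression column
  freqs <- prune_hap_freq(freqs, 0.25 / nrow(G))
  D <- hap_dosages(G, freqs)
  col <- collapse_rare(D, freqs, collapse_threshold)
  X <- cbind(age = cohort$phen$age, sex = cohort$phen$sex)
  Xo <- cbind(X, col$dosages)
  fit <- lmm_fit(cohort$phen$trait, Xo, cohort$kin)
  K <- ncol(col$dosages)
  hap_ix <- 2L + seq_len(K)
  structure(list(cohort = cohort_id, n = length(cohort$phen$trait),
                 labels = colnames(col$dosages),
                 frequencies = col$freqs$frequency[
                   match(colnames(col$dosages), col$freqs$label)],
                 beta = fit$coefficients[hap_ix],
                 beta_vcov = fit$vcov[hap_ix, hap_ix, drop = FALSE],
                 alpha = fit$coefficients[1:2],
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                 variants = panel$variants$name),
            class = "cohort_summary")
}

simulate_design <- function(design, panel, scenario = NULL) {
  lapply(seq_len(nrow(design)), function(i)
    simulate_cohort(design$n_units[i], design$unit[i], panel,
                    scenario = scenario, dense_kinship = FALSE))
}

experiment_result <- function(id, rejections, n_used, n_failed, alpha,
                              seed, pvals = NULL, extra = list()) {
  rate <- rejections / n_used
  structure(c(list(experiment = id, rate = rate, rejections = rejections,
                   replicates = n_used, failed = n_failed, alpha = alpha,
                   mc_se = sqrt(rate * (1 - rate) / n_used),
                   seed = seed, pvals = pvals), extra),
            class = "hap_experiment")
}

#' @export
print.hap_experiment <- function(x, ...) {
  cat("Experiment:", x$experiment, "\n")
  cat(sprintf("  rejection rate %.4f (%d / %d replicates, alpha = %g, MC SE %.4f)\n",
              x$rate, x$rejections, x$replicates, x$alpha, x$mc_se))
  if (x$failed > 0) cat("  failed replicates:", x$failed, "\n")
  if (!is.null(x$comparators)) {
    cat("  comparator rejection rates:\n")
    print(round(unlist(x$comparators), 4))
  }
  invisible(x)
}

#' Type-I error experiment for the haplotype meta-analysis global test
#'
#' Simulates `n_sims` null replicates of a multi-cohort study design, runs
#' the full pipeline on each (per-cohort EM, rare-haplotype collapsing,
#' kinship LMM; GLS meta-analysis; global Wald test) and reports the
#' fraction of global-test p-values below `alpha`. Replicates failing with
#' a numerical error (e.g., a singular design) are excluded and counted;
#' more than 1% failures aborts the experiment.
#'
#' @param design_id Study design id 1-10, see [study_designs()].
#' @param gene `"G6PC2"` or `"JAZF1"`.
#' @param n_sims Number of null replicates.
#' @param alpha Nominal level (default 0.01).
#' @param seed RNG seed (all randomness in the experiment derives from it).
#' @return A `hap_experiment` object; `$pvals` holds the global-test
#'   p-values of all successful replicates.
#' @export
run_type1 <- function(design_id, gene = c("G6PC2", "JAZF1"),
                      n_sims = 2000L, alpha = 0.01, seed = 1L) {
  gene <- match.arg(gene)
  panel <- reference_panel(gene)
  design <- study_designs(design_id)
  set.seed(seed)
  pvals <- rep(NA_real_, n_sims)
  for (r in seq_len(n_sims)) {
    pvals[r] <- tryCatch({
      cohorts <- simulate_design(design, panel)
      sums <- lapply(seq_along(cohorts), function(i)
        analyze_cohort_hap(cohorts[[i]], panel, paste0("cohort", i)))
      hap_meta(sums)$global$p
    }, error = function(e) NA_real_)
  }
  failed <- sum(is.na(pvals))
  if (failed > 0.01 * n_sims)
    stop("more than 1% of replicates failed (", failed, " of ", n_sims, ")")
  ok <- pvals[!is.na(pvals)]
  experiment_result(sprintf("type1 design %d, %s", design_id, gene),
                    sum(ok < alpha), length(ok), failed, alpha, seed,
                    pvals = ok)
}

# Single-variant LMM effect estimates for one cohort (intercept + age +
# sex + one variant at a time, kinship random effect as in the haplotype
# model).
snv_cohort_estimates <- function(cohort) {
  G <- cohort$genotypes
  y <- cohort$phen$trait
  base <- cbind(`(Intercept)` = 1, age = cohort$phen$age,
                sex = cohort$phen$sex)
  # variants monomorphic within the cohort carry no information there and
  # are contributed by the other cohorts only
  poly <- which(apply(G, 2L, function(g) min(g) != max(g)))
  out <- lapply(poly, function(j) {
    X <- cbind(base, g = G[, j])
    fit <- lmm_fit(y, X, cohort$kin)
    c(beta = unname(fit$coefficients["g"]),
      se = sqrt(fit$vcov["g", "g"]))
  })
  data.frame(variant = colnames(G)[poly],
             beta = vapply(out, `[[`, numeric(1L), "beta"),
             se = vapply(out, `[[`, numeric(1L), "se"),
             n = length(y), maf = colMeans(G)[poly] / 2,
             stringsAsFactors = FALSE)
}

#' Power experiment: haplotype meta-analysis vs comparators
#'
#' Simulates `n_sims` replicates of a causal scenario and evaluates, on
#' the same replicates, (i) the haplotype meta-analysis global test,
#' (ii) inverse-variance single-variant meta-analysis taking the minimum
#' p-value with a Bonferroni correction for the effective number of
#' independent variants, (iii) burden and (iv) SKAT meta-analysis from
#' pooled family-aware score statistics with Wu weights.
#'
#' @inheritParams run_type1
#' @param scenario_kind `"1SNV"`, `"2SNV"`, `"1HAP"` or `"2HAP"` (or
#'   `"null"` for a calibration run).
#' @param r2 Variance explained per causal term (default 0.01).
#' @param alpha Nominal level (default 0.001).
#' @return A `hap_experiment`; `$rate` is the haplotype-meta power and
#'   `$comparators` the min-P/burden/SKAT rates. `$power_table` collects
#'   all four.
#' @export
run_power <- function(design_id, gene = c("G6PC2", "JAZF1"),
                      scenario_kind = "2HAP", n_sims = 500L,
                      alpha = 0.001, r2 = 0.01, seed = 1L) {
  gene <- match.arg(gene)
  panel <- reference_panel(gene)
  design <- study_designs(design_id)
  scenario <- effect_scenario(panel, scenario_kind, r2 = r2)
  set.seed(seed)
  rej <- matrix(NA, n_sims, 4L,
                dimnames = list(NULL, c("hap", "minp", "burden", "skat")))
  for (r in seq_len(n_sims)) {
    res <- tryCatch({
      cohorts <- simulate_design(design, panel, scenario)
      sums <- lapply(seq_along(cohorts), function(i)
        analyze_cohort_hap(cohorts[[i]], panel, paste0("cohort", i)))
      p_hap <- hap_meta(sums)$global$p

      snv <- do.call(rbind, lapply(cohorts, snv_cohort_estimates))
      pooled <- ivw_meta(snv)
      Gall <- do.call(rbind, lapply(cohorts, `[[`, "genotypes"))
      poly <- apply(Gall, 2L, function(g) min(g) != max(g))
      meff <- effective_tests(stats::cor(Gall[, poly, drop = FALSE]))
      p_minp <- min_p_test(pooled$p, meff, alpha)

      scores <- lapply(cohorts, function(co)
        lmm_score(co$phen$trait,
                  cbind(1, co$phen$age, co$phen$sex),
                  co$genotypes, co$kin))
      bs <- burden_skat_meta(scores)
      c(p_hap < alpha, p_minp$reject, bs$burden$p < alpha, bs$skat$p < alpha)
    }, error = function(e) rep(NA, 4L))
    rej[r, ] <- res
  }
  failed <- sum(apply(is.na(rej), 1L, any))
  if (failed > 0.01 * n_sims)
    stop("more than 1% of replicates failed (", failed, " of ", n_sims, ")")
  ok <- !apply(is.na(rej), 1L, any)
  rates <- colMeans(rej[ok, , drop = FALSE])
  experiment_result(
    sprintf("power design %d, %s, %s", design_id, gene, scenario_kind),
    sum(rej[ok, "hap"]), sum(ok), failed, alpha, seed,
    extra = list(comparators = as.list(rates[-1L]),
                 power_table = rates,
                 scenario = scenario))
}

#' Bias of meta-analyzed haplotype contrasts
#'
#' Runs causal replicates and compares the mean meta-analyzed contrast
#' (each haplotype vs the baseline) with the generating value
#' `b(label) - b(baseline)` implied by the scenario effects.
#'
#' @inheritParams run_power
#' @param baseline Baseline label; default the panel's most frequent
#'   haplotype (fixed across replicates so contrasts are comparable).
#' @return A list of class `hap_bias`: per-label `mean`, `se` (of the
#'   mean), `truth`, `n_reps`, plus the scenario.
#' @export
run_estimate_bias <- function(design_id, gene = c("G6PC2", "JAZF1"),
                              scenario_kind = "2HAP", n_sims = 500L,
                              r2 = 0.01, seed = 1L, baseline = NULL) {
  gene <- match.arg(gene)
  panel <- reference_panel(gene)
  design <- study_designs(design_id)
  scenario <- effect_scenario(panel, scenario_kind, r2 = r2)
  if (is.null(baseline)) baseline <- panel$haplotypes$label[1L]
  set.seed(seed)
  labels <- panel$haplotypes$label
  est <- matrix(NA_real_, n_sims, length(labels),
                dimnames = list(NULL, labels))
  for (r in seq_len(n_sims)) {
    got <- tryCatch({
      cohorts <- simulate_design(design, panel, scenario)
      sums <- lapply(seq_along(cohorts), function(i)
        analyze_cohort_hap(cohorts[[i]], panel, paste0("cohort", i)))
      m <- hap_meta(sums, baseline = baseline)
      m$contrasts
    }, error = function(e) NULL)
    if (!is.null(got)) {
      hit <- intersect(got$label, labels)
      est[r, hit] <- got$estimate[match(hit, got$label)]
    }
  }
  b <- stats::setNames(numeric(length(labels)), labels)
  if (scenario$kind != "null" && scenario$type == "hap")
    b[scenario$causal] <- scenario$effects
  truth <- b - b[baseline]
  mean_est <- colMeans(est, na.rm = TRUE)
  n_eff <- colSums(!is.na(est))
  se <- apply(est, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1L))
  structure(list(labels = labels, baseline = baseline, mean = mean_est,
                 se = se, truth = truth, n_reps = n_eff,
                 scenario = scenario, seed = seed),
            class = "hap_bias")
}

#' @export
print.hap_bias <- function(x, ...) {
  cat("Contrast bias vs baseline", x$baseline, "\n")
  tab <- data.frame(label = x$labels, mean = x$mean, truth = x$truth,
                    se = x$se, n = x$n_reps)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}
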