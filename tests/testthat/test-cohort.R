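# Fixture: one small family cohort with dosages, shared across blocks.
cohort_fixture <- function(n_fam = 60, unit = "NF2", seed = 7) {
  set.seed(seed)
  panel <- reference_panel("G6PC2")
  co <- simulate_cohort(n_fam, unit, panel)
  f <- hap_em(co$genotypes)
  f <- prune_hap_freq(f, 0.25 / nrow(co$genotypes))
  col <- collapse_rare(hap_dosages(co$genotypes, f), f)
  list(co = co, dosages = col$dosages, freqs = col$freqs, panel = panel)
}

test_that("with unrelated subjects the fit equals ordinary least squares", {
  set.seed(2)
  panel <- reference_panel("G6PC2")
  co <- simulate_cohort(400, "U", panel)
  f <- prune_hap_freq(hap_em(co$genotypes), 0.25 / 400)
  col <- collapse_rare(hap_dosages(co$genotypes, f), f)
  fit <- hap_lmm(trait ~ age + sex, co$phen, col$dosages,
                 kinship = co$kinship, freqs = col$freqs)
  X <- cbind(age = co$phen$age, sex = co$phen$sex, col$dosages)
  ols <- lm.fit(X, co$phen$trait)
  expect_lt(max(abs(coef(fit) - ols$coefficients)), 1e-8)
  # covariance equals the ML-variance OLS covariance
  n <- nrow(X)
  s2 <- sum(ols$residuals^2) / n
  Vo <- s2 * chol2inv(qr.R(qr(X)))
  K <- ncol(col$dosages)
  expect_equal(unname(vcov(fit)), Vo[2 + (1:K), 2 + (1:K)], tolerance = 1e-8)
  expect_false(fit$vc_identifiable)
})

test_that("coefficients and covariance match the dense GLS oracle", {
  fx <- cohort_fixture(40)
  fit <- hap_lmm(trait ~ age + sex, fx$co$phen, fx$dosages,
                 kinship = fx$co$kinship, freqs = fx$freqs)
  Omega <- fit$sigma_a2 * fx$co$kinship +
    fit$sigma_e2 * diag(nrow(fx$co$kinship))
  Xo <- cbind(age = fx$co$phen$age, sex = fx$co$phen$sex, fx$dosages)
  Oi <- solve(Omega)
  A <- t(Xo) %*% Oi %*% Xo
  bb <- solve(A, t(Xo) %*% Oi %*% fx$co$phen$trait)
  expect_equal(unname(coef(fit)), as.vector(bb), tolerance = 1e-8)
  VV <- solve(A)
  K <- ncol(fx$dosages)
  expect_equal(unname(vcov(fit)), unname(VV[2 + (1:K), 2 + (1:K)]),
               tolerance = 1e-10)
})

test_that("profiled likelihood at the optimum beats a variance-component grid", {
  fx <- cohort_fixture(30, seed = 12)
  y <- fx$co$phen$trait
  Xo <- cbind(age = fx$co$phen$age, sex = fx$co$phen$sex, fx$dosages)
  fit <- hap_lmm(trait ~ age + sex, fx$co$phen, fx$dosages,
                 kinship = fx$co$kinship, freqs = fx$freqs)
  Phi <- fx$co$kinship
  n <- length(y)
  dense_ll <- function(sa, se) {
    Om <- sa * Phi + se * diag(n)
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Oi <- chol2inv(ch)
    b <- solve(t(Xo) %*% Oi %*% Xo, t(Xo) %*% Oi %*% y)
    r <- y - Xo %*% b
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + t(r) %*% Oi %*% r)
  }
  grid <- expand.grid(sa = seq(0.04, 2, length.out = 25),
                      se = seq(0.04, 2, length.out = 25))
  grid_ll <- max(mapply(dense_ll, grid$sa, grid$se))
  expect_gte(fit$loglik + 1e-6, grid_ll)
  # and the reported optimum agrees with the dense likelihood at the MLE
  expect_equal(fit$loglik, as.vector(dense_ll(fit$sigma_a2, fit$sigma_e2)),
               tolerance = 1e-6)
})

test_that("variance components are recovered in family data", {
  set.seed(31)
  panel <- reference_panel("G6PC2")
  est <- replicate(40, {
    s <- simulate_cohort(200, "NF2", panel)
    vc <- fit_variance_components(s$phen$trait,
                                  cbind(1, s$phen$age, s$phen$sex),
                                  s$kinship)
    c(vc$sigma_a2, vc$sigma_e2)
  })
  for (k in 1:2) {
    se <- sd(est[k, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[k, ]) - 0.5), 3 * se + 0.02)
  }
})

test_that("degenerate traits hit the variance boundary", {
  fx <- cohort_fixture(20, seed = 9)
  phen <- fx$co$phen
  phen$trait <- rep(1, nrow(phen))
  fit <- suppressWarnings(
    hap_lmm(trait ~ age + sex, phen, fx$dosages, kinship = fx$co$kinship))
  expect_true(fit$boundary || fit$sigma_a2 < 1e-6)
})

test_that("estimates are invariant to haplotype column order", {
  fx <- cohort_fixture(50, seed = 15)
  fit1 <- hap_lmm(trait ~ age + sex, fx$co$phen, fx$dosages,
                  kinship = fx$co$kinship)
  perm <- sample(ncol(fx$dosages))
  fit2 <- hap_lmm(trait ~ age + sex, fx$co$phen,
                  fx$dosages[, perm, drop = FALSE], kinship = fx$co$kinship)
  expect_equal(fit2$beta[fit1$labels], fit1$beta, tolerance = 1e-6)
  expect_equal(fit2$beta_vcov[fit1$labels, fit1$labels], fit1$beta_vcov,
               tolerance = 1e-6)
})

test_that("a single haplotype column reduces to the GLS intercept model", {
  set.seed(44)
  panel <- reference_panel("G6PC2")
  co <- simulate_cohort(50, "NF2", panel)
  D1 <- matrix(2, nrow(co$phen), 1, dimnames = list(co$phen$id, "ALL"))
  fit <- hap_lmm(trait ~ age + sex, co$phen, D1, kinship = co$kinship)
  # direct solve: y = 2 beta + X alpha under Omega-hat
  Omega <- fit$sigma_a2 * co$kinship + fit$sigma_e2 * diag(nrow(co$kinship))
  Xo <- cbind(co$phen$age, co$phen$sex, 2)
  Oi <- solve(Omega)
  bb <- solve(t(Xo) %*% Oi %*% Xo, t(Xo) %*% Oi %*% co$phen$trait)
  expect_equal(unname(fit$beta), bb[3], tolerance = 1e-8)
})

test_that("rank-deficient designs raise an error naming the columns", {
  fx <- cohort_fixture(30, seed = 2)
  D <- cbind(fx$dosages, DUP = fx$dosages[, 1])
  expect_error(hap_lmm(trait ~ age + sex, fx$co$phen, D,
                       kinship = fx$co$kinship), "rank deficient")
})

test_that("cohort summaries round-trip through JSON", {
  fx <- cohort_fixture(30, seed = 27)
  fit <- hap_lmm(trait ~ age + sex, fx$co$phen, fx$dosages,
                 kinship = fx$co$kinship, freqs = fx$freqs,
                 cohort = "fhs", variants = fx$panel$variants$name)
  tf <- tempfile(fileext = ".json")
  write_cohort_summary(fit, tf)
  got <- read_cohort_summary(tf)
  expect_equal(got$labels, fit$labels)
  expect_equal(got$beta, fit$beta)
  expect_equal(unname(got$beta_vcov), unname(fit$beta_vcov))
  expect_equal(got$n, fit$n)
  expect_equal(got$variants, fx$panel$variants$name)
})

test_that("null-cohort pairwise effect contrasts are standard normal", {
  set.seed(61)
  panel <- reference_panel("G6PC2")
  z <- replicate(120, {
    co <- simulate_cohort(80, "NF2", panel)
    f <- prune_hap_freq(hap_em(co$genotypes), 0.25 / nrow(co$genotypes))
    col <- collapse_rare(hap_dosages(co$genotypes, f), f)
    fit <- hap_lmm(trait ~ age + sex, co$phen, col$dosages,
                   kinship = co$kinship, freqs = col$freqs)
    i <- match("CCAC", fit$labels); j <- match("TCAG", fit$labels)
    if (is.na(i) || is.na(j)) return(NA_real_)
    d <- fit$beta[i] - fit$beta[j]
    d / sqrt(fit$beta_vcov[i, i] + fit$beta_vcov[j, j] - 2 * fit$beta_vcov[i, j])
  })
  z <- z[!is.na(z)]
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(sd(z) - 1), 0.2)
  expect_gt(shapiro.test(z)$p.value, 1e-4)
})
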