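# Shared fixtures and independent oracles used across test files.

# A three-generation pedigree: grandparents gp1 x gp2 -> parent p1;
# p1 x spouse -> two grandchildren. Plus an avuncular line.
three_gen_pedigree <- function() {
  as_pedigree(data.frame(
    fam = "1",
    id = c("gp1", "gp2", "p1", "p2", "sp", "c1", "c2"),
    father = c(NA, NA, "gp1", "gp1", NA, "p1", "p1"),
    mother = c(NA, NA, "gp2", "gp2", NA, "sp", "sp"),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L, 2L),
    stringsAsFactors = FALSE))
}

nuclear_pedigree <- function(fam = "1") {
  as_pedigree(data.frame(
    fam = fam, id = paste0(fam, c("_f", "_m", "_k1", "_k2")),
    father = c(NA, NA, paste0(fam, "_f"), paste0(fam, "_f")),
    mother = c(NA, NA, paste0(fam, "_m"), paste0(fam, "_m")),
    sex = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE))
}

# Tiny two-variant genotype fixture with known phase structure.
toy_genotypes <- function(counts, alleles = NULL) {
  G <- do.call(rbind, counts)
  storage.mode(G) <- "integer"
  rownames(G) <- paste0("s", seq_len(nrow(G)))
  if (!is.null(alleles)) attr(G, "alleles") <- alleles
  G
}

# Direct maximization of the phase-unknown log-likelihood over the
# haplotype frequency simplex (softmax parameterization, multi-start).
# Independent of the EM path; used as the oracle for small problems.
direct_hap_loglik <- function(G, codes, f) {
  n <- nrow(G)
  ll <- 0
  for (i in seq_len(n)) {
    dp <- enumerate_diplotypes(G[i, ])
    a <- match(dp[, 1L], codes); b <- match(dp[, 2L], codes)
    ok <- !is.na(a) & !is.na(b)
    pr <- sum(f[a[ok]] * f[b[ok]] * ifelse(a[ok] == b[ok], 1, 2))
    ll <- ll + log(pr)
  }
  ll
}

direct_hap_ml <- function(G, codes, n_starts = 8, seed = 99) {
  set.seed(seed)
  K <- length(codes)
  best <- -Inf
  for (s in seq_len(n_starts)) {
    th0 <- if (s == 1) rep(0, K) else rnorm(K)
    opt <- optim(th0, function(th) {
      f <- exp(th - max(th)); f <- f / sum(f)
      -direct_hap_loglik(G, codes, f)
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    if (-opt$value > best) best <- -opt$value
  }
  best
}

# Brute-force stacked GLS solve: build the full W matrix and
# block-diagonal covariance explicitly.
brute_meta <- function(summaries, labels) {
  Ws <- lapply(summaries, function(s) {
    Wi <- matrix(0, length(s$labels), length(labels))
    Wi[cbind(seq_along(s$labels), match(s$labels, labels))] <- 1
    Wi
  })
  W <- do.call(rbind, Ws)
  beta_hat <- unlist(lapply(summaries, `[[`, "beta"))
  Vs <- lapply(summaries, `[[`, "beta_vcov")
  m <- sum(vapply(Vs, nrow, integer(1L)))
  Sigma <- matrix(0, m, m)
  at <- 0
  for (V in Vs) {
    k <- nrow(V)
    Sigma[at + seq_len(k), at + seq_len(k)] <- V
    at <- at + k
  }
  Si <- solve(Sigma)
  A <- t(W) %*% Si %*% W
  beta <- solve(A, t(W) %*% Si %*% beta_hat)
  list(beta = as.vector(beta), V = solve(A))
}

mock_summary <- function(cohort, labels, beta, vcov, n = 100,
                         freq = NULL, variants = NULL) {
  structure(list(cohort = cohort, n = n, labels = labels,
                 frequencies = if (is.null(freq)) rep(1 / length(labels),
                                                      length(labels))
                               else freq,
                 beta = stats::setNames(beta, labels),
                 beta_vcov = `dimnames<-`(vcov, list(labels, labels)),
                 alpha = numeric(0), sigma_a2 = 0, sigma_e2 = 1,
                 variants = variants),
            class = "cohort_summary")
}

# Chi-square mixture tail by a fine Riemann sum over the Imhof integrand,
# with its own step-size control (independent of integrate()).
mixture_tail_oracle <- function(q, lambda, upper = 3000, step = 2e-4,
                                chunk = 5e5) {
  total <- 0
  lo <- 0
  while (lo < upper) {
    hi <- min(lo + chunk * step, upper)
    u <- seq(lo + step / 2, hi, by = step)
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    total <- total + sum(sin(theta) / (u * rho)) * step
    lo <- hi
  }
  0.5 + total / pi
}
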