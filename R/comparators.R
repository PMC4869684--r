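# Competitor meta-analyses for the power study: inverse-variance single-SNV
# meta with an effective-number-corrected min-P, and burden/SKAT built from
# pooled family-aware score statistics with Wu weights.

#' Inverse-variance weighted single-variant meta-analysis
#'
#' Pools per-cohort effect estimates variant by variant with weights
#' `1/SE^2`; two-sided normal p-values.
#'
#' @param input Data frame with columns `variant`, `beta`, `se` (one row per
#'   cohort x variant; additional columns ignored).
#' @return Data frame with one row per variant: `variant`, `beta`, `se`,
#'   `z`, `p`.
#' @export
ivw_meta <- function(input) {
  stopifnot(all(c("variant", "beta", "se") %in% names(input)))
  if (any(input$se <= 0)) stop("standard errors must be positive")
  out <- do.call(rbind, lapply(split(input, input$variant), function(d) {
    w <- 1 / d$se^2
    b <- sum(w * d$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    data.frame(variant = d$variant[1L], beta = b, se = se,
               z = b / se, stringsAsFactors = FALSE)
  }))
  out <- out[match(unique(input$variant), out$variant), , drop = FALSE]
  out$p <- 2 * stats::pnorm(-abs(out$z))
  rownames(out) <- NULL
  out
}

#' Effective number of independent tests (simpleM)
#'
#' The smallest number of leading eigenvalues of the genotype correlation
#' matrix whose sum exceeds 99.5% of the eigenvalue total.
#'
#' @param R q x q genotype correlation matrix.
#' @param cut Proportion of eigenvalue mass to capture (default 0.995).
#' @return Integer Meff, between 1 and q.
#' @export
effective_tests <- function(R, cut = 0.995) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  ev <- pmax(ev, 0)
  which(cumsum(ev) >= cut * sum(ev))[1L]
}

#' Minimum-P single-variant test with effective-number Bonferroni correction
#'
#' @param p Vector of per-variant meta-analysis p-values in `(0, 1]`.
#' @param meff Effective number of independent tests, see
#'   [effective_tests()].
#' @param alpha Nominal significance level.
#' @return List: `min_p`, `adjusted` (`min(1, meff * min_p)`), `reject`.
#' @export
min_p_test <- function(p, meff, alpha = 0.001) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  adj <- min(1, meff * min(p))
  list(min_p = min(p), adjusted = adj, reject = adj < alpha)
}

#' Family-aware score statistics for region-based tests
#'
#' Computes, for one cohort, the score vector and score covariance of the
#' region's genotypes under the null mixed model (covariates and kinship
#' random effect, no genotypes):
#' `U = G' Omega^-1 (Y - X alpha)` and
#' `V = G' Omega^-1 G - G' Omega^-1 X (X' Omega^-1 X)^-1 X' Omega^-1 G`,
#' with `Omega` at the null-model ML variance components. These are the
#' per-cohort inputs pooled by [burden_skat_meta()].
#'
#' @param y Trait vector.
#' @param X Null-model design matrix (should include an intercept).
#' @param G n x q genotype (minor-allele count) matrix.
#' @param kinship Relationship matrix or `NULL`.
#' @return List of class `score_summary`: `U`, `V`, `maf`, `n`.
#' @export
lmm_score <- function(y, X, G, kinship = NULL) {
  X <- as.matrix(X); G <- as.matrix(G)
  ks <- kin_structure(kinship, length(y))
  null_fit <- lmm_fit(y, X, ks)
  lam <- if (null_fit$sigma_e2 > 0) null_fit$sigma_a2 / null_fit$sigma_e2 else 0
  d <- kin_eigenvalues(ks)
  w <- 1 / (lam * d + 1)
  ystar <- kin_rotate(ks, matrix(y, ncol = 1L))
  Xstar <- kin_rotate(ks, X)
  Gstar <- kin_rotate(ks, G)
  s2 <- null_fit$sigma_e2
  XtWX <- crossprod(Xstar * sqrt(w))
  XtWy <- crossprod(Xstar, w * ystar)
  alpha <- solve(XtWX, XtWy)
  r <- w * (ystar - Xstar %*% alpha)
  U <- crossprod(Gstar, r) / s2
  GtWG <- crossprod(Gstar * sqrt(w))
  GtWX <- crossprod(Gstar, w * Xstar)
  V <- (GtWG - GtWX %*% solve(XtWX, t(GtWX))) / s2
  structure(list(U = as.vector(U), V = V, maf = colMeans(G) / 2,
                 n = length(y), variants = colnames(G)),
            class = "score_summary")
}

#' Wu variant weights
#'
#' Beta(1, 25) density evaluated at the minor allele frequency, the default
#' weighting that upweights rare variants in SKAT/burden tests.
#'
#' @param maf Minor allele frequencies in `[0, 1)`.
#' @return Numeric weights (`25 * (1 - maf)^24`).
#' @export
wu_weights <- function(maf) stats::dbeta(maf, 1, 25)

#' Burden and SKAT meta-analysis from pooled score statistics
#'
#' Pools per-cohort score summaries (`U = sum U_i`, `V = sum V_i`) and
#' computes the weighted burden test `T = (w'U)^2 / (w'Vw)` against
#' chi-square(1), and the SKAT statistic `Q = sum_j w_j^2 U_j^2` whose null
#' distribution is the mixture `sum_k lambda_k chi^2_1` with `lambda_k` the
#' eigenvalues of `W^(1/2) V W^(1/2)` (`W = diag(w^2)`); the mixture tail is
#' evaluated by numerical characteristic-function inversion with a
#' moment-matching fallback.
#'
#' @param scores List of `score_summary` objects, one per cohort.
#' @param weights Per-variant weights; default Wu weights at the pooled
#'   (2n-weighted) minor allele frequency.
#' @return List: `burden` (stat, p), `skat` (stat, p), `maf`, `weights`.
#' @export
burden_skat_meta <- function(scores, weights = NULL) {
  stopifnot(length(scores) >= 1L)
  q <- length(scores[[1L]]$U)
  U <- Reduce(`+`, lapply(scores, `[[`, "U"))
  V <- Reduce(`+`, lapply(scores, `[[`, "V"))
  ntot <- sum(vapply(scores, `[[`, numeric(1L), "n"))
  maf <- Reduce(`+`, lapply(scores, function(s) s$maf * s$n)) / ntot
  if (is.null(weights)) weights <- wu_weights(maf)
  if (all(weights == 0)) stop("all variant weights are zero")
  w <- weights
  burden_stat <- drop(crossprod(w, U))^2 / drop(crossprod(w, V %*% w))
  burden_p <- stats::pchisq(burden_stat, 1, lower.tail = FALSE)
  Q <- sum(w^2 * U^2)
  M <- (w %o% w) * V    # W^(1/2) V W^(1/2) for diagonal W = diag(w^2)
  lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  if (!length(lam)) stop("score covariance has no positive eigenvalues")
  skat_p <- chisq_mixture_pvalue(Q, lam)
  list(burden = list(stat = burden_stat, p = burden_p),
       skat = list(stat = Q, p = skat_p),
       maf = maf, weights = weights)
}

#' Tail probability of a positive linear combination of chi-square(1)
#'
#' `P(sum_k lambda_k chi^2_1 > q)` by Imhof-type numerical inversion of the
#' characteristic function, falling back to the Liu et al. moment-matching
#' chi-square approximation if the integration fails. Components below
#' 1/1000 of the leading eigenvalue are absorbed by their mean (absolute
#' cost below ~1e-7); otherwise absolute accuracy is about 1e-9.
#'
#' @param q Observed statistic (scalar).
#' @param lambda Positive mixture weights.
#' @return The upper-tail probability, clamped to `[0, 1]`.
#' @export
chisq_mixture_pvalue <- function(q, lambda) {
  stopifnot(length(q) == 1L, all(lambda > 0))
  # scale invariance: normalize the largest mixture weight to 1
  s <- max(lambda)
  lambda <- lambda / s
  q <- q / s
  # components far below the leading eigenvalue shift the distribution by
  # essentially their mean; absorbing them keeps the oscillatory integral
  # short (absolute error on p below ~1e-7 at this cutoff)
  minor <- lambda < 1e-3
  if (any(minor)) {
    q <- max(q - sum(lambda[minor]), 0)
    lambda <- lambda[!minor]
  }
  if (length(lambda) == 1L)
    return(stats::pchisq(q / lambda, 1, lower.tail = FALSE))
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)  # integrand limit at the origin
    out
  }
  # truncation point: beyond U the oscillatory tail is bounded by the
  # monotone envelope 1/(u rho(u)) times the oscillation period, so run U
  # out until that bound drops below the accuracy target
  envelope <- function(u)
    exp(-log(u) - 0.25 * sum(log1p(lambda^2 * u^2)))
  period <- 4 * pi / max(q, sum(lambda))
  U <- 64
  while (envelope(U) * period > 1e-10 && U < 2^21) U <- 2 * U
  # the infinite-range transformation of integrate() is inaccurate for this
  # oscillatory integrand; a finite interval with ample subdivisions is not
  p <- tryCatch(
    0.5 + stats::integrate(imhof, 0, U, rel.tol = 1e-9, abs.tol = 1e-11,
                           subdivisions = 100000L)$value / pi,
    error = function(e) NA_real_)
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) p <- liu_pvalue(q, lambda)
  min(max(p, 0), 1)
}

# Liu et al. four-moment chi-square approximation to the mixture tail.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  qq <- tstar * sqrt(2) * sqrt(l + 2 * delta) + l + delta
  stats::pchisq(qq, df = l, ncp = delta, lower.tail = FALSE)
}
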