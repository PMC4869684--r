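as_cohort_summary <- function(x) {
  if (inherits(x, "hap_lmm")) return(cohort_summary(x))
  if (inherits(x, "cohort_summary")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_cohort_summary(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a cohort summary")
}

check_psd <- function(V, what) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(what, " covariance matrix is not positive semi-definite")
  invisible(TRUE)
}

#' Align cohort haplotype sets for meta-analysis
#'
#' Builds the stacked generalized-least-squares design: the union of the
#' haplotype labels observed across cohorts (K' of them, ordered by pooled
#' frequency), one 0/1 selection matrix per cohort mapping its local
#' haplotype order into the union order, and the block-diagonal covariance.
#' Haplotypes observed in a single cohort are retained.
#'
#' @param summaries List of `hap_lmm` fits, `cohort_summary` objects, or
#'   paths to cohort summary JSON files.
#' @return A list of class `meta_design`: `labels` (union, ordered),
#'   `summaries`, `W` (list of selection matrices), `pooled_freq`
#'   (sample-size-weighted mean frequency), `n_obs` (cohorts observing each
#'   label).
#' @export
build_meta_design <- function(summaries) {
  summaries <- lapply(summaries, as_cohort_summary)
  if (!length(summaries)) stop("no cohort summaries supplied")
  v0 <- summaries[[1L]]$variants
  for (s in summaries[-1L]) {
    if (!identical(is.null(v0), is.null(s$variants)) ||
        (!is.null(v0) && !isTRUE(all.equal(v0, s$variants))))
      stop("cohorts disagree on the variant list; summaries are incompatible")
  }
  for (s in summaries)
    check_psd(s$beta_vcov, paste0("cohort '", s$cohort, "'"))

  all_labels <- unique(unlist(lapply(summaries, `[[`, "labels")))
  wsum <- stats::setNames(numeric(length(all_labels)), all_labels)
  fsum <- wsum; nobs <- wsum
  for (s in summaries) {
    wsum[s$labels] <- wsum[s$labels] + s$n
    fsum[s$labels] <- fsum[s$labels] + s$n * s$frequencies
    nobs[s$labels] <- nobs[s$labels] + 1
  }
  pooled <- fsum / wsum
  labels <- all_labels[order(-nobs[all_labels], -pooled[all_labels])]
  W <- lapply(summaries, function(s) {
    Wi <- matrix(0, length(s$labels), length(labels),
                 dimnames = list(s$labels, labels))
    Wi[cbind(seq_along(s$labels), match(s$labels, labels))] <- 1
    Wi
  })
  structure(list(labels = labels, summaries = summaries, W = W,
                 pooled_freq = pooled[labels], n_obs = nobs[labels]),
            class = "meta_design")
}

# GLS pooling on a meta_design: beta_tilde = (W' S^-1 W)^-1 W' S^-1 beta_hat.
# Solved by accumulating the normal equations cohort by cohort (the
# covariance is block-diagonal) and a symmetric factorization.
gls_combine <- function(design) {
  labels <- design$labels
  Kp <- length(labels)
  A <- matrix(0, Kp, Kp, dimnames = list(labels, labels))
  rhs <- stats::setNames(numeric(Kp), labels)
  for (i in seq_along(design$summaries)) {
    s <- design$summaries[[i]]
    pos <- match(s$labels, labels)
    Vi_inv <- tryCatch(chol2inv(chol(s$beta_vcov)),
                       error = function(e)
                         stop("cohort '", s$cohort,
                              "' covariance is singular: ", conditionMessage(e)))
    A[pos, pos] <- A[pos, pos] + Vi_inv
    rhs[pos] <- rhs[pos] + Vi_inv %*% s$beta
  }
  cond <- kappa(A, exact = FALSE)
  if (cond > 1e10)
    warning("meta normal equations are ill-conditioned (kappa ~ ",
            format(cond, digits = 3), ")")
  ch <- tryCatch(chol(A), error = function(e) {
    zero <- labels[abs(diag(A)) < 1e-300]
    stop("W' Sigma^-1 W is singular",
         if (length(zero)) paste0(" (no information for: ",
                                  paste(zero, collapse = ", "), ")"))
  })
  V <- chol2inv(ch)
  dimnames(V) <- list(labels, labels)
  beta <- as.vector(V %*% rhs)
  names(beta) <- labels
  list(beta = beta, V = V, condition = cond)
}

# Global Wald test of equality of all pooled haplotype effects, via
# contrasts against the baseline label; chi-square with K'-1 df. The
# statistic is invariant to the baseline choice.
wald_global <- function(beta, V, baseline) {
  labels <- names(beta)
  Kp <- length(labels)
  if (Kp < 2L) stop("global test undefined with a single haplotype")
  b <- match(baseline, labels)
  if (is.na(b)) stop("unknown baseline label: ", baseline)
  oth <- setdiff(seq_len(Kp), b)
  gamma <- beta[oth] - beta[b]
  Vstar <- V[oth, oth, drop = FALSE] -
    outer(V[oth, b], rep(1, Kp - 1L)) -
    outer(rep(1, Kp - 1L), V[b, oth]) + V[b, b]
  chi2 <- tryCatch(drop(crossprod(gamma, solve(Vstar, gamma))),
                   error = function(e)
                     stop("contrast covariance V* is singular: ",
                          conditionMessage(e)))
  df <- Kp - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       gamma = gamma, Vstar = Vstar)
}

#' Multivariate GLS meta-analysis of cohort haplotype effects
#'
#' Pools cohort-level haplotype effect vectors and covariance matrices by
#' generalized least squares over the union of observed haplotypes,
#' tolerating haplotype sets that only partially overlap across cohorts.
#' Produces the pooled effect vector with covariance, a global Wald test of
#' no haplotype-trait association (equality of all pooled effects,
#' chi-square with K'-1 degrees of freedom), and per-haplotype contrasts
#' against a baseline haplotype. Because the cohort model has no intercept,
#' individual haplotype effects are identified only as contrasts; the
#' baseline row of the contrast table is blank by construction.
#'
#' @param summaries List of `hap_lmm` fits, `cohort_summary` objects or
#'   JSON paths; or a `meta_design` from [build_meta_design()].
#' @param baseline Baseline haplotype label. Default: among haplotypes
#'   observed in every cohort, the one with the highest pooled frequency.
#'   The global statistic does not depend on this choice.
#' @return An object of class `hap_meta` with `print`, `summary`, `coef`
#'   and `vcov` methods. Fields include `beta` (pooled effects), `V`,
#'   `global` (chi2, df, p), `contrasts` (label, estimate, se, z, p) and
#'   `baseline`.
#' @examples
#' s1 <- list(cohort = "a", n = 100, labels = c("AC", "AG"),
#'            frequencies = c(0.6, 0.4), beta = c(0.2, -0.1),
#'            beta_vcov = diag(2) * 0.01, variants = NULL)
#' class(s1) <- "cohort_summary"
#' s2 <- s1; s2$cohort <- "b"; s2$beta <- c(0.25, -0.05)
#' class(s2) <- "cohort_summary"
#' hap_meta(list(s1, s2))
#' @export
hap_meta <- function(summaries, baseline = NULL) {
  design <- if (inherits(summaries, "meta_design")) summaries
            else build_meta_design(summaries)
  pooled <- gls_combine(design)
  labels <- design$labels
  Kp <- length(labels)

  if (is.null(baseline)) {
    common <- labels[design$n_obs == length(design$summaries)]
    cand <- if (length(common)) common else labels
    baseline <- cand[which.max(design$pooled_freq[cand])]
  }
  if (!baseline %in% labels) stop("unknown baseline label: ", baseline)

  global <- if (Kp >= 2L) wald_global(pooled$beta, pooled$V, baseline) else NULL
  contrasts <- hap_contrast_table(pooled$beta, pooled$V, baseline)
  contrasts$frequency <- design$pooled_freq[contrasts$label]

  freq_range <- t(vapply(labels, function(l) {
    fr <- unlist(lapply(design$summaries, function(s) {
      s$frequencies[match(l, s$labels)]
    }))
    range(fr, na.rm = TRUE)
  }, numeric(2L)))
  colnames(freq_range) <- c("freq_min", "freq_max")

  structure(list(labels = labels, beta = pooled$beta, V = pooled$V,
                 baseline = baseline, global = global,
                 contrasts = contrasts, freq_range = freq_range,
                 n_obs = design$n_obs, pooled_freq = design$pooled_freq,
                 condition = pooled$condition,
                 n_cohorts = length(design$summaries),
                 n_total = sum(vapply(design$summaries, `[[`, numeric(1L), "n"))),
            class = "hap_meta")
}

hap_contrast_table <- function(beta, V, baseline) {
  labels <- names(beta)
  b <- match(baseline, labels)
  est <- beta - beta[b]
  se <- sqrt(pmax(diag(V) - 2 * V[, b] + V[b, b], 0))
  z <- ifelse(labels == baseline, NA_real_, est / se)
  data.frame(label = labels, estimate = ifelse(labels == baseline, NA, est),
             se = ifelse(labels == baseline, NA, se), z = z,
             p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.hap_meta <- function(x, ...) {
  cat(sprintf("Haplotype meta-analysis: %d cohorts, %d subjects, K' = %d haplotypes\n",
              x$n_cohorts, x$n_total, length(x$labels)))
  if (!is.null(x$global))
    cat(sprintf("Global Wald test: chi2 = %.3f, df = %d, p = %.3g\n",
                x$global$chi2, x$global$df, x$global$p))
  cat("Per-haplotype contrasts vs baseline", x$baseline, "\n")
  tab <- x$contrasts
  tab$frequency <- round(tab$frequency, 4)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.hap_meta <- function(object, ...) object

#' @export
coef.hap_meta <- function(object, ...) object$beta

#' @export
vcov.hap_meta <- function(object, ...) object$V

#' Write meta-analysis results to TSV and JSON
#'
#' @param meta A `hap_meta` object.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @export
write_meta_result <- function(meta, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    tab <- cbind(meta$contrasts[, c("label", "frequency")],
                 meta$freq_range[meta$contrasts$label, , drop = FALSE],
                 meta$contrasts[, c("estimate", "se", "p")])
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    obj <- list(labels = meta$labels, beta = unname(meta$beta),
                V = as.vector(t(meta$V)), baseline = meta$baseline,
                chi2 = meta$global$chi2, df = meta$global$df,
                p = meta$global$p)
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(meta)
}
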