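#' Cohort-level haplotype association fit (kinship linear mixed model)
#'
#' Fits the stage-1 model
#' `Y = X alpha + beta_1 h_1 + ... + beta_K h_K + u + e`, where the `h_m`
#' are expected haplotype dosages, `u ~ N(0, sigma_a^2 Phi)` captures
#' familial correlation through the pedigree relationship matrix, and
#' `e ~ N(0, sigma_e^2 I)`. There is no intercept: the dosage columns sum
#' to 2 per subject and absorb it. Variance components are estimated by
#' maximum likelihood; fixed effects and their covariance are the
#' generalized-least-squares expressions evaluated at the ML variance
#' components. With unrelated subjects (`Phi = I`) the fit reduces to
#' ordinary linear regression.
#'
#' @param formula A formula `trait ~ covariate1 + covariate2 + ...`. The
#'   intercept is always dropped. Use `trait ~ 1` for no covariates.
#' @param data Data frame holding the trait and covariates. If it has an
#'   `id` column (or rownames) subjects are aligned to `dosages` by id,
#'   otherwise rows are matched positionally.
#' @param dosages Expected haplotype dosage matrix from [hap_dosages()]
#'   (optionally after [collapse_rare()]).
#' @param kinship Relationship matrix, or `NULL` for unrelated subjects.
#' @param freqs Optional `hap_freq` table recorded in the result for the
#'   meta-analysis stage.
#' @param cohort Cohort identifier string stored in the summary.
#' @param variants Optional variant metadata data.frame (name, position,
#'   alleles); cohorts entering one meta-analysis must agree on it.
#' @return An object of class `hap_lmm` with `print`, `summary`, `coef`,
#'   `vcov`, `fitted`, `residuals` and `logLik` methods. The haplotype
#'   effect vector and its covariance block (the meta-analysis inputs) are
#'   in `$beta` and `$beta_vcov`.
#' @examples
#' panel <- reference_panel("G6PC2")
#' sim <- simulate_cohort(60, "NF2", panel, seed = 1)
#' freqs <- hap_em(sim$genotypes)
#' dos <- collapse_rare(hap_dosages(sim$genotypes, freqs), freqs)
#' fit <- hap_lmm(trait ~ age + sex, data = sim$phen, dosages = dos$dosages,
#'                kinship = sim$kinship, freqs = dos$freqs)
#' coef(fit)
#' @export
hap_lmm <- function(formula, data, dosages, kinship = NULL, freqs = NULL,
                    cohort = "cohort1", variants = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  icpt <- which(colnames(X) == "(Intercept)")
  if (length(icpt)) X <- X[, -icpt, drop = FALSE]

  ids <- if (!is.null(data$id)) as.character(data$id) else rownames(data)
  D <- as.matrix(dosages)
  if (!is.null(ids) && !is.null(rownames(D)) &&
      all(ids %in% rownames(D))) {
    D <- D[ids, , drop = FALSE]
  } else if (nrow(D) != length(y)) {
    stop("dosages and data cannot be aligned (", nrow(D), " vs ",
         length(y), " rows)")
  }
  ks <- kin_structure(kinship, length(y), ids = ids)

  K <- ncol(D)
  Xo <- cbind(X, D)
  fit <- lmm_fit(y, Xo, ks)

  p <- ncol(X)
  hap_ix <- p + seq_len(K)
  beta <- fit$coefficients[hap_ix]
  beta_vcov <- fit$vcov[hap_ix, hap_ix, drop = FALSE]
  alpha <- if (p) fit$coefficients[seq_len(p)] else numeric(0)
  alpha_se <- if (p) sqrt(diag(fit$vcov)[seq_len(p)]) else numeric(0)

  structure(list(
    cohort = cohort, n = fit$n,
    labels = colnames(D),
    frequencies = if (!is.null(freqs)) {
      freqs$frequency[match(colnames(D), freqs$label)]
    } else colMeans(D) / 2,
    beta = beta, beta_vcov = beta_vcov,
    alpha = alpha, alpha_se = alpha_se,
    sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
    loglik = fit$loglik, boundary = fit$boundary,
    vc_identifiable = fit$vc_identifiable,
    fitted = fit$fitted, residuals = fit$residuals,
    variants = variants, call = match.call()),
    class = "hap_lmm")
}

#' @export
print.hap_lmm <- function(x, ...) {
  cat("Cohort haplotype mixed-model fit:", x$cohort,
      sprintf("(n = %d, K = %d haplotypes)\n", x$n, length(x$beta)))
  cat(sprintf("Variance components (ML): sigma_a^2 = %.4g, sigma_e^2 = %.4g%s\n",
              x$sigma_a2, x$sigma_e2,
              if (!x$vc_identifiable) " [Phi = I: only the sum is identified]"
              else if (x$boundary) " [boundary]" else ""))
  tab <- data.frame(frequency = round(x$frequencies, 4),
                    estimate = x$beta,
                    se = sqrt(diag(x$beta_vcov)))
  rownames(tab) <- x$labels
  print(tab, digits = 4)
  invisible(x)
}

#' @export
summary.hap_lmm <- function(object, ...) {
  se <- sqrt(diag(object$beta_vcov))
  z <- object$beta / se
  out <- data.frame(label = object$labels,
                    frequency = object$frequencies,
                    estimate = object$beta, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(cohort = object$cohort, n = object$n, table = out,
                 sigma_a2 = object$sigma_a2, sigma_e2 = object$sigma_e2,
                 loglik = object$loglik),
            class = "summary.hap_lmm")
}

#' @export
print.summary.hap_lmm <- function(x, ...) {
  cat("Cohort:", x$cohort, " n =", x$n, "\n")
  cat(sprintf("sigma_a^2 = %.4g  sigma_e^2 = %.4g  logLik = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$loglik))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hap_lmm <- function(object, ...) c(object$alpha, object$beta)

#' @export
vcov.hap_lmm <- function(object, ...) object$beta_vcov

#' @export
fitted.hap_lmm <- function(object, ...) object$fitted

#' @export
residuals.hap_lmm <- function(object, ...) object$residuals

#' @export
logLik.hap_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$alpha) + length(object$beta) + 2,
            class = "logLik")
}

#' Extract the stage-1 -> stage-2 exchange object from a cohort fit
#'
#' @param fit A `hap_lmm` object.
#' @return A list of class `cohort_summary`: cohort id, n, haplotype labels,
#'   frequencies, effect vector, covariance matrix, covariate estimates,
#'   variance components and variant metadata. This object (or its JSON
#'   serialization) is all a cohort shares with the meta-analysis.
#' @export
cohort_summary <- function(fit) {
  stopifnot(inherits(fit, "hap_lmm"))
  structure(list(cohort = fit$cohort, n = fit$n, labels = fit$labels,
                 frequencies = fit$frequencies, beta = fit$beta,
                 beta_vcov = fit$beta_vcov, alpha = fit$alpha,
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                 variants = fit$variants),
            class = "cohort_summary")
}

#' Write a cohort summary to JSON
#'
#' Serializes the haplotype labels, frequencies, effect vector, covariance
#' matrix (row-major), covariate effects, variance components and variant
#' metadata of one cohort. The JSON file is the only artifact a cohort needs
#' to contribute to the meta-analysis.
#'
#' @param x A `hap_lmm` fit or `cohort_summary`.
#' @param file Output path.
#' @export
write_cohort_summary <- function(x, file) {
  if (inherits(x, "hap_lmm")) x <- cohort_summary(x)
  stopifnot(inherits(x, "cohort_summary"))
  obj <- list(cohort = x$cohort, n = x$n, labels = x$labels,
              frequencies = x$frequencies, beta = unname(x$beta),
              vcov = as.vector(t(x$beta_vcov)),
              alpha = as.list(x$alpha),
              sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2,
              variants = x$variants)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' Read a cohort summary from JSON
#' @param file Path written by [write_cohort_summary()].
#' @return A `cohort_summary` object.
#' @export
read_cohort_summary <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  K <- length(obj$labels)
  V <- matrix(obj$vcov, K, K, byrow = TRUE,
              dimnames = list(obj$labels, obj$labels))
  structure(list(cohort = obj$cohort, n = obj$n, labels = obj$labels,
                 frequencies = obj$frequencies,
                 beta = stats::setNames(obj$beta, obj$labels),
                 beta_vcov = V, alpha = unlist(obj$alpha),
                 sigma_a2 = obj$sigma_a2, sigma_e2 = obj$sigma_e2,
                 variants = obj$variants),
            class = "cohort_summary")
}
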