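# Kinship-structured linear mixed model machinery.
#
# The model is Y = Xo b + u + e with u ~ N(0, sigma_a^2 Phi) and
# e ~ N(0, sigma_e^2 I). Writing lambda = sigma_a^2 / sigma_e^2 and
# Phi = U D U' blockwise (Phi is block-diagonal over families), the
# rotated model U'Y has independent errors with variances
# sigma_e^2 (lambda d_i + 1), so each likelihood evaluation after one
# eigendecomposition per distinct family block is O(n). ML (not REML)
# estimates are used throughout.

# Cache of eigendecompositions of small family blocks, keyed by the
# rounded block contents.
.block_cache <- new.env(parent = emptyenv())

block_eigen <- function(B) {
  key <- paste(nrow(B), paste(signif(B, 12), collapse = ","), sep = "|")
  hit <- .block_cache[[key]]
  if (!is.null(hit)) return(hit)
  e <- eigen(B, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("family kinship block is not positive semi-definite")
  res <- list(U = e$vectors, d = pmax(e$values, 0))
  assign(key, res, envir = .block_cache)
  res
}

# A `kin_struct` captures the block structure of Phi for fast fitting:
# groups of families sharing the same block matrix, each with the row
# indices (family-major) it occupies. Identity blocks are left untransformed.
#
# kin may be: a dense symmetric matrix (block structure is discovered from
# its sparsity pattern), a `kin_struct`, or NULL (identity).
kin_structure <- function(kin, n, ids = NULL) {
  if (is.null(kin)) {
    return(structure(list(n = n, identity = TRUE, groups = list()),
                     class = "kin_struct"))
  }
  if (inherits(kin, "kin_struct")) {
    stopifnot(kin$n == n)
    return(kin)
  }
  stopifnot(is.matrix(kin), nrow(kin) == n, ncol(kin) == n)
  if (!is.null(ids) && !is.null(rownames(kin))) {
    if (!all(ids %in% rownames(kin)))
      stop("kinship matrix is missing ids: ",
           paste(utils::head(setdiff(ids, rownames(kin))), collapse = ", "))
    kin <- kin[ids, ids]
  }
  # connected components of the nonzero pattern
  nz <- abs(kin) > 1e-12
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(nz[v, ] & comp == 0L)
      queue <- c(queue, nb)
    }
  }
  fam_idx <- split(seq_len(n), comp)
  make_kin_struct(lapply(fam_idx, function(ix) kin[ix, ix, drop = FALSE]),
                  fam_idx, n)
}

# blocks: list of family Phi blocks; fam_idx: matching row-index vectors
make_kin_struct <- function(blocks, fam_idx, n) {
  sizes <- lengths(fam_idx)
  is_ident <- vapply(blocks, function(B)
    nrow(B) == 1L && abs(B[1L, 1L] - 1) < 1e-12 ||
      (all(abs(B - diag(nrow(B))) < 1e-12)), logical(1L))
  if (all(is_ident)) {
    return(structure(list(n = n, identity = TRUE, groups = list()),
                     class = "kin_struct"))
  }
  keys <- vapply(seq_along(blocks), function(i) {
    if (is_ident[i]) "I" else
      paste(sizes[i], paste(signif(blocks[[i]], 12), collapse = ","), sep = "|")
  }, character(1L))
  groups <- list()
  for (k in unique(keys[keys != "I"])) {
    sel <- which(keys == k)
    eg <- block_eigen(blocks[[sel[1L]]])
    groups[[length(groups) + 1L]] <-
      list(idx = unlist(fam_idx[sel], use.names = FALSE),
           m = sizes[sel[1L]], nfam = length(sel), U = eg$U, d = eg$d)
  }
  structure(list(n = n, identity = FALSE, groups = groups),
            class = "kin_struct")
}

# Rotate columns of A (n x p) by the blockwise transpose-eigenvector matrix.
kin_rotate <- function(ks, A) {
  if (ks$identity) return(A)
  A <- as.matrix(A)
  p <- ncol(A)
  for (g in ks$groups) {
    sub <- A[g$idx, , drop = FALSE]
    arr <- array(sub, dim = c(g$m, g$nfam, p))
    rot <- crossprod(g$U, matrix(arr, nrow = g$m))
    A[g$idx, ] <- matrix(array(rot, dim = c(g$m, g$nfam, p)),
                         nrow = g$m * g$nfam)
  }
  A
}

# Eigenvalue vector of Phi aligned with the (rotated) rows.
kin_eigenvalues <- function(ks) {
  d <- rep(1, ks$n)
  for (g in ks$groups) d[g$idx] <- rep(g$d, g$nfam)
  d
}

# Profiled ML fit of y = X b + u + e over lambda = sigma_a^2/sigma_e^2.
# X must be full column rank. Returns coefficients, their covariance
# (the full (X' Omega^-1 X)^-1 at the ML variance components), variance
# components, log-likelihood and diagnostic flags.
lmm_fit <- function(y, X, ks, lower = -12, upper = 12, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  ystar <- kin_rotate(ks, matrix(y, ncol = 1L))
  Xstar <- kin_rotate(ks, X)
  d <- kin_eigenvalues(ks)
  identity_phi <- ks$identity || all(abs(d - 1) < 1e-12)

  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    fit <- .lm.fit(Xstar * sw, ystar * sw)
    rss <- sum(fit$residuals^2)
    ll <- -0.5 * n * (log(2 * pi) + 1) - 0.5 * n * log(rss / n) +
      0.5 * sum(log(w))
    list(ll = ll, rss = rss, w = w)
  }

  if (identity_phi) {
    lam <- 0
    at <- prof(-Inf)
    boundary <- TRUE
  } else {
    opt <- stats::optimize(function(x) prof(x)$ll, c(lower, upper),
                           maximum = TRUE, tol = tol)
    at0 <- prof(-Inf)          # sigma_a^2 = 0 boundary
    if (at0$ll >= opt$objective) {
      lam <- 0; at <- at0; boundary <- TRUE
    } else {
      lam <- exp(opt$maximum); at <- prof(opt$maximum)
      boundary <- opt$maximum <= lower + 1e-6
      if (boundary) { lam <- 0; at <- at0 }
    }
  }

  sigma_e2 <- at$rss / n
  sigma_a2 <- lam * sigma_e2
  sw <- sqrt(at$w)
  qrW <- qr(Xstar * sw)
  R <- qr.R(qrW)
  XtWX_inv <- chol2inv(R)
  beta <- qr.coef(qrW, ystar * sw)
  vcov <- sigma_e2 * XtWX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  fitted <- as.vector(X %*% beta)
  list(coefficients = beta, vcov = vcov,
       sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
       loglik = at$ll, fitted = fitted, residuals = y - fitted,
       boundary = boundary, vc_identifiable = !identity_phi, n = n)
}

#' Maximum-likelihood variance components of the kinship mixed model
#'
#' Profiles the Gaussian log-likelihood of `y = X b + u + e`,
#' `u ~ N(0, sigma_a^2 Phi)`, `e ~ N(0, sigma_e^2 I)` over the fixed effects
#' and the heritability ratio, using one eigendecomposition per distinct
#' family block of `Phi`. The boundary `sigma_a^2 = 0` is permitted and
#' flagged; with `Phi = I` only the total variance is identifiable.
#'
#' @param y Numeric response vector.
#' @param X Full-rank fixed-effect design matrix (including any intercept or
#'   dosage columns).
#' @param kinship Relationship matrix (see [kinship_matrix()]), or `NULL`
#'   for unrelated subjects.
#' @return List with `sigma_a2`, `sigma_e2`, `loglik`, `boundary`,
#'   `vc_identifiable`.
#' @export
fit_variance_components <- function(y, X, kinship = NULL) {
  ks <- kin_structure(kinship, length(y))
  fit <- lmm_fit(y, as.matrix(X), ks)
  fit[c("sigma_a2", "sigma_e2", "loglik", "boundary", "vc_identifiable")]
}
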