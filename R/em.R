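# Haplotypes at q biallelic sites are coded as integers in [0, 2^q), bit j
# set when the minor allele is carried at site j. Labels are allele strings
# (minor/major letters when known, otherwise "1"/"0").

hap_label <- function(code, q, alleles = NULL) {
  bits <- vapply(seq_len(q) - 1L, function(j) bitwAnd(bitwShiftR(code, j), 1L),
                 integer(length(code)))
  if (length(code) == 1L) bits <- matrix(bits, nrow = 1L)
  if (is.null(alleles)) {
    apply(bits, 1L, function(b) paste(b, collapse = ""))
  } else {
    apply(bits, 1L, function(b)
      paste(ifelse(b == 1L, alleles$minor, alleles$major), collapse = ""))
  }
}

hap_code <- function(label, alleles) {
  chars <- strsplit(label, "")
  q <- nrow(alleles)
  vapply(chars, function(ch) {
    if (length(ch) != q) stop("haplotype label of wrong length: ",
                              paste(ch, collapse = ""))
    bad <- ch != alleles$minor & ch != alleles$major
    if (any(bad))
      stop("allele '", ch[which(bad)[1L]], "' at site ", which(bad)[1L],
           " matches neither declared allele")
    sum(as.integer(ch == alleles$minor) * 2L^(seq_len(q) - 1L))
  }, numeric(1L))
}

#' Enumerate phase configurations consistent with one genotype row
#'
#' For a vector of minor-allele counts at `q` sites, returns every unordered
#' pair of haplotypes whose allele counts reproduce the genotypes. With `H`
#' heterozygous sites there are `max(1, 2^(H-1))` such diplotypes.
#'
#' @param g Integer vector of 0/1/2 minor-allele counts (no missing values).
#' @return A two-column integer matrix of haplotype codes (bit j = minor
#'   allele at site j), one row per diplotype, first code <= second code.
#' @export
enumerate_diplotypes <- function(g) {
  if (anyNA(g)) stop("missing genotypes are not allowed here")
  if (!all(g %in% 0:2)) stop("genotypes must be 0, 1 or 2")
  q <- length(g)
  base <- sum((g == 2L) * 2L^(seq_len(q) - 1L))  # homozygous-minor sites
  hets <- which(g == 1L)
  H <- length(hets)
  if (H == 0L) return(matrix(c(base, base), ncol = 2L))
  first <- hets[1L]
  rest <- hets[-1L]
  m <- 2L^(H - 1L)
  a <- integer(m); b <- integer(m)
  for (s in seq_len(m)) {
    pick <- as.integer(intToBits(s - 1L))[seq_len(max(0L, H - 1L))]
    h1 <- base + 2L^(first - 1L) + sum(2L^(rest - 1L) * pick)
    h2 <- base + sum(2L^(rest - 1L) * (1L - pick))
    a[s] <- min(h1, h2); b[s] <- max(h1, h2)
  }
  cbind(a, b)
}

# Internal: pair structure over the distinct genotype rows of G.
# Returns per-pair arrays plus the row -> distinct-genotype map.
diplotype_structure <- function(G) {
  q <- ncol(G)
  key <- as.vector(G %*% 3L^(seq_len(q) - 1L))
  ukey <- sort(unique(key))
  grp_of_row <- match(key, ukey)
  counts <- tabulate(grp_of_row, nbins = length(ukey))
  urows <- G[match(ukey, key), , drop = FALSE]
  pa <- integer(0); pb <- integer(0); pg <- integer(0)
  for (u in seq_along(ukey)) {
    dp <- enumerate_diplotypes(urows[u, ])
    pa <- c(pa, dp[, 1L]); pb <- c(pb, dp[, 2L])
    pg <- c(pg, rep.int(u, nrow(dp)))
  }
  list(pa = pa, pb = pb, grp = pg, counts = counts,
       grp_of_row = grp_of_row, n_grp = length(ukey))
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Maximizes the phase-unknown multinomial likelihood of the genotype sample
#' over haplotype frequencies by expectation-maximization, starting from the
#' deterministic product-of-allele-frequencies initialization. Subjects with
#' any missing genotype in the region are excluded. Intended for a moderate
#' number of variants (q < 15 or so); the support enumerated is the set of
#' haplotypes compatible with at least one subject.
#'
#' @param G Integer matrix of 0/1/2 minor-allele counts, subjects x variants.
#'   An `"alleles"` attribute (data.frame, columns `minor`/`major`) supplies
#'   the letters used in haplotype labels.
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 5000). Non-convergence is
#'   flagged on the result, not an error.
#' @param prune Frequencies below this floor are removed from the returned
#'   table (default 1e-10).
#' @return An object of class `hap_freq`: a data.frame with columns `label`
#'   and `frequency` (decreasing), with attributes `codes`, `alleles`,
#'   `loglik`, `iterations`, `converged`, `n` (subjects used).
#' @export
hap_em <- function(G, tol = 1e-8, max_iter = 5000L, prune = 1e-10) {
  alleles <- attr(G, "alleles")
  keep <- !apply(is.na(G), 1L, any)
  if (!all(keep)) G <- G[keep, , drop = FALSE]
  n <- nrow(G); q <- ncol(G)
  if (n < 1L) stop("no complete genotype rows")
  st <- diplotype_structure(G)
  codes <- sort(unique(c(st$pa, st$pb)))
  K <- length(codes)
  a_idx <- match(st$pa, codes); b_idx <- match(st$pb, codes)
  mult <- ifelse(a_idx == b_idx, 1, 2)
  cnt_g <- st$counts
  ia <- split(seq_along(a_idx), factor(a_idx, levels = seq_len(K)))
  ib <- split(seq_along(b_idx), factor(b_idx, levels = seq_len(K)))

  # deterministic start: product of observed allele frequencies
  p_site <- colMeans(G) / 2
  bits <- vapply(seq_len(q) - 1L,
                 function(j) bitwAnd(bitwShiftR(codes, j), 1L),
                 integer(K))
  if (K == 1L) bits <- matrix(bits, nrow = 1L)
  f <- exp(bits %*% log(pmax(p_site, 1e-12)) +
           (1 - bits) %*% log(pmax(1 - p_site, 1e-12)))
  f <- as.vector(f) / sum(f)

  ll_old <- -Inf; it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    num <- f[a_idx] * f[b_idx] * mult
    den <- rowsum_grp(num, st$grp, st$n_grp)
    ll <- sum(cnt_g * log(den))
    post <- num * cnt_g[st$grp] / den[st$grp]
    cnt <- numeric(K)
    for (k in seq_len(K))
      cnt[k] <- sum(post[ia[[k]]]) + sum(post[ib[[k]]])
    f <- cnt / (2 * n)
    if (is.finite(ll) && ll - ll_old < tol && ll >= ll_old - 1e-12) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")

  keep_h <- f >= prune
  codes <- codes[keep_h]; f <- f[keep_h] / sum(f[keep_h])
  ord <- order(f, decreasing = TRUE)
  out <- data.frame(label = hap_label(codes[ord], q, alleles),
                    frequency = f[ord], stringsAsFactors = FALSE)
  structure(out, class = c("hap_freq", "data.frame"),
            codes = codes[ord], alleles = alleles, q = q,
            loglik = ll, iterations = it, converged = converged, n = n)
}

# rowsum by integer group without reordering surprises
rowsum_grp <- function(x, grp, ngrp) {
  out <- numeric(ngrp)
  s <- rowsum(x, grp)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.hap_freq <- function(x, ...) {
  cat("Haplotype frequencies (EM), ", nrow(x), " haplotypes, n = ",
      attr(x, "n"), " subjects\n", sep = "")
  cat("log-likelihood ", format(attr(x, "loglik")), ", ",
      attr(x, "iterations"), " iterations",
      if (!attr(x, "converged")) " [NOT CONVERGED]", "\n\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Expected haplotype dosages given genotypes and haplotype frequencies
#'
#' For each subject, the expected number of copies of every haplotype in
#' `freqs`, conditional on the unphased genotypes: the posterior-probability
#' weighted copy count over all compatible diplotypes. Every row sums to 2;
#' subjects with at most one heterozygous site get integer rows.
#'
#' @param G Genotype matrix as in [hap_em()]. Rows with missing genotypes
#'   are dropped (with a message).
#' @param freqs A `hap_freq` table.
#' @return An n x K numeric matrix of dosages in `[0, 2]`, columns named by
#'   haplotype label, rows by subject id.
#' @export
hap_dosages <- function(G, freqs) {
  stopifnot(inherits(freqs, "hap_freq"))
  keep <- !apply(is.na(G), 1L, any)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) with missing genotypes dropped")
    G <- G[keep, , drop = FALSE]
  }
  n <- nrow(G)
  codes <- attr(freqs, "codes")
  K <- length(codes)
  f <- freqs$frequency
  st <- diplotype_structure(G)
  a_idx <- match(st$pa, codes); b_idx <- match(st$pb, codes)
  supported <- !is.na(a_idx) & !is.na(b_idx)
  w <- numeric(length(a_idx))
  w[supported] <- f[a_idx[supported]] * f[b_idx[supported]] *
    ifelse(a_idx[supported] == b_idx[supported], 1, 2)
  den <- rowsum_grp(w, st$grp, st$n_grp)
  if (any(den <= 0)) {
    bad_grp <- which(den <= 0)[1L]
    bad_row <- which(st$grp_of_row == bad_grp)[1L]
    id <- rownames(G)[bad_row]
    stop("subject ", if (is.null(id)) bad_row else id,
         " has no diplotype with nonzero frequency support")
  }
  post <- w / den[st$grp]
  # per distinct genotype, expected copies of each haplotype
  D_grp <- matrix(0, st$n_grp, K)
  sel <- which(supported)
  for (s in sel) {
    g <- st$grp[s]
    D_grp[g, a_idx[s]] <- D_grp[g, a_idx[s]] + post[s]
    D_grp[g, b_idx[s]] <- D_grp[g, b_idx[s]] + post[s]
  }
  D <- D_grp[st$grp_of_row, , drop = FALSE]
  dimnames(D) <- list(rownames(G), freqs$label)
  D
}

#' Collapse rare haplotypes into a pooled column
#'
#' Haplotypes with estimated frequency below `threshold` are merged into a
#' single reserved column (label `"RARE"`): dosages and frequencies are
#' summed. Collapsing stabilizes the cohort regression by removing columns
#' with near-zero frequency. The sentinel label is fixed so that pooled
#' categories align by label across cohorts in the meta-analysis stage.
#'
#' @param dosages Dosage matrix from [hap_dosages()].
#' @param freqs Matching `hap_freq` table.
#' @param threshold Frequency threshold in `[0, 1)`; default 0.001.
#' @return A list with elements `dosages` and `freqs` (the `hap_freq` table
#'   gains a `"RARE"` row when anything was collapsed). If no haplotype falls
#'   below the threshold the inputs are returned unchanged.
#' @export
collapse_rare <- function(dosages, freqs, threshold = 0.001) {
  stopifnot(threshold >= 0, threshold < 1)
  rare <- freqs$frequency < threshold
  if (!any(rare)) return(list(dosages = dosages, freqs = freqs))
  if (all(rare))
    stop("all haplotypes fall below the collapse threshold")
  keep <- !rare
  D <- cbind(dosages[, keep, drop = FALSE],
             RARE = rowSums(dosages[, rare, drop = FALSE]))
  tab <- data.frame(label = c(freqs$label[keep], "RARE"),
                    frequency = c(freqs$frequency[keep],
                                  sum(freqs$frequency[rare])),
                    stringsAsFactors = FALSE)
  at <- attributes(freqs)
  structure_tab <- structure(tab, class = c("hap_freq", "data.frame"),
                             codes = c(at$codes[keep], NA_integer_),
                             alleles = at$alleles, q = at$q,
                             loglik = at$loglik, iterations = at$iterations,
                             converged = at$converged, n = at$n)
  list(dosages = D, freqs = structure_tab)
}

#' Drop haplotypes below a frequency floor and renormalize
#'
#' Removes haplotypes with estimated frequency below `min_freq` from a
#' `hap_freq` table. Useful before [hap_dosages()] to discard haplotypes
#' whose expected chromosome count in the sample is negligible (e.g.
#' `min_freq = 0.25/n` keeps everything with at least half an expected
#' copy; a haplotype that is any subject's only compatible phase always
#' has at least one expected copy, so no subject loses support).
#'
#' @param freqs A `hap_freq` table.
#' @param min_freq Frequency floor.
#' @return The filtered, renormalized `hap_freq` table.
#' @export
prune_hap_freq <- function(freqs, min_freq) {
  keep <- freqs$frequency >= min_freq
  if (all(keep)) return(freqs)
  if (!any(keep)) stop("frequency floor removes every haplotype")
  at <- attributes(freqs)
  out <- data.frame(label = freqs$label[keep],
                    frequency = freqs$frequency[keep] /
                      sum(freqs$frequency[keep]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("hap_freq", "data.frame"),
            codes = at$codes[keep], alleles = at$alleles, q = at$q,
            loglik = at$loglik, iterations = at$iterations,
            converged = at$converged, n = at$n)
}

#' Write / read a haplotype frequency table as TSV
#' @param freqs A `hap_freq` table.
#' @param file Path.
#' @export
write_hap_freq <- function(freqs, file) {
  utils::write.table(freqs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
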