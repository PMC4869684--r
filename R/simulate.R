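# Gene-dropping simulator for nuclear-family and unrelated cohorts.
#
# Cohort units: NF2 = two founders + 2 offspring, NFv = two founders +
# Uniform{1..4} offspring, U = singleton founder. Individuals are laid out
# family-major: father, mother, offspring... within each family.

# Relationship matrix block of a nuclear family with c offspring.
nuclear_phi <- function(c) {
  m <- 2L + c
  B <- diag(m)
  if (c > 0L) {
    kids <- 3:m
    B[1L, kids] <- B[kids, 1L] <- 0.5
    B[2L, kids] <- B[kids, 2L] <- 0.5
    B[kids, kids] <- 0.5 + 0.5 * diag(c)
  }
  B
}

# Offspring counts per family for a unit type (0 = singleton).
unit_counts <- function(n_units, unit) {
  switch(unit,
         NF2 = rep(2L, n_units),
         NFv = sample(1:4, n_units, replace = TRUE),
         U   = rep(0L, n_units),
         stop("unknown cohort unit: ", unit))
}

# kin_struct for a cohort laid out family-major with the given offspring
# counts (0 = singleton founder).
counts_kin_struct <- function(counts) {
  fam_sizes <- ifelse(counts == 0L, 1L, 2L + counts)
  n <- sum(fam_sizes)
  ends <- cumsum(fam_sizes)
  starts <- ends - fam_sizes + 1L
  groups <- list()
  for (c in sort(unique(counts[counts > 0L]))) {
    sel <- which(counts == c)
    idx <- unlist(lapply(sel, function(i) starts[i]:ends[i]),
                  use.names = FALSE)
    eg <- block_eigen(nuclear_phi(c))
    groups[[length(groups) + 1L]] <-
      list(idx = idx, m = 2L + c, nfam = length(sel), U = eg$U, d = eg$d)
  }
  structure(list(n = n, identity = length(groups) == 0L, groups = groups),
            class = "kin_struct")
}

#' Generate pedigrees for a cohort of simulation units
#'
#' @param n_units Number of families (or singletons).
#' @param unit `"NF2"`, `"NFv"` or `"U"`.
#' @param seed Optional seed.
#' @param fam_prefix Prefix for family ids.
#' @return A `pedigree_df` (valid by construction) with an `"counts"`
#'   attribute giving the per-family offspring count (0 for singletons).
#'   Offspring sex is Bernoulli(1/2); founders form one father-mother pair.
#' @export
simulate_pedigrees <- function(n_units, unit = c("NF2", "NFv", "U"),
                               seed = NULL, fam_prefix = "F") {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  counts <- unit_counts(n_units, unit)
  ped <- counts_pedigree(counts, fam_prefix)
  ped
}

counts_pedigree <- function(counts, fam_prefix = "F") {
  singles <- counts == 0L
  fam_sizes <- ifelse(singles, 1L, 2L + counts)
  n <- sum(fam_sizes)
  famn <- rep(seq_along(counts), fam_sizes)
  fam <- paste0(fam_prefix, famn)
  within <- sequence(fam_sizes)
  id <- paste0(fam, "_", within)
  role <- ifelse(rep(singles, fam_sizes), 3L,        # 3 = singleton
                 ifelse(within == 1L, 1L, ifelse(within == 2L, 2L, 0L)))
  father <- ifelse(role == 0L, paste0(fam, "_1"), NA_character_)
  mother <- ifelse(role == 0L, paste0(fam, "_2"), NA_character_)
  sex <- integer(n)
  sex[role == 1L] <- 1L
  sex[role == 2L] <- 2L
  off <- role == 0L
  sex[off] <- sample(1:2, sum(off), replace = TRUE)
  sex[role == 3L] <- sample(1:2, sum(role == 3L), replace = TRUE)
  ped <- data.frame(fam = fam, id = id, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_df", "data.frame")
  attr(ped, "counts") <- counts
  attr(ped, "role") <- role
  ped
}

# Offspring counts from a generic nuclear/singleton pedigree.
ped_counts <- function(ped) {
  counts <- attr(ped, "counts")
  if (!is.null(counts)) return(counts)
  fams <- unique(ped$fam)
  counts <- integer(length(fams))
  for (i in seq_along(fams)) {
    sub <- ped[ped$fam == fams[i], ]
    founders <- is.na(sub$father)
    if (nrow(sub) == 1L && founders) { counts[i] <- 0L; next }
    if (sum(founders) != 2L || any(!founders & (sub$father != sub$id[founders][1] |
                                                sub$mother != sub$id[founders][2])))
      stop("pedigree is not in nuclear-family layout (father, mother, offspring...)")
    counts[i] <- nrow(sub) - 2L
  }
  counts
}

#' Assign ages satisfying the family age rules
#'
#' Unrelated subjects and first offspring: Uniform(30, 50). Additional
#' offspring: uniform within 5 years of the first offspring, with at least
#' a 1-year gap to every sibling (no twins). The mother is 20-45 years
#' older than each of her offspring; the father is within 5 years of the
#' mother and at least 20 years older than the oldest offspring. All
#' constraints hold by construction for every family.
#'
#' @param ped A nuclear/singleton `pedigree_df` (see
#'   [simulate_pedigrees()]).
#' @param seed Optional seed.
#' @return Numeric age vector aligned with `ped` rows.
#' @export
assign_ages <- function(ped, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- ped_counts(ped)
  ages_from_counts(counts)
}

ages_from_counts <- function(counts) {
  singles <- counts == 0L
  fam_sizes <- ifelse(singles, 1L, 2L + counts)
  n <- sum(fam_sizes)
  age <- numeric(n)
  ends <- cumsum(fam_sizes); starts <- ends - fam_sizes + 1L
  age[starts[singles]] <- stats::runif(sum(singles), 30, 50)
  for (c in sort(unique(counts[counts > 0L]))) {
    sel <- which(counts == c)
    nf <- length(sel)
    kid <- matrix(0, nf, c)
    kid[, 1L] <- stats::runif(nf, 30, 50)
    if (c > 1L) for (k in 2:c) {
      todo <- seq_len(nf)
      while (length(todo)) {
        cand <- stats::runif(length(todo), kid[todo, 1L] - 5, kid[todo, 1L] + 5)
        gap <- abs(cand - kid[todo, 1:(k - 1L), drop = FALSE])
        ok <- apply(gap >= 1, 1L, all)
        kid[todo[ok], k] <- cand[ok]
        todo <- todo[!ok]
      }
    }
    oldest <- apply(kid, 1L, max)
    youngest <- apply(kid, 1L, min)
    mother <- stats::runif(nf, oldest + 20, youngest + 45)
    father <- stats::runif(nf, pmax(mother - 5, oldest + 20), mother + 5)
    for (j in seq_len(nf)) {
      i0 <- starts[sel[j]]
      age[i0] <- father[j]
      age[i0 + 1L] <- mother[j]
      age[i0 + 1L + seq_len(c)] <- kid[j, ]
    }
  }
  age
}

#' Gene-drop haplotypes through a pedigree
#'
#' Founders receive two haplotypes drawn independently from the panel
#' frequencies; each offspring receives one uniformly chosen haplotype from
#' each parent (no recombination). Genotypes are the per-site minor-allele
#' counts of the two haplotypes.
#'
#' @param panel A [reference_panel()].
#' @param ped A nuclear/singleton `pedigree_df`.
#' @param seed Optional seed.
#' @return List: `hap1`, `hap2` (integer indices into
#'   `panel$haplotypes$label`), `genotypes` (n x q integer matrix with an
#'   `"alleles"` attribute and subject-id rownames).
#' @export
drop_genes <- function(panel, ped, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- ped_counts(ped)
  out <- drop_from_counts(panel, counts)
  rownames(out$genotypes) <- ped$id
  out
}

drop_from_counts <- function(panel, counts) {
  freq <- panel$haplotypes$frequency
  K <- length(freq)
  singles <- counts == 0L
  fam_sizes <- ifelse(singles, 1L, 2L + counts)
  n <- sum(fam_sizes)
  ends <- cumsum(fam_sizes); starts <- ends - fam_sizes + 1L
  hap1 <- integer(n); hap2 <- integer(n)
  founder_rows <- c(starts[singles],
                    starts[!singles], starts[!singles] + 1L)
  nf <- length(founder_rows)
  hap1[founder_rows] <- sample.int(K, nf, replace = TRUE, prob = freq)
  hap2[founder_rows] <- sample.int(K, nf, replace = TRUE, prob = freq)
  off_rows <- unlist(lapply(which(!singles), function(i)
    (starts[i] + 2L):ends[i]), use.names = FALSE)
  if (length(off_rows)) {
    fam_of_off <- rep(which(!singles), counts[!singles])
    fa <- starts[fam_of_off]; mo <- starts[fam_of_off] + 1L
    pick_f <- stats::runif(length(off_rows)) < 0.5
    pick_m <- stats::runif(length(off_rows)) < 0.5
    hap1[off_rows] <- ifelse(pick_f, hap1[fa], hap2[fa])
    hap2[off_rows] <- ifelse(pick_m, hap1[mo], hap2[mo])
  }
  G <- panel$bits[hap1, , drop = FALSE] + panel$bits[hap2, , drop = FALSE]
  storage.mode(G) <- "integer"
  rownames(G) <- NULL
  attr(G, "alleles") <- data.frame(minor = panel$variants$minor,
                                   major = panel$variants$major,
                                   row.names = panel$variants$name,
                                   stringsAsFactors = FALSE)
  list(hap1 = hap1, hap2 = hap2, genotypes = G)
}

#' Effect scenarios and effect-size calibration
#'
#' Defines the genetic architecture of a power-study scenario and derives
#' the effect sizes from the panel. Variant effects are
#' `b_g = sqrt(R2 / (4 MAF (1 - MAF)))` and haplotype effects
#' `b_h = sqrt(R2 / (2 hbar (1 - hbar/2)))` with `hbar` the mean dosage
#' (twice the panel frequency), so each causal term explains a fraction
#' `R2` of the unit residual variance. In single-causal scenarios the
#' remaining effect is doubled. Causal choices: *G6PC2* haplotypes CCAC and
#' TCAG, variants rs560887 and rs2232323; *JAZF1* haplotypes GTATA and
#' GCGCG, variants rs849134 and rs38523.
#'
#' @param panel A [reference_panel()].
#' @param kind One of `"null"`, `"1SNV"`, `"2SNV"`, `"1HAP"`, `"2HAP"`.
#' @param r2 Proportion of variance explained per causal term (default
#'   0.01).
#' @param denom_factor Variance denominators `(4, 2)` as above (default),
#'   or an alternative pair such as `c(2, 1)`.
#' @return List of class `effect_scenario`: `kind`, `causal` (labels or
#'   rsids), `type` (`"hap"` or `"snv"`), `effects` (named numeric), `r2`.
#' @export
effect_scenario <- function(panel, kind = c("null", "1SNV", "2SNV", "1HAP", "2HAP"),
                            r2 = 0.01, denom_factor = c(4, 2)) {
  kind <- match.arg(kind)
  picks <- switch(panel$gene,
    G6PC2 = list(hap = c("CCAC", "TCAG"), snv = c("rs560887", "rs2232323")),
    JAZF1 = list(hap = c("GTATA", "GCGCG"), snv = c("rs849134", "rs38523")))
  out <- list(kind = kind, r2 = r2, type = NULL, causal = character(0),
              effects = numeric(0))
  if (kind != "null") {
    stopifnot(r2 > 0, r2 < 1)
    type <- if (grepl("HAP", kind)) "hap" else "snv"
    k <- if (grepl("^1", kind)) 1L else 2L
    causal <- picks[[type]][seq_len(k)]
    if (type == "hap") {
      f <- panel$haplotypes$frequency[match(causal, panel$haplotypes$label)]
      if (anyNA(f)) stop("causal haplotype not in panel")
      hbar <- 2 * f
      b <- sqrt(r2 / (denom_factor[2L] * hbar * (1 - hbar / 2)))
    } else {
      maf <- panel$maf[match(causal, panel$variants$rsid)]
      if (anyNA(maf) || any(maf <= 0) || any(maf >= 1))
        stop("causal variant missing or with degenerate allele frequency")
      b <- sqrt(r2 / (denom_factor[1L] * maf * (1 - maf)))
    }
    if (k == 1L) b <- 2 * b
    out$type <- type
    out$causal <- causal
    out$effects <- stats::setNames(b, causal)
  }
  structure(out, class = "effect_scenario")
}

#' @rdname effect_scenario
#' @param scenario An `effect_scenario`.
#' @export
calibrate_effects <- function(scenario) scenario$effects

# Trait draw: mean mu, covariance 0.5 Phi + 0.5 I blockwise.
trait_from_counts <- function(counts, mu, sigma_a2 = 0.5, sigma_e2 = 0.5) {
  singles <- counts == 0L
  fam_sizes <- ifelse(singles, 1L, 2L + counts)
  n <- sum(fam_sizes)
  y <- numeric(n)
  ends <- cumsum(fam_sizes); starts <- ends - fam_sizes + 1L
  srow <- starts[singles]
  y[srow] <- stats::rnorm(length(srow), sd = sqrt(sigma_a2 + sigma_e2))
  for (c in sort(unique(counts[counts > 0L]))) {
    sel <- which(counts == c)
    m <- 2L + c
    L <- t(chol(sigma_a2 * nuclear_phi(c) + sigma_e2 * diag(m)))
    Z <- matrix(stats::rnorm(m * length(sel)), m)
    noise <- L %*% Z
    idx <- unlist(lapply(sel, function(i) starts[i]:ends[i]),
                  use.names = FALSE)
    y[idx] <- as.vector(noise)
  }
  mu + y
}

#' Simulate the trait given pedigree structure and genetics
#'
#' One multivariate-normal draw with mean
#' `0.02 * age + 0.5 * sex + genetic terms` and covariance
#' `sigma_a^2 Phi + sigma_e^2 I` (default 0.5 each), sampled independently
#' family block by family block. Sex is coded 1 = male, 2 = female. Causal
#' haplotype terms use the true gene-dropped haplotype counts; causal
#' variant terms use minor-allele counts.
#'
#' @param ped Nuclear/singleton `pedigree_df`.
#' @param age,sex Vectors aligned with `ped`.
#' @param drop Result of [drop_genes()] for this pedigree.
#' @param scenario An [effect_scenario()] (default null).
#' @param panel The panel used in `drop` (needed to resolve causal labels).
#' @param sigma_a2,sigma_e2 Variance components (defaults 0.5, 0.5).
#' @param seed Optional seed.
#' @return Numeric trait vector.
#' @export
simulate_phenotype <- function(ped, age, sex, drop = NULL, scenario = NULL,
                               panel = NULL, sigma_a2 = 0.5, sigma_e2 = 0.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- ped_counts(ped)
  mu <- 0.02 * age + 0.5 * sex
  mu <- mu + genetic_mean(drop, scenario, panel)
  trait_from_counts(counts, mu, sigma_a2, sigma_e2)
}

genetic_mean <- function(drop, scenario, panel) {
  if (is.null(scenario) || scenario$kind == "null") return(0)
  if (is.null(drop) || is.null(panel))
    stop("causal scenarios need the gene-drop result and the panel")
  term <- 0
  if (scenario$type == "hap") {
    k <- match(scenario$causal, panel$haplotypes$label)
    for (i in seq_along(k)) {
      h <- (drop$hap1 == k[i]) + (drop$hap2 == k[i])
      term <- term + scenario$effects[i] * h
    }
  } else {
    j <- match(scenario$causal, panel$variants$rsid)
    for (i in seq_along(j)) {
      term <- term + scenario$effects[i] * drop$genotypes[, j[i]]
    }
  }
  term
}

#' Simulate one cohort end to end
#'
#' Pedigree structure, ages, sexes, gene-dropped genotypes and trait for a
#' cohort of `n_units` units of one type, under a null or causal scenario.
#'
#' @param n_units Number of families / singletons.
#' @param unit `"NF2"`, `"NFv"` or `"U"`.
#' @param panel A [reference_panel()].
#' @param scenario Optional [effect_scenario()].
#' @param seed Optional seed.
#' @param dense_kinship If `TRUE` (default) include the dense relationship
#'   matrix in the result; the block representation used internally is
#'   always attached as `$kin`.
#' @return List: `ped`, `phen` (data.frame id/trait/age/sex), `genotypes`,
#'   `hap1`, `hap2`, `kinship` (dense, optional), `kin` (internal block
#'   structure), `counts`.
#' @export
simulate_cohort <- function(n_units, unit = c("NF2", "NFv", "U"), panel,
                            scenario = NULL, seed = NULL,
                            dense_kinship = TRUE) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  counts <- unit_counts(n_units, unit)
  ped <- counts_pedigree(counts)
  age <- ages_from_counts(counts)
  drop <- drop_from_counts(panel, counts)
  rownames(drop$genotypes) <- ped$id
  trait <- simulate_phenotype(ped, age, ped$sex, drop, scenario, panel)
  out <- list(ped = ped,
              phen = data.frame(id = ped$id, trait = trait, age = age,
                                sex = ped$sex, stringsAsFactors = FALSE),
              genotypes = drop$genotypes, hap1 = drop$hap1, hap2 = drop$hap2,
              kin = counts_kin_struct(counts), counts = counts)
  if (dense_kinship) out$kinship <- kinship_matrix(ped)
  out
}
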