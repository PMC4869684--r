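test_that("diplotype enumeration counts follow 2^(H-1)", {
  expect_equal(nrow(enumerate_diplotypes(c(0L, 2L, 0L))), 1L)
  expect_equal(nrow(enumerate_diplotypes(c(1L, 1L))), 2L)
  expect_equal(nrow(enumerate_diplotypes(c(1L, 1L, 1L))), 4L)
  expect_equal(nrow(enumerate_diplotypes(c(1L, 0L, 2L, 1L, 1L))), 4L)
  # homozygous row resolves to the fixed pair
  dp <- enumerate_diplotypes(c(2L, 0L))
  expect_equal(dp, matrix(c(1, 1), ncol = 2), ignore_attr = TRUE)
  # each enumerated pair reproduces the genotypes
  g <- c(1L, 2L, 1L, 0L)
  dp <- enumerate_diplotypes(g)
  for (r in seq_len(nrow(dp))) {
    al <- function(h) as.integer(intToBits(h))[1:4]
    expect_equal(al(dp[r, 1]) + al(dp[r, 2]), g)
  }
})

test_that("EM recovers degenerate and simple mixtures", {
  # all subjects homozygous identical: single haplotype, frequency 1
  G <- toy_genotypes(rep(list(c(0L, 2L, 0L)), 10))
  f <- hap_em(G)
  expect_equal(nrow(f), 1L)
  expect_equal(f$frequency, 1)
  # two complementary homozygote groups: frequencies match counts
  G2 <- toy_genotypes(c(rep(list(c(0L, 0L)), 6), rep(list(c(2L, 2L)), 4)))
  f2 <- hap_em(G2)
  expect_equal(sort(f2$frequency), c(0.4, 0.6), tolerance = 1e-8)
})

test_that("EM matches direct likelihood maximization on small samples", {
  set.seed(21)
  for (q in c(2L, 3L, 4L)) {
    freq <- rexp(2^q %/% 2 + 1); freq <- freq / sum(freq)
    codes <- sample(0:(2^q - 1), length(freq))
    n <- 25L
    bits <- sapply(seq_len(q) - 1L, function(j) bitwAnd(bitwShiftR(codes, j), 1L))
    h1 <- sample(seq_along(codes), n, TRUE, prob = freq)
    h2 <- sample(seq_along(codes), n, TRUE, prob = freq)
    G <- matrix(bits[h1, , drop = FALSE] + bits[h2, , drop = FALSE], n, q)
    storage.mode(G) <- "integer"
    f <- hap_em(G, tol = 1e-12)
    em_ll <- attr(f, "loglik")
    or_ll <- direct_hap_ml(G, attr(f, "codes"))
    expect_lt(abs(em_ll - or_ll), 1e-4)
  }
})

test_that("EM log-likelihood is monotone over iterations", {
  set.seed(5)
  panel <- reference_panel("JAZF1")
  co <- simulate_cohort(100, "U", panel)
  G <- co$genotypes
  # re-run EM manually, checking each step via successive one-iteration calls
  lls <- numeric(30)
  f <- suppressWarnings(hap_em(G, tol = -1, max_iter = 1))
  for (i in 1:30) {
    f_i <- suppressWarnings(hap_em(G, tol = -1, max_iter = i))
    lls[i] <- attr(f_i, "loglik")
  }
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("dosage rows sum to 2, unambiguous rows are integer", {
  set.seed(8)
  panel <- reference_panel("G6PC2")
  co <- simulate_cohort(150, "NF2", panel)
  f <- hap_em(co$genotypes)
  D <- hap_dosages(co$genotypes, f)
  expect_true(all(abs(rowSums(D) - 2) < 1e-8))
  expect_true(all(D >= -1e-12 & D <= 2 + 1e-12))
  hets <- rowSums(co$genotypes == 1L)
  unamb <- which(hets <= 1L)
  expect_true(all(abs(D[unamb, ] - round(D[unamb, ])) < 1e-8))
  # column means / 2 equal EM frequencies at the fixed point
  expect_equal(colMeans(D) / 2,
               setNames(f$frequency, f$label), tolerance = 1e-6)
})

test_that("double-heterozygote dosages match the enumerate-and-normalize oracle", {
  alleles <- data.frame(minor = c("a", "b"), major = c("A", "B"))
  G <- toy_genotypes(list(c(1L, 1L)), alleles)
  # hand-built frequency table over AB, ab, Ab, aB
  fr <- c(0.4, 0.4, 0.1, 0.1)
  codes <- c(0L, 3L, 1L, 2L)  # AB, ab, aB(bit1), Ab(bit2)
  labels <- c("AB", "ab", "aB", "Ab")
  ft <- structure(data.frame(label = labels, frequency = fr),
                  class = c("hap_freq", "data.frame"),
                  codes = codes, alleles = alleles, q = 2L)
  D <- hap_dosages(G, ft)
  # posterior: (AB,ab) prop 2*.4*.4 = .32 ; (aB,Ab) prop 2*.1*.1 = .02
  p1 <- 0.32 / 0.34
  expect_equal(as.vector(D), c(p1, p1, 1 - p1, 1 - p1), tolerance = 1e-12)
  expect_equal(sum(D), 2)
})

test_that("dosage computation rejects unsupported subjects", {
  alleles <- data.frame(minor = c("a", "b"), major = c("A", "B"))
  G <- toy_genotypes(list(c(2L, 2L)), alleles)
  ft <- structure(data.frame(label = "AB", frequency = 1),
                  class = c("hap_freq", "data.frame"),
                  codes = 0L, alleles = alleles, q = 2L)
  expect_error(hap_dosages(G, ft), "no diplotype")
})

test_that("rare-haplotype collapsing pools the sub-threshold panel rows", {
  set.seed(13)
  for (gene in c("G6PC2", "JAZF1")) {
    panel <- reference_panel(gene)
    # dosages taken at the panel truth: simulate unambiguous carriers
    n <- 500
    h1 <- sample(nrow(panel$haplotypes), n, TRUE, panel$haplotypes$frequency)
    h2 <- sample(nrow(panel$haplotypes), n, TRUE, panel$haplotypes$frequency)
    D <- matrix(0, n, nrow(panel$haplotypes),
                dimnames = list(NULL, panel$haplotypes$label))
    for (i in seq_len(n)) {
      D[i, h1[i]] <- D[i, h1[i]] + 1
      D[i, h2[i]] <- D[i, h2[i]] + 1
    }
    ft <- structure(data.frame(label = panel$haplotypes$label,
                               frequency = panel$haplotypes$frequency),
                    class = c("hap_freq", "data.frame"),
                    codes = seq_len(nrow(panel$haplotypes)),
                    alleles = NULL, q = ncol(panel$bits))
    out <- collapse_rare(D, ft, 0.001)
    n_rare <- sum(panel$haplotypes$raw_frequency < 0.001)
    if (gene == "G6PC2") {
      # the four printed "<0.001" rows are transcribed at the threshold and
      # survive; nothing falls strictly below it
      expect_equal(n_rare, 0L)
      expect_identical(out$dosages, D)
    } else {
      # JAZF1: the 0.0005 haplotype collapses; 13 named + pool columns
      expect_equal(ncol(out$dosages), 14L)
      expect_true("RARE" %in% colnames(out$dosages))
      expect_false("GCGTA" %in% colnames(out$dosages))
    }
    expect_true(all(abs(rowSums(out$dosages) - 2) < 1e-8))
    # threshold 0 is the identity
    out0 <- collapse_rare(D, ft, 0)
    expect_identical(out0$dosages, D)
  }
  # degenerate collapse errors
  ft2 <- structure(data.frame(label = c("A", "B"), frequency = c(.5, .5)),
                   class = c("hap_freq", "data.frame"))
  expect_error(collapse_rare(matrix(1, 2, 2), ft2, 0.9), "all haplotypes")
})

test_that("EM recovers the panel frequencies from a gene-dropped sample", {
  set.seed(4)
  panel <- reference_panel("G6PC2")
  co <- simulate_cohort(2000, "U", panel)
  f <- hap_em(co$genotypes)
  truth <- panel$haplotypes$frequency
  names(truth) <- panel$haplotypes$label
  for (lab in c("CCAC", "TCAG", "CCAG", "TCCG")) {
    se <- sqrt(truth[lab] * (1 - truth[lab]) / (2 * 2000))
    est <- f$frequency[match(lab, f$label)]
    expect_lt(abs(est - truth[lab]), 3 * se + 1e-3)
  }
})
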