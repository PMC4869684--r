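test_that("panels transcribe the printed frequencies and renormalize", {
  g <- reference_panel("G6PC2")
  expect_equal(nrow(g$haplotypes), 8L)
  expect_equal(g$haplotypes$raw_frequency[1:4], c(0.46, 0.29, 0.24, 0.006))
  expect_equal(sum(g$haplotypes$frequency), 1)
  j <- reference_panel("JAZF1")
  expect_equal(nrow(j$haplotypes), 14L)
  expect_equal(sum(j$haplotypes$frequency), 1)
  # panel-derived MAFs agree with the printed ones up to printed rounding
  expect_lt(max(abs(unname(j$maf) - j$variants$maf)), 0.01)
  expect_lt(max(abs(unname(g$maf) - g$variants$maf)), 0.01)
})

test_that("study designs have the printed cohort structure", {
  d1 <- study_designs(1)
  expect_equal(nrow(d1), 5L)
  expect_true(all(d1$unit == "NF2" & d1$n_units == 250))
  d3 <- study_designs(3)
  expect_equal(d3$n_units, c(100, 175, 400, 700, 1000))
  expect_equal(d3$unit, c("NF2", "NF2", "U", "U", "U"))
  expect_equal(nrow(study_designs(6)), 10L)
  expect_error(study_designs(99), "unknown")
})

test_that("pedigree generation yields the unit structures", {
  set.seed(1)
  p <- simulate_pedigrees(250, "NF2")
  expect_equal(nrow(p), 1000L)  # 250 x (2 founders + 2 offspring)
  expect_true(all(table(p$fam) == 4L))
  u <- simulate_pedigrees(100, "U")
  expect_equal(nrow(u), 100L)
  expect_true(all(is.na(u$father)))
  # NFv offspring counts are Uniform{1..4}
  v <- simulate_pedigrees(4000, "NFv")
  counts <- attr(v, "counts")
  expect_true(all(counts %in% 1:4))
  expect_lt(abs(mean(counts) - 2.5), 3 * sd(counts) / sqrt(length(counts)))
  # founder sexes fixed, offspring sexes random
  expect_true(all(p$sex[is.na(p$father)] %in% 1:2))
  k1 <- p$sex[grepl("_3$", p$id)]
  expect_gt(mean(k1 == 1), 0.4); expect_lt(mean(k1 == 1), 0.6)
})

test_that("every age rule holds in every generated family", {
  set.seed(2)
  for (unit in c("NF2", "NFv")) {
    ped <- simulate_pedigrees(400, unit)
    age <- assign_ages(ped)
    counts <- attr(ped, "counts")
    at <- 0
    ok <- TRUE
    for (i in seq_along(counts)) {
      m <- 2L + counts[i]
      fa <- age[at + 1L]; mo <- age[at + 2L]
      kids <- age[at + 2L + seq_len(counts[i])]
      ok <- ok && kids[1] >= 30 && kids[1] <= 50
      if (counts[i] > 1L) {
        gaps <- outer(kids, kids, function(a, b) abs(a - b))
        ok <- ok && all(abs(kids[-1] - kids[1]) <= 5) &&
          all(gaps[upper.tri(gaps)] >= 1)
      }
      ok <- ok && mo - max(kids) >= 20 && mo - min(kids) <= 45 &&
        abs(fa - mo) <= 5 && fa - max(kids) >= 20
      at <- at + m
    }
    expect_true(ok)  # every age rule, every family
  }
  # unrelated ages are Uniform(30, 50)
  set.seed(3)
  u <- simulate_pedigrees(20000, "U")
  a <- assign_ages(u)
  expect_true(all(a >= 30 & a <= 50))
  expect_lt(abs(mean(a) - 40), 3 * sd(a) / sqrt(length(a)))
})

test_that("gene dropping is Mendelian and matches panel frequencies", {
  set.seed(4)
  panel <- reference_panel("G6PC2")
  ped <- simulate_pedigrees(2000, "NF2")
  dr <- drop_genes(panel, ped)
  counts <- attr(ped, "counts")
  # every offspring haplotype occurs in the corresponding parent
  at <- 0
  ok <- TRUE
  for (i in seq_along(counts)) {
    fa <- at + 1L; mo <- at + 2L
    for (k in seq_len(counts[i])) {
      r <- at + 2L + k
      ok <- ok && dr$hap1[r] %in% c(dr$hap1[fa], dr$hap2[fa]) &&
        dr$hap2[r] %in% c(dr$hap1[mo], dr$hap2[mo])
    }
    at <- at + 2L + counts[i]
  }
  expect_true(ok)
  # founder chromosome frequencies within 3 binomial SE of the panel
  founders <- which(is.na(ped$father))
  chroms <- c(dr$hap1[founders], dr$hap2[founders])
  ncz <- length(chroms)
  for (h in 1:3) {
    fhat <- mean(chroms == h)
    f0 <- panel$haplotypes$frequency[h]
    expect_lt(abs(fhat - f0), 3 * sqrt(f0 * (1 - f0) / ncz))
  }
  # genotypes are the allele counts of the two haplotypes
  expect_equal(unname(dr$genotypes),
               unname(panel$bits[dr$hap1, ] + panel$bits[dr$hap2, ]),
               ignore_attr = TRUE)
  # single-haplotype panel: everyone homozygous
  mono <- panel
  mono$haplotypes <- mono$haplotypes[1, ]
  mono$haplotypes$frequency <- 1
  mono$bits <- mono$bits[1, , drop = FALSE]
  drm <- drop_genes(mono, simulate_pedigrees(10, "NF2"))
  expect_true(all(drm$genotypes %in% c(0L, 2L)))
})

test_that("effect sizes follow the variance-explained calibration", {
  panel <- reference_panel("JAZF1")
  sc <- effect_scenario(panel, "2HAP", r2 = 0.01)
  f <- panel$haplotypes$frequency[match(c("GTATA", "GCGCG"),
                                        panel$haplotypes$label)]
  hbar <- 2 * f
  expect_equal(unname(sc$effects),
               sqrt(0.01 / (2 * hbar * (1 - hbar / 2))), tolerance = 1e-12)
  # single-causal doubling
  sc1 <- effect_scenario(panel, "1HAP", r2 = 0.01)
  expect_equal(unname(sc1$effects),
               2 * sqrt(0.01 / (2 * hbar[1] * (1 - hbar[1] / 2))))
  # SNV calibration closed form at MAF 0.5 gives b = sqrt(R2)
  panel2 <- panel
  panel2$maf[match("rs849134", panel2$variants$rsid)] <- 0.5
  s2 <- effect_scenario(panel2, "2SNV", r2 = 0.01)
  expect_equal(unname(s2$effects["rs849134"]), 0.1)
  expect_equal(calibrate_effects(sc), sc$effects)
})

test_that("trait moments match the generating model", {
  set.seed(9)
  panel <- reference_panel("G6PC2")
  # unrelated: iid variance 1 around 0.02 age + 0.5 sex
  co <- simulate_cohort(20000, "U", panel)
  resid <- co$phen$trait - 0.02 * co$phen$age - 0.5 * co$phen$sex
  expect_lt(abs(mean(resid)), 0.03)
  expect_lt(abs(var(resid) - 1), 0.03)
  # sib-sib covariance = sigma_a^2 * 0.5 = 0.25
  co2 <- simulate_cohort(8000, "NF2", panel, dense_kinship = FALSE)
  r2 <- co2$phen$trait - 0.02 * co2$phen$age - 0.5 * co2$phen$sex
  sib1 <- r2[seq(3, length(r2), by = 4)]
  sib2 <- r2[seq(4, length(r2), by = 4)]
  expect_lt(abs(cov(sib1, sib2) - 0.25), 0.04)
  # parent-offspring covariance also 0.25, spouse covariance ~ 0
  fa <- r2[seq(1, length(r2), by = 4)]
  mo <- r2[seq(2, length(r2), by = 4)]
  expect_lt(abs(cov(fa, sib1) - 0.25), 0.04)
  expect_lt(abs(cov(fa, mo)), 0.04)
})

test_that("causal scenarios shift the trait mean by the calibrated effects", {
  set.seed(12)
  panel <- reference_panel("JAZF1")
  sc <- effect_scenario(panel, "2HAP")
  co <- simulate_cohort(15000, "U", panel, scenario = sc,
                        dense_kinship = FALSE)
  h1 <- (co$hap1 == match("GTATA", panel$haplotypes$label)) +
    (co$hap2 == match("GTATA", panel$haplotypes$label))
  h2 <- (co$hap1 == match("GCGCG", panel$haplotypes$label)) +
    (co$hap2 == match("GCGCG", panel$haplotypes$label))
  resid <- co$phen$trait - 0.02 * co$phen$age - 0.5 * co$phen$sex
  slopes <- coef(lm(resid ~ h1 + h2))[2:3]
  expect_lt(max(abs(slopes - sc$effects)), 0.04)
})
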