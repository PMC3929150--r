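test_that("transmission probabilities follow Mendelian rules", {
  expect_equal(transmission_probability(0, 0, 0), 1)
  expect_equal(transmission_probability(1, 1, 1), 0.5)
  expect_equal(transmission_probability(0, 1, 1), 0.25)
  expect_equal(transmission_probability(2, 0, 2), 0)
  expect_equal(transmission_probability(1, 2, 0), 1)
  # each parental pair yields a distribution over offspring genotypes
  for (gs in 0:2) {
    for (gd in 0:2) {
      expect_equal(sum(transmission_probability(0:2, gs, gd)), 1)
    }
  }
})

test_that("allele frequencies come from the reference and are clamped", {
  G <- rbind(a = c(0L, 0L), b = c(1L, 0L), c = c(2L, 0L), x = c(2L, 2L))
  colnames(G) <- c("snp1", "snp2")
  f <- estimate_allele_frequency(G, c("a", "b", "c"))
  expect_equal(f[["snp1"]], 0.5)
  expect_gt(f[["snp2"]], 0)            # all-zero reference clamps up
  expect_equal(f[["snp2"]], 1 / 8)     # 1/(2*3+2)
  # invariant to masked test rows
  G2 <- G; G2["x", ] <- NA_integer_
  expect_equal(estimate_allele_frequency(G2, c("a", "b", "c")), f)
  G3 <- G; G3[c("a", "b", "c"), 2] <- NA_integer_
  expect_error(estimate_allele_frequency(G3, c("a", "b", "c")),
               "no observed reference genotype")
})

test_that("Mendelian rules fill exactly the forced genotypes", {
  ped <- trio_ped()
  G <- function(s, d, x) {
    m <- rbind(s = s, d = d, x = x)
    colnames(m) <- paste0("snp", seq_len(ncol(m)))
    storage.mode(m) <- "integer"
    m
  }
  # sire 2 x dam 0 forces offspring 1; sire 2 x dam 1 forces nothing
  filled <- mendelian_rules_fill(ped, G(c(2L, 2L), c(0L, 1L), c(NA, NA)))
  expect_equal(filled["x", ], c(snp1 = 1L, snp2 = NA))

  # homozygous-opposite offspring force a het dam
  ped2 <- as_pedigree(data.frame(id = c("s1", "s2", "d", "k1", "k2"),
                                 sire = c(NA, NA, NA, "s1", "s2"),
                                 dam = c(NA, NA, NA, "d", "d")))
  m <- rbind(s1 = 2L, s2 = 0L, d = NA_integer_, k1 = 2L, k2 = 0L)
  colnames(m) <- "snp1"
  expect_equal(unname(mendelian_rules_fill(ped2, m)["d", ]), 1L)

  # conflicting trio raises a named error
  expect_error(mendelian_rules_fill(ped, G(2L, 2L, 0L)), "Mendelian conflict")
})

test_that("peeling reproduces closed-form trio posteriors", {
  ped <- trio_ped()
  p <- 0.3
  # no genotyped relatives: HWE triplet, dosage 2p
  q <- peel_locus(ped, c(s = NA, d = NA, x = NA), freq = p)
  expect_equal(q["x", ], c(p0 = (1 - p)^2, p1 = 2 * p * (1 - p), p2 = p^2),
               tolerance = 1e-9)
  # sire observed 2, dam unknown: dosage 1 + p (exact trio enumeration)
  q <- peel_locus(ped, c(s = 2, d = NA, x = NA), freq = p)
  expect_equal(unname(q["x", 2] + 2 * q["x", 3]), 1 + p, tolerance = 1e-9)
  # both parents observed: dosage is the parent average
  for (gs in 0:2) {
    for (gd in 0:2) {
      q <- peel_locus(ped, c(s = gs, d = gd, x = NA), freq = p)
      expect_equal(unname(q["x", 2] + 2 * q["x", 3]), (gs + gd) / 2,
                   tolerance = 1e-9)
    }
  }
  expect_error(peel_locus(ped, c(s = NA, d = NA, x = NA), freq = 0))
})

test_that("peeling equals brute-force enumeration on loop-free pedigrees", {
  worst <- 0
  for (s in 1:12) {
    ped <- random_loopfree_pedigree(sample(6:12, 1), seed = 500 + s)
    freq <- stats::runif(1, 0.1, 0.9)
    col <- simulated_column(ped, freq, p_missing = 0.5, seed = 700 + s)
    oracle <- brute_force_peel(ped, col, freq)
    q <- peel_locus(ped, col, freq,
                    peeling_options(max_rounds = 200, tolerance = 1e-12))
    worst <- max(worst, max(abs(oracle - q)))
  }
  expect_lt(worst, 1e-6)
})

test_that("triplets normalize and dosages stay in range", {
  study <- generate_study_pedigree(
    study_design(10, n_mate_sires = 5, n_offspring_per_cow = 2), seed = 61)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 40),
                                      200, seed = 62)
  tg <- gene_drop(study$pedigree, pool, seed = 63)
  obs <- apply_scenario(tg, study$scenario)
  imp <- impute_all(study$pedigree, obs)
  sums <- apply(imp$probabilities, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all(imp$dosage >= 0 & imp$dosage <= 2))
  expect_true(all(imp$probabilities >= 0))
})

test_that("rule-based fills agree with peeling certainties", {
  for (s in 1:6) {
    ped <- random_loopfree_pedigree(10, seed = 800 + s)
    freq <- stats::runif(1, 0.2, 0.8)
    col <- simulated_column(ped, freq, p_missing = 0.5, seed = 900 + s)
    m <- matrix(as.integer(col), ncol = 1, dimnames = list(ped$id, "snp1"))
    filled <- mendelian_rules_fill(ped, m)
    q <- peel_locus(ped, col, freq,
                    peeling_options(max_rounds = 200, tolerance = 1e-12))
    forced <- which(!is.na(filled[, 1]) & is.na(m[, 1]))
    for (i in forced) {
      expect_equal(unname(q[i, filled[i, 1] + 1L]), 1, tolerance = 1e-6)
    }
  }
})

test_that("called genotypes respect the threshold and Mendelian consistency", {
  ped <- trio_ped()
  G <- rbind(s = c(1L, 2L), d = c(1L, 2L), x = c(NA, NA))
  colnames(G) <- c("snp1", "snp2")
  imp <- impute_all(ped, G)
  # het x het: triplet (1/4, 1/2, 1/4) is uncalled at 0.98, dosage 1
  expect_true(is.na(imp$called["x", "snp1"]))
  expect_equal(unname(imp$dosage["x", "snp1"]), 1)
  # hom x hom: certainty, called 2
  expect_equal(unname(imp$called["x", "snp2"]), 2L)
  expect_equal(unname(imp$probabilities["x", "p2", "snp2"]), 1)

  # wherever called, the call is the argmax and meets the threshold
  study <- generate_study_pedigree(
    study_design(8, n_mate_sires = 4, n_offspring_per_cow = 4), seed = 71)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 30),
                                      200, seed = 72)
  tg <- gene_drop(study$pedigree, pool, seed = 73)
  imp2 <- impute_all(study$pedigree, apply_scenario(tg, study$scenario))
  called <- which(!is.na(imp2$called), arr.ind = TRUE)
  for (r in sample(nrow(called), min(50, nrow(called)))) {
    i <- called[r, 1]; j <- called[r, 2]
    trip <- imp2$probabilities[i, , j]
    expect_equal(unname(which.max(trip)) - 1L, unname(imp2$called[i, j]))
    expect_gte(max(trip), imp2$options$call_threshold)
  }
})

test_that("an added genotyped offspring never increases posterior entropy on average", {
  # test cow with sire+MGS genotyped; compare 0 vs 1 genotyped offspring
  entropy <- function(tri) {
    tri <- tri[tri > 0]
    -sum(tri * log(tri))
  }
  des1 <- study_design(30, n_mate_sires = 5, n_offspring_per_cow = 1)
  study <- generate_study_pedigree(des1, seed = 81)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 25),
                                      300, seed = 82)
  tg <- gene_drop(study$pedigree, pool, seed = 83)
  ent <- sapply(c(0, 1), function(k) {
    sp <- off_scenario(study, k)
    imp <- impute_all(study$pedigree, apply_scenario(tg, sp))
    mean(apply(imp$probabilities[study$cows, , , drop = FALSE], c(1, 3),
               entropy))
  })
  expect_lte(ent[2], ent[1])
})
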