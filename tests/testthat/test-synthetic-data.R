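test_that("study pedigree matches the design arithmetic and is reproducible", {
  des <- study_design(50, n_mate_sires = 10, n_offspring_per_cow = 4)
  study <- generate_study_pedigree(des, seed = 1)
  ped <- study$pedigree
  # beyond cows, dams and their genotyped ancestors: offspring + mate sires
  n_extra <- 50 * 4 + 10
  n_core <- des$n_genotyped_sires + des$n_genotyped_mgs + 50 + 50
  expect_equal(nrow(ped), n_core + n_extra)
  expect_setequal(study$cows, paste0("C", 1:50))
  expect_length(study$scenario$genotyped_ids,
                des$n_genotyped_sires + des$n_genotyped_mgs + 200)

  # offspring of one cow are strict maternal half sibs: distinct sires
  for (off in study$offspring[1:5]) {
    sires <- ped$sire[match(off, ped$id)]
    expect_equal(anyDuplicated(sires), 0L)
    expect_equal(unique(ped$dam[match(off, ped$id)]),
                 unique(sub("O(\\d+)_.*", "C\\1", off)))
  }

  expect_identical(generate_study_pedigree(des, seed = 7)$pedigree,
                   generate_study_pedigree(des, seed = 7)$pedigree)
  expect_false(identical(generate_study_pedigree(des, seed = 7)$pedigree,
                         generate_study_pedigree(des, seed = 8)$pedigree))

  # with no offspring every cow is SireMGS
  s0 <- generate_study_pedigree(study_design(20, n_offspring_per_cow = 0,
                                             n_mate_sires = 5), seed = 2)
  cats <- classify_relatives(s0$pedigree, s0$scenario$genotyped_ids, s0$cows)
  expect_true(all(cats == "SireMGS"))

  expect_error(study_design(10, n_mate_sires = 2, n_offspring_per_cow = 4),
               "cannot exceed")
  expect_error(study_design(10, n_offspring_per_cow = 3), "must be 0, 1, 2 or 4")
})

test_that("offspring-subset scenarios only change the reference set", {
  des <- study_design(10, n_mate_sires = 6, n_offspring_per_cow = 4)
  study <- generate_study_pedigree(des, seed = 5)
  s2 <- off_scenario(study, 2)
  expect_equal(s2$name, "Off2")
  expect_setequal(s2$test_ids, study$cows)
  expect_length(setdiff(study$scenario$genotyped_ids, s2$genotyped_ids), 10 * 2)
  s0 <- off_scenario(study, 0)
  expect_length(intersect(s0$genotyped_ids, unlist(study$offspring)), 0L)
  expect_error(off_scenario(study, 5), "exceeds")
})

test_that("sfs founder pools hit their target frequencies", {
  # point frequency 0.5: every SNP has MAF 0.5 in expectation and the pool
  # frequency stays within binomial sampling error of the target
  n_hap <- 400
  pool <- simulate_founder_haplotypes(
    founder_model("sfs", n_snps = 200, sfs_freq = 0.5), n_hap, seed = 3)
  expect_true(all(pool$freq > 0 & pool$freq < 1))
  # 5 sigma binomial bound, Bonferroni-safe for 200 SNPs
  bound <- 5 * sqrt(0.5 * 0.5 / n_hap)
  expect_true(all(abs(pool$freq - 0.5) < bound))

  # general targets: each pool frequency within binomial error of its draw
  pool2 <- simulate_founder_haplotypes(
    founder_model("sfs", n_snps = 500), n_hap, seed = 4)
  p <- pool2$target_freq
  bound2 <- 5 * sqrt(p * (1 - p) / n_hap) + 1 / n_hap
  expect_true(mean(abs(pool2$freq - p) < bound2) > 0.99)

  # map positions sorted within the chromosome
  expect_true(!is.unsorted(pool2$map$pos_cM))
  expect_true(all(pool2$map$pos_cM >= 0 & pool2$map$pos_cM <= 100))
})

test_that("coalescent founder pools contain only segregating sites", {
  fm <- founder_model("coalescent", n_snps = 100, seq_length_bp = 5e5,
                      chunk_length_bp = 1e5)
  pool <- simulate_founder_haplotypes(fm, 200, seed = 9)
  cs <- colSums(pool$haplotypes)
  expect_true(all(cs > 0 & cs < 200))
  expect_equal(pool$freq, cs / 200)
  expect_error(
    simulate_founder_haplotypes(
      founder_model("coalescent", n_snps = 1e5, seq_length_bp = 1e5,
                    chunk_length_bp = 1e5), 50, seed = 1),
    "fewer than n_snps")
})

test_that("gene dropping is Mendelian-consistent with phased bookkeeping", {
  des <- study_design(15, n_mate_sires = 6, n_offspring_per_cow = 2)
  study <- generate_study_pedigree(des, seed = 11)
  ped <- study$pedigree
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 120),
                                      300, seed = 12)
  tg <- gene_drop(ped, pool, seed = 13)
  expect_true(all(tg$genotypes %in% 0:2))
  expect_equal(tg$genotypes, tg$paternal + tg$maternal)

  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  pos <- tg$map$pos_cM
  for (i in which(!is.na(si))) {
    # paternal gamete is a mosaic of exactly the sire's two gametes, with
    # segment boundaries at the recorded crossovers
    xo <- tg$crossovers[[i]]$paternal
    strand <- (xo$start + findInterval(pos, xo$crossovers)) %% 2L
    expected <- ifelse(strand == 0L, tg$paternal[si[i], ], tg$maternal[si[i], ])
    expect_equal(tg$paternal[i, ], expected, ignore_attr = TRUE)
  }

  # both parents fixed for allele 1 at a SNP forces offspring genotype 2
  fixpool <- simulate_founder_haplotypes(
    founder_model("sfs", n_snps = 5, sfs_freq = 0.999), 50, seed = 14)
  fixpool$haplotypes[] <- 1L
  tg2 <- gene_drop(trio_ped(), fixpool, seed = 15)
  expect_true(all(tg2$genotypes["x", ] == 2L))

  # reproducibility is bit-identical
  expect_identical(gene_drop(ped, pool, seed = 21)$genotypes,
                   gene_drop(ped, pool, seed = 21)$genotypes)
})

test_that("crossover counts average one per 100 cM and founder frequencies persist", {
  ped <- as_pedigree(data.frame(id = c("s", "d", paste0("k", 1:300)),
                                sire = c(NA, NA, rep("s", 300)),
                                dam = c(NA, NA, rep("d", 300))))
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 50),
                                      200, seed = 31)
  tg <- gene_drop(ped, pool, seed = 32)
  n_xo <- unlist(lapply(tg$crossovers[-(1:2)], function(x) {
    c(length(x$paternal$crossovers), length(x$maternal$crossovers))
  }))
  # 600 Poisson(1) draws: mean within 4 standard errors of 1
  expect_lt(abs(mean(n_xo) - 1), 4 / sqrt(length(n_xo)))

  # allele frequency among many offspring tracks the parental frequency
  par_freq <- colMeans(tg$genotypes[1:2, , drop = FALSE]) / 2
  kid_freq <- colMeans(tg$genotypes[-(1:2), , drop = FALSE]) / 2
  se <- sqrt(par_freq * (1 - par_freq) / 300) + 0.02
  expect_true(all(abs(kid_freq - par_freq) < 5 * se))
})

test_that("scenario masking hides exactly the non-reference rows", {
  study <- generate_study_pedigree(
    study_design(8, n_mate_sires = 4, n_offspring_per_cow = 1), seed = 41)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 30),
                                      100, seed = 42)
  tg <- gene_drop(study$pedigree, pool, seed = 43)
  obs <- apply_scenario(tg, study$scenario)
  geno_rows <- rownames(obs) %in% study$scenario$genotyped_ids
  expect_equal(sum(rowSums(!is.na(obs)) > 0), sum(geno_rows))
  expect_true(all(is.na(obs[match(study$cows, rownames(obs)), ])))
  expect_equal(obs[geno_rows, ], tg$genotypes[geno_rows, ])

  empty <- scenario_spec("none", character(0), study$cows)
  expect_true(all(is.na(apply_scenario(tg, empty))))
  expect_error(scenario_spec("bad", "C1", "C1"), "disjoint")
})
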