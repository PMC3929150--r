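test_that("mean gene content is the reference mean and doubles the frequency", {
  G <- rbind(a = c(0L, 2L), b = c(1L, 2L), c = c(2L, 2L), x = c(0L, 0L))
  colnames(G) <- c("snp1", "snp2")
  mgc <- mean_gene_content(G, c("a", "b", "c"))
  expect_equal(mgc, c(snp1 = 1, snp2 = 2))
  # identity with the unclamped allele-frequency estimate (mgc = 2p)
  expect_equal(mgc / 2, colMeans(G[1:3, ]) / 2)
})

test_that("animal accuracies handle perfect, uninformative and shifted dosages", {
  set.seed(1)
  mgc <- runif(50, 0, 2)
  true <- rbinom(50, 2, mgc / 2)
  expect_equal(animal_accuracy(true, true, mgc),
               c(corrected = 1, uncorrected = 1))
  # dosage identical to mean gene content: zero variance, undefined
  expect_true(is.na(animal_accuracy(true, mgc, mgc)["corrected"]))
  # constant mean gene content: corrected equals uncorrected exactly
  dos <- true * 0.5 + runif(50)
  const <- rep(1, 50)
  acc <- animal_accuracy(true, dos, const)
  expect_equal(acc[["corrected"]], acc[["uncorrected"]])
  expect_error(animal_accuracy(true, dos[-1], const), "align")
})

test_that("SNP accuracy catches sign flips and monomorphic columns", {
  true <- c(0, 1, 2, 1, 0)
  expect_equal(snp_accuracy(true, true), 1)
  expect_equal(snp_accuracy(true, 2 - true), -1)
  expect_true(is.na(snp_accuracy(rep(1, 5), true)))
})

test_that("call rates partition each animal's and SNP's genotypes", {
  true <- rbind(x = c(0L, 1L, 2L, 1L), y = c(2L, 2L, 0L, 0L))
  colnames(true) <- paste0("snp", 1:4)
  called <- rbind(x = c(0L, 1L, 2L, NA), y = c(NA, NA, NA, NA))
  colnames(called) <- paste0("snp", 1:4)
  cr <- genotype_call_rates(true, called, c("x", "y"))
  expect_equal(unlist(cr$by_animal[1, -1]),
               c(pct_correct = 75, pct_incorrect = 0, pct_not_imputed = 25))
  expect_equal(unlist(cr$by_animal[2, -1]),
               c(pct_correct = 0, pct_incorrect = 0, pct_not_imputed = 100))
  sums <- rowSums(cr$by_animal[, -1]) + rowSums(cr$by_snp[, -1]) * 0
  expect_true(all(abs(rowSums(cr$by_animal[, -1]) - 100) < 1e-6))
  expect_true(all(abs(rowSums(cr$by_snp[, -1]) - 100) < 1e-6))
  # a wrong call counts as incorrect
  called2 <- called; called2["x", 1] <- 2L
  cr2 <- genotype_call_rates(true, called2, "x")
  expect_equal(cr2$by_animal$pct_incorrect, 25)
})

test_that("scoring and summarizing produce a coherent report", {
  des <- study_design(12, n_mate_sires = 5, n_offspring_per_cow = 2)
  study <- generate_study_pedigree(des, seed = 91)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 60),
                                      200, seed = 92)
  tg <- gene_drop(study$pedigree, pool, seed = 93)
  sp <- study$scenario
  imp <- impute_all(study$pedigree, apply_scenario(tg, sp))
  rep1 <- score_imputation(tg, imp, sp, study$pedigree, replicate = 1L)

  expect_equal(nrow(rep1$by_animal), 12L)
  expect_equal(nrow(rep1$by_snp), 60L)
  expect_true(all(abs(rowSums(rep1$by_animal[, c("pct_correct",
                                                 "pct_incorrect",
                                                 "pct_not_imputed")]) - 100)
                  < 1e-6))
  expect_true(all(rep1$by_snp$maf >= 0 & rep1$by_snp$maf <= 0.5))
  ok <- !is.na(rep1$by_animal$r_corrected)
  expect_true(all(abs(rep1$by_animal$r_corrected[ok]) <= 1))

  smry <- summarize_accuracy(rep1)
  # category counts equal the classification partition
  cats <- table(classify_relatives(study$pedigree, sp$genotyped_ids,
                                   study$cows))
  for (cc in names(cats)[cats > 0]) {
    expect_equal(smry$by_category$n[smry$by_category$category == cc],
                 unname(cats[cc]))
  }
  # single animal: overall mean equals that animal's value
  one <- rep1
  one$by_animal <- one$by_animal[1, ]
  s1 <- summarize_accuracy(one)
  expect_equal(s1$overall$r_corrected_mean, rep1$by_animal$r_corrected[1])

  # pooling replicates doubles the n
  s2 <- summarize_accuracy(list(rep1, rep1))
  expect_equal(s2$overall$n, 24L)

  # tidiers
  expect_equal(nrow(tidy(rep1)), 12L)
  expect_equal(glance(rep1)$n_animals, 12L)
  td <- tidy(imp)
  expect_equal(nrow(td), nrow(study$pedigree) * 60L)
  expect_equal(glance(imp)$n_snps, 60L)
  expect_s3_class(autoplot(smry), "ggplot")
  expect_s3_class(autoplot(smry, type = "category"), "ggplot")
})

test_that("corrected accuracy of the parent average approaches sqrt(0.5)", {
  # with both parents genotyped and many unlinked SNPs the parent-average
  # dosage has accuracy sqrt(0.5); the uncorrected correlation exceeds it
  # under a non-degenerate allele-frequency spectrum
  study <- generate_trio_pedigree(60)
  pool <- simulate_founder_haplotypes(founder_model("sfs", n_snps = 3000),
                                      400, seed = 101)
  tg <- gene_drop(study$pedigree, pool, seed = 102)
  sp <- study$scenario
  imp <- impute_all(study$pedigree, apply_scenario(tg, sp))
  rep1 <- score_imputation(tg, imp, sp, study$pedigree)
  expect_equal(mean(rep1$by_animal$r_corrected), sqrt(0.5), tolerance = 0.02)
  expect_gt(mean(rep1$by_animal$r_uncorrected),
            mean(rep1$by_animal$r_corrected))
})
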