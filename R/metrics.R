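#' Mean gene content per SNP
#'
#' The per-SNP mean of the genotype codes (0, 1, 2) over the reference
#' individuals, i.e. twice the reference allele frequency. Subtracting it
#' from both true genotypes and dosages before correlating removes the
#' between-SNP variance driven by allele-frequency differences.
#'
#' @param obs Genotype matrix with id rownames (`NA` allowed).
#' @param reference Ids of the reference individuals.
#' @return Numeric vector in `[0, 2]`, one value per SNP.
#' @export
mean_gene_content <- function(obs, reference) {
  stopifnot(is.matrix(obs), length(reference) >= 1)
  ref <- obs[rownames(obs) %in% reference, , drop = FALSE]
  colMeans(ref, na.rm = TRUE)
}

cor_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Animal-specific imputation accuracy
#'
#' The corrected accuracy is the Pearson correlation, over SNPs, of the
#' true genotypes minus the mean gene content with the imputed dosages
#' minus the mean gene content. The uncorrected accuracy correlates the
#' raw values and is biased upward by between-SNP allele-frequency
#' variance. Either is `NA` (undefined) when one argument has zero
#' variance.
#'
#' @param true_row True genotypes over SNPs for one animal.
#' @param dosage_row Imputed dosages over the same SNPs.
#' @param mgc Per-SNP mean gene content from the scenario's reference set.
#' @return Named vector with elements `corrected` and `uncorrected`.
#' @export
animal_accuracy <- function(true_row, dosage_row, mgc) {
  if (length(true_row) != length(dosage_row) ||
      length(true_row) != length(mgc)) {
    stop("true genotypes, dosages and mean gene content must align",
         call. = FALSE)
  }
  c(corrected = cor_or_na(true_row - mgc, dosage_row - mgc),
    uncorrected = cor_or_na(true_row, dosage_row))
}

#' SNP-specific imputation accuracy
#'
#' Pearson correlation of true genotypes with imputed dosages across test
#' animals at one SNP; `NA` when undefined (e.g. a SNP monomorphic among
#' the tests).
#'
#' @param true_col True genotypes across test animals.
#' @param dosage_col Imputed dosages across the same animals.
#' @return A correlation or `NA`.
#' @export
snp_accuracy <- function(true_col, dosage_col) {
  stopifnot(length(true_col) == length(dosage_col))
  cor_or_na(true_col, dosage_col)
}

pct_rates <- function(true_v, called_v) {
  n <- length(true_v)
  not_imp <- is.na(called_v)
  correct <- !not_imp & called_v == true_v
  c(pct_correct = 100 * sum(correct) / n,
    pct_incorrect = 100 * sum(!not_imp & !correct) / n,
    pct_not_imputed = 100 * sum(not_imp) / n)
}

#' Genotype call rates per animal and per SNP
#'
#' For each test animal (and each SNP), the percentages of genotypes
#' called correctly, called incorrectly, and not imputed; the three sum
#' to 100.
#'
#' @param true True genotype matrix with id rownames.
#' @param called Called genotype matrix (`NA` = not imputed), aligned.
#' @param tests Ids of the test animals.
#' @return A list with tibbles `by_animal` (id + three percentages) and
#'   `by_snp` (snp + three percentages over test animals).
#' @export
genotype_call_rates <- function(true, called, tests) {
  stopifnot(is.matrix(true), is.matrix(called),
            all(dim(true) == dim(called)))
  tt <- true[match(tests, rownames(true)), , drop = FALSE]
  cc <- called[match(tests, rownames(called)), , drop = FALSE]
  by_animal <- tibble::as_tibble(t(vapply(seq_along(tests), function(i) {
    pct_rates(tt[i, ], cc[i, ])
  }, numeric(3))))
  by_animal <- dplyr::bind_cols(tibble::tibble(id = tests), by_animal)
  snps <- colnames(true) %||% paste0("snp", seq_len(ncol(true)))
  by_snp <- tibble::as_tibble(t(vapply(seq_len(ncol(true)), function(j) {
    pct_rates(tt[, j], cc[, j])
  }, numeric(3))))
  by_snp <- dplyr::bind_cols(tibble::tibble(snp = snps), by_snp)
  list(by_animal = by_animal, by_snp = by_snp)
}

#' Score an imputation run against the simulated truth
#'
#' Computes the full accuracy report for one scenario and replicate:
#' per-animal corrected and uncorrected accuracies, call rates and
#' relative category, and per-SNP accuracy, reference MAF and call rates.
#' Mean gene content is computed from the scenario's genotyped reference
#' set, never from the truth of the test animals.
#'
#' @param truth A `true_genotypes` object (or genotype matrix with id
#'   rownames).
#' @param result An [impute_all()] result.
#' @param spec The [scenario_spec()] that produced the observed data.
#' @param ped The pedigree.
#' @param replicate Optional replicate label stored in the tables.
#' @return A list of class `accuracy_report` with tibbles `by_animal` and
#'   `by_snp`, plus `mgc` and `scenario`.
#' @export
score_imputation <- function(truth, result, spec, ped, replicate = 1L) {
  stopifnot(inherits(result, "imputation_result"),
            inherits(spec, "scenario_spec"), inherits(ped, "pedigree"))
  G <- if (inherits(truth, "true_genotypes")) truth$genotypes else truth
  tests <- spec$test_ids
  obs <- apply_scenario(G, spec)
  mgc <- mean_gene_content(obs, spec$genotyped_ids)
  dos <- result$dosage[match(tests, rownames(result$dosage)), , drop = FALSE]
  tru <- G[match(tests, rownames(G)), , drop = FALSE]

  acc <- t(vapply(seq_along(tests), function(i) {
    animal_accuracy(tru[i, ], dos[i, ], mgc)
  }, numeric(2)))
  rates <- genotype_call_rates(G, result$called, tests)
  cat_f <- classify_relatives(ped, spec$genotyped_ids, tests)

  by_animal <- tibble::tibble(
    replicate = replicate,
    scenario = spec$name,
    id = tests,
    category = cat_f,
    r_corrected = acc[, "corrected"],
    r_uncorrected = acc[, "uncorrected"]
  )
  by_animal <- dplyr::left_join(by_animal, rates$by_animal, by = "id")

  p_ref <- mgc / 2
  snps <- colnames(G) %||% paste0("snp", seq_len(ncol(G)))
  r_snp <- vapply(seq_len(ncol(G)), function(j) {
    snp_accuracy(tru[, j], dos[, j])
  }, numeric(1))
  by_snp <- tibble::tibble(
    replicate = replicate,
    scenario = spec$name,
    snp = snps,
    maf = pmin(p_ref, 1 - p_ref),
    r = r_snp
  )
  by_snp <- dplyr::left_join(by_snp, rates$by_snp, by = "snp")

  structure(list(by_animal = by_animal, by_snp = by_snp,
                 mgc = mgc, scenario = spec$name),
            class = "accuracy_report")
}

#' Aggregate accuracy reports by category and MAF bin
#'
#' Pools animal-by-replicate values for means and standard deviations by
#' relative category (plus an overall row), and bins per-SNP accuracy and
#' call rates by reference minor allele frequency. Undefined (`NA`)
#' correlations are excluded from means rather than zero-filled.
#'
#' @param reports One `accuracy_report` or a list of them (e.g. one per
#'   replicate or scenario).
#' @param maf_bins Number of equal-width MAF bins on `[0, 0.5]`
#'   (default 20).
#' @return A list of class `accuracy_summary` with tibbles `by_category`
#'   (per scenario), `overall`, and `by_maf_bin`.
#' @export
summarize_accuracy <- function(reports, maf_bins = 20) {
  if (inherits(reports, "accuracy_report")) reports <- list(reports)
  animals <- dplyr::bind_rows(lapply(reports, `[[`, "by_animal"))
  snps <- dplyr::bind_rows(lapply(reports, `[[`, "by_snp"))

  summarize_block <- function(df) {
    dplyr::summarise(
      df,
      n = dplyr::n(),
      r_corrected_mean = mean(.data$r_corrected, na.rm = TRUE),
      r_corrected_sd = stats::sd(.data$r_corrected, na.rm = TRUE),
      r_uncorrected_mean = mean(.data$r_uncorrected, na.rm = TRUE),
      pct_correct = mean(.data$pct_correct),
      pct_incorrect = mean(.data$pct_incorrect),
      pct_not_imputed = mean(.data$pct_not_imputed),
      .groups = "drop"
    )
  }
  by_category <- summarize_block(
    dplyr::group_by(animals, .data$scenario, .data$category)
  )
  overall <- summarize_block(dplyr::group_by(animals, .data$scenario))

  breaks <- seq(0, 0.5, length.out = maf_bins + 1)
  snps$maf_bin <- cut(snps$maf, breaks, include.lowest = TRUE)
  by_maf_bin <- dplyr::summarise(
    dplyr::group_by(snps, .data$scenario, .data$maf_bin),
    n_snps = dplyr::n(),
    r_mean = mean(.data$r, na.rm = TRUE),
    pct_correct = mean(.data$pct_correct),
    pct_incorrect = mean(.data$pct_incorrect),
    pct_not_imputed = mean(.data$pct_not_imputed),
    .groups = "drop"
  )
  structure(list(by_category = by_category, overall = overall,
                 by_maf_bin = by_maf_bin),
            class = "accuracy_summary")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Accuracy report for scenario", x$scenario, "-",
      nrow(x$by_animal), "test animals,", nrow(x$by_snp), "SNPs\n")
  cat("  mean corrected r:",
      sprintf("%.3f", mean(x$by_animal$r_corrected, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("Accuracy summary\n")
  print(x$overall)
  invisible(x)
}
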