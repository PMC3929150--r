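#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an imputation result into a long tibble
#'
#' @param x An [impute_all()] result.
#' @param ... Unused.
#' @return A tibble with one row per individual and SNP: `id`, `snp`,
#'   `p0`, `p1`, `p2`, `dosage`, `called` (`NA` = not imputed).
#' @export
tidy.imputation_result <- function(x, ...) {
  ids <- rownames(x$dosage)
  snps <- colnames(x$dosage) %||% paste0("snp", seq_len(ncol(x$dosage)))
  tibble::tibble(
    id = rep(ids, times = length(snps)),
    snp = rep(snps, each = length(ids)),
    p0 = as.vector(x$probabilities[, 1L, ]),
    p1 = as.vector(x$probabilities[, 2L, ]),
    p2 = as.vector(x$probabilities[, 3L, ]),
    dosage = as.vector(x$dosage),
    called = as.vector(x$called)
  )
}

#' One-row summary of an imputation result
#'
#' @param x An [impute_all()] result.
#' @param ... Unused.
#' @return A tibble with the problem size, call rate and convergence
#'   diagnostics.
#' @export
glance.imputation_result <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$dosage),
    n_snps = ncol(x$dosage),
    n_reference = length(x$reference),
    call_rate = mean(!is.na(x$called)),
    mean_rounds = mean(x$rounds),
    prop_converged = mean(x$converged)
  )
}

#' Per-animal rows of an accuracy report
#'
#' @param x A [score_imputation()] report.
#' @param ... Unused.
#' @return The `by_animal` tibble.
#' @export
tidy.accuracy_report <- function(x, ...) x$by_animal

#' One-row summary of an accuracy report
#'
#' @param x A [score_imputation()] report.
#' @param ... Unused.
#' @return A tibble with pooled means over test animals.
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n_animals = nrow(x$by_animal),
    n_snps = nrow(x$by_snp),
    r_corrected_mean = mean(x$by_animal$r_corrected, na.rm = TRUE),
    r_uncorrected_mean = mean(x$by_animal$r_uncorrected, na.rm = TRUE),
    pct_correct = mean(x$by_animal$pct_correct),
    pct_incorrect = mean(x$by_animal$pct_incorrect),
    pct_not_imputed = mean(x$by_animal$pct_not_imputed)
  )
}

#' Plot an accuracy summary
#'
#' Two views of a pooled [summarize_accuracy()] object: per-SNP accuracy
#' against minor allele frequency (binned means per scenario), or
#' per-category corrected accuracy bars per scenario.
#'
#' @param object An `accuracy_summary`.
#' @param type `"maf"` (default) or `"category"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_summary <- function(object, type = c("maf", "category"),
                                      ...) {
  type <- match.arg(type)
  if (type == "maf") {
    df <- object$by_maf_bin
    df$maf_mid <- (as.numeric(df$maf_bin) - 0.5) * 0.5 /
      nlevels(df$maf_bin)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$maf_mid, y = .data$r_mean,
                                     colour = .data$scenario)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "Minor allele frequency (bin midpoint)",
                    y = "Mean SNP-specific accuracy (r)",
                    colour = "Scenario") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$by_category,
                    ggplot2::aes(x = .data$category,
                                 y = .data$r_corrected_mean,
                                 fill = .data$scenario)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "Most recent genotyped ancestors",
                    y = "Mean corrected accuracy (r)", fill = "Scenario") +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' Plot pooled accuracy against selection-index predictions
#'
#' @param x An [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot comparing observed pooled corrected accuracy per
#'   scenario with the predicted accuracy for the dominant category.
#' @export
autoplot.experiment_result <- function(x, ...) {
  obs <- x$summary$overall
  obs$offspring <- as.integer(sub("^Off", "", obs$scenario))
  theo <- tidyr::pivot_longer(x$theory, -"ancestors",
                              names_to = "offspring", values_to = "r")
  theo$offspring <- as.integer(sub("^off", "", theo$offspring))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = theo,
                       ggplot2::aes(x = .data$offspring, y = .data$r,
                                    colour = .data$ancestors),
                       linetype = "dashed") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$offspring,
                                     y = .data$r_corrected_mean),
                        size = 3) +
    ggplot2::labs(x = "Genotyped offspring per test animal",
                  y = "Corrected imputation accuracy (r)",
                  colour = "Predicted (ancestors)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
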