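#' Configuration of a replicated imputation experiment
#'
#' @param design A [study_design()]; its offspring count is the maximum
#'   used by any requested scenario.
#' @param model A [founder_model()].
#' @param offspring_scenarios Genotyped-offspring counts to evaluate; each
#'   count `k` becomes scenario `Off<k>` by masking (the pedigree is
#'   shared).
#' @param opts A [peeling_options()].
#' @param n_replicates Number of genotype replicates (default 10); the
#'   pedigree is generated once, genotypes afresh per replicate.
#' @param base_seed Integer base seed; pedigree generation, founder
#'   simulation and gene dropping use independent seeds derived from it.
#' @param output_dir Optional directory; when given, report tables are
#'   written there as TSV.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(design, model,
                              offspring_scenarios = c(0, 1, 2, 4),
                              opts = peeling_options(),
                              n_replicates = 10,
                              base_seed = 1,
                              output_dir = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(model, "founder_model"),
            n_replicates >= 1)
  offspring_scenarios <- sort(unique(as.integer(offspring_scenarios)))
  if (any(offspring_scenarios > design$n_offspring_per_cow)) {
    stop("scenario offspring count exceeds the design's offspring per cow",
         call. = FALSE)
  }
  structure(list(design = design, model = model,
                 offspring_scenarios = offspring_scenarios,
                 opts = opts, n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

# Independent, reproducible seed streams below 2^31.
derive_seed <- function(base_seed, replicate, stream) {
  as.integer((as.double(base_seed) * 7919 + replicate * 104729 +
                stream * 1299721) %% 2147483647)
}

#' Run a replicated simulate-mask-impute-score experiment
#'
#' Generates the study pedigree once, then per replicate simulates founder
#' haplotypes, gene-drops them, and for every requested offspring scenario
#' masks the genotypes, imputes by segregation analysis and scores against
#' the truth. Scenario masks within a replicate share identical true
#' genotypes, so scenarios differ only in the reference set. Results are
#' pooled over replicates and compared with selection-index predictions.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `experiment_result`: `summary` (an
#'   `accuracy_summary` pooled over replicates), `theory` (category by
#'   offspring-count grid of predicted accuracies), `reports` (per
#'   replicate and scenario), and `log` (seeds and convergence notes).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  study <- generate_study_pedigree(cfg$design, derive_seed(cfg$base_seed, 0, 1))
  ped <- study$pedigree
  scen <- lapply(cfg$offspring_scenarios, function(k) off_scenario(study, k))
  n_founder_hap <- 2L * sum(is.na(ped$sire) & is.na(ped$dam))
  n_hap <- min(max(n_founder_hap, 400L), 4000L)

  reports <- list()
  log <- list(seeds = list(), warnings = character())
  for (r in seq_len(cfg$n_replicates)) {
    seeds <- c(founders = derive_seed(cfg$base_seed, r, 2),
               drop = derive_seed(cfg$base_seed, r, 3))
    log$seeds[[r]] <- seeds
    pool <- simulate_founder_haplotypes(cfg$model, n_hap, seeds["founders"])
    truth <- gene_drop(ped, pool, seed = seeds["drop"])
    for (sp in scen) {
      obs <- apply_scenario(truth, sp)
      imp <- withCallingHandlers(
        impute_all(ped, obs, cfg$opts),
        warning = function(w) {
          log$warnings <<- c(log$warnings,
                             paste0("replicate ", r, " ", sp$name, ": ",
                                    conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      reports[[paste0(sp$name, "_rep", r)]] <-
        score_imputation(truth, imp, sp, ped, replicate = r)
    }
  }
  summary <- summarize_accuracy(reports)
  theory <- predict_grid(cfg$offspring_scenarios)

  res <- structure(list(summary = summary, theory = theory,
                        reports = reports, config = cfg, log = log),
                   class = "experiment_result")
  if (!is.null(cfg$output_dir)) write_experiment(res, cfg$output_dir)
  res
}

write_experiment <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(res$summary$by_category, "accuracy_by_category.tsv")
  tsv(res$summary$overall, "accuracy_overall.tsv")
  tsv(res$summary$by_maf_bin, "accuracy_by_maf_bin.tsv")
  tsv(res$theory, "selection_index_predictions.tsv")
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Imputation experiment:", x$config$n_replicates, "replicate(s),",
      "scenarios", paste0("Off", x$config$offspring_scenarios, collapse = " "),
      "\n\nPooled accuracy by scenario:\n")
  print(x$summary$overall)
  cat("\nSelection-index predictions:\n")
  print(x$theory)
  invisible(x)
}
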