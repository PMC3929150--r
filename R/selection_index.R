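#' Selection-index matrices for predicting imputation accuracy
#'
#' Gene content (the 0/1/2 count of a reference allele) behaves as a trait
#' with heritability one, so the accuracy of a linear prediction of a
#' candidate's gene content from genotyped relatives follows from selection
#' index theory. `build_P_G()` assembles the index matrices from pedigree
#' relationships: `P` holds the additive relationships among the information
#' sources (diagonal `1 + F`), `G` the relationships between each source and
#' the candidate.
#'
#' @param ped A pedigree.
#' @param candidate Id of the individual to be imputed.
#' @param sources Character vector of genotyped relative ids (distinct, not
#'   including the candidate).
#' @return A list with components `P` (matrix) and `G` (named vector).
#' @export
build_P_G <- function(ped, candidate, sources) {
  stopifnot(inherits(ped, "pedigree"), length(candidate) == 1L)
  if (candidate %in% sources) {
    stop("candidate cannot be one of its own information sources", call. = FALSE)
  }
  if (anyDuplicated(sources)) {
    stop("duplicated information source: ", sources[duplicated(sources)][1L],
         call. = FALSE)
  }
  A <- relationship_matrix(ped, c(candidate, sources))
  P <- A[-1L, -1L, drop = FALSE]
  G <- A[-1L, 1L]
  list(P = P, G = G)
}

#' Predicted imputation accuracy from selection index theory
#'
#' The accuracy of the best linear prediction of the candidate's gene
#' content from its genotyped relatives is `r = sqrt(G' P^-1 G)` for a
#' non-inbred candidate; an empty source set yields 0.
#'
#' @param P Source-by-source additive relationship matrix (symmetric
#'   positive definite).
#' @param G Vector of source-to-candidate additive relationships.
#' @return The predicted accuracy, a number in `[0, 1]`.
#' @examples
#' # both (unrelated, non-inbred) parents genotyped:
#' predicted_accuracy(diag(2), c(0.5, 0.5)) # sqrt(0.5)
#' @export
predicted_accuracy <- function(P, G) {
  if (length(G) == 0L) return(0)
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), length(G) == nrow(P))
  if (max(abs(P - t(P))) > 1e-8) stop("P must be symmetric", call. = FALSE)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("P is not positive definite (duplicated or redundant source?)",
         call. = FALSE)
  }
  sqrt(drop(crossprod(G, solve(P, G))))
}

#' Predicted accuracy for a candidate given genotyped relatives
#'
#' Convenience wrapper chaining [build_P_G()] and [predicted_accuracy()].
#'
#' @inheritParams build_P_G
#' @return Predicted imputation accuracy.
#' @export
si_accuracy <- function(ped, candidate, sources) {
  if (length(sources) == 0L) return(0)
  pg <- build_P_G(ped, candidate, sources)
  predicted_accuracy(pg$P, pg$G)
}

# Fixture pedigree for the standard prediction grid: candidate cow X with
# sire S (sire's parents SS x SD), dam D (dam's parents MGS x MGD), and four
# offspring O1..O4 from four unrelated, ungenotyped mate sires U1..U4
# (maternal half sibs). All founders mutually unrelated and non-inbred.
si_grid_pedigree <- function() {
  as_pedigree(data.frame(
    id   = c("SS", "SD", "MGS", "MGD", "S", "D", "X",
             paste0("U", 1:4), paste0("O", 1:4)),
    sire = c(NA, NA, NA, NA, "SS", "MGS", "S", rep(NA, 4), paste0("U", 1:4)),
    dam  = c(NA, NA, NA, NA, "SD", "MGD", "D", rep(NA, 4), rep("X", 4))
  ))
}

#' Grid of predicted imputation accuracies by ancestor set and offspring count
#'
#' Predicts animal-specific imputation accuracy for the standard design
#' grid: rows are the genotyped-ancestor configurations both parents,
#' sire + maternal grandsire (equivalent to dam + paternal grandsire by
#' symmetry), and a single parent; columns are 0, 1, 2 or 4 genotyped
#' offspring of the candidate. Offspring are maternal half sibs with
#' unrelated, ungenotyped mates; all other relatives are unrelated and
#' ungenotyped, and no individual is inbred.
#'
#' @param offspring_counts Integer vector of genotyped-offspring counts.
#' @param digits Decimal places for rounding (default 2); `NULL` to skip.
#' @return A tibble with one row per ancestor configuration (`ancestors`)
#'   and one column per offspring count (`off0`, `off1`, ...).
#' @examples
#' predict_grid()
#' @export
predict_grid <- function(offspring_counts = c(0, 1, 2, 4), digits = 2) {
  ped <- si_grid_pedigree()
  ancestor_sets <- list(
    BothParents    = c("S", "D"),
    `SireMGS/DamPGS` = c("S", "MGS"),
    `Sire/Dam`     = "S"
  )
  rows <- purrr::map(names(ancestor_sets), function(conf) {
    vals <- purrr::map_dbl(offspring_counts, function(k) {
      src <- c(ancestor_sets[[conf]],
               if (k > 0) paste0("O", seq_len(k)))
      r <- si_accuracy(ped, "X", src)
      if (is.null(digits)) r else round(r, digits)
    })
    names(vals) <- paste0("off", offspring_counts)
    tibble::tibble(ancestors = conf, !!!vals)
  })
  dplyr::bind_rows(rows)
}
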