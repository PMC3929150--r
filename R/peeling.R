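#' Options controlling segregation-analysis imputation
#'
#' @param call_threshold Minimum posterior probability for calling a
#'   genotype; below it the genotype is reported as not imputed (default
#'   0.98). Dosages are always reported regardless.
#' @param max_rounds Maximum peeling iterations per SNP (default 30).
#' @param tolerance Convergence tolerance: maximum absolute change of any
#'   genotype probability between rounds (default 1e-6).
#' @param frequency_clamp Minimum allele frequency; `NULL` (default) uses
#'   `1 / (2 * n_reference + 2)`, so a SNP fixed in a finite reference
#'   keeps a nonzero prior for the unobserved allele.
#' @return A list of class `peeling_options`.
#' @export
peeling_options <- function(call_threshold = 0.98, max_rounds = 30,
                            tolerance = 1e-6, frequency_clamp = NULL) {
  stopifnot(call_threshold > 1 / 3, call_threshold <= 1,
            max_rounds >= 1, tolerance > 0)
  if (!is.null(frequency_clamp)) {
    stopifnot(frequency_clamp > 0, frequency_clamp < 0.5)
  }
  structure(list(call_threshold = call_threshold,
                 max_rounds = as.integer(max_rounds),
                 tolerance = tolerance,
                 frequency_clamp = frequency_clamp),
            class = "peeling_options")
}

#' Estimate per-SNP allele frequencies from the reference set
#'
#' The frequency of the allele coded 1 (whose homozygote is genotype 2) is
#' half the mean genotype code over reference individuals with an observed
#' genotype, clamped away from 0 and 1.
#'
#' @param obs Observed genotype matrix (individuals x SNPs, `NA` missing),
#'   rownames are ids.
#' @param reference Ids of the reference individuals.
#' @param clamp Minimum frequency; default `1 / (2 * length(reference) + 2)`.
#' @return Numeric vector of per-SNP frequencies in
#'   `[clamp, 1 - clamp]`.
#' @export
estimate_allele_frequency <- function(obs, reference,
                                      clamp = 1 / (2 * length(reference) + 2)) {
  stopifnot(is.matrix(obs), length(reference) >= 1)
  ref <- obs[rownames(obs) %in% reference, , drop = FALSE]
  n_obs <- colSums(!is.na(ref))
  if (any(n_obs == 0L)) {
    stop("SNP with no observed reference genotype: column ",
         which(n_obs == 0L)[1L], call. = FALSE)
  }
  p <- colMeans(ref, na.rm = TRUE) / 2
  pmin(pmax(p, clamp), 1 - clamp)
}

#' Mendelian single-locus transmission probability
#'
#' Probability that parents with genotypes `g_sire` and `g_dam` produce an
#' offspring with genotype `g_off`, each parent transmitting its coded
#' allele with probability 0, 1/2 or 1 for genotypes 0, 1 and 2.
#'
#' @param g_off,g_sire,g_dam Genotypes in `{0, 1, 2}`; vectors are
#'   recycled.
#' @return Transmission probabilities.
#' @examples
#' transmission_probability(1, 1, 1) # 0.5
#' @export
transmission_probability <- function(g_off, g_sire, g_dam) {
  stopifnot(all(g_off %in% 0:2), all(g_sire %in% 0:2), all(g_dam %in% 0:2))
  ps <- g_sire / 2
  pd <- g_dam / 2
  out <- numeric(length(ps + pd + g_off)) # recycled length
  g_off <- rep_len(g_off, length(out))
  ps <- rep_len(ps, length(out))
  pd <- rep_len(pd, length(out))
  out[g_off == 0] <- ((1 - ps) * (1 - pd))[g_off == 0]
  out[g_off == 1] <- (ps * (1 - pd) + (1 - ps) * pd)[g_off == 1]
  out[g_off == 2] <- (ps * pd)[g_off == 2]
  out
}

#' Deterministic Mendelian fill-in of forced genotypes
#'
#' Iterates simple inheritance rules to a fixpoint, writing a genotype only
#' when both of an individual's alleles are forced: two homozygous parents
#' force the offspring genotype; a homozygous parent forces one offspring
#' allele; a homozygous offspring forces one allele in each parent; a
#' heterozygous offspring whose other parent is homozygous forces the
#' complementary allele in this parent.
#'
#' @param ped A pedigree.
#' @param obs Observed genotype matrix (rows in pedigree order or with id
#'   rownames, `NA` missing).
#' @return The genotype matrix with forced genotypes filled in.
#' @export
mendelian_rules_fill <- function(ped, obs) {
  stopifnot(inherits(ped, "pedigree"), is.matrix(obs))
  idx <- match(ped$id, rownames(obs))
  if (anyNA(idx)) {
    stop("genotype matrix is missing pedigree individuals", call. = FALSE)
  }
  obs <- obs[idx, , drop = FALSE]
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  lo <- obs; lo[is.na(lo)] <- 0L
  hi <- obs; hi[is.na(hi)] <- 2L

  nonf_s <- which(!is.na(si))
  nonf_d <- which(!is.na(di))
  repeat {
    lo0 <- lo; hi0 <- hi
    # parent -> offspring: a homozygous parent forces one allele
    forced1 <- matrix(0L, n, ncol(obs))
    forced0 <- matrix(0L, n, ncol(obs))
    forced1[nonf_s, ] <- forced1[nonf_s, ] + (lo[si[nonf_s], , drop = FALSE] == 2L)
    forced0[nonf_s, ] <- forced0[nonf_s, ] + (hi[si[nonf_s], , drop = FALSE] == 0L)
    forced1[nonf_d, ] <- forced1[nonf_d, ] + (lo[di[nonf_d], , drop = FALSE] == 2L)
    forced0[nonf_d, ] <- forced0[nonf_d, ] + (hi[di[nonf_d], , drop = FALSE] == 0L)
    lo <- pmax(lo, forced1)
    hi <- pmin(hi, 2L - forced0)

    # offspring -> parent: homozygous offspring forces one allele in each
    # parent; a het offspring with the other parent homozygous forces the
    # complementary allele in this parent
    for (parent in c("sire", "dam")) {
      pi <- if (parent == "sire") si else di
      oi <- if (parent == "sire") di else si
      rows <- which(!is.na(pi))
      if (!length(rows)) next
      het <- lo[rows, , drop = FALSE] == 1L & hi[rows, , drop = FALSE] == 1L
      other_lo <- matrix(0L, length(rows), ncol(obs))
      other_hi <- matrix(2L, length(rows), ncol(obs))
      known_other <- !is.na(oi[rows])
      other_lo[known_other, ] <- lo[oi[rows][known_other], , drop = FALSE]
      other_hi[known_other, ] <- hi[oi[rows][known_other], , drop = FALSE]
      carries1 <- (lo[rows, , drop = FALSE] == 2L) | (het & other_hi == 0L)
      carries0 <- (hi[rows, , drop = FALSE] == 0L) | (het & other_lo == 2L)
      min1 <- rowsum(carries1 * 1L, pi[rows]) > 0
      max1 <- rowsum(carries0 * 1L, pi[rows]) > 0
      tgt <- as.integer(rownames(min1))
      lo[tgt, ] <- pmax(lo[tgt, , drop = FALSE], min1 * 1L)
      hi[tgt, ] <- pmin(hi[tgt, , drop = FALSE], 2L - max1 * 1L)
    }

    bad <- which(lo > hi, arr.ind = TRUE)
    if (nrow(bad)) {
      i <- bad[1L, 1L]
      stop("Mendelian conflict at SNP ", bad[1L, 2L], " in trio (",
           ped$id[i], ", sire ", ped$sire[i] %||% "unknown", ", dam ",
           ped$dam[i] %||% "unknown", ")", call. = FALSE)
    }
    if (identical(lo, lo0) && identical(hi, hi0)) break
  }
  out <- obs
  fill <- lo == hi & is.na(obs)
  out[fill] <- lo[fill]
  rownames(out) <- ped$id
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

# Insert a phantom founder parent for every individual with exactly one
# known parent, so the kernel only sees complete or empty parent pairs.
# Phantoms come first to preserve topological order.
complete_parents <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  half <- which(is.na(si) != is.na(di))
  n_ph <- length(half)
  si2 <- c(rep(NA_integer_, n_ph), ifelse(is.na(si), NA_integer_, si + n_ph))
  di2 <- c(rep(NA_integer_, n_ph), ifelse(is.na(di), NA_integer_, di + n_ph))
  for (k in seq_along(half)) {
    i <- half[k] + n_ph
    if (is.na(si2[i])) si2[i] <- k else di2[i] <- k
  }
  list(sire = si2, dam = di2, n_phantom = n_ph,
       keep = seq_len(nrow(ped)) + n_ph)
}

peel_kernel <- function(ped, obs, freq, opts) {
  cp <- complete_parents(ped)
  n_ph <- cp$n_phantom
  obs_ext <- rbind(matrix(NA_integer_, n_ph, ncol(obs)), obs)
  res <- .peel_all_cpp(obs_ext, as.integer(cp$sire) - 1L,
                       as.integer(cp$dam) - 1L,
                       as.numeric(freq), opts$tolerance, opts$max_rounds)
  n_tot <- nrow(obs_ext)
  prob <- array(res$prob, dim = c(n_tot, 3L, ncol(obs)))
  prob <- prob[cp$keep, , , drop = FALSE]
  dimnames(prob) <- list(ped$id, c("p0", "p1", "p2"), colnames(obs))
  if (any(!res$converged)) {
    warning(sum(!res$converged), " SNP(s) did not reach tolerance ",
            opts$tolerance, " within ", opts$max_rounds, " peeling rounds",
            call. = FALSE)
  }
  list(prob = prob, rounds = res$rounds, converged = res$converged)
}

#' Iterative peeling of a single locus
#'
#' Computes per-individual genotype probability triplets for one SNP by
#' iterative peeling: founders carry a Hardy-Weinberg prior at the given
#' allele frequency, observed genotypes enter as indicator penetrances,
#' anterior and posterior messages are iterated to convergence. On
#' loop-free pedigrees the result equals exact single-locus marginals; on
#' looped pedigrees it is the standard iterative approximation.
#'
#' @param ped A pedigree.
#' @param column Per-individual observed genotypes for one SNP (`NA`
#'   missing), in pedigree order or named by id.
#' @param freq Frequency of the allele coded 1, strictly inside (0, 1).
#' @param opts A [peeling_options()].
#' @return Matrix of genotype probabilities (individuals x 3), rownames
#'   are ids.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("s", "d", "x"),
#'                               sire = c(NA, NA, "s"), dam = c(NA, NA, "d")))
#' peel_locus(ped, c(s = 2, d = NA, x = NA), freq = 0.3)["x", ]
#' @export
peel_locus <- function(ped, column, freq, opts = peeling_options()) {
  stopifnot(inherits(ped, "pedigree"), freq > 0, freq < 1)
  if (!is.null(names(column))) column <- column[match(ped$id, names(column))]
  stopifnot(length(column) == nrow(ped))
  obs <- matrix(as.integer(column), ncol = 1L,
                dimnames = list(ped$id, "snp1"))
  peel_kernel(ped, obs, freq, opts)$prob[, , 1L]
}

#' Impute all individuals by Mendelian rules and segregation analysis
#'
#' Runs the deterministic Mendelian fill-in, then iterative peeling per
#' SNP with allele frequencies estimated from the reference individuals.
#' A genotype is called when the largest of its three probabilities
#' reaches the call threshold (ties are not called); otherwise it is
#' reported as not imputed. Genotype dosages `p1 + 2 p2` are always
#' reported.
#'
#' @param ped A pedigree.
#' @param obs Observed genotype matrix (individuals x SNPs, `NA` missing),
#'   rownames are ids covering the pedigree.
#' @param opts A [peeling_options()].
#' @return A list of class `imputation_result`: `probabilities`
#'   (individuals x 3 x SNPs), `dosage`, `called` (`NA` = not imputed),
#'   `freq`, `reference` (ids with any observed genotype), `rounds`,
#'   `converged` and `options`.
#' @export
impute_all <- function(ped, obs, opts = peeling_options()) {
  stopifnot(inherits(ped, "pedigree"), is.matrix(obs))
  idx <- match(ped$id, rownames(obs))
  if (anyNA(idx)) {
    stop("genotype matrix is missing pedigree individuals", call. = FALSE)
  }
  obs <- obs[idx, , drop = FALSE]
  storage.mode(obs) <- "integer"
  reference <- ped$id[rowSums(!is.na(obs)) > 0L]
  if (!length(reference)) stop("no observed genotypes", call. = FALSE)
  clamp <- opts$frequency_clamp %||% (1 / (2 * length(reference) + 2))
  freq <- estimate_allele_frequency(obs, reference, clamp = clamp)
  filled <- mendelian_rules_fill(ped, obs)
  pk <- peel_kernel(ped, filled, freq, opts)
  prob <- pk$prob
  dosage <- prob[, 2L, ] + 2 * prob[, 3L, ]
  dosage <- matrix(dosage, nrow(obs), ncol(obs),
                   dimnames = dimnames(obs))
  pmax_idx <- apply(prob, c(1L, 3L), which.max)
  pmax_val <- apply(prob, c(1L, 3L), max)
  ties <- apply(prob, c(1L, 3L), function(v) sum(v == max(v)) > 1L)
  called <- matrix(as.integer(pmax_idx) - 1L, nrow(obs), ncol(obs),
                   dimnames = dimnames(obs))
  called[pmax_val < opts$call_threshold | ties] <- NA_integer_
  structure(list(probabilities = prob, dosage = dosage, called = called,
                 freq = freq, reference = reference,
                 rounds = pk$rounds, converged = pk$converged,
                 options = opts),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("Segregation-analysis imputation of", nrow(x$dosage), "individuals at",
      ncol(x$dosage), "SNPs\n")
  cat("  reference individuals:", length(x$reference), "\n")
  cat("  genotypes called:",
      sprintf("%.1f%%", 100 * mean(!is.na(x$called))), "\n")
  invisible(x)
}
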