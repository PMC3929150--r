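# Independent oracles used by the test suite. These deliberately avoid the
# package's own computational paths: the A-matrix oracle uses the tabular
# method, the peeling oracle enumerates every genotype configuration.

# Tabular-method additive relationship matrix over a whole pedigree.
tabular_A <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    js <- seq_len(i - 1L)
    if (length(js)) {
      a <- numeric(length(js))
      if (!is.na(s)) a <- a + 0.5 * A[js, s]
      if (!is.na(d)) a <- a + 0.5 * A[js, d]
      A[i, js] <- A[js, i] <- a
    }
  }
  A
}

# Exact single-locus genotype marginals by brute-force enumeration of all
# 3^n configurations. An individual with exactly one known parent has the
# unknown parent marginalised over Hardy-Weinberg.
brute_force_peel <- function(ped, column, freq) {
  n <- nrow(ped)
  stopifnot(n <= 12)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  hwe <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  cfg <- as.matrix(expand.grid(rep(list(0:2), n)))
  joint <- rep(1, nrow(cfg))
  marg_T <- function(g, gp) { # one parent known, other ~ HWE
    hwe[1] * transmission_probability(g, gp, rep(0L, length(g))) +
      hwe[2] * transmission_probability(g, gp, rep(1L, length(g))) +
      hwe[3] * transmission_probability(g, gp, rep(2L, length(g)))
  }
  for (i in seq_len(n)) {
    g <- cfg[, i]
    term <- if (is.na(si[i]) && is.na(di[i])) {
      hwe[g + 1]
    } else if (!is.na(si[i]) && !is.na(di[i])) {
      transmission_probability(g, cfg[, si[i]], cfg[, di[i]])
    } else if (!is.na(si[i])) {
      marg_T(g, cfg[, si[i]])
    } else {
      marg_T(g, cfg[, di[i]])
    }
    if (!is.na(column[i])) term <- term * (g == column[i])
    joint <- joint * term
  }
  out <- matrix(0, n, 3, dimnames = list(ped$id, c("p0", "p1", "p2")))
  for (i in seq_len(n)) {
    for (g in 0:2) out[i, g + 1] <- sum(joint[cfg[, i] == g])
  }
  out / rowSums(out)
}

# Random loop-free pedigree: every new mating pairs an existing individual
# with a brand-new founder (keeping the marriage graph a tree); full sibs
# are added by reusing an existing mating.
random_loopfree_pedigree <- function(n_max, seed) {
  set.seed(seed)
  id <- "I1"
  sire <- NA_character_
  dam <- NA_character_
  matings <- list()
  cnt <- 1L
  while (cnt < n_max) {
    move <- sample(1:3, 1, prob = c(0.2, 0.5, 0.3))
    if (move == 1L || cnt < 2L) {
      cnt <- cnt + 1L
      id <- c(id, paste0("I", cnt)); sire <- c(sire, NA); dam <- c(dam, NA)
    } else if (move == 2L && cnt + 2L <= n_max) {
      p <- paste0("I", sample(cnt, 1))
      cnt <- cnt + 1L
      mate <- paste0("I", cnt)
      id <- c(id, mate); sire <- c(sire, NA); dam <- c(dam, NA)
      cnt <- cnt + 1L
      p_as_sire <- if (p %in% dam) FALSE else if (p %in% sire) TRUE else
        stats::runif(1) < 0.5
      id <- c(id, paste0("I", cnt))
      if (p_as_sire) {
        sire <- c(sire, p); dam <- c(dam, mate)
        matings[[length(matings) + 1L]] <- c(p, mate)
      } else {
        sire <- c(sire, mate); dam <- c(dam, p)
        matings[[length(matings) + 1L]] <- c(mate, p)
      }
    } else if (move == 3L && length(matings)) {
      m <- matings[[sample(length(matings), 1)]]
      cnt <- cnt + 1L
      id <- c(id, paste0("I", cnt)); sire <- c(sire, m[1]); dam <- c(dam, m[2])
    }
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# Simulate one consistent observed genotype column on a pedigree by a
# single-locus gene drop at the given allele frequency, then mask.
simulated_column <- function(ped, freq, p_missing, seed) {
  set.seed(seed)
  pool <- simulate_founder_haplotypes(
    founder_model("sfs", n_snps = 1, sfs_freq = freq),
    max(2L * nrow(ped), 10L), seed = seed + 1L
  )
  tg <- gene_drop(ped, pool, seed = seed + 2L)
  col <- tg$genotypes[, 1L]
  col[stats::runif(length(col)) < p_missing] <- NA
  col
}

# Small standard trio pedigree used across tests.
trio_ped <- function() {
  as_pedigree(data.frame(id = c("s", "d", "x"),
                         sire = c(NA, NA, "s"),
                         dam = c(NA, NA, "d")))
}

# Candidate cow X with parents S (of SS x SD) and D (of MGS x MGD), plus four
# maternal-half-sib offspring O1..O4 by unrelated mate sires U1..U4.
si_grid_ped_for_tests <- function() {
  as_pedigree(data.frame(
    id   = c("SS", "SD", "MGS", "MGD", "S", "D", "X",
             paste0("U", 1:4), paste0("O", 1:4)),
    sire = c(NA, NA, NA, NA, "SS", "MGS", "S", rep(NA, 4), paste0("U", 1:4)),
    dam  = c(NA, NA, NA, NA, "SD", "MGD", "D", rep(NA, 4), rep("X", 4))
  ))
}
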