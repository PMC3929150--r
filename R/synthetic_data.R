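#' Study design for a half-sib imputation experiment
#'
#' Describes the simulated data structure: ungenotyped test cows whose sires
#' and maternal grandsires are genotyped, a shared pool of ungenotyped mate
#' sires, and 0--4 genotyped maternal-half-sib offspring per cow. Each cow's
#' dam is an ungenotyped daughter of a maternal grandsire; offspring sires
#' are drawn from the mate-sire pool without replacement within a cow, so
#' offspring of one cow are strict maternal half sibs, while mate sires are
#' shared across cows.
#'
#' @param n_test_cows Number of ungenotyped test cows.
#' @param n_mate_sires Size of the shared ungenotyped mate-sire pool
#'   (default 60).
#' @param n_offspring_per_cow Genotyped offspring simulated per cow; one of
#'   0, 1, 2, 4.
#' @param n_genotyped_sires,n_genotyped_mgs Distinct genotyped sires and
#'   maternal grandsires of the test cows. Defaults give roughly 16
#'   daughters per sire, a realistic dairy half-sib family size.
#' @param extra_reference Additional genotyped founders unrelated to the
#'   tests.
#' @param p_sire_genotyped,p_mgs_genotyped Probability that a cow's sire
#'   (maternal grandsire) comes from the genotyped pool rather than an
#'   ungenotyped one; lowering these approximates a real data scenario where
#'   only a minority of tests have genotyped ancestors.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_test_cows,
                         n_mate_sires = 60,
                         n_offspring_per_cow = 4,
                         n_genotyped_sires = max(1L, round(n_test_cows / 16)),
                         n_genotyped_mgs = max(1L, round(n_test_cows / 16)),
                         extra_reference = 0,
                         p_sire_genotyped = 1,
                         p_mgs_genotyped = 1) {
  stopifnot(n_test_cows >= 1, n_mate_sires >= 0,
            n_genotyped_sires >= 1, n_genotyped_mgs >= 1,
            extra_reference >= 0,
            p_sire_genotyped >= 0, p_sire_genotyped <= 1,
            p_mgs_genotyped >= 0, p_mgs_genotyped <= 1)
  if (!n_offspring_per_cow %in% c(0L, 1L, 2L, 4L)) {
    stop("n_offspring_per_cow must be 0, 1, 2 or 4", call. = FALSE)
  }
  if (n_offspring_per_cow > n_mate_sires) {
    stop("n_offspring_per_cow cannot exceed n_mate_sires ",
         "(offspring sires are drawn without replacement within a cow)",
         call. = FALSE)
  }
  structure(list(
    n_test_cows = as.integer(n_test_cows),
    n_mate_sires = as.integer(n_mate_sires),
    n_offspring_per_cow = as.integer(n_offspring_per_cow),
    n_genotyped_sires = as.integer(n_genotyped_sires),
    n_genotyped_mgs = as.integer(n_genotyped_mgs),
    extra_reference = as.integer(extra_reference),
    p_sire_genotyped = p_sire_genotyped,
    p_mgs_genotyped = p_mgs_genotyped
  ), class = "study_design")
}

#' Scenario specification: who is genotyped, who is imputed
#'
#' @param name Scenario name (e.g. `"Off2"`).
#' @param genotyped_ids Ids forming the genotyped reference set.
#' @param test_ids Ids to impute; disjoint from `genotyped_ids`.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name, genotyped_ids, test_ids) {
  if (length(intersect(genotyped_ids, test_ids))) {
    stop("genotyped and test sets must be disjoint", call. = FALSE)
  }
  structure(list(name = name,
                 genotyped_ids = unique(as.character(genotyped_ids)),
                 test_ids = unique(as.character(test_ids))),
            class = "scenario_spec")
}

#' Generate a study-like pedigree and its scenario
#'
#' Builds the pedigree implied by a [study_design()]: genotyped sire and
#' maternal-grandsire pools, one ungenotyped dam per test cow (a daughter of
#' a maternal grandsire), the test cows themselves, a shared pool of
#' ungenotyped founder mate sires, the genotyped maternal-half-sib offspring
#' and any extra unrelated reference founders.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; identical seeds give identical pedigrees.
#' @return A list of class `study` with elements `pedigree`, `scenario`
#'   (for the design's full offspring count), `design`, `cows` (test cow
#'   ids) and `offspring` (list of per-cow offspring id vectors, in the
#'   order they were produced).
#' @export
generate_study_pedigree <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  n <- design$n_test_cows
  k <- design$n_offspring_per_cow

  sires <- paste0("S", seq_len(design$n_genotyped_sires))
  mgs <- paste0("G", seq_len(design$n_genotyped_mgs))
  usires <- paste0("US", seq_len(design$n_genotyped_sires))
  umgs <- paste0("UG", seq_len(design$n_genotyped_mgs))
  dams <- paste0("D", seq_len(n))
  cows <- paste0("C", seq_len(n))
  mates <- if (design$n_mate_sires > 0) paste0("U", seq_len(design$n_mate_sires)) else character()
  extras <- if (design$extra_reference > 0) paste0("R", seq_len(design$extra_reference)) else character()

  sire_geno <- stats::runif(n) < design$p_sire_genotyped
  mgs_geno <- stats::runif(n) < design$p_mgs_genotyped
  cow_sire <- ifelse(sire_geno,
                     sample(sires, n, replace = TRUE),
                     sample(usires, n, replace = TRUE))
  dam_sire <- ifelse(mgs_geno,
                     sample(mgs, n, replace = TRUE),
                     sample(umgs, n, replace = TRUE))

  used_usires <- unique(cow_sire[!sire_geno])
  used_umgs <- unique(dam_sire[!mgs_geno])

  off_by_cow <- vector("list", n)
  off_id <- off_sire <- off_dam <- character(0)
  if (k > 0) {
    for (i in seq_len(n)) {
      ids <- paste0("O", i, "_", seq_len(k))
      off_by_cow[[i]] <- ids
      off_id <- c(off_id, ids)
      off_sire <- c(off_sire, sample(mates, k, replace = FALSE))
      off_dam <- c(off_dam, rep(cows[i], k))
    }
  }

  founders <- c(sires, mgs, used_usires, used_umgs, mates, extras)
  ped <- as_pedigree(data.frame(
    id = c(founders, dams, cows, off_id),
    sire = c(rep(NA, length(founders)), dam_sire, cow_sire, off_sire),
    dam = c(rep(NA, length(founders)), rep(NA, n), dams, off_dam)
  ))

  spec <- scenario_spec(paste0("Off", k),
                        genotyped_ids = c(sires, mgs, extras, off_id),
                        test_ids = cows)
  structure(list(pedigree = ped, scenario = spec, design = design,
                 cows = cows, offspring = off_by_cow),
            class = "study")
}

#' Scenario with only the first k offspring per cow genotyped
#'
#' A study simulated with four offspring per cow yields the 0/1/2/4
#' offspring scenarios by masking: the pedigree is unchanged, only the
#' reference set varies.
#'
#' @param study A [generate_study_pedigree()] result.
#' @param k Number of genotyped offspring per cow (at most the design's
#'   offspring count).
#' @return A [scenario_spec()] named `Off<k>`.
#' @export
off_scenario <- function(study, k) {
  stopifnot(inherits(study, "study"))
  if (k > study$design$n_offspring_per_cow) {
    stop("k exceeds the number of simulated offspring per cow", call. = FALSE)
  }
  base <- setdiff(study$scenario$genotyped_ids, unlist(study$offspring))
  keep <- if (k > 0) unlist(lapply(study$offspring, utils::head, k)) else character()
  scenario_spec(paste0("Off", k), c(base, keep), study$cows)
}

#' Pedigree of independent genotyped-parent trios
#'
#' Each trio has two genotyped founder parents and one ungenotyped test
#' offspring; trios are mutually unrelated. Used to study parent-average
#' imputation in isolation.
#'
#' @param n_trios Number of trios.
#' @return A list of class `study` (with `offspring` empty).
#' @export
generate_trio_pedigree <- function(n_trios) {
  s <- paste0("TS", seq_len(n_trios))
  d <- paste0("TD", seq_len(n_trios))
  x <- paste0("TX", seq_len(n_trios))
  ped <- as_pedigree(data.frame(
    id = c(s, d, x),
    sire = c(rep(NA, 2 * n_trios), s),
    dam = c(rep(NA, 2 * n_trios), d)
  ))
  structure(list(pedigree = ped,
                 scenario = scenario_spec("Trio", c(s, d), x),
                 design = NULL, cows = x, offspring = vector("list", 0)),
            class = "study")
}

#' Founder haplotype model
#'
#' Two modes generate the founder haplotype pool. `"coalescent"` simulates
#' sequence under a piecewise-constant effective population size (a cattle
#' demography: 100 now, 1256 at 1000 years, 4350 at 10 000 years, 43 500 at
#' 100 000 years; mutation rate 2.5e-8 per site) and samples SNPs uniformly
#' from the segregating sites without any frequency filter. `"sfs"` draws
#' per-SNP allele frequencies from a symmetric Beta distribution whose
#' default shape (0.815) is calibrated so the pool's mean minor allele
#' frequency matches the coalescent mode's (about 0.23), then samples
#' alleles independently per site. Segregation analysis uses no linkage or
#' LD, so the cheaper independent-sites mode is the default.
#'
#' @param mode `"sfs"` or `"coalescent"`.
#' @param n_snps Number of SNPs (default 2000).
#' @param chrom_length_cM Map length in centimorgans (default 100).
#' @param sfs_shape Beta shape parameter for sfs mode.
#' @param sfs_freq Optional fixed vector of allele frequencies (recycled to
#'   `n_snps`); overrides `sfs_shape`.
#' @param seq_length_bp Coalescent mode: total sequence length in base
#'   pairs (default 1e8).
#' @param mutation_rate Per-site per-generation mutation rate (default
#'   2.5e-8).
#' @param epoch_years Times (years ago) at which the effective size
#'   changes.
#' @param epoch_sizes Effective sizes from the present backwards; one more
#'   entry than `epoch_years`.
#' @param generation_years Years per generation used to convert the
#'   demography to coalescent time (default 5, a typical dairy-cattle
#'   value).
#' @param chunk_length_bp Length of the independently simulated sequence
#'   chunks standing in for recombination along the chromosome.
#' @return A list of class `founder_model`.
#' @export
founder_model <- function(mode = c("sfs", "coalescent"),
                          n_snps = 2000,
                          chrom_length_cM = 100,
                          sfs_shape = 0.815,
                          sfs_freq = NULL,
                          seq_length_bp = 1e8,
                          mutation_rate = 2.5e-8,
                          epoch_years = c(1000, 10000, 100000),
                          epoch_sizes = c(100, 1256, 4350, 43500),
                          generation_years = 5,
                          chunk_length_bp = 1e5) {
  mode <- match.arg(mode)
  stopifnot(n_snps >= 1, chrom_length_cM > 0,
            length(epoch_sizes) == length(epoch_years) + 1L,
            all(diff(epoch_years) > 0), all(epoch_sizes > 0),
            generation_years > 0, mutation_rate > 0)
  if (!is.null(sfs_freq)) {
    stopifnot(all(sfs_freq > 0), all(sfs_freq < 1))
  }
  structure(list(mode = mode, n_snps = as.integer(n_snps),
                 chrom_length_cM = chrom_length_cM,
                 sfs_shape = sfs_shape, sfs_freq = sfs_freq,
                 seq_length_bp = seq_length_bp,
                 mutation_rate = mutation_rate,
                 epoch_years = epoch_years, epoch_sizes = epoch_sizes,
                 generation_years = generation_years,
                 chunk_length_bp = chunk_length_bp),
            class = "founder_model")
}

# One Kingman coalescent genealogy for n_hap haploid samples under a
# piecewise-constant diploid effective size, with infinite-sites mutations
# over seq_len_bp. Returns per-site carrier index lists and frequencies.
sim_coalescent_chunk <- function(n_hap, seq_len_bp, mutation_rate,
                                 epoch_gens, epoch_sizes) {
  n_nodes <- 2L * n_hap - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  lchild <- rchild <- integer(n_nodes)
  active <- seq_len(n_hap)
  k <- n_hap
  t <- 0
  epoch <- 1L
  nxt <- n_hap
  bounds <- c(epoch_gens, Inf)
  while (k > 1L) {
    rate <- k * (k - 1) / (4 * epoch_sizes[epoch])
    wait <- stats::rexp(1L, rate)
    if (t + wait > bounds[epoch]) {
      t <- bounds[epoch]
      epoch <- epoch + 1L
      next
    }
    t <- t + wait
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    nxt <- nxt + 1L
    time[nxt] <- t
    lchild[nxt] <- a; rchild[nxt] <- b
    parent[a] <- nxt; parent[b] <- nxt
    active[pick[1L]] <- nxt
    active[pick[2L]] <- active[k]
    k <- k - 1L
  }
  # tips below each node (children are always created before their parent)
  tips <- vector("list", n_nodes)
  for (v in seq_len(n_hap)) tips[[v]] <- v
  for (v in (n_hap + 1L):n_nodes) {
    tips[[v]] <- c(tips[[lchild[v]]], tips[[rchild[v]]])
  }
  blen <- numeric(n_nodes)
  has_parent <- parent > 0L
  blen[has_parent] <- time[parent[has_parent]] - time[has_parent]
  total <- sum(blen)
  n_mut <- stats::rpois(1L, total * mutation_rate * seq_len_bp)
  if (n_mut == 0L) {
    return(list(carriers = list(), freq = numeric(0)))
  }
  mut_node <- sample.int(n_nodes, n_mut, replace = TRUE, prob = blen)
  list(carriers = tips[mut_node],
       freq = lengths(tips[mut_node]) / n_hap)
}

#' Simulate founder haplotypes and a genetic map
#'
#' In coalescent mode, independent sequence chunks are simulated under the
#' model's piecewise demography and `n_snps` segregating sites are sampled
#' uniformly at random (no MAF filter). In sfs mode, per-SNP allele
#' frequencies are drawn from the configured distribution and haplotype
#' alleles sampled independently; sites fixed in the finite pool are
#' redrawn so every SNP segregates. SNP map positions are uniform on the
#' chromosome and sorted.
#'
#' @param model A [founder_model()].
#' @param n_haplotypes Number of founder haplotypes in the pool.
#' @param seed Integer seed.
#' @return A list of class `haplotype_pool`: `haplotypes` (matrix
#'   `n_haplotypes` x `n_snps` of 0/1), `freq` (pool frequency of allele
#'   1 per SNP), `target_freq` (sfs mode only), `map` (tibble with `snp`,
#'   `chrom`, `pos_cM`) and `model`.
#' @export
simulate_founder_haplotypes <- function(model, n_haplotypes, seed) {
  stopifnot(inherits(model, "founder_model"), n_haplotypes >= 2)
  set.seed(as.integer(seed))
  n_snps <- model$n_snps
  target <- NULL
  if (model$mode == "coalescent") {
    epoch_gens <- model$epoch_years / model$generation_years
    n_chunks <- max(1L, ceiling(model$seq_length_bp / model$chunk_length_bp))
    lens <- rep(model$seq_length_bp / n_chunks, n_chunks)
    carriers <- list()
    freq_all <- numeric(0)
    for (ch in seq_len(n_chunks)) {
      sim <- sim_coalescent_chunk(n_haplotypes, lens[ch], model$mutation_rate,
                                  epoch_gens, model$epoch_sizes)
      carriers <- c(carriers, sim$carriers)
      freq_all <- c(freq_all, sim$freq)
    }
    if (length(carriers) < n_snps) {
      stop("coalescent simulation produced ", length(carriers),
           " segregating sites, fewer than n_snps = ", n_snps,
           "; increase seq_length_bp", call. = FALSE)
    }
    keep <- sample.int(length(carriers), n_snps)
    H <- matrix(0L, n_haplotypes, n_snps)
    for (j in seq_len(n_snps)) H[carriers[[keep[j]]], j] <- 1L
    freq <- freq_all[keep]
  } else {
    target <- if (!is.null(model$sfs_freq)) {
      rep_len(model$sfs_freq, n_snps)
    } else {
      stats::rbeta(n_snps, model$sfs_shape, model$sfs_shape)
    }
    H <- matrix(stats::rbinom(n_haplotypes * n_snps, 1L,
                              rep(target, each = n_haplotypes)),
                n_haplotypes, n_snps)
    # redraw sites fixed in the finite pool so every SNP segregates
    repeat {
      cs <- colSums(H)
      bad <- which(cs == 0L | cs == n_haplotypes)
      if (!length(bad)) break
      if (is.null(model$sfs_freq)) {
        target[bad] <- stats::rbeta(length(bad), model$sfs_shape, model$sfs_shape)
      }
      H[, bad] <- stats::rbinom(n_haplotypes * length(bad), 1L,
                                rep(target[bad], each = n_haplotypes))
    }
    freq <- colSums(H) / n_haplotypes
  }
  map <- tibble::tibble(
    snp = paste0("snp", seq_len(n_snps)),
    chrom = "1",
    pos_cM = sort(stats::runif(n_snps, 0, model$chrom_length_cM))
  )
  attr(map, "length_cM") <- model$chrom_length_cM
  structure(list(haplotypes = H, freq = freq, target_freq = target,
                 map = map, model = model),
            class = "haplotype_pool")
}

# Transmit one recombinant gamete: Haldane model, crossover count Poisson
# with mean length_cM/100, fair-coin starting strand.
transmit_gamete <- function(hap1, hap2, pos_cM, length_cM) {
  n_xo <- stats::rpois(1L, length_cM / 100)
  xo <- if (n_xo > 0) sort(stats::runif(n_xo, 0, length_cM)) else numeric(0)
  start <- sample.int(2L, 1L)
  strand <- (start + findInterval(pos_cM, xo)) %% 2L
  gam <- ifelse(strand == 0L, hap1, hap2)
  list(gamete = gam, crossovers = xo, start = start)
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive two haplotypes from the pool (without replacement while
#' the pool lasts, then with replacement); every non-founder receives one
#' recombinant gamete per parent, with crossovers from a Poisson process at
#' one event per 100 cM (Haldane, no interference) and a fair-coin starting
#' strand. An unknown parent of a non-founder transmits a recombinant of
#' two fresh pool haplotypes.
#'
#' @param ped A pedigree.
#' @param pool A [simulate_founder_haplotypes()] pool.
#' @param map Genetic map tibble (defaults to the pool's map).
#' @param seed Integer seed.
#' @return A list of class `true_genotypes`: `genotypes` (individuals x
#'   SNPs, 0/1/2, rownames are ids), `paternal`/`maternal` (gamete
#'   matrices), `crossovers` (per individual, crossover positions and
#'   starting strand per gamete) and `map`.
#' @export
gene_drop <- function(ped, pool, map = pool$map, seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(pool, "haplotype_pool"))
  if (is.null(map) || nrow(map) == 0L) stop("empty genetic map", call. = FALSE)
  set.seed(as.integer(seed))
  H <- pool$haplotypes
  n_hap <- nrow(H)
  n_snp <- ncol(H)
  stopifnot(nrow(map) == n_snp)
  pos <- map$pos_cM
  len <- attr(map, "length_cM")
  if (is.null(len)) len <- max(pos)

  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  is_founder <- is.na(si) & is.na(di)
  n_draw <- 2L * sum(is_founder)
  draws <- if (n_draw <= n_hap) sample.int(n_hap, n_draw) else
    sample.int(n_hap, n_draw, replace = TRUE)
  pat <- matrix(0L, n, n_snp)
  mat <- matrix(0L, n, n_snp)
  xo <- vector("list", n)
  fi <- 0L
  for (i in seq_len(n)) {
    if (is_founder[i]) {
      pat[i, ] <- H[draws[2L * fi + 1L], ]
      mat[i, ] <- H[draws[2L * fi + 2L], ]
      fi <- fi + 1L
      xo[[i]] <- list(paternal = NULL, maternal = NULL)
    } else {
      tp <- if (!is.na(si[i])) {
        transmit_gamete(pat[si[i], ], mat[si[i], ], pos, len)
      } else {
        ex <- sample.int(n_hap, 2L)
        transmit_gamete(H[ex[1L], ], H[ex[2L], ], pos, len)
      }
      tm <- if (!is.na(di[i])) {
        transmit_gamete(pat[di[i], ], mat[di[i], ], pos, len)
      } else {
        ex <- sample.int(n_hap, 2L)
        transmit_gamete(H[ex[1L], ], H[ex[2L], ], pos, len)
      }
      pat[i, ] <- tp$gamete
      mat[i, ] <- tm$gamete
      xo[[i]] <- list(paternal = tp[c("crossovers", "start")],
                      maternal = tm[c("crossovers", "start")])
    }
  }
  geno <- pat + mat
  rownames(geno) <- rownames(pat) <- rownames(mat) <- ped$id
  colnames(geno) <- colnames(pat) <- colnames(mat) <- map$snp
  names(xo) <- ped$id
  structure(list(genotypes = geno, paternal = pat, maternal = mat,
                 crossovers = xo, map = map),
            class = "true_genotypes")
}

#' Mask genotypes according to a scenario
#'
#' Individuals outside the scenario's genotyped set have all their
#' genotypes set to missing (`NA`); genotyped individuals keep complete
#' genotypes.
#'
#' @param true_g A `true_genotypes` object or a genotype matrix with id
#'   rownames.
#' @param spec A [scenario_spec()].
#' @return The observed genotype matrix with masked rows `NA`.
#' @export
apply_scenario <- function(true_g, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  G <- if (inherits(true_g, "true_genotypes")) true_g$genotypes else true_g
  stopifnot(is.matrix(G), !is.null(rownames(G)))
  miss <- setdiff(spec$genotyped_ids, rownames(G))
  if (length(miss)) {
    stop("scenario id not in genotype matrix: ", miss[1L], call. = FALSE)
  }
  obs <- G
  obs[!(rownames(G) %in% spec$genotyped_ids), ] <- NA_integer_
  obs
}
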