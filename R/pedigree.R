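#' Construct a validated pedigree
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam` and optionally
#' `sex`, topologically sorted so that every parent appears before any of its
#' offspring. Unknown parents are `NA`. Individuals that are referenced as a
#' sire or dam but have no row of their own are appended as founders.
#'
#' @param x A data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`. In `sire`/`dam`, `NA`, `""` or `"0"` denote an unknown parent.
#' @return A tibble of class `pedigree` with columns `id`, `sire`, `dam`,
#'   `sex` (character; `sex` is `"male"`, `"female"` or `NA`), in
#'   topological order.
#' @details Cycles (an individual that is its own ancestor) and duplicated
#'   ids are hard errors. Sexes are reconciled with parental roles: an
#'   individual used as a sire is male, as a dam female; a conflict is an
#'   error.
#' @examples
#' ped <- as_pedigree(data.frame(id = "C", sire = "A", dam = "B"))
#' ped$id # A and B appended as founders, ahead of C
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "sire", "dam") %in% names(x)))
  id <- as.character(x$id)
  sire <- normalize_parent(x$sire)
  dam <- normalize_parent(x$dam)
  if (anyNA(id) || any(!nzchar(id))) {
    stop("pedigree ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicated pedigree id: ", id[duplicated(id)][1L], call. = FALSE)
  }
  sex <- if ("sex" %in% names(x)) normalize_sex(x$sex) else rep(NA_character_, length(id))

  # append parents that never occur as individuals, as founders
  parents <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(parents)) {
    id <- c(id, parents)
    psex <- ifelse(parents %in% sire, "male", "female")
    sire <- c(sire, rep(NA_character_, length(parents)))
    dam <- c(dam, rep(NA_character_, length(parents)))
    sex <- c(sex, psex)
  }
  sex <- reconcile_sex(id, sire, dam, sex)

  ord <- topological_order(id, sire, dam)
  ped <- tibble::tibble(id = id[ord], sire = sire[ord], dam = dam[ord], sex = sex[ord])
  class(ped) <- c("pedigree", class(ped))
  ped
}

normalize_parent <- function(p) {
  p <- as.character(p)
  p[is.na(p) | p %in% c("0", "")] <- NA_character_
  p
}

normalize_sex <- function(s) {
  s <- tolower(as.character(s))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "1")] <- "male"
  out[s %in% c("f", "female", "2")] <- "female"
  out
}

reconcile_sex <- function(id, sire, dam, sex) {
  as_sire <- id %in% sire
  as_dam <- id %in% dam
  conflict <- (as_sire & as_dam) |
    (as_sire & !is.na(sex) & sex == "female") |
    (as_dam & !is.na(sex) & sex == "male")
  if (any(conflict)) {
    stop("individual used as both sire and dam (or sex conflict): ",
         id[conflict][1L], call. = FALSE)
  }
  sex[as_sire] <- "male"
  sex[as_dam] <- "female"
  sex
}

# Kahn's algorithm; returns a permutation placing parents first, or errors
# naming an individual on a cycle.
topological_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) {
      if (!is.na(p)) {
        indeg[k] <- indeg[k] + 1L
        children[[p]] <- c(children[[p]], k)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree cycle involving individual: ", id[setdiff(seq_len(n), ord)][1L],
         call. = FALSE)
  }
  ord
}

#' Read a pedigree file
#'
#' Reads a whitespace- or comma-delimited text file with columns id, sire,
#' dam and optionally sex. The token `0` denotes an unknown parent; lines
#' starting with `#` are comments.
#'
#' @param path Path to the pedigree file.
#' @return A [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty pedigree file: ", path, call. = FALSE)
  fields <- strsplit(lines, "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("pedigree rows need at least 3 fields (id sire dam)", call. = FALSE)
  }
  df <- data.frame(
    id = vapply(fields, `[`, "", 1L),
    sire = vapply(fields, `[`, "", 2L),
    dam = vapply(fields, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (all(nf >= 4L)) df$sex <- vapply(fields, `[`, "", 4L)
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped A pedigree.
#' @param path Output path. Unknown parents are written as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- cbind(ped$id,
               ifelse(is.na(ped$sire), "0", ped$sire),
               ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

ped_index <- function(ped, ids) {
  pos <- match(ids, ped$id)
  if (anyNA(pos)) {
    stop("id not in pedigree: ", ids[is.na(pos)][1L], call. = FALSE)
  }
  pos
}

#' Additive (numerator) relationship between two individuals
#'
#' Twice the coefficient of kinship, computed by the recursive (memoised)
#' tabular rules with unknown parents treated as unrelated, non-inbred
#' founders. Inbreeding accumulates through the recursion; the
#' self-relationship of individual i is 1 + F_i.
#'
#' @param ped A pedigree.
#' @param a_id,b_id Individual ids.
#' @return The additive relationship, a number in `[0, 2]`.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("A", "B", "C"),
#'                               sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
#' additive_relationship(ped, "A", "C") # parent-offspring: 0.5
#' @export
additive_relationship <- function(ped, a_id, b_id) {
  stopifnot(inherits(ped, "pedigree"))
  i <- ped_index(ped, a_id)
  j <- ped_index(ped, b_id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  2 * kinship_rec(i, j, si, di, cache)
}

kinship_rec <- function(i, j, si, di, cache) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  key <- paste0(i, "|", j)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  if (i == j) {
    f <- if (is.na(si[i]) || is.na(di[i])) 0.5 else
      0.5 * (1 + kinship_rec(si[i], di[i], si, di, cache))
  } else {
    # j is later in topological order, so i is not a descendant of j
    f <- 0
    if (!is.na(si[j])) f <- f + 0.5 * kinship_rec(i, si[j], si, di, cache)
    if (!is.na(di[j])) f <- f + 0.5 * kinship_rec(i, di[j], si, di, cache)
  }
  cache[[key]] <- f
  f
}

#' Additive relationship matrix for a subset of individuals
#'
#' @param ped A pedigree.
#' @param ids Ids to include; the result has these as dimnames, in order.
#' @return A symmetric matrix of additive relationships with `1 + F` on the
#'   diagonal.
#' @export
relationship_matrix <- function(ped, ids) {
  stopifnot(inherits(ped, "pedigree"))
  pos <- ped_index(ped, ids)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n <- length(pos)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in a:n) {
      A[a, b] <- A[b, a] <- 2 * kinship_rec(pos[a], pos[b], si, di, cache)
    }
  }
  A
}

relative_category_levels <- c("BothParents", "SireMGS", "DamPGS",
                              "Sire", "Dam", "Other")

#' Classify test individuals by their most recent genotyped ancestors
#'
#' Each non-genotyped individual falls into exactly one category, checked in
#' this precedence order: both parents genotyped (`BothParents`); sire and
#' maternal grandsire genotyped, dam not (`SireMGS`); dam and paternal
#' grandsire genotyped, sire not (`DamPGS`); only the sire (`Sire`); only
#' the dam (`Dam`); anything else (`Other`).
#'
#' @param ped A pedigree.
#' @param genotyped Character vector of genotyped ids (the reference set).
#' @param ids Ids to classify; must not be in `genotyped`.
#' @return A factor with levels `BothParents`, `SireMGS`, `DamPGS`, `Sire`,
#'   `Dam`, `Other`, one per element of `ids`.
#' @export
classify_relatives <- function(ped, genotyped, ids) {
  stopifnot(inherits(ped, "pedigree"))
  if (any(ids %in% genotyped)) {
    stop("cannot classify a genotyped individual: ",
         intersect(ids, genotyped)[1L], call. = FALSE)
  }
  pos <- ped_index(ped, ids)
  sire <- ped$sire[pos]
  dam <- ped$dam[pos]
  mgs <- ped$sire[match(dam, ped$id)]   # maternal grandsire: dam's sire
  pgs <- ped$sire[match(sire, ped$id)]  # paternal grandsire: sire's sire
  g <- function(x) !is.na(x) & x %in% genotyped
  out <- rep("Other", length(ids))
  out[g(dam)] <- "Dam"
  out[g(sire)] <- "Sire"
  out[g(dam) & !g(sire) & g(pgs)] <- "DamPGS"
  out[g(sire) & !g(dam) & g(mgs)] <- "SireMGS"
  out[g(sire) & g(dam)] <- "BothParents"
  factor(out, levels = relative_category_levels)
}
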