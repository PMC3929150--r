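#' Read and write AlphaImpute-style genotype matrices
#'
#' One row per individual: the id followed by one code per SNP, whitespace
#' delimited. Codes are 0/1/2 with 9 for missing.
#'
#' @param path File path.
#' @param x Genotype matrix with id rownames; `NA` is written as 9.
#' @return `read_genotypes()` returns an integer matrix with id rownames;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  G <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  G[G == 9L] <- NA_integer_
  dimnames(G) <- list(ids, paste0("snp", seq_len(ncol(G))))
  G
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  out <- x
  out[is.na(out)] <- 9L
  utils::write.table(cbind(rownames(x), out), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write genotype dosage matrices
#'
#' Same layout as genotype files but with decimal dosages in `[0, 2]`.
#'
#' @param path File path.
#' @param x Dosage matrix with id rownames.
#' @return `read_dosages()` returns a numeric matrix; `write_dosages()`
#'   returns `path` invisibly.
#' @export
read_dosages <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(D) <- list(as.character(df[[1L]]), paste0("snp", seq_len(ncol(D))))
  D
}

#' @rdname read_dosages
#' @export
write_dosages <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  utils::write.table(cbind(rownames(x), formatC(x, format = "g", digits = 10)),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write genetic map files
#'
#' Three whitespace-delimited columns: SNP id, chromosome, position in cM.
#'
#' @param path File path.
#' @param map Map tibble with columns `snp`, `chrom`, `pos_cM`.
#' @param length_cM Chromosome length stored on the map attribute when
#'   reading (defaults to the largest position).
#' @return `read_map()` returns the map tibble; `write_map()` returns
#'   `path` invisibly.
#' @export
read_map <- function(path, length_cM = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("snp", "chrom", "pos_cM"))
  map <- tibble::as_tibble(df)
  if (is.unsorted(map$pos_cM)) stop("map positions must be non-decreasing",
                                    call. = FALSE)
  attr(map, "length_cM") <- length_cM %||% max(map$pos_cM)
  map
}

#' @rdname read_map
#' @export
write_map <- function(map, path) {
  utils::write.table(map[, c("snp", "chrom", "pos_cM")], path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-SNP allele frequency table
#'
#' @param freq Named or unnamed numeric vector of allele-1 frequencies.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freq, path) {
  snp <- names(freq) %||% paste0("snp", seq_along(freq))
  utils::write.table(data.frame(snp = snp, freq = freq), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
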