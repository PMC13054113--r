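#' Write genotypes in the single-line-per-animal layout
#'
#' One line per animal: the ID, whitespace, then a contiguous string of
#' per-marker codes `{0,1,2,5}` (5 = missing), the layout used by the
#' BLUPF90 family of programs.
#'
#' @param g a [genotype_matrix()].
#' @param path output genotype file.
#' @param map_path optional path for a companion SNP map CSV
#'   (`snp,chrom,pos`).
#' @export
write_genotypes <- function(g, path, map_path = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  lines <- paste(g$animal_ids,
                 apply(g$codes, 1, paste, collapse = ""))
  writeLines(lines, path)
  if (!is.null(map_path))
    utils::write.csv(g$map, map_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from the single-line-per-animal layout
#'
#' @param path genotype file as written by [write_genotypes()].
#' @param map_path optional SNP map CSV; a default map is synthesised when
#'   absent.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, map_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1)
  strs <- vapply(parts, `[[`, character(1), 2)
  widths <- nchar(strs)
  if (length(unique(widths)) != 1)
    stop("genotype rows have unequal marker counts")
  codes <- matrix(as.integer(unlist(strsplit(strs, ""))),
                  nrow = length(ids), byrow = TRUE)
  map <- if (!is.null(map_path)) utils::read.csv(map_path, colClasses = c(
    snp = "character", chrom = "character", pos = "integer")) else NULL
  snp_ids <- if (!is.null(map)) map$snp else sprintf("SNP%05d", seq_len(widths[1]))
  genotype_matrix(ids, snp_ids, codes, map = map)
}

#' Write a phenotype table to CSV
#' @param phenos data.frame.
#' @param path output file.
#' @export
write_phenotypes <- function(phenos, path) {
  utils::write.csv(phenos, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#' @param path CSV file.
#' @return data.frame with `animal` as character.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$animal <- as.character(df$animal)
  df
}

#' Write a symmetric matrix as `i j value` triplets
#'
#' Only the lower triangle (including the diagonal) is written; zero
#' entries of sparse matrices are skipped.
#'
#' @param M dense or sparse symmetric matrix.
#' @param path output text file.
#' @export
write_triplet <- function(M, path) {
  if (methods::is(M, "sparseMatrix")) {
    T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    i <- T@i + 1L; j <- T@j + 1L; x <- T@x
    keep <- i >= j
    df <- data.frame(i = i[keep], j = j[keep], value = x[keep])
  } else {
    M <- as.matrix(M)
    idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], value = M[idx])
    df <- df[df$value != 0, ]
  }
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an `i j value` triplet file into a dense symmetric matrix
#' @param path triplet text file.
#' @param n matrix order (inferred from the indices when omitted).
#' @return dense symmetric matrix.
#' @export
read_triplet <- function(path, n = NULL) {
  df <- utils::read.table(path, col.names = c("i", "j", "value"))
  if (is.null(n)) n <- max(df$i, df$j)
  M <- matrix(0, n, n)
  M[cbind(df$i, df$j)] <- df$value
  M[cbind(df$j, df$i)] <- df$value
  M
}
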