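#' Construct a pedigree object
#'
#' Builds a topologically sorted pedigree (parents before offspring) from
#' animal/sire/dam identifier vectors.  Unknown parents are coded `0`, `NA`
#' or `""`.  Parent identifiers that never appear as animals are appended as
#' founders with a warning.  Self-ancestry (cycles) is a hard error.
#'
#' @param animal vector of unique animal identifiers.
#' @param sire,dam parent identifiers aligned with `animal`.
#' @param sex optional per-animal sex, `"M"`/`"F"`.
#' @param birth_year optional per-animal integer birth year.
#' @param generation optional per-animal discrete generation number.
#' @return An object of class `pedigree`: a list with `animal_ids` (in sorted
#'   storage order), integer parent positions `sire_index`/`dam_index`
#'   (0 = unknown), and any of the optional columns, reordered accordingly.
#' @export
new_pedigree <- function(animal, sire, dam, sex = NULL, birth_year = NULL,
                         generation = NULL) {
  animal <- as.character(animal)
  if (anyDuplicated(animal)) stop("animal identifiers must be unique")
  n <- length(animal)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "0" | p == ""] <- NA_character_
    p
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("animal listed as its own parent: ",
         animal[which(sire == animal | dam == animal)[1]])

  extra <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), animal)
  if (length(extra)) {
    warning(length(extra), " parent id(s) absent from the file; treated as founders")
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    pad <- function(x) if (is.null(x)) NULL else c(x, rep(NA, length(extra)))
    sex <- pad(sex); birth_year <- pad(birth_year); generation <- pad(generation)
    n <- length(animal)
  }

  pos <- seq_len(n)
  names(pos) <- animal
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])

  # Kahn's algorithm for a parent-first order; leftovers indicate a cycle
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(animal[setdiff(seq_len(n), order)], 5), collapse = ", "))

  rank <- integer(n); rank[order] <- seq_len(n)
  remap <- function(ix) ifelse(ix == 0L, 0L, rank[pmax(ix, 1L)])
  ped <- structure(list(
    animal_ids = animal[order],
    sire_index = as.integer(remap(si)[order]),
    dam_index = as.integer(remap(di)[order]),
    inbreeding = NULL
  ), class = "pedigree")
  if (!is.null(sex)) ped$sex <- sex[order]
  if (!is.null(birth_year)) ped$birth_year <- as.integer(birth_year)[order]
  if (!is.null(generation)) ped$generation <- as.integer(generation)[order]
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", length(x$animal_ids), " animals, ",
      sum(x$sire_index == 0L & x$dam_index == 0L), " founders",
      if (!is.null(x$inbreeding))
        sprintf(", mean F = %.4g", mean(x$inbreeding)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of animals in a pedigree
#' @param ped a `pedigree`.
#' @return integer count.
#' @export
n_animals <- function(ped) length(ped$animal_ids)

#' Read a pedigree from a 3-column CSV
#'
#' Expects columns `animal,sire,dam` with `0` for unknown parents, in any row
#' order; the result is sorted parents-first.
#'
#' @param path CSV file path.
#' @return a [new_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 3) stop("pedigree file needs at least 3 columns (animal,sire,dam)")
  new_pedigree(df[[1]], df[[2]], df[[3]],
               sex = if ("sex" %in% names(df)) df$sex else NULL,
               birth_year = if ("birth_year" %in% names(df)) df$birth_year else NULL)
}

#' Write a pedigree to CSV
#' @param ped a `pedigree`.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  id <- ped$animal_ids
  par <- function(ix) ifelse(ix == 0L, "0", id[pmax(ix, 1L)])
  df <- data.frame(animal = id, sire = par(ped$sire_index),
                   dam = par(ped$dam_index), stringsAsFactors = FALSE)
  if (!is.null(ped$sex)) df$sex <- ped$sex
  if (!is.null(ped$birth_year)) df$birth_year <- ped$birth_year
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo recursion)
#'
#' Computes F for every animal by the Meuwissen & Luo ancestor-traversal
#' form of the tabular diagonal, which scales to very large pedigrees.
#'
#' @param ped a `pedigree`.
#' @return the pedigree with `$inbreeding` filled in.
#' @export
compute_inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$inbreeding <- inbreeding_ml_cpp(ped$sire_index, ped$dam_index)
  ped
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Row-recursive tabular construction: `A[i,j] = 0.5 (A[j,s] + A[j,d])` for
#' `j < i` and `A[i,i] = 1 + 0.5 A[s,d]`.  Quadratic in pedigree size; meant
#' for moderate pedigrees and as the reference for the sparse inverse.
#'
#' @param ped a `pedigree`.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  n <- n_animals(ped)
  A <- matrix(0, n, n)
  s <- ped$sire_index; d <- ped$dam_index
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (si > 0L) A[j, si] else numeric(i - 1L)
      ad_ <- if (di > 0L) A[j, di] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  dimnames(A) <- list(ped$animal_ids, ped$animal_ids)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: animal i contributes
#' `1/b_i` to (i,i), `-0.5/b_i` to (i,parent) and `0.25/b_i` to the
#' parent-parent cells, where `b_i` is the Mendelian-sampling variance
#' `0.5 - 0.25 (F_s + F_d)` (adjusted for unknown parents).
#'
#' @param ped a `pedigree`; inbreeding is computed if absent.
#' @return a symmetric sparse `Matrix::dgCMatrix`.
#' @export
build_A_inverse <- function(ped) {
  if (is.null(ped$inbreeding)) ped <- compute_inbreeding(ped)
  n <- n_animals(ped)
  s <- ped$sire_index; d <- ped$dam_index; F <- ped$inbreeding
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
  b <- 0.5 - 0.25 * (Fs + Fd)          # F = -1 convention for unknown parent
  alpha <- 1 / b
  ii <- list(seq_len(n)); jj <- list(seq_len(n)); xx <- list(alpha)
  add <- function(i, j, x) {
    ii[[length(ii) + 1]] <<- i; jj[[length(jj) + 1]] <<- j
    xx[[length(xx) + 1]] <<- x
  }
  hs <- which(s > 0L); hd <- which(d > 0L); hb <- which(s > 0L & d > 0L)
  if (length(hs)) {
    add(hs, s[hs], -0.5 * alpha[hs]); add(s[hs], hs, -0.5 * alpha[hs])
    add(s[hs], s[hs], 0.25 * alpha[hs])
  }
  if (length(hd)) {
    add(hd, d[hd], -0.5 * alpha[hd]); add(d[hd], hd, -0.5 * alpha[hd])
    add(d[hd], d[hd], 0.25 * alpha[hd])
  }
  if (length(hb)) {
    add(s[hb], d[hb], 0.25 * alpha[hb]); add(d[hb], s[hb], 0.25 * alpha[hb])
  }
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n),
                            dimnames = list(ped$animal_ids, ped$animal_ids))
  methods::as(M, "generalMatrix")
}

#' Restrict a pedigree to a subset of animals and all their ancestors
#' @param ped a `pedigree`.
#' @param ids animal identifiers to keep (with ancestors).
#' @return a pruned, still sorted `pedigree`.
#' @export
prune_to_ancestors <- function(ped, ids) {
  pos <- match(as.character(ids), ped$animal_ids)
  if (anyNA(pos)) stop("unknown animal id(s): ",
                       paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  keep <- logical(n_animals(ped))
  keep[pos] <- TRUE
  for (i in rev(seq_len(n_animals(ped)))) {
    if (keep[i]) {
      if (ped$sire_index[i] > 0L) keep[ped$sire_index[i]] <- TRUE
      if (ped$dam_index[i] > 0L) keep[ped$dam_index[i]] <- TRUE
    }
  }
  old <- which(keep)
  rank <- integer(n_animals(ped)); rank[old] <- seq_along(old)
  remap <- function(ix) ifelse(ix == 0L, 0L, rank[pmax(ix, 1L)])
  out <- structure(list(
    animal_ids = ped$animal_ids[old],
    sire_index = as.integer(remap(ped$sire_index[old])),
    dam_index = as.integer(remap(ped$dam_index[old])),
    inbreeding = ped$inbreeding[old]
  ), class = "pedigree")
  for (f in c("sex", "birth_year", "generation"))
    if (!is.null(ped[[f]])) out[[f]] <- ped[[f]][old]
  out
}

#' Pedigree relationships among genotyped animals (A22)
#'
#' The genotyped-by-genotyped block of the full A, computed on the pedigree
#' restricted to the genotyped animals and their ancestors (the block is
#' unchanged by dropping non-ancestors).  Small problems use the dense
#' tabular method; larger ones use Colleau's indirect method (A times
#' indicator vectors through the gene-flow decomposition `A = T D T'`),
#' which never forms A.
#'
#' @param ped a `pedigree`.
#' @param genotyped_ids identifiers of genotyped animals.
#' @param method `"auto"`, `"tabular"` or `"colleau"`.
#' @return dense symmetric matrix in the order of `genotyped_ids`.
#' @export
build_A22 <- function(ped, genotyped_ids,
                      method = c("auto", "tabular", "colleau")) {
  method <- match.arg(method)
  genotyped_ids <- as.character(genotyped_ids)
  sub <- prune_to_ancestors(ped, genotyped_ids)
  if (method == "auto")
    method <- if (n_animals(sub) > 1500L) "colleau" else "tabular"
  if (method == "tabular") {
    A <- build_A(sub)
    return(A[genotyped_ids, genotyped_ids, drop = FALSE])
  }
  if (is.null(sub$inbreeding)) sub <- compute_inbreeding(sub)
  idx <- match(genotyped_ids, sub$animal_ids)
  V <- matrix(0, n_animals(sub), length(idx))
  V[cbind(idx, seq_along(idx))] <- 1
  AV <- A_times_cpp(sub$sire_index, sub$dam_index, sub$inbreeding, V)
  A22 <- AV[idx, , drop = FALSE]
  A22 <- (A22 + t(A22)) / 2               # exact up to rounding; symmetrise
  dimnames(A22) <- list(genotyped_ids, genotyped_ids)
  A22
}
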