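#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z'` with `Z = (M - P) / sqrt(2 sum_j p_j (1 - p_j))`, where `M`
#' holds allele counts and `P = 2 p_j` per column.  Missing codes (5) are
#' replaced by `2 p_j`, i.e. zero after centring (mean imputation).
#'
#' @param g a [genotype_matrix()] (post-QC).
#' @param p allele frequencies; defaults to [allele_frequencies()] of `g`.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_G <- function(g, p = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(p)) p <- allele_frequencies(g)
  stopifnot(length(p) == length(g$snp_ids))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("sum of 2p(1-p) is zero; no polymorphic markers")
  M <- g$codes
  storage.mode(M) <- "double"
  miss <- M == 5
  if (any(miss)) M[miss] <- rep(2 * p, each = nrow(M))[miss]
  Z <- sweep(M, 2, 2 * p)
  tcrossprod(Z) / denom
}

#' Rescale G to align with the pedigree relationships of genotyped animals
#'
#' Finds scalars `a`, `b` such that `a + b G` matches `A22` in both mean
#' diagonal and mean off-diagonal, and returns the adjusted matrix.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationships among the same animals, same order.
#' @return tuned matrix `a + b G`, with `a`, `b` in attribute `"tuning"`.
#' @export
tune_G <- function(G, A22) {
  stopifnot(all(dim(G) == dim(A22)))
  n <- nrow(G)
  md <- function(M) mean(diag(M))
  mo <- function(M) if (n == 1) 0 else (sum(M) - sum(diag(M))) / (n * (n - 1))
  X <- rbind(c(1, md(G)), c(1, mo(G)))
  if (abs(det(X)) < 1e-12)
    stop("tuning system is singular: G has equal mean diagonal and off-diagonal")
  ab <- solve(X, c(md(A22), mo(A22)))
  out <- ab[1] + ab[2] * G
  attr(out, "tuning") <- c(a = ab[1], b = ab[2])
  out
}

#' Blend G with A22
#'
#' `tau * G + (1 - tau) * A22`; with the default `tau = 0.95` this folds 5%
#' of the pedigree relationships into G to guarantee invertibility.
#'
#' @param G genomic relationship matrix (typically already tuned).
#' @param A22 pedigree relationships, same order.
#' @param tau weight on G in [0, 1].
#' @return blended matrix.
#' @export
blend_G <- function(G, A22, tau = 0.95) {
  if (!all(dim(G) == dim(A22))) stop("G and A22 dimensions differ")
  stopifnot(tau >= 0, tau <= 1)
  tau * G + (1 - tau) * A22
}

#' APY inverse of a genomic relationship matrix
#'
#' Algorithm for proven and young: with a core/non-core split, the sparse
#' inverse is built from the dense inverse of the core block plus a diagonal
#' of conditional (Mendelian-sampling-like) variances
#' `m_ii = g_ii - g_ic Gcc^-1 g_ci` for non-core animals.  Matrix-vector
#' products never densify the full inverse.
#'
#' @param G genomic relationship matrix with dimnames.
#' @param core_ids identifiers (or indices) of core animals.
#' @return object of class `apy_inverse` with the core/non-core blocks.
#' @export
apy_inverse <- function(G, core_ids) {
  ids <- rownames(G)
  core <- if (is.character(core_ids)) match(core_ids, ids) else as.integer(core_ids)
  if (anyNA(core) || !length(core)) stop("invalid core ids")
  core <- sort(unique(core))
  noncore <- setdiff(seq_len(nrow(G)), core)
  Gcc_inv <- tryCatch(chol2inv(chol(G[core, core, drop = FALSE])),
                      error = function(e) stop("core block of G is not positive definite"))
  Gcn <- G[core, noncore, drop = FALSE]
  W <- Gcc_inv %*% Gcn                       # Gcc^-1 Gcn
  m <- diag(G)[noncore] - colSums(Gcn * W)
  if (length(m) && any(m <= 0))
    stop("non-positive APY conditional variance; enlarge the core")
  structure(list(core = core, noncore = noncore, ids = ids,
                 Gcc_inv = Gcc_inv, W = W, minv = 1 / m, n = nrow(G)),
            class = "apy_inverse")
}

#' Multiply an APY inverse by a vector
#' @param op an `apy_inverse`.
#' @param v numeric vector in the original animal order of G.
#' @return `G^-1_APY %*% v`.
#' @export
apy_matvec <- function(op, v) {
  stopifnot(length(v) == op$n)
  vc <- v[op$core]; vn <- v[op$noncore]
  out <- numeric(op$n)
  if (length(op$noncore)) {
    s <- op$minv * (vn - drop(crossprod(op$W, vc)))
    out[op$core] <- drop(op$Gcc_inv %*% vc) - drop(op$W %*% (op$minv * vn)) +
      drop(op$W %*% (op$minv * drop(crossprod(op$W, vc))))
    out[op$noncore] <- s
  } else {
    out[op$core] <- drop(op$Gcc_inv %*% vc)
  }
  out
}

#' @export
as.matrix.apy_inverse <- function(x, ...) {
  out <- vapply(seq_len(x$n), function(j) {
    v <- numeric(x$n); v[j] <- 1
    apy_matvec(x, v)
  }, numeric(x$n))
  dimnames(out) <- list(x$ids, x$ids)
  out
}

#' Assemble the single-step H-inverse operator
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` on the genotyped block.  The
#' genomic inverse is either the dense inverse of the (tuned, blended) G or
#' its APY factorization.
#'
#' @param A_inv sparse A-inverse from [build_A_inverse()].
#' @param A22 pedigree relationships among genotyped animals.
#' @param G_final final (tuned, blended) genomic relationship matrix with
#'   genotyped ids as dimnames.
#' @param mode `"direct"` dense inversion or `"apy"`.
#' @param core_ids core animals for APY mode (default: all genotyped).
#' @return object of class `h_inverse`: the A-inverse, genotyped positions,
#'   and the genotyped-block adjustment, supporting [h_matvec()],
#'   [h_diag()] and `as.matrix()`.
#' @export
assemble_H_inverse <- function(A_inv, A22, G_final, mode = c("direct", "apy"),
                               core_ids = NULL) {
  mode <- match.arg(mode)
  ids <- rownames(A_inv)
  gids <- rownames(G_final)
  if (is.null(gids)) stop("G_final must carry animal ids as dimnames")
  idx <- match(gids, ids)
  if (anyNA(idx))
    stop("genotyped animal(s) absent from the pedigree: ",
         paste(utils::head(gids[is.na(idx)], 5), collapse = ", "))
  A22_inv <- if (length(gids)) solve(A22) else matrix(0, 0, 0)
  if (mode == "direct") {
    G_inv <- if (length(gids)) chol2inv(chol(G_final)) else matrix(0, 0, 0)
    diff <- G_inv - A22_inv
    apy <- NULL
  } else {
    if (is.null(core_ids)) core_ids <- gids
    apy <- apy_inverse(G_final, core_ids)
    diff <- NULL
  }
  structure(list(A_inv = A_inv, idx = idx, ids = ids, gids = gids,
                 A22_inv = A22_inv, diff = diff, apy = apy, mode = mode),
            class = "h_inverse")
}

#' Multiply the H-inverse operator by a vector
#' @param h an `h_inverse`.
#' @param v numeric vector over all pedigree animals (A-inverse order).
#' @return `H^-1 %*% v`.
#' @export
h_matvec <- function(h, v) {
  out <- as.numeric(h$A_inv %*% v)
  if (length(h$idx)) {
    vg <- v[h$idx]
    adj <- if (h$mode == "direct") drop(h$diff %*% vg)
           else apy_matvec(h$apy, vg) - drop(h$A22_inv %*% vg)
    out[h$idx] <- out[h$idx] + adj
  }
  out
}

#' Diagonal of the H-inverse operator
#' @param h an `h_inverse`.
#' @return numeric vector, used e.g. as a PCG preconditioner.
#' @export
h_diag <- function(h) {
  d <- Matrix::diag(h$A_inv)
  if (length(h$idx)) {
    dd <- if (h$mode == "direct") diag(h$diff)
          else diag(as.matrix(h$apy)) - diag(h$A22_inv)
    d[h$idx] <- d[h$idx] + dd
  }
  d
}

#' @export
as.matrix.h_inverse <- function(x, ...) {
  out <- as.matrix(x$A_inv)
  if (length(x$idx)) {
    adj <- if (x$mode == "direct") x$diff else as.matrix(x$apy) - x$A22_inv
    out[x$idx, x$idx] <- out[x$idx, x$idx] + adj
  }
  out
}

#' H-inverse as a sparse matrix
#'
#' Folds the genotyped-block adjustment into the sparse A-inverse; used by
#' the Gibbs sampler, which wants compressed-column access.
#'
#' @param h an `h_inverse`.
#' @return a `Matrix::dgCMatrix`.
#' @export
h_sparse <- function(h) {
  out <- h$A_inv
  if (length(h$idx)) {
    adj <- if (h$mode == "direct") h$diff else as.matrix(h$apy) - h$A22_inv
    ng <- length(h$idx)
    S <- Matrix::sparseMatrix(i = rep(h$idx, ng), j = rep(h$idx, each = ng),
                              x = as.numeric(adj), dims = dim(out))
    out <- out + S
  }
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Build the full relationship set for single-step evaluation
#'
#' Convenience wrapper running A-inverse, A22, G (VanRaden 1), tuning,
#' blending, and H-inverse assembly in the standard order.
#'
#' @param ped a `pedigree`.
#' @param geno a post-QC [genotype_matrix()], or `NULL` for a pedigree-only
#'   set (H = A).
#' @param tau blending weight on G.
#' @param mode `"direct"` or `"apy"` for the G inverse.
#' @param core_size APY core size (default `min(n_genotyped, 2000)`),
#'   sampled uniformly among genotyped animals under `seed`.
#' @param seed seed for the core draw.
#' @return list of class `relationship_set` with `A_inv`, `A22`, `G_raw`,
#'   `G_tuned`, `G_blended`, `H_inv`, `ped`, `genotyped_ids`.
#' @export
build_relationship_set <- function(ped, geno = NULL, tau = 0.95,
                                   mode = c("direct", "apy"),
                                   core_size = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(ped$inbreeding)) ped <- compute_inbreeding(ped)
  A_inv <- build_A_inverse(ped)
  if (is.null(geno)) {
    H <- structure(list(A_inv = A_inv, idx = integer(0), ids = ped$animal_ids,
                        gids = character(0), A22_inv = matrix(0, 0, 0),
                        diff = NULL, apy = NULL, mode = "direct"),
                   class = "h_inverse")
    return(structure(list(A_inv = A_inv, A22 = NULL, G_raw = NULL,
                          G_tuned = NULL, G_blended = NULL, H_inv = H,
                          ped = ped, genotyped_ids = character(0)),
                     class = "relationship_set"))
  }
  A22 <- build_A22(ped, geno$animal_ids)
  G <- build_G(geno)
  Gt <- tune_G(G, A22)
  Gb <- blend_G(Gt, A22, tau = tau)
  core_ids <- NULL
  if (mode == "apy") {
    n_g <- length(geno$animal_ids)
    if (is.null(core_size)) core_size <- min(n_g, 2000L)
    set.seed(stage_seed(seed, "core"))
    core_ids <- sample(geno$animal_ids, core_size)
  }
  H <- assemble_H_inverse(A_inv, A22, Gb, mode = mode, core_ids = core_ids)
  structure(list(A_inv = A_inv, A22 = A22, G_raw = G, G_tuned = Gt,
                 G_blended = Gb, H_inv = H, ped = ped,
                 genotyped_ids = geno$animal_ids),
            class = "relationship_set")
}
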