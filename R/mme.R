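#' Linear model specification for the animal model
#'
#' `y = X beta + Z u + e` with contemporary group as the only fixed effect
#' and `u ~ (0, H sigma_u2)`.  The variance ratio
#' `lambda = sigma_e2 / sigma_u2` shrinks the animal equations.
#'
#' @param response name of the phenotype column (scores kept as stored,
#'   e.g. `{1,2}`; solutions are translation invariant).
#' @param sigma_u2,sigma_e2 variance components on the scale of the
#'   analysis (for the observed-scale linear model, from
#'   [liability_to_observed()]).
#' @return object of class `model_spec` with `lambda`.
#' @export
model_spec <- function(response, sigma_u2, sigma_e2) {
  stopifnot(sigma_u2 > 0, sigma_e2 > 0)
  structure(list(response = response, sigma_u2 = sigma_u2,
                 sigma_e2 = sigma_e2, lambda = sigma_e2 / sigma_u2),
            class = "model_spec")
}

mme_design <- function(phenos, ped, response) {
  stopifnot(all(c("animal", "cg", response) %in% names(phenos)))
  a <- match(phenos$animal, ped$animal_ids)
  if (anyNA(a)) stop("phenotyped animal(s) missing from pedigree")
  cg <- factor(phenos$cg)
  list(y = as.numeric(phenos[[response]]), animal = a,
       cg = as.integer(cg), cg_levels = levels(cg))
}

#' Solve the single-step mixed-model equations
#'
#' Preconditioned conjugate gradients (diagonal preconditioner) on
#' `[X'X, X'Z; Z'X, Z'Z + H^-1 lambda] [beta; u] = [X'y; Z'y]`, with the
#' H-inverse applied as an operator (never densified).  Breeding values are
#' returned for every pedigree animal, phenotyped or not.
#'
#' @param phenos data.frame with columns `animal`, `cg` and the response.
#' @param ped a `pedigree`.
#' @param relset a `relationship_set` (or an `h_inverse` directly).
#' @param spec a [model_spec()].
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return object of class `model_fit`: `beta_hat` (named by CG level),
#'   `gebv` (named by animal), and `convergence` (iterations, residual,
#'   converged flag).
#' @export
solve_mme <- function(phenos, ped, relset, spec, tol = 1e-12, max_iter = 5000L) {
  H <- if (inherits(relset, "relationship_set")) relset$H_inv else relset
  stopifnot(inherits(H, "h_inverse"), inherits(spec, "model_spec"))
  d <- mme_design(phenos, ped, spec$response)
  p <- length(d$cg_levels); q <- n_animals(ped); nrec <- length(d$y)
  lambda <- spec$lambda

  Xt <- Matrix::sparseMatrix(i = d$cg, j = seq_len(nrec), x = 1, dims = c(p, nrec))
  Zt <- Matrix::sparseMatrix(i = d$animal, j = seq_len(nrec), x = 1, dims = c(q, nrec))
  ztz <- tabulate(d$animal, nbins = q)
  rhs <- c(as.numeric(Xt %*% d$y), as.numeric(Zt %*% d$y))

  matvec <- function(v) {
    b <- v[seq_len(p)]; u <- v[p + seq_len(q)]
    fitted <- b[d$cg] + u[d$animal]            # (X,Z) %*% v per record
    c(as.numeric(Xt %*% fitted),
      as.numeric(Zt %*% fitted) + lambda * h_matvec(H, u))
  }
  prec <- c(tabulate(d$cg, nbins = p), ztz + lambda * h_diag(H))
  prec[prec <= 0] <- 1

  x <- numeric(p + q)
  r <- rhs - matvec(x)
  z <- r / prec
  pv <- z
  rz <- sum(r * z)
  rhs_norm <- sqrt(sum(rhs^2))
  if (rhs_norm == 0) rhs_norm <- 1
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Ap <- matvec(pv)
    alpha <- rz / sum(pv * Ap)
    x <- x + alpha * pv
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / rhs_norm
    if (res <= tol) { converged <- TRUE; break }
    z <- r / prec
    rz_new <- sum(r * z)
    pv <- z + (rz_new / rz) * pv
    rz <- rz_new
  }
  structure(list(
    beta_hat = stats::setNames(x[seq_len(p)], d$cg_levels),
    gebv = stats::setNames(x[p + seq_len(q)], ped$animal_ids),
    convergence = list(iterations = it,
                       residual = sqrt(sum(r^2)) / rhs_norm,
                       converged = converged),
    spec = spec
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", length(x$beta_hat), " CG solutions, ",
      length(x$gebv), " breeding values; ",
      if (x$convergence$converged) "converged" else "NOT converged",
      " in ", x$convergence$iterations, " iterations (residual ",
      format(x$convergence$residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Approximate per-animal reliability from the dense MME inverse
#'
#' Builds and inverts the full coefficient matrix (small problems only) and
#' reports `1 - PEV_i / (sigma_u2 (1 + F_i))`, truncated at 0.
#'
#' @param phenos,ped,relset,spec as in [solve_mme()].
#' @param max_n refuse problems with more equations than this.
#' @return named numeric vector of reliabilities.
#' @export
reliability_proxy <- function(phenos, ped, relset, spec, max_n = 2000L) {
  H <- if (inherits(relset, "relationship_set")) relset$H_inv else relset
  d <- mme_design(phenos, ped, spec$response)
  p <- length(d$cg_levels); q <- n_animals(ped)
  if (p + q > max_n) stop("problem too large for the dense reliability proxy")
  Hm <- as.matrix(H)
  X <- matrix(0, length(d$y), p); X[cbind(seq_along(d$y), d$cg)] <- 1
  Z <- matrix(0, length(d$y), q); Z[cbind(seq_along(d$y), d$animal)] <- 1
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + spec$lambda * Hm))
  Ci <- tryCatch(solve(C), error = function(e) MASS_ginv(C))
  pev <- diag(Ci)[p + seq_len(q)] * spec$sigma_e2
  F <- if (is.null(ped$inbreeding)) numeric(q) else ped$inbreeding
  rel <- pmax(0, 1 - pev / (spec$sigma_u2 * (1 + F)))
  stats::setNames(rel, ped$animal_ids)
}

# Moore-Penrose fallback for singular coefficient matrices (confounded CG)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
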