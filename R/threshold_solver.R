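#' Threshold-model GEBV by expectation-maximisation iteration on data
#'
#' Deterministic nonlinear solver for the liability-scale animal model with
#' known variance components, in the style of the iteration-on-data
#' threshold solvers used for routine categorical evaluations: alternate
#' (E) replacing each record's liability by its conditional expectation
#' given the current fitted value and its observed category — the truncated
#' normal mean `m + phi(m)/Phi(m)` above the threshold, `m - phi(m)/(1 -
#' Phi(m))` below — and (M) solving the liability-scale mixed-model
#' equations for the CG effects and breeding values by PCG.  The residual
#' liability variance is fixed at 1 and the threshold at 0.  A vague
#' Gaussian prior (`beta_prior_var`) on CG effects keeps groups with only
#' one observed category finite (the extreme-category problem).
#'
#' @param phenos data.frame with `animal`, `cg` and a `{1,2}` score column.
#' @param ped a `pedigree`.
#' @param relset a `relationship_set` (or `h_inverse`).
#' @param sigma_u2 liability-scale additive variance.
#' @param response score column name.
#' @param beta_prior_var prior variance of CG effects (ridge on the fixed
#'   equations).
#' @param max_outer cap on EM iterations.
#' @param tol convergence on the max change in fitted liabilities.
#' @return a `model_fit` (as from [solve_mme()]) on the liability scale.
#' @export
solve_threshold_mme <- function(phenos, ped, relset, sigma_u2,
                                response = "score", beta_prior_var = 4,
                                max_outer = 200L, tol = 1e-6) {
  H <- if (inherits(relset, "relationship_set")) relset$H_inv else relset
  stopifnot(inherits(H, "h_inverse"), sigma_u2 > 0)
  d <- mme_design(phenos, ped, response)
  if (!all(d$y %in% c(1, 2))) stop("threshold solver expects scores coded {1,2}")
  p <- length(d$cg_levels); q <- n_animals(ped); nrec <- length(d$y)
  lambda <- 1 / sigma_u2                     # residual liability variance 1
  ridge <- 1 / beta_prior_var
  success <- d$y == 2

  Xt <- Matrix::sparseMatrix(i = d$cg, j = seq_len(nrec), x = 1, dims = c(p, nrec))
  Zt <- Matrix::sparseMatrix(i = d$animal, j = seq_len(nrec), x = 1, dims = c(q, nrec))
  matvec <- function(v) {
    b <- v[seq_len(p)]; u <- v[p + seq_len(q)]
    fitted <- b[d$cg] + u[d$animal]
    c(as.numeric(Xt %*% fitted) + ridge * b,
      as.numeric(Zt %*% fitted) + lambda * h_matvec(H, u))
  }
  prec <- c(tabulate(d$cg, nbins = p) + ridge,
            tabulate(d$animal, nbins = q) + lambda * h_diag(H))
  prec[prec <= 0] <- 1

  pcg <- function(rhs, x0) {
    x <- x0
    r <- rhs - matvec(x)
    z <- r / prec; pv <- z; rz <- sum(r * z)
    nrm <- max(sqrt(sum(rhs^2)), 1e-300)
    for (it in 1:2000) {
      Ap <- matvec(pv)
      alpha <- rz / sum(pv * Ap)
      x <- x + alpha * pv
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) / nrm <= 1e-9) break
      z <- r / prec
      rz2 <- sum(r * z)
      pv <- z + (rz2 / rz) * pv
      rz <- rz2
    }
    x
  }

  sol <- numeric(p + q)
  fitted_old <- rep(Inf, nrec)
  outer <- 0L; converged <- FALSE
  repeat {
    outer <- outer + 1L
    m <- sol[d$cg] + sol[p + d$animal]       # current fitted liabilities
    # E-step: truncated-normal means, tail-safe via Mills ratio in log space
    lg <- dnorm(m, log = TRUE)
    up <- pnorm(m, log.p = TRUE)             # log Phi(m)
    lo <- pnorm(m, lower.tail = FALSE, log.p = TRUE)
    lhat <- ifelse(success, m + exp(lg - up), m - exp(lg - lo))
    sol <- pcg(c(as.numeric(Xt %*% lhat), as.numeric(Zt %*% lhat)), sol)
    delta <- max(abs(m - fitted_old))
    fitted_old <- m
    if (delta < tol) { converged <- TRUE; break }
    if (outer >= max_outer) break
  }
  structure(list(
    beta_hat = stats::setNames(sol[seq_len(p)], d$cg_levels),
    gebv = stats::setNames(sol[p + seq_len(q)], ped$animal_ids),
    convergence = list(iterations = outer, residual = delta,
                       converged = converged),
    spec = list(sigma_u2 = sigma_u2, sigma_e2 = 1, lambda = lambda,
                scale = "liability")
  ), class = "model_fit")
}
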