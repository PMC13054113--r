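#' Gibbs sampler configuration
#'
#' Chain settings and scaled-inverse-chi-square hyper-parameters for the
#' variance components.  The production-scale settings in routine
#' evaluations are 300,000 iterations, 100,000 burn-in and thinning of 100;
#' the defaults here are desk scale.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed.
#' @param nu_u,S_u degrees of belief and scale for `sigma_u2`; the default
#'   `(-2, 0)` is flat on the variance.
#' @param nu_e,S_e same for `sigma_e2` (linear mode only; threshold mode
#'   fixes `sigma_e2 = 1`).
#' @param sigma_u2_init,sigma_e2_init starting values.
#' @param update_sigma_u set `FALSE` to hold `sigma_u2` fixed (e.g. when
#'   sampling breeding values at known variance components).
#' @param beta_prior_var prior variance of the systematic (CG) effects.
#'   `NULL` resolves to 4 in threshold mode — a vague proper Gaussian on
#'   the liability scale that keeps CG effects of all-success/all-failure
#'   groups from random-walking (the extreme-category problem) — and to
#'   `Inf` (flat) in linear mode.
#' @return object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 4000L, burn_in = 1000L, thin = 5L, seed = 1L,
                         nu_u = -2, S_u = 0, nu_e = -2, S_e = 0,
                         sigma_u2_init = 0.25, sigma_e2_init = 1,
                         update_sigma_u = TRUE, beta_prior_var = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1, sigma_u2_init > 0, sigma_e2_init > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 nu_u = nu_u, S_u = S_u, nu_e = nu_e, S_e = S_e,
                 sigma_u2_init = sigma_u2_init, sigma_e2_init = sigma_e2_init,
                 update_sigma_u = isTRUE(update_sigma_u),
                 beta_prior_var = beta_prior_var),
            class = "gibbs_config")
}

#' One-sided truncated normal draws (inverse-CDF method)
#'
#' @param n number of draws.
#' @param mean,sd location and scale (recycled).
#' @param side `"geq"` for draws `>= t`, `"lt"` for draws `< t`.
#' @param t truncation point (recycled).
#' @return numeric vector of length `n`.
#' @export
truncated_normal_draw <- function(n, mean = 0, sd = 1, side = c("geq", "lt"),
                                  t = 0) {
  side <- match.arg(side)
  if (any(sd <= 0)) stop("sd must be positive")
  if (side == "geq")
    rtruncnorm_cpp(n, mean, sd, t, Inf)
  else
    rtruncnorm_cpp(n, mean, sd, -Inf, t)
}

#' Run the Gibbs sampler for the threshold or linear animal model
#'
#' Threshold mode augments a liability per record, truncated at 0 on the
#' side given by the `{1,2}` score, with the residual liability variance
#' fixed at 1; `sigma_u2` is drawn from its scaled inverse chi-square full
#' conditional `(u' H^-1 u + nu S) / chisq(q + nu)`.  Linear mode treats the
#' response as Gaussian and also samples `sigma_e2`.  Location effects are
#' updated by single-site Gibbs over the mixed-model equations.  Posterior
#' breeding-value means are accumulated as running means over kept draws.
#'
#' @param phenos data.frame with `animal`, `cg` and the response column.
#' @param relset a `relationship_set` (or `h_inverse`).
#' @param cfg a [gibbs_config()].
#' @param mode `"threshold"` or `"linear"`.
#' @param response response column name (default `"score"`).
#' @return object of class `posterior_chain`: `samples` data.frame
#'   (`sigma_u2`, `sigma_e2`, `h2`), posterior-mean `gebv` and `beta`,
#'   and the settings used.
#' @export
run_gibbs <- function(phenos, relset, cfg = gibbs_config(),
                      mode = c("threshold", "linear"), response = "score") {
  mode <- match.arg(mode)
  H <- if (inherits(relset, "relationship_set")) relset$H_inv else relset
  ped <- if (inherits(relset, "relationship_set")) relset$ped else NULL
  stopifnot(inherits(H, "h_inverse"), inherits(cfg, "gibbs_config"))
  ids <- H$ids
  a <- match(phenos$animal, ids)
  if (anyNA(a)) stop("phenotyped animal(s) missing from the relationship set")
  cg <- factor(phenos$cg)
  if (any(table(cg) == 0)) stop("contemporary group with zero records")
  y <- as.numeric(phenos[[response]])
  if (mode == "threshold" && !all(y %in% c(1, 2)))
    stop("threshold mode expects scores coded {1,2}")
  K <- h_sparse(H)
  bpv <- cfg$beta_prior_var
  if (is.null(bpv)) bpv <- if (mode == "threshold") 4 else Inf
  set.seed(cfg$seed)
  res <- gibbs_animal_cpp(
    y, a - 1L, as.integer(cg) - 1L, length(ids), nlevels(cg),
    K@p, K@i, K@x,
    cfg$n_iter, cfg$burn_in, cfg$thin,
    mode == "threshold", cfg$update_sigma_u,
    cfg$nu_u, cfg$S_u, cfg$nu_e, cfg$S_e,
    cfg$sigma_u2_init, cfg$sigma_e2_init, 0.0, bpv)
  samples <- data.frame(sigma_u2 = res$chain[, 1], sigma_e2 = res$chain[, 2],
                        h2 = res$chain[, 3])
  structure(list(samples = samples,
                 gebv = stats::setNames(res$u_rb, ids),
                 gebv_draw_mean = stats::setNames(res$u_mean, ids),
                 beta = stats::setNames(res$beta_mean, levels(cg)),
                 n_kept = res$n_kept, mode = mode, config = cfg),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("<posterior_chain> ", x$mode, " model, ", x$n_kept, " kept draws\n",
      sep = "")
  print(summarize_posterior(x))
  invisible(x)
}

hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Posterior summaries: mean, SD and 95% HPD interval
#'
#' The HPD interval is the shortest window containing the target mass of
#' the sorted draws.
#'
#' @param chain a `posterior_chain`, or a data.frame/matrix of draws.
#' @param prob HPD mass.
#' @return data.frame with one row per parameter.
#' @export
summarize_posterior <- function(chain, prob = 0.95) {
  draws <- if (inherits(chain, "posterior_chain")) chain$samples else
    as.data.frame(chain)
  if (nrow(draws) == 0) stop("no kept samples to summarize")
  rows <- lapply(names(draws), function(par) {
    x <- draws[[par]]
    h <- hpd_interval(x, prob)
    data.frame(parameter = par, mean = mean(x), sd = stats::sd(x),
               hpd_lower = h["lower"], hpd_upper = h["upper"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# non-overlapping batch means with batch size ~ sqrt(n), capped so that at
# least 20 batches support the variance estimate; a few trailing samples
# may be dropped when the batch grid does not tile the segment
batch_means <- function(x) {
  n <- length(x)
  b <- max(2L, min(floor(sqrt(n)), n %/% 20L))
  nb <- max(2L, n %/% b)
  colMeans(matrix(x[seq_len(nb * b)], nrow = b))
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first 10% of a chain with the mean of the last
#' 50%, standardising by spectral-density-at-zero variance estimates from
#' non-overlapping batch means.  Because the variance estimates rest on a
#' modest number of batches, the two-sided p-value uses a Student reference
#' with Welch-Satterthwaite degrees of freedom, which keeps the nominal
#' rejection rate accurate on short segments.  P-values below `alpha` are
#' evidence against convergence.
#'
#' @param x numeric chain of kept samples.
#' @param frac_first,frac_last segment fractions.
#' @param alpha significance level for the pass/fail call.
#' @param min_len minimum chain length.
#' @return list with `z`, `p`, `pass`, and the segment means.
#' @export
geweke_z <- function(x, frac_first = 0.1, frac_last = 0.5, alpha = 0.05,
                     min_len = 40L) {
  n <- length(x)
  if (n < min_len) stop("chain too short for the Geweke diagnostic")
  x1 <- x[seq_len(max(2L, floor(frac_first * n)))]
  x2 <- x[(n - max(2L, floor(frac_last * n)) + 1L):n]
  b1 <- batch_means(x1); b2 <- batch_means(x2)
  v1 <- stats::var(b1) / length(b1)     # spectral variance of segment mean
  v2 <- stats::var(b2) / length(b2)
  se <- sqrt(v1 + v2)
  z <- if (se == 0) 0 else (mean(b1) - mean(b2)) / se
  df <- if (se == 0) Inf else
    (v1 + v2)^2 / (v1^2 / (length(b1) - 1) + v2^2 / (length(b2) - 1))
  p <- 2 * stats::pt(-abs(z), df = df)
  list(z = z, p = p, df = df, pass = p >= alpha,
       mean_first = mean(x1), mean_last = mean(x2))
}
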