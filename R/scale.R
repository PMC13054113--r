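#' Liability-to-observed scale conversion of variance components
#'
#' Robertson's transformation for binary traits (Dempster & Lerner; extended
#' to multiple categories by Gianola): with success incidence `alpha`,
#' threshold `t = qnorm(1 - alpha)` and normal ordinate `z = dnorm(t)`,
#' `h2_obs = z^2 h2_l / (alpha (1 - alpha))`.  The observed-scale variances
#' follow as `sigma_u2 = z^2 h2_l`, `sigma_p2 = alpha (1 - alpha)` and
#' `sigma_e2 = sigma_p2 - (sigma_u2 + sigma_pe2 + sigma_cg2)`.
#'
#' @param h2_l heritability on the liability scale, in (0,1).
#' @param alpha incidence of the success category, in (0,1).
#' @param sigma_pe2,sigma_cg2 permanent-environment and contemporary-group
#'   variances on the observed scale (zero for the single-record animal
#'   model used here).
#' @return object of class `scale_conversion` with fields `alpha`, `t`,
#'   `z`, `h2_liability`, `h2_observed`, `sigma_u2_obs`, `sigma_p2_obs`,
#'   `sigma_e2_obs`.
#' @export
liability_to_observed <- function(h2_l, alpha, sigma_pe2 = 0, sigma_cg2 = 0) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(h2_l > 0 && h2_l < 1)) stop("h2_l must be in (0, 1)")
  t <- qnorm(1 - alpha)
  z <- dnorm(t)
  sigma_u2 <- z^2 * h2_l
  sigma_p2 <- alpha * (1 - alpha)
  structure(list(alpha = alpha, t = t, z = z,
                 h2_liability = h2_l,
                 h2_observed = z^2 * h2_l / (alpha * (1 - alpha)),
                 sigma_u2_obs = sigma_u2,
                 sigma_p2_obs = sigma_p2,
                 sigma_e2_obs = sigma_p2 - (sigma_u2 + sigma_pe2 + sigma_cg2)),
            class = "scale_conversion")
}

#' @export
print.scale_conversion <- function(x, ...) {
  cat(sprintf(
    "Liability -> observed scale at incidence %.4f (t = %.4f, z = %.4f)\n",
    x$alpha, x$t, x$z))
  cat(sprintf("  h2 liability  : %.4f\n", x$h2_liability))
  cat(sprintf("  h2 observed   : %.4f\n", x$h2_observed))
  cat(sprintf("  sigma_u2 obs  : %.4f\n", x$sigma_u2_obs))
  cat(sprintf("  sigma_p2 obs  : %.4f\n", x$sigma_p2_obs))
  cat(sprintf("  sigma_e2 obs  : %.4f\n", x$sigma_e2_obs))
  invisible(x)
}

#' Observed-to-liability heritability (inverse transformation)
#'
#' @param h2_obs heritability on the observed scale.
#' @param alpha success incidence in (0,1).
#' @return liability-scale heritability; errors if outside (0,1).
#' @export
observed_to_liability <- function(h2_obs, alpha) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  z <- dnorm(qnorm(1 - alpha))
  h2_l <- h2_obs * alpha * (1 - alpha) / z^2
  if (!(h2_l > 0 && h2_l < 1))
    stop("implied liability heritability outside (0, 1): ", format(h2_l))
  h2_l
}
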