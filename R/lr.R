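#' Split phenotypes into whole and partial datasets for LR validation
#'
#' The partial dataset drops every record whose record year falls in the
#' last `cutoff_years` years.  Focal animals are genotyped females with no
#' own record and no progeny record in the partial data (operationally:
#' young animals whose information exists only in the whole data).
#'
#' @param phenos phenotype data.frame with `animal` and a record-year
#'   column.
#' @param ped a `pedigree` with `sex`.
#' @param genotyped_ids identifiers of genotyped animals.
#' @param cutoff_years number of trailing years to remove (2 in routine
#'   use).
#' @param record_year_col name of the record-year column.
#' @return list with `whole`, `partial` (data.frames) and `focal_ids`.
#' @export
make_partial <- function(phenos, ped, genotyped_ids, cutoff_years = 2L,
                         record_year_col = "record_year") {
  stopifnot(record_year_col %in% names(phenos))
  if (cutoff_years < 1) stop("cutoff_years must be at least 1 (focal set empty otherwise)")
  ry <- phenos[[record_year_col]]
  cut <- max(ry) - cutoff_years
  partial <- phenos[ry <= cut, , drop = FALSE]
  if (nrow(partial) == 0)
    stop("partial dataset is empty; choose a smaller cutoff")

  genotyped_ids <- as.character(genotyped_ids)
  pos <- match(genotyped_ids, ped$animal_ids)
  if (anyNA(pos)) stop("genotyped animal(s) missing from pedigree")
  females <- genotyped_ids[!is.na(ped$sex[pos]) & ped$sex[pos] == "F"]

  has_partial_record <- unique(partial$animal)
  # progeny record in partial: any partial-record animal whose sire/dam is focal
  rec_pos <- match(partial$animal, ped$animal_ids)
  parents_with_rec <- unique(c(
    ped$animal_ids[ped$sire_index[rec_pos][ped$sire_index[rec_pos] > 0L]],
    ped$animal_ids[ped$dam_index[rec_pos][ped$dam_index[rec_pos] > 0L]]))
  focal <- setdiff(females, union(has_partial_record, parents_with_rec))
  focal <- intersect(focal, phenos$animal)   # young: recorded only in whole
  if (!length(focal))
    stop("no focal animals; choose a smaller cutoff or genotype more females")
  list(whole = phenos, partial = partial, focal_ids = focal)
}

#' LR-method validation statistics
#'
#' Given whole-data and partial-data GEBV for the focal animals:
#' accuracy `acc = cov(u_w, u_p) / sqrt((1 - F_bar) sigma_u2)`,
#' bias `delta = (mean(u_p) - mean(u_w)) / sigma_u`,
#' dispersion `b1 = cov(u_w, u_p) / var(u_p)`, and the Pearson correlation;
#' sample moments use denominator `n - 1`.
#'
#' @param u_w,u_p aligned GEBV vectors (whole, partial) for focal animals.
#' @param F_bar average pedigree inbreeding among focal animals.
#' @param sigma_u2_hat additive genetic variance on the scale of the model
#'   being validated.
#' @param model,trait optional labels carried into the report.
#' @return object of class `validation_report` with `acc`, `delta`, `b1`,
#'   `corr`, `n_focal`.
#' @export
lr_statistics <- function(u_w, u_p, F_bar = 0, sigma_u2_hat,
                          model = NA_character_, trait = NA_character_) {
  if (length(u_w) != length(u_p) || length(u_w) < 2)
    stop("u_w and u_p must be aligned vectors of length >= 2")
  if (stats::var(u_w) == 0 || stats::var(u_p) == 0)
    stop("zero variance in a GEBV vector")
  stopifnot(sigma_u2_hat > 0, F_bar < 1)
  cv <- stats::cov(u_w, u_p)
  acc <- cv / sqrt((1 - F_bar) * sigma_u2_hat)
  if (cv < 0) {
    warning("negative whole/partial GEBV covariance; accuracy reported as 0")
    acc <- 0
  }
  structure(list(
    acc = acc,
    delta = (mean(u_p) - mean(u_w)) / sqrt(sigma_u2_hat),
    b1 = cv / stats::var(u_p),
    corr = stats::cor(u_w, u_p),
    n_focal = length(u_w), model = model, trait = trait
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("LR validation (%s%s, n_focal = %d)\n",
              ifelse(is.na(x$model), "model", x$model),
              ifelse(is.na(x$trait), "", paste0(", ", x$trait)), x$n_focal))
  cat(sprintf("  accuracy   : %.3f\n", x$acc))
  cat(sprintf("  bias       : %.4f\n", x$delta))
  cat(sprintf("  dispersion : %.3f\n", x$b1))
  cat(sprintf("  correlation: %.3f\n", x$corr))
  invisible(x)
}

#' Run a whole/partial LR validation experiment
#'
#' Fits the chosen model on the whole and on the partial dataset with
#' identical settings and variance components (the whole-data estimates, or
#' the supplied ones), extracts focal-animal GEBV from both fits, and
#' returns the LR statistics.  The threshold model is fitted on the
#' liability scale by the deterministic iteration-on-data solver
#' ([solve_threshold_mme()]) at fixed variance components; the linear model
#' solves the observed-scale mixed-model equations by PCG with components
#' converted through [liability_to_observed()].
#'
#' @param phenos phenotype data.frame (`animal`, `cg`, `score`,
#'   `record_year`).
#' @param relset a `relationship_set` (with inbreeding available).
#' @param model `"threshold"` or `"linear"`.
#' @param sigma_u2_l,sigma_e2_l liability-scale variance components used
#'   for both fits.
#' @param cutoff_years trailing years removed for the partial data.
#' @param trait label for the report.
#' @return a [lr_statistics()] report, with the focal GEBV vectors attached
#'   as attributes `u_w` and `u_p`.
#' @export
run_lr_experiment <- function(phenos, relset, model = c("threshold", "linear"),
                              sigma_u2_l, sigma_e2_l = 1, cutoff_years = 2L,
                              trait = "stay") {
  model <- match.arg(model)
  ped <- relset$ped
  split <- make_partial(phenos, ped, relset$genotyped_ids, cutoff_years)
  fit_one <- function(dat) {
    dat <- drop_small_cgs(dat)
    if (model == "threshold") {
      solve_threshold_mme(dat, ped, relset, sigma_u2 = sigma_u2_l)$gebv
    } else {
      alpha <- mean(dat$score == 2)
      conv <- liability_to_observed(sigma_u2_l / (sigma_u2_l + sigma_e2_l), alpha)
      spec <- model_spec("score", conv$sigma_u2_obs, conv$sigma_e2_obs)
      solve_mme(dat, ped, relset, spec, tol = 1e-10)$gebv
    }
  }
  g_w <- fit_one(split$whole)
  g_p <- fit_one(split$partial)
  focal <- split$focal_ids
  if (anyNA(g_w[focal]) || anyNA(g_p[focal]))
    stop("focal animal missing from a fitted solution")
  F_bar <- mean(ped$inbreeding[match(focal, ped$animal_ids)])
  sig <- if (model == "threshold") sigma_u2_l else {
    alpha_w <- mean(split$whole$score == 2)
    liability_to_observed(sigma_u2_l / (sigma_u2_l + sigma_e2_l),
                          alpha_w)$sigma_u2_obs
  }
  rep <- lr_statistics(g_w[focal], g_p[focal], F_bar, sig,
                       model = model, trait = trait)
  attr(rep, "u_w") <- g_w[focal]
  attr(rep, "u_p") <- g_p[focal]
  rep
}
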