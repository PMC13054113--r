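#' Simulation configuration
#'
#' Holds the study conditions the synthetic-data generator emulates: a
#' multi-generation Nellore-like pedigree, biallelic SNP genotypes dropped
#' through it, farm-by-management-by-year-by-season contemporary groups, and
#' calving histories from which the five stayability definitions are scored.
#'
#' @param n_founders animals per generation (the founder generation sets the
#'   per-generation size).
#' @param n_generations number of offspring generations below the founders.
#' @param n_snps number of biallelic markers.
#' @param maf_range founder allele-frequency range, within (0, 0.5].
#' @param heritability_liability target liability-scale heritability in (0,1);
#'   the residual liability variance is fixed at 1, so the additive variance
#'   is `h2/(1-h2)`.
#' @param n_farms,n_mgmt_groups counts used to build contemporary groups.
#' @param years length-2 integer vector; birth years start at `years[1]`,
#'   each generation spanning two consecutive years.
#' @param per_opportunity_base_rates marginal conception probabilities, one
#'   per annual breeding opportunity.  The defaults were calibrated once by
#'   Monte Carlo so that the realized STAY48-2 incidence sits near 14% and
#'   STAY72-3 near 38%, the incidence regime of large Nellore programmes.
#' @param sigma_cg2 variance of the simulated contemporary-group effects on
#'   the liability scale.
#' @param missing_rate genotype missingness rate in [0, 0.1] (code 5).
#' @param prop_sires fraction of available males used as sires each
#'   generation.
#' @param seed integer seed; every generator stage derives its own stream
#'   from it, so a config reproduces all outputs bit-for-bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 500L, n_generations = 4L, n_snps = 1000L,
                       maf_range = c(0.1, 0.5), heritability_liability = 0.20,
                       n_farms = 6L, n_mgmt_groups = 2L, years = c(2006L, 2015L),
                       per_opportunity_base_rates = c(0.13, 0.23, 0.38, 0.80, 0.90),
                       sigma_cg2 = 0.10, missing_rate = 0, prop_sires = 0.10,
                       seed = 1L) {
  stopifnot(n_founders >= 1, n_generations >= 0, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            heritability_liability > 0, heritability_liability < 1,
            n_farms >= 1, n_mgmt_groups >= 1,
            all(per_opportunity_base_rates >= 0),
            all(per_opportunity_base_rates <= 1),
            sigma_cg2 >= 0, missing_rate >= 0, missing_rate <= 0.1)
  structure(list(
    n_founders = as.integer(n_founders), n_generations = as.integer(n_generations),
    n_snps = as.integer(n_snps), maf_range = maf_range,
    heritability_liability = heritability_liability,
    n_farms = as.integer(n_farms), n_mgmt_groups = as.integer(n_mgmt_groups),
    years = as.integer(years),
    per_opportunity_base_rates = per_opportunity_base_rates,
    sigma_cg2 = sigma_cg2, missing_rate = missing_rate,
    prop_sires = prop_sires, seed = as.integer(seed)
  ), class = "sim_config")
}

# sample() treats a length-1 numeric-like vector as 1:n; guard against it
sample_from <- function(x, size, replace = FALSE) {
  if (length(x) == 1L) {
    if (!replace && size > 1L) stop("cannot sample ", size, " from one item")
    return(rep(x, size))
  }
  sample(x, size, replace = replace)
}

# fixed seed-splitting rule so stages can be re-run in isolation
stage_seed <- function(seed, stage) {
  offs <- c(pedigree = 11L, genotypes = 23L, truth = 37L, cg = 41L,
            histories = 53L, binary = 67L, core = 71L)
  (as.integer(seed) * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate a discrete-generation pedigree
#'
#' Founders form generation 0; each later generation has the same size, with
#' sires drawn from a restricted male subset of the previous generation and
#' dams drawn from its females, so inbreeding accrues as in a finite
#' population under random mating.
#'
#' @param cfg a [sim_config()].
#' @return a [new_pedigree()] with `sex`, `birth_year` and `generation`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2 && cfg$n_generations > 0)
    stop("need at least 2 founders to breed subsequent generations")
  set.seed(stage_seed(cfg$seed, "pedigree"))
  ng <- cfg$n_generations
  n_per <- cfg$n_founders
  total <- n_per * (ng + 1L)
  id <- sprintf("ID%06d", seq_len(total))
  sex <- character(total); sire <- dam <- rep(NA_character_, total)
  gen <- rep(0:ng, each = n_per)
  birth_year <- cfg$years[1] + 2L * gen + sample(0:1, total, replace = TRUE)

  balanced_sex <- function(n) {
    sx <- sample(c("M", "F"), n, replace = TRUE)
    if (n >= 2 && length(unique(sx)) == 1L) sx[1] <- setdiff(c("M", "F"), sx[1])
    sx
  }
  sex[gen == 0L] <- balanced_sex(n_per)
  for (g in seq_len(ng)) {
    prev <- which(gen == g - 1L)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    n_sires <- min(length(males),
                   max(2L, ceiling(cfg$prop_sires * length(males))))
    sires <- sample_from(males, n_sires)
    cur <- which(gen == g)
    sire[cur] <- sample_from(sires, n_per, replace = TRUE)
    dam[cur] <- sample_from(females, n_per, replace = TRUE)
    sex[cur] <- balanced_sex(n_per)
  }
  new_pedigree(id, sire, dam, sex = sex, birth_year = birth_year,
               generation = gen)
}

#' Genotype container
#'
#' @param animal_ids,snp_ids identifiers for rows/columns of `codes`.
#' @param codes integer matrix of allele counts in `{0,1,2}` with 5 for
#'   missing.
#' @param map data.frame with columns `snp`, `chrom`, `pos`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(animal_ids, snp_ids, codes, map = NULL) {
  codes <- as.matrix(codes)
  stopifnot(nrow(codes) == length(animal_ids), ncol(codes) == length(snp_ids),
            all(codes %in% c(0L, 1L, 2L, 5L)), !anyDuplicated(snp_ids))
  dimnames(codes) <- list(as.character(animal_ids), as.character(snp_ids))
  if (is.null(map))
    map <- data.frame(snp = as.character(snp_ids),
                      chrom = rep_len(as.character(1:29), length(snp_ids)),
                      pos = seq_along(snp_ids) * 1000L,
                      stringsAsFactors = FALSE)
  structure(list(animal_ids = as.character(animal_ids),
                 snp_ids = as.character(snp_ids),
                 codes = codes, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$animal_ids), " animals x ",
      length(x$snp_ids), " SNPs (", sum(x$codes == 5L), " missing calls)\n",
      sep = "")
  invisible(x)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders are Hardy-Weinberg at frequencies drawn uniformly within
#' `cfg$maf_range`; each offspring receives one allele per parent
#' (heterozygous parents transmit at random).  Optional missingness writes
#' code 5; when it is active the complete codes are kept in the
#' `"complete_codes"` attribute so simulation truth stays well defined.
#'
#' @param ped sorted `pedigree`.
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with founder frequencies in attribute
#'   `"founder_freq"`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (any(ped$sire_index > seq_len(n_animals(ped))) ||
      any(ped$dam_index > seq_len(n_animals(ped))))
    stop("pedigree is not sorted parents-first")
  set.seed(stage_seed(cfg$seed, "genotypes"))
  n <- n_animals(ped); m <- cfg$n_snps
  p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # paternal/maternal gametes, row per animal
  pat <- mat <- matrix(0L, n, m)
  transmit <- function(g) {                 # g: allele-count vector for parent
    (g == 2L) + (g == 1L) * (runif(length(g)) < 0.5)
  }
  for (i in seq_len(n)) {
    s <- ped$sire_index[i]; d <- ped$dam_index[i]
    pat[i, ] <- if (s > 0L) transmit(pat[s, ] + mat[s, ]) else rbinom(m, 1L, p)
    mat[i, ] <- if (d > 0L) transmit(pat[d, ] + mat[d, ]) else rbinom(m, 1L, p)
  }
  codes <- pat + mat
  storage.mode(codes) <- "integer"
  complete <- NULL
  if (cfg$missing_rate > 0) {
    complete <- codes
    miss <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    codes[miss] <- 5L
  }
  g <- genotype_matrix(ped$animal_ids, sprintf("SNP%05d", seq_len(m)), codes)
  attr(g, "founder_freq") <- p
  attr(g, "complete_codes") <- complete
  g
}

#' Simulation ground truth: marker effects, breeding values, variances
#'
#' Additive effects are drawn as `alpha_j ~ N(0, sigma_u2 / sum 2 p_j (1-p_j))`
#' at the founder frequencies, and true breeding values are the centred
#' marker scores times the effects, so genomic information is genuinely
#' predictive downstream.  The residual liability variance is fixed at 1 and
#' `sigma_u2 = h2/(1-h2)`, making `sigma_u2/(sigma_u2+sigma_e2)` equal the
#' configured liability heritability exactly.
#'
#' With `method = "pedigree"` breeding values are instead gene-dropped
#' through the pedigree (parent average plus Mendelian-sampling noise with
#' variance `sigma_u2 (0.5 - 0.25 (F_s + F_d))`), so their covariance is
#' exactly `A sigma_u2` — the analysis model's own assumption, which is what
#' parameter-recovery studies of pedigree-based samplers should match.
#'
#' @param ped a `pedigree` (with inbreeding for `method = "pedigree"`; it is
#'   computed if absent).
#' @param geno a [genotype_matrix()] from [simulate_genotypes()]; may be
#'   `NULL` for `method = "pedigree"`.
#' @param cfg a [sim_config()].
#' @param method `"markers"` (breeding values from marker effects) or
#'   `"pedigree"` (gene-dropped under A).
#' @return object of class `sim_truth`: true breeding values (named),
#'   variances, contemporary-group effects (filled by
#'   [assign_contemporary_groups()]), and marker effects.
#' @export
sim_truth <- function(ped, geno, cfg, method = c("markers", "pedigree")) {
  method <- match.arg(method)
  set.seed(stage_seed(cfg$seed, "truth"))
  h2 <- cfg$heritability_liability
  sigma_e2 <- 1
  sigma_u2 <- h2 / (1 - h2) * sigma_e2
  if (method == "markers") {
    stopifnot(inherits(geno, "genotype_matrix"))
    p <- attr(geno, "founder_freq")
    if (is.null(p)) p <- allele_frequencies(geno)
    codes <- attr(geno, "complete_codes")
    if (is.null(codes)) codes <- geno$codes
    denom <- sum(2 * p * (1 - p))
    alpha <- rnorm(length(p), 0, sqrt(sigma_u2 / denom))
    u <- drop(sweep(codes, 2, 2 * p) %*% alpha)
    names(u) <- geno$animal_ids
  } else {
    if (is.null(ped$inbreeding)) ped <- compute_inbreeding(ped)
    n <- n_animals(ped)
    s <- ped$sire_index; d <- ped$dam_index; F <- ped$inbreeding
    Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
    Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
    msv <- sigma_u2 * (0.5 - 0.25 * (Fs + Fd))
    noise <- rnorm(n, 0, sqrt(msv))
    u <- numeric(n)
    for (i in seq_len(n)) {
      pa <- 0.5 * (if (s[i] > 0L) u[s[i]] else 0) +
            0.5 * (if (d[i] > 0L) u[d[i]] else 0)
      u[i] <- pa + noise[i]
    }
    names(u) <- ped$animal_ids
    alpha <- NULL
  }
  structure(list(true_breeding_values = u,
                 true_sigma_u2 = sigma_u2, true_sigma_e2 = sigma_e2,
                 cg_effects = NULL, marker_effects = alpha),
            class = "sim_truth")
}

#' Assign contemporary groups (farm x management group x year x season)
#'
#' Every female gets a farm and management group multinomially, a birth
#' season (dry Apr-Sep / rainy Oct-Mar), and a CG label combining them with
#' birth year.  CG effects are drawn `N(0, sigma_cg2)` per label and stored
#' into the truth object.
#'
#' @param ped a `pedigree` with `sex` and `birth_year`.
#' @param truth a [sim_truth()] (updated in the return value).
#' @param cfg a [sim_config()].
#' @param include `"females"` (calving histories concern females only) or
#'   `"all"` (e.g. for a generic binary trait recorded on every animal).
#' @return list with `cg`: data.frame (`animal`, `farm`, `mgmt`, `year`,
#'   `season`, `cg`), and the updated `truth`.
#' @export
assign_contemporary_groups <- function(ped, truth, cfg,
                                       include = c("females", "all")) {
  include <- match.arg(include)
  stopifnot(!is.null(ped$sex), !is.null(ped$birth_year))
  set.seed(stage_seed(cfg$seed, "cg"))
  fem <- if (include == "all") seq_len(n_animals(ped)) else
    which(ped$sex == "F")
  cg <- data.frame(
    animal = ped$animal_ids[fem],
    farm = sample(seq_len(cfg$n_farms), length(fem), replace = TRUE),
    mgmt = sample(seq_len(cfg$n_mgmt_groups), length(fem), replace = TRUE),
    year = ped$birth_year[fem],
    season = sample(c("dry", "rainy"), length(fem), replace = TRUE),
    stringsAsFactors = FALSE)
  cg$cg <- paste(cg$farm, cg$mgmt, cg$year, cg$season, sep = "_")
  labels <- sort(unique(cg$cg))
  eff <- stats::setNames(rnorm(length(labels), 0, sqrt(cfg$sigma_cg2)), labels)
  truth$cg_effects <- eff
  list(cg = cg, truth = truth)
}

#' Simulate calving histories for challenged females
#'
#' Each female is exposed from 10-14 months of age with annual breeding
#' opportunities.  Conception at opportunity k follows a probit liability
#' `mu_k + u_i + cg_i + eps_ik > 0` with `eps ~ N(0, sigma_e2)` and `mu_k`
#' chosen so the marginal conception rate matches
#' `per_opportunity_base_rates[k]`.  A conception yields one calving age
#' (exposure + 2 months mid-season + 9 months gestation + 12 (k-1)).
#'
#' @param ped a `pedigree` with `sex`.
#' @param truth a [sim_truth()] with `cg_effects` filled.
#' @param cfg a [sim_config()].
#' @param cg data.frame from [assign_contemporary_groups()].
#' @return named list of `calving_history` objects (one per female), each a
#'   list with `animal` and ascending `calving_ages_months`.
#' @export
simulate_calving_histories <- function(ped, truth, cfg, cg) {
  stopifnot(inherits(truth, "sim_truth"), !is.null(truth$cg_effects))
  set.seed(stage_seed(cfg$seed, "histories"))
  rates <- cfg$per_opportunity_base_rates
  K <- length(rates)
  nf <- nrow(cg)
  u <- truth$true_breeding_values[cg$animal]
  gce <- truth$cg_effects[cg$cg]
  tot_sd <- sqrt(truth$true_sigma_u2 + truth$true_sigma_e2)
  mu <- qnorm(pmin(pmax(rates, 1e-12), 1 - 1e-12)) * tot_sd
  mu[rates == 0] <- -Inf; mu[rates == 1] <- Inf
  exposure <- sample(10:14, nf, replace = TRUE)
  eps <- matrix(rnorm(nf * K, 0, sqrt(truth$true_sigma_e2)), nf, K)
  conceived <- sweep(eps, 2, mu, "+") + u + gce > 0
  ages0 <- exposure + 2L + 9L                 # age at first-opportunity calving
  histories <- lapply(seq_len(nf), function(i) {
    k <- which(conceived[i, ])
    structure(list(animal = cg$animal[i],
                   calving_ages_months = ages0[i] + 12L * (k - 1L)),
              class = "calving_history")
  })
  names(histories) <- cg$animal
  histories
}

#' Score one stayability definition from a calving history
#'
#' Score 2 (success) iff the number of calvings at or before
#' `age_limit_months` reaches `min_calvings`; otherwise 1 (failure).
#'
#' @param history a `calving_history` (or bare numeric vector of ages).
#' @param age_limit_months age limit in months (48, 54 or 72 in the standard
#'   definitions).
#' @param min_calvings required calvings (2 or 3).
#' @return integer score, 1 or 2.
#' @export
score_stayability <- function(history, age_limit_months, min_calvings) {
  if (!(age_limit_months > 0) || !(min_calvings > 0))
    stop("age_limit_months and min_calvings must be positive")
  ages <- if (inherits(history, "calving_history"))
    history$calving_ages_months else as.numeric(history)
  if (sum(ages <= age_limit_months) >= min_calvings) 2L else 1L
}

stay_definitions <- function() {
  data.frame(trait = c("stay48_2", "stay48_3", "stay54_2", "stay54_3", "stay72_3"),
             age_limit = c(48L, 48L, 54L, 54L, 72L),
             min_calvings = c(2L, 3L, 2L, 3L, 3L),
             stringsAsFactors = FALSE)
}

#' Score all five stayability definitions into a phenotype table
#'
#' @param histories list from [simulate_calving_histories()].
#' @param cg data.frame from [assign_contemporary_groups()].
#' @return data.frame with CG columns, `birth_year`, one `{1,2}` column per
#'   definition, and a per-definition record year (`birth_year` plus the
#'   age limit in whole years).
#' @export
score_phenotypes <- function(histories, cg) {
  defs <- stay_definitions()
  out <- cg
  out$birth_year <- cg$year
  for (k in seq_len(nrow(defs))) {
    sc <- vapply(histories[cg$animal], score_stayability, integer(1),
                 age_limit_months = defs$age_limit[k],
                 min_calvings = defs$min_calvings[k])
    out[[defs$trait[k]]] <- sc
    out[[paste0("record_year_", defs$trait[k])]] <-
      out$birth_year + ceiling(defs$age_limit[k] / 12)
  }
  out
}

#' Drop contemporary groups with too few records
#' @param phenos phenotype data.frame with a `cg` column.
#' @param min_n minimum records per CG (default 3).
#' @return filtered data.frame.
#' @export
drop_small_cgs <- function(phenos, min_n = 3L) {
  tab <- table(phenos$cg)
  phenos[phenos$cg %in% names(tab)[tab >= min_n], , drop = FALSE]
}

#' Simulate a single-liability binary trait under the threshold model
#'
#' Generates one binary record per female directly from the analysis model's
#' own assumptions: liability `l = cg + u + e`, score 2 iff `l` exceeds the
#' threshold placed so the marginal success incidence equals `incidence`.
#' This is the generator used for parameter-recovery and LR-method checks,
#' where the fitted model must be correctly specified.
#'
#' @param ped a `pedigree` with `sex`/`birth_year`.
#' @param truth a [sim_truth()] with `cg_effects`.
#' @param cfg a [sim_config()].
#' @param cg data.frame from [assign_contemporary_groups()].
#' @param incidence target marginal success rate.
#' @return data.frame `animal`, `cg`, `birth_year`, `record_year`
#'   (birth + 4), `score` in `{1,2}`, plus the latent `liability`.
#' @export
simulate_binary_trait <- function(ped, truth, cfg, cg, incidence = 0.1436) {
  if (is.null(truth$cg_effects))
    stop("truth has no cg_effects; pass the truth returned by assign_contemporary_groups()")
  set.seed(stage_seed(cfg$seed, "binary"))
  u <- truth$true_breeding_values[cg$animal]
  gce <- truth$cg_effects[cg$cg]
  e <- rnorm(nrow(cg), 0, sqrt(truth$true_sigma_e2))
  l <- gce + u + e
  t <- qnorm(1 - incidence) *
    sqrt(truth$true_sigma_u2 + truth$true_sigma_e2 + cfg$sigma_cg2)
  data.frame(animal = cg$animal, cg = cg$cg, birth_year = cg$year,
             record_year = cg$year + 4L,
             score = ifelse(l > t, 2L, 1L), liability = l,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic stayability dataset
#'
#' Runs every generator stage under one seed: pedigree, genotypes, truth,
#' contemporary groups, calving histories and the scored phenotype table.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `truth`, `cg`, `histories`,
#'   `phenotypes` and the `config`.
#' @export
simulate_stayability_data <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  truth <- sim_truth(ped, geno, cfg)
  acg <- assign_contemporary_groups(ped, truth, cfg)
  histories <- simulate_calving_histories(ped, acg$truth, cfg, acg$cg)
  phenos <- score_phenotypes(histories, acg$cg)
  list(pedigree = ped, genotypes = geno, truth = acg$truth, cg = acg$cg,
       histories = histories, phenotypes = phenos, config = cfg)
}
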