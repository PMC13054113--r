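#' Descriptive statistics for one stayability definition
#'
#' Reports record and contemporary-group counts, the mean and population SD
#' of the `{1,2}`-coded score, and success/failure counts and percentages.
#' With incidence `alpha` these satisfy `mean = 1 + alpha` and
#' `SD = sqrt(alpha (1 - alpha))` exactly.
#'
#' @param phenos phenotype data.frame with a `cg` column.
#' @param trait score column name.
#' @return one-row data.frame.
#' @export
describe_trait <- function(phenos, trait) {
  if (!trait %in% names(phenos)) stop("trait column not found: ", trait)
  sc <- phenos[[trait]]
  sc <- sc[!is.na(sc)]
  if (!length(sc)) stop("no records for trait ", trait)
  n <- length(sc)
  n2 <- sum(sc == 2)
  alpha <- n2 / n
  data.frame(trait = trait, n = n, n_cg = length(unique(phenos$cg)),
             mean = mean(sc), sd = sqrt(alpha * (1 - alpha)),
             success = n2, success_pct = 100 * alpha,
             failure = n - n2, failure_pct = 100 * (1 - alpha),
             stringsAsFactors = FALSE)
}

#' Run the full single-step stayability analysis pipeline
#'
#' Simulates a dataset (or uses a supplied one), applies genotype QC,
#' builds the relationship set, estimates liability-scale variance
#' components for the selected trait by threshold-model Gibbs sampling,
#' converts them to the observed scale, fits the observed-scale linear
#' model, and runs the LR whole/partial validation for both models.
#' Per-stage outputs (data files, QC report, posterior summary, validation
#' statistics and a combined text report) are written under `out_dir`.
#'
#' @param cfg a [sim_config()] describing the dataset.
#' @param out_dir output directory (created).
#' @param trait one of `stay48_2`, `stay48_3`, `stay54_2`, `stay54_3`,
#'   `stay72_3`, or `binary` for the single-liability trait.
#' @param gibbs_cfg a [gibbs_config()] for variance-component estimation.
#' @param cutoff_years trailing years removed in the LR design.
#' @param genotyped_generations generations (counted from the last) whose
#'   animals are treated as genotyped.
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(cfg, out_dir, trait = "stay48_2",
                         gibbs_cfg = gibbs_config(), cutoff_years = 2L,
                         genotyped_generations = 2L) {
  traits <- c(stay_definitions()$trait, "binary")
  if (!trait %in% traits)
    stop("trait must be one of: ", paste(traits, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  cat("", file = logf)
  log("stage simulate: seed=%d founders=%d generations=%d snps=%d",
      cfg$seed, cfg$n_founders, cfg$n_generations, cfg$n_snps)

  bundle <- simulate_stayability_data(cfg)
  ped <- compute_inbreeding(bundle$pedigree)
  write_pedigree(ped, file.path(out_dir, "pedigree.csv"))
  write_genotypes(bundle$genotypes, file.path(out_dir, "genotypes.txt"),
                  file.path(out_dir, "snp_map.csv"))

  if (trait == "binary") {
    phenos <- simulate_binary_trait(ped, bundle$truth, cfg, bundle$cg)
    score_col <- "score"; ry_col <- "record_year"
  } else {
    phenos <- bundle$phenotypes
    score_col <- trait; ry_col <- paste0("record_year_", trait)
  }
  phenos <- drop_small_cgs(phenos)
  write_phenotypes(phenos, file.path(out_dir, "phenotypes.csv"))

  desc <- do.call(rbind, lapply(
    intersect(c(stay_definitions()$trait, "score"), names(phenos)),
    function(tr) describe_trait(phenos, tr)))
  utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  log("stage describe: %d records, %d CGs for %s",
      nrow(phenos), length(unique(phenos$cg)), score_col)

  # genotyped subset: the youngest generations
  gen <- ped$generation
  geno_ids <- ped$animal_ids[gen > max(gen) - genotyped_generations]
  qc <- apply_qc(subset_genotypes(bundle$genotypes, geno_ids), ped)
  writeLines(utils::capture.output(print(qc$report)),
             file.path(out_dir, "qc_report.txt"))
  utils::write.csv(qc_report_table(qc$report),
                   file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  log("stage qc: retained %d samples x %d markers",
      qc$report$retained["samples"], qc$report$retained["markers"])

  relset <- build_relationship_set(ped, qc$genotypes)
  log("stage relationships: %d genotyped of %d animals",
      length(relset$genotyped_ids), n_animals(ped))

  mdl <- data.frame(animal = phenos$animal, cg = phenos$cg,
                    score = phenos[[score_col]],
                    record_year = phenos[[ry_col]],
                    stringsAsFactors = FALSE)
  chain <- run_gibbs(mdl, relset, gibbs_cfg, mode = "threshold")
  post <- summarize_posterior(chain)
  utils::write.csv(post, file.path(out_dir, "posterior_summary.csv"),
                   row.names = FALSE)
  gw <- geweke_z(chain$samples$h2)
  log("stage gibbs: posterior mean h2=%.3f (Geweke z=%.2f, %s)",
      post$mean[post$parameter == "h2"], gw$z,
      if (gw$pass) "pass" else "FAIL")

  alpha <- mean(mdl$score == 2)
  conv <- liability_to_observed(post$mean[post$parameter == "h2"], alpha)
  writeLines(utils::capture.output(print(conv)),
             file.path(out_dir, "scale_conversion.txt"))

  su_l <- post$mean[post$parameter == "sigma_u2"]
  se_l <- post$mean[post$parameter == "sigma_e2"]
  val <- lapply(c("threshold", "linear"), function(m) {
    r <- run_lr_experiment(mdl, relset, model = m, sigma_u2_l = su_l,
                           sigma_e2_l = se_l, cutoff_years = cutoff_years,
                           trait = trait)
    data.frame(model = m, trait = trait, n_focal = r$n_focal,
               accuracy = r$acc, bias = r$delta, dispersion = r$b1,
               correlation = r$corr, stringsAsFactors = FALSE)
  })
  val <- do.call(rbind, val)
  utils::write.csv(val, file.path(out_dir, "validation.csv"),
                   row.names = FALSE)
  log("stage validate: threshold acc=%.3f b1=%.3f; linear acc=%.3f b1=%.3f",
      val$accuracy[1], val$dispersion[1], val$accuracy[2], val$dispersion[2])

  report <- c(
    "== Descriptive statistics ==",
    utils::capture.output(print(desc, row.names = FALSE)),
    "", "== Posterior summary (liability scale) ==",
    utils::capture.output(print(post, row.names = FALSE)),
    "", "== Observed-scale conversion ==",
    utils::capture.output(print(conv)),
    "", "== LR validation ==",
    utils::capture.output(print(val, row.names = FALSE)))
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(bundle = bundle, phenotypes = phenos, qc = qc,
                 relset = relset, chain = chain, posterior = post,
                 conversion = conv, validation = val,
                 descriptives = desc, out_dir = out_dir))
}

#' Subset a genotype matrix by animal ids
#' @param g a [genotype_matrix()].
#' @param ids animal identifiers to keep.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(g, ids) {
  ids <- intersect(as.character(ids), g$animal_ids)
  if (!length(ids)) stop("no matching animals in the genotype matrix")
  out <- genotype_matrix(ids, g$snp_ids, g$codes[ids, , drop = FALSE],
                         map = g$map)
  attr(out, "founder_freq") <- attr(g, "founder_freq")
  cc <- attr(g, "complete_codes")
  if (!is.null(cc)) {
    rownames(cc) <- g$animal_ids
    attr(out, "complete_codes") <- cc[ids, , drop = FALSE]
  }
  out
}
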