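#' Per-marker allele frequencies
#'
#' Frequency of the counted (second) allele per marker over non-missing
#' calls: `p_j = sum(codes) / (2 * n_called)`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector named by SNP id.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  codes <- g$codes
  miss <- codes == 5L
  called <- colSums(!miss)
  if (any(called == 0))
    stop("marker(s) with no called genotypes: ",
         paste(utils::head(g$snp_ids[called == 0], 5), collapse = ", "))
  codes[miss] <- 0L
  stats::setNames(colSums(codes) / (2 * called), g$snp_ids)
}

#' Default genotype QC thresholds
#'
#' @param call_rate minimum call rate for both samples and markers.
#' @param maf markers with minor allele frequency strictly below this are
#'   removed.
#' @param hwe_p markers with Hardy-Weinberg chi-square p strictly below this
#'   are removed.
#' @param mendel_rate markers with a parent-offspring opposing-homozygote
#'   rate strictly above this are removed.
#' @param excluded_chroms chromosome labels removed outright (sex and
#'   mitochondrial).
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.90, maf = 0.05, hwe_p = 1e-10,
                          mendel_rate = 0.01,
                          excluded_chroms = c("X", "Y", "MT")) {
  list(call_rate = call_rate, maf = maf, hwe_p = hwe_p,
       mendel_rate = mendel_rate, excluded_chroms = excluded_chroms)
}

hwe_chisq_p <- function(codes_col) {
  obs <- c(sum(codes_col == 0L), sum(codes_col == 1L), sum(codes_col == 2L))
  n <- sum(obs)
  if (n == 0) return(1)
  p <- (obs[3] * 2 + obs[2]) / (2 * n)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  ok <- exp > 0
  if (!any(ok)) return(1)
  stat <- sum((obs[ok] - exp[ok])^2 / exp[ok])
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Applies, in a fixed logged order: sample call rate, marker call rate,
#' excluded chromosomes, duplicate map positions (the marker with the
#' highest call rate is kept), Mendelian conflicts against genotyped
#' parents, minor allele frequency, and Hardy-Weinberg equilibrium
#' (chi-square, 1 df).  All marker statistics are computed on the matrix as
#' it stands after sample filtering, before any marker is removed, so the
#' final retained set does not depend on filter order.
#'
#' @param g a [genotype_matrix()].
#' @param ped optional `pedigree` used for Mendelian-conflict checks; when
#'   `NULL` that filter removes nothing.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (class `qc_report`): per-filter removal counts and the thresholds used.
#' @export
apply_qc <- function(g, ped = NULL, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  th <- thresholds
  codes <- g$codes
  n0 <- nrow(codes); m0 <- ncol(codes)

  # 1. sample call rate
  sample_cr <- rowMeans(codes != 5L)
  keep_sample <- sample_cr >= th$call_rate
  removed_samples <- sum(!keep_sample)
  codes <- codes[keep_sample, , drop = FALSE]
  if (nrow(codes) == 0) stop("no samples left after call-rate filtering")

  # marker statistics on the post-sample-filter matrix, pre-removal
  marker_cr <- colMeans(codes != 5L)
  called <- colSums(codes != 5L)
  p <- ifelse(called > 0,
              colSums(ifelse(codes == 5L, 0L, codes)) / pmax(2 * called, 1), NA)
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(codes)),
                  function(j) hwe_chisq_p(codes[codes[, j] != 5L, j]),
                  numeric(1))

  # Mendelian-conflict rate per marker over genotyped parent-offspring pairs
  mend_rate <- rep(0, ncol(codes))
  if (!is.null(ped)) {
    ids <- rownames(codes)
    pos <- match(ids, ped$animal_ids)
    pairs_o <- integer(0); pairs_p <- integer(0)
    for (side in c("sire_index", "dam_index")) {
      par_pos <- ped[[side]][pos]
      par_id <- ifelse(par_pos > 0L, ped$animal_ids[pmax(par_pos, 1L)], NA)
      par_row <- match(par_id, ids)
      ok <- !is.na(par_row)
      pairs_o <- c(pairs_o, which(ok)); pairs_p <- c(pairs_p, par_row[ok])
    }
    if (length(pairs_o)) {
      conf <- inf <- rep(0L, ncol(codes))
      for (k in seq_along(pairs_o)) {
        a <- codes[pairs_o[k], ]; b <- codes[pairs_p[k], ]
        both <- a != 5L & b != 5L
        inf <- inf + both
        conf <- conf + (both & abs(a - b) == 2L)
      }
      mend_rate <- ifelse(inf > 0, conf / inf, 0)
    }
  }

  # duplicate positions: keep the best-called marker of each (chrom,pos) set
  map <- g$map[match(colnames(codes), g$map$snp), ]
  key <- paste(map$chrom, map$pos, sep = ":")
  dup_drop <- logical(ncol(codes))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    keep_one <- idx[which.max(marker_cr[idx])]
    dup_drop[setdiff(idx, keep_one)] <- TRUE
  }

  fail <- list(
    marker_call_rate = marker_cr < th$call_rate,
    excluded_chrom = map$chrom %in% th$excluded_chroms,
    duplicate_position = dup_drop,
    mendelian_conflicts = mend_rate > th$mendel_rate,
    maf = maf < th$maf,
    hwe = hwe_p < th$hwe_p
  )
  # attribute each removed marker to the first filter (in order) that hits it
  seen <- rep(FALSE, ncol(codes))
  removed_markers <- integer(length(fail))
  names(removed_markers) <- names(fail)
  for (f in names(fail)) {
    new <- fail[[f]] & !seen
    removed_markers[f] <- sum(new)
    seen <- seen | fail[[f]]
  }
  keep_marker <- !seen
  if (!any(keep_marker)) stop("no markers left after quality control")

  out <- genotype_matrix(rownames(codes), colnames(codes)[keep_marker],
                         codes[, keep_marker, drop = FALSE],
                         map = g$map[g$map$snp %in% colnames(codes)[keep_marker], ])
  report <- structure(list(
    input = c(samples = n0, markers = m0),
    removed_samples = c(sample_call_rate = removed_samples),
    removed_markers = removed_markers,
    retained = c(samples = nrow(codes), markers = sum(keep_marker)),
    thresholds = th
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  input: %d samples x %d markers\n",
              x$input["samples"], x$input["markers"]))
  cat(sprintf("  samples removed (call rate < %.2f): %d\n",
              x$thresholds$call_rate, x$removed_samples[["sample_call_rate"]]))
  for (f in names(x$removed_markers))
    cat(sprintf("  markers removed by %s: %d\n", f, x$removed_markers[[f]]))
  cat(sprintf("  retained: %d samples x %d markers\n",
              x$retained["samples"], x$retained["markers"]))
  invisible(x)
}

#' Turn a QC report into a one-row-per-filter table
#' @param report a `qc_report`.
#' @return data.frame with `filter`, `axis`, `removed`.
#' @export
qc_report_table <- function(report) {
  data.frame(
    filter = c(names(report$removed_samples), names(report$removed_markers)),
    axis = c(rep("sample", length(report$removed_samples)),
             rep("marker", length(report$removed_markers))),
    removed = c(unname(report$removed_samples), unname(report$removed_markers)),
    stringsAsFactors = FALSE)
}
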