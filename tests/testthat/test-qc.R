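test_that("allele frequencies count the second allele over called genotypes", {
  g <- geno_from_codes(matrix(c(0L, 1L, 2L), ncol = 1))
  expect_equal(unname(allele_frequencies(g)), 0.5)
  g2 <- geno_from_codes(matrix(c(2L, 2L, 5L), ncol = 1))
  expect_equal(unname(allele_frequencies(g2)), 1.0)
  expect_error(allele_frequencies(geno_from_codes(matrix(c(5L, 5L), ncol = 1))),
               "no called")

  # brute-force counting oracle on a random matrix
  set.seed(1)
  codes <- matrix(sample(c(0L, 1L, 2L, 5L), 50 * 200, TRUE,
                         prob = c(.3, .3, .3, .1)), 50, 200)
  codes[, 1] <- 0L                     # guard against all-missing columns
  g3 <- geno_from_codes(codes)
  oracle <- apply(codes, 2, function(col) {
    col <- col[col != 5L]
    sum(col) / (2 * length(col))
  })
  expect_equal(unname(allele_frequencies(g3)), unname(oracle))
})

test_that("call-rate filters use strict thresholds on both axes", {
  set.seed(2)
  # 100 animals x 40 markers, so one missing call costs a sample only 2.5%
  codes <- matrix(rbinom(100 * 40, 2, 0.5), 100, 40)
  codes[1:11, 2] <- 5L                 # marker call rate 0.89 -> removed
  codes[12:21, 3] <- 5L                # 0.90 exactly -> retained
  g <- geno_from_codes(codes)
  res <- apply_qc(g)
  expect_equal(res$report$removed_samples[["sample_call_rate"]], 0L)
  expect_false("m002" %in% res$genotypes$snp_ids)
  expect_true("m003" %in% res$genotypes$snp_ids)

  # sample with call rate below 0.90 is removed
  codes2 <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  codes2[1, 1:6] <- 5L                 # 44/50 = 0.88
  res2 <- apply_qc(geno_from_codes(codes2))
  expect_false("a1" %in% res2$genotypes$animal_ids)
  expect_equal(res2$report$removed_samples[["sample_call_rate"]], 1L)
})

test_that("MAF exactly at the threshold is retained; below is removed", {
  # 100 animals; marker A: p = 0.05 exactly; marker B: p = 0.04
  mk <- function(n_alt, n) c(rep(1L, n_alt), rep(0L, n - n_alt))
  codes <- cbind(mk(10, 100), mk(8, 100),
                 rbinom(100, 2, 0.5))   # p = 0.05, 0.04, ~0.5
  g <- geno_from_codes(codes)
  res <- apply_qc(g)
  expect_true("m001" %in% res$genotypes$snp_ids)
  expect_false("m002" %in% res$genotypes$snp_ids)
})

test_that("Mendelian conflicts, chromosome and duplicate-position filters act", {
  set.seed(3)
  n <- 60; m <- 40
  ids <- c(paste0("p", 1:(n / 2)), paste0("k", 1:(n / 2)))
  ped <- new_pedigree(ids, c(rep("0", n / 2), paste0("p", 1:(n / 2))),
                      rep("0", n))
  par_codes <- matrix(rbinom(n / 2 * m, 2, 0.5), n / 2, m)
  # offspring inherit one allele from the recorded parent, so no marker has
  # Mendelian conflicts by construction
  transmitted <- (par_codes == 2L) + (par_codes == 1L) *
    matrix(rbinom(n / 2 * m, 1, 0.5), n / 2, m)
  kid_codes <- transmitted + matrix(rbinom(n / 2 * m, 1, 0.5), n / 2, m)
  codes <- rbind(par_codes, kid_codes)
  storage.mode(codes) <- "integer"
  # marker 1: every parent-offspring pair becomes an opposing homozygote
  codes[1:(n / 2), 1] <- 0L
  codes[(n / 2 + 1):n, 1] <- 2L
  codes[1, 4] <- 5L                     # m004 has lower call rate than m003
  map <- data.frame(snp = sprintf("m%03d", 1:m),
                    chrom = c("1", "X", "2", "2", rep("3", m - 4)),
                    pos = c(100L, 200L, 300L, 300L, seq(500L, by = 10L,
                                                        length.out = m - 4)))
  g <- geno_from_codes(codes, ids = ids, map = map)
  res <- apply_qc(g, ped = ped)
  kept <- res$genotypes$snp_ids
  expect_false("m001" %in% kept)        # mendelian conflicts
  expect_false("m002" %in% kept)        # sex chromosome
  expect_true("m003" %in% kept)         # duplicate position, better call rate
  expect_false("m004" %in% kept)
  expect_equal(res$report$removed_markers[["excluded_chrom"]], 1L)
  expect_equal(res$report$removed_markers[["duplicate_position"]], 1L)
  expect_gte(res$report$removed_markers[["mendelian_conflicts"]], 1L)
})

test_that("severe Hardy-Weinberg violation is removed", {
  set.seed(4)
  codes <- cbind(rep(c(0L, 2L), 150),          # no heterozygotes at p = 0.5
                 rbinom(300, 2, 0.4))
  res <- apply_qc(geno_from_codes(codes))
  expect_false("m001" %in% res$genotypes$snp_ids)
  expect_true("m002" %in% res$genotypes$snp_ids)
  expect_equal(res$report$removed_markers[["hwe"]], 1L)
})

test_that("QC is idempotent and conserves counts", {
  set.seed(5)
  codes <- matrix(sample(c(0L, 1L, 2L), 80 * 60, TRUE), 80, 60)
  # missingness spread so no sample sits near the call-rate boundary:
  # exactly one missing call per animal (59/60 = 0.983)
  codes[cbind(1:80, rep_len(1:60, 80))] <- 5L
  g <- geno_from_codes(codes)
  r1 <- apply_qc(g)
  r2 <- apply_qc(r1$genotypes)
  expect_identical(r2$genotypes$codes, r1$genotypes$codes)
  expect_equal(sum(r2$report$removed_markers), 0L)

  rep1 <- r1$report
  expect_equal(rep1$retained[["markers"]] + sum(rep1$removed_markers),
               rep1$input[["markers"]])
  expect_equal(rep1$retained[["samples"]] +
                 sum(rep1$removed_samples), rep1$input[["samples"]])
  # report table mirrors the counts
  tab <- qc_report_table(rep1)
  expect_equal(sum(tab$removed[tab$axis == "marker"]),
               sum(rep1$removed_markers))
})
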