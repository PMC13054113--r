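# small pedigrees and genotype fixtures built in code

# sire, dam, offspring trio
trio_pedigree <- function() {
  compute_inbreeding(new_pedigree(c("s", "d", "o"), c("0", "0", "s"),
                                  c("0", "0", "d")))
}

# random discrete-generation pedigree (parents from previous generation)
random_pedigree <- function(n_founders, n_gen, seed = 1) {
  set.seed(seed)
  id <- as.character(seq_len(n_founders * (n_gen + 1)))
  gen <- rep(0:n_gen, each = n_founders)
  sex <- rep_len(c("M", "F"), length(id))
  sire <- dam <- rep("0", length(id))
  pick <- function(x, k) if (length(x) == 1) rep(x, k) else sample(x, k, TRUE)
  for (g in seq_len(n_gen)) {
    prev <- which(gen == g - 1)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    cur <- which(gen == g)
    sire[cur] <- pick(males, length(cur))
    dam[cur] <- pick(females, length(cur))
  }
  compute_inbreeding(new_pedigree(id, sire, dam, sex = sex,
                                  birth_year = 2000L + gen,
                                  generation = gen))
}

# genotype matrix with given codes (animals x snps)
geno_from_codes <- function(codes, ids = NULL, map = NULL) {
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(codes)))
  genotype_matrix(ids, sprintf("m%03d", seq_len(ncol(codes))), codes, map = map)
}

# symmetric positive-definite random matrix with animal dimnames
random_spd <- function(n, seed = 1, ridge = 0.5) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n)
  M <- crossprod(B) / n + ridge * diag(n)
  dimnames(M) <- list(paste0("g", 1:n), paste0("g", 1:n))
  M
}

# G following the APY generative recursion: non-core animals are linear
# functions of the core plus independent residuals, so the non-core
# conditional covariance is exactly diagonal and the APY inverse is exact
apy_recursion_G <- function(n_core, n_noncore, seed = 1) {
  set.seed(seed)
  Gcc <- random_spd(n_core, seed = seed + 1, ridge = 0.3)
  P <- matrix(rnorm(n_noncore * n_core, sd = 1 / sqrt(n_core)),
              n_noncore, n_core)
  D <- diag(runif(n_noncore, 0.2, 0.6))
  G <- rbind(cbind(Gcc, Gcc %*% t(P)),
             cbind(P %*% Gcc, P %*% Gcc %*% t(P) + D))
  ids <- paste0("g", seq_len(n_core + n_noncore))
  dimnames(G) <- list(ids, ids)
  G
}
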