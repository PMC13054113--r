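make_fit_fixture <- function(n_founders = 20, n_gen = 9, seed = 15,
                             n_cg = 8, h2 = 0.3) {
  ped <- random_pedigree(n_founders, n_gen, seed = seed)
  n <- n_animals(ped)
  set.seed(seed + 100)
  su <- h2 / (1 - h2)
  A <- build_A(ped)
  u <- drop(chol(A + 1e-8 * diag(n)) %*% rnorm(n)) * sqrt(su)
  cg <- sample(seq_len(n_cg), n, replace = TRUE)
  phenos <- data.frame(animal = ped$animal_ids, cg = cg,
                       score = 1 + (cg / n_cg) + u + rnorm(n),
                       stringsAsFactors = FALSE)
  list(ped = ped, phenos = phenos, spec = model_spec("score", su, 1))
}

dense_mme_solution <- function(phenos, ped, H, spec) {
  cgf <- factor(phenos$cg)
  X <- model.matrix(~ 0 + cgf)
  Z <- matrix(0, nrow(phenos), n_animals(ped))
  Z[cbind(seq_len(nrow(phenos)), match(phenos$animal, ped$animal_ids))] <- 1
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + spec$lambda * as.matrix(H)))
  y <- phenos[[spec$response]]
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  list(beta = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

test_that("PCG solutions match the dense direct solve", {
  fx <- make_fit_fixture()                       # 200 animals
  relset <- build_relationship_set(fx$ped, NULL)
  fit <- solve_mme(fx$phenos, fx$ped, relset, fx$spec)
  expect_true(fit$convergence$converged)
  oracle <- dense_mme_solution(fx$phenos, fx$ped, relset$H_inv, fx$spec)
  expect_lt(max(abs(unname(fit$gebv) - oracle$u)), 1e-6)
  expect_lt(max(abs(unname(fit$beta_hat) - oracle$beta)), 1e-6)
})

test_that("with genomic information the solver still matches the dense oracle", {
  fx <- make_fit_fixture(seed = 16)
  gids <- sample(fx$ped$animal_ids, 60)
  A22 <- build_A22(fx$ped, gids)
  G <- blend_G(tune_G(random_spd(60, seed = 17), A22), A22)
  dimnames(G) <- list(gids, gids)
  H <- assemble_H_inverse(build_A_inverse(fx$ped), A22, G)
  fit <- solve_mme(fx$phenos, fx$ped, H, fx$spec)
  oracle <- dense_mme_solution(fx$phenos, fx$ped, H, fx$spec)
  expect_lt(max(abs(unname(fit$gebv) - oracle$u)), 1e-6)
})

test_that("solutions are translation invariant and shrink with lambda", {
  fx <- make_fit_fixture(seed = 18)
  relset <- build_relationship_set(fx$ped, NULL)
  fit1 <- solve_mme(fx$phenos, fx$ped, relset, fx$spec)
  ph2 <- fx$phenos; ph2$score <- ph2$score + 7
  fit2 <- solve_mme(ph2, fx$ped, relset, fx$spec)
  expect_lt(max(abs(fit2$gebv - fit1$gebv)), 1e-5)
  expect_equal(unname(fit2$beta_hat - fit1$beta_hat),
               rep(7, length(fit1$beta_hat)), tolerance = 1e-5)

  # increasing lambda shrinks the spread of GEBV
  specs <- lapply(c(0.5, 2, 8), function(l) model_spec("score", 1 / l, 1))
  vars <- vapply(specs, function(s)
    var(solve_mme(fx$phenos, fx$ped, relset, s)$gebv), numeric(1))
  expect_true(all(diff(vars) < 0))

  # identical records for two full sibs in one CG give equal GEBV
  ped <- compute_inbreeding(new_pedigree(c("s", "d", "f1", "f2"),
                                         c("0", "0", "s", "s"),
                                         c("0", "0", "d", "d")))
  rs <- build_relationship_set(ped, NULL)
  ph <- data.frame(animal = c("f1", "f2"), cg = c(1, 1), score = c(2, 2))
  fit <- solve_mme(ph, ped, rs, model_spec("score", 0.5, 1))
  expect_equal(fit$gebv[["f1"]], fit$gebv[["f2"]], tolerance = 1e-9)
})

test_that("reliability proxy matches the dense inverse and orders information", {
  fx <- make_fit_fixture(n_founders = 10, n_gen = 4, seed = 19)   # 50 animals
  relset <- build_relationship_set(fx$ped, NULL)
  rel <- reliability_proxy(fx$phenos, fx$ped, relset, fx$spec)

  # direct dense recomputation
  cgf <- factor(fx$phenos$cg)
  X <- model.matrix(~ 0 + cgf)
  Z <- diag(n_animals(fx$ped))[match(fx$phenos$animal, fx$ped$animal_ids), ]
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X),
                   crossprod(Z) + fx$spec$lambda * as.matrix(relset$H_inv)))
  pev <- diag(solve(C))[-seq_len(ncol(X))] * fx$spec$sigma_e2
  oracle <- pmax(0, 1 - pev / (fx$spec$sigma_u2 * (1 + fx$ped$inbreeding)))
  expect_lt(max(abs(unname(rel) - oracle)), 1e-8)

  # an unphenotyped, unrelated founder carries no information; a recorded
  # animal does (a second recorded animal anchors the CG solution)
  ped2 <- compute_inbreeding(new_pedigree(c("a", "b", "c"),
                                          c("0", "0", "0"), c("0", "0", "0")))
  rs2 <- build_relationship_set(ped2, NULL)
  ph2 <- data.frame(animal = rep(c("a", "c"), each = 8), cg = 1,
                    score = rnorm(16) + 2)
  rel2 <- reliability_proxy(ph2, ped2, rs2, model_spec("score", 1, 1))
  expect_equal(rel2[["b"]], 0)
  expect_gt(rel2[["a"]], rel2[["b"]])

  expect_error(reliability_proxy(fx$phenos, fx$ped, relset, fx$spec,
                                 max_n = 10), "too large")
})

test_that("EM threshold solver reduces to the linear solver in the no-data limit and is deterministic", {
  fx <- make_fit_fixture(seed = 20)
  relset <- build_relationship_set(fx$ped, NULL)
  ph <- fx$phenos
  ph$score <- ifelse(ph$score > median(ph$score), 2L, 1L)
  fit1 <- solve_threshold_mme(ph, fx$ped, relset, sigma_u2 = 0.4)
  fit2 <- solve_threshold_mme(ph, fx$ped, relset, sigma_u2 = 0.4)
  expect_true(fit1$convergence$converged)
  expect_identical(fit1$gebv, fit2$gebv)

  # ranking broadly agrees with a linear fit on the same scores
  lin <- solve_mme(ph, fx$ped, relset, model_spec("score", 0.4, 1))
  expect_gt(cor(fit1$gebv, lin$gebv), 0.95)

  # swapping the category labels flips the sign of the GEBV
  ph3 <- ph; ph3$score <- 3L - ph3$score
  fit3 <- solve_threshold_mme(ph3, fx$ped, relset, sigma_u2 = 0.4)
  expect_lt(max(abs(fit3$gebv + fit1$gebv)), 1e-4)
})
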