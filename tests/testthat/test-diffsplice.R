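test_that("negative-binomial fits handle saturated and empty regions", {
  ## all spliced-in: retention at the upper bound
  f1 <- nb_fit(k = c(200, 200, 200), n = c(200, 200, 200))
  expect_gt(f1$p_hat, 0.999)
  ## never spliced-in: retention at the floor
  f2 <- nb_fit(k = c(0, 0, 0), n = c(200, 200, 200))
  expect_lt(f2$p_hat, 1e-5)
  ## no coverage at all is reported, not fitted
  f3 <- nb_fit(k = c(0, 0), n = c(0, 0))
  expect_equal(f3$status, "no_coverage")
  ## invalid counts are rejected
  expect_error(nb_fit(k = 5, n = 3), "k_i <= n_i")
})

test_that("the retention MLE recovers the generating probability", {
  set.seed(202)
  n_cov <- 200L
  for (p in c(0.3, 0.8)) {
    est <- replicate(100, {
      k <- pmin(rnbinom(3, mu = p * n_cov, size = 50), n_cov)
      nb_fit(k, rep(n_cov, 3))$p_hat
    })
    expect_lt(abs(mean(est) - p), 0.03)
  }
})

test_that("identical data in both conditions gives lambda exactly 1", {
  k <- c(37L, 52L, 41L); n <- c(180L, 210L, 190L)
  r <- likelihood_ratio(k, n, k, n)
  expect_identical(r$lambda, 1)
  expect_identical(r$log_lambda, 0)
  expect_equal(r$delta_psi, 0)
})

test_that("lambda shrinks monotonically with the retention difference", {
  n <- rep(200L, 3)
  k_a <- c(190L, 195L, 192L)
  lam <- vapply(list(c(60L, 65L, 58L),   # large shift
                     c(120L, 125L, 118L), # medium
                     c(160L, 165L, 158L), # small
                     c(185L, 192L, 194L)),# near-null
                function(k_b) likelihood_ratio(k_a, n, k_b, n)$lambda, 0)
  expect_lt(lam[1], 1e-4)
  expect_true(all(diff(lam) > 0))
})

test_that("opposite extremes minimise lambda over the count grid", {
  n <- 50L
  grid <- expand.grid(ka = seq(0L, n, by = 5L), kb = seq(0L, n, by = 5L))
  lam <- mapply(function(ka, kb)
    likelihood_ratio(ka, n, kb, n)$lambda, grid$ka, grid$kb)
  best <- grid[which.min(lam), ]
  expect_equal(abs(best$ka - best$kb), n)
})

test_that("the joint model is always nested: lambda <= 1", {
  set.seed(303)
  worst <- 0
  for (i in 1:400) {
    n_a <- sample(50:400, 3, replace = TRUE)
    n_b <- sample(50:400, 3, replace = TRUE)
    k_a <- rbinom(3, n_a, runif(1))
    k_b <- rbinom(3, n_b, runif(1))
    r <- likelihood_ratio(k_a, n_a, k_b, n_b)
    worst <- max(worst, r$log_lambda)
  }
  expect_lte(worst, 1e-6)
})

test_that("lambda separates true differential retention from the null", {
  set.seed(404)
  n_cov <- rep(200L, 3)
  sim_lambda <- function(p_a, p_b) {
    k_a <- pmin(rnbinom(3, mu = p_a * 200, size = 50), 200L)
    k_b <- pmin(rnbinom(3, mu = p_b * 200, size = 50), 200L)
    likelihood_ratio(k_a, n_cov, k_b, n_cov)$lambda
  }
  alt <- replicate(60, sim_lambda(0.3, 0.6))
  null <- replicate(60, sim_lambda(0.45, 0.45))
  expect_lt(median(alt), quantile(null, 0.05))
})

test_that("Benjamini-Hochberg adjustment follows the hand formula", {
  expect_equal(fdr_correct(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_correct(numeric(0)), numeric(0))
  ## order invariance
  x <- c(0.5, 0.001, 0.2, 0.04)
  perm <- c(3, 1, 4, 2)
  expect_equal(fdr_correct(x)[perm], fdr_correct(x[perm]))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("diff_splice assembles a full per-region table", {
  counts <- rbind(
    data.frame(gene_id = "g", region_id = "g:0-100", start = 0L, end = 100L,
               sample_id = paste0("a_", 1:3), condition = "a",
               replicate = 1:3, k = c(190L, 195L, 192L), n = rep(200L, 3)),
    data.frame(gene_id = "g", region_id = "g:0-100", start = 0L, end = 100L,
               sample_id = paste0("b_", 1:3), condition = "b",
               replicate = 1:3, k = c(60L, 65L, 58L), n = rep(200L, 3)),
    data.frame(gene_id = "g", region_id = "g:100-200", start = 100L,
               end = 200L, sample_id = paste0("a_", 1:3), condition = "a",
               replicate = 1:3, k = c(50L, 52L, 49L), n = rep(200L, 3)),
    data.frame(gene_id = "g", region_id = "g:100-200", start = 100L,
               end = 200L, sample_id = paste0("b_", 1:3), condition = "b",
               replicate = 1:3, k = c(50L, 52L, 49L), n = rep(200L, 3)))
  res <- diff_splice(counts, "a", "b", calibrate = TRUE)
  expect_equal(nrow(res), 2L)
  shifted <- res[res$region_id == "g:0-100", ]
  null <- res[res$region_id == "g:100-200", ]
  expect_lt(shifted$lambda, 1e-4)
  expect_identical(null$lambda, 1)
  expect_lt(shifted$delta_psi, -0.5)
  expect_true(all(res$fdr >= res$lambda - 1e-12))
  expect_true(all(c("neg_log10_fdr", "p_chisq") %in% names(res)))
})
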