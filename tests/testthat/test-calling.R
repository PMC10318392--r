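test_that("zero-depth sites return the prior weights exactly", {
  fit <- point_mass_fit(c(0.5, 0.3, 0.2), c(0.002, 0.5, 0.998),
                        c(500, 20, 500))
  p <- genotype_posteriors(fit, counts_tab(0, 0))
  expect_equal(unname(p[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-12)
  # Hardy-Weinberg prior mode
  cts <- counts_tab(0, 0)
  cts$eaf <- 0.2
  p2 <- genotype_posteriors(fit, cts, prior_mode = "hwe")
  expect_equal(unname(p2[1, ]), c(0.64, 0.32, 0.04), tolerance = 1e-12)
  expect_error(genotype_posteriors(fit, counts_tab(0, 0),
                                   prior_mode = "hwe"), "eaf")
})

test_that("posterior matches a hand-evaluated single-draw Bayes rule", {
  theta <- c(1, 1, 1) / 3
  mu <- c(0.002, 0.5, 0.998)
  kappa <- c(500, 20, 500)
  fit <- point_mass_fit(theta, mu, kappa)
  p <- genotype_posteriors(fit, counts_tab(20, 40))
  lik <- vapply(1:3, function(g) oracle_bb_pmf(20, 40, mu[g], kappa[g]),
                numeric(1))
  expect_equal(unname(p[1, ]), theta * lik / sum(theta * lik),
               tolerance = 1e-9)
  # with equalized component likelihoods the posterior is the prior
  pr <- c(0.6, 0.3, 0.1)
  fit2 <- point_mass_fit(pr, c(0.25, 0.5, 0.75), c(2, 2, 2))
  # kappa = 2 makes every component uniform on 0..n for mu = 0.5; for the
  # symmetric mu pair a single read splits evenly too: engineer n = 0
  p3 <- genotype_posteriors(fit2, counts_tab(0, 0))
  expect_equal(unname(p3[1, ]), pr, tolerance = 1e-12)
})

test_that("plugin and averaged posteriors agree for point-mass draws", {
  fit <- point_mass_fit(c(0.5, 0.3, 0.2), c(0.002, 0.5, 0.998),
                        c(500, 20, 500))
  cts <- counts_tab(c(0, 10, 25), c(30, 20, 26))
  expect_equal(genotype_posteriors(fit, cts, method = "average"),
               genotype_posteriors(fit, cts, method = "plugin"),
               tolerance = 1e-12)
})

test_that("hard calls threshold the argmax with an inclusive boundary", {
  expect_identical(hard_call(c(0.995, 0.004, 0.001), 0.99), 0L)
  expect_identical(hard_call(c(0.5, 0.3, 0.2), 0.99), NA_integer_)
  expect_identical(hard_call(c(0.90, 0.06, 0.04), 0.90), 0L)
  expect_identical(hard_call(rbind(c(0.01, 0.01, 0.98),
                                   c(0.2, 0.75, 0.05)), 0.7),
                   c(2L, 1L))
  expect_error(hard_call(c(0.4, 0.3, 0.3), threshold = 1 / 3), "threshold")
  expect_error(hard_call(c(0.6, 0.3, 0.2)), "sum to 1")
})

test_that("call_genotypes is order-preserving, site-independent, complete", {
  fit <- point_mass_fit(c(0.5, 0.3, 0.2), c(0.002, 0.5, 0.998),
                        c(500, 20, 500))
  empty <- call_genotypes(fit, counts_tab(integer(0), integer(0)))
  expect_equal(nrow(empty), 0)
  cts <- counts_tab(c(0, 10, 25, 1), c(30, 20, 26, 40))
  calls <- call_genotypes(fit, cts, threshold = 0.99)
  expect_identical(calls$site_id, cts$site_id)
  # duplicating every observation (fresh ids) duplicates the calls
  dup <- rbind(cts, counts_tab(cts$n_alt, cts$n_total))
  dup$site_id <- paste0("r", seq_len(nrow(dup)))
  calls2 <- call_genotypes(fit, dup, threshold = 0.99)
  expect_equal(calls2$p_g1[1:4], calls2$p_g1[5:8], tolerance = 1e-12)
  expect_identical(calls2$hard_call[1:4], calls2$hard_call[5:8])
  # dosage populated everywhere, including missing hard calls
  expect_true(all(is.finite(calls$dosage)))
  expect_equal(calls$dosage, calls$p_g1 + 2 * calls$p_g2, tolerance = 1e-12)
})

test_that("non-missing hard calls are non-increasing in the threshold", {
  sim <- simulate_counts(1500, theta = c(0.6, 0.25, 0.15), seed = 41)
  fit <- quick_fit(select_training(sim$counts, 500, 10, seed = 1),
                   seed = 2)
  p <- genotype_posteriors(fit, sim$counts)
  n_called <- vapply(c(0.90, 0.95, 0.99),
                     function(t) sum(!is.na(hard_call(p, t))), numeric(1))
  expect_true(all(diff(n_called) <= 0))
  # dosage rounding agrees with the hard call whenever one is made
  calls <- call_genotypes(fit, sim$counts, threshold = 0.95)
  made <- !is.na(calls$hard_call)
  expect_true(all(floor(calls$dosage[made] + 0.5) ==
                  calls$hard_call[made]))
})

test_that("confidence in the true genotype grows with depth", {
  sim <- simulate_counts(3000, theta = c(0.6, 0.25, 0.15), seed = 42,
                         depth = "nbinom", depth_mean = 30, depth_size = 3)
  fit <- quick_fit(select_training(sim$counts, 800, 10, seed = 3),
                   seed = 4)
  p <- genotype_posteriors(fit, sim$counts)
  p_true <- p[cbind(seq_len(nrow(p)), sim$genotypes + 1L)]
  depth <- sim$counts$n_total
  bins <- cut(depth, c(-1, 5, 15, 30, Inf))
  m <- tapply(p_true, bins, mean)
  expect_true(all(diff(m) > -0.02)) # non-decreasing within MC error
})
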