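test_that("beta-binomial pmf matches direct Beta-function evaluation", {
  # empty observation has probability one
  expect_identical(dbetabinom(0, 0, 0.3, 5, log = TRUE), 0)
  expect_identical(dbetabinom(0, 0, 0.9, 100, log = TRUE), 0)
  # mu = 0.5, kappa = 2 gives alpha = beta = 1: discrete uniform on 0..n
  expect_equal(dbetabinom(0:10, 10, 0.5, 2), rep(1 / 11, 11),
               tolerance = 1e-12)
  # direct evaluation oracle
  expect_equal(dbetabinom(3, 10, 0.5, 4), oracle_bb_pmf(3, 10, 0.5, 4),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(0:40, 1)
    x <- if (n > 0) sample(0:n, 1) else 0L
    mu <- runif(1, 0.01, 0.99)
    kappa <- runif(1, 0.1, 300)
    expect_equal(dbetabinom(x, n, mu, kappa),
                 oracle_bb_pmf(x, n, mu, kappa), tolerance = 1e-10)
  }
})

test_that("pmf normalizes, is symmetric, and reaches the binomial limit", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    mu <- runif(1, 0.01, 0.99)
    kappa <- exp(runif(1, log(0.1), log(1e4)))
    expect_equal(sum(dbetabinom(0:n, n, mu, kappa)), 1, tolerance = 1e-10)
    k <- sample(0:n, 1)
    expect_equal(dbetabinom(k, n, mu, kappa, log = TRUE),
                 dbetabinom(n - k, n, 1 - mu, kappa, log = TRUE),
                 tolerance = 1e-9)
  }
  for (n in c(10, 50, 100)) {
    mu <- 0.37
    expect_lt(max(abs(dbetabinom(0:n, n, mu, 1e8) -
                      dbinom(0:n, n, mu))), 1e-6)
  }
  # no overflow at extreme depth
  expect_true(is.finite(dbetabinom(5e5, 1e6, 0.5, 50, log = TRUE)))
})

test_that("component samples match the mean and are overdispersed", {
  set.seed(31)
  n <- 100L
  mu <- 0.48
  kappa <- 20
  x <- rbetabinom(20000, n, mu, kappa)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - n * mu), 4 * se)
  # variance exceeds binomial variance for finite kappa
  expect_gt(var(x), n * mu * (1 - mu))
  # boundary means give noise-free homozygote limits
  expect_true(all(rbetabinom(50, 100, 0, 1e9) == 0))
  expect_true(all(rbetabinom(50, 100, 1, 1e9) == 100))
})

test_that("shape/mean-overdispersion reparameterization round-trips", {
  r <- ab_to_mulambda(10, 10)
  expect_equal(r$mu, 0.5)
  expect_equal(r$lambda, 1 / 21)
  r <- ab_to_mulambda(1, 499)
  expect_equal(r$mu, 0.002)
  expect_equal(r$lambda, 1 / 501)
  set.seed(41)
  for (i in 1:20) {
    mu <- runif(1, 0.01, 0.99)
    lam <- runif(1, 0.001, 0.9)
    ab <- mulambda_to_ab(mu, lam)
    back <- ab_to_mulambda(ab$alpha, ab$beta)
    expect_equal(back$mu, mu, tolerance = 1e-12)
    expect_equal(back$lambda, lam, tolerance = 1e-12)
  }
  expect_error(ab_to_mulambda(-1, 2), "alpha")
  expect_error(mulambda_to_ab(0.5, 1.2), "lambda")
})

test_that("pmf rejects out-of-domain arguments by name", {
  expect_error(dbetabinom(5, 3, 0.5, 2), "size")
  expect_error(dbetabinom(1, 3, 1.2, 2), "mu")
  expect_error(dbetabinom(1, 3, 0.5, -2), "kappa")
})

test_that("mixture log-likelihood matches the brute-force oracle", {
  theta <- c(0.5, 0.3, 0.2)
  mu <- c(0.002, 0.48, 0.998)
  kappa <- c(500, 20, 500)
  # degenerate mixture reduces to a single component
  cts <- counts_tab(c(0, 1, 0, 2, 0), c(20, 25, 14, 30, 9))
  expect_equal(bb_mixture_loglik(cts, c(1, 0, 0), mu, kappa),
               sum(dbetabinom(cts$n_alt, cts$n_total, mu[1], kappa[1],
                              log = TRUE)), tolerance = 1e-12)
  # zero-depth site contributes exactly nothing
  ll0 <- bb_mixture_loglik(cts, theta, mu, kappa)
  cts2 <- counts_tab(c(cts$n_alt, 0), c(cts$n_total, 0))
  expect_equal(bb_mixture_loglik(cts2, theta, mu, kappa), ll0,
               tolerance = 1e-12)
  # hand-enumerated five-site instance against plain-arithmetic summation
  five <- counts_tab(c(0, 10, 19, 3, 7), c(18, 21, 20, 30, 15))
  expect_equal(bb_mixture_loglik(five, theta, mu, kappa),
               oracle_mix_ll(five, theta, mu, kappa), tolerance = 1e-9)
  # randomized small instances
  set.seed(51)
  for (i in 1:15) {
    m <- sample(1:10, 1)
    n <- sample(5:60, m, replace = TRUE)
    x <- vapply(n, function(ni) sample(0:ni, 1), 1L)
    th <- as.vector(rmultinom(1, 100, c(1, 1, 1))) / 100
    cc <- counts_tab(x, n)
    expect_equal(bb_mixture_loglik(cc, th, mu, kappa),
                 oracle_mix_ll(cc, th, mu, kappa), tolerance = 1e-9)
  }
  # site order is irrelevant
  perm <- five[c(3, 1, 5, 2, 4), ]
  expect_equal(bb_mixture_loglik(perm, theta, mu, kappa),
               bb_mixture_loglik(five, theta, mu, kappa),
               tolerance = 1e-12)
  expect_error(bb_mixture_loglik(counts_tab(integer(0), integer(0)),
                                 theta, mu, kappa), "at least one")
})

test_that("log prior matches independent density evaluations", {
  pr <- bb_priors()
  theta <- c(0.2, 0.5, 0.3)
  mu <- c(0.002, 0.5, 0.998)
  kappa <- c(500, 20, 500)
  # flat Dirichlet contributes log Gamma(3) = log 2 for any valid theta
  lp1 <- bb_log_prior(theta, mu, kappa, pr)
  lp2 <- bb_log_prior(c(1, 1, 1) / 3, mu, kappa, pr)
  expect_equal(lp1, lp2, tolerance = 1e-12)
  # isolate component terms with hand-written densities
  lbeta_dens <- function(x, a, b)
    (a - 1) * log(x) + (b - 1) * log(1 - x) - (lgamma(a) + lgamma(b) -
                                               lgamma(a + b))
  lgamma_dens <- function(x, shape) (shape - 1) * log(x) - x -
    lgamma(shape)
  expected <- log(2) +
    lbeta_dens(mu[1], 1, 499) + lbeta_dens(mu[2], 10, 10) +
    lbeta_dens(mu[3], 499, 1) +
    lgamma_dens(kappa[1], 500) + lgamma_dens(kappa[2], 20) +
    lgamma_dens(kappa[3], 500)
  expect_equal(lp1, expected, tolerance = 1e-9)
  # boundary of support yields -Inf, not an error
  expect_identical(bb_log_prior(c(1, 0, 0), mu, kappa, pr), -Inf)
})
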