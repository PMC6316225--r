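test_that("closed-form MLEs use the n denominator and satisfy the AIC identity", {
  f <- fit_family(c(1, 3), "normal")
  expect_equal(unname(f$params), c(2, 1)) # sd with n denominator, not n-1
  expect_equal(f$aic, 2 * 2 - 2 * f$loglik)

  x <- exp(rnorm(50, 1, 0.3))
  f <- fit_family(x, "lognormal")
  expect_equal(f$params[["meanlog"]], mean(log(x)))
  expect_equal(f$params[["sdlog"]], sqrt(mean((log(x) - mean(log(x)))^2)))

  f <- fit_family(c(0.5, 1.5, 4), "exponential")
  expect_equal(f$params[["rate"]], 1 / 2)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik) # one free parameter

  expect_error(fit_family(c(1, -1), "lognormal"), "positive")
  expect_error(fit_family(1, "normal"), "at least 2")
})

test_that("truncated-normal log-likelihood matches its definition", {
  # far from the truncation point the correction vanishes
  x <- rnorm(200, 100, 1)
  expect_equal(truncated_normal_loglik(100, 1, x),
               sum(dnorm(x, 100, 1, log = TRUE)), tolerance = 1e-9)
  # single datum at the mode
  mu <- 1.3; sigma <- 0.7
  expect_equal(truncated_normal_loglik(mu, sigma, mu),
               log(dnorm(0)) - log(sigma) - log(1 - pnorm(-mu / sigma)))
  expect_error(truncated_normal_loglik(1, -1, c(1, 2)), "sigma")
  expect_error(truncated_normal_loglik(1, 1, c(-0.1, 2)), "non-negative")
})

test_that("truncated-normal density integrates to 1 on [0, Inf)", {
  for (par in list(c(1, 2), c(-0.5, 1), c(0.037, 0.06), c(10, 3))) {
    dens <- function(x) {
      exp(vapply(x, function(xi)
        truncated_normal_loglik(par[1], par[2], xi), numeric(1)))
    }
    total <- integrate(dens, 0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("every family recovers known parameters within 3 SE at n = 10,000", {
  n <- 10000
  set.seed(101)
  truth <- list(
    normal = list(params = c(mean = 199, sd = 111),
                  draw = function(n) rnorm(n, 199, 111)),
    lognormal = list(params = c(meanlog = 2.05, sdlog = 0.792),
                     draw = function(n) rlnorm(n, 2.05, 0.792)),
    gamma = list(params = c(shape = 3.00, rate = 0.0151),
                 draw = function(n) rgamma(n, 3.00, 0.0151)),
    weibull = list(params = c(shape = 6.53, scale = 0.027),
                   draw = function(n) rweibull(n, 6.53, 0.027)),
    exponential = list(params = c(rate = 13.5),
                       draw = function(n) rexp(n, 13.5)),
    truncated_normal = list(
      params = c(mu = 0.5, sigma = 1),
      draw = function(n) {
        p0 <- pnorm(0, 0.5, 1)
        qnorm(p0 + runif(n) * (1 - p0), 0.5, 1)
      }))
  loglik_fun <- function(fam, x) {
    switch(fam,
      normal = function(p) sum(dnorm(x, p[1], p[2], log = TRUE)),
      lognormal = function(p) sum(dlnorm(x, p[1], p[2], log = TRUE)),
      gamma = function(p) sum(dgamma(x, p[1], p[2], log = TRUE)),
      weibull = function(p) sum(dweibull(x, p[1], p[2], log = TRUE)),
      exponential = function(p) sum(dexp(x, p[1], log = TRUE)),
      truncated_normal = function(p) truncated_normal_loglik(p[1], p[2], x))
  }
  for (fam in names(truth)) {
    x <- truth[[fam]]$draw(n)
    fit <- fit_family(x, fam)
    # observed-information standard errors at the fitted optimum
    H <- optimHess(unname(fit$params), loglik_fun(fam, x))
    se <- sqrt(diag(solve(-H)))
    err <- abs(unname(fit$params) - unname(truth[[fam]]$params))
    expect_true(all(err < 3 * se),
                label = sprintf("%s parameters within 3 SE (err %s, se %s)",
                                fam, paste(signif(err, 3), collapse = "/"),
                                paste(signif(se, 3), collapse = "/")))
  }
})

test_that("fitted optimum beats perturbed parameter vectors", {
  set.seed(5)
  x <- rweibull(2000, 6.53, 0.027)
  fit <- fit_family(x, "weibull")
  ll_at <- function(shape, scale) {
    sum(dweibull(x, shape, scale, log = TRUE))
  }
  for (eps in c(-0.05, 0.05)) {
    expect_gte(fit$loglik, ll_at(fit$params[["shape"]] * (1 + eps),
                                 fit$params[["scale"]]))
    expect_gte(fit$loglik, ll_at(fit$params[["shape"]],
                                 fit$params[["scale"]] * (1 + eps)))
  }

  p0 <- pnorm(0, 0.02, 0.05)
  xt <- qnorm(p0 + runif(2000) * (1 - p0), 0.02, 0.05)
  tf <- fit_family(xt, "truncated_normal")
  for (eps in c(-0.1, 0.1)) {
    expect_gte(tf$loglik,
               truncated_normal_loglik(tf$params[["mu"]] * (1 + eps),
                                       tf$params[["sigma"]], xt))
    expect_gte(tf$loglik,
               truncated_normal_loglik(tf$params[["mu"]],
                                       tf$params[["sigma"]] * (1 + eps), xt))
  }
})

test_that("numerical fits agree with an independent MLE implementation", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- rgamma(800, 3, 0.0151)
  ours <- fit_family(x, "gamma")
  ref <- MASS::fitdistr(x, "gamma")
  expect_equal(unname(ours$params), unname(ref$estimate), tolerance = 1e-2)
  expect_gte(ours$loglik, ref$loglik - 1e-6) # at least as good an optimum

  y <- rweibull(800, 6.53, 0.027)
  ours <- fit_family(y, "weibull")
  ref <- suppressWarnings(MASS::fitdistr(y, "weibull"))
  expect_equal(unname(ours$params), unname(ref$estimate), tolerance = 1e-2)
  expect_gte(ours$loglik, ref$loglik - 1e-6)
})

test_that("AIC selection recovers the generating family at large n", {
  set.seed(31)
  wins_gamma <- 0
  wins_lnorm <- 0
  for (i in 1:20) {
    g <- select_best_model(rgamma(5000, 3, 0.0151))
    wins_gamma <- wins_gamma + (g$family == "gamma")
    l <- select_best_model(rlnorm(5000, 2.05, 0.792))
    wins_lnorm <- wins_lnorm + (l$family == "lognormal")
  }
  expect_gte(wins_gamma, 18)
  expect_gte(wins_lnorm, 18)
})

test_that("select_best_model exposes the full competition and handles edge cases", {
  set.seed(41)
  x <- rgamma(500, 3, 0.0151)
  best <- select_best_model(x)
  tab <- aic_table(best)
  expect_setequal(tab$family, c("normal", "lognormal", "truncated_normal",
                                "gamma", "weibull"))
  expect_equal(tab$aic, sort(tab$aic))
  expect_equal(min(tab$aic), best$aic)

  only <- select_best_model(x, families = "weibull")
  expect_equal(only$family, "weibull")

  # a family that cannot fit (non-positive data) is dropped, not fatal
  y <- c(-1, 0.5, 1.2, 2.5, 0.1, 3)
  sel <- select_best_model(y, families = c("lognormal", "normal"))
  expect_equal(sel$family, "normal")
  expect_error(select_best_model(y, families = "lognormal"), "all candidate")
})

test_that("sampling from a fit is inverse-CDF, seeded, with the right mean", {
  fit <- dist_spec("gamma", shape = 3.00, rate = 0.0151)
  set.seed(8); a <- sample_from_fit(fit, 1000)
  set.seed(8); b <- sample_from_fit(fit, 1000)
  expect_identical(a, b)
  expect_error(sample_from_fit(fit, 0), "positive")

  set.seed(9)
  big <- sample_from_fit(fit, 1e6)
  expect_equal(mean(big), 3 / 0.0151, tolerance = 0.005)

  # truncated-normal sampler honours the support and its closed-form mean
  tn <- dist_spec("truncated_normal", mu = 0.5, sigma = 1)
  set.seed(10)
  s <- sample_from_fit(tn, 2e5)
  expect_true(all(s >= 0))
  mu <- 0.5; sig <- 1
  tn_mean <- mu + sig * dnorm(-mu / sig) / (1 - pnorm(-mu / sig))
  expect_equal(mean(s), tn_mean, tolerance = 0.01)
})

test_that("dist_spec validates its parameters", {
  expect_error(dist_spec("weibull", shape = 6.53), "scale")
  expect_error(dist_spec("gamma", shape = -1, rate = 2), "positive")
  f <- dist_spec("lognormal", meanlog = 2.05, sdlog = 0.792)
  expect_true(is.na(f$loglik))
})
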