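test_that("design rows match their functional forms", {
  expect_equal(design_row(c(100, 200), "linear"),
               cbind(1, c(100, 200)), ignore_attr = TRUE)
  expect_equal(design_row(c(5, 50, 500), "intercept_only"),
               matrix(1, 3, 1))
})

test_that("the underlying B-spline basis is a partition of unity", {
  x <- seq(10, 2000, length.out = 200)
  df <- 4; degree <- 3
  D <- design_row(x, "spline", spline_df = df, spline_degree = degree)
  expect_equal(dim(D), c(200L, df + 1L))
  expect_true(all(D[, 1] == 1))
  # reference evaluator: full B-spline basis via splineDesign sums to 1;
  # the design carries all but its first member, so bs columns + the
  # omitted first basis function must reconstruct the unit partition
  n_interior <- df - degree
  interior <- if (n_interior > 0) {
    quantile(x, seq_len(n_interior) / (n_interior + 1), names = FALSE)
  } else numeric(0)
  all_knots <- sort(c(rep(range(x), degree + 1), interior))
  full <- splines::splineDesign(all_knots, x, ord = degree + 1)
  expect_equal(rowSums(full), rep(1, length(x)))
  expect_equal(rowSums(D[, -1, drop = FALSE]) + full[, 1], rep(1, length(x)))
  # and the drop-first columns agree with the reference evaluator
  expect_equal(unname(D[, -1]), unname(full[, -1]))
})

test_that("spline evaluation outside the training range clamps with a warning", {
  x_train <- seq(100, 1000, length.out = 50)
  fit <- suppressWarnings(
    fit_mixture(make_cells(rep(x_train, 4),
                           rep(c(1, 1.5, 30, 35), each = 50)),
                model_spec("linear", "spline"))
  )
  expect_warning(p_out <- predict_component(fit, "compromised", 2000),
                 "clamp")
  p_edge <- predict_component(fit, "compromised", 1000)
  expect_equal(p_out, p_edge)
})

test_that("quantile initialization splits on the 75th percentile", {
  cells <- make_cells(x = c(1000, 1000, 1000, 200), y = c(1, 2, 3, 90))
  r <- initialize_responsibilities(cells, "quantile")
  expect_equal(r$gamma_compromised, c(0.05, 0.05, 0.05, 0.95))
  expect_equal(r$gamma_intact + r$gamma_compromised, rep(1, 4))
})

test_that("random initialization is seeded and well-formed", {
  cells <- make_cells(x = rep(500, 20), y = runif(20, 0, 50))
  r1 <- initialize_responsibilities(cells, "random", seed = 9)
  r2 <- initialize_responsibilities(cells, "random", seed = 9)
  expect_identical(r1, r2)
  for (s in 1:10) {
    r <- initialize_responsibilities(cells, "random", seed = s)
    expect_true(all(r$gamma_compromised > 0 & r$gamma_compromised < 1))
    expect_equal(r$gamma_intact + r$gamma_compromised, rep(1, 20))
  }
  flat <- make_cells(x = 1:5, y = rep(3, 5))
  expect_warning(initialize_responsibilities(flat, "quantile"), "identical")
})

test_that("E-step reduces to the prior for identical components", {
  cells <- make_cells(x = c(100, 800, 2500), y = c(3, 10, 40))
  comp <- list(coefficients = c(5, 0.001), variance = 4)
  post <- e_step(cells, model_spec(), c(0.7, 0.3), list(comp, comp))
  expect_equal(post$gamma_compromised, rep(0.3, 3))
})

test_that("E-step gives 1/2 for an equidistant cell under equal weights", {
  cells <- make_cells(x = 1234, y = 5)
  post <- e_step(cells, model_spec("intercept_only", "intercept_only"),
                 c(0.5, 0.5),
                 list(list(coefficients = 0, variance = 1),
                      list(coefficients = 10, variance = 1)))
  expect_equal(post$gamma_compromised, 0.5)
})

test_that("E-step agrees with the plain-density Bayes oracle", {
  # the worked case: pi = (0.6, 0.4), f0 = 2, sd0 = 1; f1 = 30 - 0.01 x,
  # sd1 = 5; cell (x = 1000, y = 15)
  cells <- make_cells(x = 1000, y = 15)
  comps <- list(list(coefficients = c(2, 0), variance = 1),
                list(coefficients = c(30, -0.01), variance = 25))
  post <- e_step(cells, model_spec(), c(0.6, 0.4), comps)
  expected <- oracle_gamma(15, mu1 = 2, sd1 = 1, mu2 = 30 - 0.01 * 1000,
                           sd2 = 5, pi1 = 0.6, pi2 = 0.4)
  expect_equal(post$gamma_compromised, expected, tolerance = 1e-12)

  # posteriors always pair-sum to exactly 1
  set.seed(3)
  cells <- make_cells(x = runif(200, 100, 3000), y = runif(200, 0, 60))
  post <- e_step(cells, model_spec(), c(0.55, 0.45), comps)
  expect_identical(post$gamma_intact + post$gamma_compromised, rep(1, 200))
})

test_that("M-step recovers exact flat lines from a hard split", {
  cells <- make_cells(x = c(1:6) * 100, y = c(2, 2, 2, 20, 20, 20))
  # hard split (responsibilities exactly 0/1) on intercept-only forms
  resp01 <- data.frame(gamma_intact = c(1, 1, 1, 0, 0, 0),
                       gamma_compromised = c(0, 0, 0, 1, 1, 1))
  ms <- m_step(cells, resp01, model_spec("intercept_only", "intercept_only"))
  expect_equal(ms$components[[1]]$coefficients, 2)
  expect_equal(ms$components[[2]]$coefficients, 20)
  expect_equal(ms$components[[1]]$variance, 1e-6)  # perfect fit: floored
  expect_true(all(ms$variance_floored))
})

test_that("M-step weights are mean responsibilities", {
  cells <- make_cells(x = seq(100, 1200, length.out = 12),
                      y = runif(12, 0, 50))
  resp <- data.frame(gamma_intact = rep(0.75, 12),
                     gamma_compromised = rep(0.25, 12))
  ms <- m_step(cells, resp, model_spec())
  expect_equal(ms$weights, c(0.75, 0.25))
})

test_that("M-step coefficients solve the weighted normal equations", {
  set.seed(5)
  cells <- make_cells(x = c(120, 400, 900, 1500, 2600, 3300),
                      y = c(40, 35, 20, 8, 4, 3))
  g1 <- c(0.1, 0.2, 0.45, 0.8, 0.95, 0.99)
  resp <- data.frame(gamma_intact = g1, gamma_compromised = 1 - g1)
  ms <- m_step(cells, resp, model_spec())
  X <- cbind(1, cells$detected_genes)
  for (z in 1:2) {
    w <- if (z == 1) g1 else 1 - g1
    expect_equal(ms$components[[z]]$coefficients,
                 oracle_wls(X, cells$pct_mito, w), tolerance = 1e-10)
    r <- cells$pct_mito - drop(X %*% ms$components[[z]]$coefficients)
    expect_equal(ms$components[[z]]$variance, sum(w * r^2) / sum(w))
  }
})

test_that("M-step fails loudly on a rank-deficient design", {
  cells <- make_cells(x = rep(500, 10), y = runif(10, 0, 20))
  resp <- data.frame(gamma_intact = rep(0.5, 10),
                     gamma_compromised = rep(0.5, 10))
  expect_error(m_step(cells, resp, model_spec()), "rank-deficient")
})

test_that("log-likelihood collapses to one Gaussian regression when pi1 = 0", {
  set.seed(8)
  cells <- make_cells(x = runif(50, 100, 3000), y = runif(50, 0, 30))
  comps <- list(list(coefficients = c(3, 1e-3), variance = 9),
                list(coefficients = c(40, -0.01), variance = 36))
  ll <- log_likelihood(cells, model_spec(), c(1, 0), comps)
  direct <- sum(dnorm(cells$pct_mito,
                      3 + 1e-3 * cells$detected_genes, 3, log = TRUE))
  expect_equal(ll, direct)
})

test_that("log-likelihood is permutation-invariant and matches naive densities", {
  set.seed(9)
  cells <- make_cells(x = runif(100, 100, 3000), y = runif(100, 0, 60))
  comps <- list(list(coefficients = c(2, 5e-4), variance = 4),
                list(coefficients = c(45, -0.01), variance = 64))
  w <- c(0.7, 0.3)
  ll <- log_likelihood(cells, model_spec(), w, comps)
  perm <- sample(100)
  expect_equal(log_likelihood(cells[perm, ], model_spec(), w, comps), ll)
  mu1 <- 2 + 5e-4 * cells$detected_genes
  mu2 <- 45 - 0.01 * cells$detected_genes
  naive <- sum(log(w[1] * dnorm(cells$pct_mito, mu1, 2) +
                   w[2] * dnorm(cells$pct_mito, mu2, 8)))
  expect_equal(ll, naive, tolerance = 1e-12)
})

test_that("fitting requires more cells than free parameters", {
  cells <- make_cells(x = c(100, 200, 300), y = c(1, 2, 50))
  expect_error(fit_mixture(cells), "under-determined")
  flat <- make_cells(x = seq(100, 2000, length.out = 20), y = rep(5, 20))
  expect_error(fit_mixture(flat), "distinct pct_mito")
})

test_that("EM log-likelihood trace is nondecreasing and the fit converges", {
  for (s in 1:5) {
    cells <- simulate_qc_metrics(synthetic_params(n_cells = 1000, seed = s))
    fit <- fit_mixture(cells)
    expect_true(fit$converged)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("the fit is invariant to cell ordering under quantile initialization", {
  cells <- simulate_qc_metrics(synthetic_params(n_cells = 1500, seed = 21))
  fit1 <- fit_mixture(cells)
  set.seed(99)
  fit2 <- fit_mixture(cells[sample(nrow(cells)), ])
  expect_equal(fit1$weights, fit2$weights, tolerance = 1e-6)
  for (z in 1:2) {
    expect_equal(fit1$components[[z]]$coefficients,
                 fit2$components[[z]]$coefficients, tolerance = 1e-6)
  }
  expect_identical(fit1$compromised_index, fit2$compromised_index)
})

test_that("the greater-intercept component is labeled compromised", {
  f <- manual_fit(intact_coef = c(2, 1e-4), compromised_coef = c(30, -0.01))
  f$compromised_index <- NA_integer_
  expect_identical(label_components(f)$compromised_index, 2L)
  # swap the components: the label must follow the intercept
  f$components <- rev(f$components)
  expect_identical(label_components(f)$compromised_index, 1L)

  g <- manual_fit(intact_coef = 3, compromised_coef = 60)
  g$spec <- model_spec("intercept_only", "intercept_only")
  g$compromised_index <- NA_integer_
  expect_identical(label_components(g)$compromised_index, 2L)

  tie <- manual_fit(intact_coef = c(5, 0), compromised_coef = c(5, -0.01))
  tie$compromised_index <- NA_integer_
  expect_error(label_components(tie), "indistinguishable")
})

test_that("spline components are labeled by their value at minimum x", {
  set.seed(31)
  n <- 600
  x <- round(runif(n, 100, 3000))
  z <- rbinom(n, 1, 0.3)
  y <- ifelse(z == 1, 50 - 0.012 * x, 2 + 5e-4 * x) + rnorm(n, 0, c(1.5, 6)[z + 1])
  cells <- make_cells(x, pmin(pmax(y, 0), 100))
  fit <- fit_mixture(cells, model_spec("linear", "spline"))
  x_min <- min(cells$detected_genes)
  preds <- c(predict_component(fit, "intact", x_min),
             predict_component(fit, "compromised", x_min))
  expect_gt(preds[2], preds[1])
})

test_that("component prediction is the design-row dot product", {
  f <- manual_fit(intact_coef = c(2, 0.001), compromised_coef = c(30, -0.01))
  expect_equal(predict_component(f, "intact", 1000), 3)
  g <- manual_fit(intact_coef = 7, compromised_coef = 50)
  g$spec <- model_spec("intercept_only", "intercept_only")
  expect_equal(predict_component(g, "intact", c(10, 99999)), c(7, 7))

  cells <- simulate_qc_metrics(synthetic_params(n_cells = 800, seed = 13))
  fit <- fit_mixture(cells, model_spec("linear", "spline"))
  z <- fit$compromised_index
  x0 <- cells$detected_genes[25]
  manual <- drop(design_row(x0, "spline",
                            basis = fit$bases[[z]]) %*%
                 fit$components[[z]]$coefficients)
  expect_equal(predict_component(fit, "compromised", x0), manual)
})

test_that("a well-separated sample recovers the generating intercepts", {
  cells <- simulate_qc_metrics(synthetic_params(seed = 4))
  fit <- fit_mixture(cells)
  ci <- fit$compromised_index
  b0c <- fit$components[[ci]]$coefficients[1]
  b0i <- fit$components[[3 - ci]]$coefficients[1]
  expect_lt(abs(b0i - 1.5) / 1.5, 0.10)
  expect_lt(abs(b0c - 45) / 45, 0.10)
  expect_identical(ci, 2L)  # generator truth: compromised has the high intercept
})

test_that("a fitted model round-trips through JSON bit-exactly", {
  cells <- simulate_qc_metrics(synthetic_params(n_cells = 1200, seed = 6))
  for (spec in list(model_spec(), model_spec("linear", "spline"),
                    model_spec("intercept_only", "intercept_only"))) {
    fit <- fit_mixture(cells, spec)
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(fit, path)
    back <- read_model_json(path)
    expect_identical(back, fit)
  }
})
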