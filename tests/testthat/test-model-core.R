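test_that("model construction validates its inputs", {
  expect_s3_class(inheritance_model(20, matrix(0.5), matrix(1)),
                  "inheritance_model")
  expect_error(inheritance_model(20, matrix(1.2), matrix(1)),
               "spectral radius")
  expect_error(inheritance_model(20, matrix(0.5), matrix(-1)),
               "semi-definite")
  expect_error(inheritance_model(-3, matrix(0.5), matrix(1)), "tau_bar")
  expect_error(
    inheritance_model(20, matrix(0.5), matrix(1), alpha = 0.7),
    "binary")
  expect_error(
    inheritance_model(20, diag(c(0.5, 0.2)), diag(2), alpha = c(0, 0)),
    "nonzero")
  # sister cross-covariance too strong for a valid joint law
  expect_error(
    inheritance_model(20, matrix(0.5), matrix(1), s2 = matrix(2)),
    "semi-definite")
})

test_that("Lyapunov solver: fixed points, scalar case, series oracle", {
  # no inheritance: Sigma is the noise covariance itself
  s1 <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  expect_equal(solve_lyapunov(matrix(0, 2, 2), s1), s1)
  # scalar geometric series 0.75 / (1 - 0.25)
  expect_equal(solve_lyapunov(matrix(0.5), matrix(0.75)), matrix(1))
  # random models against the truncated power series
  for (seed in 1:5) {
    m <- random_model(seed)
    sigma <- solve_lyapunov(m$theta, m$s1)
    expect_lt(max(abs(sigma - series_lyapunov(m$theta, m$s1))), 1e-10)
    # residual of the defining equation
    expect_lt(max(abs(sigma - m$theta %*% sigma %*% t(m$theta) - m$s1)),
              1e-10)
    expect_gte(min(eigen(sigma, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
  }
  expect_error(solve_lyapunov(matrix(1.01), matrix(1)), "spectral radius")
  expect_error(solve_lyapunov(matrix(0.5, 2, 2),
                              matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
})

test_that("interdivision variance selects the alpha-weighted covariance", {
  # alpha = (1, 0) picks Sigma[1,1]; here theta = 0 so Sigma = S1
  s1 <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  m <- inheritance_model(20, matrix(0, 2, 2), s1, alpha = c(1, 0))
  expect_equal(interdivision_variance(m), 2)
  m2 <- inheritance_model(20, matrix(0, 2, 2), diag(2))
  expect_equal(interdivision_variance(m2), 2)
})

test_that("interdivision variance matches the ensemble of simulated roots", {
  m <- random_model(11)
  f <- simulate_lineage(m, n_trees = 1e5, depth = 1, seed = 42)
  v <- var(f$interdivision_time)
  se <- v * sqrt(2 / (nrow(f) - 1))  # SE of a normal sample variance
  expect_lt(abs(v - interdivision_variance(m)), 3 * se)
})

test_that("tree correlation function: exact values and invariants", {
  # scalar closed form: rho(k, 0) = a^k, rho(1,1) = a^2 when S2 = 0
  a <- 0.6
  m1 <- inheritance_model(20, matrix(a), matrix(1))
  expect_equal(tree_correlation(m1, 0:4, 0), a^(0:4))
  expect_equal(tree_correlation(m1, 1, 1), a^2)
  # self-correlation is exactly 1, symmetry, boundedness, decay
  for (seed in 1:4) {
    m <- random_model(seed, with_s2 = (seed %% 2 == 0))
    expect_identical(tree_correlation(m, 0, 0), 1)
    g <- expand.grid(k = 0:5, l = 0:5)
    rho <- tree_correlation(m, g$k, g$l)
    rho_t <- tree_correlation(m, g$l, g$k)
    expect_equal(rho, rho_t)
    expect_true(all(abs(rho) <= 1 + 1e-12))
    expect_lt(abs(tree_correlation(m, 12, 12)),
              abs(tree_correlation(m, 1, 1)) + 1e-6)
    expect_lt(abs(tree_correlation(m, 14, 0)), 0.05)
  }
  expect_error(tree_correlation(m1, -1, 0), "non-negative")
})

test_that("sister cross-noise adds alpha' S2 alpha / s_tau to the sister
           correlation", {
  m0 <- random_model(5)
  s2 <- diag(0.2, 2)
  m2 <- inheritance_model(m0$tau_bar, m0$theta, m0$s1, s2 = s2)
  s_tau <- interdivision_variance(m0)
  excess <- drop(crossprod(m0$alpha, s2 %*% m0$alpha)) / s_tau
  expect_equal(tree_correlation(m2, 1, 1) - tree_correlation(m0, 1, 1),
               excess)
})

test_that("simple one-factor inheritance cannot satisfy the cousin-mother
           inequality", {
  for (a in seq(0, 0.95, by = 0.05)) {
    m <- inheritance_model(20, matrix(a), matrix(1))
    rho <- tree_correlation(m, c(1, 2), c(0, 2))
    expect_lte(rho[2], rho[1] + 1e-12)  # rho(2,2) = a^4 <= a = rho(1,0)
    expect_equal(rho[2], a^4)
  }
})

test_that("eigen-expansion reproduces the matrix-power formula", {
  g <- expand.grid(k = 0:6, l = 0:6)
  for (seed in 1:6) {
    m <- random_model(seed, with_s2 = (seed %% 2 == 0))
    e <- eigen_expansion(m)
    expect_lt(max(abs(correlation_function(e, g$k, g$l) -
                        tree_correlation(m, g$k, g$l))), 1e-8)
    # Sigma reconstructed from the transformed noise matches the solver
    expect_lt(max(abs(e$sigma - stationary_covariance(m))), 1e-8)
    expect_lt(max(abs(Im(e$sigma))), 1e-10)
  }
})

test_that("eigen-expansion handles diagonal and complex-pair cases", {
  # diagonal theta: eigenvalues are the diagonal, weights from S1 directly
  m <- inheritance_model(20, diag(c(0.5, -0.3)), diag(2))
  e <- eigen_expansion(m)
  expect_equal(sort(Re(e$eigenvalues)), c(-0.3, 0.5))
  # complex pair: conjugate weights, real correlations
  mo <- pattern_exemplars()$oscillator
  eo <- eigen_expansion(mo)
  expect_true(any(Im(eo$eigenvalues) != 0))
  w <- eo$weights_s1
  expect_equal(w[1, 2], Conj(w[2, 1]), tolerance = 1e-12)
  kk <- seq(0, 5, by = 0.25)
  expect_true(all(is.finite(correlation_function(eo, kk, 0))))
  # defective matrix is flagged; the matrix-power path still works
  def <- matrix(c(0.5, 0, 1, 0.5), 2, 2)  # Jordan block
  md <- inheritance_model(20, def, diag(2))
  expect_error(eigen_expansion(md), "defective")
  expect_identical(tree_correlation(md, 0, 0), 1)
})
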