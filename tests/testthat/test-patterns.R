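test_that("eigenvalue taxonomy labels the three patterns", {
  expect_equal(classify_pattern(c(0.5, 0.2))$label, "aperiodic")
  expect_equal(classify_pattern(c(0.5, -0.3))$label, "alternator")
  expect_equal(classify_pattern(0.5 * exp(c(1, -1) * 2i * pi / 5))$label,
               "oscillator")
  # zero eigenvalue carries no alternation
  expect_equal(classify_pattern(c(0.4, 0))$label, "aperiodic")
  expect_error(classify_pattern(c(1.0, 0.2)), "non-stationary")
  # dominant eigenvalue: largest modulus, +Im member of a pair
  pc <- classify_pattern(0.5 * exp(c(1, -1) * 2i * pi / 5))
  expect_gt(Im(pc$dominant), 0)
  # mixed flag for N >= 3 composites
  expect_true(classify_pattern(c(0.5 * exp(c(1, -1) * 2i * pi / 5),
                                 0.3))$is_mixed)
})

test_that("2x2 classification uses the exact discriminant and is
           conjugation invariant", {
  mods <- pattern_exemplars()
  expect_equal(classify_theta(mods$aperiodic$theta)$label, "aperiodic")
  expect_equal(classify_theta(mods$alternator$theta)$label, "alternator")
  expect_equal(classify_theta(mods$oscillator$theta)$label, "oscillator")
  set.seed(3)
  for (i in 1:20) {
    th <- matrix(runif(4, -0.7, 0.7), 2, 2)
    if (spectral_radius(th) >= 1) next
    v <- matrix(rnorm(4), 2, 2)
    while (abs(det(v)) < 0.1) v <- matrix(rnorm(4), 2, 2)
    conj <- v %*% th %*% solve(v)
    expect_equal(classify_theta(th)$label,
                 classify_pattern(eigen(conj)$values)$label)
  }
})

test_that("correlation period: principal argument, wrapping, limits", {
  # an eigenvalue at angle 2*pi/5 oscillates with period 5 generations
  expect_equal(correlation_period(0.5 * exp(2i * pi / 5), 1), 5)
  # alternator limit: argument pi gives the Nyquist period of 2
  expect_equal(correlation_period(-0.5, 1), 2)
  # P < 2 wraps: 2*pi / (4/3) = 3*pi/2 has principal argument -pi/2
  expect_equal(correlation_period(0.5 * exp(2i * pi / (4 / 3)), 1), 4)
  # independent phase-wrap oracle across many P
  for (p in seq(1.05, 6, by = 0.12)) {
    lam <- 0.5 * exp(2i * pi / p)
    phi <- (2 * pi / p) %% (2 * pi)
    if (phi > pi) phi <- phi - 2 * pi
    expect_equal(correlation_period(lam, 1), 2 * pi / abs(phi))
    expect_gte(correlation_period(lam, 1), 2 - 1e-12)
  }
  # positive real eigenvalues carry no oscillation; zero is undefined
  expect_identical(correlation_period(0.7, 1), Inf)
  expect_error(correlation_period(0, 1), "zero eigenvalue")
  # scales linearly with the mean interdivision time
  expect_equal(correlation_period(0.5 * exp(2i * pi / 5), 10), 50)
})

test_that("the period bound T0 >= 2 tau_bar is tight at argument pi", {
  args <- seq(1e-6, pi, length.out = 1e5)
  ratio <- 2 * pi / args
  expect_equal(min(ratio), 2, tolerance = 1e-6)
  expect_equal(args[which.min(ratio)], pi)
})

test_that("aliased periods follow Tn = tau T0 / |tau + n T0|", {
  al <- aliased_periods(t0 = 3, tau_bar = 1, n = -1:1)
  expect_equal(al$period[al$n == 0], 3)     # identity alias
  expect_equal(al$period[al$n == -1], 1.5)
  expect_equal(al$period[al$n == 1], 0.75)
  expect_true(all(al$period > 0))
  # infinite-frequency alias is dropped with a note
  expect_warning(out <- aliased_periods(t0 = 1, tau_bar = 2, n = -2:0),
                 "infinite-frequency")
  expect_false(-2 %in% out$n)
})

test_that("alias round trip: wrapped per-generation phase returns T0", {
  for (t0 in c(2.2, 3, 5.8, 11)) {
    al <- aliased_periods(t0, tau_bar = 1, n = -3:3)
    for (i in seq_len(nrow(al))) {
      phi <- wrap_phase(al$period[i], 1)
      expect_equal(correlation_period(0.5 * exp(1i * phi), 1), t0,
                   tolerance = 1e-9)
    }
  }
})

test_that("a division-sampled fast oscillator shows the aliased slow
           period", {
  # deterministic phase oscillator with period T-1, observed once per
  # interdivision time: the sampled sequence oscillates with period T0
  tau_bar <- 1
  t0 <- 3
  t_minus1 <- aliased_periods(t0, tau_bar, n = -1)$period  # 1.5
  times <- (0:2000) * tau_bar
  signal <- cos(2 * pi * times / t_minus1)
  # dominant discrete frequency of the sampled signal
  sp <- Mod(fft(signal))[2:1000]
  freq <- (which.max(sp)) / length(signal)  # cycles per generation
  expect_equal(1 / freq, t0, tolerance = 0.02)
})

test_that("region scan reports patterns and the cousin-mother mask", {
  # one-factor family: inequality satisfied nowhere
  g1 <- tibble::tibble(a = seq(0, 0.95, by = 0.05))
  sc1 <- scan_inequality_region(g1, function(row) matrix(row$a))
  expect_true(all(!sc1$cousin_mother))
  expect_equal(sc1$rho_cc, sc1$a^4)
  # damped rotation family: known oscillator point
  rot <- function(row) {
    om <- 2 * pi / row$p
    row$d * matrix(c(cos(om), sin(om), -sin(om), cos(om)), 2, 2)
  }
  sc2 <- scan_inequality_region(tibble::tibble(d = 0.5, p = 5), rot)
  expect_equal(sc2$pattern, "oscillator")
  # partial overlap: the oscillator and inequality regions intersect but
  # neither contains the other
  g3 <- tidyr::expand_grid(d = seq(0.1, 0.9, by = 0.1),
                           p = seq(2, 12, by = 0.5))
  sc3 <- scan_inequality_region(g3, rot)
  both <- sc3$pattern == "oscillator" & sc3$cousin_mother
  osc_only <- sc3$pattern == "oscillator" & !sc3$cousin_mother
  ineq_only <- sc3$pattern != "oscillator" & sc3$cousin_mother
  expect_gt(sum(both), 0)
  expect_gt(sum(osc_only), 0)
  expect_gt(sum(ineq_only), 0)
  # non-stationary grid points are masked, not errors
  sc4 <- scan_inequality_region(tibble::tibble(a = c(0.5, 1.2)),
                                function(row) matrix(row$a))
  expect_equal(sc4$valid, c(TRUE, FALSE))
  expect_true(is.na(sc4$pattern[2]))
})
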