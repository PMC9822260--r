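#' Classify a lineage correlation pattern from inheritance eigenvalues
#'
#' The qualitative shape of the tree correlation function is set entirely by
#' the eigenvalues of the inheritance matrix: all-real-positive eigenvalues
#' give a monotonically decaying *aperiodic* pattern; at least one negative
#' real eigenvalue gives an *alternator* (period-two sign flips down the
#' lineage); a complex-conjugate pair gives a damped *oscillator*. A zero
#' eigenvalue counts as aperiodic (no sign alternation). For `N >= 3` the
#' pattern can mix classes; `is_mixed` flags eigenvalue sets that combine an
#' oscillatory pair with a nonzero real eigenvalue (or several distinct real
#' behaviours).
#'
#' @param eigenvalues Complex (or numeric) vector of inheritance-matrix
#'   eigenvalues, all with modulus `< 1`.
#' @param imag_tol Relative tolerance above which an imaginary part counts
#'   as genuinely complex (guards against eigensolver noise for `N > 2`).
#'   For 2x2 matrices prefer [classify_theta()], which uses the exact sign
#'   of the discriminant.
#' @return A one-row tibble: `label` (one of `"aperiodic"`, `"alternator"`,
#'   `"oscillator"`), `dominant` (eigenvalue of largest modulus, complex;
#'   the positive-imaginary member of a conjugate pair), `is_mixed`.
#' @examples
#' classify_pattern(c(0.5, 0.2))                    # aperiodic
#' classify_pattern(c(0.5, -0.3))                   # alternator
#' classify_pattern(0.5 * exp(c(1, -1) * 2i * pi / 5))  # oscillator
#' @export
classify_pattern <- function(eigenvalues, imag_tol = 1e-9) {
  lam <- as.complex(eigenvalues)
  if (length(lam) == 0) stop("need at least one eigenvalue.", call. = FALSE)
  if (any(Mod(lam) >= 1)) {
    stop("non-stationary eigenvalue set: all moduli must be < 1.",
         call. = FALSE)
  }
  is_cplx <- abs(Im(lam)) > imag_tol * (1 + Mod(lam))
  re <- Re(lam)
  label <- if (any(is_cplx)) {
    "oscillator"
  } else if (any(re < -imag_tol)) {
    "alternator"
  } else {
    "aperiodic"
  }
  # dominant eigenvalue: largest modulus; represent conjugate pairs by the
  # +Im member.
  cand <- lam[order(-Mod(lam), -Im(lam))]
  dominant <- cand[1]
  is_mixed <- any(is_cplx) && any(!is_cplx & abs(re) > imag_tol)
  tibble::tibble(label = label, dominant = dominant, is_mixed = is_mixed)
}

#' Classify the pattern of a 2x2 inheritance matrix exactly
#'
#' For two factors the complex-pair test is the exact sign of the
#' discriminant `tr(theta)^2 - 4 det(theta)`, avoiding any tolerance on
#' eigensolver output.
#'
#' @param theta A 2x2 (or 1x1) inheritance matrix.
#' @return A one-row tibble as in [classify_pattern()].
#' @export
classify_theta <- function(theta) {
  theta <- as_square_matrix(theta, "theta")
  if (nrow(theta) == 1) return(classify_pattern(theta[1, 1]))
  if (nrow(theta) != 2) return(classify_pattern(eigen(theta)$values))
  tr <- theta[1, 1] + theta[2, 2]
  dt <- theta[1, 1] * theta[2, 2] - theta[1, 2] * theta[2, 1]
  disc <- tr^2 - 4 * dt
  if (disc < 0) {
    lam <- complex(real = tr / 2, imaginary = sqrt(-disc) / 2)
    if (Mod(lam) >= 1) stop("non-stationary eigenvalue set: all moduli must",
                            " be < 1.", call. = FALSE)
    return(tibble::tibble(label = "oscillator", dominant = lam,
                          is_mixed = FALSE))
  }
  lam <- (tr + c(1, -1) * sqrt(disc)) / 2
  out <- classify_pattern(lam, imag_tol = 0)
  # exact rule: any strictly negative real eigenvalue => alternator
  out$label <- if (any(lam < 0)) "alternator" else "aperiodic"
  out
}

#' Period of correlation oscillations
#'
#' For a complex inheritance eigenvalue `lambda` the lineage correlation
#' function oscillates with period `T0 = tau_bar * 2 * pi / |Arg(lambda)|`
#' (hours), where `Arg` is the principal argument in `(-pi, pi]`. Positive
#' real eigenvalues carry no oscillation and return `Inf`; a strictly
#' negative eigenvalue is the alternator limit `T0 = 2 tau_bar`. The period
#' is always at least twice the mean interdivision time — a Nyquist-type
#' bound for per-division sampling. For `lambda = D exp(2i pi / P)` one has
#' `T0 = P tau_bar` exactly when `P > 2`; faster underlying periods wrap
#' around (alias) into slower apparent ones.
#'
#' @param eigenvalue A single nonzero complex (or numeric) eigenvalue.
#' @param tau_bar Mean interdivision time (hours).
#' @return Period in hours (`>= 2 * tau_bar`), or `Inf` for a non-negative
#'   real eigenvalue.
#' @examples
#' correlation_period(0.5 * exp(2i * pi / 5), tau_bar = 1)  # 5
#' correlation_period(-0.5, tau_bar = 1)                    # 2
#' @export
correlation_period <- function(eigenvalue, tau_bar) {
  lam <- as.complex(eigenvalue)
  stopifnot(length(lam) == 1)
  if (Mod(lam) == 0) stop("zero eigenvalue: correlation period undefined.",
                          call. = FALSE)
  if (!is.numeric(tau_bar) || tau_bar <= 0) {
    stop("`tau_bar` must be positive.", call. = FALSE)
  }
  arg <- Arg(lam)  # in (-pi, pi]
  if (arg == 0) return(Inf)  # positive real eigenvalue: no oscillation
  tau_bar * 2 * pi / abs(arg)
}

#' Aliased oscillator periods compatible with a correlation oscillation
#'
#' Interdivision times sample any underlying biological oscillator once per
#' division, so an observed correlation-oscillation period `T0` is
#' compatible with a whole family of true oscillator periods
#' `Tn = tau_bar * T0 / |tau_bar + n * T0|`, `n` integer; `n = 0` recovers
#' `T0` itself and `n = -1` is the alias closest to `T0` (the headline
#' candidate when matching, e.g., a circadian rhythm).
#'
#' @param t0 Correlation-oscillation period (hours, positive).
#' @param tau_bar Mean interdivision time (hours, positive).
#' @param n Integer alias indices (default `-3:3`).
#' @return A tibble with columns `n` and `period` (hours). An index with
#'   `tau_bar + n * T0 == 0` (infinite-frequency alias) is dropped with a
#'   warning.
#' @examples
#' aliased_periods(t0 = 3, tau_bar = 1, n = -1:1)  # 1.5, 3, 0.75
#' @export
aliased_periods <- function(t0, tau_bar, n = -3:3) {
  stopifnot(is.numeric(t0), t0 > 0, is.numeric(tau_bar), tau_bar > 0,
            all(n == round(n)))
  denom <- abs(tau_bar + n * t0)
  bad <- denom == 0
  if (any(bad)) {
    warning("dropping alias n = ", paste(n[bad], collapse = ", "),
            ": tau_bar + n * T0 = 0 (infinite-frequency alias).")
  }
  tibble::tibble(n = as.integer(n[!bad]),
                 period = tau_bar * t0 / denom[!bad])
}

#' Per-generation phase of an aliased oscillator, wrapped to (-pi, pi]
#'
#' Wrapping the per-generation phase `2 * pi * tau_bar / Tn` of any alias
#' back into the principal branch and applying [correlation_period()]
#' recovers `T0`: the round-trip property behind the alias family.
#'
#' @param period Oscillator period in hours.
#' @param tau_bar Mean interdivision time in hours.
#' @return Phase in `(-pi, pi]`.
#' @export
wrap_phase <- function(period, tau_bar) {
  phi <- 2 * pi * tau_bar / period
  phi <- phi %% (2 * pi)
  ifelse(phi > pi, phi - 2 * pi, phi)
}

#' Scan a parameterised model family for patterns and the cousin-mother
#' inequality
#'
#' Walks a parameter grid, builds the inheritance matrix at each point and
#' reports the pattern class together with whether the cousin-mother
#' inequality `rho(2,2) > rho(1,0)` holds there — the region-plot view of
#' which parameter combinations can produce the counter-intuitive
#' observation that cousins correlate more strongly than mother-daughter
#' pairs. Grid points whose matrix is non-stationary are kept but flagged
#' invalid.
#'
#' @param grid A data frame; each row is one parameter point.
#' @param theta_fn Function taking one grid row (as a list) and returning
#'   the inheritance matrix at that point.
#' @param s1 Noise covariance shared across the grid (default identity).
#' @param s2 Sister cross-covariance (default zero).
#' @param alpha Binary weight vector (default all ones).
#' @param tau_bar Mean interdivision time (irrelevant to the masks; default
#'   1).
#' @return The grid tibble with added columns `valid`, `pattern`,
#'   `cousin_mother` (logical: inequality satisfied), `rho_md`, `rho_cc`.
#' @examples
#' g <- tidyr::expand_grid(d = c(0.3, 0.6), omega = c(0.5, 2.5))
#' scan_inequality_region(g, function(p)
#'   p$d * matrix(c(cos(p$omega), sin(p$omega),
#'                  -sin(p$omega), cos(p$omega)), 2, 2))
#' @export
scan_inequality_region <- function(grid, theta_fn, s1 = NULL, s2 = NULL,
                                   alpha = NULL, tau_bar = 1) {
  grid <- tibble::as_tibble(grid)
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, , drop = FALSE])
    theta <- theta_fn(row)
    n <- nrow(as.matrix(theta))
    s1_i <- if (is.null(s1)) diag(n) else s1
    ok <- spectral_radius(theta) < 1
    if (!ok) {
      return(tibble::tibble(valid = FALSE, pattern = NA_character_,
                            cousin_mother = NA, rho_md = NA_real_,
                            rho_cc = NA_real_))
    }
    m <- inheritance_model(tau_bar, theta, s1_i, s2 = s2, alpha = alpha)
    rho <- tree_correlation(m, c(1, 2), c(0, 2))
    tibble::tibble(valid = TRUE,
                   pattern = classify_theta(as.matrix(theta))$label,
                   cousin_mother = rho[2] > rho[1],
                   rho_md = rho[1], rho_cc = rho[2])
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
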