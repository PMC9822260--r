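#' Exemplar models of the three correlation patterns
#'
#' Two-factor inheritance models whose eigenvalue structure places them
#' firmly in each pattern class, used throughout the package's examples,
#' tests and demonstration pipeline:
#'
#' * `aperiodic`: a strongly non-normal matrix with well-separated real
#'   positive eigenvalues (about 0.78 and 0.37), whose correlation
#'   signature is not reproducible by negative-eigenvalue models;
#' * `alternator`: `diag(0.5, -0.5)` — one inherited factor flips sign
#'   each generation;
#' * `oscillator`: a damped rotation `0.5 R(2 pi / 5)`, i.e. eigenvalues
#'   `0.5 exp(+-2 i pi / 5)`: a five-generation correlation oscillation
#'   with damping 0.5 per generation.
#'
#' All three use unit white noise (`S1 = I`, `S2 = 0`) and both factors
#' feeding the interdivision time (`alpha = (1, 1)`).
#'
#' @param tau_bar Mean interdivision time in hours (default 20, a typical
#'   mammalian cell line).
#' @return Named list of three [inheritance_model()] objects.
#' @examples
#' mods <- pattern_exemplars()
#' sapply(mods, function(m) classify_theta(m$theta)$label)
#' @export
pattern_exemplars <- function(tau_bar = 20) {
  omega <- 2 * pi / 5
  list(
    aperiodic = inheritance_model(
      tau_bar, matrix(c(0.74, -0.02, -0.82, 0.41), 2, 2), diag(2)),
    alternator = inheritance_model(tau_bar, diag(c(0.5, -0.5)), diag(2)),
    oscillator = inheritance_model(
      tau_bar,
      0.5 * matrix(c(cos(omega), sin(omega), -sin(omega), cos(omega)), 2, 2),
      diag(2))
  )
}
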