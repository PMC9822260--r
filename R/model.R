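#' Define an inheritance-matrix model of interdivision times
#'
#' Constructs the generative model in which every cell carries `N` hidden
#' heritable *cell cycle factors*. Factor fluctuations `x` propagate from a
#' mother `m` to her daughters `2m` and `2m + 1` through the linear map
#' `x_daughter = theta x_m + z_daughter`, where the two daughter noise
#' vectors have per-cell covariance `s1` and sister-sister cross-covariance
#' `s2`, and are independent between different mothers. A cell's
#' interdivision time is `tau = tau_bar + alpha' x`, with `alpha` a binary
#' vector selecting the factors that feed into division timing.
#'
#' Stationarity of the correlation pattern requires the spectral radius of
#' `theta` to be below one; the joint sister-noise law requires the
#' `2N x 2N` block matrix `[[s1, s2], [s2', s1]]` to be positive
#' semi-definite. Both are validated here.
#'
#' @param tau_bar Mean interdivision time (hours, positive).
#' @param theta `N x N` inheritance matrix (spectral radius `< 1`).
#' @param s1 `N x N` symmetric PSD within-cell noise covariance.
#' @param s2 `N x N` sister-sister noise cross-covariance (default zero).
#' @param alpha Length-`N` binary (0/1) vector with at least one 1 selecting
#'   the factors that contribute to the interdivision time; defaults to all
#'   ones.
#'
#' @return An object of class `inheritance_model`: a list with elements
#'   `tau_bar`, `theta`, `s1`, `s2`, `alpha`, `n_factors`.
#' @examples
#' m <- inheritance_model(tau_bar = 20,
#'                        theta = matrix(c(0.5, -0.3, 0.3, 0.5), 2, 2),
#'                        s1 = diag(2))
#' tree_correlation(m, 1, 0)
#' @seealso [tree_correlation()], [simulate_lineage()], [eigen_expansion()]
#' @export
inheritance_model <- function(tau_bar, theta, s1, s2 = NULL, alpha = NULL) {
  theta <- as_square_matrix(theta, "theta")
  n <- nrow(theta)
  s1 <- as_square_matrix(s1, "s1", n)
  if (is.null(s2)) s2 <- matrix(0, n, n)
  s2 <- as_square_matrix(s2, "s2", n)
  if (is.null(alpha)) alpha <- rep(1, n)
  alpha <- as.numeric(alpha)
  if (length(alpha) != n) {
    stop("`alpha` must have length ", n, call. = FALSE)
  }
  if (!all(alpha %in% c(0, 1))) {
    stop("`alpha` must be a binary (0/1) vector; rescale the factors instead.",
         call. = FALSE)
  }
  if (!any(alpha == 1)) {
    stop("`alpha` must have at least one nonzero entry.", call. = FALSE)
  }
  if (!is.numeric(tau_bar) || length(tau_bar) != 1 || !is.finite(tau_bar) ||
      tau_bar <= 0) {
    stop("`tau_bar` must be a single positive number (hours).", call. = FALSE)
  }
  sr <- spectral_radius(theta)
  if (sr >= 1) {
    stop("non-stationary model: spectral radius of `theta` is ",
         formatC(sr, digits = 4), " but must be < 1.", call. = FALSE)
  }
  if (max(abs(s1 - t(s1))) > 1e-8) {
    stop("`s1` must be symmetric.", call. = FALSE)
  }
  check_psd(s1, "s1")
  joint <- rbind(cbind(s1, s2), cbind(t(s2), s1))
  check_psd(joint, "the joint sister-noise covariance [[s1, s2], [s2', s1]]")

  structure(
    list(tau_bar = tau_bar, theta = theta, s1 = (s1 + t(s1)) / 2, s2 = s2,
         alpha = alpha, n_factors = n),
    class = "inheritance_model"
  )
}

as_square_matrix <- function(x, name, n = NULL) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, sqrt(length(x)))
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("`", name, "` must be a square matrix.", call. = FALSE)
  }
  if (!is.null(n) && nrow(x) != n) {
    stop("`", name, "` must be ", n, "x", n, " to match `theta`.",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("`", name, "` has non-finite entries.",
                               call. = FALSE)
  x
}

# PSD check used throughout: smallest eigenvalue >= -1e-12 (tiny negative
# values from roundoff are tolerated, larger ones are an invalid noise law).
check_psd <- function(m, what) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(1, max(abs(ev)))) {
    stop(what, " must be positive semi-definite (smallest eigenvalue ",
         formatC(min(ev), digits = 4), ").", call. = FALSE)
  }
  invisible(TRUE)
}

#' Spectral radius of a matrix
#'
#' Largest eigenvalue modulus; the model is stationary iff this is `< 1`.
#'
#' @param m A square numeric matrix.
#' @return A single non-negative number.
#' @export
spectral_radius <- function(m) {
  max(Mod(eigen(as.matrix(m), only.values = TRUE)$values))
}

#' @export
print.inheritance_model <- function(x, ...) {
  cat("<inheritance_model> N =", x$n_factors,
      "factors, tau_bar =", x$tau_bar, "h\n")
  cat("theta (spectral radius", formatC(spectral_radius(x$theta), digits = 3),
      "):\n")
  print(round(x$theta, 4))
  pat <- classify_pattern(eigen(x$theta, only.values = TRUE)$values)
  cat("pattern:", pat$label, "\n")
  invisible(x)
}

#' Tidy an inheritance model into a parameter tibble
#'
#' @param x An [inheritance_model()].
#' @param ... Unused.
#' @return A tibble with one row per scalar parameter (`term`, `value`).
#' @export
tidy.inheritance_model <- function(x, ...) {
  n <- x$n_factors
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  tibble::tibble(
    term = c("tau_bar",
             sprintf("theta[%d,%d]", idx$i, idx$j),
             sprintf("s1[%d,%d]", idx$i, idx$j),
             sprintf("s2[%d,%d]", idx$i, idx$j),
             sprintf("alpha[%d]", seq_len(n))),
    value = c(x$tau_bar, as.vector(x$theta), as.vector(x$s1),
              as.vector(x$s2), x$alpha)
  )
}

#' Stationary factor covariance: discrete-time Lyapunov equation
#'
#' Solves `S1 = Sigma - theta Sigma theta'` for the stationary covariance
#' `Sigma` of the hidden factor fluctuations. The solution is obtained
#' directly from the vectorised linear system
#' `vec(Sigma) = (I - theta (x) theta)^{-1} vec(S1)`, which is exact and
#' cheap for the small factor counts used here (`N <= 4`).
#'
#' @param theta Square inheritance matrix with spectral radius `< 1`.
#' @param s1 Symmetric PSD noise covariance of the same dimension.
#' @return The unique symmetric PSD solution `Sigma`.
#' @examples
#' solve_lyapunov(matrix(0.5), matrix(0.75))  # 0.75 / (1 - 0.25) = 1
#' @export
solve_lyapunov <- function(theta, s1) {
  theta <- as_square_matrix(theta, "theta")
  n <- nrow(theta)
  s1 <- as_square_matrix(s1, "s1", n)
  if (max(abs(s1 - t(s1))) > 1e-8) stop("`s1` must be symmetric.",
                                        call. = FALSE)
  check_psd(s1, "s1")
  if (spectral_radius(theta) >= 1) {
    stop("non-stationary `theta`: spectral radius must be < 1.",
         call. = FALSE)
  }
  a <- diag(n * n) - kronecker(theta, theta)
  sigma <- matrix(solve(a, as.vector(s1)), n, n)
  (sigma + t(sigma)) / 2
}

#' Stationary covariance of a model
#'
#' @param model An [inheritance_model()].
#' @return The `N x N` stationary factor covariance.
#' @export
stationary_covariance <- function(model) {
  stopifnot(inherits(model, "inheritance_model"))
  solve_lyapunov(model$theta, model$s1)
}

#' Stationary interdivision-time variance
#'
#' The variance of `tau = tau_bar + alpha' x` under the stationary factor
#' law: `s_tau = alpha' Sigma alpha` (hours squared).
#'
#' @param model An [inheritance_model()].
#' @return A single non-negative number.
#' @export
interdivision_variance <- function(model) {
  stopifnot(inherits(model, "inheritance_model"))
  sigma <- stationary_covariance(model)
  drop(crossprod(model$alpha, sigma %*% model$alpha))
}

# omega(k, l) = theta^k Sigma (theta^l)' + 1{k>=1} 1{l>=1}
#               theta^(k-1) S2 (theta^(l-1))'
omega_kl <- function(model, sigma, k, l) {
  th <- model$theta
  out <- mat_power(th, k) %*% sigma %*% t(mat_power(th, l))
  if (k >= 1 && l >= 1) {
    out <- out + mat_power(th, k - 1) %*% model$s2 %*% t(mat_power(th, l - 1))
  }
  out
}

mat_power <- function(m, k) {
  stopifnot(k >= 0, k == round(k))
  out <- diag(nrow(m))
  p <- m
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% p
    p <- p %*% p
    k <- k %/% 2
  }
  out
}

#' Generalised tree correlation function
#'
#' Pearson correlation of interdivision times between two cells whose most
#' recent common ancestor lies `k` generations above the first cell and `l`
#' above the second: `(1,0)` mother-daughter, `(1,1)` sisters, `(2,0)`
#' grandmother, `(2,2)` cousins, `(2,1)` aunt-niece. Computed exactly from
#' the matrix-power form
#' `rho(k, l) = alpha' omega(k, l) alpha / alpha' Sigma alpha` with
#' `omega(k, l) = theta^k Sigma (theta^l)' + 1{k>=1} 1{l>=1}
#' theta^(k-1) S2 (theta^(l-1))'`; this needs no eigendecomposition and is
#' valid for defective `theta` as well. `k` and `l` are vectorised.
#'
#' @param model An [inheritance_model()].
#' @param k,l Non-negative integer generation counts (recycled together).
#' @return Numeric vector of correlations in `[-1, 1]`; `rho(0,0) = 1`.
#' @examples
#' m <- inheritance_model(20, matrix(0.5), matrix(1))
#' tree_correlation(m, c(1, 2, 1, 2), c(0, 0, 1, 2))
#' @export
tree_correlation <- function(model, k, l) {
  stopifnot(inherits(model, "inheritance_model"))
  if (any(k < 0) || any(l < 0) || any(k != round(k)) || any(l != round(l))) {
    stop("`k` and `l` must be non-negative integers; use ",
         "`correlation_function()` for the continuous eigen-expansion.",
         call. = FALSE)
  }
  kl <- vctrs_recycle(k, l)
  sigma <- stationary_covariance(model)
  s_tau <- drop(crossprod(model$alpha, sigma %*% model$alpha))
  if (s_tau <= 0) stop("degenerate model: zero interdivision-time variance.",
                       call. = FALSE)
  a <- model$alpha
  vapply(seq_along(kl$k), function(i) {
    drop(crossprod(a, omega_kl(model, sigma, kl$k[i], kl$l[i]) %*% a)) / s_tau
  }, numeric(1))
}

vctrs_recycle <- function(k, l) {
  n <- max(length(k), length(l))
  list(k = rep_len(k, n), l = rep_len(l, n))
}

#' Evaluate the correlation function over a grid of family relations
#'
#' Convenience wrapper returning a tibble, handy for plotting the lineage
#' (`l = 0`) and cross-branch (`k = l`) correlation functions.
#'
#' @param model An [inheritance_model()].
#' @param k_max Largest generation distance (default 6).
#' @return A tibble with columns `k`, `l`, `rho`.
#' @export
correlation_grid <- function(model, k_max = 6) {
  g <- tidyr::expand_grid(k = 0:k_max, l = 0:k_max)
  g <- dplyr::filter(g, .data$k >= .data$l)
  g$rho <- tree_correlation(model, g$k, g$l)
  g
}

#' Eigen-expansion of the tree correlation function
#'
#' Diagonalises the inheritance matrix, `U theta U^{-1} = diag(lambda)`, and
#' expresses the tree correlation function as a weighted sum of powers of
#' the eigenvalues, `rho(k, l) = sum_ij w_ij lambda_i^k lambda_j^l` (for
#' `k, l >= 1`; on the boundary the sister-noise part of the weights is
#' dropped). The expansion separates the pattern — set by the eigenvalues —
#' from the weights set by the transformed noise matrices, and extends to
#' continuous `k`, `l` for smooth plotting.
#'
#' @param model An [inheritance_model()] with diagonalizable `theta`.
#' @return An object of class `eigen_expansion`: list with `eigenvalues`
#'   (complex), `transform` (`U`), `s1_hat`, `s2_hat`, `alpha_hat`,
#'   `sigma_hat`, `weights_s1`, `weights_s2` (complex matrices such that
#'   `rho(k,l) = sum_ij (w1_ij + 1{k,l>=1} w2_ij) lambda_i^k lambda_j^l`),
#'   `sigma` (reconstructed stationary covariance) and `tau_bar`.
#' @examples
#' m <- inheritance_model(20, matrix(c(0.5, -0.3, 0.3, 0.5), 2, 2), diag(2))
#' e <- eigen_expansion(m)
#' e$eigenvalues
#' @export
eigen_expansion <- function(model) {
  stopifnot(inherits(model, "inheritance_model"))
  n <- model$n_factors
  ed <- eigen(model$theta)
  v <- ed$vectors
  # Defective theta: eigenvector matrix (numerically) singular.
  sv <- svd(v, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) {
    stop("`theta` is defective (not diagonalizable); ",
         "use `tree_correlation()`, which needs no eigendecomposition.",
         call. = FALSE)
  }
  u <- solve(v)                       # U theta U^{-1} = diag(lambda)
  lambda <- ed$values
  s1_hat <- u %*% model$s1 %*% t(u)
  s2_hat <- u %*% model$s2 %*% t(u)
  alpha_hat <- drop(t(v) %*% model$alpha)     # (U^{-1})' alpha, U^{-1} = V
  denom_mat <- 1 - tcrossprod(lambda, lambda) # outer 1 - lambda_i lambda_j
  sigma_hat <- s1_hat / denom_mat
  sigma <- v %*% sigma_hat %*% t(v)           # U^{-1} Sigma_hat U^{-T}
  sigma <- Re(sigma)
  s_tau <- Re(drop(crossprod(alpha_hat, sigma_hat %*% alpha_hat)))
  aa <- tcrossprod(alpha_hat, alpha_hat)
  weights_s1 <- aa * s1_hat / denom_mat / s_tau
  # The sister-noise weight carries a 1/(lambda_i lambda_j) factor; it is
  # undefined for a zero eigenvalue, where the lambda^(k-1) form used by
  # correlation_function() remains valid.
  lamlam <- tcrossprod(lambda, lambda)
  weights_s2 <- aa * s2_hat / lamlam / s_tau
  weights_s2[Mod(s2_hat) == 0] <- 0

  structure(
    list(eigenvalues = lambda, transform = u, s1_hat = s1_hat,
         s2_hat = s2_hat, alpha_hat = alpha_hat, sigma_hat = sigma_hat,
         weights_s1 = weights_s1, weights_s2 = weights_s2,
         sigma = sigma, tau_bar = model$tau_bar),
    class = "eigen_expansion"
  )
}

#' Correlation function from the eigen-expansion (continuous arguments)
#'
#' Evaluates `rho(k, l) = sum_ij w_ij lambda_i^k lambda_j^l` using principal
#' complex powers, so `k` and `l` may be non-integer for smooth curves. For
#' integer arguments the result agrees with [tree_correlation()]. The
#' sister-noise weight term is included only when both `k >= 1` and
#' `l >= 1`, matching the indicator in the exact formula.
#'
#' @param expansion An [eigen_expansion()].
#' @param k,l Non-negative generation distances (recycled, possibly
#'   fractional).
#' @return Numeric vector of correlations (imaginary residue `< 1e-8`
#'   discarded).
#' @export
correlation_function <- function(expansion, k, l) {
  stopifnot(inherits(expansion, "eigen_expansion"))
  kl <- vctrs_recycle(k, l)
  lam <- expansion$eigenvalues
  w1 <- expansion$weights_s1
  s_tau <- Re(drop(crossprod(expansion$alpha_hat,
                             expansion$sigma_hat %*% expansion$alpha_hat)))
  aa <- tcrossprod(expansion$alpha_hat, expansion$alpha_hat)
  w2_raw <- aa * expansion$s2_hat / s_tau   # multiplies lambda^(k-1) lambda^(l-1)
  out <- vapply(seq_along(kl$k), function(i) {
    val <- sum(w1 * tcrossprod(cpow(lam, kl$k[i]), cpow(lam, kl$l[i])))
    if (kl$k[i] >= 1 && kl$l[i] >= 1) {
      val <- val + sum(w2_raw * tcrossprod(cpow(lam, kl$k[i] - 1),
                                           cpow(lam, kl$l[i] - 1)))
    }
    Re(val)
  }, numeric(1))
  out
}

cpow <- function(z, p) {
  out <- z^p
  # 0^0 = 1, 0^p = 0 for p > 0 (complex pow of exact zero is fine in R)
  out[z == 0] <- ifelse(p == 0, 1 + 0i, 0 + 0i)
  out
}

#' @export
print.eigen_expansion <- function(x, ...) {
  cat("<eigen_expansion> eigenvalues:\n")
  print(round(x$eigenvalues, 4))
  invisible(x)
}
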