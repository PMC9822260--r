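#' Plot the lineage and cross-branch correlation functions of a model
#'
#' Draws the generalised tree correlation function along its two standard
#' sections: down the lineage (`rho(k, 0)`) and across branches
#' (`rho(k, k)`). Integer family relations are drawn as points; when
#' `theta` is diagonalizable a continuous interpolation through the
#' eigen-expansion is added, which makes damped correlation oscillations
#' easy to see.
#'
#' @param model An [inheritance_model()].
#' @param k_max Largest generation distance shown (default 6).
#' @param continuous Overlay the continuous eigen-expansion curves
#'   (default `TRUE`; silently skipped for defective `theta`).
#' @return A ggplot object.
#' @export
plot_correlation_functions <- function(model, k_max = 6, continuous = TRUE) {
  stopifnot(inherits(model, "inheritance_model"))
  pts <- dplyr::bind_rows(
    tibble::tibble(k = 0:k_max, section = "lineage (l = 0)",
                   rho = tree_correlation(model, 0:k_max, 0)),
    tibble::tibble(k = 0:k_max, section = "cross-branch (k = l)",
                   rho = tree_correlation(model, 0:k_max, 0:k_max))
  )
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$k, y = .data$rho,
                                         colour = .data$section)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2)
  if (continuous) {
    exp_ok <- tryCatch(eigen_expansion(model), error = function(e) NULL)
    if (!is.null(exp_ok)) {
      kk <- seq(0, k_max, by = 0.05)
      cur <- dplyr::bind_rows(
        tibble::tibble(k = kk, section = "lineage (l = 0)",
                       rho = correlation_function(exp_ok, kk, 0)),
        tibble::tibble(k = kk, section = "cross-branch (k = l)",
                       rho = correlation_function(exp_ok, kk, kk))
      )
      p <- p + ggplot2::geom_line(data = cur, alpha = 0.7)
    }
  }
  p + ggplot2::labs(x = "generations to common ancestor",
                    y = "interdivision-time correlation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlation_functions
#' @param object,... An [inheritance_model()]; further arguments passed on.
#' @export
autoplot.inheritance_model <- function(object, ...) {
  plot_correlation_functions(object, ...)
}

#' Plot estimated correlations with bootstrap intervals
#'
#' @param object A [lineage_summary()].
#' @param ... Unused.
#' @return A ggplot object: one point with a 95% interval per family
#'   relation.
#' @export
autoplot.lineage_summary <- function(object, ...) {
  co <- object$correlations
  co$relation <- factor(co$relation, levels = co$relation)
  ggplot2::ggplot(co, ggplot2::aes(x = .data$relation, y = .data$rho_hat)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(x = NULL, y = "interdivision-time correlation") +
    ggplot2::theme_minimal()
}

#' Plot a posterior: pattern fractions or correlation-function draws
#'
#' `type = "patterns"` shows the posterior mass of the aperiodic,
#' alternator and oscillator classes. `type = "correlations"` overlays
#' posterior draws of the lineage and cross-branch correlation functions
#' on the data's estimates — the posterior-predictive view of the fit.
#'
#' @param object An [fit_inheritance()] result.
#' @param type `"patterns"` (default) or `"correlations"`.
#' @param n_draws Posterior draws shown for `type = "correlations"`
#'   (default 50).
#' @param k_max Largest generation distance (default 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inheritance_fit <- function(object, type = c("patterns",
                                                      "correlations"),
                                     n_draws = 50, k_max = 4, ...) {
  type <- match.arg(type)
  if (type == "patterns") {
    fr <- classify_posterior(object)$fractions
    return(
      ggplot2::ggplot(fr, ggplot2::aes(x = .data$label,
                                       y = .data$fraction)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = NULL, y = "posterior fraction") +
        ggplot2::ylim(0, 1) +
        ggplot2::theme_minimal()
    )
  }
  ch <- object$chain
  idx <- round(seq(1, nrow(ch), length.out = min(n_draws, nrow(ch))))
  pars <- parameter_names(object$n_factors, object$s2_free)
  draws <- purrr::map_dfr(idx, function(i) {
    mats <- par_to_matrices(as.numeric(ch[i, pars]), object$n_factors,
                            object$s2_free)
    m <- inheritance_model(1, mats$theta, mats$s1, s2 = mats$s2,
                           alpha = object$alpha)
    dplyr::bind_rows(
      tibble::tibble(draw = i, k = 0:k_max, section = "lineage (l = 0)",
                     rho = tree_correlation(m, 0:k_max, 0)),
      tibble::tibble(draw = i, k = 0:k_max,
                     section = "cross-branch (k = l)",
                     rho = tree_correlation(m, 0:k_max, 0:k_max))
    )
  })
  co <- object$summary$correlations
  data_pts <- dplyr::bind_rows(
    tibble::tibble(k = co$k[co$l == 0], rho = co$rho_hat[co$l == 0],
                   lo = co$ci_lo[co$l == 0], hi = co$ci_hi[co$l == 0],
                   section = "lineage (l = 0)"),
    tibble::tibble(k = co$k[co$l == co$k], rho = co$rho_hat[co$l == co$k],
                   lo = co$ci_lo[co$l == co$k], hi = co$ci_hi[co$l == co$k],
                   section = "cross-branch (k = l)")
  )
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$k, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(group = .data$draw), alpha = 0.15,
                       colour = "steelblue") +
    ggplot2::geom_pointrange(data = data_pts,
                             ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             colour = "black") +
    ggplot2::facet_wrap(~section) +
    ggplot2::labs(x = "generations to common ancestor",
                  y = "interdivision-time correlation") +
    ggplot2::theme_minimal()
}

#' Plot the identifiability diagnostic
#'
#' Log-log mean-squared-displacement curves from [msd_diagnostic()]:
#' diffusing parameters versus plateauing eigenvalues.
#'
#' @param msd A tibble from [msd_diagnostic()].
#' @return A ggplot object.
#' @export
plot_msd <- function(msd) {
  ggplot2::ggplot(msd, ggplot2::aes(x = .data$lag, y = .data$msd,
                                    colour = .data$series,
                                    linetype = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (samples)", y = "mean squared displacement",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
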