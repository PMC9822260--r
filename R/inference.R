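#' Names and count of free parameters
#'
#' The model is fitted in the natural coordinates: the entries of the
#' inheritance matrix plus a variance/correlation parameterisation of the
#' symmetric noise covariance `S1` (`N` variances and `N(N-1)/2`
#' correlation coefficients). With the sister cross-covariance `S2` free
#' the model has `d(1 + 2d)` parameters; with `S2 = 0` it reduces to
#' `d(1 + 3d)/2` — seven for two factors.
#'
#' @param n_factors Number of hidden factors `d` (1 or 2).
#' @param s2_free Whether the sister noise cross-covariance is free.
#' @return `n_parameters()`: integer count. `parameter_names()`: character
#'   vector naming the coordinates of the sampled vector.
#' @export
n_parameters <- function(n_factors, s2_free = n_factors == 1) {
  d <- n_factors
  if (s2_free) d * (1 + 2 * d) else d * (1 + 3 * d) / 2
}

#' @rdname n_parameters
#' @export
parameter_names <- function(n_factors, s2_free = n_factors == 1) {
  if (n_factors == 1) {
    c("theta", "var1", if (s2_free) "sister_corr")
  } else if (n_factors == 2) {
    if (s2_free) {
      stop("a free S2 is only supported for the 1-factor model.",
           call. = FALSE)
    }
    c("theta11", "theta21", "theta12", "theta22", "var1", "var2",
      "noise_corr")
  } else {
    stop("`n_factors` must be 1 or 2.", call. = FALSE)
  }
}

#' Is a parameter vector inside the flat prior's support?
#'
#' The prior is flat with support restricted to spectral radius
#' `SR(theta) < 1` (stationarity), positive noise variances, and noise
#' correlation coefficients in `[-1, 1]` (so the implied `S1` is PSD).
#'
#' @param par Numeric parameter vector in the layout of
#'   [parameter_names()].
#' @param n_factors 1 or 2.
#' @param s2_free Whether the sister cross-covariance is a free parameter.
#' @return `TRUE` or `FALSE`.
#' @examples
#' prior_support(c(0.5, 0, 0, 0.2, 1, 1, 0), n_factors = 2)    # TRUE
#' prior_support(c(1.1, 1), n_factors = 1, s2_free = FALSE)    # FALSE
#' @export
prior_support <- function(par, n_factors = 2, s2_free = n_factors == 1) {
  check_par_length(par, n_factors, s2_free)
  cpp_in_support(as.numeric(par), as.integer(n_factors), isTRUE(s2_free))
}

check_par_length <- function(par, n_factors, s2_free) {
  expected <- length(parameter_names(n_factors, s2_free))
  if (length(par) != expected) {
    stop("parameter vector must have length ", expected, " for ",
         n_factors, " factor(s) (", if (s2_free) "free" else "zero",
         " S2).", call. = FALSE)
  }
  invisible(TRUE)
}

#' Rebuild model matrices from a sampled parameter vector
#'
#' @param par Numeric vector in the layout of [parameter_names()].
#' @inheritParams prior_support
#' @return List with `theta`, `s1`, `s2`.
#' @export
par_to_matrices <- function(par, n_factors = 2, s2_free = n_factors == 1) {
  check_par_length(par, n_factors, s2_free)
  if (n_factors == 1) {
    list(theta = matrix(par[1]), s1 = matrix(par[2]),
         s2 = matrix(if (s2_free) par[3] * par[2] else 0))
  } else {
    theta <- matrix(par[1:4], 2, 2)
    v1 <- par[5]; v2 <- par[6]; r <- par[7]
    s1 <- matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
    list(theta = theta, s1 = s1, s2 = matrix(0, 2, 2))
  }
}

summary_data_vectors <- function(summary) {
  stopifnot(inherits(summary, "lineage_summary"))
  co <- summary$correlations
  tr <- training_relations()
  idx <- match(paste(tr$k, tr$l), paste(co$k, co$l))
  if (anyNA(idx)) {
    stop("summary is missing training relation(s) ",
         paste0("(", tr$k[is.na(idx)], ",", tr$l[is.na(idx)], ")",
                collapse = ", "), call. = FALSE)
  }
  data <- c(summary$s_tau_hat, co$rho_hat[idx])
  sds <- c(summary$boot_sd_var, co$boot_sd[idx])
  if (any(!is.finite(data)) || any(!is.finite(sds)) || any(sds <= 0)) {
    stop("degenerate weights: every training statistic needs a finite ",
         "positive bootstrap SD.", call. = FALSE)
  }
  list(data = data, sds = sds)
}

#' Log-likelihood of summary statistics under the model
#'
#' `-ln L` is the sum of squared residuals between the data's five summary
#' statistics (variance plus mother-daughter, grandmother, sister and
#' cousin correlations) and the model's analytic values, each standardised
#' by its bootstrap SD — the large-sample normal approximation for sample
#' statistics, neglecting their cross-correlations. The likelihood does
#' not involve the mean interdivision time. Returns `-Inf` outside the
#' prior support. This is a plain-R reference implementation; the sampler
#' uses an equivalent compiled one.
#'
#' @param par Parameter vector ([parameter_names()] layout).
#' @param summary A [lineage_summary()] containing the training relations.
#' @inheritParams prior_support
#' @param alpha Binary factor-weight vector (default all ones).
#' @return `ln L` (0 when the model reproduces the data exactly).
#' @export
log_likelihood <- function(par, summary, n_factors = 2,
                           s2_free = n_factors == 1, alpha = NULL) {
  if (!prior_support(par, n_factors, s2_free)) return(-Inf)
  if (is.null(alpha)) alpha <- rep(1, n_factors)
  mats <- par_to_matrices(par, n_factors, s2_free)
  dv <- summary_data_vectors(summary)
  sigma <- solve_lyapunov(mats$theta, mats$s1)
  s_tau <- drop(crossprod(alpha, sigma %*% alpha))
  if (s_tau <= 0) return(-Inf)
  model <- inheritance_model(1, mats$theta, mats$s1, s2 = mats$s2,
                             alpha = alpha)
  tr <- training_relations()
  stats <- c(s_tau, tree_correlation(model, tr$k, tr$l))
  -sum(((dv$data - stats) / dv$sds)^2)
}

#' Fit the inheritance-matrix model by adaptive MCMC
#'
#' Samples the posterior of the model parameters given the summary
#' statistics of a lineage forest, under a flat prior restricted to the
#' stationary region. The sampler is Metropolis-within-Gibbs: one
#' coordinate is updated per step with a Gaussian proposal whose scale
#' adapts toward a target acceptance rate during burn-in and is then
#' frozen. Out-of-support proposals are rejected. The default chain length
#' (200,000 with 20,000 burn-in) is a desk-scale setting under which the
#' eigenvalue, pattern and period posteriors are well converged even
#' though the raw inheritance parameters are not identifiable; production
#' runs can raise it arbitrarily.
#'
#' @param summary A [lineage_summary()] (from data, or [manual_summary()]).
#' @param n_factors Number of hidden factors (1 or 2; default 2).
#' @param s2_free Free sister noise cross-covariance. Default `TRUE` for
#'   the 1-factor model (without it the sister correlation is forced to
#'   `theta^2`), `FALSE` for the 2-factor model.
#' @param alpha Binary factor-weight vector (default all ones).
#' @param n_samples Total chain length including burn-in (default 2e5).
#' @param n_burnin Discarded prefix (default 2e4).
#' @param thin Keep every `thin`-th post-burn-in sample (default 1).
#' @param seed Optional integer seed; the chain is bit-reproducible given
#'   it.
#' @param target_accept Adaptation target acceptance rate (default 0.44,
#'   the standard value for coordinate-wise updates).
#' @param init Optional start vector. By default several short pilot
#'   chains are launched from independent random points in the support
#'   and the main chain starts from the best state found — a standard
#'   guard against the random-walk sampler stalling in a poor mode of
#'   this multimodal posterior.
#' @param n_pilot Number of pilot chains (default 8; 0 disables).
#' @param pilot_samples Steps per pilot chain (default 4000).
#' @param polish Refine the best sample by Nelder-Mead before reporting
#'   the maximum log-likelihood (default `TRUE`).
#' @return An object of class `inheritance_fit`; see [tidy.inheritance_fit()],
#'   [glance.inheritance_fit()], [classify_posterior()],
#'   [period_posterior()], [aic()].
#' @examples
#' \donttest{
#' m <- inheritance_model(20, matrix(c(0.3, 0.5, -0.5, 0.3), 2, 2), diag(2))
#' f <- simulate_lineage(m, n_trees = 100, depth = 5, seed = 1)
#' s <- lineage_summary(f, n_boot = 500, seed = 2)
#' fit <- fit_inheritance(s, n_samples = 20000, n_burnin = 5000, seed = 3)
#' glance(fit)
#' }
#' @export
fit_inheritance <- function(summary, n_factors = 2,
                            s2_free = n_factors == 1, alpha = NULL,
                            n_samples = 2e5, n_burnin = 2e4, thin = 1,
                            seed = NULL, target_accept = 0.44, init = NULL,
                            n_pilot = 8, pilot_samples = 4000,
                            polish = TRUE) {
  stopifnot(inherits(summary, "lineage_summary"))
  if (!n_factors %in% c(1, 2)) stop("`n_factors` must be 1 or 2.",
                                    call. = FALSE)
  if (n_burnin >= n_samples) stop("`n_burnin` must be < `n_samples`.",
                                  call. = FALSE)
  if (is.null(alpha)) alpha <- rep(1, n_factors)
  alpha <- as.numeric(alpha)
  if (!all(alpha %in% c(0, 1)) || !any(alpha == 1)) {
    stop("`alpha` must be binary with at least one 1.", call. = FALSE)
  }
  dv <- summary_data_vectors(summary)
  if (!is.null(seed)) set.seed(seed)
  p <- length(parameter_names(n_factors, s2_free))
  prop_sd <- c(rep(0.1, n_factors^2),                    # theta entries
               rep(0.2 * summary$s_tau_hat, n_factors),  # variances
               rep(0.1, p - n_factors^2 - n_factors))    # correlations
  if (is.null(init)) {
    init <- draw_init(summary$s_tau_hat, n_factors, s2_free)
    if (n_pilot > 0) {
      # multi-start: short pilot chains from independent random points;
      # the main chain starts from the best state any pilot visited.
      best_ll <- -Inf
      for (i in seq_len(n_pilot)) {
        start <- draw_init(summary$s_tau_hat, n_factors, s2_free)
        pilot <- cpp_mcmc(start, as.integer(n_factors), isTRUE(s2_free),
                          alpha, dv$data, dv$sds,
                          as.integer(pilot_samples), 0L, 1L, target_accept,
                          prop_sd)
        j <- which.max(pilot$log_lik)
        if (pilot$log_lik[j] > best_ll) {
          best_ll <- pilot$log_lik[j]
          init <- as.numeric(pilot$chain[j, ])
        }
      }
    }
  }
  init <- as.numeric(init)
  check_par_length(init, n_factors, s2_free)
  if (!prior_support(init, n_factors, s2_free)) {
    stop("`init` lies outside the prior support.", call. = FALSE)
  }

  res <- cpp_mcmc(init, as.integer(n_factors), isTRUE(s2_free), alpha,
                  dv$data, dv$sds, as.integer(n_samples),
                  as.integer(n_burnin), as.integer(thin), target_accept,
                  prop_sd)
  chain <- tibble::as_tibble(as.data.frame(res$chain),
                             .name_repair = "minimal")
  names(chain) <- parameter_names(n_factors, s2_free)
  chain$log_lik <- res$log_lik
  chain <- dplyr::bind_cols(chain, derive_eigen(chain, n_factors))
  chain <- tibble::add_column(chain, .iter = seq_len(nrow(chain)),
                              .before = 1)

  best <- which.max(chain$log_lik)
  map_par <- as.numeric(chain[best, parameter_names(n_factors, s2_free)])
  max_ll <- chain$log_lik[best]
  polished <- FALSE
  if (polish) {
    obj <- function(x) {
      ll <- log_likelihood(x, summary, n_factors, s2_free, alpha)
      if (!is.finite(ll)) 1e10 else -ll
    }
    cur <- map_par
    val <- -max_ll
    for (i in 1:4) {   # restarted simplex: refreshes the shrunken simplex
      opt <- stats::optim(cur, obj, method = "Nelder-Mead",
                          control = list(maxit = 3000,
                                         reltol = 1e-12))
      if (opt$value >= val - 1e-9) { val <- min(val, opt$value); break }
      val <- opt$value
      cur <- opt$par
    }
    if (-val > max_ll) {
      max_ll <- -val
      map_par <- cur
      polished <- TRUE
    }
  }
  accept <- as.numeric(res$accept_rate)
  if (mean(accept) < 0.01) {
    warning("post-adaptation acceptance rate below 1%; the chain has ",
            "likely not mixed.", call. = FALSE)
  }

  structure(
    list(chain = chain, summary = summary, n_factors = n_factors,
         s2_free = s2_free, alpha = alpha, n_samples = n_samples,
         n_burnin = n_burnin, thin = thin, seed = seed,
         target_accept = target_accept,
         accept_rate = stats::setNames(accept,
                                       parameter_names(n_factors, s2_free)),
         prop_sd = exp(as.numeric(res$prop_sd)),
         max_log_lik = max_ll, map_par = map_par, polished = polished,
         k = n_parameters(n_factors, s2_free),
         tau_bar_hat = summary$tau_bar_hat),
    class = "inheritance_fit"
  )
}

draw_init <- function(s_tau_hat, n_factors, s2_free) {
  repeat {
    th <- stats::runif(n_factors^2, -0.6, 0.6)
    if (spectral_radius(matrix(th, n_factors)) < 1) break
  }
  vars <- rep(max(s_tau_hat, 1e-6) / 2, n_factors)
  corr <- rep(0, length(parameter_names(n_factors, s2_free)) -
                n_factors^2 - n_factors)
  c(th, vars, corr)
}

# per-sample eigenvalues, pattern label and oscillation period (in
# generations) from the chain's theta columns; exact 2x2 discriminant.
derive_eigen <- function(chain, n_factors) {
  if (n_factors == 1) {
    lam <- chain$theta
    pattern <- ifelse(lam < 0, "alternator", "aperiodic")
    t0_gen <- ifelse(lam < 0, 2, NA_real_)
    return(tibble::tibble(eig1_re = lam, eig1_im = 0,
                          eig2_re = NA_real_, eig2_im = NA_real_,
                          pattern = pattern, t0_gen = t0_gen))
  }
  tr <- chain$theta11 + chain$theta22
  dt <- chain$theta11 * chain$theta22 - chain$theta12 * chain$theta21
  disc <- tr^2 - 4 * dt
  cplx <- disc < 0
  sq <- sqrt(abs(disc))
  eig1_re <- ifelse(cplx, tr / 2, (tr + sq) / 2)
  eig1_im <- ifelse(cplx, sq / 2, 0)
  eig2_re <- ifelse(cplx, tr / 2, (tr - sq) / 2)
  eig2_im <- ifelse(cplx, -sq / 2, 0)
  pattern <- dplyr::case_when(
    cplx ~ "oscillator",
    eig1_re < 0 | eig2_re < 0 ~ "alternator",
    TRUE ~ "aperiodic"
  )
  arg <- atan2(eig1_im, eig1_re)
  t0_gen <- dplyr::case_when(
    cplx ~ 2 * pi / abs(arg),
    pattern == "alternator" ~ 2,
    TRUE ~ NA_real_
  )
  tibble::tibble(eig1_re = eig1_re, eig1_im = eig1_im,
                 eig2_re = eig2_re, eig2_im = eig2_im,
                 pattern = pattern, t0_gen = t0_gen)
}

#' @export
print.inheritance_fit <- function(x, ...) {
  cat("<inheritance_fit> N =", x$n_factors, "factors,",
      nrow(x$chain), "retained samples\n")
  cat("  max ln L =", formatC(x$max_log_lik, digits = 4),
      " AIC =", formatC(aic(x), digits = 4),
      " (k =", x$k, "parameters)\n")
  fr <- classify_posterior(x)$fractions
  cat("  patterns:",
      paste(sprintf("%s %.1f%%", fr$label, 100 * fr$fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Posterior parameter summaries
#'
#' @param x An [fit_inheritance()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior `mean`, `sd`,
#'   `q2.5`, `median`, `q97.5`, `accept_rate`.
#' @export
tidy.inheritance_fit <- function(x, ...) {
  pars <- parameter_names(x$n_factors, x$s2_free)
  purrr::map_dfr(pars, function(p) {
    v <- x$chain[[p]]
    qs <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(term = p, mean = mean(v), sd = stats::sd(v),
                   q2.5 = qs[1], median = qs[2], q97.5 = qs[3],
                   accept_rate = unname(x$accept_rate[p]))
  })
}

#' One-row fit overview
#'
#' @param x An [fit_inheritance()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_factors`, `s2_free`, `k`, `max_log_lik`,
#'   `aic`, pattern fractions, mean acceptance rate.
#' @export
glance.inheritance_fit <- function(x, ...) {
  fr <- classify_posterior(x)$fractions
  frac <- stats::setNames(fr$fraction, fr$label)
  tibble::tibble(
    n_factors = x$n_factors, s2_free = x$s2_free, k = x$k,
    max_log_lik = x$max_log_lik, aic = aic(x),
    frac_aperiodic = unname(frac["aperiodic"]),
    frac_alternator = unname(frac["alternator"]),
    frac_oscillator = unname(frac["oscillator"]),
    mean_accept = mean(x$accept_rate),
    n_retained = nrow(x$chain)
  )
}

#' Classify posterior samples into correlation patterns
#'
#' Every retained sample is labelled aperiodic, alternator or oscillator
#' from its inheritance-matrix eigenvalues (exact discriminant for two
#' factors). Oscillator samples are additionally clustered by the sign of
#' the eigenvalues' real part — cluster A negative, cluster B positive —
#' the two qualitatively different damped-oscillation motifs a bimodal
#' posterior can mix.
#'
#' @param fit An [fit_inheritance()] result.
#' @return List with `fractions` (tibble `label`, `n`, `fraction`; the
#'   fractions sum to 1) and `clusters` (tibble `cluster`, `n`, `fraction`
#'   of oscillator mass).
#' @export
classify_posterior <- function(fit) {
  stopifnot(inherits(fit, "inheritance_fit"))
  pat <- factor(fit$chain$pattern,
                levels = c("aperiodic", "alternator", "oscillator"))
  tab <- table(pat)
  fractions <- tibble::tibble(label = names(tab), n = as.integer(tab),
                              fraction = as.integer(tab) / length(pat))
  osc <- fit$chain[fit$chain$pattern == "oscillator", , drop = FALSE]
  clusters <- if (nrow(osc) > 0) {
    cl <- ifelse(osc$eig1_re < 0, "A", "B")
    tab2 <- table(factor(cl, levels = c("A", "B")))
    tibble::tibble(cluster = names(tab2), n = as.integer(tab2),
                   fraction = as.integer(tab2) / nrow(osc))
  } else {
    tibble::tibble(cluster = character(0), n = integer(0),
                   fraction = numeric(0))
  }
  list(fractions = fractions, clusters = clusters)
}

#' Posterior of correlation and aliased oscillator periods
#'
#' For every oscillator sample, converts the positive-imaginary eigenvalue
#' into the correlation-oscillation period `T0` and the aliased oscillator
#' period `Tn` (default `n = -1`, the alias closest to `T0`). Summaries
#' are reported overall and per eigenvalue-sign cluster.
#'
#' @param fit An [fit_inheritance()] result.
#' @param tau_bar Mean interdivision time in hours (defaults to the
#'   summary's estimate; with neither available, periods are in
#'   generations).
#' @param n Alias index (default `-1`).
#' @return List with `samples` (tibble `t0`, `tn`, `cluster`) and
#'   `summary` (tibble of medians and 95% credible intervals per cluster
#'   and overall). Empty, with a message, when the chain holds no
#'   oscillator samples.
#' @export
period_posterior <- function(fit, tau_bar = NULL, n = -1) {
  stopifnot(inherits(fit, "inheritance_fit"), length(n) == 1, n == round(n))
  if (is.null(tau_bar)) tau_bar <- fit$tau_bar_hat
  if (is.null(tau_bar) || is.na(tau_bar)) {
    tau_bar <- 1
    message("no mean interdivision time available; periods are in ",
            "generations.")
  }
  osc <- fit$chain[fit$chain$pattern == "oscillator", , drop = FALSE]
  if (nrow(osc) == 0) {
    message("chain contains no oscillator samples; empty period posterior.")
    return(list(samples = tibble::tibble(t0 = numeric(0), tn = numeric(0),
                                         cluster = character(0)),
                summary = tibble::tibble()))
  }
  t0 <- osc$t0_gen * tau_bar
  denom <- abs(tau_bar + n * t0)
  tn <- ifelse(denom == 0, NA_real_, tau_bar * t0 / denom)
  cluster <- ifelse(osc$eig1_re < 0, "A", "B")
  samples <- tibble::tibble(t0 = t0, tn = tn, cluster = cluster)
  summarise_one <- function(d, label) {
    tibble::tibble(
      cluster = label, n = nrow(d),
      t0_median = stats::median(d$t0),
      t0_lo = stats::quantile(d$t0, 0.025, names = FALSE),
      t0_hi = stats::quantile(d$t0, 0.975, names = FALSE),
      tn_median = stats::median(d$tn, na.rm = TRUE),
      tn_lo = stats::quantile(d$tn, 0.025, na.rm = TRUE, names = FALSE),
      tn_hi = stats::quantile(d$tn, 0.975, na.rm = TRUE, names = FALSE)
    )
  }
  summary <- dplyr::bind_rows(
    summarise_one(samples, "all"),
    purrr::map_dfr(unique(cluster), function(cl) {
      summarise_one(samples[cluster == cl, ], cl)
    })
  )
  list(samples = samples, summary = summary, n = n, tau_bar = tau_bar)
}

#' Mean-squared-displacement identifiability diagnostic
#'
#' The posterior of the raw inheritance parameters is not identifiable:
#' independent chains wander without settling, so their mean squared
#' displacement (MSD) grows with lag. The eigenvalues, in contrast, are
#' identifiable and their MSD plateaus. This diagnostic computes the MSD
#' of each inheritance-matrix entry and of the (consistently ordered)
#' eigenvalues as a function of lag, averaged over chains.
#'
#' @param fits A list of two or more [fit_inheritance()] results (same
#'   configuration, different seeds).
#' @param n_lags Number of log-spaced lags (default 30).
#' @return A tibble with columns `lag`, `series`, `type`
#'   (`"parameter"`/`"eigenvalue"`) and `msd`.
#' @seealso [msd_ratio()]
#' @export
msd_diagnostic <- function(fits, n_lags = 30) {
  if (inherits(fits, "inheritance_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "inheritance_fit")))
  n_factors <- fits[[1]]$n_factors
  theta_cols <- grep("^theta", parameter_names(n_factors, fits[[1]]$s2_free),
                     value = TRUE)
  n_min <- min(vapply(fits, function(f) nrow(f$chain), integer(1)))
  lags <- unique(round(exp(seq(log(1), log(max(2, n_min / 2)),
                               length.out = n_lags))))
  series_msd <- function(x, lag) mean((x[(1 + lag):length(x)] -
                                         x[1:(length(x) - lag)])^2)
  purrr::map_dfr(lags, function(L) {
    per_chain <- purrr::map(fits, function(f) {
      ch <- f$chain[1:n_min, ]
      th <- vapply(theta_cols, function(cn) series_msd(ch[[cn]], L),
                   numeric(1))
      if (n_factors == 2) {
        eig <- c(
          lambda1 = series_msd(ch$eig1_re, L) + series_msd(ch$eig1_im, L),
          lambda2 = series_msd(ch$eig2_re, L) + series_msd(ch$eig2_im, L)
        )
      } else {
        eig <- c(lambda1 = series_msd(ch$eig1_re, L))
      }
      c(th, eig)
    })
    avg <- Reduce(`+`, per_chain) / length(per_chain)
    tibble::tibble(
      lag = L,
      series = names(avg),
      type = ifelse(grepl("^theta", names(avg)), "parameter", "eigenvalue"),
      msd = unname(avg)
    )
  })
}

#' Parameter-to-eigenvalue MSD ratio at the largest lag
#'
#' A single unidentifiability score: the largest parameter MSD divided by
#' the largest eigenvalue MSD at the maximal lag. Values well above 1 mean
#' the raw parameters diffuse while the eigenvalues have converged.
#'
#' @param msd A tibble from [msd_diagnostic()].
#' @return A single number.
#' @export
msd_ratio <- function(msd) {
  top <- msd[msd$lag == max(msd$lag), ]
  max(top$msd[top$type == "parameter"]) /
    max(top$msd[top$type == "eigenvalue"])
}

#' Posterior of hidden-factor mother-daughter correlations
#'
#' The fitted model predicts how each hidden factor correlates between
#' mother and daughter even though the factors themselves are unobserved:
#' `Cov(x_daughter, x_mother) = theta Sigma`, normalised by the stationary
#' factor standard deviations. Same-factor correlations are the diagonal
#' entries; alternate-factor correlations the off-diagonals. Requires a
#' two-factor fit.
#'
#' @param fit A two-factor [fit_inheritance()] result.
#' @param max_samples Posterior samples used (evenly thinned; default
#'   5000).
#' @return A tibble with per-sample columns `same_1`, `same_2`, `alt_12`
#'   (mother factor 2 to daughter factor 1), `alt_21`, and `pattern`.
#' @export
factor_correlations <- function(fit, max_samples = 5000) {
  stopifnot(inherits(fit, "inheritance_fit"))
  if (fit$n_factors != 2) {
    stop("factor correlations require a 2-factor fit.", call. = FALSE)
  }
  n <- nrow(fit$chain)
  idx <- if (n > max_samples) round(seq(1, n, length.out = max_samples)) else
    seq_len(n)
  ch <- fit$chain[idx, ]
  purrr::map_dfr(seq_len(nrow(ch)), function(i) {
    mats <- par_to_matrices(as.numeric(ch[i, parameter_names(2, FALSE)]),
                            2, FALSE)
    sigma <- solve_lyapunov(mats$theta, mats$s1)
    m <- mats$theta %*% sigma          # Cov(x_daughter, x_mother)
    sds <- sqrt(diag(sigma))
    tibble::tibble(
      same_1 = m[1, 1] / (sds[1] * sds[1]),
      same_2 = m[2, 2] / (sds[2] * sds[2]),
      alt_12 = m[1, 2] / (sds[1] * sds[2]),
      alt_21 = m[2, 1] / (sds[2] * sds[1]),
      pattern = ch$pattern[i]
    )
  })
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2k - 2 ln(L_max)` with `k` the free-parameter count
#' ([n_parameters()]) and `ln(L_max)` the maximum log-likelihood over
#' retained samples (optionally polished by local optimisation — see
#' `fit$polished`).
#'
#' @param fit An [fit_inheritance()] result.
#' @return A single number (smaller is better).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "inheritance_fit"))
  2 * fit$k - 2 * fit$max_log_lik
}

#' Compare 1- and 2-factor fits by AIC
#'
#' Fits both model sizes to the same summary statistics and tabulates
#' their parameter counts, maximum log-likelihoods and AIC values.
#'
#' @param summary A [lineage_summary()].
#' @param n_samples,n_burnin,thin Chain settings shared by both fits.
#' @param seed Optional integer seed (each fit gets a derived sub-seed).
#' @param s2_free_1 Free sister cross-covariance for the 1-factor model
#'   (default `TRUE`).
#' @param ... Passed to [fit_inheritance()].
#' @return A tibble with one row per model: `n_factors`, `s2_free`, `k`,
#'   `max_log_lik`, `aic`, `delta_aic` (relative to the best model), and a
#'   list-column `fit`.
#' @export
compare_models <- function(summary, n_samples = 2e5, n_burnin = 2e4,
                           thin = 1, seed = NULL, s2_free_1 = TRUE, ...) {
  seeds <- if (is.null(seed)) c(NA, NA) else seed + c(0L, 1L)
  fit1 <- fit_inheritance(summary, n_factors = 1, s2_free = s2_free_1,
                          n_samples = n_samples, n_burnin = n_burnin,
                          thin = thin,
                          seed = if (is.na(seeds[1])) NULL else seeds[1],
                          ...)
  fit2 <- fit_inheritance(summary, n_factors = 2, s2_free = FALSE,
                          n_samples = n_samples, n_burnin = n_burnin,
                          thin = thin,
                          seed = if (is.na(seeds[2])) NULL else seeds[2],
                          ...)
  out <- tibble::tibble(
    n_factors = c(1L, 2L),
    s2_free = c(s2_free_1, FALSE),
    k = c(fit1$k, fit2$k),
    max_log_lik = c(fit1$max_log_lik, fit2$max_log_lik),
    aic = c(aic(fit1), aic(fit2))
  )
  out$delta_aic <- out$aic - min(out$aic)
  out$fit <- list(fit1, fit2)
  out
}
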