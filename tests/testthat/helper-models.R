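# Shared fixtures: models and small forests built in code.

# random stationary 2-factor model; resamples until spectral radius < 0.9
random_model <- function(seed, n = 2, with_s2 = FALSE, tau_bar = 20) {
  set.seed(seed)
  repeat {
    theta <- matrix(stats::runif(n * n, -0.8, 0.8), n, n)
    if (spectral_radius(theta) < 0.9) break
  }
  a <- matrix(stats::rnorm(n * n), n, n)
  s1 <- crossprod(a) / n + diag(n) * 0.2
  s2 <- NULL
  if (with_s2) {
    # scale a symmetric cross-covariance until the joint law is PSD
    b <- matrix(stats::rnorm(n * n), n, n)
    s2 <- 0.5 * (b + t(b)) / n
    repeat {
      joint <- rbind(cbind(s1, s2), cbind(t(s2), s1))
      if (min(eigen(joint, symmetric = TRUE,
                    only.values = TRUE)$values) > 1e-8) break
      s2 <- s2 / 2
    }
  }
  inheritance_model(tau_bar, theta, s1, s2 = s2)
}

# brute-force series solution of the Lyapunov equation (independent oracle)
series_lyapunov <- function(theta, s1, n_terms = 200) {
  acc <- s1
  p <- theta
  for (k in seq_len(n_terms)) {
    acc <- acc + p %*% s1 %*% t(p)
    p <- p %*% theta
  }
  acc
}

# brute-force (k, l) pair enumeration by walking parent chains of every
# cell pair (independent oracle for enumerate_pairs)
brute_pairs <- function(forest, k, l) {
  key <- paste(forest$tree_id, forest$cell_id)
  parent_row <- match(paste(forest$tree_id, forest$parent_id), key)
  anc_of <- function(i, g) {
    while (g > 0 && !is.na(i)) {
      i <- parent_row[i]
      g <- g - 1
    }
    i
  }
  out <- list()
  n <- nrow(forest)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (forest$tree_id[i] != forest$tree_id[j]) next
      if (i == j) next
      ai <- anc_of(i, l)  # ancestor-side cell: l generations up
      aj <- anc_of(j, k)
      if (is.na(ai) || is.na(aj) || ai != aj) next
      # MRCA exactness: paths must split immediately below the ancestor
      if (k >= 1 && l >= 1 &&
          identical(anc_of(i, l - 1), anc_of(j, k - 1))) next
      if (k == l && i >= j) next
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# minimal hand-built fit object for post-processing unit tests
fake_fit <- function(chain, n_factors = 2, s2_free = FALSE,
                     tau_bar_hat = NA_real_) {
  structure(
    list(chain = chain, n_factors = n_factors, s2_free = s2_free,
         alpha = rep(1, n_factors), accept_rate = NA, k = NA,
         max_log_lik = NA, tau_bar_hat = tau_bar_hat),
    class = "inheritance_fit"
  )
}
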