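#' Enumerate (k, l)-related cell pairs in a lineage forest
#'
#' Finds every pair of cells whose most recent common ancestor lies exactly
#' `k` generations above the first cell and `l` above the second, both
#' interdivision times observed. A cell may appear in several pairs (a cell
#' with two cousins contributes two cousin pairs). For `k = l` each
#' unordered pair is listed once; for `k > l` pairs are ordered with the
#' ancestor-side (closer) cell first, each ordered instance once. Trees in
#' the forest are pooled.
#'
#' @param forest Lineage tibble (`tree_id`, `cell_id`, `parent_id`,
#'   `interdivision_time`).
#' @param k,l Non-negative integers with `k >= l`, not both zero. `(1,0)`
#'   mother-daughter, `(1,1)` sisters, `(2,0)` grandmother, `(2,2)`
#'   cousins, `(2,1)` aunt-niece.
#' @return Tibble with columns `tree_id`, `cell_a` (ancestor-side, `l`
#'   generations from the common ancestor), `cell_b` (`k` generations),
#'   `tau_a`, `tau_b`, `k`, `l`. Empty (with a warning) when the forest is
#'   too shallow for the relation.
#' @examples
#' m <- inheritance_model(20, matrix(0.5), matrix(1))
#' f <- simulate_lineage(m, n_trees = 2, depth = 4, seed = 1)
#' nrow(enumerate_pairs(f, 1, 1))  # sister pairs: one per mother
#' @export
enumerate_pairs <- function(forest, k, l) {
  forest <- validate_forest(forest)
  stopifnot(length(k) == 1, length(l) == 1, k == round(k), l == round(l))
  if (k < l) stop("use the canonical orientation `k >= l`.", call. = FALSE)
  if (l < 0) stop("`k` and `l` must be non-negative.", call. = FALSE)
  if (k == 0 && l == 0) {
    stop("(0, 0) is the self-relation; its correlation is 1 by definition.",
         call. = FALSE)
  }
  obs <- !is.na(forest$interdivision_time)

  # row index of the g-th ancestor of every cell, by iterating parent rows
  parent_row <- match(paste(forest$tree_id, forest$parent_id),
                      paste(forest$tree_id, forest$cell_id))
  anc <- vector("list", k + 1)
  anc[[1]] <- seq_len(nrow(forest))
  for (g in seq_len(k)) {
    prev <- anc[[g]]
    nxt <- rep(NA_integer_, length(prev))
    ok <- !is.na(prev)
    nxt[ok] <- parent_row[prev[ok]]
    anc[[g + 1]] <- nxt
  }
  anc_at <- function(g) anc[[g + 1]]

  empty <- tibble::tibble(tree_id = forest$tree_id[0],
                          cell_a = forest$cell_id[0],
                          cell_b = forest$cell_id[0],
                          tau_a = numeric(0), tau_b = numeric(0),
                          k = integer(0), l = integer(0))

  if (l == 0) {
    b_rows <- which(!is.na(anc_at(k)) & obs)
    a_rows <- anc_at(k)[b_rows]          # the ancestor itself
    keep <- obs[a_rows]
    a_rows <- a_rows[keep]; b_rows <- b_rows[keep]
  } else {
    side_b <- tibble::tibble(row = which(!is.na(anc_at(k)) & obs))
    side_b$key <- anc_at(k)[side_b$row]
    side_b$sub <- anc_at(k - 1)[side_b$row]
    side_a <- tibble::tibble(row = which(!is.na(anc_at(l)) & obs))
    side_a$key <- anc_at(l)[side_a$row]
    side_a$sub <- anc_at(l - 1)[side_a$row]
    j <- dplyr::inner_join(side_a, side_b, by = "key",
                           suffix = c("_a", "_b"),
                           relationship = "many-to-many")
    j <- dplyr::filter(j, .data$sub_a != .data$sub_b)
    if (k == l) j <- dplyr::filter(j, .data$row_a < .data$row_b)
    a_rows <- j$row_a; b_rows <- j$row_b
  }

  if (length(a_rows) == 0) {
    warning("no (", k, ", ", l, ") pairs found; the trees may not be deep ",
            "enough for this relation.")
    return(empty)
  }
  tibble::tibble(
    tree_id = forest$tree_id[a_rows],
    cell_a = forest$cell_id[a_rows],
    cell_b = forest$cell_id[b_rows],
    tau_a = forest$interdivision_time[a_rows],
    tau_b = forest$interdivision_time[b_rows],
    k = as.integer(k), l = as.integer(l)
  )
}

#' Human-readable name of a family relation
#'
#' @param k,l Generation distances to the most recent common ancestor.
#' @return Character vector (`"mother-daughter"`, `"sister"`, ...).
#' @export
relation_name <- function(k, l) {
  key <- paste(pmax(k, l), pmin(k, l))
  known <- c("1 0" = "mother-daughter", "2 0" = "grandmother",
             "3 0" = "great-grandmother", "1 1" = "sister",
             "2 2" = "cousin", "2 1" = "aunt-niece", "3 3" = "second cousin")
  out <- unname(known[key])
  out[is.na(out)] <- paste0("(", pmax(k, l), ",", pmin(k, l), ")")[is.na(out)]
  out
}

#' Pearson correlation of a pair list
#'
#' Sample correlation coefficient of interdivision times over an enumerated
#' pair list, using the per-margin means of the paired sets (`pooled =
#' TRUE` instead centres both margins on the grand mean of the pooled
#' values, for sensitivity analysis).
#'
#' @param pairs Tibble from [enumerate_pairs()] (columns `tau_a`, `tau_b`).
#' @param pooled Use a pooled grand mean and variance for both margins
#'   (default `FALSE`).
#' @return A single correlation in `[-1, 1]`.
#' @export
sample_correlation <- function(pairs, pooled = FALSE) {
  if (nrow(pairs) < 2) {
    stop("need at least 2 pairs to compute a correlation.", call. = FALSE)
  }
  a <- pairs$tau_a; b <- pairs$tau_b
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("undefined correlation: one margin has zero variance.",
         call. = FALSE)
  }
  if (pooled) {
    mu <- mean(c(a, b))
    v <- mean(c(a - mu, b - mu)^2)
    return(mean((a - mu) * (b - mu)) / v)
  }
  stats::cor(a, b)
}

#' Bootstrap a pair-list correlation
#'
#' Resamples *pairs* (not cells) with replacement and recomputes the
#' Pearson coefficient, giving the standard deviation and 2.5/97.5
#' percentile interval of the replicates. Degenerate replicates (a margin
#' with zero variance) are dropped and counted.
#'
#' @param pairs Tibble from [enumerate_pairs()].
#' @param n_boot Number of replicates (default 10000, minimum 100).
#' @param seed Optional integer seed (replicates are deterministic given
#'   it).
#' @param pooled Passed to [sample_correlation()].
#' @return One-row tibble: `rho_hat`, `n_pairs`, `boot_sd`, `ci_lo`,
#'   `ci_hi`, `n_degenerate`.
#' @export
bootstrap_correlation <- function(pairs, n_boot = 10000, seed = NULL,
                                  pooled = FALSE) {
  stopifnot(n_boot >= 100)
  if (!is.null(seed)) set.seed(seed)
  rho_hat <- sample_correlation(pairs, pooled = pooled)
  n <- nrow(pairs)
  a <- pairs$tau_a; b <- pairs$tau_b
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    ai <- a[idx]; bi <- b[idx]
    if (stats::var(ai) == 0 || stats::var(bi) == 0) return(NA_real_)
    if (pooled) {
      mu <- mean(c(ai, bi))
      mean((ai - mu) * (bi - mu)) / mean(c(ai - mu, bi - mu)^2)
    } else {
      stats::cor(ai, bi)
    }
  }, numeric(1))
  bad <- is.na(reps)
  reps <- reps[!bad]
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(rho_hat = rho_hat, n_pairs = n,
                 boot_sd = stats::sd(reps),
                 ci_lo = qs[1], ci_hi = qs[2],
                 n_degenerate = sum(bad))
}

training_relations <- function() {
  tibble::tibble(k = c(1L, 2L, 1L, 2L), l = c(0L, 0L, 1L, 2L))
}

#' Summary statistics of a lineage forest
#'
#' Computes the data a model fit consumes: the interdivision-time sample
#' variance with a bootstrap error, and Pearson correlations with bootstrap
#' errors for a set of family relations — by default the training set
#' mother-daughter `(1,0)`, grandmother `(2,0)`, sister `(1,1)` and cousin
#' `(2,2)`. The variance is computed over the cells that appear in at least
#' one enumerated pair, each distinct cell once (set `variance_cells =
#' "all"` to use every observed cell instead); its bootstrap error
#' resamples cells with replacement.
#'
#' @param forest Lineage tibble.
#' @param relations Tibble with integer columns `k`, `l` (default the four
#'   training relations).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Optional integer seed.
#' @param min_pairs Relations with fewer pairs than this are flagged
#'   (default 10): bootstrap intervals below it are not meaningful.
#' @param variance_cells `"paired"` (default) or `"all"`.
#' @param pooled Passed to [sample_correlation()].
#' @return An object of class `lineage_summary`: list with `tau_bar_hat`,
#'   `s_tau_hat`, `boot_sd_var`, `n_cells_var`, `correlations` (tibble with
#'   `k`, `l`, `relation`, `n_pairs`, `rho_hat`, `boot_sd`, `ci_lo`,
#'   `ci_hi`, `flagged`), `n_boot`.
#' @examples
#' m <- inheritance_model(20, matrix(0.5), matrix(1))
#' f <- simulate_lineage(m, n_trees = 50, depth = 5, seed = 1)
#' s <- lineage_summary(f, n_boot = 200, seed = 2)
#' tidy(s)
#' @export
lineage_summary <- function(forest, relations = training_relations(),
                            n_boot = 10000, seed = NULL, min_pairs = 10,
                            variance_cells = c("paired", "all"),
                            pooled = FALSE) {
  forest <- validate_forest(forest)
  variance_cells <- match.arg(variance_cells)
  relations <- tibble::as_tibble(relations)
  stopifnot(all(c("k", "l") %in% names(relations)))
  if (!is.null(seed)) set.seed(seed)

  pair_lists <- purrr::map(seq_len(nrow(relations)), function(i) {
    tryCatch(enumerate_pairs(forest, relations$k[i], relations$l[i]),
             warning = function(w) {
               warning(conditionMessage(w), call. = FALSE)
               suppressWarnings(enumerate_pairs(forest, relations$k[i],
                                                relations$l[i]))
             })
  })
  n_pairs <- vapply(pair_lists, nrow, integer(1))
  training <- training_relations()
  is_training <- paste(relations$k, relations$l) %in%
    paste(training$k, training$l)
  missing <- is_training & n_pairs < 2
  if (any(missing)) {
    stop("incomplete statistics: fewer than 2 pairs for relation(s) ",
         paste0("(", relations$k[missing], ",", relations$l[missing], ")",
                collapse = ", "),
         "; the trees are not deep enough.", call. = FALSE)
  }

  corr <- purrr::map2(pair_lists, seq_len(nrow(relations)), function(p, i) {
    if (nrow(p) < 2) {
      return(tibble::tibble(rho_hat = NA_real_, n_pairs = nrow(p),
                            boot_sd = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, n_degenerate = NA_integer_))
    }
    bootstrap_correlation(p, n_boot = n_boot, pooled = pooled)
  })
  corr <- dplyr::bind_rows(corr)
  correlations <- dplyr::bind_cols(
    relations,
    tibble::tibble(relation = relation_name(relations$k, relations$l)),
    corr
  )
  correlations$flagged <- correlations$n_pairs < min_pairs

  # variance population: distinct cells appearing in >= 1 pair
  if (variance_cells == "paired") {
    used <- unique(dplyr::bind_rows(purrr::map(pair_lists, function(p) {
      tibble::tibble(tree_id = rep(p$tree_id, 2),
                     cell_id = c(p$cell_a, p$cell_b))
    })))
    taus <- dplyr::inner_join(used, forest,
                              by = c("tree_id", "cell_id"))$interdivision_time
  } else {
    taus <- forest$interdivision_time[!is.na(forest$interdivision_time)]
  }
  if (length(taus) < 2 || stats::var(taus) == 0) {
    stop("degenerate forest: interdivision-time variance is zero or ",
         "undefined over the paired cells.", call. = FALSE)
  }
  var_reps <- vapply(seq_len(n_boot), function(i) {
    stats::var(taus[sample.int(length(taus), replace = TRUE)])
  }, numeric(1))

  structure(
    list(tau_bar_hat = mean(taus),
         s_tau_hat = stats::var(taus),
         boot_sd_var = stats::sd(var_reps),
         n_cells_var = length(taus),
         correlations = correlations,
         n_boot = n_boot),
    class = "lineage_summary"
  )
}

#' Assemble summary statistics from known values
#'
#' Builds a `lineage_summary` directly from numbers (e.g. published tables
#' or analytically computed model statistics with nominal errors) instead
#' of a forest, so it can be fed to [fit_inheritance()].
#'
#' @param s_tau_hat Interdivision-time variance (hours^2).
#' @param boot_sd_var Its standard error.
#' @param correlations Tibble with columns `k`, `l`, `rho_hat`, `boot_sd`
#'   (and optionally `n_pairs`).
#' @param tau_bar_hat Mean interdivision time (hours; optional, only used
#'   for period conversion downstream).
#' @return A `lineage_summary` object.
#' @export
manual_summary <- function(s_tau_hat, boot_sd_var, correlations,
                           tau_bar_hat = NA_real_) {
  correlations <- tibble::as_tibble(correlations)
  stopifnot(all(c("k", "l", "rho_hat", "boot_sd") %in% names(correlations)))
  if (!"n_pairs" %in% names(correlations)) {
    correlations$n_pairs <- NA_integer_
  }
  correlations$relation <- relation_name(correlations$k, correlations$l)
  if (!"ci_lo" %in% names(correlations)) {
    correlations$ci_lo <- correlations$rho_hat - 1.96 * correlations$boot_sd
    correlations$ci_hi <- correlations$rho_hat + 1.96 * correlations$boot_sd
  }
  correlations$flagged <- FALSE
  structure(
    list(tau_bar_hat = tau_bar_hat, s_tau_hat = s_tau_hat,
         boot_sd_var = boot_sd_var, n_cells_var = NA_integer_,
         correlations = correlations, n_boot = NA_integer_),
    class = "lineage_summary"
  )
}

#' @export
print.lineage_summary <- function(x, ...) {
  cat("<lineage_summary>\n")
  cat("  mean interdivision time:", formatC(x$tau_bar_hat, digits = 4),
      "h\n")
  cat("  variance:", formatC(x$s_tau_hat, digits = 4), "+/-",
      formatC(x$boot_sd_var, digits = 3), "h^2  (",
      x$n_cells_var, "cells )\n")
  print(x$correlations)
  invisible(x)
}

#' Tidy a lineage summary
#'
#' @param x A [lineage_summary()].
#' @param ... Unused.
#' @return The correlation tibble (one row per family relation).
#' @export
tidy.lineage_summary <- function(x, ...) x$correlations

#' One-row overview of a lineage summary
#'
#' @param x A [lineage_summary()].
#' @param ... Unused.
#' @return One-row tibble: `tau_bar_hat`, `s_tau_hat`, `boot_sd_var`,
#'   `n_cells_var`, `n_relations`, `cousin_mother` (whether the point
#'   estimates satisfy the cousin-mother inequality, `NA` if either
#'   relation is absent).
#' @export
glance.lineage_summary <- function(x, ...) {
  co <- x$correlations
  md <- co$rho_hat[co$k == 1 & co$l == 0]
  cc <- co$rho_hat[co$k == 2 & co$l == 2]
  tibble::tibble(
    tau_bar_hat = x$tau_bar_hat,
    s_tau_hat = x$s_tau_hat,
    boot_sd_var = x$boot_sd_var,
    n_cells_var = x$n_cells_var,
    n_relations = nrow(co),
    cousin_mother = if (length(md) == 1 && length(cc) == 1) cc > md else NA
  )
}
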