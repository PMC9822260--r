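#' Simulate binary lineage trees of interdivision times
#'
#' Generates a forest of full binary lineage trees from an
#' [inheritance_model()]. The root's hidden factor vector is drawn from the
#' stationary law (so no burn-in generations are needed) or fixed; for each
#' mother the two daughter noise vectors are drawn jointly with block
#' covariance `[[S1, S2], [S2', S1]]`, giving correlated sister noise, and
#' independently across mothers. Each cell's interdivision time is
#' `tau = tau_bar + alpha' x`.
#'
#' Cells are keyed by heap index within a tree: the root is 1 and the
#' daughters of cell `m` are `2m` and `2m + 1`, so the parent of `p > 1` is
#' `floor(p / 2)`. The linear model can produce negative interdivision
#' times in heavy noise; they are kept by default because truncation would
#' bias the second moments the model is defined by (set `tau_floor` to
#' clip, with a warning).
#'
#' @param model An [inheritance_model()].
#' @param n_trees Number of independent trees (default 1).
#' @param depth Generations per tree (`depth = 1` is a lone root; a tree
#'   has `2^depth - 1` cells).
#' @param root_init `"stationary"` (default) or a fixed numeric vector of
#'   length `N` used as every root's factor state.
#' @param record_factors If `TRUE`, include the hidden factor columns
#'   `x1..xN` in the output.
#' @param tau_floor Optional lower clip for interdivision times (default
#'   `NULL`, no clipping).
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the forest is reproducible.
#' @param noise_sampler Function `(n, d)` returning an `n x d` matrix of
#'   zero-mean unit-variance iid variates; defaults to Gaussian. Only the
#'   first two moments enter any quantity the model predicts.
#' @return A tibble with columns `tree_id`, `cell_id`, `parent_id` (`NA`
#'   for roots), `generation` (root = 0), `interdivision_time`, and
#'   optionally `x1..xN`.
#' @examples
#' m <- inheritance_model(20, matrix(c(0.5, -0.3, 0.3, 0.5), 2, 2), diag(2))
#' f <- simulate_lineage(m, n_trees = 10, depth = 4, seed = 1)
#' dplyr::count(f, generation)
#' @export
simulate_lineage <- function(model, n_trees = 1, depth,
                             root_init = "stationary",
                             record_factors = FALSE, tau_floor = NULL,
                             seed = NULL, noise_sampler = NULL) {
  stopifnot(inherits(model, "inheritance_model"))
  if (!is.numeric(depth) || depth < 1 || depth != round(depth)) {
    stop("`depth` must be an integer >= 1.", call. = FALSE)
  }
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop("`n_trees` must be >= 1.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sampler)) {
    noise_sampler <- function(n, d) matrix(stats::rnorm(n * d), n, d)
  }
  n <- model$n_factors
  n_cells <- 2^depth - 1

  sigma <- stationary_covariance(model)
  joint <- rbind(cbind(model$s1, model$s2), cbind(t(model$s2), model$s1))
  sqrt_sigma <- psd_sqrt(sigma)
  sqrt_joint <- psd_sqrt(joint)

  # factor states per heap index, each an n_trees x N matrix
  x <- vector("list", n_cells)
  if (identical(root_init, "stationary")) {
    x[[1]] <- noise_sampler(n_trees, n) %*% t(sqrt_sigma)
  } else {
    root_init <- as.numeric(root_init)
    if (length(root_init) != n) {
      stop("fixed `root_init` must have length ", n, call. = FALSE)
    }
    x[[1]] <- matrix(root_init, n_trees, n, byrow = TRUE)
  }
  if (depth > 1) {
    tth <- t(model$theta)
    for (m in seq_len(2^(depth - 1) - 1)) {
      z <- noise_sampler(n_trees, 2 * n) %*% t(sqrt_joint)
      inherited <- x[[m]] %*% tth
      x[[2 * m]] <- inherited + z[, seq_len(n), drop = FALSE]
      x[[2 * m + 1]] <- inherited + z[, n + seq_len(n), drop = FALSE]
    }
  }

  cell_id <- rep(seq_len(n_cells), each = n_trees)
  tree_id <- rep(seq_len(n_trees), times = n_cells)
  xmat <- do.call(rbind, x)
  tau <- model$tau_bar + drop(xmat %*% model$alpha)
  if (!is.null(tau_floor)) {
    n_clip <- sum(tau < tau_floor)
    if (n_clip > 0) {
      warning(n_clip, " interdivision times clipped at the floor ",
              tau_floor, "; second moments are no longer exact.")
      tau <- pmax(tau, tau_floor)
    }
  }
  out <- tibble::tibble(
    tree_id = tree_id,
    cell_id = cell_id,
    parent_id = ifelse(cell_id > 1, cell_id %/% 2, NA_integer_),
    generation = floor(log2(cell_id)),
    interdivision_time = tau
  )
  if (record_factors) {
    colnames(xmat) <- paste0("x", seq_len(n))
    out <- dplyr::bind_cols(out, tibble::as_tibble(xmat))
  }
  dplyr::arrange(out, .data$tree_id, .data$cell_id)
}

# symmetric PSD square root via eigendecomposition; tiny negative
# eigenvalues from roundoff are clipped to zero.
psd_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Randomly prune a lineage forest
#'
#' Emulates cells lost to tracking: each cell is independently retained
#' with probability `keep_prob`; removing a cell removes its whole subtree,
#' so every surviving non-root cell still has its full ancestor chain.
#' Trees whose root is removed are dropped with a warning.
#'
#' @param forest A lineage tibble as produced by [simulate_lineage()] or
#'   [read_lineage_table()].
#' @param keep_prob Per-cell retention probability in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return The pruned forest tibble.
#' @export
prune_forest <- function(forest, keep_prob, seed = NULL) {
  forest <- validate_forest(forest)
  stopifnot(is.numeric(keep_prob), keep_prob > 0, keep_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (keep_prob == 1) return(forest)
  keep <- stats::runif(nrow(forest)) < keep_prob
  # survival requires all ancestors kept; resolve via parent row pointers
  # in (tree, depth) order so parents are decided before children.
  parent_row <- match(paste(forest$tree_id, forest$parent_id),
                      paste(forest$tree_id, forest$cell_id))
  ord <- order(forest$tree_id, cell_depth(forest))
  surv <- logical(nrow(forest))
  for (i in ord) {
    pr <- parent_row[i]
    surv[i] <- keep[i] && (is.na(pr) || surv[pr])
  }
  dead_roots <- unique(forest$tree_id[is.na(parent_row) & !surv])
  if (length(dead_roots) > 0) {
    warning(length(dead_roots),
            " tree(s) lost their root and were dropped entirely.")
  }
  forest[surv, , drop = FALSE]
}

# generations above the root for every cell, following parent pointers.
cell_depth <- function(forest) {
  parent_row <- match(paste(forest$tree_id, forest$parent_id),
                      paste(forest$tree_id, forest$cell_id))
  depth <- rep(NA_integer_, nrow(forest))
  cur <- which(is.na(parent_row))
  depth[cur] <- 0L
  g <- 0L
  while (TRUE) {
    nxt <- which(!is.na(parent_row) & parent_row %in% cur)
    if (length(nxt) == 0) break
    depth[nxt] <- g + 1L
    cur <- nxt
    g <- g + 1L
  }
  if (anyNA(depth)) {
    stop("forest has rows unreachable from any root (orphans or cycles).",
         call. = FALSE)
  }
  depth
}
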