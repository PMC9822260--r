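#' Read a lineage table
#'
#' Reads the canonical interchange format for lineage-tree interdivision
#' times: comma-separated UTF-8 text with a mandatory header naming
#' `tree_id`, `cell_id`, `parent_id` (empty for roots) and
#' `interdivision_time` (decimal hours). A heap-indexed convenience layout
#' is also accepted: when `heap = TRUE` (or the `parent_id` column is
#' absent and `cell_id` is integer), the parent of cell `p > 1` is
#' inferred as `floor(p / 2)`.
#'
#' Validation failures are reported with offending rows: duplicate cell
#' ids within a tree, parents that do not resolve within the same tree
#' (orphans, listed with line numbers), and parent cycles (including
#' self-parenting).
#'
#' @param path File path.
#' @param heap Force heap-index parent inference (default auto).
#' @param time_unit Unit of the `interdivision_time` column: `"hours"`
#'   (default), `"minutes"` or `"days"`; values are converted to hours on
#'   read. No auto-detection is attempted.
#' @return A lineage forest tibble (`tree_id`, `cell_id`, `parent_id`,
#'   `generation`, `interdivision_time`).
#' @export
read_lineage_table <- function(path, heap = FALSE,
                               time_unit = c("hours", "minutes", "days")) {
  time_unit <- match.arg(time_unit)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  need <- c("tree_id", "cell_id", "interdivision_time")
  if (!all(need %in% names(raw))) {
    stop("lineage table must have a header naming tree_id, cell_id, ",
         "parent_id, interdivision_time; missing: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  no_parent_col <- !"parent_id" %in% names(raw)
  if (no_parent_col || heap) {
    p <- suppressWarnings(as.integer(raw$cell_id))
    if (anyNA(p)) {
      stop("heap-index import needs integer cell_id values.", call. = FALSE)
    }
    raw$parent_id <- ifelse(p > 1, as.character(p %/% 2L), "")
  }
  tau <- suppressWarnings(as.numeric(raw$interdivision_time))
  bad_tau <- which(is.na(tau) & trimws(raw$interdivision_time) != "")
  if (length(bad_tau) > 0) {
    stop("non-numeric interdivision_time at line(s) ",
         paste(bad_tau + 1L, collapse = ", "), call. = FALSE)
  }
  scale <- c(hours = 1, minutes = 1 / 60, days = 24)[[time_unit]]
  forest <- tibble::tibble(
    tree_id = raw$tree_id,
    cell_id = raw$cell_id,
    parent_id = dplyr::na_if(trimws(raw$parent_id), ""),
    interdivision_time = tau * scale
  )
  validate_forest(forest, full = TRUE)
}

#' Write a lineage table
#'
#' Writes the canonical comma-separated layout read by
#' [read_lineage_table()]; roots get an empty `parent_id`. A round-trip
#' write-then-read preserves all statistics.
#'
#' @param forest A lineage forest tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(forest, path) {
  forest <- validate_forest(forest)
  out <- data.frame(
    tree_id = forest$tree_id,
    cell_id = forest$cell_id,
    parent_id = ifelse(is.na(forest$parent_id), "",
                       as.character(forest$parent_id)),
    interdivision_time = forest$interdivision_time
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared forest validation. `full = TRUE` additionally proves every cell
# reachable from a root (catching cycles), which costs a pass per
# generation.
validate_forest <- function(forest, full = FALSE) {
  forest <- tibble::as_tibble(forest)
  need <- c("tree_id", "cell_id", "parent_id", "interdivision_time")
  if (!all(need %in% names(forest))) {
    stop("a lineage forest needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(forest$tree_id, forest$cell_id)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate cell id(s) within a tree: ",
         paste(utils::head(key[dup], 5), collapse = "; "), call. = FALSE)
  }
  has_parent <- !is.na(forest$parent_id)
  pkey <- paste(forest$tree_id, forest$parent_id)
  orphan <- has_parent & !(pkey %in% key)
  if (any(orphan)) {
    stop("orphaned row(s): parent does not resolve within the same tree ",
         "at line(s) ", paste(utils::head(which(orphan) + 1L, 10),
                              collapse = ", "), call. = FALSE)
  }
  self <- has_parent & forest$parent_id == forest$cell_id
  if (any(self)) {
    stop("cycle: cell is its own parent at line(s) ",
         paste(which(self) + 1L, collapse = ", "), call. = FALSE)
  }
  if (full) {
    depth <- tryCatch(cell_depth(forest), error = function(e) {
      stop("parent links contain a cycle or unreachable rows: ",
           conditionMessage(e), call. = FALSE)
    })
    forest$generation <- depth
  } else if (!"generation" %in% names(forest)) {
    forest$generation <- cell_depth(forest)
  }
  forest
}

#' Read or write an inheritance-model configuration
#'
#' Plain-text (YAML) serialisation of an [inheritance_model()]: scalar
#' `tau_bar`, row-wise matrices `theta`, `s1`, optional `s2`, and `alpha`.
#'
#' @param path File path.
#' @return `read_model_config()`: an [inheritance_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  to_mat <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric)) else
      as_square_matrix(as.numeric(x), "config matrix")
  }
  inheritance_model(
    tau_bar = as.numeric(cfg$tau_bar),
    theta = to_mat(cfg$theta),
    s1 = to_mat(cfg$s1),
    s2 = if (!is.null(cfg$s2)) to_mat(cfg$s2) else NULL,
    alpha = if (!is.null(cfg$alpha)) as.numeric(cfg$alpha) else NULL
  )
}

#' @rdname read_model_config
#' @param model An [inheritance_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "inheritance_model"))
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  yaml::write_yaml(list(
    tau_bar = model$tau_bar,
    theta = mat_rows(model$theta),
    s1 = mat_rows(model$s1),
    s2 = mat_rows(model$s2),
    alpha = as.numeric(model$alpha)
  ), path, precision = 15)
  invisible(path)
}

#' Write a summary-statistics table
#'
#' One row per statistic: a `mean` and a `variance` row, then one
#' `correlation` row per family relation with its pair count, bootstrap SD
#' and percentile interval. [read_summary_table()] reconstructs the
#' [lineage_summary()].
#'
#' @param summary A [lineage_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  stopifnot(inherits(summary, "lineage_summary"))
  co <- summary$correlations
  out <- rbind(
    data.frame(statistic = "mean", k = NA, l = NA, n_pairs = NA,
               estimate = summary$tau_bar_hat, boot_sd = NA,
               ci_lo = NA, ci_hi = NA),
    data.frame(statistic = "variance", k = NA, l = NA,
               n_pairs = summary$n_cells_var,
               estimate = summary$s_tau_hat, boot_sd = summary$boot_sd_var,
               ci_lo = NA, ci_hi = NA),
    data.frame(statistic = "correlation", k = co$k, l = co$l,
               n_pairs = co$n_pairs, estimate = co$rho_hat,
               boot_sd = co$boot_sd, ci_lo = co$ci_lo, ci_hi = co$ci_hi)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @return `read_summary_table()`: a [lineage_summary()].
#' @export
read_summary_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("statistic", "k", "l", "estimate", "boot_sd") %in%
                  names(d)))
  v <- d[d$statistic == "variance", ]
  mu <- d[d$statistic == "mean", ]
  co <- d[d$statistic == "correlation", ]
  if (nrow(v) != 1 || nrow(co) < 1) {
    stop("summary table needs one variance row and correlation rows.",
         call. = FALSE)
  }
  corr <- tibble::tibble(k = as.integer(co$k), l = as.integer(co$l),
                         rho_hat = co$estimate, boot_sd = co$boot_sd,
                         n_pairs = as.integer(co$n_pairs),
                         ci_lo = co$ci_lo, ci_hi = co$ci_hi)
  manual_summary(s_tau_hat = v$estimate, boot_sd_var = v$boot_sd,
                 correlations = corr,
                 tau_bar_hat = if (nrow(mu) == 1) mu$estimate else NA_real_)
}

#' Write a run manifest
#'
#' Plain key-value (YAML) record of a run: command, seed, settings,
#' package version. Re-running from a manifest reproduces deterministic
#' stages bit-identically and stochastic stages identically given the
#' recorded seed.
#'
#' @param path Output file path.
#' @param ... Named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$package_version <- as.character(utils::packageVersion("heritime"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(fields, path)
  invisible(path)
}
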