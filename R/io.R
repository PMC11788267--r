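# Plain-text round-tripping of the package's tabular artefacts. All outputs
# carry a commented metadata header (package version, config hash, seed)
# and serialise numerics at full double precision.

SURVIVAL_CSV_COLS <- c(cell_line = "cell_line", alpha_x = "alpha_x",
                       beta_x = "beta_x", dose_Gy = "dose",
                       letd_primary_keV_um = "letd_primary_reported",
                       sf = "sf", replicates = "replicates")

# render doubles with 17 significant digits so a write -> read round trip
# restores every field to the last unit in the last place
full_precision <- function(df) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  df
}

meta_header <- function(seed = NULL, extra = list()) {
  items <- c(list(package = paste0("dirtydose ",
                                   utils::packageVersion("dirtydose"))),
             if (!is.null(seed)) list(seed = seed), extra)
  paste0("# ", names(items), ": ", vapply(items, function(x)
    paste(format(x), collapse = " "), character(1)))
}

#' Write survival records as CSV
#'
#' Columns follow the interchange schema `cell_line, alpha_x, beta_x,
#' dose_Gy, letd_primary_keV_um, sf, replicates`; any attached metric
#' columns are appended unchanged. A commented metadata header records the
#' package version and seed.
#'
#' @param records survival-record tibble.
#' @param path output file.
#' @param seed seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(records, path, seed = NULL) {
  out <- records
  inv <- stats::setNames(names(SURVIVAL_CSV_COLS), SURVIVAL_CSV_COLS)
  names(out) <- ifelse(names(out) %in% names(inv), inv[names(out)], names(out))
  hash <- rlang::hash(out)
  writeLines(meta_header(seed, list(config_hash = hash)), path)
  readr::write_csv(full_precision(out), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read survival records from CSV
#'
#' Accepts the interchange schema of [write_survival_csv()]; commented
#' header lines are skipped. Schema violations are reported with the
#' offending column names.
#'
#' @param path CSV file.
#' @return Tibble with internal column names (`dose`,
#'   `letd_primary_reported`, ...).
#' @export
read_survival_csv <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("cell_line", "alpha_x", "beta_x", "dose_Gy", "sf", "replicates")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("survival CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  names(out) <- ifelse(names(out) %in% names(SURVIVAL_CSV_COLS),
                       SURVIVAL_CSV_COLS[names(out)], names(out))
  if (nrow(out) == 0) stop("no records in ", path, call. = FALSE)
  out
}

#' Write a (scored) depth profile as TSV
#'
#' Tab-separated per-voxel table: depth, dose, averaged metrics and one
#' dirty-dose-fraction column per threshold.
#'
#' @param profile a `ddk_profile` or `ddk_quality` tibble.
#' @inheritParams write_survival_csv
#' @export
write_profile_tsv <- function(profile, path, seed = NULL) {
  meta <- attr(profile, "meta") %||% list()
  writeLines(meta_header(seed, list(kind = meta$kind %||% "profile",
                                    config_hash = rlang::hash(profile))), path)
  readr::write_tsv(tibble::as_tibble(profile), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Write traversal records as CSV
#'
#' @param profile a `ddk_profile`.
#' @inheritParams write_survival_csv
#' @export
write_traversals_csv <- function(profile, path, seed = NULL) {
  tr <- traversals(profile)
  writeLines(meta_header(seed), path)
  readr::write_csv(full_precision(tr), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read traversal records from CSV
#'
#' @param path CSV with columns `voxel`, `e1`, `e2`, `weight`.
#' @return Traversal tibble.
#' @export
read_traversals_csv <- function(path) {
  tr <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  miss <- setdiff(c("voxel", "e1", "e2", "weight"), names(tr))
  if (length(miss)) {
    stop("traversal CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' Write a fit result as JSON
#'
#' @param fit a `ddk_fit`.
#' @inheritParams write_survival_csv
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  out <- list(
    package = paste0("dirtydose ", as.character(utils::packageVersion("dirtydose"))),
    model = fit$model_kind,
    parameters = as.list(tibble::deframe(tidy(fit)[, c("term", "estimate")])),
    active_bounds = fit$active_bounds,
    rmse_weighted = fit$rmse_weighted,
    rmse_unweighted = fit$rmse_unweighted,
    n_points = fit$n_points,
    ab_min = fit$ab_min,
    optimizer = list(method = fit$method, seed = fit$seed,
                     objective = fit$objective)
  )
  if (!is.null(seed)) out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
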