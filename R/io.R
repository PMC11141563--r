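#' Read a measurement table
#'
#' Reads the canonical CSM input CSV with columns `station, d, S, C` and
#' optional `label`, in consistent caller-defined units. Empty fields become
#' `NA`.
#'
#' @param path CSV path.
#' @return A data.frame sorted by station.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station", "d", "S", "C")
  if (!all(need %in% names(tab)))
    stop("measurement CSV must have columns station, d, S, C")
  for (col in need) tab[[col]] <- as.numeric(tab[[col]])
  tab[order(tab$station), , drop = FALSE]
}

#' Write a measurement table
#'
#' @param tab Data.frame with columns `station, d, S, C` (and optionally
#'   `label`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a run configuration
#'
#' Declarative YAML configuration for the estimation commands. Recognised
#' top-level fields: `slab_bounds` (numeric vector), `n_subslabs`, `modes`
#' (optional per-slab `"frustum"`/`"cone"`), `density` (block with `default`,
#' optional `per_slab` map and `voids` list), `gdi_slabs`, `k_range`
#' (length-2), `seed`.
#'
#' @param path YAML path.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$slab_bounds)) cfg$slab_bounds <- as.numeric(cfg$slab_bounds)
  if (!is.null(cfg$k_range)) {
    cfg$k_range <- as.numeric(cfg$k_range)
    stopifnot(length(cfg$k_range) == 2L, cfg$k_range[1] <= cfg$k_range[2])
  }
  if (!is.null(cfg$n_subslabs)) stopifnot(all(cfg$n_subslabs >= 1))
  if (!is.null(cfg$gdi_slabs)) stopifnot(cfg$gdi_slabs >= 1)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

# density_model from a config density block
config_density <- function(block) {
  if (is.null(block)) return(NULL)
  density_model(default = block$default,
                per_slab = block$per_slab,
                voids = if (is.null(block$voids)) list() else block$voids)
}

#' Write an estimation report
#'
#' Serialises an estimate (the list returned by [csm_estimate()]) to JSON, or
#' its per-slab table to CSV when `format = "csv"`.
#'
#' @param report A report list.
#' @param path Output path.
#' @param format `"json"` (default) or `"csv"` (per-slab table only).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    clean <- report
    clean$slab_table <- if (!is.null(report$slab_table)) report$slab_table
    jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    if (is.null(report$slab_table)) stop("report has no per-slab table")
    utils::write.csv(report$slab_table, path, row.names = FALSE)
  }
  invisible(path)
}
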