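#' Sample tables and suites
#'
#' A *sample table* holds replicate measurements of one experiment:
#' one row per (time, replicate) with the measured value.  Tables play
#' either the data role (few replicates, e.g. 7) or the model role
#' (many replicates, e.g. 100).  A *sample suite* is the named triple of
#' tables for the transition, basal-uptake and insulin-uptake protocols
#' produced by one batch of simulation runs.
#'
#' @param experiment experiment identifier (one of `"transition"`,
#'   `"basal_uptake"`, `"insulin_uptake"`).
#' @param time numeric measurement times.
#' @param replicate integer replicate indices.
#' @param value numeric measured values.
#' @param role `"data"` or `"model"`.
#' @param normalised logical; whether values have been normalised.
#' @return `sample_table()` returns a data frame of class `sample_table`
#'   with attributes `role` and `normalised`.
#' @export
sample_table <- function(experiment, time, replicate, value,
                         role = c("model", "data"), normalised = FALSE) {
  role <- match.arg(role)
  tbl <- data.frame(experiment = as.character(experiment),
                    time = as.numeric(time),
                    replicate = as.integer(replicate),
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  structure(tbl,
            role = role, normalised = normalised,
            class = c("sample_table", "data.frame"))
}

validate_sample_table <- function(tbl) {
  need <- c("experiment", "time", "replicate", "value")
  if (!all(need %in% names(tbl)))
    stop("sample table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tbl$value)))
    stop("sample table contains non-finite values", call. = FALSE)
  counts <- table(tbl$time)
  if (length(unique(counts)) > 1)
    stop("every (experiment, time) cell must have the same replicate count",
         call. = FALSE)
  invisible(tbl)
}

#' @rdname sample_table
#' @param tables named list of three `sample_table`s (one per protocol).
#' @param ... further metadata stored as attributes (e.g. `params`,
#'   `seed`, `divisors`, `noise`).
#' @export
sample_suite <- function(tables, normalised = FALSE, ...) {
  if (!setequal(names(tables), experiment_ids()))
    stop("a sample suite needs tables named ",
         paste(experiment_ids(), collapse = ", "), call. = FALSE)
  meta <- list(...)
  structure(tables[experiment_ids()],
            normalised = normalised,
            meta = meta,
            class = "sample_suite")
}

is_sample_suite <- function(x) inherits(x, "sample_suite")

suite_meta <- function(suite) attr(suite, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sample_suite <- function(x, ...) {
  meta <- suite_meta(x)
  cat("Sample suite (", if (isTRUE(attr(x, "normalised"))) "normalised"
      else "raw", ")\n", sep = "")
  for (nm in names(x)) {
    tbl <- x[[nm]]
    cat(sprintf("  %-15s %3d replicates x %2d times\n", nm,
                length(unique(tbl$replicate)), length(unique(tbl$time))))
  }
  if (!is.null(meta$seed)) cat("  seed:", meta$seed, "\n")
  invisible(x)
}

# full-precision decimal rendering so CSV round trips are exact
fmt_full <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, digits = 17, format = "g")
    if (as.numeric(s) != v) s <- sprintf("%.17e", v)
    s
  }, character(1))
}

#' Read and write sample tables as CSV
#'
#' Sample tables are stored as plain CSV with header
#' `experiment,time,replicate,value`, values rendered with enough decimal
#' digits that a write-then-read round trip reproduces every double
#' exactly.
#'
#' @param tbl a [sample_table()].
#' @param path file path.
#' @param role,normalised metadata for the table being read (CSV itself
#'   carries only the measurements; suite-level metadata lives in the
#'   sidecar JSON written by [write_sample_suite()]).
#' @return `read_sample_table()` returns a `sample_table`.
#' @export
write_sample_table <- function(tbl, path) {
  validate_sample_table(tbl)
  out <- data.frame(experiment = tbl$experiment,
                    time = fmt_full(tbl$time),
                    replicate = tbl$replicate,
                    value = fmt_full(tbl$value))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path, role = "model", normalised = FALSE) {
  if (!file.exists(path))
    stop("sample table file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(experiment = "character", time = "numeric",
                                 replicate = "integer", value = "numeric"))
  sample_table(raw$experiment, raw$time, raw$replicate, raw$value,
               role = role, normalised = normalised)
}

#' Read and write sample suites
#'
#' Writes `transition.csv`, `basal_uptake.csv` and `insulin_uptake.csv`
#' plus a `metadata.json` sidecar recording the role, normalisation
#' divisors, generating parameters, seed and noise specification, which
#' together suffice to regenerate the suite bit-identically.
#'
#' @param suite a [sample_suite()].
#' @param dir directory to write into (created if needed).
#' @return `read_sample_suite()` returns a `sample_suite`.
#' @export
write_sample_suite <- function(suite, dir) {
  stopifnot(is_sample_suite(suite))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(suite))
    write_sample_table(suite[[nm]], file.path(dir, paste0(nm, ".csv")))
  meta <- suite_meta(suite)
  meta$normalised <- isTRUE(attr(suite, "normalised"))
  meta$role <- attr(suite[[1]], "role")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_sample_suite
#' @export
read_sample_suite <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  normalised <- isTRUE(meta$normalised)
  role <- meta$role %||% "model"
  tables <- lapply(experiment_ids(), function(nm) {
    read_sample_table(file.path(dir, paste0(nm, ".csv")),
                      role = role, normalised = normalised)
  })
  names(tables) <- experiment_ids()
  keep <- setdiff(names(meta), c("normalised", "role"))
  do.call(sample_suite, c(list(tables = tables, normalised = normalised),
                          meta[keep]))
}
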