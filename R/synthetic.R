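#' Relative noise specification
#'
#' Measurement error is modelled as relative noise: a value v becomes
#' `v * (1 + eps)` with `eps` drawn from `Normal(0, level^2)` (so "5%
#' noise" means `level = 0.05`) or from `Uniform(-level, +level)`.  A draw
#' that would make the value negative (non-physical) is rejected and
#' redrawn.
#'
#' @param distribution `"none"`, `"gaussian"` or `"uniform"`.
#' @param level non-negative relative noise level (e.g. `0.05` for 5%).
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("gaussian", 0.05)
#' @export
noise_spec <- function(distribution = c("none", "gaussian", "uniform"),
                       level = 0) {
  distribution <- match.arg(distribution)
  stopifnot(is.numeric(level), length(level) == 1, is.finite(level),
            level >= 0)
  structure(list(distribution = distribution, level = level),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  if (x$distribution == "none" || x$level == 0)
    cat("Noise spec: none\n")
  else
    cat(sprintf("Noise spec: %s relative noise, level %.3g (%.3g%%)\n",
                x$distribution, x$level, 100 * x$level))
  invisible(x)
}

#' Add relative noise to a sample table
#'
#' Every value v is replaced by `v * (1 + eps)` with `eps` drawn per the
#' noise specification; draws yielding a negative value are rejected and
#' redrawn (values are measurements of a non-negative quantity).  With
#' `distribution = "none"` or `level = 0` the table is returned unchanged.
#'
#' @param tbl a [sample_table()] with non-negative values.
#' @param spec a [noise_spec()].
#' @param seed optional integer seed.
#' @param draw_fun optional function `k -> k draws of eps`, overriding the
#'   spec's distribution (used to make the rejection rule testable with a
#'   forced draw sequence).
#' @param max_attempts rejection-loop cap per value; exceeding it is an
#'   error (only reachable at enormous noise levels).
#' @return The noisy `sample_table` (same shape, same metadata).
#' @examples
#' tbl <- sample_table("transition", 0, 1, 0.1)
#' add_relative_noise(tbl, noise_spec("gaussian", 0), seed = 1)$value  # 0.1
#' @export
add_relative_noise <- function(tbl, spec, seed = NULL, draw_fun = NULL,
                               max_attempts = 1e6) {
  stopifnot(inherits(spec, "noise_spec"))
  validate_sample_table(tbl)
  if (any(tbl$value < 0))
    stop("relative noise requires non-negative input values", call. = FALSE)
  if (is.null(draw_fun) &&
      (spec$distribution == "none" || spec$level == 0))
    return(tbl)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(draw_fun)) {
    draw_fun <- switch(spec$distribution,
      gaussian = function(k) rnorm(k, 0, spec$level),
      uniform = function(k) runif(k, -spec$level, spec$level),
      none = function(k) numeric(k))
  }

  v <- tbl$value
  noisy <- v * (1 + draw_fun(length(v)))
  attempts <- 1
  bad <- which(noisy < 0)
  while (length(bad) > 0) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("relative-noise rejection loop exceeded ", max_attempts,
           " attempts; noise level is degenerate", call. = FALSE)
    noisy[bad] <- v[bad] * (1 + draw_fun(length(bad)))
    bad <- bad[noisy[bad] < 0]
  }

  out <- tbl
  out$value <- noisy
  out
}

#' Generate a synthetic dataset
#'
#' Creates the synthetic stand-in for the experimental measurements:
#' `n_reps` independent protocol-suite runs at known ("true") parameters,
#' normalised as the experimental data are, optionally with relative
#' noise applied to the normalised values.  The default of 7 replicates
#' per time point matches the sparsity of the immunofluorescence
#' experiments the protocols emulate.
#'
#' @param params the generating ("true") [network_params()].
#' @param n_reps replicates per (experiment, time) cell.
#' @param seed master seed.
#' @param noise a [noise_spec()]; the default adds no noise.
#' @param schedules measurement schedules.
#' @return An object of class `synthetic_dataset`: the normalised
#'   [sample_suite()] in `$suite` plus the generating `params`, `seed` and
#'   `noise`.
#' @examples
#' sd1 <- generate_synthetic_data(network_params(), n_reps = 2, seed = 7)
#' sd1$suite
#' @export
generate_synthetic_data <- function(params, n_reps = 7, seed,
                                    noise = noise_spec("none"),
                                    schedules = default_schedules()) {
  stopifnot(inherits(noise, "noise_spec"))
  raw <- run_protocol_suite(params, n_runs = n_reps,
                            seed = substream_seed(seed, "synthetic"),
                            schedules = schedules, role = "data")
  suite <- normalize_suite(raw)
  if (noise$distribution != "none" && noise$level > 0) {
    tables <- lapply(seq_along(suite), function(i) {
      add_relative_noise(suite[[i]], noise,
                         seed = substream_seed(seed, "noise", i))
    })
    names(tables) <- names(suite)
    meta <- suite_meta(suite)
    meta$noise <- unclass(noise)
    suite <- do.call(sample_suite,
                     c(list(tables = tables, normalised = TRUE), meta))
  }
  structure(list(suite = suite, params = params, seed = seed,
                 noise = noise, n_reps = n_reps),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d replicates per time point, seed %d\n",
              x$n_reps, x$seed))
  print(x$noise)
  print(x$suite)
  invisible(x)
}

as_suite <- function(x) {
  if (inherits(x, "synthetic_dataset")) x$suite
  else if (is_sample_suite(x)) x
  else stop("expected a sample_suite or synthetic_dataset", call. = FALSE)
}

#' Re-sampling and noise robustness study
#'
#' Quantifies how the hierarchical distance responds to re-sampling of
#' the sparse synthetic data and to added measurement noise.  For each of
#' `n_resamples` re-samples a fresh 7-replicate synthetic dataset is
#' generated at the true parameters; for each noise level, relative noise
#' is added to the *same* base dataset (so level 0 reproduces the base
#' exactly and the effects of re-sampling and noise separate); point and
#' combined distances are then computed against one fixed model table of
#' `n_model_runs` replicates at the true parameters.
#'
#' @param params the true [network_params()].
#' @param n_resamples number of synthetic-data re-samples (>= 2).
#' @param levels noise levels in percent; the default is the full
#'   catalogue \{0, 1, 2, 3, 4, 5, 7.5, 10, 12.5, 15, 17.5, 20\}.
#' @param metrics point metrics to evaluate.
#' @param seed master seed.
#' @param n_reps data replicates per re-sample.
#' @param n_model_runs model replicates in the fixed reference table.
#' @param distribution noise distribution, `"gaussian"` or `"uniform"`.
#' @param aggregation time-course aggregation for the combined distance.
#' @return An object of class `resampling_study`: `point` (one row per
#'   resample x level x metric x experiment x time), `combined` (one row
#'   per resample x level x metric), and `summary` tables of means and
#'   standard deviations over re-samples.
#' @export
resampling_study <- function(params, n_resamples = 1000,
                             levels = c(0, 1, 2, 3, 4, 5, 7.5, 10, 12.5,
                                        15, 17.5, 20),
                             metrics = c("ks", "w1"), seed,
                             n_reps = 7, n_model_runs = 100,
                             distribution = c("gaussian", "uniform"),
                             aggregation = "mean") {
  stopifnot(n_resamples >= 2)
  distribution <- match.arg(distribution)
  bad <- setdiff(metrics, point_metrics())
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)

  model <- normalize_suite(run_protocol_suite(
    params, n_runs = n_model_runs,
    seed = substream_seed(seed, "model"), role = "model"))

  point_rows <- vector("list", n_resamples * length(levels) * length(metrics))
  comb_rows <- vector("list", length(point_rows))
  k <- 0L
  for (r in seq_len(n_resamples)) {
    base <- generate_synthetic_data(params, n_reps = n_reps,
                                    seed = substream_seed(seed, "resample", r))
    for (li in seq_along(levels)) {
      lev <- levels[li]
      noisy <- if (lev == 0) base$suite else {
        spec <- noise_spec(distribution, lev / 100)
        tables <- lapply(seq_along(base$suite), function(i) {
          add_relative_noise(base$suite[[i]], spec,
                             seed = substream_seed(seed, "noise", r, li, i))
        })
        names(tables) <- names(base$suite)
        sample_suite(tables, normalised = TRUE)
      }
      for (met in metrics) {
        hd <- hierarchical_distance(noisy, model, metric = met,
                                    aggregation = aggregation)
        k <- k + 1L
        pt <- hd$point
        pt$resample <- r; pt$level <- lev; pt$metric <- met
        point_rows[[k]] <- pt
        comb_rows[[k]] <- data.frame(resample = r, level = lev,
                                     metric = met, distance = hd$combined,
                                     stringsAsFactors = FALSE)
      }
    }
  }

  point <- do.call(rbind, c(point_rows, list(make.row.names = FALSE)))
  point <- point[c("resample", "level", "metric", "experiment", "time",
                   "distance")]
  combined <- do.call(rbind, c(comb_rows, list(make.row.names = FALSE)))

  psum <- aggregate(distance ~ level + metric + experiment + time,
                    data = point,
                    FUN = function(x) c(mean = mean(x), sd = sd(x)))
  psum <- cbind(psum[setdiff(names(psum), "distance")],
                mean = psum$distance[, "mean"], sd = psum$distance[, "sd"])
  csum <- aggregate(distance ~ level + metric, data = combined,
                    FUN = function(x) c(mean = mean(x), sd = sd(x)))
  csum <- cbind(csum[setdiff(names(csum), "distance")],
                mean = csum$distance[, "mean"], sd = csum$distance[, "sd"])

  structure(list(point = point, combined = combined,
                 point_summary = psum, combined_summary = csum,
                 config = list(params = unclass(params), levels = levels,
                               metrics = metrics, seed = seed,
                               n_resamples = n_resamples, n_reps = n_reps,
                               n_model_runs = n_model_runs,
                               distribution = distribution,
                               aggregation = aggregation)),
            class = "resampling_study")
}

#' @export
print.resampling_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Re-sampling study: %d re-samples, %s noise at levels {%s}%%\n",
    cfg$n_resamples, cfg$distribution,
    paste(cfg$levels, collapse = ", ")))
  print(x$combined_summary, row.names = FALSE)
  invisible(x)
}

#' Write a re-sampling study to CSV
#'
#' Writes `<prefix>_point.csv` (`resample,level,metric,experiment,time,`
#' `distance`), `<prefix>_combined.csv`, the two summary CSVs and a
#' metadata JSON with the full configuration and seed.
#'
#' @param study a `resampling_study`.
#' @param prefix output path prefix.
#' @export
write_resampling_study <- function(study, prefix) {
  stopifnot(inherits(study, "resampling_study"))
  write.csv(study$point, paste0(prefix, "_point.csv"), row.names = FALSE)
  write.csv(study$combined, paste0(prefix, "_combined.csv"),
            row.names = FALSE)
  write.csv(study$point_summary, paste0(prefix, "_point_summary.csv"),
            row.names = FALSE)
  write.csv(study$combined_summary, paste0(prefix, "_combined_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(study$config, paste0(prefix, "_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}
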