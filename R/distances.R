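#' Two-sample ECDF point distances
#'
#' Distances between the ECDFs F and G of two samples, computed exactly
#' from the combined sample: the step functions change only at combined
#' sample values, so suprema are taken over those points and integrals are
#' exact piecewise-constant sums between consecutive distinct values (no
#' binning, no quadrature tolerance).  Samples may have different sizes.
#'
#' Two classes are provided.  *Discrete* distances use only the step
#' values: Kolmogorov-Smirnov `sup |F - G|` (in `[0, 1]`, attaining 1 only
#' for disjoint supports, and taking at most `n*m` distinct values for
#' sample sizes n and m); Kuiper `sup (F - G) + sup (G - F)`; the
#' two-sample Cramer-von Mises criterion
#' `nm/(n+m)^2 * sum over pooled points of (F - G)^2`; and the two-sample
#' Anderson-Darling criterion, the `(F - G)^2` sum weighted by
#' `1 / (H (1 - H))` with H the pooled ECDF (the final pooled point, where
#' H = 1, is excluded).  *Integrated* distances account for the spacing of
#' the sample values: the Wasserstein-1 (earthmover's) distance
#' `integral |F - G| dx`, the signed area `integral (F - G) dx`
#' (antisymmetric in its arguments), and the squared L2 area
#' `integral (F - G)^2 dx`.
#'
#' @param f,g numeric samples or [build_ecdf()] objects.
#' @param metric one of `"ks"`, `"w1"`, `"kuiper"`, `"cramer_von_mises"`,
#'   `"anderson_darling"`, `"signed_area"`, `"squared_area"`.
#' @return A single numeric distance.
#' @examples
#' ks_distance(c(1, 2), c(1, 3))            # 0.5
#' wasserstein1_distance(c(1, 2), c(1, 3))  # 0.5
#' point_distance(c(1, 2), c(1, 3), "squared_area")  # 0.25
#' @name point_distances
NULL

point_metrics <- function() {
  c("ks", "w1", "kuiper", "cramer_von_mises", "anderson_darling",
    "signed_area", "squared_area")
}

#' @rdname point_distances
#' @export
point_distance <- function(f, g, metric = "w1") {
  if (!is.character(metric) || length(metric) != 1 ||
      !(metric %in% point_metrics()))
    stop("unknown point metric '", paste(metric, collapse = ","),
         "'; valid metrics: ", paste(point_metrics(), collapse = ", "),
         call. = FALSE)
  st <- ecdf_steps(f, g)
  switch(metric,
    ks = max(abs(st$F - st$G)),
    kuiper = max(c(0, st$F - st$G)) + max(c(0, st$G - st$F)),
    cramer_von_mises = {
      (st$n * st$m) / (st$n + st$m)^2 * sum(st$mult * (st$F - st$G)^2)
    },
    anderson_darling = {
      H <- (st$n * st$F + st$m * st$G) / (st$n + st$m)
      keep <- H < 1
      if (!any(keep)) 0 else
        (st$n * st$m) / (st$n + st$m)^2 *
          sum(st$mult[keep] * (st$F[keep] - st$G[keep])^2 /
                (H[keep] * (1 - H[keep])))
    },
    w1 = step_integral(st, function(d) abs(d)),
    signed_area = step_integral(st, identity),
    squared_area = step_integral(st, function(d) d^2)
  )
}

# exact integral of h(F - G) between consecutive distinct combined values
step_integral <- function(st, h) {
  k <- length(st$z)
  if (k < 2) return(0)
  sum(h(st$F[-k] - st$G[-k]) * diff(st$z))
}

#' @rdname point_distances
#' @export
ks_distance <- function(f, g) point_distance(f, g, "ks")

#' @rdname point_distances
#' @export
wasserstein1_distance <- function(f, g) point_distance(f, g, "w1")

#' @rdname point_distances
#' @export
extended_point_distance <- function(f, g,
                                    metric = c("kuiper", "cramer_von_mises",
                                               "anderson_darling",
                                               "signed_area", "squared_area")) {
  metric <- match.arg(metric)
  point_distance(f, g, metric)
}

#' Aggregate point distances over a time course
#'
#' Combines the vector of per-time point distances d(t_j), j = 1..tau, of
#' one experiment into a single experiment distance, with non-negative
#' per-time weights w_j (default 1): the weighted mean
#' `(1/tau) * sum(w_j d_j)`, the L2 norm `sqrt(sum((w_j d_j)^2))`, or the
#' maximum / minimum of the weighted entries.
#'
#' @param d non-empty numeric vector of point distances.
#' @param method aggregation method.
#' @param weights optional non-negative weights, same length as `d`.
#' @return A single non-negative numeric distance.
#' @examples
#' experiment_distance(c(3, 4), "l2")      # 5
#' experiment_distance(c(0.1, 0.3, 0.5))   # 0.3
#' @export
experiment_distance <- function(d, method = c("mean", "l2", "max", "min"),
                                weights = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(d), length(d) >= 1)
  if (is.null(weights)) weights <- rep(1, length(d))
  if (length(weights) != length(d))
    stop("weights must have the same length as the distance vector",
         call. = FALSE)
  if (any(weights < 0))
    stop("negative time-point weights are not allowed", call. = FALSE)
  wd <- weights * d
  switch(method,
         mean = sum(wd) / length(d),
         l2 = sqrt(sum(wd^2)),
         max = max(wd),
         min = min(wd))
}

#' Combine experiment distances across protocols
#'
#' The combined distance is the weighted Euclidean (L2) combination
#' `Delta = sqrt(sum(W_i * D_i^2))` of the E per-experiment distances,
#' with non-negative experiment weights W_i (default 1).
#'
#' @param D numeric vector of experiment distances.
#' @param W optional non-negative weights, same length as `D`.
#' @return The combined distance `Delta` (non-negative scalar).
#' @examples
#' combined_distance(c(3, 4))            # 5
#' combined_distance(c(1, 1, 1), c(4, 0, 0))  # 2
#' @export
combined_distance <- function(D, W = NULL) {
  stopifnot(is.numeric(D), length(D) >= 1)
  if (is.null(W)) W <- rep(1, length(D))
  if (length(W) != length(D))
    stop("experiment weights must match the number of experiments",
         call. = FALSE)
  if (any(W < 0))
    stop("negative experiment weights are not allowed", call. = FALSE)
  sqrt(sum(W * D^2))
}

#' Hierarchical distance between data and model suites
#'
#' The three-level comparison: at every measurement time of every
#' experiment, a two-sample ECDF point distance between the data
#' replicates and the model replicates; per experiment, an aggregation of
#' the point-distance vector over the time course; across experiments,
#' the weighted L2 combination `Delta`.  The same point metric and
#' aggregation are applied to every experiment.
#'
#' @param data,model [sample_suite()]s sharing experiment names and
#'   measurement times.  A mismatch in the time grids is an error; no
#'   silent interpolation is performed.
#' @param metric point metric (see [point_distance()]).
#' @param aggregation time-course aggregation (see
#'   [experiment_distance()]).
#' @param time_weights optional named list of per-time weight vectors.
#' @param experiment_weights optional named vector of experiment weights.
#' @return An object of class `hier_distance`: the per-time `point`
#'   distance table, the named per-experiment distances `experiment`, the
#'   `combined` distance, and the full `config` echo.
#' @examples
#' suite <- normalize_suite(run_protocol_suite(network_params(),
#'                                             n_runs = 3, seed = 1))
#' hierarchical_distance(suite, suite)$combined  # identical tables: 0
#' @export
hierarchical_distance <- function(data, model, metric = "w1",
                                  aggregation = "mean",
                                  time_weights = NULL,
                                  experiment_weights = NULL) {
  stopifnot(is_sample_suite(data), is_sample_suite(model))
  if (!setequal(names(data), names(model)))
    stop("data and model suites must contain the same experiments",
         call. = FALSE)

  exps <- names(data)
  point_rows <- list()
  D <- setNames(numeric(length(exps)), exps)
  for (nm in exps) {
    dt <- data[[nm]]; mt <- model[[nm]]
    td <- sort(unique(dt$time)); tm <- sort(unique(mt$time))
    if (length(td) != length(tm) || any(td != tm))
      stop("time-grid mismatch for experiment '", nm, "': data times {",
           paste(td, collapse = ", "), "} vs model times {",
           paste(tm, collapse = ", "), "}", call. = FALSE)
    dvec <- vapply(td, function(t0) {
      point_distance(dt$value[dt$time == t0], mt$value[mt$time == t0],
                     metric)
    }, numeric(1))
    point_rows[[nm]] <- data.frame(experiment = nm, time = td,
                                   distance = dvec,
                                   stringsAsFactors = FALSE)
    D[[nm]] <- experiment_distance(dvec, aggregation,
                                   weights = time_weights[[nm]])
  }
  W <- if (is.null(experiment_weights)) setNames(rep(1, length(exps)), exps)
       else experiment_weights[exps]
  delta <- combined_distance(unname(D), unname(W))

  structure(
    list(point = do.call(rbind, c(point_rows, list(make.row.names = FALSE))),
         experiment = D,
         combined = delta,
         config = list(metric = metric, aggregation = aggregation,
                       time_weights = time_weights,
                       experiment_weights = as.list(W),
                       data_seed = suite_meta(data)$seed,
                       model_seed = suite_meta(model)$seed)),
    class = "hier_distance"
  )
}

#' @export
print.hier_distance <- function(x, ...) {
  cat(sprintf("Hierarchical distance (%s point metric, %s aggregation)\n",
              x$config$metric, x$config$aggregation))
  for (nm in names(x$experiment))
    cat(sprintf("  D[%s] = %.6g\n", nm, x$experiment[[nm]]))
  cat(sprintf("  combined Delta = %.6g\n", x$combined))
  invisible(x)
}

#' Write a hierarchical distance report as JSON
#'
#' The report carries the per-time point-distance vectors, the
#' per-experiment distances, the combined distance and the full
#' configuration, so a comparison can be audited or regenerated.
#'
#' @param hd a `hier_distance` object.
#' @param path output file path.
#' @export
write_distance_report <- function(hd, path) {
  stopifnot(inherits(hd, "hier_distance"))
  report <- list(
    combined = hd$combined,
    experiment = as.list(hd$experiment),
    point = split(hd$point[c("time", "distance")], hd$point$experiment),
    config = hd$config
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "columns")
  invisible(path)
}
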