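#' Build an evenly spaced parameter grid
#'
#' A Cartesian grid over a subset of the network parameters (by default
#' the four the landscape studies vary: the store, fusion and membrane
#' rates and the basal activation probability), each range divided into
#' `n_points` equally spaced values (21 by default).  All remaining
#' parameters are fixed at the values in `base_params`.  Every grid point
#' must be a valid parameter configuration; an invalid point (e.g.
#' `p_basal` above `p_insulin`) rejects the grid with the offending point
#' reported.
#'
#' @param varied named list of ranges, one entry per varied parameter:
#'   each a list/vector with elements `min`, `max` and optionally
#'   `n_points`.
#' @param base_params a [network_params()] supplying the fixed values.
#' @param n_points default number of grid points per parameter.
#' @return An object of class `parameter_grid`: the `points` data frame
#'   (one row per grid point), per-parameter `step` sizes, the varied
#'   names and the base parameters.
#' @examples
#' g <- build_grid(list(rate_fusion = list(min = 0.05, max = 0.15,
#'                                         n_points = 5)))
#' nrow(g$points)
#' @export
build_grid <- function(varied, base_params = network_params(),
                       n_points = 21) {
  validate_network_params(base_params)
  if (length(varied) == 0 || is.null(names(varied)) ||
      any(names(varied) == ""))
    stop("'varied' must be a named list of parameter ranges", call. = FALSE)
  unknown <- setdiff(names(varied), names(base_params))
  if (length(unknown))
    stop("unknown parameter(s) in grid: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  axes <- lapply(names(varied), function(nm) {
    rg <- as.list(varied[[nm]])
    np <- rg$n_points %||% n_points
    if (is.null(rg$min) || is.null(rg$max))
      stop("range for '", nm, "' needs 'min' and 'max'", call. = FALSE)
    if (np < 2 || np != round(np))
      stop("n_points for '", nm, "' must be an integer >= 2", call. = FALSE)
    if (rg$min >= rg$max)
      stop("range for '", nm, "' must have min < max", call. = FALSE)
    seq(rg$min, rg$max, length.out = np)
  })
  names(axes) <- names(varied)
  points <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)

  # every grid point must yield valid parameters
  for (i in seq_len(nrow(points))) {
    p <- modifyList(unclass(base_params), as.list(points[i, , drop = FALSE]))
    ok <- tryCatch({ validate_network_params(p); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("grid point ", i, " (",
           paste(sprintf("%s = %g", names(points), unlist(points[i, ])),
                 collapse = ", "),
           ") is invalid: ", conditionMessage(ok), call. = FALSE)
  }

  step <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  structure(list(points = points, step = step, varied = names(varied),
                 axes = axes, base_params = base_params),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("Parameter grid: %d points over {%s}\n", nrow(x$points),
              paste(x$varied, collapse = ", ")))
  for (nm in x$varied)
    cat(sprintf("  %-16s [%g, %g] in %d steps of %g\n", nm,
                min(x$axes[[nm]]), max(x$axes[[nm]]),
                length(x$axes[[nm]]) - 1, x$step[[nm]]))
  invisible(x)
}

#' Scaled parameter distance
#'
#' Euclidean distance between two parameter points in grid units: along
#' every varied dimension, adjacent grid points are one distance unit
#' apart, so `dist = sqrt(sum(((theta_k - theta*_k) / step_k)^2))`.
#'
#' @param theta,theta_true named numeric vectors (or `network_params`)
#'   holding at least the grid's varied parameters.
#' @param grid a [build_grid()] object supplying the step sizes.
#' @return Non-negative scalar distance in grid units.
#' @examples
#' g <- build_grid(list(rate_fusion = list(min = 1, max = 3, n_points = 3)))
#' parameter_distance(c(rate_fusion = 2), c(rate_fusion = 1), g)  # 1
#' @export
parameter_distance <- function(theta, theta_true, grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  theta <- unlist(theta)[grid$varied]
  theta_true <- unlist(theta_true)[grid$varied]
  if (any(is.na(theta)) || any(is.na(theta_true)))
    stop("both points must supply every varied parameter: ",
         paste(grid$varied, collapse = ", "), call. = FALSE)
  if (any(grid$step <= 0))
    stop("zero grid step: parameter distance undefined", call. = FALSE)
  sqrt(sum(((theta - theta_true) / grid$step)^2))
}

#' Map the distance landscape over a parameter grid
#'
#' For every grid point, simulates a fresh model table (`n_model_runs`
#' replicate protocol runs at that parameter configuration, independently
#' seeded per point), computes the full hierarchical distance to the
#' synthetic dataset, and records the per-experiment and combined
#' distances together with the scaled parameter distance to the dataset's
#' true parameters.  Simulator failures at individual points are recorded
#' in the `error` column rather than aborting the sweep.
#'
#' @param grid a [build_grid()] object.
#' @param data a [generate_synthetic_data()] result (or a normalised
#'   [sample_suite()]).
#' @param metric,aggregation distance configuration, fixed across the
#'   grid.
#' @param n_model_runs model replicates per grid point.
#' @param seed master seed; grid point i uses the sub-stream
#'   `substream_seed(seed, "grid", i)`.
#' @param true_params true parameters for the parameter-distance column;
#'   defaults to the dataset's generating parameters.
#' @return A data frame of class `landscape_table`: one row per grid
#'   point with the varied parameter values, `param_distance`,
#'   `D_transition`, `D_basal_uptake`, `D_insulin_uptake`, `combined` and
#'   `error`.
#' @export
evaluate_landscape <- function(grid, data, metric = "w1",
                               aggregation = "mean", n_model_runs = 100,
                               seed, true_params = NULL) {
  stopifnot(inherits(grid, "parameter_grid"))
  suite <- as_suite(data)
  if (!isTRUE(attr(suite, "normalised")))
    stop("the data suite must be normalised", call. = FALSE)
  if (is.null(true_params) && inherits(data, "synthetic_dataset"))
    true_params <- data$params

  pts <- grid$points
  n <- nrow(pts)
  res <- data.frame(pts,
                    param_distance = NA_real_,
                    D_transition = NA_real_, D_basal_uptake = NA_real_,
                    D_insulin_uptake = NA_real_, combined = NA_real_,
                    error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- do.call(network_params,
                 modifyList(unclass(grid$base_params),
                            as.list(pts[i, , drop = FALSE])))
    if (!is.null(true_params))
      res$param_distance[i] <- parameter_distance(p, true_params, grid)
    out <- tryCatch({
      model <- normalize_suite(run_protocol_suite(
        p, n_runs = n_model_runs,
        seed = substream_seed(seed, "grid", i), role = "model"))
      hierarchical_distance(suite, model, metric = metric,
                            aggregation = aggregation)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      res$error[i] <- conditionMessage(out)
    } else {
      res$D_transition[i] <- out$experiment[["transition"]]
      res$D_basal_uptake[i] <- out$experiment[["basal_uptake"]]
      res$D_insulin_uptake[i] <- out$experiment[["insulin_uptake"]]
      res$combined[i] <- out$combined
    }
  }
  structure(res,
            grid = grid,
            config = list(metric = metric, aggregation = aggregation,
                          n_model_runs = n_model_runs, seed = seed,
                          true_params = if (!is.null(true_params))
                            unclass(true_params)),
            class = c("landscape_table", "data.frame"))
}

landscape_grid <- function(landscape) {
  g <- attr(landscape, "grid")
  if (is.null(g)) stop("not a landscape table (no grid attribute)",
                       call. = FALSE)
  g
}

#' Single-parameter slices through a landscape
#'
#' For each varied parameter, extracts the grid rows where every *other*
#' varied parameter sits at its true value: the one-dimensional profiles
#' of the distance through the true point.
#'
#' @param landscape a [evaluate_landscape()] table.
#' @param true_point named vector/list of the true values of the varied
#'   parameters; must lie on the grid.
#' @return A named list of data frames, one per varied parameter, ordered
#'   by that parameter.
#' @export
single_parameter_slices <- function(landscape, true_point) {
  grid <- landscape_grid(landscape)
  tp <- unlist(true_point)[grid$varied]
  tol <- 1e-8
  for (nm in grid$varied) {
    if (is.na(tp[[nm]]) ||
        min(abs(grid$axes[[nm]] - tp[[nm]])) > tol * max(1, abs(tp[[nm]])))
      stop("true point is not on the grid along '", nm, "'", call. = FALSE)
  }
  slices <- lapply(grid$varied, function(nm) {
    others <- setdiff(grid$varied, nm)
    keep <- rep(TRUE, nrow(landscape))
    for (o in others)
      keep <- keep & abs(landscape[[o]] - tp[[o]]) <=
        tol * max(1, abs(tp[[o]]))
    sl <- landscape[keep, , drop = FALSE]
    sl[order(sl[[nm]]), , drop = FALSE]
  })
  names(slices) <- grid$varied
  slices
}

#' Locate the landscape minimum
#'
#' Returns every grid row attaining the minimal combined distance (ties
#' are reported, not broken).
#'
#' @param landscape a [evaluate_landscape()] table.
#' @return The subset of rows with minimal `combined`.
#' @export
locate_minimum <- function(landscape) {
  stopifnot(nrow(landscape) >= 1)
  cmb <- landscape$combined
  if (all(is.na(cmb)))
    stop("no grid point evaluated successfully", call. = FALSE)
  landscape[!is.na(cmb) & cmb == min(cmb, na.rm = TRUE), , drop = FALSE]
}

#' Write a landscape table to CSV
#'
#' One column per varied parameter followed by `param_distance`,
#' `D_transition`, `D_basal_uptake`, `D_insulin_uptake`, `combined`; a
#' sidecar JSON echoes the sweep configuration (ranges, fixed values,
#' seed, metric).
#'
#' @param landscape a [evaluate_landscape()] table.
#' @param path CSV output path; the sidecar is written to
#'   `<path>.json`.
#' @export
write_landscape_csv <- function(landscape, path) {
  grid <- landscape_grid(landscape)
  cols <- c(grid$varied, "param_distance", "D_transition",
            "D_basal_uptake", "D_insulin_uptake", "combined")
  write.csv(as.data.frame(landscape)[cols], path, row.names = FALSE)
  cfg <- attr(landscape, "config")
  cfg$ranges <- lapply(grid$axes, function(a)
    list(min = min(a), max = max(a), n_points = length(a)))
  cfg$base_params <- unclass(grid$base_params)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
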