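#' Run the three in-silico experiments in sequence
#'
#' Each replicate run reproduces the experimental protocol sequence within
#' a single simulation: all vesicles start at the endosome store in the
#' basal phase; the system equilibrates for `warmup` time units; the basal
#' uptake experiment then records the cumulative number of unique
#' plasma-membrane visitors at its measurement times (visited flags reset
#' to the current membrane occupants at onset); at the end of basal uptake
#' the fusion-site activity is switched to the insulin state and the
#' transition experiment records the plasma-membrane level at its times
#' (its t = 0 sample is the basal steady-state level, taken at the switch
#' instant); the system then equilibrates for `equilibration` units into
#' the insulin steady state before the insulin uptake experiment runs.
#'
#' @param params a [network_params()] object.
#' @param n_runs number of replicate runs (>= 1); each run contributes one
#'   replicate to each of the three tables.
#' @param seed master seed; run `r` uses the sub-stream
#'   `substream_seed(seed, "run", r)`, so extending `n_runs` never changes
#'   the earlier replicates.
#' @param schedules measurement schedules, by default
#'   [default_schedules()].
#' @param role `"model"` or `"data"`: how the resulting tables will be
#'   used in distance computations.
#' @param warmup,equilibration lengths of the basal warm-up and of the
#'   post-switch equilibration, in simulation time units.
#' @return A raw (unnormalised) [sample_suite()].
#' @examples
#' suite <- run_protocol_suite(network_params(), n_runs = 2, seed = 1)
#' suite
#' @export
run_protocol_suite <- function(params, n_runs, seed,
                               schedules = default_schedules(),
                               role = c("model", "data"),
                               warmup = 500, equilibration = 500) {
  validate_network_params(params)
  validate_schedules(schedules)
  role <- match.arg(role)
  stopifnot(is.numeric(n_runs), length(n_runs) == 1, n_runs >= 1,
            n_runs == round(n_runs))
  n_runs <- as.integer(n_runs)
  pv <- as_param_vector(params)

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(substream_seed(seed, "run", r))
    runs[[r]] <- .qnet_run_suite_cpp(pv,
                                     schedules$transition,
                                     schedules$basal_uptake,
                                     schedules$insulin_uptake,
                                     warmup, equilibration)
  }

  tables <- lapply(experiment_ids(), function(nm) {
    tt <- schedules[[nm]]
    sample_table(
      experiment = nm,
      time = rep(tt, times = n_runs),
      replicate = rep(seq_len(n_runs), each = length(tt)),
      value = unlist(lapply(runs, `[[`, nm)),
      role = role, normalised = FALSE
    )
  })
  names(tables) <- experiment_ids()

  sample_suite(tables, normalised = FALSE,
               params = unclass(params), seed = seed, n_runs = n_runs,
               schedules = unclass(schedules),
               warmup = warmup, equilibration = equilibration)
}

#' Normalise a protocol suite
#'
#' Both uptake tables are divided by the mean of the insulin-uptake values
#' at its final measurement time (the steady-state recycling level under
#' maximum insulin); the transition table is divided by the mean of its
#' own final-time values (its steady-state level, reached by the last
#' measurement).  Divisors pool all replicates of the suite being
#' normalised, so data and model suites are normalised independently.
#'
#' @param suite a raw [sample_suite()].
#' @return The normalised suite; the divisors used are recorded in the
#'   suite metadata.  By construction the normalised insulin-uptake and
#'   transition final-time means equal 1 exactly.
#' @export
normalize_suite <- function(suite) {
  stopifnot(is_sample_suite(suite))
  if (isTRUE(attr(suite, "normalised")))
    stop("suite is already normalised", call. = FALSE)

  final_mean <- function(tbl) {
    tmax <- max(tbl$time)
    mean(tbl$value[tbl$time == tmax])
  }
  div_uptake <- final_mean(suite$insulin_uptake)
  div_transition <- final_mean(suite$transition)
  if (!is.finite(div_uptake) || div_uptake <= 0 ||
      !is.finite(div_transition) || div_transition <= 0)
    stop("degenerate run: non-positive normaliser (insulin-uptake final ",
         "mean = ", div_uptake, ", transition final mean = ",
         div_transition, ")", call. = FALSE)

  divisors <- c(transition = div_transition,
                basal_uptake = div_uptake,
                insulin_uptake = div_uptake)
  tables <- lapply(experiment_ids(), function(nm) {
    tbl <- suite[[nm]]
    out <- sample_table(tbl$experiment, tbl$time, tbl$replicate,
                        tbl$value / divisors[[nm]],
                        role = attr(tbl, "role"), normalised = TRUE)
    out
  })
  names(tables) <- experiment_ids()

  meta <- suite_meta(suite)
  meta$divisors <- as.list(divisors)
  do.call(sample_suite,
          c(list(tables = tables, normalised = TRUE), meta))
}
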