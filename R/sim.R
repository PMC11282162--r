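#' Advance the queuing network in a fixed insulin phase
#'
#' Initialises the network with all vesicles at the endosome store, draws
#' the fusion-site activity, and processes events in time order until
#' `t_end`.  Intended for inspecting the simulator itself: occupancy time
#' fractions (for renewal-reward checks), conservation, event logs and
#' plasma-membrane traces.  The full experimental protocols are run by
#' [run_protocol_suite()].
#'
#' @param params a [network_params()] object.
#' @param phase `"basal"` or `"insulin"`: which activity vector gates the
#'   fusion sites.
#' @param t_end simulation horizon (>= 0).
#' @param sample_times optional times at which to record the
#'   plasma-membrane level and the cumulative unique-visitor count
#'   (visited flags start empty: the membrane is unoccupied at t = 0).
#' @param seed integer seed; the same seed and configuration yield a
#'   bit-identical event sequence.
#' @param log_events if `TRUE`, return the full event log (one row per
#'   event; use only for short horizons).
#' @return An object of class `qnet_state`: final simulation `time`,
#'   station occupancy `counts`, traces `pm_levels` and `unique_visitors`
#'   at `sample_times`, time-averaged `occupancy_fractions`, the number of
#'   processed events, the drawn site activities, and (optionally) the
#'   `event_log` data frame.
#' @examples
#' st <- advance_network(network_params(), "insulin", t_end = 50, seed = 1)
#' measure_pm_level(st)
#' @export
advance_network <- function(params, phase = c("basal", "insulin"),
                            t_end, sample_times = numeric(0),
                            seed = 1L, log_events = FALSE) {
  validate_network_params(params)
  phase <- match.arg(phase)
  stopifnot(is.numeric(t_end), length(t_end) == 1, t_end >= 0)
  sample_times <- as.numeric(sample_times)
  if (any(sample_times < 0 | sample_times > t_end))
    stop("sample_times must lie within [0, t_end]", call. = FALSE)
  set.seed(seed)
  out <- .qnet_advance_cpp(as_param_vector(params), phase == "insulin",
                           t_end, sample_times, log_events)
  out$event_log <- decode_event_log(out$event_log)
  out$params <- params
  out$phase <- phase
  out$seed <- seed
  structure(out, class = "qnet_state")
}

event_labels <- c("endosome_departure", "endosome_blocked",
                  "microtubule_departure", "microtubule_head_blocked",
                  "fusion_completion", "membrane_departure", "phase_switch")
station_labels <- c("endosome", "microtubule", "fusion", "membrane")

decode_event_log <- function(log) {
  data.frame(
    time = log$time,
    event_type = event_labels[log$code + 1L],
    vesicle_id = log$vesicle,
    station = ifelse(log$station >= 0, station_labels[log$station + 1L], NA),
    queue_index = ifelse(log$queue_index >= 0, log$queue_index, NA),
    stringsAsFactors = FALSE
  )
}

#' @export
print.qnet_state <- function(x, ...) {
  cat(sprintf("Queuing-network state at t = %g (%s phase, %s events)\n",
              x$time, x$phase, format(x$n_events, big.mark = ",")))
  print(x$counts)
  invisible(x)
}

#' Plasma-membrane occupancy of a simulated state
#'
#' The in-silico analogue of the surface GLUT4 level: the queue length of
#' the plasma-membrane station, in vesicle units.
#'
#' @param state a `qnet_state` from [advance_network()].
#' @return Integer in `[0, N]`.
#' @export
measure_pm_level <- function(state) {
  stopifnot(inherits(state, "qnet_state"))
  as.integer(state$counts[["membrane"]])
}

#' Cumulative unique plasma-membrane visitors
#'
#' The in-silico analogue of the uptake readout: the number of distinct
#' vesicles whose visited flag is set.  Non-decreasing along any
#' trajectory and bounded by `N`.
#'
#' @param state a `qnet_state` from [advance_network()].
#' @return Integer in `[0, N]`.
#' @export
measure_unique_visitors <- function(state) {
  stopifnot(inherits(state, "qnet_state"))
  as.integer(state$n_visited)
}

#' Export an event log as CSV
#'
#' Columns `time,event_type,vesicle_id,station,queue_index`; one row per
#' processed event.
#'
#' @param state a `qnet_state` produced with `log_events = TRUE`.
#' @param path file path.
#' @export
write_event_log <- function(state, path) {
  stopifnot(inherits(state, "qnet_state"))
  if (nrow(state$event_log) == 0)
    warning("event log is empty; was the state created with log_events = TRUE?")
  write.csv(state$event_log, path, row.names = FALSE)
  invisible(path)
}
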