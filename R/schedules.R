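#' Default experiment schedules
#'
#' The three in-silico protocols measure at the same times as the
#' corresponding immunofluorescence experiments: the transition experiment
#' at \{0, 0.5, 1, 2, 5, 10, 15, 20, 25, 30, 45, 60\} and both uptake
#' experiments at \{0, 2, 5, 10, 20, 30, 60, 90, 120, 180, 240, 300\}
#' simulation time units (the experimental minute values reused verbatim).
#'
#' @return A named list of class `schedule_set` with numeric measurement
#'   time vectors `transition`, `basal_uptake` and `insulin_uptake`.
#' @examples
#' sch <- default_schedules()
#' lengths(sch)
#' @export
default_schedules <- function() {
  validate_schedules(structure(
    list(
      transition = c(0, 0.5, 1, 2, 5, 10, 15, 20, 25, 30, 45, 60),
      basal_uptake = c(0, 2, 5, 10, 20, 30, 60, 90, 120, 180, 240, 300),
      insulin_uptake = c(0, 2, 5, 10, 20, 30, 60, 90, 120, 180, 240, 300)
    ),
    class = "schedule_set"
  ))
}

experiment_ids <- function() c("transition", "basal_uptake", "insulin_uptake")

validate_schedules <- function(sch) {
  if (!setequal(names(sch), experiment_ids()))
    stop("schedules must be named ", paste(experiment_ids(), collapse = ", "),
         call. = FALSE)
  for (nm in names(sch)) {
    tt <- sch[[nm]]
    if (!is.numeric(tt) || length(tt) < 1)
      stop("schedule '", nm, "' must be a non-empty numeric vector",
           call. = FALSE)
    if (tt[1] != 0)
      stop("schedule '", nm, "' must start at time 0", call. = FALSE)
    if (any(diff(tt) <= 0))
      stop("schedule '", nm, "' must be strictly increasing", call. = FALSE)
  }
  sch
}
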