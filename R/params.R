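#' Closed queuing-network parameters
#'
#' The nine parameters of the GLUT4 recycling network: the vesicle
#' population `N`, the microtubule count `M` and per-microtubule capacity
#' `L`, the four exponential service rates (endosome store, microtubule
#' transit, fusion, plasma membrane), and the basal and insulin fusion-site
#' activation probabilities.
#'
#' The defaults are the package's reference synthetic-truth parameter set:
#' a stand-in configuration chosen for qualitative correspondence with
#' immunofluorescence GLUT4 translocation data (basal uptake plateauing
#' well below the insulin uptake level, insulin uptake saturating near the
#' whole recycling pool, and a several-fold rise in surface GLUT4 on
#' insulin application).  Rates are in events per simulation time unit;
#' the protocol schedules reuse the experimental minute values verbatim as
#' time units.
#'
#' @param n_vesicles number of vesicles `N` cycling in the closed network.
#' @param n_microtubules number of parallel microtubule queues `M`, each
#'   feeding its own fusion site.
#' @param microtubule_capacity vesicles a microtubule can hold, `L`.
#' @param rate_store endosome service rate (per time unit).
#' @param rate_microtubule unimpeded microtubule transit rate; advancement
#'   increments behind a departing vesicle are exponential with rate
#'   `microtubule_capacity * rate_microtubule`.
#' @param rate_fusion fusion-site service rate.
#' @param rate_membrane plasma-membrane service (return) rate.
#' @param p_basal probability a fusion site is active without insulin.
#' @param p_insulin probability a fusion site is active under insulin;
#'   must be at least `p_basal` (insulin activates sites, never
#'   deactivates them).
#' @return An object of class `network_params` (a validated named list).
#' @examples
#' p <- network_params()
#' p
#' network_params(rate_fusion = 0.2, p_basal = 0.1)
#' @export
network_params <- function(n_vesicles = 100,
                           n_microtubules = 10,
                           microtubule_capacity = 5,
                           rate_store = 0.2,
                           rate_microtubule = 1,
                           rate_fusion = 0.1,
                           rate_membrane = 0.05,
                           p_basal = 0.2,
                           p_insulin = 0.9) {
  p <- list(
    n_vesicles = n_vesicles,
    n_microtubules = n_microtubules,
    microtubule_capacity = microtubule_capacity,
    rate_store = rate_store,
    rate_microtubule = rate_microtubule,
    rate_fusion = rate_fusion,
    rate_membrane = rate_membrane,
    p_basal = p_basal,
    p_insulin = p_insulin
  )
  validate_network_params(p)
  structure(p, class = "network_params")
}

validate_network_params <- function(p) {
  counts <- c("n_vesicles", "n_microtubules", "microtubule_capacity")
  rates <- c("rate_store", "rate_microtubule", "rate_fusion", "rate_membrane")
  for (nm in c(counts, rates, "p_basal", "p_insulin")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in counts) {
    if (p[[nm]] < 1 || p[[nm]] != round(p[[nm]]))
      stop("parameter '", nm, "' must be an integer >= 1 (got ", p[[nm]], ")",
           call. = FALSE)
  }
  for (nm in rates) {
    if (p[[nm]] <= 0)
      stop("rate '", nm, "' must be strictly positive (got ", p[[nm]], ")",
           call. = FALSE)
  }
  if (p$p_basal < 0 || p$p_basal > 1 || p$p_insulin < 0 || p$p_insulin > 1)
    stop("activation probabilities must lie in [0, 1]", call. = FALSE)
  if (p$p_basal > p$p_insulin)
    stop("p_basal (", p$p_basal, ") must not exceed p_insulin (",
         p$p_insulin, "): insulin activates fusion sites", call. = FALSE)
  invisible(p)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Closed queuing-network parameters\n")
  cat(sprintf("  vesicles N = %d, microtubules M = %d (capacity L = %d)\n",
              x$n_vesicles, x$n_microtubules, x$microtubule_capacity))
  cat(sprintf("  rates: store %.4g, microtubule %.4g, fusion %.4g, membrane %.4g\n",
              x$rate_store, x$rate_microtubule, x$rate_fusion, x$rate_membrane))
  cat(sprintf("  fusion-site activity: p_basal = %.3g, p_insulin = %.3g\n",
              x$p_basal, x$p_insulin))
  invisible(x)
}

# flat named numeric vector handed to the C++ core
as_param_vector <- function(p) {
  validate_network_params(p)
  keys <- names(formals(network_params))
  setNames(vapply(keys, function(k) as.numeric(p[[k]]), numeric(1)), keys)
}

#' Read network parameters from a JSON configuration file
#'
#' The configuration is a flat JSON object with the nine parameter keys of
#' [network_params()] (an optional `seed` key is returned as an attribute).
#'
#' @param path path to a JSON file.
#' @return A `network_params` object; the file's `seed`, if present, is
#'   attached as attribute `"seed"`.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path))
    stop("parameter file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- names(formals(network_params))
  unknown <- setdiff(names(cfg), c(keys, "seed"))
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- do.call(network_params, cfg[intersect(names(cfg), keys)])
  if (!is.null(cfg$seed)) attr(p, "seed") <- as.integer(cfg$seed)
  p
}

#' Draw the insulin-gated fusion-site activity
#'
#' Each of the `M` fusion sites is predetermined to be active or inactive
#' in each insulin state.  One persistent uniform is drawn per site and
#' both activity vectors derive from it (`active iff uniform < p`), so
#' switching from the basal to the insulin state can only activate sites,
#' never deactivate them.
#'
#' @param params a [network_params()] object.
#' @param seed optional integer seed for the draw.
#' @return A list of class `fusion_activity` with components
#'   `site_uniforms`, `basal_active` and `insulin_active`.
#' @examples
#' a <- draw_fusion_activity(network_params(), seed = 1)
#' all(a$insulin_active | !a$basal_active)  # basal-active implies insulin-active
#' @export
draw_fusion_activity <- function(params, seed = NULL) {
  validate_network_params(params)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(params$n_microtubules)
  structure(
    list(site_uniforms = u,
         basal_active = u < params$p_basal,
         insulin_active = u < params$p_insulin),
    class = "fusion_activity"
  )
}
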