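# Shared fixtures and independent oracles for the test suite.

# small, fast network for property-style simulator tests
small_params <- function(...) {
  base <- list(n_vesicles = 30, n_microtubules = 5,
               microtubule_capacity = 3,
               rate_store = 1, rate_microtubule = 2,
               rate_fusion = 1, rate_membrane = 0.5,
               p_basal = 0.4, p_insulin = 0.8)
  do.call(network_params, utils::modifyList(base, list(...)))
}

# the reference synthetic-truth configuration (package defaults)
truth_params <- function() network_params()

# independent KS oracle: exhaustive evaluation of both stats::ecdf
# functions at every combined sample point
oracle_ks <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
}

# independent integral oracle: fine-grid Riemann sum of h(F - G) with the
# grid refined between consecutive combined sample points
oracle_area <- function(x, y, h = abs, refine = 16) {
  z <- sort(unique(c(x, y)))
  if (length(z) < 2) return(0)
  Fx <- stats::ecdf(x); Gy <- stats::ecdf(y)
  total <- 0
  for (i in seq_len(length(z) - 1)) {
    xs <- seq(z[i], z[i + 1], length.out = refine + 1)
    mids <- (xs[-1] + xs[-(refine + 1)]) / 2
    total <- total + sum(h(Fx(mids) - Gy(mids)) * diff(xs))
  }
  total
}

# random small sample with ties (rounded) or continuous values
random_sample <- function(n, tie_prone = FALSE) {
  x <- rnorm(n, sd = 2)
  if (tie_prone) round(x) else x
}

# per-replicate trajectories of a sample table as a list of value vectors
replicate_trajectories <- function(tbl) {
  lapply(split(tbl, tbl$replicate), function(d) d$value[order(d$time)])
}
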