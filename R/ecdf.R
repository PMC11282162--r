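#' Empirical cumulative distribution function of a sample
#'
#' The ECDF of a sample x_1, ..., x_n is the right-continuous step
#' function P(x) = (1/n) * #\{x_i <= x\}: zero below the smallest sample
#' point, one at and above the largest, with a jump of multiplicity/n at
#' each distinct value.  Evaluation is delegated to [stats::ecdf()]; the
#' sorted sample is retained because every two-sample distance in this
#' package is computed exactly from the combined sample points.
#'
#' @param values non-empty numeric sample (finite values).
#' @return An object of class `emp_cdf`: list with the sorted `values`,
#'   the sample size `n`, and the evaluator `fun`.
#' @examples
#' P <- build_ecdf(c(2, 2, 4))
#' P$fun(2)   # 2/3: jump of 2/3 at the tie
#' @export
build_ecdf <- function(values) {
  if (inherits(values, "emp_cdf")) return(values)
  values <- as.numeric(values)
  if (length(values) == 0)
    stop("cannot build an ECDF from an empty sample", call. = FALSE)
  if (any(!is.finite(values)))
    stop("ECDF sample must contain only finite values", call. = FALSE)
  s <- sort(values)
  structure(list(values = s, n = length(s), fun = stats::ecdf(s)),
            class = "emp_cdf")
}

#' @export
print.emp_cdf <- function(x, ...) {
  cat(sprintf("Empirical CDF of %d sample points on [%g, %g]\n",
              x$n, x$values[1], x$values[x$n]))
  invisible(x)
}

# Evaluate two ECDFs on the sorted distinct values of their combined
# sample -- the only points where either step function changes.
# Returns z, F(z), G(z) and the pooled multiplicities at z.
ecdf_steps <- function(f, g) {
  f <- build_ecdf(f); g <- build_ecdf(g)
  z <- sort(unique(c(f$values, g$values)))
  cf <- findInterval(z, f$values)       # counts <= z (values sorted)
  cg <- findInterval(z, g$values)
  list(z = z,
       F = cf / f$n,
       G = cg / g$n,
       mult = diff(c(0L, cf)) + diff(c(0L, cg)),
       n = f$n, m = g$n)
}
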