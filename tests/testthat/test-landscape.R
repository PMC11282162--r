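test_that("grids are evenly spaced Cartesian products with validation", {
  g1 <- build_grid(list(rate_fusion = list(min = 1, max = 3, n_points = 3)))
  expect_equal(g1$points$rate_fusion, c(1, 2, 3))
  expect_equal(g1$step[["rate_fusion"]], 1)

  g2 <- build_grid(list(rate_fusion = list(min = 0.1, max = 0.5, n_points = 5),
                        rate_membrane = list(min = 0.02, max = 0.1,
                                             n_points = 5)))
  expect_equal(nrow(g2$points), 25)

  g3 <- build_grid(list(rate_store = list(min = 0.1, max = 0.2)))
  expect_equal(nrow(g3$points), 21)  # default resolution

  expect_error(build_grid(list(rate_fusion = list(min = 3, max = 1))),
               "min < max")
  expect_error(build_grid(list(bogus = list(min = 0, max = 1))), "unknown")
  # a grid whose p_basal exceeds the fixed p_insulin anywhere is rejected
  expect_error(
    build_grid(list(p_basal = list(min = 0.5, max = 0.95, n_points = 4)),
               base_params = network_params(p_insulin = 0.9)),
    "invalid")
})

test_that("the scaled parameter distance counts grid steps", {
  g <- build_grid(list(rate_fusion = list(min = 1, max = 3, n_points = 3),
                       rate_membrane = list(min = 10, max = 30,
                                            n_points = 3)))
  truth <- c(rate_fusion = 2, rate_membrane = 20)
  expect_equal(parameter_distance(truth, truth, g), 0)
  expect_equal(parameter_distance(c(rate_fusion = 3, rate_membrane = 20),
                                  truth, g), 1)
  expect_equal(parameter_distance(c(rate_fusion = 3, rate_membrane = 30),
                                  truth, g), sqrt(2))
  expect_error(parameter_distance(c(rate_fusion = 1), truth, g),
               "every varied parameter")
})

test_that("landscape evaluation fills every grid row deterministically", {
  p <- small_params()
  data <- generate_synthetic_data(p, n_reps = 3, seed = 2)
  g <- build_grid(list(rate_fusion = list(min = 0.5, max = 1.5,
                                          n_points = 2)),
                  base_params = p)
  land <- evaluate_landscape(g, data, n_model_runs = 3, seed = 8)
  expect_equal(nrow(land), 2)
  expect_true(all(is.na(land$error)))
  expect_true(all(land$combined >= 0))
  expect_true(all(c("D_transition", "D_basal_uptake", "D_insulin_uptake")
                  %in% names(land)))

  again <- evaluate_landscape(g, data, n_model_runs = 3, seed = 8)
  expect_identical(land$combined, again$combined)

  # single-point grid at the truth: parameter distance 0
  g0 <- build_grid(list(rate_fusion = list(min = p$rate_fusion / 2,
                                           max = p$rate_fusion,
                                           n_points = 2)),
                   base_params = p)
  land0 <- evaluate_landscape(g0, data, n_model_runs = 2, seed = 9)
  expect_equal(land0$param_distance[2], 0)
})

test_that("slices hold the off-axis parameters at their true values", {
  p <- small_params()
  data <- generate_synthetic_data(p, n_reps = 2, seed = 3)
  g <- build_grid(list(rate_fusion = list(min = 0.5, max = 1.5,
                                          n_points = 3),
                       rate_membrane = list(min = 0.25, max = 0.75,
                                            n_points = 3)),
                  base_params = p)
  land <- evaluate_landscape(g, data, n_model_runs = 2, seed = 4)
  truth <- c(rate_fusion = 1, rate_membrane = 0.5)
  slices <- single_parameter_slices(land, truth)
  expect_named(slices, c("rate_fusion", "rate_membrane"))
  expect_equal(nrow(slices$rate_fusion), 3)
  expect_true(all(slices$rate_fusion$rate_membrane == 0.5))
  expect_true(!is.unsorted(slices$rate_fusion$rate_fusion))
  expect_error(single_parameter_slices(land, c(rate_fusion = 0.77,
                                               rate_membrane = 0.5)),
               "not on the grid")

  # a one-parameter grid slices to the whole table
  g1 <- build_grid(list(rate_fusion = list(min = 0.5, max = 1.5,
                                           n_points = 3)),
                   base_params = p)
  land1 <- evaluate_landscape(g1, data, n_model_runs = 2, seed = 5)
  expect_equal(nrow(single_parameter_slices(land1,
                                            c(rate_fusion = 1))[[1]]), 3)
})

test_that("locate_minimum reports ties and matches the column minimum", {
  df <- data.frame(rate_fusion = 1:4, param_distance = 0:3,
                   D_transition = 1, D_basal_uptake = 1,
                   D_insulin_uptake = 1,
                   combined = c(0.5, 0.2, 0.2, 0.9),
                   error = NA_character_)
  attr(df, "grid") <- structure(list(varied = "rate_fusion"),
                                class = "parameter_grid")
  class(df) <- c("landscape_table", "data.frame")
  mins <- locate_minimum(df)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$combined, c(0.2, 0.2))
  df$combined <- rep(0.3, 4)
  expect_equal(nrow(locate_minimum(df)), 4)
})

test_that("W1 slices descend smoothly to the truth while KS localises sharply", {
  p <- truth_params()
  g <- build_grid(list(rate_fusion = list(min = 0.5 * p$rate_fusion,
                                          max = 1.5 * p$rate_fusion,
                                          n_points = 9)),
                  base_params = p)
  data <- generate_synthetic_data(p, n_reps = 7, seed = 11)
  off <- NULL
  for (met in c("w1", "ks")) {
    land <- evaluate_landscape(g, data, metric = met, n_model_runs = 200,
                               seed = 12)
    off <- abs(land$rate_fusion - p$rate_fusion)
    # distance grows with the offset from the truth in aggregate
    expect_gt(cor(off, land$combined, method = "spearman"), 0)
    if (met == "ks") {
      # plateau-then-drop: the relative drop from the slice edges to the
      # truth exceeds the relative variation (coefficient of variation)
      # across the outer half of the slice
      truth_val <- land$combined[off < 1e-12]
      outer <- land$combined[off >= max(off) / 2 - 1e-12]
      edge <- mean(land$combined[off == max(off)])
      rel_drop <- (edge - truth_val) / edge
      rel_var <- sd(outer) / mean(outer)
      expect_gt(rel_drop, rel_var)
    }
  }
})

test_that("100 model replicates make the distance stable against redraws", {
  # redrawing the model table at the true parameters shifts the combined
  # W1 distance by less (sd over redraws) than the mean change induced by
  # one grid step along each swept parameter
  p <- truth_params()
  data <- generate_synthetic_data(p, n_reps = 7, seed = 21)
  delta_at <- function(pars, s) {
    m <- normalize_suite(run_protocol_suite(pars, 100, seed = s))
    hierarchical_distance(data$suite, m, "w1", "mean")$combined
  }
  redraws <- vapply(1:6, function(k)
    delta_at(p, substream_seed(50, "redraw", k)), numeric(1))
  spread <- sd(redraws)
  for (nm in c("rate_fusion", "rate_membrane")) {
    step <- p[[nm]] * 0.25
    gap <- mean(vapply(c(-1, 1), function(sgn) {
      q <- unclass(p)
      q[[nm]] <- q[[nm]] + sgn * step
      abs(delta_at(do.call(network_params, q),
                   substream_seed(50, "nbr", nm, sgn)) - mean(redraws))
    }, numeric(1)))
    expect_lt(spread, gap)
  }
})
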