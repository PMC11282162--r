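test_that("ECDF evaluation follows the step-function definition", {
  P <- build_ecdf(5)
  expect_equal(P$fun(4.9), 0)
  expect_equal(P$fun(5), 1)       # right continuity at the sample point
  expect_equal(build_ecdf(c(1, 2, 3))$fun(2), 2 / 3)
  Q <- build_ecdf(c(2, 2, 4))
  expect_equal(Q$fun(2), 2 / 3)   # jump of 2/3 at the tie
  expect_equal(Q$fun(1.99), 0)
  expect_error(build_ecdf(numeric(0)), "empty")
  expect_error(build_ecdf(c(1, NA)), "finite")
})

test_that("frozen two-sample examples evaluate exactly", {
  expect_equal(ks_distance(c(1, 2), c(1, 3)), 0.5)
  expect_equal(wasserstein1_distance(c(1, 2), c(1, 3)), 0.5)
  expect_equal(point_distance(c(1, 2), c(1, 3), "squared_area"), 0.25)
  expect_equal(ks_distance(c(0, 0, 0), c(10, 10, 10)), 1)  # disjoint supports
  expect_equal(wasserstein1_distance(c(2, 2), c(7, 7)), 5) # translated masses
  for (met in c("ks", "w1", "kuiper", "cramer_von_mises",
                "anderson_darling", "signed_area", "squared_area"))
    expect_equal(point_distance(c(1, 2, 2, 5), c(1, 2, 2, 5), met), 0)
  expect_error(point_distance(1:3, 1:3, "bogus"), "valid metrics")
})

test_that("distances agree with independent oracles on random samples", {
  set.seed(2024)
  for (i in 1:300) {
    x <- random_sample(sample(2:10, 1), tie_prone = i %% 3 == 0)
    y <- random_sample(sample(2:10, 1), tie_prone = i %% 2 == 0)
    expect_equal(ks_distance(x, y), oracle_ks(x, y), tolerance = 1e-12)
    expect_equal(wasserstein1_distance(x, y), oracle_area(x, y, abs),
                 tolerance = 1e-9)
    expect_equal(point_distance(x, y, "squared_area"),
                 oracle_area(x, y, function(d) d^2), tolerance = 1e-9)
    expect_equal(point_distance(x, y, "signed_area"),
                 oracle_area(x, y, identity), tolerance = 1e-9)
  }
})

test_that("metric axioms hold on random sample pairs", {
  set.seed(7)
  for (i in 1:100) {
    x <- random_sample(sample(2:8, 1), tie_prone = TRUE)
    y <- random_sample(sample(2:8, 1))
    z <- random_sample(sample(2:8, 1))
    for (met in c("ks", "w1", "kuiper", "cramer_von_mises",
                  "anderson_darling", "squared_area")) {
      dxy <- point_distance(x, y, met)
      expect_gte(dxy, 0)
      expect_equal(dxy, point_distance(y, x, met), tolerance = 1e-12)
    }
    # signed area is antisymmetric
    expect_equal(point_distance(x, y, "signed_area"),
                 -point_distance(y, x, "signed_area"), tolerance = 1e-12)
    # triangle inequality for the two headline metrics
    for (met in c("ks", "w1")) {
      expect_lte(point_distance(x, z, met),
                 point_distance(x, y, met) + point_distance(y, z, met)
                 + 1e-12)
    }
    # KS and Kuiper bounds
    expect_lte(point_distance(x, y, "ks"), 1)
    expect_lte(point_distance(x, y, "kuiper"), 2)
  }
})

test_that("scaling both samples scales W1 and leaves KS unchanged", {
  set.seed(31)
  for (i in 1:30) {
    x <- random_sample(6); y <- random_sample(9)
    cc <- runif(1, 0.1, 10)
    expect_equal(ks_distance(cc * x, cc * y), ks_distance(x, y),
                 tolerance = 1e-12)
    expect_equal(wasserstein1_distance(cc * x, cc * y),
                 cc * wasserstein1_distance(x, y), tolerance = 1e-9)
    # translation property for equal-size samples
    expect_equal(wasserstein1_distance(x, x + 0.7), 0.7, tolerance = 1e-9)
  }
})

test_that("the KS distance takes at most n*m distinct values", {
  # discrete metric: |i/n - j/m| over step counts, so for sample sizes n
  # and m at most n*m unique values can ever occur
  set.seed(5)
  for (n in 2:5) for (m in 2:5) {
    allowed <- unique(as.vector(abs(outer((0:n) / n, (0:m) / m, `-`))))
    seen <- replicate(150, {
      ks_distance(sample(1:4, n, replace = TRUE),
                  sample(1:4, m, replace = TRUE))
    })
    expect_true(all(vapply(seen, function(v)
      any(abs(v - allowed) < 1e-12), logical(1))))
    expect_lte(length(unique(round(seen, 12))), n * m)
  }
})

test_that("time-course aggregation implements the four combinations", {
  expect_equal(experiment_distance(c(0.1, 0.3, 0.5), "mean"), 0.3)
  expect_equal(experiment_distance(c(3, 4), "l2"), 5)
  expect_equal(experiment_distance(c(0.2, 0.4), "max"), 0.4)
  expect_equal(experiment_distance(c(0.2, 0.4), "min"), 0.2)
  # weighted mean keeps the 1/tau prefactor
  expect_equal(experiment_distance(c(1, 1), "mean", weights = c(2, 0)), 1)
  expect_error(experiment_distance(c(1, 2), weights = c(-1, 1)), "negative")
  expect_error(experiment_distance(c(1, 2), weights = 1), "length")
})

test_that("the combined distance is the weighted L2 combination", {
  expect_equal(combined_distance(c(3, 4)), 5)
  expect_equal(combined_distance(0.7), 0.7)
  expect_equal(combined_distance(c(1, 1, 1), c(4, 0, 0)), 2)
  expect_error(combined_distance(c(1, 2), c(1, -1)), "negative")
  expect_error(combined_distance(c(1, 2), 1), "match")
})

test_that("the hierarchical distance assembles all three levels", {
  p <- small_params()
  data <- normalize_suite(run_protocol_suite(p, n_runs = 3, seed = 1,
                                             role = "data"))
  model <- normalize_suite(run_protocol_suite(p, n_runs = 5, seed = 2))

  # identical tables: everything collapses to zero
  self <- hierarchical_distance(data, data)
  expect_true(all(self$point$distance == 0))
  expect_true(all(self$experiment == 0))
  expect_equal(self$combined, 0)

  hd <- hierarchical_distance(data, model, metric = "w1",
                              aggregation = "mean")
  expect_equal(nrow(hd$point), 36)
  expect_gte(hd$combined, 0)
  # combined equals the L2 combination of the experiment distances
  expect_equal(hd$combined, sqrt(sum(hd$experiment^2)), tolerance = 1e-12)
  # per-experiment values equal the mean of the point distances
  for (nm in names(hd$experiment)) {
    expect_equal(hd$experiment[[nm]],
                 mean(hd$point$distance[hd$point$experiment == nm]),
                 tolerance = 1e-12)
  }

  # one experiment, one shared time point: Delta is the point distance
  one <- function(vals, role) sample_suite(list(
    transition = sample_table("transition", rep(0, length(vals)),
                              seq_along(vals), vals, role = role),
    basal_uptake = sample_table("basal_uptake", rep(0, 2), 1:2, c(1, 1),
                                role = role),
    insulin_uptake = sample_table("insulin_uptake", rep(0, 2), 1:2, c(1, 1),
                                  role = role)
  ), normalised = TRUE)
  d1 <- one(c(0.2, 0.4, 0.9), "data"); m1 <- one(c(0.1, 0.5, 0.7), "model")
  hd1 <- hierarchical_distance(d1, m1, metric = "w1")
  expect_equal(hd1$experiment[["transition"]],
               wasserstein1_distance(c(0.2, 0.4, 0.9), c(0.1, 0.5, 0.7)))

  # mismatched time grids are a hard alignment error
  shifted <- model
  shifted$transition$time <- shifted$transition$time + 1
  expect_error(hierarchical_distance(data, shifted, "w1"),
               "time-grid mismatch")
})

test_that("distance reports serialise the full hierarchy", {
  p <- small_params()
  data <- normalize_suite(run_protocol_suite(p, n_runs = 2, seed = 3,
                                             role = "data"))
  model <- normalize_suite(run_protocol_suite(p, n_runs = 3, seed = 4))
  hd <- hierarchical_distance(data, model)
  path <- tempfile(fileext = ".json")
  write_distance_report(hd, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$combined, hd$combined, tolerance = 1e-12)
  expect_equal(rep$experiment$transition, hd$experiment[["transition"]],
               tolerance = 1e-12)
  expect_equal(rep$config$metric, "w1")
})
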