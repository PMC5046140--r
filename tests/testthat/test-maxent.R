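test_that("maxent with no features is the uniform distribution", {
  gf <- gibbs_fixture(seed = 1)
  m <- fit_maxent(gf$presence, gf$background, features = character(0))
  raw <- predict(m, gf$background, type = "raw")
  expect_equal(raw, rep(1 / nrow(gf$background), nrow(gf$background)))
  logi <- predict(m, gf$background, type = "logistic")
  expect_equal(logi, rep(0.5, nrow(gf$background)))
})

test_that("a known Gibbs coefficient is recovered from sampled presences", {
  gf <- gibbs_fixture(lambda = 2, seed = 42)
  m <- fit_maxent(gf$presence, gf$background, features = "linear", beta = 0)
  expect_lt(abs(unname(m$lambda["linear(x)"]) - 2), 0.2)
  expect_true(m$converged)
})

test_that("duplicating every background cell leaves coefficients unchanged", {
  gf <- gibbs_fixture(lambda = 1.5, n_background = 500, n_presence = 400,
                      seed = 3)
  m1 <- fit_maxent(gf$presence, gf$background)
  m2 <- fit_maxent(gf$presence, rbind(gf$background, gf$background))
  expect_equal(m1$lambda, m2$lambda, tolerance = 1e-5)
})

test_that("raw predictions are a probability distribution over background", {
  land <- small_landscape(seed = 4, n = 30, n_points = 80)
  pres <- as.data.frame(lapply(land$factors, extract_at_points,
                               points = land$points))
  set.seed(10)
  idx <- sample.int(900, 400)
  bg <- as.data.frame(lapply(land$factors, function(r) as.vector(r$values)[idx]))
  m <- suppressWarnings(fit_maxent(pres, bg))
  expect_equal(sum(predict(m, bg, type = "raw")), 1, tolerance = 1e-9)
  logi <- predict(m, bg, type = "logistic")
  expect_true(all(logi >= 0 & logi <= 1))
})

test_that("the regularized objective never increases across iterations", {
  gf <- gibbs_fixture(lambda = 3, n_background = 800, n_presence = 600, seed = 5)
  m <- fit_maxent(gf$presence, gf$background, beta = 0.5)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
})

test_that("constant variables are dropped with a warning", {
  gf <- gibbs_fixture(seed = 6, n_background = 200, n_presence = 100)
  gf$presence$flat <- 1; gf$background$flat <- 1
  expect_warning(m <- fit_maxent(gf$presence, gf$background), "constant")
  expect_identical(m$variables, "x")
})

test_that("AUC matches hand-worked examples and handles ties", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(auc_score(c(0.8, 0.3), c(0.5, 0.2)), 0.75)
  s <- c(0.4, 0.1, 0.7)
  expect_equal(auc_score(s, s), 0.5)
})

test_that("AUC equals the brute-force all-pairs count on random instances", {
  brute <- function(p, b) {
    mean(outer(p, b, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  set.seed(123)
  for (i in 1:25) {
    np <- sample(1:100, 1); nb <- sample(1:100, 1)
    # mix continuous scores and heavy ties
    p <- sample(c(stats::runif(np), stats::rbinom(np, 3, 0.4) / 3), np)
    b <- sample(c(stats::runif(nb), stats::rbinom(nb, 3, 0.6) / 3), nb)
    expect_equal(auc_score(p, b), brute(p, b), tolerance = 1e-12)
  }
})

test_that("permutation contributions sum to 100 and expose pure noise", {
  gf <- gibbs_fixture(lambda = 3, n_background = 600, n_presence = 500, seed = 7)
  set.seed(8)
  gf$presence$noise <- stats::runif(nrow(gf$presence))
  gf$background$noise <- stats::runif(nrow(gf$background))
  m <- fit_maxent(gf$presence, gf$background)
  ct <- percent_contribution(m, gf$presence, gf$background, seed = 2)
  expect_equal(sum(ct$contribution), 100, tolerance = 1e-9)
  expect_lt(ct$contribution[ct$variable == "noise"], 10)
})

test_that("exchangeable duplicate variables share the contribution", {
  gf <- gibbs_fixture(lambda = 2.5, n_background = 800, n_presence = 800, seed = 9)
  gf$presence$x2 <- gf$presence$x
  gf$background$x2 <- gf$background$x
  m <- fit_maxent(gf$presence, gf$background)
  ct <- percent_contribution(m, gf$presence, gf$background, n_perm = 20, seed = 3)
  expect_lt(abs(diff(ct$contribution)), 5)
})

test_that("response curves have the analytic shape of their features", {
  gf <- gibbs_fixture(lambda = 2, n_background = 400, n_presence = 300, seed = 10)
  set.seed(11)
  gf$presence$other <- stats::runif(nrow(gf$presence))
  gf$background$other <- stats::runif(nrow(gf$background))
  m <- fit_maxent(gf$presence, gf$background)

  # zero out one variable's coefficients -> flat curve in that variable
  m0 <- m
  m0$lambda[grepl("other", names(m0$lambda))] <- 0
  rc0 <- response_curve(m0, "other", n_grid = 41)
  expect_lt(diff(range(rc0$response)), 1e-12)

  # a pure negative-quadratic model is unimodal along its variable
  m2 <- fit_maxent(gf$presence, gf$background, features = c("linear", "quadratic"))
  m2$lambda[] <- c(4, -4, 0, 0)  # peak at scaled x = 0.5
  rc2 <- response_curve(m2, "x", n_grid = 101)
  peak <- which.max(rc2$response)
  expect_true(all(diff(rc2$response[seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(rc2$response[peak:101]) <= 1e-12))

  # endpoints evaluate the model at the training extremes
  df_min <- as.data.frame(as.list(m$bg_means)); df_min$x <- min(gf$background$x)
  rc <- response_curve(m, "x", n_grid = 21)
  expect_equal(rc$response[1], predict(m, df_min), tolerance = 1e-12)
})

test_that("optimal ranges bracket the high-response region", {
  flat <- structure(tibble::tibble(value = 0:10, response = rep(0.4, 11)),
                    class = c("response_curve", class(tibble::tibble())))
  expect_equal(unname(optimal_range(flat, 0.8)), c(0, 10))

  # a K-t shaped curve recovers its plateau as fraction -> 1
  p <- membership_params(a = 0, b = 4, c = 6, d = 10, K = 2)
  x <- seq(0, 10, length.out = 201)
  kt <- structure(tibble::tibble(value = x, response = kt_membership(x, p)),
                  class = c("response_curve", class(tibble::tibble())))
  r <- optimal_range(kt, 0.999)
  step <- diff(x)[1]
  expect_lt(abs(r[["low"]] - 4), 2 * step)
  expect_lt(abs(r[["high"]] - 6), 2 * step)

  # symmetric unimodal curve -> symmetric range about the mode
  bell <- structure(tibble::tibble(value = x,
                                   response = exp(-((x - 5) / 2)^2)),
                    class = c("response_curve", class(tibble::tibble())))
  r2 <- optimal_range(bell, 0.8)
  expect_lt(abs((r2[["low"]] + r2[["high"]]) / 2 - 5), step)

  # non-contiguous high regions warn
  bimodal <- structure(tibble::tibble(
    value = x, response = pmax(exp(-((x - 2) / 0.5)^2), exp(-((x - 8) / 0.5)^2))),
    class = c("response_curve", class(tibble::tibble())))
  expect_warning(optimal_range(bimodal, 0.8), "non-contiguous")
})

test_that("factor selection keeps the top contributors deterministically", {
  ct <- tibble::tibble(variable = c("A", "B", "C"),
                       contribution = c(50, 30, 20))
  expect_identical(select_factors(ct, k = 2), c("A", "B"))
  expect_identical(select_factors(ct, k = 3), c("A", "B", "C"))
  expect_identical(select_factors(ct, min_percent = 25), c("A", "B"))
  ties <- tibble::tibble(variable = c("z", "a"), contribution = c(10, 10))
  expect_identical(select_factors(ties, k = 1), "a")
})

test_that("models round-trip through their JSON serialization", {
  gf <- gibbs_fixture(lambda = 2, n_background = 300, n_presence = 200, seed = 12)
  m <- fit_maxent(gf$presence, gf$background)
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent(m, f)
  m2 <- read_maxent(f)
  expect_equal(predict(m2, gf$background), predict(m, gf$background),
               tolerance = 1e-12)
})

test_that("train/test evaluation separates suitable from background", {
  land <- small_landscape(seed = 13, n = 40, n_points = 150)
  pres <- as.data.frame(lapply(land$factors, extract_at_points,
                               points = land$points))
  set.seed(14)
  idx <- sample.int(1600, 600)
  bg <- as.data.frame(lapply(land$factors, function(r) as.vector(r$values)[idx]))
  ev <- suppressWarnings(maxent_evaluate(pres, bg, seed = 15))
  expect_gt(ev$auc_train, 0.5)
  expect_gt(ev$auc_test, 0.5)
})
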