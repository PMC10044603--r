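repaired <- repair_correlation(wheat_correlation_target())

test_that("Pearson matrix matches the explicit covariance formula", {
  # exact linear relation
  d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
  expect_equal(pearson_matrix(d)$r["x", "y"], 1, tolerance = 1e-12)
  # orthogonal +/-1 patterns
  d2 <- data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(pearson_matrix(d2)$r["a", "b"], 0, tolerance = 1e-12)
  # hand formula oracle on the 5-point set
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  rep5 <- pearson_matrix(data.frame(x = x, y = y))
  expect_equal(rep5$r["x", "y"], oracle, tolerance = 1e-12)
  # p-value consistent with cor.test
  ct <- cor.test(x, y)
  expect_equal(rep5$p["x", "y"], ct$p.value, tolerance = 1e-10)
})

test_that("correlation report structure: symmetry, stars, constant columns", {
  set.seed(2)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  d$c <- d$a * 2 + rnorm(30, 0, 0.1)  # strongly correlated pair
  rep <- pearson_matrix(d)
  expect_equal(rep$r, t(rep$r))
  expect_true(all(abs(rep$r) <= 1 + 1e-12))
  expect_identical(rep$stars["a", "c"], "**")
  expect_warning(repc <- pearson_matrix(cbind(d, k = 1)), "constant")
  expect_true(all(is.na(repc$r["k", ])))
  expect_error(pearson_matrix(d[1:2, ]), "at least 3")
})

test_that("OLS agrees with the normal-equations oracle and its identities", {
  set.seed(3)
  for (i in 1:10) {
    n <- 30
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1.5 + 2 * d$x1 - 0.7 * d$x3 + rnorm(n, 0, 0.4)
    eq <- ols_fit(d, "y", c("x1", "x2", "x3"))
    oracle <- ols_normal_equations(d$y, d[, c("x1", "x2", "x3")])
    expect_equal(eq$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(unname(eq$coefficients), unname(oracle$slopes),
                 tolerance = 1e-10)
    expect_equal(eq$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(eq$rsd, sqrt(oracle$sse / (n - 3 - 1)), tolerance = 1e-10)
    # mean-point identity: prediction at predictor means is the response mean
    at_means <- predict_ne(eq, colMeans(d[, c("x1", "x2", "x3")]))
    expect_equal(at_means, mean(d$y), tolerance = 1e-10)
  }
})

test_that("zero-noise structural panel returns the generating equation", {
  panel <- generate_wheat_panel(
    generator_config(n_samples = 40, seed = 17, noise_sd = 0),
    target = repaired)
  eq <- ols_fit(panel, "NE", c("AME", "NDF", "ADF"))
  expect_equal(unname(eq$coefficients), c(0.380, -0.147, -0.274),
               tolerance = 1e-10)
  expect_equal(eq$intercept, 5.262, tolerance = 1e-9)
  expect_equal(eq$r_squared, 1, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  d <- data.frame(x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  d$y <- d$x1 + rnorm(20)
  expect_error(ols_fit(d, "y", c("x1", "x2")), "collinear.*x2")
  expect_error(ols_fit(d[1:3, ], "y", c("x1", "x2")), "need n >")
  expect_error(ols_fit(d, "y", "zz"), "not in panel")
})

test_that("stepwise finds a single true predictor among pure noise", {
  set.seed(5)
  n <- 200
  d <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, paste0("n", 1:6))))
  d$sig <- rnorm(n)
  d$y <- 3 * d$sig + rnorm(n)
  # strict entry threshold: with 6 pure-noise candidates, alpha 0.05 would
  # admit a spurious term in about a quarter of draws by construction
  path <- stepwise_select(d, "y", c(paste0("n", 1:6), "sig"),
                          alpha_enter = 0.01, alpha_remove = 0.02)
  expect_identical(path$final$predictors, "sig")
  # pure-noise candidates only: empty selection with a warning
  set.seed(6)
  d2 <- data.frame(a = rnorm(50), b = rnorm(50), y = rnorm(50))
  expect_warning(p2 <- stepwise_select(d2, "y", c("a", "b")),
                 "no candidate")
  expect_null(p2$final)
})

test_that("stepwise on the structural panel enters NDF first among chemistry", {
  panel <- generate_wheat_panel(
    generator_config(n_samples = 40, seed = 1, noise_sd = 0.19),
    target = repaired)
  chem <- c("CP", "CF", "NDF", "ADF", "EE", "Ash", "BulkWeight")
  path <- stepwise_select(panel, "NE", chem)
  expect_identical(path$steps[[1]]$predictors, "NDF")
  # nested sequence: R2 non-decreasing along the path
  r2 <- vapply(path$steps, function(e) e$r_squared, 0)
  expect_true(all(diff(r2) >= -1e-12))
  # the AME-augmented family begins with AME and improves on chemistry alone
  path_ame <- stepwise_select(panel, "NE", c("AME", chem))
  expect_identical(path_ame$steps[[1]]$predictors, "AME")
  expect_gte(path_ame$final$r_squared, path$final$r_squared - 1e-12)
})

test_that("stepwise final model attains the best RSD it visited (all-subsets oracle)", {
  set.seed(8)
  for (i in 1:5) {
    n <- 60
    d <- as.data.frame(matrix(rnorm(n * 5), n, 5,
                              dimnames = list(NULL, paste0("x", 1:5))))
    d$y <- 1 + 1.2 * d$x1 - 0.8 * d$x2 + 0.5 * d$x3 + rnorm(n, 0, 0.6)
    path <- stepwise_select(d, "y", paste0("x", 1:5))
    visited <- vapply(path$steps, function(e)
      paste(sort(e$predictors), collapse = "+"), "")
    oracle <- all_subsets_rsd(d, "y", paste0("x", 1:5))
    key <- vapply(strsplit(oracle$predictors, "\\+"), function(s)
      paste(sort(s), collapse = "+"), "")
    visited_rsd <- oracle$rsd[key %in% visited]
    expect_equal(path$final$rsd, min(visited_rsd), tolerance = 1e-10)
  }
})

test_that("stepwise validates thresholds and candidates", {
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_error(stepwise_select(d, "y", character(0)), "at least one")
  expect_error(stepwise_select(d, "y", "x", alpha_enter = 0.2,
                               alpha_remove = 0.1), "<=")
})

test_that("published equations predict the published panel means", {
  eqs <- reference_ne_equations()
  means <- c(AME = 13.15, NDF = 9.56, ADF = 2.58)
  expect_equal(round(predict_ne(eqs$eq5, means), 2), 8.15)
  expect_equal(round(predict_ne(eqs$eq1, means["NDF"]), 2), 8.15)
  expect_equal(predict_ne(eqs$eq1, c(NDF = 9.56)), 11.919 - 0.394 * 9.56,
               tolerance = 1e-12)
  # all-zero slopes reduce to the intercept
  eq0 <- new_prediction_equation("NDF", 0, 4.2, NA, NA, NA, 40)
  expect_equal(predict_ne(eq0, c(NDF = 99)), 4.2)
  # data-frame input vectorizes
  df <- data.frame(AME = c(13.15, 12), NDF = c(9.56, 10), ADF = c(2.58, 3))
  expect_length(predict_ne(eqs$eq5, df), 2)
  expect_error(predict_ne(eqs$eq5, c(AME = 13)), "lacks predictor")
  expect_error(predict_ne(list(), c(AME = 13)), "prediction_equation")
})
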