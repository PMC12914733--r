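test_that("Latin hypercube designs are stratified and reproducible", {
  b <- data.frame(name = "x", lo = 0, hi = 1)
  d <- lhs_sample(b, 4, seed = 1)
  strata <- findInterval(sort(d$samples[, 1]), c(0, 0.25, 0.5, 0.75, 1),
                         rightmost.closed = TRUE)
  expect_equal(strata, 1:4)
  expect_identical(lhs_sample(b, 4, seed = 1)$samples, d$samples)
  expect_error(lhs_sample(data.frame(name = "x", lo = 1, hi = 1), 4),
               "degenerate")
  expect_error(lhs_sample(b, 1), "at least 2")
  ## marginal mean of a large design approaches the interval midpoint
  b2 <- data.frame(name = c("a", "b"), lo = c(2, -1), hi = c(4, 1))
  big <- lhs_sample(b2, 10000, seed = 2)
  se <- (b2$hi - b2$lo) / sqrt(12 * 10000)
  expect_lt(abs(mean(big$samples[, "a"]) - 3), 3 * se[1])
  expect_lt(abs(mean(big$samples[, "b"]) - 0), 3 * se[2])
})

test_that("PRCC separates a perfect driver from inert parameters", {
  set.seed(31)
  n <- 1000
  X <- matrix(stats::runif(n * 6), n, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 1]
  pr <- prcc(X, y)
  expect_gte(pr$prcc[1], 0.99)
  expect_true(pr$significant[1])
  expect_true(all(abs(pr$prcc[-1]) < 0.1))
  expect_false(any(pr$significant[-1]))
})

test_that("PRCC matches brute-force partial correlation on ranks", {
  set.seed(32)
  n <- 400
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3] + stats::rnorm(n, 0, 0.3)
  pr <- prcc(X, y)
  ## oracle: partial correlation from the inverse rank-correlation matrix
  R <- cbind(apply(X, 2, rank), y = rank(y))
  P <- solve(stats::cor(R))
  oracle <- vapply(1:4, function(j)
    -P[j, 5] / sqrt(P[j, j] * P[5, 5]), numeric(1))
  expect_equal(pr$prcc, oracle, tolerance = 1e-6)
})

test_that("PRCC is invariant to monotone transforms of the output", {
  set.seed(33)
  n <- 300
  X <- matrix(stats::runif(n * 3), n, 3,
              dimnames = list(NULL, paste0("x", 1:3)))
  y <- X[, 1] + 0.2 * X[, 2] + stats::rnorm(n, 0, 0.05)
  expect_equal(prcc(X, y)$prcc, prcc(X, exp(y))$prcc, tolerance = 1e-12)
})

test_that("PRCC handles degenerate and failed outputs", {
  X <- matrix(stats::runif(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  const <- prcc(X, rep(1, 30))
  expect_true(attr(const, "degenerate"))
  expect_equal(const$prcc, c(0, 0))
  y <- X[, 1]
  y[1:10] <- NA  # 33% failures
  expect_error(prcc(X, y), "10%")
})

test_that("the monotonicity screen flags folded relationships", {
  set.seed(34)
  x <- stats::runif(600, -1, 1)
  X <- cbind(x = x, z = stats::runif(600))
  sq <- monotonicity_screen(X, x^2)
  expect_false(sq$monotone[sq$parameter == "x"])
  lin <- monotonicity_screen(X, 3 * x + stats::rnorm(600, 0, 0.5))
  expect_true(lin$monotone[lin$parameter == "x"])
  ## verdicts are stable across seeds at this sample size
  set.seed(35)
  x2 <- stats::runif(600, -1, 1)
  X2 <- cbind(x = x2, z = stats::runif(600))
  sq2 <- monotonicity_screen(X2, x2^2)
  expect_identical(sq$monotone[sq$parameter == "x"],
                   sq2$monotone[sq2$parameter == "x"])
})

test_that("the GSA parameter inventory covers kinetics and modulations", {
  b <- gsa_parameter_bounds(default_p, mod_fb)
  expect_true(all(c("lamA4", "pDN", "sigmaSP4", "fb:lamN4base",
                    "mod:lamA4:max_change") %in% b$name))
  expect_true(all(b$lo < b$hi))
  expect_true(all(b$lo >= 0))
  ## around 70 parameters enter the analysis
  expect_gt(nrow(b), 60)
  ## bounded fractions are capped at 1
  expect_lte(b$hi[b$name == "mod:phiCM4:max_change"], 1)
})

test_that("model GSA flags clonal expansion as the driver of memory cells", {
  g <- run_gsa(default_p, mod_fb, ages = c(0, 20),
               outputs = c("BL_RTE_conc", "BL_CM_conc"), n = 2000,
               seed = 7)
  expect_lte(g$failed_fraction, 0.1)
  cm <- g$prcc[g$prcc$output == "BL_CM_conc", ]
  for (a in c(0, 20)) {
    at_age <- cm[cm$age == a, ]
    expect_true(at_age$significant[at_age$parameter == "lamA4"])
    expect_true(at_age$significant[at_age$parameter == "phiA4"])
  }
  ## structurally inert pairing: effector gut egress cannot shape blood RTE
  rte <- g$prcc[g$prcc$output == "BL_RTE_conc" & g$prcc$age == 20, ]
  expect_lt(abs(rte$prcc[rte$parameter == "omEFF4bl_git"]), 0.1)
  ## PRCC estimates have settled: half-sample drift of top parameters
  expect_lt(max(g$convergence$drift_top5, na.rm = TRUE), 0.05)
})

test_that("response surfaces are consistent and show known interactions", {
  cg <- contour_grid(c("lamA4", "phiA4"), default_p, mod_static,
                     grid_size = 3, age = 2, output = "total_LT")
  expect_equal(nrow(cg), 9L)
  ## the centre node equals a direct steady-state evaluation
  ss <- solve_steady_state(default_p, mod_static, age_fixed = 2)
  centre <- observables_from_state(ss, attr(ss, "effective")$BV)
  expect_equal(cg$value[5], centre$totals[["total_LT"]], tolerance = 1e-8)
  ## compensatory tilt: output rises with lamA4 and falls with phiA4
  m <- matrix(cg$value, 3, 3)  # rows: lamA4, cols: phiA4
  expect_true(all(diff(m[, 1]) > 0))
  expect_true(all(m[2, 1] > m[2, 3]))
  expect_error(contour_grid(c("lamA4", "lamA4")), "distinct")
})
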