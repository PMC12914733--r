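test_that("blood concentrations and tissue percentages are mapped correctly", {
  s <- state_vector(c(N_BL = 5e9))
  obs <- observables_from_state(s, BV = 5)
  expect_equal(obs$values[["BL_N_conc"]], 1000)

  ## equal counts across the six lymphoid-tissue subsets -> 16.67% each
  s2 <- state_vector(setNames(rep(7e8, 6),
                              paste0(c("RTE", "N", "A", "CM", "EM", "EFF"),
                                     "_LT")))
  obs2 <- observables_from_state(s2, BV = 5)
  lt <- obs2$values[grep("^LT_", names(obs2$values))]
  expect_equal(unname(lt), rep(100 / 6, 6), tolerance = 1e-12)

  ## memory concentration is CM + EM in blood
  s3 <- state_vector(c(CM_BL = 2e9, EM_BL = 1e9, N_BL = 4e9))
  obs3 <- observables_from_state(s3, BV = 4)
  expect_equal(obs3$totals[["BL_memory_conc"]],
               obs3$values[["BL_CM_conc"]] + obs3$values[["BL_EM_conc"]])
  expect_equal(obs3$totals[["BL_total_conc"]],
               sum(obs3$values[grep("_conc$", names(obs3$values))]))

  expect_error(observables_from_state(s, BV = 0), "positive")
  empty <- observables_from_state(state_vector(c(N_BL = 1)), BV = 1)
  expect_true(all(c("LT", "GIT", "LUNG") %in% empty$degenerate))
  expect_equal(unname(empty$values[grep("pct$", names(empty$values))]),
               rep(0, 14))
})

test_that("percentages normalise to 100 along a simulated life course", {
  init <- solve_steady_state(default_p, mod_fb, age_fixed = 0)
  tr <- simulate_trajectory(init, default_p, mod_fb,
                            t_grid = seq(0, 60 * 365.25, length.out = 13))
  for (k in seq_len(nrow(tr))) {
    obs <- observables_from_state(as.numeric(tr[k, state_labels()]),
                                  BV = blood_volume(tr$age_years[k]))
    v <- obs$values
    expect_equal(sum(v[grep("^LT_", names(v))]), 100, tolerance = 1e-9)
    expect_equal(sum(v[grep("^GIT_", names(v))]), 100, tolerance = 1e-9)
    expect_equal(sum(v[grep("^LUNG_", names(v))]), 100, tolerance = 1e-9)
  }
})

test_that("CD4 reference counts split totals by the CD4/CD8 ratio", {
  expect_equal(reference_cd4_counts(8e9, 2.0), 8e9 * 2 / 3)
  expect_equal(signif(reference_cd4_counts(8e9, 2.0), 2), 5.3e9)
  expect_equal(reference_cd4_counts(1.7e10, 1.0), 8.5e9)
  expect_equal(reference_cd4_counts(1e10, 1e12), 1e10, tolerance = 1e-10)
  expect_equal(reference_cd4_counts(6e9, 1.0), 3e9)  # ratio 1 halves
  expect_error(reference_cd4_counts(1, 0), "positive")
})

test_that("percent differences reproduce simple arithmetic", {
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(round(percent_difference(5.09e9, 5.3e9), 1), 4.0)
  expect_equal(round(percent_difference(4.14e9, 6.5e9)), 36)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("the proportional-error likelihood matches the hand formula", {
  d <- data.frame(mean = 110, cv = 0.1)
  nll <- proportional_loglik(100, d)
  expect_equal(as.numeric(nll), 0.5 * log(2 * pi * 100) + 0.5)

  ## zero residual leaves only the normalising terms
  d2 <- data.frame(mean = c(10, 20), cv = c(0.2, 0.3))
  nll2 <- proportional_loglik(c(10, 20), d2)
  expect_equal(as.numeric(nll2),
               sum(0.5 * log(2 * pi * (c(0.2, 0.3) * c(10, 20))^2)))

  ## doubling CVs shrinks every quadratic penalty
  d3 <- data.frame(mean = c(12, 8), cv = c(0.1, 0.1))
  quad <- function(cv) {
    dd <- d3; dd$cv <- cv
    as.numeric(proportional_loglik(c(10, 10), dd)) -
      sum(0.5 * log(2 * pi * (cv * 10)^2))
  }
  expect_lt(quad(0.2), quad(0.1))

  ## zero prediction against data is flagged, not infinite
  d4 <- data.frame(mean = 5, cv = 0.1)
  nll4 <- proportional_loglik(0, d4)
  expect_true(is.finite(as.numeric(nll4)))
  expect_equal(attr(nll4, "n_flagged"), 1L)
})

test_that("likelihood falls as predictions approach the data", {
  set.seed(8)
  d <- data.frame(mean = stats::runif(10, 10, 100), cv = 0.15)
  far <- d$mean * 1.5
  for (lam in c(0.8, 0.5, 0.2)) {
    closer <- d$mean + lam * (far - d$mean)
    expect_lt(as.numeric(proportional_loglik(closer, d)),
              as.numeric(proportional_loglik(far, d)))
  }
})

test_that("AIC selection takes the lowest value with deterministic ties", {
  f <- function(nll, k) list(nll = nll, k = k, aic = aic(nll, k))
  expect_equal(aic(0, 1), 2)
  sel <- aic_compare(list(f(2431.175, 15), f(2376.615, 17)))
  expect_equal(sel$aic, aic(2376.615, 17))
  ## tie broken by fewer estimated parameters
  tie <- aic_compare(list(list(nll = 10, k = 7, aic = 24),
                          list(nll = 12, k = 5, aic = 24)))
  expect_equal(tie$k, 5)
  expect_error(aic_compare(list()), "no fits")
  expect_error(aic_compare(list(f(Inf, 1))), "finite")
})

test_that("RSE from the likelihood curvature matches the analytic toy", {
  nll <- function(th) 0.5 * ((th[[1]] - 2) / 0.5)^2
  tab <- rse_estimate(nll, c(theta = 2))
  expect_equal(tab$se, 0.5, tolerance = 1e-4)
  expect_equal(tab$rse, 25, tolerance = 1e-3)
  expect_true(tab$identifiable)

  ## wide curvature -> RSE above the 51% cut-off is flagged
  nll2 <- function(th) 0.5 * ((th[[1]] - 2) / 1.1)^2
  tab2 <- rse_estimate(nll2, c(theta = 2))
  expect_gt(tab2$rse, 51)
  expect_false(tab2$identifiable)

  ## flat likelihood -> singular information, flagged unidentifiable
  tab3 <- rse_estimate(function(th) 0, c(a = 1, b = 2))
  expect_false(any(tab3$identifiable))
})
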