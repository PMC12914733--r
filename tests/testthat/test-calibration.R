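# desk-scale fits: few starts and a reduced iteration cap keep each fit in
# the seconds range; the acceptance suite runs the full recovery experiment

# a small nominal CV keeps the O(CV^2) shrinkage bias of the
# prediction-scaled proportional-error likelihood negligible on clean data
ds_noiseless <- generate_calibration_dataset(
  synthetic_spec(default_p, mod_static, cv = 0.02, noise = FALSE, seed = 5))

test_that("multi-start fits are seeded, deterministic and take the best start", {
  free <- c("omRTE4bl_lt", "phiN4")
  f1 <- fit_multistart(ds_noiseless, default_p, mod_static, free,
                       n_starts = 3, seed = 11, maxit = 120,
                       compute_rse = FALSE)
  f2 <- fit_multistart(ds_noiseless, default_p, mod_static, free,
                       n_starts = 3, seed = 11, maxit = 120,
                       compute_rse = FALSE)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$nll, f2$nll)
  expect_true(all(f1$nll <= f1$start_values + 1e-12))
  expect_equal(f1$aic, 2 * f1$k + 2 * f1$nll)
  expect_error(fit_multistart(ds_noiseless, default_p, mod_static,
                              character(0)), "free")
})

test_that("a displaced model recovers the generating rates on clean data", {
  free <- c("omRTE4bl_lt", "phiN4")
  truth <- default_p$values[free]
  pstart <- default_p
  pstart$values[free] <- truth * c(3, 0.3)
  fit <- fit_multistart(ds_noiseless, pstart, mod_static, free,
                        n_starts = 3, seed = 2, maxit = 500)
  expect_lt(max(abs(fit$estimate - truth) / truth), 0.01)
  expect_true(all(fit$rse$identifiable))
})

test_that("profile likelihood is anchored at the optimum and bounded", {
  fit <- fit_multistart(ds_noiseless, default_p, mod_static, "phiN4",
                        n_starts = 2, seed = 4, maxit = 200,
                        compute_rse = FALSE)
  prof <- profile_likelihood(fit, ds_noiseless, "phiN4",
                             grid = fit$estimate[["phiN4"]] *
                               c(0.25, 0.5, 1, 2, 4))
  ## at the MLE the profile equals the fitted NLL
  expect_equal(prof$nll[3], fit$nll, tolerance = 1e-6)
  ## clean data identify phiN4: the profile rises steeply away from it
  expect_false(attr(prof, "flat"))
  expect_false(prof$in_ci[1])
  expect_false(prof$in_ci[5])
  expect_true(prof$in_ci[3])
  expect_error(profile_likelihood(fit, ds_noiseless, "lamA4"), "not free")
})

test_that("a structurally uninformative parameter yields a flat profile", {
  ## tissue percentages are (near-)invariant to a uniform rescaling of
  ## thymic egress, so sigmaSP4 is practically unidentifiable from them;
  ## judged at the ordinary 10% assay CV
  ds10 <- generate_calibration_dataset(
    synthetic_spec(default_p, mod_static, cv = 0.1, noise = FALSE,
                   seed = 5))
  pct_only <- ds10[grepl("_pct$", ds10$observable_id), ]
  fit <- fit_multistart(pct_only, default_p, mod_static, "sigmaSP4",
                        n_starts = 2, seed = 6, maxit = 150,
                        compute_rse = FALSE)
  prof <- profile_likelihood(fit, pct_only, "sigmaSP4",
                             grid = fit$estimate[["sigmaSP4"]] *
                               c(0.8, 1, 1.25))
  expect_true(attr(prof, "flat"))
})

test_that("stepwise selection returns nothing when the data carry no age effect", {
  cands <- data.frame(target = c("lamA4", "phiCM4"),
                      direction = c("up", "down"))
  sel <- stepwise_selection(ds_noiseless, cands, forms = "hyperbolic",
                            params = default_p, n_starts = 2, maxit = 80,
                            seed = 13)
  expect_length(sel$accepted, 0L)
  fw <- sel$audit[sel$audit$step == "forward", ]
  expect_false(any(fw$accepted))
})

test_that("stepwise selection recovers an injected hyperbolic age effect", {
  mtrue <- mod_static
  mtrue$variant <- "AGE"
  mtrue$entries <- mod_age$entries["lamA4"]
  ds <- generate_calibration_dataset(
    synthetic_spec(default_p, mtrue, cv = 0.1, noise = TRUE, seed = 11))
  cands <- data.frame(target = c("lamA4", "phiCM4", "omCM4lt_bl"),
                      direction = c("up", "down", "down"))
  sel <- stepwise_selection(ds, cands, forms = c("hyperbolic", "linear"),
                            params = default_p, n_starts = 2, maxit = 120,
                            seed = 3)
  expect_true("lamA4" %in% sel$accepted)
  expect_equal(sel$modulations$entries[["lamA4"]]$form, "hyperbolic")
  expect_equal(sel$modulations$entries[["lamA4"]]$direction, "up")
  ## the audit's accepted forward steps have non-increasing AIC
  acc <- sel$audit[sel$audit$step == "forward" & sel$audit$accepted, ]
  expect_true(all(diff(acc$aic) <= 0))
})
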