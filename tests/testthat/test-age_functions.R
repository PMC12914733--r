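test_that("hill_up matches its anchors and bounds", {
  expect_equal(hill_up(0, base = 2, amax = 3, age50 = 10), 2)
  expect_equal(hill_up(10, base = 2, amax = 3, age50 = 10), 2 * (1 + 1.5))
  expect_equal(hill_up(1e8, base = 2, amax = 3, age50 = 10), 8,
               tolerance = 1e-6)
  ages <- seq(0, 120, by = 0.5)
  expect_true(all(diff(hill_up(ages, 1, 2, 30, h = 3)) >= 0))
  expect_error(hill_up(5, 1, 1, age50 = 0), "age50")
  expect_error(hill_up(-1, 1, 1, 10), "age")
})

test_that("hill_down decreases to base*(1-dmax) and validates dmax", {
  expect_equal(hill_down(0, 3, 0.5, 20), 3)
  expect_equal(hill_down(20, 3, 0.5, 20), 3 * 0.75)
  expect_lt(hill_down(1e8, 3, 1, 20), 1e-6)
  expect_error(hill_down(5, 1, 1.2, 10), "dmax")
})

test_that("blood volume scales body weight growth and is non-decreasing", {
  expect_equal(blood_volume(0), 5 * 3.5 / 70)
  expect_equal(blood_volume(200), 5, tolerance = 1e-6)
  bv <- blood_volume(seq(0, 90, by = 0.25))
  expect_true(all(diff(bv) >= 0))
})

test_that("thymus wet weight peaks in early childhood then involutes", {
  grid <- seq(0, 30, by = 0.01)
  w <- thymus_wet_weight(grid)
  peak_age <- grid[which.max(w)]
  expect_gt(peak_age, 0.5)
  expect_lt(peak_age, 2.5)

  caps20 <- thymus_capacity(20)
  caps80 <- thymus_capacity(80)
  expect_true(all(caps80 < caps20))
  expect_true(all(caps80 > 0))

  ## no-involution limit: plateau at the mature-growth asymptote
  const <- cd4kinetics:::.PHYSIOLOGY_DEFAULTS
  const$k_involution <- 0
  plateau <- thymus_capacity(1e6, const)
  expect_equal(unname(plateau[["Tcortmax"]]),
               const$kappa_cort * const$w_birth * (1 + const$w_growth) *
                 (1 + const$cap_growth),
               tolerance = 1e-6)
})

test_that("RTE-concentration feedbacks hit their anchors and are monotone", {
  expect_equal(feedback_naive_prolif(0, 0.0012, 0.4, 100), 0.0012)
  expect_equal(feedback_naive_prolif(100, 0.0012, 0.4, 100),
               0.0012 * (1 - 0.2))
  expect_equal(feedback_rte_death(0, 0.0015, 4, 100), 0.0015)
  expect_equal(feedback_rte_death(100, 0.0015, 4, 100), 0.0015 * 3)
  grid <- seq(0, 2000, length.out = 100)
  lam <- feedback_naive_prolif(grid, 0.0012, 0.4167, 195)
  mu <- feedback_rte_death(grid, 0.00152, 4, 310)
  expect_true(all(diff(lam) <= 0))
  expect_true(all(diff(mu) >= 0))
  expect_error(feedback_naive_prolif(-1, 1, 0.5, 10), "C_RTE")
  expect_error(feedback_naive_prolif(1, 1, 1.5, 10), "fmax")
})

test_that("the AGE modulation inventory is the calibrated 13-function set", {
  m <- default_modulations("AGE")
  dirs <- vapply(m$entries, `[[`, "", "direction")
  expect_length(m$entries, 13L)
  expect_setequal(names(dirs)[dirs == "up"],
                  c("lamN4", "lamA4", "omEM4lung_bl", "omEFF4bl_git",
                    "omEFF4bl_lung", "omEFF4bl_tis"))
  expect_setequal(names(dirs)[dirs == "down"],
                  c("muRTE4", "omRTE4bl_lt", "phiCM4", "phiEM4",
                    "omA4lt_bl", "omCM4lt_bl", "omEFF4lt_bl"))
  ## fixed structural constants: 100% decreases and anchor Hill exponents
  for (tgt in c("omRTE4bl_lt", "phiCM4", "phiEM4", "omA4lt_bl",
                "omCM4lt_bl", "omEFF4lt_bl")) {
    expect_equal(m$entries[[tgt]]$max_change, 1)
  }
  expect_equal(m$entries[["lamN4"]]$hill, 10)
  expect_equal(m$entries[["phiCM4"]]$hill, 3)
  expect_equal(m$feedback$Nh_lamN4, 10)
  expect_equal(m$feedback$Nh_muRTE4, 10)
  grp <- vapply(m$entries, `[[`, "", "group")
  expect_setequal(names(grp)[!is.na(grp)],
                  c("phiEM4", "omEM4lung_bl", "omEFF4bl_git",
                    "omEFF4bl_lung", "omEFF4bl_tis"))
})

test_that("effective rates honour the variant semantics", {
  p <- default_p
  ## STATIC: peripheral rates untouched at any age
  es <- effective_parameters(57, 0, p, mod_static)
  expect_equal(es$values[["lamA4"]], 1.725)
  expect_equal(es$values[setdiff(names(p$values), character(0))],
               p$values)
  ## AGE at age 0 reduces to the base rates
  e0 <- effective_parameters(0, 0, p, mod_age)
  expect_equal(e0$values, p$values)
  ## feedback variant at zero concentration exposes the base feedback rates
  ef <- effective_parameters(40, 0, p, mod_fb)
  expect_equal(ef$values[["lamN4"]], mod_fb$feedback$lamN4base)
  expect_equal(ef$values[["muRTE4"]], mod_fb$feedback$muRTE4base)
  ea <- effective_parameters(40, 0, p, mod_age)
  shared <- setdiff(names(p$values), c("lamN4", "muRTE4"))
  expect_equal(ef$values[shared], ea$values[shared])
})

test_that("AGE with all effect sizes zero reproduces STATIC exactly", {
  m0 <- mod_age
  for (nm in names(m0$entries)) m0$entries[[nm]]$max_change <- 0
  for (a in c(0, 7, 33, 80)) {
    expect_identical(effective_parameters(a, 0, default_p, m0)$values,
                     effective_parameters(a, 0, default_p, mod_static)$values)
  }
})

test_that("shared-age50 group members move together", {
  m <- mod_age
  pm <- cd4kinetics:::.free_set("mod:phiEM4:age50", 42, default_p, m)
  shifted <- pm$modulations$entries
  for (tgt in c("phiEM4", "omEM4lung_bl", "omEFF4bl_git", "omEFF4bl_lung",
                "omEFF4bl_tis")) {
    expect_equal(shifted[[tgt]]$age50, 42)
  }
  expect_equal(shifted[["omA4lt_bl"]]$age50, m$entries[["omA4lt_bl"]]$age50)
})

test_that("effective rates stay non-negative over age and concentration", {
  set.seed(4)
  for (k in 1:25) {
    a <- stats::runif(1, 0, 120)
    cc <- stats::runif(1, 0, 1e4)
    for (m in list(mod_static, mod_age, mod_fb)) {
      ev <- effective_parameters(a, cc, default_p, m)
      expect_true(all(ev$values >= 0))
      expect_gt(ev$BV, 0)
      expect_gt(ev$Tmedmax, 0)
    }
  }
})
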