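# Closed-form interface mechanics, threshold machinery and stiffening.

test_that("interface stress matches the closed form and its symmetries", {
  ep1 <- elastic_params(sigma_far = 1)
  # frozen value from independent hand evaluation of the printed expression:
  # eta = k = 1 gives 5 / (18 + 348/187) at theta = pi/2, phi = pi/4
  expect_equal(compute_sigma_rr(pi / 2, pi / 4, ep1),
               5 / (18 + 348 / 187), tolerance = 1e-10)
  expect_equal(compute_sigma_rr(pi / 2, pi / 4, ep1), 0.251750,
               tolerance = 1e-6)
  # zero along the polar axis, for any phi
  for (phi in c(0, 0.3, pi / 4, 2)) {
    expect_identical(compute_sigma_rr(0, phi, ep1), 0)
    expect_equal(compute_sigma_rr(pi, phi, ep1), 0, tolerance = 1e-25)
  }
  # antisymmetry of sin(2 phi)
  expect_equal(compute_sigma_rr(pi / 2, 3 * pi / 4, ep1),
               -compute_sigma_rr(pi / 2, pi / 4, ep1))
  # integrates to ~0 over the sphere (area-weighted lattice)
  u <- seq(-0.999, 0.999, length.out = 201)
  phi <- seq(0, 2 * pi, length.out = 402)[-1]
  g <- expand.grid(theta = acos(u), phi = phi)
  expect_lt(abs(mean(compute_sigma_rr(g$theta, g$phi, ep1))), 1e-12)
  expect_error(compute_sigma_rr(pi / 2, pi / 4, ep1, mu_ecm_current = -1),
               "positive")
  expect_error(elastic_params(mu_cell = Inf), "finite")
})

test_that("equal-area patch radius tiles the sphere exactly", {
  expect_equal(patch_radius(10e-6, 4), 10e-6)
  expect_equal(patch_radius(10e-6, 500), 2 * 10e-6 / sqrt(500))
  expect_equal(patch_radius(10e-6, 500), 0.894427e-6, tolerance = 1e-6)
  for (N in c(1, 7, 500, 4096)) {
    a <- patch_radius(10e-6, N)
    expect_equal(N * pi * a^2, 4 * pi * (10e-6)^2)  # exact tiling
  }
  expect_error(patch_radius(10e-6, 0), "positive")
})

test_that("patch force is the stress times the patch area, sign carried", {
  a <- patch_radius(10e-6, 500)
  expect_identical(integrin_force(a, 0), 0)
  expect_equal(integrin_force(a, 1), pi * a^2, tolerance = 1e-12)
  expect_equal(integrin_force(a, 1), 2.513e-12, tolerance = 1e-3)
  expect_equal(integrin_force(a, 2 * 1.7), 2 * integrin_force(a, 1.7))
  expect_lt(integrin_force(a, -1), 0)
})

test_that("reference force is the 10 pN peak at time zero", {
  expect_equal(reference_force(elastic_params(), 500), 1e-11,
               tolerance = 1e-6)
})

test_that("ECM stiffening conventions behave as documented", {
  ep <- elastic_params()
  expect_identical(update_ecm_modulus(0, ep), ep$mu_ecm_base)
  # linear relative convention (power with beta = 1)
  expect_equal(update_ecm_modulus(100, ep, convention = "linear"),
               1.1 * ep$mu_ecm_base)
  expect_equal(update_ecm_modulus(1000, ep, convention = "linear"),
               2 * ep$mu_ecm_base)
  # per-deposit compounding
  expect_equal(update_ecm_modulus(1000, ep, convention = "compound"),
               ep$mu_ecm_base * 1.001^1000)
  # calibrated default: monotone, never below base
  n <- c(0, 10, 100, 1000, 10000)
  mu <- update_ecm_modulus(n, ep)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu >= ep$mu_ecm_base))
  expect_error(update_ecm_modulus(-1, ep), "non-negative")
})

test_that("force magnitude is non-increasing as deposits accumulate", {
  ep <- elastic_params()
  lay <- integrin_layout(64)
  n_grid <- seq(0, 1e4, by = 250)
  for (i in c(1, 13, 40, 64)) {
    f <- vapply(n_grid, function(n) {
      mu <- update_ecm_modulus(n, ep)
      integrin_force(patch_radius(ep$cell_radius, 64),
                     compute_sigma_rr(lay$theta[i], lay$phi[i], ep, mu))
    }, numeric(1))
    expect_true(all(diff(abs(f)) <= 1e-25))
  }
})

test_that("threshold assignment respects the variant recipes", {
  f_ref <- 1e-11
  set.seed(1)
  sm <- assign_thresholds("SM", 500, f_ref)
  expect_true(all(sm$mt == 0.1 * f_ref))
  expect_true(all(sm$sensitivity_class == "sensitive"))
  usm <- assign_thresholds("USM", 500, f_ref)
  expect_true(all(usm$mt == 0.01 * f_ref))
  hm1 <- assign_thresholds("HM1", 500, f_ref)
  expect_identical(sum(hm1$sensitivity_class == "ultrasensitive"), 5L)
  hm10 <- assign_thresholds("HM10", 500, f_ref)
  expect_identical(sum(hm10$sensitivity_class == "ultrasensitive"), 50L)
  # odds reading of the mixing ratios is selectable
  hm10b <- assign_thresholds(
    variant_spec("HM10", ratio_convention = "odds"), 500, f_ref)
  expect_identical(sum(hm10b$sensitivity_class == "ultrasensitive"),
                   as.integer(round(500 / 11)))
  expect_error(assign_thresholds("SM", 500, -1), "positive")
  expect_error(variant_spec("XXX"))
})

test_that("activation rule: at-threshold activates, compression never", {
  mt <- 2e-12
  expect_true(check_activation(mt, mt))
  expect_false(check_activation(0.999 * mt, mt))
  expect_false(check_activation(-mt, mt))
  expect_true(check_activation(1.5 * mt, mt))
  expect_error(check_activation(1e-12, 0), "positive")
})

test_that("threshold nesting: sensitive active set within ultrasensitive", {
  set.seed(42)
  f_ref <- 1e-11
  sm <- assign_thresholds("SM", 200, f_ref)
  usm <- assign_thresholds("USM", 200, f_ref)
  for (rep in 1:20) {
    forces <- runif(200, -1, 1) * 1.2e-11
    act_sm <- check_activation(forces, sm$mt)
    act_usm <- check_activation(forces, usm$mt)
    expect_true(all(act_usm[act_sm]))  # SM-active implies USM-active
  }
})

test_that("within-patch stress variation is small for 500 patches", {
  expect_lt(patch_variation(500, n_mc = 150, seed = 1), 0.075)
})

test_that("integrin layouts sit on the unit sphere and are reproducible", {
  lay <- integrin_layout(500)
  expect_identical(lay, integrin_layout(500))
  expect_true(all(lay$theta >= 0 & lay$theta <= pi))
  set.seed(7); r1 <- integrin_layout(100, "random")
  set.seed(7); r2 <- integrin_layout(100, "random")
  expect_identical(r1, r2)
})

test_that("force table flags exactly the above-threshold patches", {
  lay <- integrin_layout(100)
  set.seed(3)
  thr <- assign_thresholds("HM10", 100, reference_force(N = 100))
  ft <- force_table(lay$theta, lay$phi, thr$mt, N = 100)
  expect_identical(ft$active, ft$force_N >= ft$mt_N)
  expect_identical(nrow(ft), 100L)
  # deposits weaken every force
  ft2 <- force_table(lay$theta, lay$phi, thr$mt, N = 100,
                     n_deposited = 2000)
  expect_true(all(abs(ft2$force_N) <= abs(ft$force_N) + 1e-30))
})
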