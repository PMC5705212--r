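regions16 <- local({
  m <- build_tube_mesh(16, 16, 0.15, 1, 0.05)
  build_region_fields(m, tag_anatomy(m))
})

test_that("all programs return zero growth during the setup steps", {
  for (prog in list(
    function(s) control_program(s, regions16),
    function(s) minimal_buckling_program(s, regions16, 0.05),
    function(s) sweep_program(s, regions16),
    function(s) variant_program("arterial_burst_variant")(s, regions16),
    function(s) variant_program("reduced_lr")(s, regions16))) {
    for (s in c(0, 5, 9)) {
      sp <- prog(s)
      expect_true(all(sp$k_par == 0) && all(sp$k_per == 0))
    }
    expect_gt(max(abs(prog(15)$k_par)), 0)
  }
})

test_that("control program reproduces the stated rates in each phase window", {
  pk <- which.max(regions16$ventral_spot)
  # ventral spot: 5% total at the peak until step 40, baseline after
  sp20 <- control_program(20, regions16)
  expect_equal(sp20$k_par[pk], 0.025 + 0.025 * regions16$ventral_spot[pk],
               tolerance = 1e-12)
  expect_gt(sp20$k_par[pk], 0.048)   # discrete element nearest the peak
  expect_equal(control_program(45, regions16)$k_par[pk], 0.025 +
                 0.5 * (0.07 - 0.025) *
                 heartloop:::burst_profile(regions16$azimuth[pk], 270) *
                 regions16$venous_gradient[pk], tolerance = 1e-12)
  # venous burst: 7% at the right venous peak during steps 30-60 only
  bw <- heartloop:::burst_profile(regions16$azimuth, 270) *
    regions16$venous_gradient
  bpk <- which.max(bw)
  sp45 <- control_program(45, regions16)
  expect_equal(sp45$k_par[bpk], 0.025 + 0.045 * bw[bpk], tolerance = 1e-12)
  expect_gt(sp45$k_par[bpk], 0.065)
  expect_lt(control_program(65, regions16)$k_par[bpk], 0.026)
  # rotation: +/-1.1% scaled by sin(azimuth) and arterial gradient, off at 30
  rot <- which.max(regions16$sin_azimuth * regions16$arterial_gradient)
  sp15 <- control_program(15, regions16)
  expect_equal(sp15$k_per[rot] -
                 (0.009 * regions16$rv_band[rot] +
                  0.014 * regions16$lv_band[rot]) -
                 0.005 * 0,
               0.011 * regions16$sin_azimuth[rot] *
                 regions16$arterial_gradient[rot] +
                 regions16$rv_band[rot] *
                 (0.009 - 0.005 * regions16$dorsal_left_inhibition[rot]) +
                 regions16$lv_band[rot] * 0.014 -
                 (0.009 * regions16$rv_band[rot] +
                  0.014 * regions16$lv_band[rot]),
               tolerance = 1e-9)
  # inflation: LV at 1.4% outside the inhibition zone, from step 10 to end
  lv <- which(regions16$lv_band > 0.999 & regions16$rv_band < 1e-9 &
              regions16$dorsal_left_inhibition < 1e-9)[1]
  sp70 <- control_program(70, regions16)
  expect_equal(sp70$k_per[lv], 0.014, tolerance = 1e-12)
  expect_equal(sp70$k_par[lv], 0.025, tolerance = 1e-12)
  expect_error(control_program(-1, regions16), "range")
})

test_that("minimal buckling program is symmetric without asymmetry and localised with it", {
  sp <- minimal_buckling_program(15, regions16, 0)
  expect_true(all(sp$k_par == 0.025))
  expect_true(all(sp$k_per == 0))
  spa <- minimal_buckling_program(15, regions16, 0.05)
  expect_lte(max(spa$k_par), 1.05 * 0.025 + 1e-12)
  expect_gt(max(spa$k_par), 1.04 * 0.025)
  expect_equal(min(spa$k_par), 0.025)
  # burst window only
  expect_true(all(minimal_buckling_program(25, regions16, 0.05)$k_par ==
                    0.025))
})

test_that("sweep program matches control minus inflation at the control point", {
  for (s in c(12, 35, 55, 70)) {
    sw <- sweep_program(s, regions16, 270, 0.07, 0.011, 1)
    ct <- control_program(s, regions16, inflation = FALSE)
    expect_equal(sw$k_par, ct$k_par, tolerance = 1e-12)
    expect_equal(sw$k_per, ct$k_per, tolerance = 1e-12)
  }
  expect_true(all(sweep_program(40, regions16, 270, 0.07, 0, 1)$k_per == 0))
  expect_error(sweep_program(40, regions16, 450, 0.07, 0.011, 1), "azimuth")
})

test_that("mirrored sweep cells are exact mirror growth programs", {
  az <- regions16$azimuth
  ord <- order(round(az, 6), regions16$axial)
  az_m <- (360 - az) %% 360
  ord_m <- order(round(az_m, 6), regions16$axial)
  a <- sweep_program(40, regions16, 90, 0.07, 0.011, -1)
  b <- sweep_program(40, regions16, 270, 0.07, 0.011, 1)
  expect_equal(a$k_par[ord], b$k_par[ord_m], tolerance = 1e-9)
  expect_equal(a$k_per[ord], -b$k_per[ord_m], tolerance = 1e-9)
})

test_that("variant programs implement the stated modifications", {
  # reduced_lr(1) is the identity on the control program
  v1 <- variant_program("reduced_lr", lr_scale = 1)
  for (s in c(15, 45, 70))
    expect_equal(v1(s, regions16), control_program(s, regions16))
  # reduced_lr(0.5): arterial k_per amplitude halved to 0.55%/step
  v05 <- variant_program("reduced_lr", lr_scale = 0.5)
  rot_peak <- which.max(regions16$sin_azimuth * regions16$arterial_gradient)
  base_inflation <- control_program(15, regions16, lr_scale = 0)$k_per
  expect_equal(v05(15, regions16)$k_per[rot_peak] -
                 base_inflation[rot_peak],
               0.5 * 0.011 * regions16$sin_azimuth[rot_peak] *
                 regions16$arterial_gradient[rot_peak], tolerance = 1e-12)
  # arterial burst variant: no rotation term, longitudinal burst at 150 deg
  vb <- variant_program("arterial_burst_variant")
  sp <- vb(15, regions16)
  expect_equal(sp$k_per, base_inflation, tolerance = 1e-12)
  art <- which.max(heartloop:::burst_profile(regions16$azimuth, 150) *
                     regions16$arterial_gradient)
  expect_gt(sp$k_par[art], 0.06)
  expect_error(variant_program("nope"), "unknown")
})

test_that("growth tensor has the specified eigenstructure", {
  fr <- diag(3)
  G0 <- growth_tensor(0, 0, 0, fr)
  expect_equal(G0, diag(3))
  G1 <- growth_tensor(0.025, 0, 0, fr)
  expect_equal(det(G1), 1.025, tolerance = 1e-12)
  G2 <- growth_tensor(0, -0.011, 0, fr)
  expect_equal(min(eigen(G2, symmetric = TRUE)$values), 0.989,
               tolerance = 1e-12)
  # arbitrary orthonormal frame: eigenvalues preserved
  q <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  G3 <- growth_tensor(0.03, -0.01, 0.002, q)
  expect_equal(sort(eigen(G3, symmetric = TRUE)$values),
               sort(c(1.03, 0.99, 1.002)), tolerance = 1e-12)
  expect_error(growth_tensor(0.03, 0, 0, matrix(1:9, 3)), "orthonormal")
})

test_that("integrated baseline growth over the active phase has the closed form", {
  total <- 1
  for (s in 0:89) {
    sp <- minimal_buckling_program(s, regions16, 0)
    total <- total * (1 + sp$k_par[1])
  }
  expect_equal(total, 1.025^80, tolerance = 1e-12)
})
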