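test_that("morphogen solution obeys the maximum principle and pole conditions", {
  m <- build_tube_mesh(12, 8, 0.15, 1, 0.05)
  pol <- solve_morphogen(m)
  expect_true(all(pol$concentration >= 0 & pol$concentration <= 1))
  tg <- tag_anatomy(m)
  expect_equal(unname(pol$concentration[tg$pole_rings$venous]),
               rep(1, 24))
  expect_equal(unname(pol$concentration[tg$pole_rings$arterial]),
               rep(0, 24))
})

test_that("polarizer directions follow the tube axis", {
  m <- build_tube_mesh(12, 8, 0.15, 1, 0.05)
  pol <- solve_morphogen(m)
  dev <- acos(pmin(1, abs(pol$direction[, 3]))) * 180 / pi
  expect_lt(max(dev), 1)   # straight cylinder: parallel to the axis
  # 90-degree arc: directions tangent to the arc within 3 degrees
  arc <- make_fixture("arc", arc_radius = 5, angle = 90, radius = 0.4,
                      thickness = 0.12, n_circ = 12, n_axial = 24)
  pa <- solve_morphogen(arc)
  tg <- tag_anatomy(arc)
  s <- tg$elem_axial
  phi <- s * pi / 2
  tan_ref <- cbind(sin(phi), 0, cos(phi))
  ang <- acos(pmin(1, abs(rowSums(pa$direction * tan_ref))))
  expect_lt(max(ang) * 180 / pi, 3)
})

test_that("swapping source and sink reverses every direction", {
  m <- build_tube_mesh(10, 6, 0.15, 1, 0.05)
  tg <- tag_anatomy(m)
  a <- solve_morphogen(m, tg$pole_rings$venous, tg$pole_rings$arterial)
  b <- solve_morphogen(m, tg$pole_rings$arterial, tg$pole_rings$venous)
  expect_equal(rowSums(a$direction * b$direction),
               rep(-1, nrow(a$direction)), tolerance = 1e-8)
})

test_that("element frames are orthonormal and circumferential on a cylinder", {
  m <- build_tube_mesh(14, 6, 0.15, 1, 0.05)
  fr <- update_frames(m, solve_morphogen(m))
  for (e in c(1, 20, 100, nrow(fr))) {
    Fm <- matrix(fr[e, ], 3, 3)
    expect_lt(max(abs(crossprod(Fm) - diag(3))), 1e-10)
    expect_gt(det(Fm), 0)   # right-handed
  }
  # circumferential direction tangent to cross-section circles (< 2 deg)
  cc <- fr[, 4:6]
  expect_lt(max(abs(cc[, 3])), sin(2 * pi / 180))
})

test_that("frames are equivariant under rigid motion", {
  m <- build_tube_mesh(10, 5, 0.15, 1, 0.05)
  fr0 <- update_frames(m, solve_morphogen(m))
  set.seed(7)
  for (rep in 1:3) {
    rig <- random_rigid()
    P2 <- apply_rigid(m$nodes, rig)
    fr2 <- update_frames(m, solve_morphogen(m, positions = P2),
                         positions = P2)
    for (blk in list(1:3, 4:6, 7:9)) {
      rot <- fr0[, blk] %*% t(rig$R)
      agree <- abs(rowSums(rot * fr2[, blk]))
      expect_gt(min(agree), 1 - 1e-6)
    }
  }
})

test_that("region fields are in range, mirror-symmetric and correctly placed", {
  m <- build_tube_mesh(16, 16, 0.15, 1, 0.05)
  tg <- tag_anatomy(m)
  rf <- build_region_fields(m, tg)
  for (f in c("ventral_spot", "left_side", "right_side",
              "arterial_gradient", "venous_gradient", "rv_band", "lv_band",
              "dorsal_left_inhibition")) {
    expect_true(all(rf[[f]] >= 0 & rf[[f]] <= 1), info = f)
  }
  # ventral spot peaks (weight ~1) at azimuth 180 mid-length
  peak <- which.max(rf$ventral_spot)
  expect_lt(abs(heartloop:::ang_diff(tg$elem_azimuth[peak], 180)), 15)
  expect_lt(abs(tg$elem_axial[peak] - 0.5), 0.1)
  expect_gt(max(rf$ventral_spot), 0.9)
  # arterial gradient: 0 in the venous half, 1 at the arterial pole
  expect_true(all(rf$arterial_gradient[tg$elem_axial <= 0.5] == 0))
  expect_gt(max(rf$arterial_gradient[tg$elem_axial > 0.95]), 0.98)
  # monotone non-increasing from the arterial pole towards mid-length
  ord <- order(tg$elem_axial, decreasing = TRUE)
  g_sorted <- rf$arterial_gradient[ord]
  ax_sorted <- tg$elem_axial[ord]
  expect_true(all(diff(g_sorted[!duplicated(ax_sorted)]) <= 1e-12))
  # left+right <= 1, equality away from the seam; mirror symmetry
  expect_true(all(rf$left_side + rf$right_side <= 1 + 1e-12))
  expect_equal(rf$left_side + rf$right_side,
               rep(1, length(rf$left_side)), tolerance = 1e-12)
  expect_error(build_region_fields(m, tg, smoothing_width = 0), "positive")
})

test_that("sagittal reflection swaps the left and right weight fields", {
  m <- build_tube_mesh(16, 8, 0.15, 1, 0.05)
  tg <- tag_anatomy(m)
  rf <- build_region_fields(m, tg)
  # element mirror map: mirror the element azimuth
  az_m <- (360 - tg$elem_azimuth) %% 360
  ord <- order(round(tg$elem_azimuth, 6), tg$elem_axial)
  ord_m <- order(round(az_m, 6), tg$elem_axial)
  expect_equal(rf$left_side[ord], rf$right_side[ord_m], tolerance = 1e-9)
  expect_equal(rf$ventral_spot[ord], rf$ventral_spot[ord_m],
               tolerance = 1e-9)
})
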