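test_that("axis extraction recovers closed-form centreline lengths", {
  cyl <- make_fixture("cylinder", length = 10, radius = 0.5,
                      thickness = 0.15)
  ax <- extract_axis(cyl, 40L)
  expect_lt(abs(ax$arclength / 10 - 1), 0.005)
  arc <- make_fixture("arc", arc_radius = 5, angle = 90, radius = 0.5,
                      thickness = 0.15)
  axa <- extract_axis(arc, 40L)
  expect_lt(abs(axa$arclength / (5 * pi / 2) - 1), 0.02)
  # every extracted point close to the analytic curve
  cp <- arc$centreline$points
  dmax <- max(apply(axa$points, 1, function(p)
    min(sqrt(colSums((t(cp) - p)^2)))))
  expect_lt(dmax, 0.05 * 0.5)
  hx <- make_fixture("helix", helix_radius = 2, pitch = 3, turns = 1,
                     radius = 0.3, thickness = 0.1)
  axh <- extract_axis(hx, 40L)
  expect_lt(abs(axh$arclength / hx$centreline$length - 1), 0.01)
})

test_that("axis extraction converges with section count", {
  arc <- make_fixture("arc", arc_radius = 5, angle = 90, radius = 0.5,
                      thickness = 0.15)
  l1 <- extract_axis(arc, 20L)$arclength
  l2 <- extract_axis(arc, 40L)$arclength
  expect_lt(abs(l2 / l1 - 1), 0.005)
})

test_that("pole distance projects on the cranio-caudal axis", {
  cyl <- make_fixture("cylinder", length = 7, radius = 0.4,
                      thickness = 0.12)
  expect_equal(pole_distance(extract_axis(cyl, 20L)), 7, tolerance = 1e-6)
  hx <- make_fixture("helix", helix_radius = 2, pitch = 3, turns = 1,
                     radius = 0.3, thickness = 0.1)
  expect_equal(pole_distance(extract_axis(hx, 40L)), 3, tolerance = 0.02)
})

test_that("mean perimeter matches the equivalent-circle closed form", {
  cyl <- make_fixture("cylinder", length = 5, radius = 0.5,
                      thickness = 0.15, n_circ = 32L)
  ax <- extract_axis(cyl, 40L)
  expect_lt(abs(mean_perimeter(ax) / (2 * pi * 0.5) - 1), 0.01)
  expect_error(mean_perimeter(structure(list(area = 1:5),
                                        class = "axis_polyline")),
               "at least")
})

test_that("transverse sector separates straight, arc and helical axes", {
  cyl <- make_fixture("cylinder", length = 5, radius = 0.4,
                      thickness = 0.12)
  expect_lt(transverse_sector(extract_axis(cyl, 20L)), 15)
  # full-turn helix: projected directions about the superimposed endpoints
  # span a half circle exactly (the chord lies on the winding cylinder)
  hx <- make_fixture("helix", helix_radius = 2, pitch = 3, turns = 1,
                     radius = 0.3, thickness = 0.1)
  sec <- transverse_sector(extract_axis(hx, 40L))
  expect_gt(sec, 160); expect_lt(sec, 200)
})

test_that("measures are invariant under rigid motion and equivariant under reflection", {
  arc <- make_fixture("arc", arc_radius = 5, angle = 90, radius = 0.5,
                      thickness = 0.15)
  ax0 <- extract_axis(arc, 30L)
  set.seed(11)
  for (rep in 1:2) {
    rig <- random_rigid()
    P2 <- apply_rigid(arc$nodes, rig)
    ax2 <- extract_axis(arc, 30L, positions = P2)
    expect_equal(ax2$arclength, ax0$arclength, tolerance = 1e-6)
    expect_equal(mean_perimeter(ax2), mean_perimeter(ax0),
                 tolerance = 1e-6)
    expect_equal(transverse_sector(ax2), transverse_sector(ax0),
                 tolerance = 0.5)
  }
})

test_that("RV-LV angle reads the section-normal orientation in the frontal plane", {
  cyl <- make_fixture("cylinder", length = 2, radius = 0.2,
                      thickness = 0.06, n_axial = 20L)
  expect_equal(rv_lv_angle(cyl), 0, tolerance = 1e-6)
  arc <- make_fixture("arc", arc_radius = 3, angle = 90, radius = 0.2,
                      thickness = 0.06, n_axial = 20L)
  # section normal at axial fraction 0.6 of a 90-degree frontal arc: 54 deg
  expect_equal(rv_lv_angle(arc), 54, tolerance = 3)
  expect_error(rv_lv_angle(cyl, boundary = 0.001), "boundary")
})

test_that("material line azimuths are invariant under rigid translation", {
  run <- cached_run("control", n_circ = 10L, n_axial = 10L, n_steps = 30L)
  traj <- run$trajectory
  tab <- track_material_line(traj)
  traj2 <- traj
  traj2$positions <- traj$positions + 0.7
  tab2 <- track_material_line(traj2)
  expect_equal(tab2$azimuth, tab$azimuth, tolerance = 1e-9)
  # ventral line starts ventral
  expect_equal(tab$azimuth[1], 180, tolerance = 1e-6)
})

test_that("tube length is non-decreasing in a growth-only scenario", {
  run <- cached_run("control", n_circ = 10L, n_axial = 10L, n_steps = 30L)
  traj <- run$trajectory
  lens <- vapply(c(1, 11, 21, 31), function(k)
    extract_axis(traj$mesh, 15L,
                 positions = traj$positions[, , k])$arclength, numeric(1))
  expect_true(all(diff(lens) > -1e-6))
})
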