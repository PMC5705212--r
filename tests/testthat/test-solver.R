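small_mesh <- build_tube_mesh(6, 2, 0.3, 1, 0.1)

test_that("zero growth leaves the mesh unmoved with zero energy", {
  rest <- rest_configuration(small_mesh)
  mask <- matrix(FALSE, nrow(small_mesh$nodes), 3)
  mask[1:3, ] <- TRUE
  eq <- equilibrate(small_mesh$nodes, rest, small_mesh, mask)
  expect_equal(eq$positions, small_mesh$nodes, tolerance = 1e-12)
  expect_lt(eq$energy, 1e-20)
  expect_equal(eq$iterations, 0L)
})

test_that("uniform isotropic growth relaxes to an exact similarity", {
  g <- 0.02
  rest <- apply_growth(rest_configuration(small_mesh),
                       diag(3) * (1 + g), small_mesh, small_mesh$nodes)
  mask <- matrix(FALSE, nrow(small_mesh$nodes), 3)
  mask[1, ] <- TRUE; mask[4, c(1, 3)] <- TRUE; mask[2, 3] <- TRUE
  eq <- equilibrate(small_mesh$nodes, rest, small_mesh, mask,
                    max_iter = 60L)
  # compatible growth: zero residual energy, all distances scaled by 1+g
  expect_lt(eq$energy, 1e-14)
  pick <- cbind(c(1, 5, 10, 3), c(20, 9, 17, 24))
  d0 <- sqrt(rowSums((small_mesh$nodes[pick[, 1], ] -
                      small_mesh$nodes[pick[, 2], ])^2))
  d1 <- sqrt(rowSums((eq$positions[pick[, 1], ] -
                      eq$positions[pick[, 2], ])^2))
  expect_equal(d1 / d0, rep(1 + g, 4), tolerance = 1e-6)
})

test_that("uniform longitudinal growth elongates the free tube by exactly its rate", {
  spec <- list(k_par = rep(0.025, nrow(small_mesh$elements)),
               k_per = rep(0, nrow(small_mesh$elements)),
               k_thk = rep(0, nrow(small_mesh$elements)))
  fr <- update_frames(small_mesh, solve_morphogen(small_mesh))
  G <- heartloop:::growth_tensors(spec, fr)
  rest <- apply_growth(rest_configuration(small_mesh), G, small_mesh,
                       small_mesh$nodes)
  mask <- matrix(FALSE, nrow(small_mesh$nodes), 3)
  mask[1, ] <- TRUE; mask[4, c(1, 3)] <- TRUE; mask[2, 3] <- TRUE
  eq <- equilibrate(small_mesh$nodes, rest, small_mesh, mask,
                    max_iter = 60L)
  z0 <- small_mesh$nodes[, 3]
  z1 <- eq$positions[, 3] - eq$positions[1, 3] + z0[1]
  span0 <- diff(range(z0)); span1 <- diff(range(eq$positions[, 3]))
  expect_equal(span1 / span0, 1.025, tolerance = 1e-5)
  # transverse dimensions unchanged
  r1 <- sqrt((eq$positions[, 1] - mean(eq$positions[, 1]))^2 +
             (eq$positions[, 2] - mean(eq$positions[, 2]))^2)
  r0 <- sqrt(small_mesh$nodes[, 1]^2 + small_mesh$nodes[, 2]^2)
  expect_equal(mean(r1) / mean(r0), 1, tolerance = 1e-4)
})

test_that("equilibrate matches a generic numerical minimizer of the same energy", {
  set.seed(42)
  mesh <- build_tube_mesh(3, 1, 0.3, 0.5, 0.1)  # 6 wedge elements
  n <- nrow(mesh$nodes)
  # random anisotropic growth per element
  fr <- update_frames(mesh, solve_morphogen(mesh))
  spec <- list(k_par = stats::runif(6, -0.01, 0.05),
               k_per = stats::runif(6, -0.02, 0.02),
               k_thk = rep(0, 6))
  G <- heartloop:::growth_tensors(spec, fr)
  rest <- apply_growth(rest_configuration(mesh), G, mesh, mesh$nodes)
  mask <- matrix(FALSE, n, 3)
  mask[mesh$ring == 0L, ] <- TRUE     # clamp one end fully
  eq <- equilibrate(mesh$nodes, rest, mesh, mask, max_iter = 60L,
                    tol = 1e-12)
  mod <- heartloop:::elastic_moduli(list(E = 1, nu = 0.3))
  tt <- mesh$tets - 1L
  vol0 <- rest$vol * rest$weight
  free <- which(!as.vector(t(mask)))
  obj <- function(th) {
    P <- mesh$nodes; Pt <- as.vector(t(P)); Pt[free] <- th
    P <- matrix(Pt, n, 3, byrow = TRUE)
    heartloop:::corot_energy_grad(P, tt, rest$Binv, vol0,
                                  mod$mu, mod$lambda)$energy
  }
  grd <- function(th) {
    P <- mesh$nodes; Pt <- as.vector(t(P)); Pt[free] <- th
    P <- matrix(Pt, n, 3, byrow = TRUE)
    as.vector(t(heartloop:::corot_energy_grad(P, tt, rest$Binv, vol0,
                                              mod$mu, mod$lambda)$grad))[free]
  }
  th0 <- as.vector(t(mesh$nodes))[free]
  ref <- stats::optim(th0, obj, grd, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  e_scale <- abs(obj(th0))
  expect_lt(eq$energy, ref$value + 1e-5 * e_scale)
  expect_lt(abs(eq$energy - ref$value), 1e-5 * e_scale)
})

test_that("constrained coordinates do not move during a simulated run", {
  run <- cached_run("control", n_circ = 10L, n_axial = 10L, n_steps = 30L)
  traj <- run$trajectory
  mesh <- traj$mesh
  pole_nodes <- c(traj$tags$pole_rings$arterial, traj$tags$pole_rings$venous)
  z0 <- mesh$nodes[pole_nodes, 3]
  for (k in c(11, 21, 31)) {
    zk <- traj$positions[pole_nodes, 3, k]
    expect_lt(max(abs(zk - z0)), 1e-9 * mesh$length)
  }
  # attached dorsal nodes keep y and z
  att <- release_step(traj$constraints, 25L)
  expect_gt(length(att), 0)
  expect_lt(max(abs(traj$positions[att, 2:3, 27] - mesh$nodes[att, 2:3])),
            1e-9)
})

test_that("pole distance is conserved to solver tolerance in constrained runs", {
  run <- cached_run("control", n_circ = 10L, n_axial = 10L, n_steps = 30L)
  traj <- run$trajectory
  for (k in c(16, 31)) {
    ax <- extract_axis(traj$mesh, 20L, positions = traj$positions[, , k])
    expect_lt(abs(pole_distance(ax) - traj$mesh$length),
              1e-6 * traj$mesh$length + 0.02 * traj$mesh$length)
  }
  # the pole rings themselves: machine-level conservation
  pn <- c(traj$tags$pole_rings$arterial, traj$tags$pole_rings$venous)
  dz <- range(traj$positions[pn, 3, 31] - traj$mesh$nodes[pn, 3])
  expect_lt(max(abs(dz)), 1e-9)
})

test_that("release schedule follows the linear mid-to-pole progression", {
  mesh <- build_tube_mesh(10, 10, 0.15, 1, 0.05)
  tags <- tag_anatomy(mesh)
  cs <- make_constraints(mesh, tags, "standard",
                         list(start = 10, half_free = 45, full_free = 80))
  expect_setequal(release_step(cs, 0), cs$dorsal_nodes)
  expect_setequal(release_step(cs, 9), cs$dorsal_nodes)
  # at the half-free step the released extent is half the tube length
  att45 <- release_step(cs, 45)
  s <- mesh$ring[att45] / mesh$n_axial
  expect_true(all(abs(s - 0.5) > 0.25 - 1e-9))
  frac_att <- length(att45) / length(cs$dorsal_nodes)
  expect_lt(abs(frac_att - 0.5), 0.15)
  expect_length(release_step(cs, 80), 0)
  expect_length(release_step(cs, 90), 0)
  # persistent never releases; no_dm never attaches after setup
  csp <- make_constraints(mesh, tags, "persistent_dm")
  expect_setequal(release_step(csp, 90), csp$dorsal_nodes)
  csn <- make_constraints(mesh, tags, "no_dm")
  expect_length(release_step(csn, 15), 0)
  csf <- make_constraints(mesh, tags, "free_poles")
  m0 <- heartloop:::constraint_mask(csf, 0)
  free_pole_nodes <- setdiff(tags$pole_rings$arterial, csf$dorsal_nodes)
  expect_false(any(m0[free_pole_nodes, 3]))
  expect_error(make_constraints(mesh, tags, "bogus"), "variant")
})

test_that("equilibration energy never increases and is node-order independent", {
  mesh <- build_tube_mesh(6, 3, 0.2, 1, 0.06)
  fr <- update_frames(mesh, solve_morphogen(mesh))
  m <- nrow(mesh$elements)
  set.seed(3)
  spec <- list(k_par = stats::runif(m, 0, 0.04),
               k_per = stats::runif(m, -0.01, 0.01), k_thk = rep(0, m))
  G <- heartloop:::growth_tensors(spec, fr)
  rest <- apply_growth(rest_configuration(mesh), G, mesh, mesh$nodes)
  mask <- matrix(FALSE, nrow(mesh$nodes), 3)
  mask[mesh$ring == 0L, ] <- TRUE
  mod <- heartloop:::elastic_moduli(list(E = 1, nu = 0.3))
  e0 <- heartloop:::corot_energy_grad(mesh$nodes, mesh$tets - 1L,
                                      rest$Binv, rest$vol * rest$weight,
                                      mod$mu, mod$lambda)$energy
  eq <- equilibrate(mesh$nodes, rest, mesh, mask)
  expect_lt(eq$energy, e0)
  expect_lt(eq$residual, 1e-7)
})

test_that("sagittally mirrored scenarios produce mirrored trajectories", {
  res <- list(n_circ = 10L, n_axial = 8L)
  a <- cached_run("sweep", n_circ = res$n_circ, n_axial = res$n_axial,
                  n_steps = 40L, burst_azimuth = 270, rotation_sign = 1)
  b <- cached_run("sweep", n_circ = res$n_circ, n_axial = res$n_axial,
                  n_steps = 40L, burst_azimuth = 90, rotation_sign = -1)
  perm <- heartloop:::mirror_permutation(a$trajectory$mesh)
  for (k in c(21, 41)) {
    Pa <- a$trajectory$positions[, , k]
    Pb <- b$trajectory$positions[, , k]
    Pb_ref <- Pb[perm, ]
    Pb_ref[, 1] <- -Pb_ref[, 1]
    expect_lt(max(abs(Pa - Pb_ref)), 1e-5)
  }
  # classifier sees mirror handedness on the final states
  ca <- classify_shape(extract_axis(a$trajectory$mesh, 25L,
                                    positions = a$trajectory$positions[, , 41]))
  cb <- classify_shape(extract_axis(b$trajectory$mesh, 25L,
                                    positions = b$trajectory$positions[, , 41]))
  expect_equal(ca$metrics$torsion, -cb$metrics$torsion, tolerance = 1e-3)
})

test_that("growth application rejects invalid tensors and updates volumes", {
  rest <- rest_configuration(small_mesh)
  v0 <- sum(rest$vol * rest$weight)
  g1 <- apply_growth(rest, diag(3) * 1.01, small_mesh, small_mesh$nodes)
  expect_equal(sum(g1$vol * g1$weight) / v0, 1.01^3, tolerance = 1e-12)
  bad <- diag(c(1, -0.5, 1))
  expect_error(apply_growth(rest, bad, small_mesh, small_mesh$nodes),
               "positive definite")
})
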