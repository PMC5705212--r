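#' Constraint set for a simulation variant
#'
#' Encodes the displacement constraints of the model and their release
#' schedule. In the `standard` variant the two pole rings cannot move along
#' z (fixed pole separation) and the nodes of the two dorsal attachment
#' lines cannot move along y or z (the dorsal mesocardium: free to slide
#' along x only). The attachment is released progressively from mid-length
#' towards the poles. Variants: `free_poles` drops the pole z-fixing,
#' `no_dm` never attaches the dorsal lines (from the first growth step),
#' `persistent_dm` never releases them, `minimal` has poles only (the
#' minimal buckling model).
#'
#' The stated constraints leave rigid-body modes free (global x
#' translation while the attachment holds, and more once it is released).
#' These are removed by mean-zero gauge constraints (Lagrange rows): the
#' attached dorsal nodes have zero net x displacement per step (the
#' mesocardium does not drift sideways through the body), and once the
#' attachment is gone the pole rings have zero net translation and
#' rotation. Gauges fix the body reference frame without tethering any
#' individual node, so they are exactly mirror-symmetric.
#'
#' @param mesh a `tube_mesh`.
#' @param tags [tag_anatomy()] output.
#' @param variant one of `"standard"`, `"free_poles"`, `"no_dm"`,
#'   `"persistent_dm"`, `"minimal"`.
#' @param schedule list with `start`, `half_free`, `full_free` step numbers
#'   of the linear release (defaults 10, 45, 80: half the tube length is
#'   free at the half-free step).
#' @return An object of class `constraint_set`.
#' @export
make_constraints <- function(mesh, tags, variant = "standard",
                             schedule = list(start = 10L, half_free = 45L,
                                             full_free = 80L)) {
  variants <- c("standard", "free_poles", "no_dm", "persistent_dm", "minimal")
  if (!variant %in% variants)
    stop("unknown constraint variant: ", variant)
  if (!is.null(schedule$half_free) &&
      abs((schedule$half_free - schedule$start) /
          (schedule$full_free - schedule$start) - 0.5) > 1e-9)
    schedule$half_free <- (schedule$start + schedule$full_free) / 2
  dorsal <- unlist(tags$dorsal_lines, use.names = FALSE)
  structure(list(
    variant = variant,
    schedule = schedule,
    dorsal_nodes = dorsal,
    dorsal_s = mesh$ring[dorsal] / mesh$n_axial,
    pole_nodes = c(tags$pole_rings$arterial, tags$pole_rings$venous),
    pole_art = tags$pole_rings$arterial,
    pole_ven = tags$pole_rings$venous,
    pin_nodes = list(
      venous_dorsal = dorsal[mesh$ring[dorsal] == 0L],
      arterial_dorsal = dorsal[mesh$ring[dorsal] == mesh$n_axial]
    ),
    n_nodes = nrow(mesh$nodes)
  ), class = "constraint_set")
}

# released half-extent fraction r(step) in [0, 1]; attachment is empty from
# the full-free step onwards
release_fraction <- function(schedule, step) {
  if (step < schedule$start) return(0)
  if (step >= schedule$full_free) return(Inf)
  (step - schedule$start) / (schedule$full_free - schedule$start)
}

#' Attached dorsal-node set at a given step
#'
#' The progressive breakdown of the dorsal mesocardium: released nodes are
#' those whose axial distance from mid-length (as a fraction of the half
#' length) is below the released extent, which grows linearly from 0 at the
#' start step to 1 at the full-free step.
#'
#' @param constraints a `constraint_set`.
#' @param step 0-based step index.
#' @return integer vector of attached node indices (possibly empty).
#' @export
release_step <- function(constraints, step) {
  v <- constraints$variant
  if (v == "minimal") return(integer(0))
  if (v == "no_dm")
    return(if (step < constraints$schedule$start) constraints$dorsal_nodes
           else integer(0))
  if (v == "persistent_dm") return(constraints$dorsal_nodes)
  if (step < constraints$schedule$start) return(constraints$dorsal_nodes)
  r <- release_fraction(constraints$schedule, step)
  keep <- 2 * abs(constraints$dorsal_s - 0.5) > r
  constraints$dorsal_nodes[keep]
}

# n x 3 logical mask of fixed coordinates at a step (TRUE = fixed)
constraint_mask <- function(constraints, step) {
  n <- constraints$n_nodes
  mask <- matrix(FALSE, n, 3)
  if (constraints$variant != "free_poles")
    mask[constraints$pole_nodes, 3] <- TRUE
  attached <- release_step(constraints, step)
  if (length(attached)) mask[attached, 2:3] <- TRUE
  mask
}

# Gauge (mean-zero) constraint rows removing the rigid modes the masks
# leave free. Returns a list of numeric vectors of length 3n (dof order
# 3*(i-1)+c), or an empty list.
constraint_gauge <- function(constraints, step, positions) {
  n <- constraints$n_nodes
  attached <- release_step(constraints, step)
  dof <- function(nodes, c3) {
    v <- numeric(3 * n); v[3 * (nodes - 1) + c3] <- 1; v
  }
  if (length(attached)) {
    # net x drift of the attachment forbidden (the mesocardium does not
    # slide sideways through the body wall); every other rigid mode is
    # killed by the y/z fixings of the attachment and the poles
    return(list(dof(attached, 1)))
  }
  pn <- constraints$pole_nodes
  ctr <- colMeans(positions[pn, , drop = FALSE])
  rel <- sweep(positions[pn, , drop = FALSE], 2, ctr)
  rotrow <- function(axis) {
    v <- numeric(3 * n)
    om <- diag(3)[axis, ]
    u <- cbind(om[2] * rel[, 3] - om[3] * rel[, 2],
               om[3] * rel[, 1] - om[1] * rel[, 3],
               om[1] * rel[, 2] - om[2] * rel[, 1])
    for (c3 in 1:3) v[3 * (pn - 1) + c3] <- u[, c3]
    v
  }
  rows <- list(dof(pn, 1), dof(pn, 2), rotrow(3L))
  if (constraints$variant == "free_poles")
    rows <- c(rows, list(dof(pn, 3), rotrow(1L), rotrow(2L)))
  rows
}

elastic_moduli <- function(material) {
  E <- material$E %||% 1
  nu <- material$nu %||% 0.3
  if (nu <= -1 || nu >= 0.5) stop("Poisson ratio must be in (-1, 0.5)")
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reusable sparse assembler: the triplet (i, j) pattern returned by
# corot_assemble is constant for a fixed tet set, so the aggregation map to
# the unique CSC entries is computed once.
make_assembler <- function(ndof) {
  map <- NULL; ui <- NULL; uj <- NULL; template <- NULL
  function(i0, j0, x) {
    if (is.null(map)) {
      i1 <- i0 + 1L; j1 <- j0 + 1L
      key <- as.numeric(j1 - 1L) * ndof + i1
      ord <- order(key)
      sk <- key[ord]
      newg <- c(TRUE, sk[-1] != sk[-length(sk)])
      gid <- cumsum(newg)
      m <- integer(length(key)); m[ord] <- gid
      map <<- m
      ui <<- i1[ord][newg]; uj <<- j1[ord][newg]
    }
    xs <- accum_triplets(map, x, length(ui))
    if (is.null(template)) {
      template <<- Matrix::sparseMatrix(i = ui, j = uj, x = xs,
                                        dims = c(ndof, ndof))
    } else {
      template@x <- xs
    }
    template
  }
}

#' Rest configuration of the elastic solver
#'
#' The per-tetrahedron rest shape, stored as the inverse rest edge matrix
#' and the rest volume. Built stress-free from a set of node positions.
#'
#' @param mesh a `tube_mesh`.
#' @param positions optional node positions (defaults to the mesh's).
#' @return list with `Binv` (m x 9), `vol` (m), and the weights.
#' @export
rest_configuration <- function(mesh, positions = NULL) {
  P <- if (is.null(positions)) mesh$nodes else positions
  tt <- mesh$tets - 1L
  m <- nrow(tt)
  Binv <- matrix(0, m, 9)
  ident <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 1)
  G <- ident[rep(1, m), , drop = FALSE]
  # grow by identity from the current configuration = copy current shapes
  res <- grow_rest_shapes(P, tt, Binv, numeric(m), G, 0L)
  list(Binv = res$Binv, vol = as.numeric(res$vol0), weight = mesh$tet_weight)
}

#' Apply specified growth to the rest configuration
#'
#' Premultiplies each element's rest shape by its growth tensor; the rest
#' volume is multiplied by the tensor determinant. With
#' `strain_retention = 0` (the default stepping mode) the new rest shape is
#' the growth tensor applied to the *current equilibrated* shape - each
#' step's unrealised growth is dissipated rather than accumulated; with
#' `strain_retention = 1` growth compounds on the stored rest shape and
#' residual strain accumulates across steps.
#'
#' @param rest a rest configuration ([rest_configuration()]).
#' @param tensors m_elem x 9 world-frame growth tensors (or a single 3x3).
#' @param mesh the `tube_mesh`.
#' @param positions current node positions.
#' @param retention 0 (dissipative) or 1 (accumulating).
#' @return updated rest configuration.
#' @export
apply_growth <- function(rest, tensors, mesh, positions, retention = 0) {
  if (is.matrix(tensors) && nrow(tensors) == 3 && ncol(tensors) == 3)
    tensors <- matrix(as.numeric(tensors), 1, 9)[rep(1, nrow(mesh$elements)), ]
  ev <- apply(tensors, 1, function(g) {
    min(eigen(matrix(g, 3, 3), symmetric = TRUE, only.values = TRUE)$values)
  })
  if (any(ev <= 0)) stop("growth tensor not positive definite")
  Gtet <- tensors[mesh$tet_elem, , drop = FALSE]
  res <- grow_rest_shapes(positions, mesh$tets - 1L, rest$Binv, rest$vol,
                          Gtet, as.integer(retention != 0))
  list(Binv = res$Binv, vol = as.numeric(res$vol0), weight = rest$weight)
}

#' Constrained elastic equilibrium
#'
#' Finds node positions minimising the total corotational small-strain
#' elastic energy of the deformation of every element relative to its
#' (grown) rest shape, holding the masked coordinates fixed. Newton
#' iteration with frozen per-element rotations and energy backtracking.
#'
#' @param positions starting node positions (n x 3).
#' @param rest rest configuration.
#' @param mesh the `tube_mesh`.
#' @param mask n x 3 logical; `TRUE` coordinates are held fixed.
#' @param material list with Young modulus `E` and Poisson ratio `nu`.
#' @param tol convergence tolerance on the residual force infinity-norm.
#' @param max_iter maximum Newton iterations.
#' @param assembler optional reusable assembler from `make_assembler`.
#' @param gauge optional list of mean-zero constraint rows (length-3n
#'   vectors) enforced on the displacement increment via Lagrange
#'   multipliers; used to remove rigid-body modes without tethering nodes.
#' @param cache optional environment reusing the Cholesky factorisation
#'   pattern across calls.
#' @return list with `positions`, `energy`, `residual`, `iterations`, and
#'   per-element strain energy `density`.
#' @export
equilibrate <- function(positions, rest, mesh, mask,
                        material = list(E = 1, nu = 0.3),
                        tol = 1e-8, max_iter = 20L, assembler = NULL,
                        gauge = NULL, cache = NULL) {
  mod <- elastic_moduli(material)
  tt <- mesh$tets - 1L
  vol0 <- rest$vol * rest$weight
  n <- nrow(positions)
  free <- which(!as.vector(t(mask)))      # dof order: 3*(i-1) + c
  if (length(free) == 0L)
    stop("no free degrees of freedom")
  if (is.null(assembler)) assembler <- make_assembler(3L * n)
  P <- positions
  eg <- corot_energy_grad(P, tt, rest$Binv, vol0, mod$mu, mod$lambda)
  energy <- eg$energy
  it <- 0L
  proj_residual <- function(g) {
    # remove the components carried by the gauge reactions
    if (!length(gauge)) return(g)
    Cf <- do.call(rbind, lapply(gauge, function(v) v[free]))
    qr_ct <- qr(t(Cf))
    g - qr.fitted(qr_ct, g)
  }
  repeat {
    g <- as.vector(t(eg$grad))[free]
    res_norm <- max(abs(proj_residual(g)))
    if (res_norm < tol || it >= max_iter) break
    it <- it + 1L
    asm <- corot_assemble(P, tt, rest$Binv, vol0, mod$mu, mod$lambda)
    K <- assembler(asm$i, asm$j, asm$x)
    Kff <- K[free, free, drop = FALSE]
    Ks <- Matrix::forceSymmetric(Kff)
    imult <- if (length(gauge)) 1e-9 * mean(abs(Matrix::diag(Ks))) else 0
    ch <- NULL
    if (!is.null(cache) && identical(cache$free, free) &&
        !is.null(cache$factor)) {
      ch <- tryCatch(Matrix::update(cache$factor, Ks, mult = imult),
                     error = function(e) NULL)
    }
    if (is.null(ch)) {
      ch <- tryCatch(Matrix::Cholesky(Ks, Imult = imult, LDL = FALSE),
                     error = function(e)
                       stop("singular system: insufficient constraints to ",
                            "remove rigid-body modes (",
                            conditionMessage(e), ")"))
    }
    if (!is.null(cache)) { cache$factor <- ch; cache$free <- free }
    if (length(gauge)) {
      # range-space treatment of the mean-zero gauge constraints:
      # du = du0 - K^-1 C' (C K^-1 C')^-1 C du0
      Cf <- do.call(rbind, lapply(gauge, function(v) v[free]))
      rhs <- cbind(-g, t(Cf))
      Y <- as.matrix(Matrix::solve(ch, rhs, system = "A"))
      du0 <- Y[, 1]
      KiCt <- Y[, -1, drop = FALSE]
      S <- Cf %*% KiCt
      lam <- solve(S, as.numeric(Cf %*% du0))
      du <- du0 - KiCt %*% lam
      du <- as.numeric(du)
    } else {
      du <- as.numeric(Matrix::solve(ch, -g, system = "A"))
    }
    step_scale <- 1
    for (bt in 1:8) {
      Pn <- P
      Pt <- as.vector(t(Pn)); Pt[free] <- Pt[free] + step_scale * du
      Pn <- matrix(Pt, n, 3, byrow = TRUE)
      egn <- corot_energy_grad(Pn, tt, rest$Binv, vol0, mod$mu, mod$lambda)
      if (egn$energy <= energy + 1e-12 * (abs(energy) + 1)) break
      step_scale <- step_scale / 2
    }
    P <- Pn; eg <- egn; energy <- egn$energy
  }
  g <- as.vector(t(eg$grad))[free]
  res_norm <- if (length(g)) max(abs(proj_residual(g))) else 0
  if (res_norm >= tol * 100)
    warning(sprintf("equilibrate: residual %.3g after %d iterations",
                    res_norm, it))
  dens <- as.numeric(eg$density)
  elem_density <- as.numeric(rowsum(dens * vol0, mesh$tet_elem)) /
    as.numeric(rowsum(vol0, mesh$tet_elem))
  dimnames(P) <- dimnames(positions)
  list(positions = P, energy = energy, residual = res_norm,
       iterations = it, density = elem_density)
}

# per-element extent of the 6 wedge nodes projected on a unit direction
# (P: n x 3, elements: m x 6, dirs: m x 3 unit vectors)
element_extent <- function(P, elements, dirs) {
  acc <- matrix(0, nrow(elements), 6L)
  for (c3 in 1:3)
    acc <- acc + matrix(P[elements, c3], nrow(elements), 6L) * dirs[, c3]
  mx <- acc[, 1]; mn <- acc[, 1]
  for (k in 2:6) { mx <- pmax(mx, acc[, k]); mn <- pmin(mn, acc[, k]) }
  mx - mn
}

#' Run a full looping simulation
#'
#' Advances the model for `n_steps` steps. Each step: recompute the
#' polarizer and element frames on the current geometry, evaluate the
#' scenario's growth program, apply the growth tensors to the rest shapes,
#' update the constraint mask from the release schedule, and equilibrate.
#' Deterministic for a fixed configuration.
#'
#' @param config a scenario configuration ([scenario_config()]).
#' @return An object of class `loop_trajectory`: the mesh, tags, regions,
#'   per-step node positions (`positions[, , step + 1]`; index 1 is the
#'   initial state), and solver diagnostics.
#' @export
simulate_looping <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  mesh <- build_tube_mesh(config$n_circ, config$n_axial, config$radius,
                          config$length, config$thickness)
  tags <- tag_anatomy(mesh)
  regions <- build_region_fields(mesh, tags, config$smoothing_width,
                                 config$gradient_width, config$burst_width)
  constraints <- make_constraints(mesh, tags, config$variant,
                                  config$schedule)
  program <- scenario_program(config)
  n <- nrow(mesh$nodes)
  P <- mesh$nodes
  rest <- rest_configuration(mesh)
  assembler <- make_assembler(3L * n)
  solver_cache <- new.env(parent = emptyenv())
  nst <- config$n_steps
  positions <- array(NA_real_, c(n, 3, nst + 1))
  positions[, , 1] <- P
  # reference element extents for the linear (fraction-of-initial-size)
  # growth accumulation mode
  frames0 <- update_frames(mesh, solve_morphogen(mesh))
  ext_l0 <- element_extent(mesh$nodes, mesh$elements, frames0[, 1:3])
  ext_c0 <- element_extent(mesh$nodes, mesh$elements, frames0[, 4:6])
  energy <- residual <- numeric(nst)
  iterations <- attached_count <- integer(nst)
  polarizer <- NULL
  for (step in 0:(nst - 1L)) {
    spec <- program(step, regions)
    if (all(spec$k_par == 0) && all(spec$k_per == 0) &&
        all(spec$k_thk == 0)) {
      positions[, , step + 2] <- P
      attached_count[step + 1] <- length(release_step(constraints, step))
      next
    }
    if (is.null(polarizer) || config$recompute_polarizer)
      polarizer <- solve_morphogen(mesh, positions = P)
    frames <- update_frames(mesh, polarizer, P)
    if (identical(config$growth_accumulation, "linear")) {
      # rates are fractions of the element's initial dimensions: an element
      # already stretched to lambda times its initial length receives a
      # proportionally smaller multiplicative increment
      lam_l <- pmax(element_extent(P, mesh$elements, frames[, 1:3]) /
                      ext_l0, 0.2)
      lam_c <- pmax(element_extent(P, mesh$elements, frames[, 4:6]) /
                      ext_c0, 0.2)
      spec$k_par <- spec$k_par / lam_l
      spec$k_per <- spec$k_per / lam_c
    }
    Gel <- growth_tensors(spec, frames)
    res <- grow_rest_shapes(P, mesh$tets - 1L, rest$Binv, rest$vol,
                            Gel[mesh$tet_elem, , drop = FALSE],
                            as.integer(config$strain_retention != 0))
    rest$Binv <- res$Binv; rest$vol <- as.numeric(res$vol0)
    mask <- constraint_mask(constraints, step)
    gauge <- constraint_gauge(constraints, step, P)
    eq <- tryCatch(
      equilibrate(P, rest, mesh, mask, config$material, config$tol,
                  assembler = assembler, gauge = gauge,
                  cache = solver_cache),
      error = function(e) stop("step ", step, ": ", conditionMessage(e)))
    P <- eq$positions
    positions[, , step + 2] <- P
    energy[step + 1] <- eq$energy
    residual[step + 1] <- eq$residual
    iterations[step + 1] <- eq$iterations
    attached_count[step + 1] <- sum(mask[, 2] & !
      (seq_len(n) %in% constraints$pin_nodes$venous_dorsal))
  }
  structure(list(
    mesh = mesh, tags = tags, regions = regions, config = config,
    constraints = constraints, positions = positions,
    energy = energy, residual = residual, iterations = iterations,
    attached_count = attached_count
  ), class = "loop_trajectory")
}

#' @exportS3Method base::print
print.loop_trajectory <- function(x, ...) {
  cat(sprintf("loop_trajectory: scenario '%s', %d steps, %d nodes\n",
              x$config$scenario, x$config$n_steps, nrow(x$mesh$nodes)))
  invisible(x)
}
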