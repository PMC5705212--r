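#' Build the cylindrical heart-tube shell mesh
#'
#' Constructs a right circular cylinder of 6-node wedge ("pentahedral")
#' elements: a triangulated mid-surface extruded into matched inner and outer
#' node layers. The axis is the cranio-caudal z axis (+z cranial, arterial
#' pole), +y is ventral and +x the anatomical left. Circumferential node
#' columns sit at azimuths k*360/n_circ measured from dorsal (0 deg), with
#' the left at 90 deg, so that column 0 lies exactly dorsal and (for even
#' `n_circ`) column `n_circ/2` exactly ventral.
#'
#' The mid-surface quads are triangulated with a sagittally mirror-symmetric
#' diagonal pattern (left and right halves mirrored, alternating axially),
#' so the discretization carries no intrinsic chirality: bilaterally
#' symmetric growth programs produce bilaterally symmetric shapes.
#'
#' @param n_circ number of circumferential columns (>= 3; default 30).
#' @param n_axial number of axial element rings (>= 1; default 30).
#' @param radius mid-wall radius of the tube (model units).
#' @param length axial length of the tube.
#' @param thickness radial wall thickness (must satisfy `radius > thickness/2`).
#' @return An object of class `tube_mesh`: node positions, wedge element
#'   connectivity, the tetrahedral decomposition used by the elastic solver,
#'   and grid bookkeeping (`surface`, `ring`, `col` per node).
#' @export
build_tube_mesh <- function(n_circ = 30L, n_axial = 30L,
                            radius = 0.15, length = 1, thickness = 0.05) {
  n_circ <- as.integer(n_circ); n_axial <- as.integer(n_axial)
  if (is.na(n_circ) || n_circ < 3L)
    stop("n_circ must be an integer >= 3 (degenerate cross-section)")
  if (is.na(n_axial) || n_axial < 1L)
    stop("n_axial must be an integer >= 1")
  if (!all(is.finite(c(radius, length, thickness))) ||
      radius <= 0 || length <= 0 || thickness <= 0)
    stop("radius, length and thickness must be positive")
  if (radius <= thickness / 2)
    stop("radius must exceed thickness/2")

  grid <- tube_grid(n_circ, n_axial)
  theta <- 2 * pi * grid$col / n_circ           # azimuth, 0 = dorsal
  rho <- ifelse(grid$surface == 0L, radius - thickness / 2,
                radius + thickness / 2)
  nodes <- cbind(x = rho * sin(theta),
                 y = -rho * cos(theta),
                 z = length * grid$ring / n_axial)

  mesh <- structure(list(
    nodes = nodes,
    elements = grid$elements,
    tets = NULL, tet_elem = NULL, tet_weight = NULL,
    surface = grid$surface, ring = grid$ring, col = grid$col,
    elem_ring = grid$elem_ring, elem_col = grid$elem_col,
    n_circ = n_circ, n_axial = n_axial,
    radius = radius, length = length, thickness = thickness,
    centreline = list(kind = "cylinder",
                      points = cbind(0, 0, seq(0, length, length.out = 200)),
                      length = length, handedness = NA_character_)
  ), class = "tube_mesh")
  mesh <- add_tets(mesh)
  mesh
}

# Node/element layout shared by the constructor and the fixtures.
# Node id (1-based): surface*nc*(na+1) + ring*nc + col + 1.
tube_grid <- function(nc, na) {
  nv <- nc * (na + 1L)
  surface <- rep(c(0L, 1L), each = nv)
  ring <- rep(rep(0:na, each = nc), 2L)
  col <- rep(rep(0:(nc - 1L), na + 1L), 2L)

  vid <- function(j, k) j * nc + (k %% nc) + 1L  # mid-surface vertex id
  # mirror-symmetric diagonal pattern: d in {0 (A: k -> k+1 up), 1 (B)}
  diag_type <- function(j, k) {
    half <- k < nc / 2
    kk <- ifelse(half, k, nc - 1L - k)
    d <- (j + kk) %% 2L
    ifelse(half, d, 1L - d)
  }
  tri <- matrix(0L, 2L * nc * na, 3L)
  e_ring <- integer(2L * nc * na); e_col <- integer(2L * nc * na)
  e <- 0L
  for (j in 0:(na - 1L)) {
    for (k in 0:(nc - 1L)) {
      v00 <- vid(j, k); v01 <- vid(j, k + 1L)
      v10 <- vid(j + 1L, k); v11 <- vid(j + 1L, k + 1L)
      if (diag_type(j, k) == 0L) {
        t1 <- c(v00, v01, v11); t2 <- c(v00, v11, v10)
      } else {
        t1 <- c(v00, v01, v10); t2 <- c(v01, v11, v10)
      }
      tri[e + 1L, ] <- t1; tri[e + 2L, ] <- t2
      e_ring[e + 1:2] <- j; e_col[e + 1:2] <- k
      e <- e + 2L
    }
  }
  # wedge: inner triangle then matched outer triangle
  elements <- cbind(tri, tri + nv)
  list(surface = surface, ring = ring, col = col,
       elements = elements, elem_ring = e_ring, elem_col = e_col)
}

# Tetrahedral decomposition of each wedge, symmetrised over all six prism
# triangulations (weight 1/6 each) so the decomposition has no preferred
# diagonal and is exactly mirror-equivariant.
add_tets <- function(mesh) {
  el <- mesh$elements
  m <- nrow(el)
  perms <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                 c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  tets <- matrix(0L, 18L * m, 4L)
  r <- 0L
  for (p in seq_len(6)) {
    a <- el[, perms[p, 1]]; b <- el[, perms[p, 2]]; c3 <- el[, perms[p, 3]]
    A <- el[, perms[p, 1] + 3L]; B <- el[, perms[p, 2] + 3L]
    C <- el[, perms[p, 3] + 3L]
    tets[r + seq_len(m), ] <- cbind(a, b, c3, A)
    tets[r + m + seq_len(m), ] <- cbind(b, c3, A, B)
    tets[r + 2L * m + seq_len(m), ] <- cbind(c3, A, B, C)
    r <- r + 3L * m
  }
  # element index per tet row, matching construction order above
  tet_elem <- integer(18L * m)
  r <- 0L
  for (p in seq_len(6)) {
    tet_elem[r + seq_len(3L * m)] <- rep(seq_len(m), 3L)
    r <- r + 3L * m
  }
  # orient: positive volume in the build configuration
  v <- tet_volumes(mesh$nodes, tets - 1L)
  flip <- v < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
  }
  v <- tet_volumes(mesh$nodes, tets - 1L)
  if (any(v <= 0)) stop("degenerate element in initial configuration")
  mesh$tets <- tets
  mesh$tet_elem <- tet_elem
  mesh$tet_weight <- rep(1 / 6, 18L * m)
  mesh
}

#' Validate a tube mesh
#'
#' Checks the structural invariants: six distinct valid node indices per
#' element, matched inner/outer triangle ordering, positive element volumes,
#' and the closed-form node/element counts implied by the grid resolution.
#'
#' @param mesh a `tube_mesh`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_tube_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "tube_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  if (n != 2L * mesh$n_circ * (mesh$n_axial + 1L))
    stop("node count does not match 2*n_circ*(n_axial+1)")
  if (m != 2L * mesh$n_circ * mesh$n_axial)
    stop("element count does not match 2*n_circ*n_axial")
  if (any(mesh$elements < 1L) || any(mesh$elements > n))
    stop("element references invalid node index")
  if (any(apply(mesh$elements, 1L, function(r) length(unique(r)) != 6L)))
    stop("element with repeated node indices")
  if (any(mesh$surface[as.vector(mesh$elements[, 1:3])] != 0L) ||
      any(mesh$surface[as.vector(mesh$elements[, 4:6])] != 1L))
    stop("inner/outer surface pairing inconsistent")
  v <- tet_volumes(mesh$nodes, mesh$tets - 1L)
  if (any(v <= 0)) stop("non-positive element volume")
  invisible(TRUE)
}

#' Total wall volume of the mesh
#' @param mesh a `tube_mesh`.
#' @param positions optional n x 3 node positions (defaults to the mesh's).
#' @return total enclosed wall volume (sum of weighted tet volumes).
#' @export
mesh_volume <- function(mesh, positions = NULL) {
  P <- if (is.null(positions)) mesh$nodes else positions
  sum(tet_volumes(P, mesh$tets - 1L) * mesh$tet_weight)
}

# node ids for (surface s in 0:1, ring j, col k), vectorised
node_id <- function(mesh, s, j, k) {
  nc <- mesh$n_circ; na <- mesh$n_axial
  s * nc * (na + 1L) + j * nc + (k %% nc) + 1L
}

#' Tag anatomical regions of the tube mesh
#'
#' Labels the mesh with the anatomical vocabulary used by the growth
#' programs and the morphometry: pole rings (arterial = cranial ring,
#' venous = caudal ring), the two dorsal attachment lines (the node columns
#' flanking azimuth 0, i.e. the edges of the dorsal mesocardium), the
#' ventral line (column nearest azimuth 180), per-node and per-element
#' azimuth (0 dorsal, 90 left, 180 ventral, 270 right), and left/right and
#' arterial/venous half memberships.
#'
#' @param mesh a `tube_mesh`.
#' @return An object of class `anatomy_tags`.
#' @export
tag_anatomy <- function(mesh) {
  validate_tube_mesh(mesh)
  nc <- mesh$n_circ; na <- mesh$n_axial
  azimuth <- (360 * mesh$col / nc) %% 360

  pole_venous <- c(node_id(mesh, 0L, 0L, 0:(nc - 1L)),
                   node_id(mesh, 1L, 0L, 0:(nc - 1L)))
  pole_arterial <- c(node_id(mesh, 0L, na, 0:(nc - 1L)),
                     node_id(mesh, 1L, na, 0:(nc - 1L)))

  dorsal_cols <- c(1L, nc - 1L)
  dorsal_lines <- lapply(dorsal_cols, function(k)
    c(node_id(mesh, 0L, 0:na, k), node_id(mesh, 1L, 0:na, k)))
  names(dorsal_lines) <- c("left", "right")   # +azimuth side, -azimuth side

  ventral_col <- as.integer(round(nc / 2)) %% nc
  ventral_line <- c(node_id(mesh, 0L, 0:na, ventral_col),
                    node_id(mesh, 1L, 0:na, ventral_col))

  # element azimuth: angle of the mean unit vector of its columns
  el <- mesh$elements[, 1:3]
  th <- 2 * pi * mesh$col[el] / nc
  dim(th) <- dim(el)
  elem_azimuth <- (atan2(rowMeans(sin(th)), rowMeans(cos(th))) * 180 / pi) %% 360
  elem_axial <- (mesh$elem_ring + 0.5) / na  # element axial fraction in (0,1)

  sin_az <- sin(elem_azimuth * pi / 180)
  structure(list(
    pole_rings = list(arterial = pole_arterial, venous = pole_venous),
    dorsal_lines = dorsal_lines,
    dorsal_cols = dorsal_cols,
    ventral_line = ventral_line,
    ventral_col = ventral_col,
    azimuth = azimuth,
    elem_azimuth = elem_azimuth,
    elem_axial = elem_axial,
    left_half = which(sin_az > 1e-9),
    right_half = which(sin_az < -1e-9),
    arterial_half = which(elem_axial > 0.5),
    venous_half = which(elem_axial <= 0.5)
  ), class = "anatomy_tags")
}

# node permutation implementing the sagittal reflection x -> -x
# (column k maps to (nc - k) mod nc); returns an index vector p such that
# reflected node i corresponds to original node p[i].
mirror_permutation <- function(mesh) {
  nc <- mesh$n_circ
  node_id(mesh, mesh$surface, mesh$ring, (nc - mesh$col) %% nc)
}

#' Analytic fixture meshes for morphometry and classifier tests
#'
#' Builds tube meshes whose centreline is a known analytic curve - a
#' straight cylinder, a circular arc in the frontal (xz) plane, or a
#' circular helix of given radius, pitch, turns and handedness. The analytic
#' centreline is stored in the mesh (`$centreline`) for oracle comparisons.
#'
#' @param kind one of `"cylinder"`, `"arc"`, `"helix"`.
#' @param length cylinder length.
#' @param arc_radius,angle arc centreline radius and subtended angle (deg).
#' @param helix_radius,pitch,turns,handedness helix parameters
#'   (`handedness` is `"right"` or `"left"`; a right-handed helix winds
#'   counter-clockwise seen from the arterial, +z, end).
#' @param radius,thickness tube cross-section parameters.
#' @param n_circ,n_axial mesh resolution.
#' @return a `tube_mesh` with stored analytic centreline.
#' @export
make_fixture <- function(kind = c("cylinder", "arc", "helix"),
                         length = 1, arc_radius = 5, angle = 90,
                         helix_radius = 2, pitch = 3, turns = 1,
                         handedness = c("right", "left"),
                         radius = 0.15, thickness = 0.05,
                         n_circ = 24L, n_axial = 40L) {
  kind <- match.arg(kind)
  handedness <- match.arg(handedness)
  if (kind == "cylinder")
    return(build_tube_mesh(n_circ, n_axial, radius, length, thickness))

  r_out <- radius + thickness / 2
  if (kind == "arc") {
    if (angle <= 0 || angle > 360) stop("arc angle must be in (0, 360]")
    if (arc_radius <= r_out)
      stop("self-intersecting geometry: tube radius >= centreline curvature radius")
    ang <- angle * pi / 180
    clen <- arc_radius * ang
    centre <- function(s) {
      phi <- s * ang
      cbind(arc_radius * (1 - cos(phi)), 0, arc_radius * sin(phi))
    }
    frame <- function(s) {
      phi <- s * ang
      list(U1 = cbind(cos(phi), 0, -sin(phi)),   # -> +x at s = 0
           U2 = cbind(0, rep(1, base::length(s)), 0))
    }
  } else {
    if (turns <= 0 || helix_radius <= 0) stop("invalid helix parameters")
    cc <- pitch / (2 * pi)
    kappa <- helix_radius / (helix_radius^2 + cc^2)
    if (r_out >= 1 / kappa)
      stop("self-intersecting geometry: tube radius >= centreline curvature radius")
    tmax <- 2 * pi * turns
    clen <- turns * sqrt((2 * pi * helix_radius)^2 + pitch^2)
    sgn <- if (handedness == "right") 1 else -1
    centre <- function(s) {
      t <- s * tmax
      cbind(helix_radius * (cos(t) - 1), sgn * helix_radius * sin(t), cc * t)
    }
    frame <- function(s) {
      t <- s * tmax
      sp <- sqrt(helix_radius^2 + cc^2)
      Tg <- cbind(-helix_radius * sin(t), sgn * helix_radius * cos(t),
                  rep(cc, base::length(t))) / sp
      N <- cbind(-cos(t), -sgn * sin(t), rep(0, base::length(t)))
      B <- cbind(Tg[, 2] * N[, 3] - Tg[, 3] * N[, 2],
                 Tg[, 3] * N[, 1] - Tg[, 1] * N[, 3],
                 Tg[, 1] * N[, 2] - Tg[, 2] * N[, 1])
      list(U1 = N, U2 = B)
    }
  }

  mesh <- build_tube_mesh(n_circ, n_axial, radius, 1, thickness)
  s <- mesh$ring / n_axial
  theta <- 2 * pi * mesh$col / n_circ
  rho <- ifelse(mesh$surface == 0L, radius - thickness / 2,
                radius + thickness / 2)
  C <- centre(s); fr <- frame(s)
  # reduces to the straight layout when the curve is the z axis
  mesh$nodes <- C + rho * sin(theta) * fr$U1 - rho * cos(theta) * fr$U2
  colnames(mesh$nodes) <- c("x", "y", "z")
  sfine <- seq(0, 1, length.out = 400)
  mesh$centreline <- list(kind = kind, points = centre(sfine), length = clen,
                          handedness = if (kind == "helix") handedness
                                       else NA_character_)
  mesh$length <- clen
  # re-orient tets for the deformed build configuration
  mesh$tets <- NULL
  mesh <- add_tets(mesh)
  mesh
}

#' @exportS3Method base::print
print.tube_mesh <- function(x, ...) {
  cat(sprintf(
    "tube_mesh: %d nodes, %d wedge elements (%d x %d grid)\n",
    nrow(x$nodes), nrow(x$elements), x$n_circ, x$n_axial))
  cat(sprintf("  radius %.3g, length %.3g, thickness %.3g, centreline: %s\n",
              x$radius, x$length, x$thickness, x$centreline$kind))
  invisible(x)
}
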