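#' Steady-state morphogen field and polarizer directions
#'
#' Solves the steady diffusion (Laplace) problem on the mesh node graph with
#' the concentration clamped to 1 on the source node set (venous pole) and 0
#' on the sink set (arterial pole). The polarizer direction of each element
#' is the negative concentration gradient, projected onto the element's
#' tangent plane and normalised: it points from the venous towards the
#' arterial pole and follows the tube axis as the tube bends.
#'
#' @param mesh a `tube_mesh`.
#' @param source,sink node index sets clamped to 1 and 0 (defaults: the
#'   venous and arterial pole rings).
#' @param positions optional deformed node positions.
#' @return list with `concentration` (per node, in `[0, 1]`) and
#'   `direction` (m x 3 unit vectors per element).
#' @export
solve_morphogen <- function(mesh, source = NULL, sink = NULL,
                            positions = NULL) {
  P <- if (is.null(positions)) mesh$nodes else positions
  tags_needed <- is.null(source) || is.null(sink)
  if (tags_needed) {
    nc <- mesh$n_circ; na <- mesh$n_axial
    if (is.null(source))
      source <- c(node_id(mesh, 0L, 0L, 0:(nc - 1L)),
                  node_id(mesh, 1L, 0L, 0:(nc - 1L)))
    if (is.null(sink))
      sink <- c(node_id(mesh, 0L, na, 0:(nc - 1L)),
                node_id(mesh, 1L, na, 0:(nc - 1L)))
  }
  if (length(source) == 0L || length(sink) == 0L)
    stop("source and sink must be non-empty")
  if (length(intersect(source, sink)) > 0L)
    stop("source and sink must be disjoint")

  n <- nrow(P)
  # unique edges from the tetrahedral decomposition
  tt <- mesh$tets
  ed <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
              tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ed <- unique(ed)
  len <- sqrt(rowSums((P[ed[, 1], , drop = FALSE] -
                       P[ed[, 2], , drop = FALSE])^2))
  w <- 1 / pmax(len, 1e-12)
  L <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]),
                            j = c(ed[, 2], ed[, 1]),
                            x = c(-w, -w), dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)

  fixed <- c(source, sink)
  free <- setdiff(seq_len(n), fixed)
  cvec <- numeric(n)
  cvec[source] <- 1
  if (length(free) > 0L) {
    rhs <- -L[free, fixed, drop = FALSE] %*% cvec[fixed]
    Lff <- L[free, free, drop = FALSE]
    sol <- tryCatch(
      Matrix::solve(Lff, rhs),
      error = function(e) stop("morphogen solve failed (mesh disconnected?): ",
                               conditionMessage(e)))
    cvec[free] <- as.numeric(sol)
  }
  cvec <- pmin(1, pmax(0, cvec))  # clip solver roundoff at the bounds

  list(concentration = cvec,
       direction = element_gradient_direction(mesh, P, cvec))
}

# per-element unit direction of -grad(c), projected on the tangent plane
element_gradient_direction <- function(mesh, P, cvec) {
  nrm <- element_normals(mesh, P)
  g <- elem_gradient(P, mesh$elements - 1L, cvec)
  d <- -g
  d <- d - rowSums(d * nrm) * nrm        # tangent-plane projection
  nd <- sqrt(rowSums(d * d))
  if (any(nd < 1e-14))
    stop("degenerate polarizer direction in element ",
         which(nd < 1e-14)[1])
  d / nd
}

# outward wall-normal per element: outer triangle centroid - inner centroid
element_normals <- function(mesh, P) {
  el <- mesh$elements
  ci <- (P[el[, 1], , drop = FALSE] + P[el[, 2], , drop = FALSE] +
         P[el[, 3], , drop = FALSE]) / 3
  co <- (P[el[, 4], , drop = FALSE] + P[el[, 5], , drop = FALSE] +
         P[el[, 6], , drop = FALSE]) / 3
  d <- co - ci
  d / sqrt(rowSums(d^2))
}

#' Per-element orthonormal growth frames
#'
#' Builds the right-handed orthonormal frame (longitudinal, circumferential,
#' wall-normal) for every element: longitudinal along the polarizer,
#' circumferential tangent to the wall and perpendicular to the polarizer
#' (wall-normal x longitudinal). Frames are recomputed on the current
#' geometry each step, so the growth orientation follows the deforming tube.
#'
#' @param mesh a `tube_mesh`.
#' @param polarizer result of [solve_morphogen()].
#' @param positions optional deformed node positions.
#' @return m x 9 matrix; each row is the frame (l, c, n) column-major.
#' @export
update_frames <- function(mesh, polarizer, positions = NULL) {
  P <- if (is.null(positions)) mesh$nodes else positions
  nrm <- element_normals(mesh, P)
  l <- polarizer$direction
  # orthonormalise: remove normal component from l, c = n x l
  l <- l - rowSums(l * nrm) * nrm
  ln <- sqrt(rowSums(l^2))
  if (any(ln < 1e-12))
    stop("degenerate element frame in element ", which(ln < 1e-12)[1])
  l <- l / ln
  cc <- cbind(nrm[, 2] * l[, 3] - nrm[, 3] * l[, 2],
              nrm[, 3] * l[, 1] - nrm[, 1] * l[, 3],
              nrm[, 1] * l[, 2] - nrm[, 2] * l[, 1])
  cc <- cc / sqrt(rowSums(cc^2))
  cbind(l, cc, nrm)
}

raised_cosine <- function(d, halfwidth) {
  u <- pmin(1, abs(d) / halfwidth)
  0.5 * (1 + cos(pi * u))
}

ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

smoothstep01 <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Smooth anatomical region weight fields
#'
#' Computes the per-element weights, all in `[0, 1]`, that modulate the
#' growth programs: the ventral spot (peak 1 at azimuth 180, mid-length),
#' left/right side weights (mirror images, summing to 1), the arterial
#' gradient (1 at the arterial pole, 0 from mid-length caudally) and its
#' venous mirror, the RV and LV circumferential bands, and the dorsal-left
#' inhibition zone. Weights are smooth raised-cosine / smoothstep profiles
#' in the material azimuth and axial fraction; `smoothing_width` (in element
#' edge lengths) sets the width of band borders.
#'
#' @param mesh a `tube_mesh`.
#' @param tags [tag_anatomy()] output.
#' @param smoothing_width border smoothing width in element edge lengths
#'   (> 0; default 2).
#' @param gradient_width axial extent (fraction of tube length) over which
#'   the arterial pole gradient falls from 1 to 0 starting at mid-length;
#'   the gradient saturates at 1 closer to the pole.
#' @param burst_width axial extent (fraction of tube length, from the venous
#'   pole) of the venous ingression zone carrying the burst; 1 at the pole,
#'   0 beyond `burst_width`.
#' @param bands axial band limits: list with `rv` and `lv` fraction ranges.
#' @return An object of class `region_fields` (list of per-element vectors).
#' @export
build_region_fields <- function(mesh, tags, smoothing_width = 2,
                                gradient_width = 0.5, burst_width = 0.3,
                                bands = list(rv = c(0.60, 0.85),
                                             lv = c(0.35, 0.60))) {
  if (smoothing_width <= 0) stop("smoothing_width must be positive")
  az <- tags$elem_azimuth
  s <- tags$elem_axial
  ds <- smoothing_width / mesh$n_axial      # axial border width (fraction)

  band_weight <- function(range) {
    lo <- smoothstep01((s - (range[1] - ds / 2)) / ds)
    hi <- 1 - smoothstep01((s - (range[2] - ds / 2)) / ds)
    pmin(lo, hi)
  }

  th <- az * pi / 180
  fields <- list(
    ventral_spot = raised_cosine(ang_diff(az, 180), 90) *
                   raised_cosine(s - 0.5, 0.25),
    left_side = 0.5 * (1 + sin(th)),
    right_side = 0.5 * (1 - sin(th)),
    sin_azimuth = sin(th),
    arterial_gradient = smoothstep01((s - 0.5) / gradient_width),
    venous_gradient = smoothstep01((burst_width - s) / burst_width),
    rv_band = band_weight(bands$rv),
    lv_band = band_weight(bands$lv),
    dorsal_left_inhibition = raised_cosine(ang_diff(az, 45), 67.5),
    azimuth = az,
    axial = s
  )
  structure(fields, class = "region_fields")
}

# raised-cosine azimuthal burst profile: 1 at the peak azimuth, 0 at the
# antipode ("decreasing smoothly" from the peak to the opposite side)
burst_profile <- function(azimuth, peak_azimuth) {
  0.5 * (1 + cos((azimuth - peak_azimuth) * pi / 180))
}
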