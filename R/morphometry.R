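#' Mid-surface triangulation of a tube mesh
#'
#' Vertices are the midpoints of matched inner/outer node pairs; faces are
#' the wedge elements' mid-triangles (one triangle per wedge).
#'
#' @param mesh a `tube_mesh`.
#' @param positions optional deformed node positions.
#' @return list with `V` (nv x 3), `F` (nf x 3), and per-vertex `ring`/`col`.
#' @export
mid_surface <- function(mesh, positions = NULL) {
  P <- if (is.null(positions)) mesh$nodes else positions
  nv <- nrow(P) / 2L
  V <- (P[seq_len(nv), , drop = FALSE] + P[nv + seq_len(nv), , drop = FALSE]) / 2
  Fc <- mesh$elements[, 1:3]
  list(V = V, F = Fc, ring = mesh$ring[seq_len(nv)],
       col = mesh$col[seq_len(nv)], n_circ = mesh$n_circ,
       n_axial = mesh$n_axial)
}

# intersection polygon of a triangulated surface with a plane, restricted to
# a ball around `centre`; returns ordered 3D loop vertices or NULL
slice_surface <- function(V, F, point, normal, centre, window) {
  d <- as.numeric(V %*% normal) - sum(point * normal)
  # deterministic nudge: vertices exactly on the plane would give triangles
  # with three crossing edges and break the loop chaining
  eps <- 1e-9 * max(abs(d), 1e-12)
  d[abs(d) < eps] <- eps
  side <- d > 0
  s1 <- side[F[, 1]]; s2 <- side[F[, 2]]; s3 <- side[F[, 3]]
  cut <- (s1 != s2) | (s2 != s3)
  if (!any(cut)) return(NULL)
  Fc <- F[cut, , drop = FALSE]
  # for each cut triangle, the two crossing edges (as sorted node pairs)
  segs <- vector("list", nrow(Fc))
  edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  for (t in seq_len(nrow(Fc))) {
    vv <- Fc[t, ]
    dd <- d[vv]
    cross <- which(c(dd[1] * dd[2] <= 0 & dd[1] != dd[2],
                     dd[2] * dd[3] <= 0 & dd[2] != dd[3],
                     dd[3] * dd[1] <= 0 & dd[3] != dd[1]))
    pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))[cross, , drop = FALSE]
    if (nrow(pairs) < 2) next
    pairs <- pairs[1:2, , drop = FALSE]
    keys <- character(2); pts <- matrix(0, 2, 3)
    for (q in 1:2) {
      a <- vv[pairs[q, 1]]; b <- vv[pairs[q, 2]]
      w <- d[a] / (d[a] - d[b])
      pts[q, ] <- (1 - w) * V[a, ] + w * V[b, ]
      keys[q] <- edge_key(a, b)
    }
    segs[[t]] <- list(keys = keys, pts = pts)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0) return(NULL)
  # keep segments near the station (a coiled tube crosses the plane several
  # times; only the pass nearest the station is wanted)
  mid <- t(vapply(segs, function(s) colMeans(s$pts), numeric(3)))
  keep <- sqrt(rowSums(sweep(mid, 2, centre)^2)) <= window
  segs <- segs[keep]
  if (length(segs) < 3) return(NULL)
  # chain all closed loops through shared edge keys, return the nearest one
  keymat <- t(vapply(segs, function(s) s$keys, character(2)))
  used <- logical(length(segs))
  loops <- list()
  repeat {
    seed <- which(!used)[1]
    if (is.na(seed)) break
    used[seed] <- TRUE
    loop <- list(segs[[seed]]$pts[1, ], segs[[seed]]$pts[2, ])
    open_key <- keymat[seed, 2]
    first_key <- keymat[seed, 1]
    closed <- FALSE
    repeat {
      nxt <- which(!used &
                   (keymat[, 1] == open_key | keymat[, 2] == open_key))
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      if (keymat[nxt, 1] == open_key) {
        loop[[length(loop) + 1L]] <- segs[[nxt]]$pts[2, ]
        open_key <- keymat[nxt, 2]
      } else {
        loop[[length(loop) + 1L]] <- segs[[nxt]]$pts[1, ]
        open_key <- keymat[nxt, 1]
      }
      if (open_key == first_key) { closed <- TRUE; break }
    }
    if (length(loop) >= 4 && closed)
      loops[[length(loops) + 1L]] <- do.call(rbind, loop)[-1, , drop = FALSE]
  }
  if (length(loops) == 0) return(NULL)
  dist <- vapply(loops, function(L)
    sqrt(sum((colMeans(L) - centre)^2)), numeric(1))
  loops[[which.min(dist)]]
}

# area, perimeter and area-centroid of a (nearly) planar 3D polygon
polygon_stats <- function(poly, normal) {
  nrm <- normal / sqrt(sum(normal^2))
  o <- colMeans(poly)
  u <- poly[1, ] - o
  u <- u - sum(u * nrm) * nrm
  u <- u / sqrt(sum(u * u))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  rel <- sweep(poly, 2, o)
  xy <- cbind(as.numeric(rel %*% u), as.numeric(rel %*% v))
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crossp <- x * yn - xn * y
  A <- sum(crossp) / 2
  cx <- sum((x + xn) * crossp) / (6 * A)
  cy <- sum((y + yn) * crossp) / (6 * A)
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  centroid <- o + cx * u + cy * v
  list(area = abs(A), perimeter = per, centroid = centroid)
}

#' Extract the tube axis by iterative perpendicular slicing
#'
#' Reconstructs the centreline of a tube the way it is measured on 3D
#' reconstructions: starting at the venous pole, the mid-surface is cut by a
#' plane perpendicular to the current local axis estimate; the centroid of
#' the section polygon is recorded, the station advances by a fixed arc
#' step, and the cutting normal is re-estimated from consecutive centroids.
#'
#' @param mesh a `tube_mesh`, or a surface list with `V` and `F` (e.g. an
#'   imported OBJ/PLY tube surface).
#' @param n_sections number of stations along the tube (>= 5).
#' @param positions optional deformed node positions (mesh input only).
#' @param start,start_normal optional start point and direction for raw
#'   surface input (defaults: the venous ring centroid and +z for a mesh).
#' @return An object of class `axis_polyline`: `points` (ordered venous to
#'   arterial), `arclength`, per-station `area` and `perimeter`, and the
#'   section polygons.
#' @export
extract_axis <- function(mesh, n_sections = 40L, positions = NULL,
                         start = NULL, start_normal = NULL) {
  if (n_sections < 5) stop("n_sections must be >= 5")
  if (inherits(mesh, "tube_mesh")) {
    ms <- mid_surface(mesh, positions)
    V <- ms$V; Fc <- ms$F
    ring0 <- which(ms$ring == 0L)
    ring1 <- which(ms$ring == 1L)
    ringN <- which(ms$ring == ms$n_axial)
    c0 <- colMeans(V[ring0, , drop = FALSE])
    c1 <- colMeans(V[ring1, , drop = FALSE])
    cN <- colMeans(V[ringN, , drop = FALSE])
    if (is.null(start)) start <- c0
    if (is.null(start_normal)) start_normal <- c1 - c0
    # arc-length estimate from the ring-centroid polyline
    ringc <- t(vapply(0:ms$n_axial, function(j)
      colMeans(V[ms$ring == j, , drop = FALSE]), numeric(3)))
    len_est <- sum(sqrt(rowSums(diff(ringc)^2)))
    rad_est <- sqrt(mean(rowSums(sweep(V[ring0, , drop = FALSE], 2, c0)^2)))
    end_point <- cN
    # close the pole openings with fan caps so stations near the ends
    # still produce closed section loops under oblique cutting planes
    nc <- ms$n_circ
    i0 <- ring0[order(ms$col[ring0])]
    iN <- ringN[order(ms$col[ringN])]
    vc0 <- nrow(V) + 1L; vcN <- nrow(V) + 2L
    V <- rbind(V, c0, cN)
    Fc <- rbind(Fc,
                cbind(vc0, i0, i0[c(2:nc, 1)]),
                cbind(vcN, iN, iN[c(2:nc, 1)]))
  } else {
    V <- mesh$V; Fc <- mesh$F
    if (is.null(start) || is.null(start_normal))
      stop("start and start_normal are required for raw surface input")
    len_est <- attr(mesh, "length_hint") %||%
      (max(V[, 3]) - min(V[, 3]))
    rad_est <- attr(mesh, "radius_hint") %||% (0.1 * len_est)
    end_point <- NULL
  }
  h <- len_est / n_sections
  pts <- list(); polys <- list(); areas <- numeric(0); pers <- numeric(0)
  if (inherits(mesh, "tube_mesh")) {
    # station guide: the material ring-centroid polyline (its centroids are
    # a stable first axis estimate); at each station the surface is cut
    # perpendicular to the guide tangent and the section polygon's area
    # centroid replaces the guide point
    guide <- resample_polyline(ringc, n_sections + 1L)
    ng <- nrow(guide)
    k <- 0L
    for (st in seq_len(ng - 1L)) {
      # stations at guide midpoints: their perpendicular planes avoid the
      # mesh's ring vertices by construction
      tgt <- guide[st + 1L, ] - guide[st, ]
      tgt <- tgt / sqrt(sum(tgt^2))
      p <- (guide[st, ] + guide[st + 1L, ]) / 2
      window <- 3 * rad_est + 2 * h
      poly <- slice_surface(V, Fc, p, tgt, p, window)
      if (is.null(poly))
        poly <- slice_surface(V, Fc, p, tgt, p, 3 * window)
      if (is.null(poly)) next
      stn <- polygon_stats(poly, tgt)
      # reject a loop that is not the local pass (an oblique plane near an
      # open end can see only a distant pass of a coiled tube)
      if (sqrt(sum((stn$centroid - p)^2)) > window) next
      k <- k + 1L
      pts[[k]] <- stn$centroid
      polys[[k]] <- poly
      areas[k] <- stn$area; pers[k] <- stn$perimeter
      rad_est <- sqrt(stn$area / pi)
    }
  } else {
    # raw surface: predictor-corrector marching from the given start
    tgt <- start_normal / sqrt(sum(start_normal^2))
    window <- 3 * rad_est + 2 * h
    p <- start + max(0.5 * h, 0.6 * rad_est) * tgt
    hh <- h
    k <- 0L
    for (st in seq_len(6L * n_sections)) {
      poly <- slice_surface(V, Fc, p, tgt, p, window)
      if (is.null(poly)) {
        # approach the far end with progressively smaller steps
        if (hh < h / 16 || k == 0L) break
        hh <- hh / 2
        p <- p - hh * tgt
        next
      }
      stn <- polygon_stats(poly, tgt)
      if (sqrt(sum((stn$centroid - p)^2)) > window) break
      k <- k + 1L
      pts[[k]] <- stn$centroid
      polys[[k]] <- poly
      areas[k] <- stn$area; pers[k] <- stn$perimeter
      rad_est <- sqrt(stn$area / pi)
      window <- 3 * rad_est + 2 * h
      if (k > 1) {
        tnew <- pts[[k]] - pts[[k - 1]]
        nt <- sqrt(sum(tnew^2))
        if (nt > 1e-12) tgt <- 0.5 * tgt + 0.5 * tnew / nt
        tgt <- tgt / sqrt(sum(tgt^2))
      }
      p <- stn$centroid + hh * tgt
    }
  }
  if (length(pts) < 3) stop("axis extraction failed: fewer than 3 sections")
  points <- do.call(rbind, pts)
  if (!is.null(start)) points <- rbind(start, points)
  if (!is.null(end_point)) points <- rbind(points, end_point)
  arclen <- sum(sqrt(rowSums(diff(points)^2)))
  structure(list(points = points, arclength = arclen,
                 area = areas, perimeter = pers, polygons = polys),
            class = "axis_polyline")
}

#' @exportS3Method base::print
print.axis_polyline <- function(x, ...) {
  cat(sprintf("axis_polyline: %d points, arc length %.4g\n",
              nrow(x$points), x$arclength))
  invisible(x)
}

#' Projected pole distance
#'
#' Separation of the two axis extremities projected on the cranio-caudal
#' (z, notochord) axis.
#' @param axis an `axis_polyline`.
#' @return length.
#' @export
pole_distance <- function(axis) {
  abs(axis$points[nrow(axis$points), 3] - axis$points[1, 3])
}

#' Equivalent-circle mean perimeter
#'
#' Mean, over `n` sections evenly distributed along the tube, of the
#' perimeter of the circular disc with the same area as the section polygon.
#' @param axis an `axis_polyline`.
#' @param n number of sections (default 10).
#' @return length.
#' @export
mean_perimeter <- function(axis, n = 10L) {
  k <- length(axis$area)
  if (k < n) stop("need at least ", n, " sections")
  idx <- unique(round(seq(1, k, length.out = n)))
  mean(2 * sqrt(pi * axis$area[idx]))
}

#' Transverse sector angle of the tube axis
#'
#' The axis is rotated so that its two extremities superimpose in the
#' cranial-view projection (the chord aligned with z); the sector is the
#' angular extent, about the common endpoint, of the projected polyline.
#' Wide for a helix, narrow for a flat loop, 0 for a straight tube.
#' @param axis an `axis_polyline`.
#' @return angle in degrees in `[0, 360]`.
#' @export
transverse_sector <- function(axis) {
  P <- axis$points
  chord <- P[nrow(P), ] - P[1, ]
  cl <- sqrt(sum(chord^2))
  if (cl < 1e-12 * axis$arclength)
    stop("degenerate axis: endpoints coincide")
  w <- chord / cl
  # orthonormal basis with w as the viewing axis
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  rel <- sweep(P, 2, P[1, ])
  xy <- cbind(as.numeric(rel %*% u), as.numeric(rel %*% v))
  r <- sqrt(rowSums(xy^2))
  # a straight axis projects to noise around the vertex: sector 0
  if (max(r) < 0.02 * axis$arclength) return(0)
  keep <- r > 0.05 * max(r)
  if (sum(keep) < 2) return(0)
  ang <- sort(atan2(xy[keep, 2], xy[keep, 1]) * 180 / pi)
  gaps <- diff(c(ang, ang[1] + 360))
  360 - max(gaps)
}

# material (arc-length) azimuth of every column of one ring: cumulative
# arc along the ring's mid-surface polygon from the dorsal column (col 0),
# normalised to 360. Equals the geometric azimuth on the undeformed mesh and
# measures circumferential material redistribution about the dorsal anchor.
ring_arc_azimuth <- function(mesh, positions, ring) {
  nc <- mesh$n_circ
  nv <- nrow(positions) / 2L
  mids <- (positions[node_id(mesh, 0L, ring, 0:(nc - 1L)), , drop = FALSE] +
           positions[node_id(mesh, 1L, ring, 0:(nc - 1L)), , drop = FALSE]) / 2
  seg <- sqrt(rowSums((mids[c(2:nc, 1), , drop = FALSE] - mids)^2))
  s <- c(0, cumsum(seg))           # s[k+1] = arc from col 0 to col k
  360 * s[1:nc] / s[nc + 1]
}

# circular mean azimuth (degrees) of a set of angles
circ_mean_deg <- function(a) {
  (atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi) %% 360
}

# azimuth (0 dorsal, 90 left) of nodes within their material cross-section
# at given positions; ring frame from the material ring centroids
node_azimuth <- function(mesh, positions, nodes) {
  vapply(nodes, function(i) {
    j <- mesh$ring[i]
    ringn <- which(mesh$ring == j)
    cj <- colMeans(positions[ringn, , drop = FALSE])
    jlo <- max(j - 1L, 0L); jhi <- min(j + 1L, mesh$n_axial)
    clo <- colMeans(positions[mesh$ring == jlo, , drop = FALSE])
    chi <- colMeans(positions[mesh$ring == jhi, , drop = FALSE])
    tg <- chi - clo; tg <- tg / sqrt(sum(tg^2))
    d0 <- c(0, -1, 0); d0 <- d0 - sum(d0 * tg) * tg
    d0 <- d0 / sqrt(sum(d0^2))
    lf <- c(tg[2] * d0[3] - tg[3] * d0[2], tg[3] * d0[1] - tg[1] * d0[3],
            tg[1] * d0[2] - tg[2] * d0[1])
    rel <- positions[i, ] - cj
    (atan2(sum(rel * lf), sum(rel * d0)) * 180 / pi) %% 360
  }, numeric(1))
}

#' Track the azimuth of a material node line over a trajectory
#'
#' For each recorded step, the mean azimuth (0 dorsal, 90 left, 180
#' ventral, 270 right) of the line's nodes within their local
#' cross-sections. Used to follow the fate of the initial ventral line.
#'
#' @param trajectory a `loop_trajectory`.
#' @param line node index set (default: the tagged ventral line).
#' @param half optionally restrict to the `"arterial"` or `"venous"` half.
#' @return data.frame with `step` and `azimuth` (degrees, unwrapped).
#' @export
track_material_line <- function(trajectory, line = NULL,
                                half = c("all", "arterial", "venous")) {
  half <- match.arg(half)
  mesh <- trajectory$mesh
  if (is.null(line)) line <- trajectory$tags$ventral_line
  s <- mesh$ring[line] / mesh$n_axial
  line <- switch(half, all = line,
                 arterial = line[s > 0.5], venous = line[s <= 0.5])
  nst <- dim(trajectory$positions)[3]
  az <- numeric(nst)
  for (k in seq_len(nst)) {
    a <- node_azimuth(mesh, trajectory$positions[, , k], line)
    az[k] <- circ_mean_deg(a)
  }
  # unwrap
  for (k in 2:nst) {
    d <- az[k] - az[k - 1]
    if (d > 180) az[k:nst] <- az[k:nst] - 360
    if (d < -180) az[k:nst] <- az[k:nst] + 360
  }
  data.frame(step = seq_len(nst) - 1L, azimuth = az)
}

#' Arterial pole rotation angle
#'
#' Signed azimuthal drift (positive toward the anatomical right, i.e.
#' clockwise seen from the arterial pole) of the ventral-line material at
#' the arterial end of the tube, between the reference step and the queried
#' step. The azimuth is the material arc-length azimuth about the dorsal
#' attachment (the rotation is a circumferential redistribution of material
#' around the dorsally anchored ring, which is how it is measured on
#' sections relative to the dorsal mesocardium).
#'
#' @param trajectory a `loop_trajectory`.
#' @param at_step step at which to evaluate (default 30).
#' @param ref_step reference step (default 10, end of field setup).
#' @return angle in degrees.
#' @export
arterial_rotation <- function(trajectory, at_step = 30L, ref_step = 10L) {
  mesh <- trajectory$mesh
  vcol <- trajectory$tags$ventral_col
  rings <- c(mesh$n_axial - 1L, mesh$n_axial)
  az_at <- function(k) {
    mean(vapply(rings, function(j)
      ring_arc_azimuth(mesh, trajectory$positions[, , k + 1L], j)[vcol + 1L],
      numeric(1)))
  }
  # the ventral line (azimuth 180) drifts toward the right (270) when the
  # pole rotates clockwise seen from the arterial pole: rightward = +drift
  az_at(at_step) - az_at(ref_step)
}

#' RV-LV axis angle
#'
#' Orientation of the right ventricle-left ventricle axis: the perpendicular
#' of the cross-section at the RV/LV band boundary, projected on the frontal
#' (xz) plane, measured against the cranio-caudal (z) axis. 0 for an
#' unlooped straight tube, approaching 90 as the RV swings to the right.
#'
#' @param trajectory a `loop_trajectory` (or a `tube_mesh` with `positions`).
#' @param positions optional node positions (defaults to the final state).
#' @param boundary axial fraction of the RV/LV boundary (default 0.6).
#' @return angle in degrees in `[0, 90]`.
#' @export
rv_lv_angle <- function(trajectory, positions = NULL, boundary = 0.6) {
  if (inherits(trajectory, "loop_trajectory")) {
    mesh <- trajectory$mesh
    if (is.null(positions))
      positions <- trajectory$positions[, , dim(trajectory$positions)[3]]
  } else {
    mesh <- trajectory
    if (is.null(positions)) positions <- mesh$nodes
  }
  jb <- round(boundary * mesh$n_axial)
  if (jb < 1 || jb > mesh$n_axial - 1) stop("boundary section not found")
  clo <- colMeans(positions[mesh$ring == jb - 1L, , drop = FALSE])
  chi <- colMeans(positions[mesh$ring == jb + 1L, , drop = FALSE])
  nrm <- chi - clo
  proj <- c(nrm[1], 0, nrm[3])   # frontal plane
  if (sqrt(sum(proj^2)) < 1e-12) return(90)
  unname(acos(abs(proj[3]) / sqrt(sum(proj^2))) * 180 / pi)
}

#' Venous pole displacement
#'
#' Signed x coordinate (positive = anatomical left) of the venous-end axis
#' centroid in the frontal projection, relative to the initial midline.
#' @param trajectory a `loop_trajectory`.
#' @param step step at which to evaluate (default: final).
#' @return signed length.
#' @export
venous_displacement <- function(trajectory, step = NULL) {
  nst <- dim(trajectory$positions)[3]
  k <- if (is.null(step)) nst else step + 1L
  mesh <- trajectory$mesh
  P <- trajectory$positions[, , k]
  c_now <- colMeans(P[mesh$ring == 0L, , drop = FALSE])
  c_ini <- colMeans(trajectory$positions[, , 1][mesh$ring == 0L, , drop = FALSE])
  c_now[1] - c_ini[1]
}

#' Full morphometric report of a trajectory
#'
#' Computes all the geometric measures at a given step: tube axis length,
#' projected pole distance, RV-LV angle, arterial rotation, transverse
#' sector, equivalent-circle mean perimeter, venous displacement, and the
#' shape classification.
#'
#' @param trajectory a `loop_trajectory`.
#' @param step step at which to evaluate (default: final step).
#' @param n_sections stations for axis extraction.
#' @return An object of class `morphometrics_report` (a list).
#' @export
morphometrics_report <- function(trajectory, step = NULL, n_sections = 40L) {
  nst <- dim(trajectory$positions)[3]
  k <- if (is.null(step)) nst - 1L else step
  P <- trajectory$positions[, , k + 1L]
  axis <- extract_axis(trajectory$mesh, n_sections, positions = P)
  cls <- classify_shape(axis, frontal = TRUE)
  rot_step <- min(k, trajectory$config$params$rot_until %||% 30L)
  structure(list(
    step = k,
    tube_length = axis$arclength,
    pole_distance = pole_distance(axis),
    rv_lv_angle_deg = rv_lv_angle(trajectory, positions = P),
    arterial_rotation_deg = arterial_rotation(trajectory, at_step = rot_step),
    transverse_sector_deg = transverse_sector(axis),
    mean_perimeter = mean_perimeter(axis),
    venous_displacement = venous_displacement(trajectory, step = k),
    shape_class = cls$label,
    shape_metrics = cls$metrics,
    resolution = c(trajectory$mesh$n_circ, trajectory$mesh$n_axial),
    axis = axis
  ), class = "morphometrics_report")
}

#' @exportS3Method base::print
print.morphometrics_report <- function(x, ...) {
  cat(sprintf("morphometrics at step %d:\n", x$step))
  cat(sprintf("  tube length       %8.4f\n", x$tube_length))
  cat(sprintf("  pole distance     %8.4f\n", x$pole_distance))
  cat(sprintf("  RV-LV angle       %8.2f deg\n", x$rv_lv_angle_deg))
  cat(sprintf("  arterial rotation %8.2f deg\n", x$arterial_rotation_deg))
  cat(sprintf("  transverse sector %8.2f deg\n", x$transverse_sector_deg))
  cat(sprintf("  mean perimeter    %8.4f\n", x$mean_perimeter))
  cat(sprintf("  venous displ.     %+8.4f (+ = left)\n",
              x$venous_displacement))
  cat(sprintf("  shape class       %s\n", x$shape_class))
  invisible(x)
}
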