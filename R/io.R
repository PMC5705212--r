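#' Load a scenario configuration from a YAML file
#'
#' An empty file yields the full-default control configuration. Unknown
#' keys are rejected with their paths; values are validated (step counts,
#' azimuth and rate ranges).
#'
#' @param path YAML config file.
#' @return validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  scenario <- raw$scenario %||% "control"
  raw$scenario <- NULL
  known <- names(scenario_config("control"))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(scenario_config, c(list(scenario = scenario), raw))
}

#' Write a scenario configuration to YAML
#' @param config a `scenario_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# FNV-1a hash of a serialized object (content fingerprint for manifests)
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Export a trajectory to disk
#'
#' Writes one legacy-ASCII VTK file per recorded step (wedge cells with
#' anatomical tags and residual-strain energy density), the final shape as
#' OBJ and PLY surfaces, the final axis polyline as CSV, the morphometrics
#' report as JSON, and a run manifest listing all files with a config hash.
#'
#' @param trajectory a `loop_trajectory`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("vtk", "obj", "ply", "csv", "json")`.
#' @param every write every `every`-th step's VTK file.
#' @return (invisibly) the manifest list.
#' @export
export_trajectory <- function(trajectory, dir,
                              formats = c("vtk", "obj", "ply", "csv",
                                          "json"),
                              every = 1L) {
  if (is.null(trajectory$positions) || dim(trajectory$positions)[3] < 1)
    stop("empty trajectory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- trajectory$mesh
  nst <- dim(trajectory$positions)[3]
  files <- character(0)
  if ("vtk" %in% formats) {
    for (k in seq(1, nst, by = every)) {
      f <- file.path(dir, sprintf("step_%03d.vtk", k - 1L))
      write_vtk_wedge(f, trajectory$positions[, , k], mesh,
                      trajectory$tags)
      files <- c(files, f)
    }
  }
  Pfin <- trajectory$positions[, , nst]
  if ("obj" %in% formats) {
    f <- file.path(dir, "final_surface.obj")
    write_obj(f, mesh, positions = Pfin)
    files <- c(files, f)
  }
  if ("ply" %in% formats) {
    f <- file.path(dir, "final_surface.ply")
    write_ply(f, mesh, positions = Pfin)
    files <- c(files, f)
  }
  rep <- morphometrics_report(trajectory)
  if ("csv" %in% formats) {
    f <- file.path(dir, "axis.csv")
    utils::write.csv(data.frame(x = rep$axis$points[, 1],
                                y = rep$axis$points[, 2],
                                z = rep$axis$points[, 3]),
                     f, row.names = FALSE)
    fd <- file.path(dir, "diagnostics.csv")
    utils::write.csv(data.frame(step = seq_along(trajectory$energy) - 1L,
                                energy = trajectory$energy,
                                residual = trajectory$residual,
                                iterations = trajectory$iterations,
                                attached = trajectory$attached_count),
                     fd, row.names = FALSE)
    files <- c(files, f, fd)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    rj <- rep[c("step", "tube_length", "pole_distance", "rv_lv_angle_deg",
                "arterial_rotation_deg", "transverse_sector_deg",
                "mean_perimeter", "venous_displacement", "shape_class")]
    jsonlite::write_json(rj, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  manifest <- list(
    scenario = trajectory$config$scenario,
    config_hash = content_hash(unclass(trajectory$config)),
    package_version = as.character(utils::packageVersion("heartloop")),
    files = basename(files),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Write a tube mesh as a legacy-ASCII VTK unstructured grid
#'
#' Wedge (pentahedral, VTK cell type 13) cells, with per-node azimuth and
#' surface tags, per-cell anatomical region weights, and (if given)
#' residual strain energy density.
#'
#' @param path output file.
#' @param positions n x 3 node positions.
#' @param mesh the `tube_mesh`.
#' @param tags optional `anatomy_tags`.
#' @param cell_data optional named list of per-element vectors.
#' @export
write_vtk_wedge <- function(path, positions, mesh, tags = NULL,
                            cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(positions); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "heartloop tube mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(positions, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 7L * m), con)
  # VTK wedge node order: bottom triangle then top triangle
  utils::write.table(cbind(6L, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(13L, m)), con)
  if (!is.null(tags)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "SCALARS azimuth double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(tags$azimuth, digits = 6), con)
    writeLines(c("SCALARS surface int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(mesh$surface), con)
  }
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 8), con)
    }
  }
  invisible(path)
}

#' Write the tube mid-surface as OBJ
#' @param path output file.
#' @param mesh a `tube_mesh` or a surface list with `V`, `F`.
#' @param positions optional deformed node positions (mesh input).
#' @param surface `"mid"`, `"inner"` or `"outer"`.
#' @param caps close the pole openings with triangle fans (default TRUE).
#' @export
write_obj <- function(path, mesh, positions = NULL, surface = "mid",
                      caps = TRUE) {
  s <- tube_surface(mesh, positions, surface, caps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# heartloop tube surface", con)
  writeLines(sprintf("v %.10g %.10g %.10g", s$V[, 1], s$V[, 2], s$V[, 3]),
             con)
  writeLines(sprintf("f %d %d %d", s$F[, 1], s$F[, 2], s$F[, 3]), con)
  invisible(path)
}

#' Write the tube mid-surface as ASCII PLY
#' @inheritParams write_obj
#' @export
write_ply <- function(path, mesh, positions = NULL, surface = "mid",
                      caps = TRUE) {
  s <- tube_surface(mesh, positions, surface, caps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(s$V)),
               "property double x", "property double y",
               "property double z",
               sprintf("element face %d", nrow(s$F)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(sprintf("%.10g %.10g %.10g", s$V[, 1], s$V[, 2], s$V[, 3]),
             con)
  writeLines(sprintf("3 %d %d %d", s$F[, 1] - 1L, s$F[, 2] - 1L,
                     s$F[, 3] - 1L), con)
  invisible(path)
}

tube_surface <- function(mesh, positions = NULL, surface = "mid",
                         caps = FALSE) {
  if (!inherits(mesh, "tube_mesh")) return(mesh)
  P <- if (is.null(positions)) mesh$nodes else positions
  nv <- nrow(P) / 2L
  V <- switch(surface,
              mid = (P[seq_len(nv), ] + P[nv + seq_len(nv), ]) / 2,
              inner = P[seq_len(nv), ],
              outer = P[nv + seq_len(nv), ])
  Fc <- mesh$elements[, 1:3]
  if (caps) {
    nc <- mesh$n_circ
    ring <- mesh$ring[seq_len(nv)]; col <- mesh$col[seq_len(nv)]
    i0 <- which(ring == 0L); i0 <- i0[order(col[i0])]
    iN <- which(ring == mesh$n_axial); iN <- iN[order(col[iN])]
    c0 <- colMeans(V[i0, , drop = FALSE])
    cN <- colMeans(V[iN, , drop = FALSE])
    V <- rbind(V, c0, cN)
    Fc <- rbind(Fc,
                cbind(nv + 1L, i0, i0[c(2:nc, 1)]),
                cbind(nv + 2L, iN, iN[c(2:nc, 1)]))
  }
  list(V = V, F = Fc)
}

#' Read a triangulated tube surface from OBJ
#' @param path OBJ file (triangular faces).
#' @return surface list with `V`, `F` usable by [extract_axis()].
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  Fc <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                              function(x)
                                as.integer(sub("/.*", "", x[1:3]))))
  list(V = V, F = Fc)
}

#' Read a triangulated tube surface from ASCII PLY
#' @param path PLY file.
#' @return surface list with `V`, `F`.
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  hdr_end <- which(ln == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", ln, value = TRUE)[1]))
  vlines <- ln[(hdr_end + 1):(hdr_end + nv)]
  flines <- ln[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  Fc <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                              function(x) as.integer(x[2:4]) + 1L))
  list(V = V, F = Fc)
}
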