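#' @name cloud_io
#' @title Read and write hemodynamic clouds
#' @description
#' Two plain-text serializations are supported. The flat CSV dialect has
#' one row per surface point with columns `x,y,z,area,nx,ny,nz,pressure,
#' velocity` followed by `wss_x_t000,wss_y_t000,wss_z_t000,...` for every
#' frame; a JSON sidecar (`<path>.json`) carries the scalar metadata
#' (subject, label, waveform parameters, geometry scalars, neck-ring
#' indices, inlet/outlet states). The VTK XML PolyData (`.vtp`) writer
#' emits the same point data as named arrays (`pressure`, `velocity`,
#' 3-component `wss_t000..`) on a vertex-only piece readable by any VTK
#' viewer. Numbers are printed with 17 significant digits, so doubles
#' round-trip bit-exactly.
NULL

.fmt <- function(x) sprintf("%.17g", x)

#' @rdname cloud_io
#' @param cloud A `hemo_cloud`.
#' @param path Output file path (`.csv`).
#' @return `write_cloud_csv` returns `path` invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  g <- cloud$geometry
  nt <- dim(cloud$wss_series)[2]
  wss_flat <- do.call(cbind, lapply(seq_len(nt), function(t)
    cloud$wss_series[, t, ]))
  colnames(wss_flat) <- as.vector(vapply(seq_len(nt) - 1L, function(t)
    sprintf("wss_%s_t%03d", c("x", "y", "z"), t), character(3)))
  tab <- cbind(x = g$surface_points[, 1], y = g$surface_points[, 2],
               z = g$surface_points[, 3], area = g$point_areas,
               nx = g$point_normals[, 1], ny = g$point_normals[, 2],
               nz = g$point_normals[, 3],
               pressure = cloud$pressure, velocity = cloud$velocity,
               wss_flat)
  lines <- c(paste(colnames(tab), collapse = ","),
             apply(tab, 1, function(r) paste(.fmt(r), collapse = ",")))
  writeLines(lines, path)
  meta <- list(subject_id = cloud$subject_id, label = cloud$label,
               parent_diameter = g$parent_diameter, radius = g$radius,
               neck_width = g$neck_width, neck_z = g$neck_z,
               shape_flag = g$shape_flag, location_flag = g$location_flag,
               neck_ring = g$neck_ring, dome_tip = g$dome_tip,
               waveform = list(period = cloud$waveform$period,
                               timestep = cloud$waveform$timestep,
                               velocities = cloud$waveform$velocities),
               parent_mean_wss = cloud$parent_mean_wss,
               inlet_state = cloud$inlet_state,
               outlet_states = cloud$outlet_states)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname cloud_io
#' @param derive Re-derive TAWSS/OSI/systolic channels after reading.
#' @return `read_cloud_csv` returns a `hemo_cloud`.
#' @export
read_cloud_csv <- function(path, derive = TRUE) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  wf <- structure(list(period = meta$waveform$period,
                       timestep = meta$waveform$timestep,
                       times = (seq_along(meta$waveform$velocities) - 1L) *
                         meta$waveform$timestep,
                       velocities = meta$waveform$velocities),
                  class = "flow_waveform")
  n <- nrow(tab)
  nt <- length(wf$velocities)
  wss <- array(0, dim = c(n, nt, 3))
  for (t in seq_len(nt) - 1L) {
    wss[, t + 1L, 1] <- tab[[sprintf("wss_x_t%03d", t)]]
    wss[, t + 1L, 2] <- tab[[sprintf("wss_y_t%03d", t)]]
    wss[, t + 1L, 3] <- tab[[sprintf("wss_z_t%03d", t)]]
  }
  g <- structure(list(
    surface_points = as.matrix(tab[, c("x", "y", "z")]),
    point_areas = tab$area,
    point_normals = as.matrix(tab[, c("nx", "ny", "nz")]),
    neck_ring = as.integer(meta$neck_ring),
    dome_tip = as.integer(meta$dome_tip),
    parent_diameter = meta$parent_diameter, radius = meta$radius,
    neck_width = meta$neck_width, neck_z = meta$neck_z,
    shape_flag = meta$shape_flag, location_flag = meta$location_flag
  ), class = "sac_geometry")
  dimnames(g$surface_points) <- NULL
  dimnames(g$point_normals) <- NULL
  cloud <- structure(list(
    geometry = g, waveform = wf, wss_series = wss,
    pressure = tab$pressure, velocity = tab$velocity,
    parent_mean_wss = meta$parent_mean_wss,
    inlet_state = as.list(meta$inlet_state),
    outlet_states = lapply(seq_len(nrow(meta$outlet_states)), function(i)
      as.list(meta$outlet_states[i, ])),
    label = meta$label, subject_id = meta$subject_id
  ), class = "hemo_cloud")
  if (derive) cloud <- derive_channels(cloud)
  cloud
}

#' @rdname cloud_io
#' @export
write_cloud_vtp <- function(cloud, path) {
  g <- cloud$geometry
  n <- nrow(g$surface_points)
  nt <- dim(cloud$wss_series)[2]
  da <- function(name, values, ncomp = 1L, type = "Float64")
    sprintf('      <DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n        %s\n      </DataArray>',
            type, name, ncomp, paste(.fmt(values), collapse = " "))
  arrays <- c(
    da("pressure", cloud$pressure),
    da("velocity", cloud$velocity),
    da("area", g$point_areas),
    da("normals", as.vector(t(g$point_normals)), 3L),
    vapply(seq_len(nt) - 1L, function(t)
      da(sprintf("wss_t%03d", t), as.vector(t(cloud$wss_series[, t + 1L, ])),
         3L), character(1))
  )
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
    '  <PolyData>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="%d">', n, n),
    '    <Points>',
    sprintf('      <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n        %s\n      </DataArray>',
            paste(.fmt(as.vector(t(g$surface_points))), collapse = " ")),
    '    </Points>',
    '    <Verts>',
    sprintf('      <DataArray type="Int64" Name="connectivity" format="ascii">\n        %s\n      </DataArray>',
            paste(seq_len(n) - 1L, collapse = " ")),
    sprintf('      <DataArray type="Int64" Name="offsets" format="ascii">\n        %s\n      </DataArray>',
            paste(seq_len(n), collapse = " ")),
    '    </Verts>',
    '    <PointData>',
    arrays,
    '    </PointData>',
    '    </Piece>',
    '  </PolyData>',
    '</VTKFile>')
  writeLines(xml, path)
  invisible(path)
}

#' @rdname cloud_io
#' @return `read_cloud_vtp` returns a list with `points` (n x 3),
#'   and the named point-data arrays (`pressure`, `velocity`, `area`,
#'   `normals`, `wss` as n x frames x 3).
#' @export
read_cloud_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)),
                                            "\\s+")[[1]])
  pts_node <- xml2::xml_find_first(doc, ".//Points/DataArray")
  pts <- matrix(num(pts_node), ncol = 3, byrow = TRUE)
  pd <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  out <- list(points = pts)
  wss_frames <- list()
  for (nd in pd) {
    nm <- xml2::xml_attr(nd, "Name")
    ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
    vals <- num(nd)
    if (ncomp > 1) vals <- matrix(vals, ncol = ncomp, byrow = TRUE)
    if (grepl("^wss_t", nm)) wss_frames[[nm]] <- vals else out[[nm]] <- vals
  }
  if (length(wss_frames)) {
    wss_frames <- wss_frames[order(names(wss_frames))]
    wss <- array(0, dim = c(nrow(pts), length(wss_frames), 3))
    for (t in seq_along(wss_frames)) wss[, t, ] <- wss_frames[[t]]
    out$wss <- wss
  }
  out
}

#' Write/read the N x 8 region point matrix as CSV
#'
#' @param regions A `region_points` object.
#' @param path Output path.
#' @return The path (writer, invisibly) or a `region_points` (reader).
#' @export
write_region_csv <- function(regions, path) {
  m <- regions$points
  lines <- c(paste(c(colnames(m), "source"), collapse = ","),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(.fmt(m[i, ]), regions$source_mask[i]),
                     collapse = ","), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_region_csv
#' @param subject_id Subject id to attach on read.
#' @export
read_region_csv <- function(path, subject_id = NA_character_) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, region_channel_names()])
  rownames(m) <- NULL
  structure(list(points = m, source_mask = tab$source, index = NULL,
                 subject_id = subject_id), class = "region_points")
}

#' Write a cohort manifest (and optionally per-subject files)
#'
#' @param cohort An `ia_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_clouds Also write one CSV per subject.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir, write_clouds = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cl) {
    g <- cl$geometry
    f <- file.path(dir, paste0(cl$subject_id, ".csv"))
    if (write_clouds) write_cloud_csv(cl, f)
    data.frame(subject_id = cl$subject_id, label = cl$label,
               radius = g$radius, neck_width = g$neck_width,
               parent_diameter = g$parent_diameter,
               shape_flag = g$shape_flag, location_flag = g$location_flag,
               n_points = nrow(g$surface_points),
               file = basename(f), stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_manifest
#' @param path Manifest path written by [write_cohort_manifest()].
#' @return `read_cohort_manifest` returns an `ia_cohort`.
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  dir <- dirname(path)
  cohort <- lapply(man$file, function(f)
    read_cloud_csv(file.path(dir, f)))
  structure(cohort, class = "ia_cohort", signal_mode = NA_character_,
            seed = NA_integer_)
}
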