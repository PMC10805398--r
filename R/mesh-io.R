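#' Read a triangle mesh from PLY or VTK PolyData
#'
#' Supports binary little-endian and ASCII PLY, and legacy ASCII VTK
#' PolyData. The mesh is passed through [validate_mesh()] on read, so
#' duplicate vertices are merged, the orientation is repaired, and a
#' structured error names the violated invariant for non-manifold or
#' non-genus-zero input.
#'
#' @param path file path; format chosen by extension (`.ply` / `.vtk`).
#' @param validate run [validate_mesh()] (default `TRUE`).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    ply = read_ply(path),
    vtk = read_vtk_polydata(path),
    stop_subshape("mesh_io", sprintf("unsupported mesh format: '%s'", ext))
  )
  if (validate) mesh <- validate_mesh(mesh) else mesh
}

#' Write a triangle mesh to PLY or VTK PolyData
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format chosen by extension (`.ply` / `.vtk`).
#' @param binary for PLY: write binary little-endian (default) or ASCII.
#' @param point_data optional named list of per-vertex numeric vectors
#'   written as VTK point-data arrays (VTK output only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE, point_data = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = binary),
    vtk = write_vtk_polydata(mesh, path, point_data = point_data),
    stop_subshape("mesh_io", sprintf("unsupported mesh format: '%s'", ext))
  )
  invisible(path)
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c(
    "ply",
    sprintf("format %s 1.0", fmt),
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    faces0 <- t(mesh$faces) - 1L
    # interleave uchar count 3 with three int32 indices per face
    counts <- as.raw(3L)
    idx <- writeBin(as.integer(faces0), raw(), size = 4, endian = "little")
    idx <- matrix(idx, nrow = 12L)
    out <- rbind(matrix(rep(counts, nf), nrow = 1L), idx)
    writeBin(as.vector(out), con)
  } else {
    writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- read_line_bin(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 1000) stop_subshape("mesh_io", "PLY header not terminated")
  }
  fmt <- sub("^format ([a-z_]+) .*$", "\\1", grep("^format", header, value = TRUE)[1])
  nv <- as.integer(sub("^element vertex (\\d+)$", "\\1", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face (\\d+)$", "\\1", grep("^element face", header, value = TRUE)[1]))
  props <- grep("^property (double|float) ", header, value = TRUE)
  vsize <- ifelse(grepl("double", props), 8L, 4L)
  if (length(vsize) != 3L) stop_subshape("mesh_io", "only x/y/z vertex properties supported")
  if (fmt == "binary_little_endian") {
    v <- matrix(readBin(con, "double", n = 3L * nv, size = vsize[1], endian = "little"),
                ncol = 3L, byrow = TRUE)
    fraw <- readBin(con, "raw", n = nf * 13L)
    fraw <- matrix(fraw, nrow = 13L)
    counts <- as.integer(fraw[1L, ])
    if (any(counts != 3L)) stop_subshape("mesh_io", "only triangular PLY faces supported")
    f <- matrix(readBin(as.vector(fraw[-1L, ]), "integer", n = 3L * nf, size = 4,
                        endian = "little"), ncol = 3L, byrow = TRUE) + 1L
  } else if (fmt == "ascii") {
    lines <- readLines(con)
    vl <- lines[seq_len(nv)]
    v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), ncol = 3L, byrow = TRUE)
    fl <- lines[nv + seq_len(nf)]
    ftok <- strsplit(trimws(fl), "\\s+")
    if (any(vapply(ftok, function(t) t[1], "") != "3"))
      stop_subshape("mesh_io", "only triangular PLY faces supported")
    f <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))), ncol = 3L, byrow = TRUE) + 1L
  } else {
    stop_subshape("mesh_io", sprintf("unsupported PLY format '%s'", fmt))
  }
  triangle_mesh(v, f)
}

# read a newline-terminated ASCII line from a binary connection
read_line_bin <- function(con) {
  chars <- raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L || ch == as.raw(10L)) break
    chars <- c(chars, ch)
  }
  sub("\r$", "", rawToChar(chars))
}

write_vtk_polydata <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "subshape surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(point_data[[nm]]), digits = 17), con)
    }
  }
  invisible(path)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop_subshape("mesh_io", "no POINTS section in VTK file")
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  toks <- numeric(0)
  i <- ip + 1L
  while (length(toks) < 3L * nv) {
    toks <- c(toks, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  v <- matrix(toks[seq_len(3L * nv)], ncol = 3L, byrow = TRUE)
  if_ <- grep("^POLYGONS", lines)[1]
  if (is.na(if_)) stop_subshape("mesh_io", "no POLYGONS section in VTK file")
  nf <- as.integer(strsplit(lines[if_], "\\s+")[[1]][2])
  ftoks <- integer(0)
  i <- if_ + 1L
  while (length(ftoks) < 4L * nf) {
    ftoks <- c(ftoks, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  fm <- matrix(ftoks[seq_len(4L * nf)], ncol = 4L, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop_subshape("mesh_io", "only triangular VTK polygons supported")
  triangle_mesh(v, fm[, 2:4] + 1L)
}
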