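#' Serialize grid-shaped objects
#'
#' Grid containers (conformal grids, deformation fields, feature sets) are
#' written as an RDS payload next to a small JSON metadata sidecar
#' (`<path>.json`) describing dims, class and provenance, so runs can be
#' inventoried without deserializing.
#'
#' @param x a `conformal_grid`, `deformation_field` or `vertex_features`.
#' @param path output path (`.rds` appended if missing).
#' @return the payload path, invisibly.
#' @export
write_grid <- function(x, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(x, path, version = 2)
  dims <- if (inherits(x, "conformal_grid")) x$dims
          else if (inherits(x, "deformation_field")) dim(x$displacement)[1:2]
          else if (inherits(x, "vertex_features")) dim(x$RD)
          else NULL
  meta <- list(class = class(x)[1], dims = dims,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package = as.character(utils::packageVersion("subshape")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}

# open-tube triangulation of the grid nodes (ring-major vertex order)
grid_tube_mesh <- function(grid) {
  pos <- grid$positions
  nu <- dim(pos)[1]; nv <- dim(pos)[2]
  v <- matrix(aperm(pos, c(2, 1, 3)), ncol = 3L)
  idx <- function(i, j) (i - 1L) * nv + ((j - 1L) %% nv) + 1L
  i <- rep(seq_len(nu - 1L), each = nv)
  j <- rep(seq_len(nv), times = nu - 1L)
  f <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  triangle_mesh(v, f)
}

#' Export grid maps for rendering
#'
#' Writes the grid's tube triangulation as VTK PolyData with the requested
#' per-node maps attached as point-data arrays (maps are `nu x nv`
#' matrices flattened in the grid's ring-major vertex order).
#'
#' @param grid a [conformal_grid()].
#' @param path output `.vtk` path.
#' @param maps named list of `nu x nv` matrices; defaults to the grid's
#'   conformal factor and mean curvature.
#' @return `path`, invisibly.
#' @export
grid_to_vtk <- function(grid, path, maps = list(lambda = grid$lambda,
                                                H = grid$H)) {
  mesh <- grid_tube_mesh(grid)
  pd <- lapply(maps, function(m) as.vector(t(m)))
  write_mesh(mesh, path, point_data = pd)
}
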