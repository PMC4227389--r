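#' Export mesh and fields to legacy-VTK ASCII
#'
#' Writes an unstructured-grid file with the tissue tag as cell data,
#' optional per-element vector/scalar fields as cell data, and optional
#' nodal fields as point data. Brain-only nodal fields (e.g. `v`) are
#' padded with `NaN` outside the brain — the documented sentinel for
#' "no transmembrane voltage here".
#'
#' @param mesh a [simplicial_mesh()].
#' @param path output `.vtk` file path.
#' @param point_data named list of nodal numeric vectors (length
#'   `n_nodes`, or `length(brain_nodes(mesh))` which are padded).
#' @param cell_data named list of per-element vectors (scalars) or
#'   2-column matrices (vectors, written with a zero z component).
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "tdcsbidomain export", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  wl(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]))
  wl(sprintf("CELLS %d %d", m, 4L * m))
  wl(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L, mesh$elements[, 2] - 1L,
             mesh$elements[, 3] - 1L))
  wl(sprintf("CELL_TYPES %d", m))
  wl(rep("5", m))

  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS tissue int 1", "LOOKUP_TABLE default")
  wl(as.character(as.integer(mesh$tissue)))
  for (nm in names(cell_data)) {
    val <- cell_data[[nm]]
    if (is.matrix(val) && ncol(val) == 2L) {
      wl(sprintf("VECTORS %s double", nm))
      wl(sprintf("%.17g %.17g 0", val[, 1], val[, 2]))
    } else {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(sprintf("%.17g", as.numeric(val)))
    }
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    bn <- brain_nodes(mesh)
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (length(val) == length(bn) && length(bn) != n) {
        full <- rep(NaN, n)
        full[bn] <- val
        val <- full
      }
      if (length(val) != n) stop("point_data '", nm, "' has wrong length")
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      wl(sprintf("%.17g", val))
    }
  }
  invisible(path)
}

#' Read back a legacy-VTK file written by [export_vtk()]
#'
#' Minimal reader for round-tripping this package's own exports (mesh,
#' tissue tags, named point/cell arrays). Not a general VTK parser.
#'
#' @param path a `.vtk` file produced by [export_vtk()].
#' @return list with `mesh`, `point_data`, `cell_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  find <- function(pat) grep(pat, lines)[1L]
  np <- as.integer(sub("POINTS (\\d+).*", "\\1", lines[find("^POINTS ")]))
  pstart <- find("^POINTS ") + 1L
  pts <- matrix(scan(text = lines[pstart:(pstart + np - 1L)], quiet = TRUE),
                ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  cl <- find("^CELLS ")
  mC <- as.integer(sub("CELLS (\\d+).*", "\\1", lines[cl]))
  ctab <- matrix(scan(text = lines[(cl + 1L):(cl + mC)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)
  elements <- ctab[, 2:4, drop = FALSE] + 1L

  read_arrays <- function(beg, end, count) {
    out <- list()
    k <- beg
    while (!is.na(k) && k <= end) {
      ln <- lines[k]
      if (grepl("^SCALARS ", ln)) {
        nm <- strsplit(ln, " ")[[1L]][2L]
        vals <- scan(text = lines[(k + 2L):(k + 1L + count)], quiet = TRUE)
        out[[nm]] <- vals
        k <- k + 2L + count
      } else if (grepl("^VECTORS ", ln)) {
        nm <- strsplit(ln, " ")[[1L]][2L]
        vals <- matrix(scan(text = lines[(k + 1L):(k + count)], quiet = TRUE),
                       ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
        out[[nm]] <- vals
        k <- k + 1L + count
      } else k <- k + 1L
    }
    out
  }
  cd_at <- find("^CELL_DATA ")
  pd_at <- find("^POINT_DATA ")
  cell_data <- if (!is.na(cd_at))
    read_arrays(cd_at + 1L, if (is.na(pd_at)) length(lines) else pd_at - 1L, mC)
  else list()
  point_data <- if (!is.na(pd_at)) read_arrays(pd_at + 1L, length(lines), np)
  else list()

  tissue <- TISSUES[as.integer(cell_data$tissue)]
  cell_data$tissue <- NULL
  list(mesh = simplicial_mesh(pts, elements, tissue),
       point_data = point_data, cell_data = cell_data)
}

#' Write probe traces to CSV
#'
#' Long format with header `time,name,quantity,value`. An empty trace set
#' produces a valid header-only file.
#'
#' @param traces the `traces` data frame of a [run_simulation()] result
#'   (or `NULL`/empty).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_probes_csv <- function(traces, path) {
  if (is.null(traces) || nrow(traces) == 0L) {
    writeLines("time,name,quantity,value", path)
    return(invisible(path))
  }
  write.csv(traces[, c("time", "name", "quantity", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
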