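#' Write a tagged mesh in Gmsh 2.2 ASCII format
#'
#' Writes nodes, triangles (element type 2) with the tissue encoded as the
#' physical-group tag, and a `$PhysicalNames` section naming each group
#' after its tissue. Coordinates are written in meters.
#'
#' @param mesh a [simplicial_mesh()].
#' @param path output file path.
#' @param tissue_ids named integer vector mapping tissue names to physical
#'   group ids; defaults to 1..5 in [TISSUES] order.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       tissue_ids = stats::setNames(seq_along(TISSUES), TISSUES)) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "2.2 0 8", "$EndMeshFormat")
  present <- TISSUES[TISSUES %in% as.character(unique(mesh$tissue))]
  wl("$PhysicalNames", as.character(length(present)))
  for (tt in present) wl(sprintf("2 %d \"%s\"", tissue_ids[[tt]], tt))
  wl("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  wl("$Nodes", as.character(n))
  wl(sprintf("%d %.17g %.17g 0", seq_len(n), mesh$nodes[, 1], mesh$nodes[, 2]))
  wl("$EndNodes")
  m <- nrow(mesh$elements)
  tags <- tissue_ids[as.character(mesh$tissue)]
  wl("$Elements", as.character(m))
  wl(sprintf("%d 2 2 %d %d %d %d %d", seq_len(m), tags, tags,
             mesh$elements[, 1], mesh$elements[, 2], mesh$elements[, 3]))
  wl("$EndElements")
  invisible(path)
}

#' Read a tagged simplicial mesh from a Gmsh 2.2 ASCII file
#'
#' Reads nodes and triangular elements and maps physical-group tags to the
#' five tissue labels. The mapping comes from, in order of precedence: the
#' `tissue_map` argument, the file's `$PhysicalNames` section (names must
#' match [TISSUES]), or the default `1..5 =` SKIN..WM order reversed
#' (`1=SKIN` ... `5=WM` is *not* assumed: the default is the same
#' `TISSUES` indexing that [write_mesh()] emits). Boundary facets are
#' recomputed as edges belonging to exactly one triangle.
#'
#' @param path input file.
#' @param tissue_map optional mapping from tissue names to physical-group
#'   ids: a named integer vector (names in [TISSUES]), or the path of a
#'   YAML file containing one (e.g. `WM: 5`), or `NULL` to use
#'   `$PhysicalNames` / defaults.
#' @return a [simplicial_mesh()].
#' @export
read_mesh <- function(path, tissue_map = NULL) {
  if (is.character(tissue_map) && length(tissue_map) == 1L && file.exists(tissue_map))
    tissue_map <- unlist(yaml::read_yaml(tissue_map))
  lines <- readLines(path)
  sec <- function(name) {
    beg <- match(paste0("$", name), lines)
    end <- match(paste0("$End", name), lines)
    if (is.na(beg) || is.na(end)) return(NULL)
    lines[(beg + 1L):(end - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1L], "2"))
    stop("unsupported mesh format (need Gmsh 2.x ASCII): ", path)

  id_to_tissue <- stats::setNames(TISSUES, seq_along(TISSUES))
  pn <- sec("PhysicalNames")
  if (!is.null(pn) && length(pn) > 1L) {
    entries <- pn[-1L]
    ids <- as.integer(vapply(strsplit(entries, " "), `[[`, "", 2L))
    nms <- gsub("\"", "", vapply(strsplit(entries, " "), `[[`, "", 3L))
    id_to_tissue <- stats::setNames(nms, ids)
  }
  if (!is.null(tissue_map))
    id_to_tissue <- stats::setNames(names(tissue_map), unname(tissue_map))

  nd <- sec("Nodes")
  n <- as.integer(nd[1L])
  ntab <- matrix(scan(text = nd[-1L], quiet = TRUE), ncol = 4, byrow = TRUE)
  nodes <- matrix(NA_real_, n, 2L)
  nodes[ntab[, 1], ] <- ntab[, 2:3, drop = FALSE]

  el <- sec("Elements")
  etab <- strsplit(el[-1L], "\\s+")
  etype <- vapply(etab, function(r) as.integer(r[2L]), integer(1))
  dims <- unique(ifelse(etype == 2L, 2L, ifelse(etype %in% c(1L, 15L), 1L, 3L)))
  if (any(etype == 4L))
    stop("mixed element dimensions: file contains tetrahedra and triangles")
  tri <- etab[etype == 2L]
  if (!length(tri)) stop("no triangular elements in ", path)
  parse_tri <- function(r) {
    ntags <- as.integer(r[3L])
    phys <- as.integer(r[4L])
    c(phys, as.integer(r[(4L + ntags):(6L + ntags)]))
  }
  ttab <- t(vapply(tri, parse_tri, integer(4)))
  phys <- ttab[, 1]
  tissue <- id_to_tissue[as.character(phys)]
  if (anyNA(tissue)) {
    bad <- unique(phys[is.na(tissue)])
    stop("physical group(s) with no tissue mapping: ", paste(bad, collapse = ", "))
  }
  if (!all(tissue %in% TISSUES)) {
    bad <- unique(tissue[!tissue %in% TISSUES])
    stop("physical group(s) mapped to unknown tissue name(s): ",
         paste(bad, collapse = ", "))
  }
  simplicial_mesh(nodes, ttab[, 2:4, drop = FALSE], tissue)
}
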