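#' Tissue labels used throughout the package
#'
#' The five head tissues, ordered from the outside in. `GM` and `WM`
#' together form the brain domain on which the bidomain equations (and the
#' transmembrane voltage `v`) live; the remaining tissues are passive volume
#' conductor.
#'
#' @export
TISSUES <- c("SKIN", "SKULL", "CSF", "GM", "WM")

#' Tissues that constitute the brain domain
#' @export
BRAIN_TISSUES <- c("GM", "WM")

#' Construct a tagged simplicial mesh
#'
#' Low-level constructor for the mesh container used by every other module.
#' Coordinates are in meters. Elements are triangles (2D) given as 1-based
#' node index triples; each carries one tissue tag. Boundary facets are the
#' edges that belong to exactly one element and are computed here unless
#' supplied.
#'
#' @param nodes numeric matrix, one row per node, columns x and y (meters).
#' @param elements integer matrix, one row per triangle, three node indices.
#' @param tissue character or factor of tissue tags, one per element; levels
#'   must be a subset of [TISSUES].
#' @param boundary_facets optional integer matrix of node pairs; recomputed
#'   from the element table when `NULL`.
#' @return an object of class `simplicial_mesh`: a list with fields
#'   `nodes`, `elements`, `tissue` (factor over [TISSUES]) and
#'   `boundary_facets`.
#' @export
simplicial_mesh <- function(nodes, elements, tissue, boundary_facets = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 2L) stop("only 2D meshes are supported: nodes must have 2 columns")
  if (ncol(elements) != 3L) stop("elements must be triangles (3 node indices per row)")
  if (length(tissue) != nrow(elements))
    stop("need exactly one tissue tag per element")
  if (any(elements < 1L) || any(elements > nrow(nodes)))
    stop("element references a node index outside 1..", nrow(nodes))
  tissue <- factor(as.character(tissue), levels = TISSUES)
  if (anyNA(tissue)) stop("unknown tissue tag; allowed: ", paste(TISSUES, collapse = ", "))

  mesh <- structure(
    list(nodes = nodes, elements = elements, tissue = tissue,
         boundary_facets = NULL),
    class = "simplicial_mesh")

  ar <- element_areas(mesh)
  if (any(ar <= 0))
    stop("degenerate or negatively oriented element(s): ",
         paste(head(which(ar <= 0), 5L), collapse = ", "),
         " (signed area <= 0)")
  mesh$boundary_facets <- if (is.null(boundary_facets)) {
    extract_boundary_facets(elements)
  } else {
    bf <- as.matrix(boundary_facets); storage.mode(bf) <- "integer"; bf
  }
  mesh
}

#' @export
print.simplicial_mesh <- function(x, ...) {
  cat("<simplicial_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elements),
      " triangles, ", nrow(x$boundary_facets), " boundary facets\n", sep = "")
  print(table(x$tissue))
  invisible(x)
}

# Edges that belong to exactly one triangle, oriented as stored.
extract_boundary_facets <- function(elements) {
  e1 <- elements[, c(1L, 2L)]; e2 <- elements[, c(2L, 3L)]; e3 <- elements[, c(3L, 1L)]
  edges <- rbind(e1, e2, e3)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- names(which(table(key) == 1L))
  edges[key %in% once, , drop = FALSE]
}

#' Signed areas of all elements (m^2)
#' @param mesh a [simplicial_mesh()]
#' @return numeric vector, one (positive) area per triangle
#' @export
element_areas <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  p2 <- mesh$nodes[el[, 2], , drop = FALSE]
  p3 <- mesh$nodes[el[, 3], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Element centroids (m)
#' @param mesh a [simplicial_mesh()]
#' @return numeric matrix, one row per element
#' @export
element_centroids <- function(mesh) {
  el <- mesh$elements
  (mesh$nodes[el[, 1], , drop = FALSE] +
   mesh$nodes[el[, 2], , drop = FALSE] +
   mesh$nodes[el[, 3], , drop = FALSE]) / 3
}

#' Indices of brain (GM/WM) elements
#' @param mesh a [simplicial_mesh()]
#' @export
brain_elements <- function(mesh) which(mesh$tissue %in% BRAIN_TISSUES)

#' Sorted node indices belonging to at least one brain element
#'
#' Nodes on the brain/extracerebral interface are included: the
#' transmembrane voltage degrees of freedom live on exactly this set.
#' @param mesh a [simplicial_mesh()]
#' @export
brain_nodes <- function(mesh) {
  sort(unique(as.vector(mesh$elements[brain_elements(mesh), ])))
}

#' Total mesh area per tissue (m^2)
#' @param mesh a [simplicial_mesh()]
#' @return named numeric vector over [TISSUES]
#' @export
tissue_areas <- function(mesh) {
  ar <- element_areas(mesh)
  vapply(TISSUES, function(tt) sum(ar[mesh$tissue == tt]), numeric(1))
}

# ---------------------------------------------------------------------------
# Phantom generation

# Ring layout for a target in-plane spacing h: radii of all node rings
# (tissue interface radii are always rings) and node count per ring.
annulus_ring_layout <- function(radii_m, h) {
  bounds <- c(0, radii_m)
  rings <- numeric(0)
  for (k in seq_len(length(bounds) - 1L)) {
    ra <- bounds[k]; rb <- bounds[k + 1L]
    nseg <- max(1L, round((rb - ra) / h))
    rings <- c(rings, seq(ra, rb, length.out = nseg + 1L)[-1L])
  }
  counts <- pmax(8L, round(2 * pi * rings / h))
  list(radii = rings, counts = counts)
}

ring_element_count <- function(layout) {
  n <- layout$counts
  # center fan + one band per consecutive ring pair
  n[1L] + sum(n[-length(n)] + n[-1L])
}

# Triangulate the band between two concentric node rings by merging the two
# angle sequences with two pointers on unrolled (monotone) angle walks;
# produces length(inner)+length(outer) triangles. Orientation is fixed by
# the caller.
triangulate_band <- function(inner_ids, inner_angles, outer_ids, outer_angles) {
  na <- length(inner_ids); nb <- length(outer_ids)
  # closed walks: visit every node once and return to the start
  ai <- c(seq_len(na), 1L)
  ib0 <- which.min((outer_angles - inner_angles[1L]) %% (2 * pi))
  bi <- c(ib0:nb, seq_len(ib0))
  Au <- inner_angles[ai]
  Bu <- outer_angles[bi]
  Bu[1L] <- Au[1L] + ((Bu[1L] - Au[1L]) %% (2 * pi))
  for (k in 2:length(Au)) if (Au[k] <= Au[k - 1L]) Au[k] <- Au[k] + 2 * pi
  for (k in 2:length(Bu)) if (Bu[k] <= Bu[k - 1L]) Bu[k] <- Bu[k] + 2 * pi
  tris <- matrix(0L, na + nb, 3L)
  i <- 1L; j <- 1L; k <- 0L
  while (i <= na || j <= nb) {
    take_a <- i <= na && (j > nb || Au[i + 1L] <= Bu[j + 1L])
    k <- k + 1L
    if (take_a) {
      tris[k, ] <- c(inner_ids[ai[i]], outer_ids[bi[j]], inner_ids[ai[i + 1L]])
      i <- i + 1L
    } else {
      tris[k, ] <- c(inner_ids[ai[i]], outer_ids[bi[j]], outer_ids[bi[j + 1L]])
      j <- j + 1L
    }
  }
  tris
}

#' Generate the five-tissue concentric-annulus head phantom
#'
#' Builds a conforming triangulation of a disc organized as a central white
#' matter (WM) disc surrounded by grey matter (GM), cerebrospinal fluid
#' (CSF), skull and scalp annuli, plus a horizontal CSF strip cutting
#' through the brain (a channel connecting the CSF annulus across the GM
#' and WM). Node rings are placed on every tissue interface radius, so the
#' annulus boundaries are resolved exactly; ring node angles are snapped to
#' the strip edge crossings so the strip boundary is crisp. Elements whose
#' centroid satisfies `|y| <= csf_strip_width/2` within radius
#' `strip_extent` are retagged CSF.
#'
#' The strip is confined to the brain region (default `strip_extent =
#' radii[2]`), so with a nonzero strip the brain splits into an upper and a
#' lower lobe; membrane waves cannot cross the channel.
#'
#' @param radii five strictly increasing outer radii in mm
#'   (WM, GM, CSF, skull, scalp); default `c(40, 50, 70, 90, 100)`.
#' @param csf_strip_width width of the horizontal CSF channel in mm
#'   (0 disables it).
#' @param target_element_count desired number of triangles; the generated
#'   count is within 20% of this.
#' @param strip_extent radius in mm up to which the strip is applied;
#'   defaults to the GM outer radius so the channel spans the brain only.
#' @return a [simplicial_mesh()] with coordinates in meters.
#' @examples
#' mesh <- build_annulus_phantom(target_element_count = 2000)
#' table(mesh$tissue)
#' @export
build_annulus_phantom <- function(radii = c(40, 50, 70, 90, 100),
                                  csf_strip_width = 10,
                                  target_element_count = 10000,
                                  strip_extent = radii[2]) {
  if (length(radii) != 5L) stop("need exactly five radii (WM, GM, CSF, skull, scalp)")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (csf_strip_width < 0) stop("csf_strip_width must be >= 0")
  if (csf_strip_width >= 2 * radii[1])
    stop("csf_strip_width must be smaller than twice the innermost radius")
  radii_m <- radii / 1000
  w2 <- csf_strip_width / 2000      # half width, meters
  strip_r <- strip_extent / 1000

  # spacing that roughly yields the requested element count, then refine the
  # guess against the exact count of the structured layout
  R <- radii_m[5L]
  h <- sqrt(4 * pi * R^2 / (sqrt(3) * target_element_count))
  if (h > min(diff(c(0, radii_m))))
    stop("target_element_count too small to resolve the thinnest annulus")
  for (it in 1:8) {
    cnt <- ring_element_count(annulus_ring_layout(radii_m, h))
    if (abs(cnt - target_element_count) / target_element_count < 0.05) break
    h <- h * sqrt(cnt / target_element_count)
  }
  layout <- annulus_ring_layout(radii_m, h)

  # nodes: center + rings (staggered), snapping angles to strip crossings
  nodes <- matrix(0, 1L + sum(layout$counts), 2L)
  ring_ids <- vector("list", length(layout$radii))
  ring_angles <- vector("list", length(layout$radii))
  nxt <- 2L
  for (j in seq_along(layout$radii)) {
    r <- layout$radii[j]; n <- layout$counts[j]
    th <- (seq_len(n) - 1L) / n * 2 * pi + (j %% 2L) * pi / n
    if (w2 > 0 && r > 1.05 * w2 && r <= strip_r + 1e-12) {
      # snap one (distinct) node to each angle where the ring crosses the
      # strip edges y = +/- w2, so the channel boundary is resolved exactly
      phi <- asin(w2 / r)
      used <- rep(FALSE, n)
      for (target in c(phi, pi - phi, pi + phi, 2 * pi - phi)) {
        d <- abs(((th - target + pi) %% (2 * pi)) - pi)
        cand <- order(d)
        pick <- cand[!used[cand]][1L]
        th[pick] <- target
        used[pick] <- TRUE
      }
      th <- sort(th %% (2 * pi))
    }
    ids <- nxt:(nxt + n - 1L)
    nodes[ids, ] <- r * cbind(cos(th), sin(th))
    ring_ids[[j]] <- ids; ring_angles[[j]] <- th
    nxt <- nxt + n
  }

  # center fan + bands
  n1 <- layout$counts[1L]
  fan <- cbind(1L, ring_ids[[1L]], c(ring_ids[[1L]][-1L], ring_ids[[1L]][1L]))
  tris <- list(fan)
  for (j in seq_len(length(layout$radii) - 1L)) {
    tris[[j + 1L]] <- triangulate_band(ring_ids[[j]], ring_angles[[j]],
                                       ring_ids[[j + 1L]], ring_angles[[j + 1L]])
  }
  elements <- do.call(rbind, tris)

  # enforce CCW orientation
  p1 <- nodes[elements[, 1], , drop = FALSE]
  p2 <- nodes[elements[, 2], , drop = FALSE]
  p3 <- nodes[elements[, 3], , drop = FALSE]
  a2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
        (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  flip <- a2 < 0
  elements[flip, ] <- elements[flip, c(1L, 3L, 2L), drop = FALSE]

  # tissue tags by centroid radius, then the CSF channel
  cen <- (nodes[elements[, 1], , drop = FALSE] +
          nodes[elements[, 2], , drop = FALSE] +
          nodes[elements[, 3], , drop = FALSE]) / 3
  cr <- sqrt(rowSums(cen^2))
  tag <- cut(cr, breaks = c(-Inf, radii_m),
             labels = c("WM", "GM", "CSF", "SKULL", "SKIN"))
  tag <- as.character(tag)
  if (w2 > 0) {
    in_strip <- abs(cen[, 2]) <= w2 + 1e-12 & cr <= strip_r + 1e-12
    tag[in_strip] <- "CSF"
  }

  simplicial_mesh(nodes, elements, tag)
}

# ---------------------------------------------------------------------------
# Electrodes

#' Place a tDCS electrode on the scalp boundary
#'
#' Selects the scalp boundary facets whose midpoint lies within
#' `arc_length/2` of the electrode center, measured along the outer circle.
#' The anode carries the (per-unit-depth) injected current; the cathode is
#' the grounded reference.
#'
#' @param mesh the phantom mesh (outer boundary on a circle).
#' @param kind `"ANODE"` or `"CATHODE"`.
#' @param center_angle angular position of the electrode center on the
#'   outer circle, radians (e.g. `pi` is (-R, 0)).
#' @param arc_length electrode size along the scalp, mm (default 10).
#' @param total_current injected current in amperes per meter of depth
#'   (anode only; default `1e-3`).
#' @return an `electrode_patch`: list with `kind`, `facets` (node pair
#'   matrix), `facet_lengths` (m) and `total_current`.
#' @export
place_electrode <- function(mesh, kind = c("ANODE", "CATHODE"),
                            center_angle, arc_length = 10,
                            total_current = 1e-3) {
  kind <- match.arg(kind)
  bf <- mesh$boundary_facets
  mid <- (mesh$nodes[bf[, 1], , drop = FALSE] + mesh$nodes[bf[, 2], , drop = FALSE]) / 2
  R <- max(sqrt(rowSums(mesh$nodes^2)))
  th <- atan2(mid[, 2], mid[, 1])
  # arc distance of facet midpoints from the electrode center
  dth <- abs(((th - center_angle + pi) %% (2 * pi)) - pi)
  sel <- which(R * dth <= (arc_length / 1000) / 2)
  if (length(sel) == 0L)
    stop("electrode arc selects no boundary facets; arc_length too small for this mesh resolution")
  facets <- bf[sel, , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[facets[, 1], , drop = FALSE] -
                       mesh$nodes[facets[, 2], , drop = FALSE])^2))
  structure(list(kind = kind, facets = facets, facet_lengths = len,
                 center_angle = center_angle, arc_length = arc_length,
                 total_current = if (kind == "ANODE") total_current else 0),
            class = "electrode_patch")
}

#' @export
print.electrode_patch <- function(x, ...) {
  cat("<electrode_patch> ", x$kind, ": ", nrow(x$facets), " facets, ",
      format(sum(x$facet_lengths) * 1000, digits = 4), " mm total",
      if (x$kind == "ANODE") paste0(", I = ", format(x$total_current), " A"), "\n",
      sep = "")
  invisible(x)
}
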