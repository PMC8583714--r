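#' Geometry of the osteotomised bone
#'
#' Axisymmetric description of a transversely osteotomised diaphysis: a
#' cortical tube (endosteal/periosteal diameters) interrupted by a
#' distraction gap, with a marrow-filled cavity inside each fragment.
#' `current_gap` grows as distraction proceeds; `initial_gap` is the
#' osteotomy gap at surgery.
#'
#' @param endosteal_diameter Inner cortical diameter in mm.
#' @param periosteal_diameter Outer cortical diameter in mm.
#' @param initial_gap Osteotomy gap in mm.
#' @param fragment_length Modelled length of each bone fragment in mm.
#' @param current_gap Present gap (initial gap plus distraction so far), mm.
#' @return An object of class `do_geometry`.
#' @examples
#' do_geometry()  # the sheep metatarsus defaults: 12/16 mm, 1 mm gap
#' @export
do_geometry <- function(endosteal_diameter = 12, periosteal_diameter = 16,
                        initial_gap = 1, fragment_length = 30,
                        current_gap = initial_gap) {
  if (!(periosteal_diameter > endosteal_diameter && endosteal_diameter > 0))
    stop("need periosteal_diameter > endosteal_diameter > 0 (zero wall thickness?)")
  if (initial_gap <= 0) stop("initial_gap must be positive")
  if (current_gap < initial_gap - 1e-12)
    stop("current_gap cannot be smaller than initial_gap")
  if (fragment_length <= 0) stop("fragment_length must be positive")
  structure(list(endosteal_diameter = endosteal_diameter,
                 periosteal_diameter = periosteal_diameter,
                 initial_gap = initial_gap,
                 fragment_length = fragment_length,
                 current_gap = current_gap),
            class = "do_geometry")
}

#' @export
print.do_geometry <- function(x, ...) {
  cat(sprintf(paste0("Osteotomised bone geometry: cortex %.3g/%.3g mm ",
                     "(endosteal/periosteal),\n  gap %.3g mm (initial %.3g), ",
                     "fragments %.3g mm\n"),
              x$endosteal_diameter, x$periosteal_diameter, x$current_gap,
              x$initial_gap, x$fragment_length))
  invisible(x)
}

# Internal: structured grid lines for one segment, spacing <= h
.grid_lines <- function(a, b, h, n_min = 1) {
  n <- max(n_min, ceiling((b - a) / h - 1e-9))
  seq(a, b, length.out = n + 1)
}

#' Build the axisymmetric finite-element mesh
#'
#' Structured 4-node quadrilateral discretisation in the (r, z) plane:
#' marrow occupies `r in [0, r_in]` inside each fragment, cortex
#' `r in [r_in, r_out]`, and the callus fills the gap over the cortical
#' annulus (`z in [0, current_gap]`, `r in [r_in, r_out]`). The region of the
#' gap radially inside the endosteal surface is not modelled (no tissue
#' transfer across the medullary void by default); set
#' `external_callus = TRUE` to extend the callus over the marrow cavity as
#' well.
#'
#' @param geometry A [do_geometry()].
#' @param callus_size Target element size in the callus, mm.
#' @param bone_size Target element size in cortex/marrow, mm.
#' @param external_callus Also fill the gap over the medullary cavity with
#'   callus tissue (untested against the reference configuration).
#' @return An object of class `do_mesh` with components `nodes` (n x 2
#'   matrix of (r, z) in mm), `elem` (m x 4 connectivity, counter-clockwise),
#'   `region` (factor: cortex/marrow/callus), `tag` (per-node boundary tag),
#'   element `centroids` and `areas` (r-z plane mm^2), and the node sets
#'   bounding the gap (`gap_face_bottom`, `gap_face_top`).
#' @examples
#' m <- build_mesh(do_geometry(), callus_size = 0.25)
#' table(m$region)
#' @export
build_mesh <- function(geometry, callus_size = 0.25,
                       bone_size = 2 * callus_size,
                       external_callus = FALSE) {
  stopifnot(inherits(geometry, "do_geometry"))
  if (callus_size > geometry$initial_gap + 1e-12)
    stop("callus_size must not exceed the initial gap")
  r_in <- geometry$endosteal_diameter / 2
  r_out <- geometry$periosteal_diameter / 2
  gap <- geometry$current_gap
  L <- geometry$fragment_length

  r_lines <- c(.grid_lines(0, r_in, bone_size),
               .grid_lines(r_in, r_out, callus_size)[-1])
  z_lines <- c(.grid_lines(-L, 0, bone_size),
               .grid_lines(0, gap, callus_size, n_min = 4)[-1],
               .grid_lines(gap, gap + L, bone_size)[-1])
  nr <- length(r_lines); nz <- length(z_lines)
  nid <- matrix(seq_len(nr * nz), nr, nz)  # node id at (r index, z index)

  rc <- (r_lines[-nr] + r_lines[-1]) / 2
  zc <- (z_lines[-nz] + z_lines[-1]) / 2
  cells <- expand.grid(i = seq_len(nr - 1), j = seq_len(nz - 1))
  cell_r <- rc[cells$i]; cell_z <- zc[cells$j]
  in_gap <- cell_z > 0 & cell_z < gap
  inside_cavity <- cell_r < r_in
  keep <- !(in_gap & inside_cavity & !external_callus)
  cells <- cells[keep, , drop = FALSE]
  cell_r <- cell_r[keep]; cell_z <- cell_z[keep]
  in_gap <- in_gap[keep]; inside_cavity <- inside_cavity[keep]

  region <- ifelse(in_gap, "callus",
                   ifelse(inside_cavity, "marrow", "cortex"))
  i <- cells$i; j <- cells$j
  elem <- cbind(nid[cbind(i, j)], nid[cbind(i + 1, j)],
                nid[cbind(i + 1, j + 1)], nid[cbind(i, j + 1)])

  used <- sort(unique(as.vector(elem)))
  renum <- integer(nr * nz); renum[used] <- seq_along(used)
  elem <- matrix(renum[elem], ncol = 4)
  nodes <- cbind(r = rep(r_lines, times = nz),
                 z = rep(z_lines, each = nr))[used, , drop = FALSE]

  # boundary edges appear in exactly one element
  e1 <- elem[, c(1, 2)]; e2 <- elem[, c(2, 3)]
  e3 <- elem[, c(3, 4)]; e4 <- elem[, c(4, 1)]
  alledges <- rbind(e1, e2, e3, e4)
  key <- paste(pmin(alledges[, 1], alledges[, 2]),
               pmax(alledges[, 1], alledges[, 2]))
  bnd <- alledges[key %in% names(which(table(key) == 1)), , drop = FALSE]
  bnd_nodes <- unique(as.vector(bnd))

  z <- nodes[, "z"]; r <- nodes[, "r"]
  tol <- 1e-9
  tag <- rep(NA_character_, nrow(nodes))
  tag[bnd_nodes] <- "free"
  tag[abs(r) < tol & !is.na(tag)] <- "axis"
  tag[abs(z - min(z)) < tol] <- "bottom_fixed"
  tag[abs(z - max(z)) < tol] <- "top_loaded"

  x1 <- nodes[elem[, 1], , drop = FALSE]; x2 <- nodes[elem[, 2], , drop = FALSE]
  x3 <- nodes[elem[, 3], , drop = FALSE]; x4 <- nodes[elem[, 4], , drop = FALSE]
  areas <- 0.5 * abs((x1[, 1] - x3[, 1]) * (x2[, 2] - x4[, 2]) -
                     (x2[, 1] - x4[, 1]) * (x1[, 2] - x3[, 2]))
  centroids <- (x1 + x2 + x3 + x4) / 4
  colnames(centroids) <- c("r", "z")

  on_gap_r <- r >= r_in - tol | external_callus
  structure(list(nodes = nodes, elem = elem, region = region, tag = tag,
                 centroids = centroids, areas = areas,
                 geometry = geometry, callus_size = callus_size,
                 bone_size = bone_size, external_callus = external_callus,
                 gap_face_bottom = which(abs(z - 0) < tol & on_gap_r),
                 gap_face_top = which(abs(z - gap) < tol & on_gap_r)),
            class = "do_mesh")
}

#' @export
print.do_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric mesh: %d nodes, %d elements (%s)\n",
              nrow(x$nodes), nrow(x$elem),
              paste(sprintf("%s %d", names(table(x$region)),
                            table(x$region)), collapse = ", ")))
  cat(sprintf("  gap %.3g mm, callus/bone element size %.3g/%.3g mm\n",
              x$geometry$current_gap, x$callus_size, x$bone_size))
  invisible(x)
}

#' Rebuild the mesh for a widened gap
#'
#' Produces a clean structured mesh for the geometry with `new_gap`, ready
#' for [transfer_fields()]. Called before every distraction increment so
#' elements never accumulate distortion. With an unchanged gap the result is
#' node-for-node identical to [build_mesh()].
#'
#' @param mesh A [build_mesh()] result.
#' @param new_gap Widened gap in mm (must be >= the present gap).
#' @return A new `do_mesh`.
#' @export
remesh <- function(mesh, new_gap) {
  stopifnot(inherits(mesh, "do_mesh"))
  g <- mesh$geometry
  if (new_gap < g$current_gap - 1e-12)
    stop("new_gap (", new_gap, ") is smaller than the current gap (",
         g$current_gap, ")")
  g$current_gap <- new_gap
  build_mesh(g, callus_size = mesh$callus_size, bone_size = mesh$bone_size,
             external_callus = mesh$external_callus)
}

#' Analytic r-z plane area of the modelled region
#'
#' Used as the mesh conservation oracle: two fragments of full radius times
#' length, plus the gap annulus (or full gap rectangle with an external
#' callus).
#'
#' @param mesh A `do_mesh`.
#' @return Area in mm^2.
#' @export
analytic_mesh_area <- function(mesh) {
  g <- mesh$geometry
  r_in <- g$endosteal_diameter / 2
  r_out <- g$periosteal_diameter / 2
  gap_width <- if (mesh$external_callus) r_out else r_out - r_in
  2 * r_out * g$fragment_length + gap_width * g$current_gap
}

# Internal: per-element 2x2 Gauss points in physical coordinates
.element_gauss_points <- function(mesh) {
  gp <- 1 / sqrt(3)
  xi <- c(-gp, gp, gp, -gp); eta <- c(-gp, -gp, gp, gp)
  n <- nrow(mesh$elem)
  out <- matrix(0, 4 * n, 2)
  for (k in 1:4) {
    N <- 0.25 * c((1 - xi[k]) * (1 - eta[k]), (1 + xi[k]) * (1 - eta[k]),
                  (1 + xi[k]) * (1 + eta[k]), (1 - xi[k]) * (1 + eta[k]))
    pts <- N[1] * mesh$nodes[mesh$elem[, 1], , drop = FALSE] +
           N[2] * mesh$nodes[mesh$elem[, 2], , drop = FALSE] +
           N[3] * mesh$nodes[mesh$elem[, 3], , drop = FALSE] +
           N[4] * mesh$nodes[mesh$elem[, 4], , drop = FALSE]
    out[seq(k, by = 4, length.out = n), ] <- pts
  }
  out
}
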