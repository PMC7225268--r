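# Structured graded tetrahedral meshing.
#
# The mesh is a tensor-product hexahedral grid whose 1D line sets are graded
# from `fine_size` near the probe to `coarse_size` in the far field, with
# grid planes snapped to the probe faces (x = +-max/2, +-min/2; y = +-t/2;
# the taper break depths). Each hex is split into six tetrahedra (Kuhn
# split); cells with centroid y < 0 use the y-mirrored split so the mesh is
# exactly mirror-symmetric about the XZ plane through the probe axis.
# Element regions are assigned by hex-centroid membership in the probe
# solid, so the probe-tissue interface is conforming and tied by shared
# nodes.

# graded 1D breakpoints from `from` to `to`: first step `fine`, growing by
# `ratio` up to `coarse`, final point snapped to `to`
graded_lines <- function(from, to, fine, coarse, ratio = 1.7) {
  stopifnot(to > from)
  pts <- from
  step <- fine
  while (tail(pts, 1) + step < to) {
    pts <- c(pts, tail(pts, 1) + step)
    step <- min(step * ratio, coarse)
  }
  if (to - tail(pts, 1) < 0.35 * (tail(pts, 1) - tail(pts, 2)[1]) &&
      length(pts) > 1) pts <- pts[-length(pts)]
  c(pts, to)
}

# Kuhn split of the unit hex along the v1-v7 diagonal (1-based local ids of
# corners ordered (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),
# (0,1,1))
KUHN_TETS <- matrix(c(1, 2, 3, 7,
                      1, 3, 4, 7,
                      1, 4, 8, 7,
                      1, 8, 5, 7,
                      1, 5, 6, 7,
                      1, 6, 2, 7), ncol = 4, byrow = TRUE)
# y-mirror corner relabelling (j -> 1 - j)
YFLIP <- c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L)

tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2], ] - nodes[elems[, 1], ]
  b <- nodes[elems[, 3], ] - nodes[elems[, 1], ]
  c_ <- nodes[elems[, 4], ] - nodes[elems[, 1], ]
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# tensor-product tet mesh over given grid lines; split mirrored across y = 0
structured_tet_mesh <- function(xl, yl, zl) {
  nx <- length(xl); ny <- length(yl); nz <- length(zl)
  nodes <- as.matrix(expand.grid(x = xl, y = yl, z = zl))
  nid <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  elems <- list(); hex_of <- list()
  h <- 0L
  for (k in seq_len(nz - 1)) for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    h <- h + 1L
    corners <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                 nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                 nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    yc <- (yl[j] + yl[j + 1]) / 2
    tets <- if (yc >= 0) KUHN_TETS else {
      tt <- matrix(YFLIP[KUHN_TETS], ncol = 4)
      tt[, c(1, 2, 4, 3), drop = FALSE]   # restore orientation after mirror
    }
    elems[[h]] <- matrix(corners[t(tets)], ncol = 4, byrow = TRUE)
    hex_of[[h]] <- rep(h, 6L)
  }
  elems <- do.call(rbind, elems)
  vol <- tet_volumes(nodes, elems)
  flip <- vol < 0
  if (any(flip)) elems[flip, c(3, 4)] <- elems[flip, c(4, 3)]
  list(nodes = nodes, elems = elems, hex = unlist(hex_of),
       volumes = abs(vol))
}

#' Generate the graded tetrahedral mesh for a probe-in-cortex model
#'
#' @param model a [build_model_geometry()] result.
#' @param coarse_size far-field element size, um (default 500).
#' @param fine_size near-interface element size, um (default ~85).
#' @param seed accepted for interface symmetry; the mesher is fully
#'   deterministic and ignores it.
#' @return A `tet_mesh`: `nodes` (n x 3 um), `elems` (m x 4), `region`
#'   (`"tissue"`/`"probe"` per element), `volumes` (um^3), and boundary node
#'   sets `fixed_outer` (bottom and side tissue surfaces) and `probe_top`
#'   (probe cross-section at the brain surface).
#' @export
generate_mesh <- function(model, coarse_size = 500, fine_size = 85,
                          seed = NULL) {
  if (fine_size >= coarse_size)
    stop_invalid("`fine_size` must be smaller than `coarse_size`")
  p <- model$probe; tt <- model$tissue
  xh <- tt$x_extent / 2; yh <- tt$y_extent / 2
  # x: probe face planes, one mid line across the shank, then graded outward
  x_half <- sort(unique(c(0, p$min_width / 2, p$max_width / 2,
                          graded_lines(p$max_width / 2, xh, fine_size,
                                       coarse_size))))
  xl <- sort(unique(c(-rev(x_half), x_half)))
  # y: probe face at t/2, then graded outward; mirrored for exact symmetry
  y_half <- sort(unique(c(0, p$thickness / 2,
                          graded_lines(p$thickness / 2, yh, fine_size,
                                       coarse_size))))
  yl <- sort(unique(c(-rev(y_half), y_half)))
  # z: near-uniform lines along the shank (snapped to the taper breaks),
  # graded below the tip
  const_len <- p$insertion_depth - p$taper_length - p$tip_length
  breaks <- c(0, const_len, const_len + p$taper_length, p$insertion_depth)
  breaks <- sort(unique(breaks[breaks >= 0]))
  zl <- numeric(0)
  dz <- fine_size * 1.6
  for (i in seq_len(length(breaks) - 1)) {
    nseg <- max(1, round((breaks[i + 1] - breaks[i]) / dz))
    zl <- c(zl, seq(breaks[i], breaks[i + 1], length.out = nseg + 1))
  }
  if (tt$depth > p$insertion_depth)
    zl <- c(zl, graded_lines(p$insertion_depth, tt$depth, fine_size * 1.5,
                             coarse_size))
  zl <- sort(unique(zl))
  msh <- structured_tet_mesh(xl, yl, zl)
  if (any(msh$volumes <= 0))
    abort("meshing produced degenerate elements", class = "imetk_mesh_error")
  # region by hex centroid (mean of the six tet centroids within a hex), so
  # a whole hex is one region and the interface stays conforming
  cen <- element_centroids(msh)
  hx <- tapply(cen[, 1], msh$hex, mean)[as.character(msh$hex)]
  hy <- tapply(cen[, 2], msh$hex, mean)[as.character(msh$hex)]
  hz <- tapply(cen[, 3], msh$hex, mean)[as.character(msh$hex)]
  hw <- probe_halfwidth(model, hz)
  in_probe <- abs(hy) < p$thickness / 2 & hz < p$insertion_depth &
    abs(hx) < hw & hw > 0
  region <- ifelse(in_probe, "probe", "tissue")
  tol <- 1e-6
  on_outer <- abs(msh$nodes[, 1]) >= xh - tol |
              abs(msh$nodes[, 2]) >= yh - tol |
              msh$nodes[, 3] >= tt$depth - tol
  probe_nodes <- unique(as.vector(msh$elems[region == "probe", ]))
  on_top <- msh$nodes[, 3] <= tol
  probe_top <- intersect(which(on_top), probe_nodes)
  if (length(probe_top) == 0)
    abort("empty probe-top node set", class = "imetk_mesh_error")
  structure(list(nodes = msh$nodes, elems = msh$elems, region = region,
                 volumes = msh$volumes, hex = msh$hex,
                 fixed_outer = which(on_outer), probe_top = probe_top),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets (%d probe, %d tissue)\n",
              nrow(x$nodes), nrow(x$elems), sum(x$region == "probe"),
              sum(x$region == "tissue")))
  cat(sprintf("  boundary sets: fixed_outer %d, probe_top %d nodes\n",
              length(x$fixed_outer), length(x$probe_top)))
  invisible(x)
}

#' Element centroids of a tetrahedral mesh
#'
#' @param mesh a `tet_mesh` (or any list with `nodes` and `elems`).
#' @return m x 3 matrix of centroid coordinates (um).
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 2], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 3], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 4], , drop = FALSE]) / 4
}

#' Uniform box mesh for verification fixtures
#'
#' A structured tet mesh of an `lx` x `ly` x `lz` box with `nx` x `ny` x
#' `nz` divisions, single region, no boundary sets. Used by patch,
#' rigid-body and bar fixtures.
#'
#' @param lx,ly,lz box edge lengths (um).
#' @param nx,ny,nz divisions per edge.
#' @return A `tet_mesh`.
#' @export
mesh_box <- function(lx, ly, lz, nx = 2L, ny = 2L, nz = 2L) {
  msh <- structured_tet_mesh(seq(0, lx, length.out = nx + 1),
                             seq(0, ly, length.out = ny + 1),
                             seq(0, lz, length.out = nz + 1))
  structure(list(nodes = msh$nodes, elems = msh$elems,
                 region = rep("tissue", nrow(msh$elems)),
                 volumes = msh$volumes, hex = msh$hex,
                 fixed_outer = integer(0), probe_top = integer(0)),
            class = "tet_mesh")
}
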