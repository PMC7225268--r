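#' Per-element strain field as a tidy table
#'
#' Combines element centroids, regions, Voigt strain components, principal
#' strains and the von Mises equivalent strain (computed with the tissue
#' Poisson's ratio throughout, since reported strains are tissue strains).
#'
#' @param mesh the `tet_mesh`.
#' @param u nodal displacements (meters) from [solve_displacements()].
#' @param model the `fem_model` (supplies the tissue Poisson's ratio).
#' @return A tibble, one row per element: `element`, `region`, `x`, `y`,
#'   `z` (centroid, um), the six Voigt components, `e1`..`e3` and
#'   `von_mises`, with attribute `species`.
#' @export
strain_field <- function(mesh, u, model) {
  eps <- compute_element_strains(mesh, u)
  pr <- principal_strains(eps)
  vm <- von_mises_strain(pr[, 1], pr[, 2], pr[, 3],
                         model$tissue$poisson_ratio)
  cen <- element_centroids(mesh)
  out <- bind_cols(
    tibble(element = seq_len(nrow(eps)), region = mesh$region,
           x = cen[, 1], y = cen[, 2], z = cen[, 3]),
    as_tibble(eps), as_tibble(pr), tibble(von_mises = vm))
  attr(out, "species") <- model$species
  out
}

#' Jointly normalize two von Mises strain fields
#'
#' Divides both fields' von Mises strains by the single maximum across both
#' models, so the combined normalized fields span `[0, 1]` with exactly one
#' element attaining 1. Probe-region elements are excluded from the maximum
#' by default, since reported strains are tissue strains.
#'
#' @param field_a,field_b [strain_field()] tibbles.
#' @param include_probe include probe elements in the joint maximum.
#' @return A list with the two normalized fields (extra column `normalized`)
#'   and `joint_max` — value, model, element and centroid of the argmax.
#' @export
normalize_fields_jointly <- function(field_a, field_b,
                                     include_probe = FALSE) {
  pick <- function(f) if (include_probe) f else
    f[f$region == "tissue", , drop = FALSE]
  ca <- pick(field_a); cb <- pick(field_b)
  ma <- max(ca$von_mises); mb <- max(cb$von_mises)
  mx <- max(ma, mb)
  if (mx <= 0) stop_degenerate("zero strain everywhere: nothing to normalize")
  src <- if (ma >= mb) ca else cb
  arg <- src[which.max(src$von_mises), ]
  norm1 <- function(f) { f$normalized <- f$von_mises / mx; f }
  list(fields = list(norm1(field_a), norm1(field_b)),
       joint_max = list(value = mx,
                        species = attr(if (ma >= mb) field_a else field_b,
                                       "species"),
                        element = arg$element,
                        x = arg$x, y = arg$y, z = arg$z))
}

#' Lateral strain profiles at the brain top, probe mid-point and tip
#'
#' Samples the normalized von Mises strain along a +X ray from the probe
#' surface at three depths (z = 0, insertion_depth/2, insertion_depth),
#' every 10 um out to 500 um by default. Element-constant values are
#' interpolated to sample points by inverse-distance weighting over the
#' nearest tissue-element centroids.
#'
#' @param field a normalized [strain_field()] (column `normalized`).
#' @param mesh the `tet_mesh`.
#' @param model the `fem_model`.
#' @param distances sample offsets from the probe surface, um.
#' @param k number of neighbor centroids for inverse-distance weighting.
#' @return A tibble: `location` (`brain_top`, `probe_mid`, `probe_tip`),
#'   `distance` (um) and `strain` (normalized).
#' @export
extract_profiles <- function(field, mesh, model,
                             distances = seq(0, 500, by = 10), k = 8L) {
  if (!"normalized" %in% names(field))
    stop_invalid("field must be normalized first (see normalize_fields_jointly)")
  tis <- field[field$region == "tissue", , drop = FALSE]
  cen <- cbind(tis$x, tis$y, tis$z)
  val <- tis$normalized
  depth <- model$probe$insertion_depth
  locs <- tibble(location = c("brain_top", "probe_mid", "probe_tip"),
                 z = c(0, depth / 2, depth))
  half_x <- model$tissue$x_extent / 2
  rows <- list()
  for (i in seq_len(nrow(locs))) {
    x0 <- probe_halfwidth(model, locs$z[i])
    xs <- x0 + distances
    if (any(xs > half_x)) {
      warn("profile ray exits the tissue block; truncating")
      keep <- xs <= half_x
      xs <- xs[keep]
    }
    v <- vapply(xs, function(x) {
      d2 <- (cen[, 1] - x)^2 + cen[, 2]^2 + (cen[, 3] - locs$z[i])^2
      nb <- order(d2)[seq_len(min(k, length(d2)))]
      w <- 1 / pmax(d2[nb], 1e-12)
      sum(w * val[nb]) / sum(w)
    }, 1.0)
    rows[[i]] <- tibble(location = locs$location[i],
                        distance = distances[seq_along(xs)], strain = v)
  }
  list_rbind(rows)
}

#' Pearson correlation between two species' profile sets
#'
#' Pairs the two profile tables on (location, distance) and correlates the
#' concatenated normalized strains (3 x 51 = 153 paired points at the
#' default sampling).
#'
#' @param profiles_a,profiles_b [extract_profiles()] tibbles on identical
#'   sampling grids.
#' @return The Pearson correlation coefficient.
#' @export
correlate_profiles <- function(profiles_a, profiles_b) {
  j <- inner_join(profiles_a, profiles_b, by = c("location", "distance"),
                  suffix = c("_a", "_b"))
  if (nrow(j) != nrow(profiles_a) || nrow(j) != nrow(profiles_b))
    stop_invalid("profile sampling grids differ")
  if (sd(j$strain_a) == 0 || sd(j$strain_b) == 0)
    stop_degenerate("zero variance in a profile set")
  cor(j$strain_a, j$strain_b)
}

#' Build, solve and post-process one species' strain model
#'
#' Convenience wrapper: geometry, graded mesh, stiffness assembly, boundary
#' conditions (20 um +X at the probe top by default), sparse solve and
#' element strain recovery.
#'
#' @param config a [fem_config()].
#' @param coarse_size,fine_size mesh sizes, um.
#' @param ... passed to [apply_boundary_conditions()].
#' @return A list: `model`, `mesh`, `u` (nodal displacements, m), `field`
#'   (unnormalized [strain_field()]).
#' @export
run_strain_model <- function(config, coarse_size = 500, fine_size = 85, ...) {
  model <- build_model_geometry(config)
  mesh <- generate_mesh(model, coarse_size, fine_size)
  sys <- assemble_elasticity(mesh, list(
    tissue = model$tissue[c("young_modulus", "poisson_ratio")],
    probe = model$probe[c("young_modulus", "poisson_ratio")]))
  fem <- apply_boundary_conditions(sys, mesh,
                                   displacement = config$displacement, ...)
  u <- solve_displacements(fem)
  list(model = model, mesh = mesh, u = u,
       field = strain_field(mesh, u, model))
}

#' Export a mesh with per-element data as legacy ASCII VTK
#'
#' @param mesh the `tet_mesh`.
#' @param cell_data named list of per-element numeric vectors.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, cell_data = list(), path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "imetk strain model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
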