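#' Species configuration for the probe-in-cortex strain model
#'
#' Geometry and materials of the micromotion model: a silicon single-shank
#' probe (15 um thick, 123 um max width narrowing to 33 um over the taper,
#' 50 um tapering tip) embedded in a linearly elastic, isotropic block of
#' cortical tissue (E = 6 kPa, nu = 0.43; silicon E = 200 GPa, nu = 0.27).
#' The rat model inserts 2000 um into a 5000 x 5000 x 2500 um block with a
#' 1500 um taper; the mouse model inserts 1000 um into a 1250 um deep block
#' with a 750 um taper. Both models prescribe the same 20 um tangential
#' displacement at the top of the shank.
#'
#' @param species `"rat"` or `"mouse"`.
#' @return A `fem_config` list with `tissue`, `probe` and `displacement`
#'   blocks (lengths in um, moduli in Pa).
#' @export
fem_config <- function(species = c("rat", "mouse")) {
  species <- match.arg(species)
  rat <- species == "rat"
  structure(list(
    species = species,
    tissue = list(young_modulus = 6e3, poisson_ratio = 0.43,
                  x_extent = 5000, y_extent = 5000,
                  depth = if (rat) 2500 else 1250),
    probe = list(young_modulus = 200e9, poisson_ratio = 0.27,
                 thickness = 15, max_width = 123, min_width = 33,
                 taper_length = if (rat) 1500 else 750, tip_length = 50,
                 insertion_depth = if (rat) 2000 else 1000),
    displacement = 20), class = "fem_config")
}

#' Validate and build the unmeshed probe-in-cortex model
#'
#' Places the probe at the center of the block's XY plane with the brain
#' surface at z = 0 and depth increasing downward. The shank width profile is
#' constant at `max_width` from the surface down to
#' `insertion_depth - taper_length - tip_length`, narrows linearly to
#' `min_width` over the taper, then tapers linearly to a point over the tip.
#'
#' @param config a [fem_config()] (or a compatible list, e.g. read from
#'   JSON).
#' @return A `fem_model` object.
#' @export
build_model_geometry <- function(config) {
  p <- config$probe; t <- config$tissue
  if (t$young_modulus <= 0 || p$young_modulus <= 0)
    stop_invalid("Young's moduli must be positive")
  for (nu in c(t$poisson_ratio, p$poisson_ratio))
    if (nu < 0 || nu >= 0.5) stop_invalid("Poisson's ratio must lie in [0, 0.5)")
  if (!(p$max_width > p$min_width && p$min_width > 0))
    stop_invalid("need max_width > min_width > 0")
  if (p$insertion_depth < p$taper_length + p$tip_length)
    stop_invalid("insertion_depth must cover taper and tip")
  if (p$insertion_depth > t$depth)
    stop_invalid("insertion_depth exceeds the tissue block depth")
  structure(c(config, list()), class = c("fem_model", "fem_config"))
}

# shank half-width (um) at depth z um below the brain surface; 0 past the tip
probe_halfwidth <- function(model, z) {
  p <- model$probe
  const_len <- p$insertion_depth - p$taper_length - p$tip_length
  hw <- numeric(length(z))
  seg1 <- z >= 0 & z <= const_len
  seg2 <- z > const_len & z <= const_len + p$taper_length
  seg3 <- z > const_len + p$taper_length & z <= p$insertion_depth
  hw[seg1] <- p$max_width / 2
  hw[seg2] <- (p$max_width +
    (p$min_width - p$max_width) * (z[seg2] - const_len) / p$taper_length) / 2
  hw[seg3] <- (p$min_width / 2) *
    (1 - (z[seg3] - const_len - p$taper_length) / p$tip_length)
  hw
}

#' Read / write a model configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_fem_config()` returns a `fem_config`.
#' @export
read_fem_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "fem_config")
}

#' @rdname read_fem_config
#' @param config a `fem_config`.
#' @export
write_fem_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
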