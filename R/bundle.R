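#' Geometry of the sample volume and axon packing
#'
#' Describes the isotropic cubic sample volume that contains the cross-section
#' of the fiber tract, together with the geometric rules used to place nodes
#' of Ranvier along myelinated axons.
#'
#' @param sample_length Edge of the cubic sample volume, in mm.  The default
#'   3.5 mm contains the whole corticospinal tract cross-section.
#' @param node_length Length of a node of Ranvier, in micrometres.
#' @param internodal_ratio Internodal distance expressed as a multiple of the
#'   axon diameter; the distance between consecutive nodes of an axon of
#'   diameter \eqn{d} is `internodal_ratio * d`.
#' @param interaxonal_space_fraction Fraction of the tract cross-section
#'   occupied by extra-axonal space when axons are packed as a square lattice
#'   of cylinders; must lie in `[0, 1)`.
#'
#' @return An object of class `"bundle_geometry"`.  All lengths are stored
#'   internally in micrometres.
#' @examples
#' bundle_geometry()
#' @export
bundle_geometry <- function(sample_length = 3.5, node_length = 2,
                            internodal_ratio = 100,
                            interaxonal_space_fraction = 0.17) {
  stopifnot(is.numeric(sample_length), is.numeric(node_length),
            is.numeric(internodal_ratio),
            is.numeric(interaxonal_space_fraction))
  if (sample_length <= 0 || node_length <= 0 || internodal_ratio <= 0)
    stop("all lengths and the internodal ratio must be positive", call. = FALSE)
  if (interaxonal_space_fraction < 0 || interaxonal_space_fraction >= 1)
    stop("'interaxonal_space_fraction' must lie in [0, 1)", call. = FALSE)
  structure(list(
    sample_length_um = sample_length * 1000,
    node_length_um = node_length,
    internodal_ratio = internodal_ratio,
    interaxonal_space_fraction = interaxonal_space_fraction
  ), class = "bundle_geometry")
}

#' Channel biophysics constants
#'
#' Sodium-channel densities and per-channel water-coupled ion flux used to
#' convert membrane area into water flow during action-potential conduction.
#'
#' @param rho_node Areal density of sodium channels at nodes of Ranvier,
#'   channels per square micrometre.
#' @param rho_unmyelinated Areal density of sodium channels on unmyelinated
#'   axon membrane, channels per square micrometre.
#' @param ion_flux_per_channel Sodium ions conducted per open channel per
#'   millisecond.
#' @param waters_per_na Water molecules co-transported per sodium ion.
#' @param waters_per_k Water molecules per potassium ion (informational; the
#'   outward water flow is fixed by mass balance, so this value does not enter
#'   the flux arithmetic).
#'
#' @return An object of class `"channel_biophysics"`.
#' @examples
#' channel_biophysics()
#' @export
channel_biophysics <- function(rho_node = 1e4, rho_unmyelinated = 200,
                               ion_flux_per_channel = 8.8e3,
                               waters_per_na = 2.5,
                               waters_per_k = c(0.9, 1.4)) {
  vals <- c(rho_node, rho_unmyelinated, ion_flux_per_channel, waters_per_na,
            waters_per_k)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("channel biophysics values must be finite and non-negative",
         call. = FALSE)
  structure(list(
    rho_node = rho_node,
    rho_unmyelinated = rho_unmyelinated,
    ion_flux_per_channel = ion_flux_per_channel,
    waters_per_na = waters_per_na,
    waters_per_k = waters_per_k
  ), class = "channel_biophysics")
}

#' Define an axon bundle from diameter classes
#'
#' An axon bundle is a discrete set of axon classes, each with a diameter, an
#' axon count and a myelination flag, plus the packing geometry of the sample
#' volume.  The built-in default, [cst_bundle()], is the corticospinal-tract
#' hand-representation model with about one million axons.
#'
#' @param classes A data frame with columns `diameter_um` (> 0), `count`
#'   (>= 0) and `myelinated` (logical), and optionally `fraction` (class
#'   fractions, which must sum to 1 when provided).
#' @param geometry A [bundle_geometry()] object.
#'
#' @return An object of class `"axon_bundle"`.
#' @seealso [cst_bundle()], [read_bundle()], [bundle_table()]
#' @examples
#' axon_bundle(data.frame(diameter_um = 3, count = 1000, myelinated = FALSE))
#' @export
axon_bundle <- function(classes, geometry = bundle_geometry()) {
  classes <- as.data.frame(classes)
  req <- c("diameter_um", "count", "myelinated")
  if (!all(req %in% names(classes)))
    stop("'classes' needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(classes) < 1)
    stop("an axon bundle needs at least one class", call. = FALSE)
  if (any(classes$diameter_um <= 0))
    stop("axon diameters must be positive", call. = FALSE)
  if (any(classes$count < 0))
    stop("axon counts must be non-negative", call. = FALSE)
  classes$myelinated <- as.logical(classes$myelinated)
  if (anyNA(classes$myelinated))
    stop("'myelinated' must be logical (TRUE/FALSE)", call. = FALSE)
  if (!is.null(classes$fraction) && !anyNA(classes$fraction) &&
      abs(sum(classes$fraction) - 1) > 1e-6)
    stop("class fractions must sum to 1", call. = FALSE)
  if (!inherits(geometry, "bundle_geometry"))
    stop("'geometry' must be a bundle_geometry object", call. = FALSE)
  structure(list(classes = classes, geometry = geometry),
            class = "axon_bundle")
}

#' Built-in corticospinal tract bundle
#'
#' The default fiber-tract composition: four myelinated diameter classes
#' (2, 5, 8 and 11 um) plus one unmyelinated class (3 um), about 10^6 axons
#' in total, 70% myelinated, packed in a 3.5 mm cubic sample volume.  The
#' class table is shipped as a plain-text fixture and can be replaced by any
#' user table via [read_bundle()].
#'
#' @param geometry A [bundle_geometry()] used for packing and node placement.
#' @return An `"axon_bundle"` object.
#' @examples
#' cst_bundle()
#' @export
cst_bundle <- function(geometry = bundle_geometry()) {
  path <- system.file("extdata", "cst_bundle.tsv", package = "adti",
                      mustWork = TRUE)
  read_bundle(path, geometry = geometry)
}

#' Read an axon bundle definition from a delimited text file
#'
#' @param path Path to a tab- or comma-separated file with header columns
#'   `diameter_um`, `count`, `myelinated` and optionally `fraction`.
#' @param geometry A [bundle_geometry()] object.
#' @return An `"axon_bundle"` object.
#' @export
read_bundle <- function(path, geometry = bundle_geometry()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  axon_bundle(tab, geometry = geometry)
}

#' Average number of nodes of Ranvier per axon in the sample volume
#'
#' The internodal distance is proportional to the axon diameter
#' (`internodal_ratio` times the diameter), so an axon of diameter `d`
#' traversing the sample volume of edge `L` carries `L / (ratio * d)` nodes.
#' The count is a population average and is deliberately left fractional.
#'
#' @param diameter Axon diameter in micrometres (vectorised).
#' @param geometry A [bundle_geometry()] object.
#' @return Nodes per axon (dimensionless, possibly fractional).
#' @examples
#' nodes_per_axon(2)   # 17.5 for the 3.5 mm default volume
#' @export
nodes_per_axon <- function(diameter, geometry = bundle_geometry()) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("'diameter' must be positive", call. = FALSE)
  geometry$sample_length_um / (geometry$internodal_ratio * diameter)
}

#' Membrane surface area of a node of Ranvier
#'
#' The node is modelled as the lateral surface of an open cylinder (no end
#' caps): area = pi * diameter * node_length.
#'
#' @param diameter Axon diameter in micrometres (vectorised).
#' @param node_length Node length in micrometres.
#' @return Area in square micrometres.
#' @examples
#' node_surface_area(2)   # 12.57 um^2
#' @export
node_surface_area <- function(diameter, node_length = 2) {
  if (any(!is.finite(diameter)) || any(diameter <= 0) || node_length <= 0)
    stop("'diameter' and 'node_length' must be positive", call. = FALSE)
  pi * diameter * node_length
}

#' Membrane surface area of an unmyelinated axon spanning the sample volume
#'
#' @param diameter Axon diameter in micrometres.
#' @param sample_length Axon length (= sample-volume edge) in mm.
#' @return Area in square micrometres.
#' @examples
#' unmyelinated_membrane_area(3, 3.5)   # about 33,000 um^2
#' @export
unmyelinated_membrane_area <- function(diameter, sample_length = 3.5) {
  if (any(!is.finite(diameter)) || any(diameter <= 0) || sample_length <= 0)
    stop("'diameter' and 'sample_length' must be positive", call. = FALSE)
  pi * diameter * sample_length * 1000
}

#' Sodium-channel counts on myelinated axons (nodes of Ranvier)
#'
#' Per diameter class: axon count x nodes per axon x node surface area x
#' nodal channel density; the total sums over myelinated classes.  A bundle
#' without myelinated classes returns a zero total.
#'
#' @param bundle An [axon_bundle()].
#' @param channels A [channel_biophysics()] object.
#' @return A list with `per_class` (named numeric vector, one entry per
#'   myelinated class, named by diameter) and `total`.
#' @examples
#' channel_count_myelinated(cst_bundle())$total   # about 1.61e12
#' @export
channel_count_myelinated <- function(bundle, channels = channel_biophysics()) {
  stopifnot(inherits(bundle, "axon_bundle"),
            inherits(channels, "channel_biophysics"))
  cl <- bundle$classes[bundle$classes$myelinated, , drop = FALSE]
  if (nrow(cl) == 0)
    return(list(per_class = numeric(0), total = 0))
  per <- cl$count *
    nodes_per_axon(cl$diameter_um, bundle$geometry) *
    node_surface_area(cl$diameter_um, bundle$geometry$node_length_um) *
    channels$rho_node
  names(per) <- format(cl$diameter_um, trim = TRUE)
  list(per_class = per, total = sum(per))
}

#' Sodium-channel counts on unmyelinated axons
#'
#' Per class: axon count x membrane area over the sample length x membrane
#' channel density, summed over unmyelinated classes.
#'
#' @inheritParams channel_count_myelinated
#' @return A list with `per_class` and `total`.
#' @examples
#' channel_count_unmyelinated(cst_bundle())$total   # about 1.98e12
#' @export
channel_count_unmyelinated <- function(bundle,
                                       channels = channel_biophysics()) {
  stopifnot(inherits(bundle, "axon_bundle"),
            inherits(channels, "channel_biophysics"))
  cl <- bundle$classes[!bundle$classes$myelinated, , drop = FALSE]
  if (nrow(cl) == 0)
    return(list(per_class = numeric(0), total = 0))
  per <- cl$count *
    unmyelinated_membrane_area(cl$diameter_um,
                               bundle$geometry$sample_length_um / 1000) *
    channels$rho_unmyelinated
  names(per) <- format(cl$diameter_um, trim = TRUE)
  list(per_class = per, total = sum(per))
}

#' Sample-volume edge implied by square-lattice packing of the bundle
#'
#' Packs all axons as a regular square lattice of cylinders with the stated
#' interaxonal space fraction and returns the edge of the square (= cubic
#' sample volume) that contains the full cross-section.
#'
#' @inheritParams channel_count_myelinated
#' @return Edge length in mm.
#' @examples
#' sample_volume_side(cst_bundle())   # about 3.5 mm
#' @export
sample_volume_side <- function(bundle) {
  stopifnot(inherits(bundle, "axon_bundle"))
  f <- bundle$geometry$interaxonal_space_fraction
  if (f >= 1)
    stop("'interaxonal_space_fraction' must be below 1", call. = FALSE)
  cross <- sum(bundle$classes$count * pi *
                 (bundle$classes$diameter_um / 2)^2)  # um^2
  sqrt(cross / (1 - f)) / 1000
}

#' Mass of water resident in the sample volume
#'
#' @param side Cube edge in mm.
#' @param water_fraction Water content of the tissue (0.9 for white matter).
#' @param tissue_density Tissue density in g per cubic cm.
#' @return Water mass in grams.
#' @examples
#' water_mass_in_volume(3.5)   # 0.0386 g
#' @export
water_mass_in_volume <- function(side, water_fraction = 0.9,
                                 tissue_density = 1) {
  if (side <= 0) stop("'side' must be positive", call. = FALSE)
  if (water_fraction < 0 || water_fraction > 1)
    stop("'water_fraction' must lie in [0, 1]", call. = FALSE)
  if (tissue_density <= 0)
    stop("'tissue_density' must be positive", call. = FALSE)
  side^3 * 1e-3 * tissue_density * water_fraction   # mm^3 -> cm^3
}

#' Tabular summary of an axon bundle
#'
#' One row per axon class with the derived node areas and channel counts,
#' mirroring the layout used to publish fiber-tract composition tables.
#'
#' @inheritParams channel_count_myelinated
#' @return A data frame with columns `diameter_um`, `count`, `myelinated`,
#'   `nodes_per_axon`, `area_um2` (node area for myelinated classes, total
#'   membrane area for unmyelinated ones) and `channels_1e10` (total sodium
#'   channels for the class, in units of 10^10).
#' @export
bundle_table <- function(bundle, channels = channel_biophysics()) {
  stopifnot(inherits(bundle, "axon_bundle"))
  cl <- bundle$classes
  geom <- bundle$geometry
  nodes <- ifelse(cl$myelinated,
                  nodes_per_axon(cl$diameter_um, geom), NA_real_)
  area <- ifelse(cl$myelinated,
                 node_surface_area(cl$diameter_um, geom$node_length_um),
                 unmyelinated_membrane_area(cl$diameter_um,
                                            geom$sample_length_um / 1000))
  chans <- ifelse(cl$myelinated,
                  cl$count * nodes * area * channels$rho_node,
                  cl$count * area * channels$rho_unmyelinated)
  data.frame(diameter_um = cl$diameter_um, count = cl$count,
             myelinated = cl$myelinated, nodes_per_axon = nodes,
             area_um2 = area, channels_1e10 = chans / 1e10)
}

#' @export
print.axon_bundle <- function(x, ...) {
  n_my <- sum(x$classes$count[x$classes$myelinated])
  n_un <- sum(x$classes$count[!x$classes$myelinated])
  cat("Axon bundle:", nrow(x$classes), "classes,",
      format(n_my + n_un, big.mark = ","), "axons",
      sprintf("(%s myelinated, %s unmyelinated)\n",
              format(n_my, big.mark = ","), format(n_un, big.mark = ",")))
  cat(sprintf("Sample volume: %.2f mm cube; node length %g um; internodal distance %g x diameter\n",
              x$geometry$sample_length_um / 1000, x$geometry$node_length_um,
              x$geometry$internodal_ratio))
  print(x$classes, row.names = FALSE)
  invisible(x)
}
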