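# Physical constants used for molecule <-> mass conversion
.WATER_MOLAR_MASS <- 18       # g mol^-1
.AVOGADRO <- 6.022e23         # mol^-1

#' One-directional water inflow through a population of open channels
#'
#' Converts a total sodium-channel count into the water inflow it carries:
#' channels x ions per channel per ms x water molecules per ion.  This is the
#' one-directional (inward) half; the bidirectional total applies a factor 2
#' because mass balance forces an equal outward flow (see [total_flux()]).
#'
#' @param channel_total Total number of open sodium channels (>= 0).
#' @param channels A [channel_biophysics()] object.
#' @return Water molecules per millisecond.
#' @examples
#' water_inflow(1.61e12)   # about 3.5e16 molecules per ms
#' @export
water_inflow <- function(channel_total, channels = channel_biophysics()) {
  if (any(channel_total < 0))
    stop("'channel_total' must be non-negative", call. = FALSE)
  stopifnot(inherits(channels, "channel_biophysics"))
  channel_total * channels$ion_flux_per_channel * channels$waters_per_na
}

#' Convert a number of water molecules to grams
#'
#' @param n Number of molecules (>= 0).
#' @return Mass in grams (18 g/mol over Avogadro's number).
#' @examples
#' molecules_to_grams(6.022e23)   # one mole = 18 g
#' @export
molecules_to_grams <- function(n) {
  if (any(n < 0)) stop("'n' must be non-negative", call. = FALSE)
  n * .WATER_MOLAR_MASS / .AVOGADRO
}

#' Activity-associated trans-membrane water flow of a bundle
#'
#' Combines the nodal (myelinated) and membrane (unmyelinated) channel counts
#' into the total water flow per sample volume during conduction.  The inward
#' sodium-coupled flow is matched by an equal outward potassium-coupled flow
#' (mass balance: no net swelling), so the bidirectional flow `F_w` is twice
#' the total inflow.
#'
#' @param bundle An [axon_bundle()].
#' @param channels A [channel_biophysics()] object.
#' @return An object of class `"water_flux"`: a list with molecule rates
#'   (`inflow_myelinated`, `inflow_unmyelinated`, `inflow_total`, `F_w`, all
#'   molecules per ms) and the corresponding mass rates in g per ms
#'   (`mass_inflow_myelinated`, `mass_inflow_unmyelinated`,
#'   `mass_inflow_total`, `mass_rate` for `F_w`).
#' @examples
#' total_flux(cst_bundle())
#' @export
total_flux <- function(bundle, channels = channel_biophysics()) {
  my <- channel_count_myelinated(bundle, channels)$total
  un <- channel_count_unmyelinated(bundle, channels)$total
  in_my <- water_inflow(my, channels)
  in_un <- water_inflow(un, channels)
  in_tot <- in_my + in_un
  structure(list(
    channels_myelinated = my,
    channels_unmyelinated = un,
    inflow_myelinated = in_my,
    inflow_unmyelinated = in_un,
    inflow_total = in_tot,
    F_w = 2 * in_tot,
    mass_inflow_myelinated = molecules_to_grams(in_my),
    mass_inflow_unmyelinated = molecules_to_grams(in_un),
    mass_inflow_total = molecules_to_grams(in_tot),
    mass_rate = molecules_to_grams(2 * in_tot)
  ), class = "water_flux")
}

#' @export
print.water_flux <- function(x, ...) {
  cat("Activity-associated water flow per sample volume\n")
  for (line in flux_report(x)) cat(" ", line, "\n")
  invisible(x)
}

#' Flat key-value report of a water-flux result
#'
#' @param flux A `"water_flux"` object from [total_flux()].
#' @return Character vector of `key = value [unit]` lines.
#' @export
flux_report <- function(flux) {
  stopifnot(inherits(flux, "water_flux"))
  fmt <- function(key, val, unit)
    sprintf("%-28s = %s [%s]", key, format(signif(val, 3)), unit)
  c(fmt("channels_myelinated", flux$channels_myelinated, "channels"),
    fmt("channels_unmyelinated", flux$channels_unmyelinated, "channels"),
    fmt("inflow_myelinated", flux$inflow_myelinated, "molecules/ms"),
    fmt("inflow_unmyelinated", flux$inflow_unmyelinated, "molecules/ms"),
    fmt("inflow_total", flux$inflow_total, "molecules/ms"),
    fmt("F_w (bidirectional)", flux$F_w, "molecules/ms"),
    fmt("mass_inflow_total", flux$mass_inflow_total, "g/ms"),
    fmt("mass_rate (F_w)", flux$mass_rate, "g/ms"))
}
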