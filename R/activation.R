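#' Activation and diffusion parameters
#'
#' Parameters controlling the conversion of water flux into the fast-water
#' fraction and the activation-perturbed diffusion tensor.
#'
#' @param diffusion_time Diffusion time of the DWI experiment, ms.
#' @param firing_rate Mean motor-neuron firing rate, Hz (retained for
#'   duty-cycle sensitivity analyses; does not enter the default computation).
#' @param repetition_time Sequence TR, s (retained like `firing_rate`).
#' @param D_parallel Parallel (axial) diffusivity of the resting tract,
#'   m^2 s^-1.
#' @param anisotropy_ratio Ratio of parallel to perpendicular diffusivity;
#'   the perpendicular diffusivity is `D_parallel / anisotropy_ratio`.
#' @param D_free Diffusivity of free (activated) water at 37 C, m^2 s^-1.
#' @param water_fraction Tissue water content (0.9 for white matter).
#' @param tissue_density Tissue density, g cm^-3.
#' @param duty_cycle Fraction of the diffusion time during which the flux is
#'   applied; the default 1 treats the tract as continuously conducting for
#'   the full diffusion time.
#'
#' @return An object of class `"activation_params"`.
#' @examples
#' activation_params()
#' @export
activation_params <- function(diffusion_time = 35, firing_rate = 15,
                              repetition_time = 2.5, D_parallel = 1e-9,
                              anisotropy_ratio = 5, D_free = 3e-9,
                              water_fraction = 0.9, tissue_density = 1,
                              duty_cycle = 1) {
  vals <- c(diffusion_time, firing_rate, repetition_time, D_parallel,
            anisotropy_ratio, D_free, water_fraction, tissue_density,
            duty_cycle)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all activation parameters must be positive and finite",
         call. = FALSE)
  if (water_fraction > 1)
    stop("'water_fraction' must lie in (0, 1]", call. = FALSE)
  if (duty_cycle > 1)
    stop("'duty_cycle' must lie in (0, 1]", call. = FALSE)
  if (D_free < D_parallel)
    stop("'D_free' must be at least 'D_parallel'", call. = FALSE)
  structure(list(
    diffusion_time = diffusion_time, firing_rate = firing_rate,
    repetition_time = repetition_time, D_parallel = D_parallel,
    anisotropy_ratio = anisotropy_ratio,
    D_perp = D_parallel / anisotropy_ratio, D_free = D_free,
    water_fraction = water_fraction, tissue_density = tissue_density,
    duty_cycle = duty_cycle
  ), class = "activation_params")
}

#' Diffusion-tensor eigenvalue triple
#'
#' @param lambda1,lambda2,lambda3 Eigenvalues in m^2 s^-1 (all positive).
#'   They are sorted into descending order.
#' @return An object of class `"tensor_state"`: numeric vector
#'   `c(lambda1, lambda2, lambda3)` with `lambda1 >= lambda2 >= lambda3`.
#' @examples
#' tensor_state(1e-9, 2e-10, 2e-10)
#' @export
tensor_state <- function(lambda1, lambda2, lambda3) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("eigenvalues must be positive and finite", call. = FALSE)
  structure(sort(l, decreasing = TRUE),
            names = c("lambda1", "lambda2", "lambda3"),
            class = "tensor_state")
}

#' Fraction of fast-moving (activated) water
#'
#' The mass of water exchanged across membranes during one diffusion time,
#' divided by the resident water mass of the sample volume.
#'
#' @param flux A `"water_flux"` object (or a bidirectional mass rate in
#'   g ms^-1).
#' @param params An [activation_params()] object.
#' @param resident_water_mass Water mass of the sample volume in grams; when
#'   `NULL` it is computed from `sample_length`, `water_fraction` and
#'   `tissue_density`.
#' @param sample_length Cube edge in mm, used when `resident_water_mass` is
#'   `NULL`.
#' @return The dimensionless fast-water fraction in `[0, 1]`.  A value above
#'   1 (exchanged water exceeding resident water) signals model breakdown and
#'   raises an error.
#' @examples
#' fast_water_fraction(total_flux(cst_bundle()))   # about 4.3e-3
#' @export
fast_water_fraction <- function(flux, params = activation_params(),
                                resident_water_mass = NULL,
                                sample_length = 3.5) {
  mass_rate <- if (inherits(flux, "water_flux")) flux$mass_rate else flux
  if (mass_rate < 0) stop("mass rate must be non-negative", call. = FALSE)
  if (is.null(resident_water_mass))
    resident_water_mass <- water_mass_in_volume(
      sample_length, params$water_fraction, params$tissue_density)
  if (resident_water_mass <= 0)
    stop("'resident_water_mass' must be positive", call. = FALSE)
  f <- mass_rate * params$diffusion_time * params$duty_cycle /
    resident_water_mass
  if (f > 1)
    stop("model breakdown: fast-water fraction exceeds 1 ",
         "(exchanged water exceeds resident water)", call. = FALSE)
  f
}

#' Perpendicular diffusivity in the active state
#'
#' Mixes the fast (free) water compartment into the perpendicular
#' diffusivity.  Two modes are provided:
#' \describe{
#'   \item{`"approx"` (default)}{`f * D_free + D_perp`, the small-fraction
#'     approximation that drops the `(1 - f)` weighting of the slow pool.}
#'   \item{`"exact"`}{the full two-compartment mixture
#'     `f * D_free + (1 - f) * D_perp`.}
#' }
#' The two differ by exactly `f * D_perp`, negligible for `f << 1`.
#'
#' @param f_w_star Fast-water fraction in `[0, 1]`.
#' @param d_perp Resting perpendicular diffusivity, m^2 s^-1.
#' @param d_free Fast-water diffusivity, m^2 s^-1.
#' @param mode `"approx"` or `"exact"`.
#' @return Active-state perpendicular diffusivity, m^2 s^-1.
#' @examples
#' d_perp_active(4.28e-3, 2e-10, 3e-9)          # 2.13e-10
#' d_perp_active(4.28e-3, 2e-10, 3e-9, "exact") # 2.12e-10
#' @export
d_perp_active <- function(f_w_star, d_perp, d_free,
                          mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (f_w_star < 0 || f_w_star > 1)
    stop("'f_w_star' must lie in [0, 1]", call. = FALSE)
  switch(mode,
         approx = f_w_star * d_free + d_perp,
         exact = f_w_star * d_free + (1 - f_w_star) * d_perp)
}

#' Apparent diffusion coefficient of a tensor state
#'
#' @param state A [tensor_state()] or numeric eigenvalue triple.
#' @return Mean of the three eigenvalues, m^2 s^-1.
#' @examples
#' d_app(tensor_state(1e-9, 2e-10, 2e-10))
#' @export
d_app <- function(state) {
  mean(unclass(state))
}

#' Fractional anisotropy of a tensor state
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2) / sum(lambda_i^2))` for a
#' general eigenvalue triple; for axially symmetric tensors
#' (`lambda2 == lambda3`) this reduces to the familiar closed form in
#' `D_parallel` and `D_perp`.
#'
#' @param state A [tensor_state()] or numeric eigenvalue triple.
#' @return FA in `[0, 1)`; 0 for isotropic tensors.
#' @examples
#' fractional_anisotropy(tensor_state(1e-9, 2e-10, 2e-10))   # 0.770
#' @export
fractional_anisotropy <- function(state) {
  l <- as.numeric(unclass(state))
  if (length(l) != 3 || any(!is.finite(l)))
    stop("'state' must be three finite eigenvalues", call. = FALSE)
  ssq <- sum(l^2)
  if (ssq == 0)
    stop("fractional anisotropy is undefined for an all-zero tensor",
         call. = FALSE)
  sqrt(1.5) * sqrt(sum((l - mean(l))^2) / ssq)
}

#' Fit the activity-dependent diffusion model of a fiber tract
#'
#' The central modelling function.  From the bundle composition it computes
#' the sodium-channel population, the activity-associated water flux, the
#' fast-water fraction over one diffusion time, and the perturbed diffusion
#' tensor of the conducting (active) state: the parallel eigenvalue is held
#' fixed and both perpendicular eigenvalues are raised by the fast-water
#' admixture.  Apparent diffusion coefficient and fractional anisotropy are
#' evaluated for both states.
#'
#' @param bundle An [axon_bundle()]; default [cst_bundle()].
#' @param channels A [channel_biophysics()] object.
#' @param params An [activation_params()] object.
#' @param mode Perpendicular-diffusivity mixing rule, see [d_perp_active()].
#' @param lambda1_shift Optional additive perturbation of the parallel
#'   eigenvalue in the active state (m^2 s^-1, default 0: the parallel
#'   diffusivity is assumed unchanged by conduction).
#'
#' @return An object of class `"adti_model"`: a list with the inputs, the
#'   `"water_flux"`, `water_mass` (g), `f_w_star`, `inactive` and `active`
#'   [tensor_state()]s, `D_app`, `D_app_star`, `FA`, `FA_star`, and relative
#'   changes `rel_change_D_perp`, `rel_change_D_app`, `rel_change_FA`
#'   (fractions, active vs inactive).
#' @seealso [summary.adti_model()], [predict.adti_model()],
#'   [simulate.adti_model()], [reproduce_report()]
#' @examples
#' m <- adti_model()
#' m$FA; m$FA_star           # 0.770 -> 0.754
#' coef(m)
#' @export
adti_model <- function(bundle = cst_bundle(),
                       channels = channel_biophysics(),
                       params = activation_params(),
                       mode = c("approx", "exact"),
                       lambda1_shift = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "axon_bundle"),
            inherits(channels, "channel_biophysics"),
            inherits(params, "activation_params"))
  flux <- total_flux(bundle, channels)
  side <- bundle$geometry$sample_length_um / 1000
  water_mass <- water_mass_in_volume(side, params$water_fraction,
                                     params$tissue_density)
  f_w_star <- fast_water_fraction(flux, params, water_mass)

  d_par <- params$D_parallel
  d_perp <- params$D_perp
  inactive <- tensor_state(d_par, d_perp, d_perp)
  d_perp_star <- d_perp_active(f_w_star, d_perp, params$D_free, mode)
  active <- tensor_state(d_par + lambda1_shift, d_perp_star, d_perp_star)

  out <- list(
    bundle = bundle, channels = channels, params = params, mode = mode,
    flux = flux, water_mass = water_mass, f_w_star = f_w_star,
    inactive = inactive, active = active,
    D_app = d_app(inactive), D_app_star = d_app(active),
    FA = fractional_anisotropy(inactive),
    FA_star = fractional_anisotropy(active),
    rel_change_D_perp = (d_perp_star - d_perp) / d_perp,
    rel_change_D_app = (d_app(active) - d_app(inactive)) / d_app(inactive),
    rel_change_FA = NA_real_
  )
  out$rel_change_FA <- (out$FA_star - out$FA) / out$FA
  structure(out, class = "adti_model")
}

#' @export
print.adti_model <- function(x, ...) {
  cat("Activity-dependent diffusion tensor model\n")
  cat(sprintf("  fast-water fraction f_w* = %.3g (diffusion time %g ms)\n",
              x$f_w_star, x$params$diffusion_time))
  cat(sprintf("  eigenvalues inactive: (%.3g, %.3g, %.3g) m^2/s\n",
              x$inactive[1], x$inactive[2], x$inactive[3]))
  cat(sprintf("  eigenvalues active:   (%.3g, %.3g, %.3g) m^2/s\n",
              x$active[1], x$active[2], x$active[3]))
  cat(sprintf("  D_app %.3g -> %.3g m^2/s (%+.1f%%)\n",
              x$D_app, x$D_app_star, 100 * x$rel_change_D_app))
  cat(sprintf("  FA    %.3f -> %.3f       (%+.1f%%)\n",
              x$FA, x$FA_star, 100 * x$rel_change_FA))
  invisible(x)
}

#' Summarise an activity-dependent diffusion model
#'
#' @param object An `"adti_model"`.
#' @param b b-value (s mm^-2) at which the perpendicular echo drop is
#'   evaluated.
#' @param snr Signal-to-noise ratio for the detectability assessment.
#' @param z Detection threshold in noise standard deviations.
#' @param ... Unused.
#' @return A `"summary.adti_model"` object: the model plus the echo drop and
#'   detectability at the stated `b` and `snr`.
#' @export
summary.adti_model <- function(object, b = 600, snr = 400, z = 3, ...) {
  drop <- relative_signal_drop(b, object$inactive["lambda2"],
                               object$active["lambda2"])
  det <- detectable(drop, snr, z)
  structure(list(model = object, b = b, snr = snr, z = z,
                 signal_drop = drop, detection = det),
            class = "summary.adti_model")
}

#' @export
print.summary.adti_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  echo drop at b = %g s/mm^2: %.2f%%\n",
              x$b, 100 * x$signal_drop))
  cat(sprintf("  detection at SNR %g (z = %g): %s (margin %+.2g)\n",
              x$snr, x$z, if (x$detection$detectable) "yes" else "no",
              x$detection$margin))
  invisible(x)
}

#' @export
coef.adti_model <- function(object, ...) {
  p <- object$params
  ch <- object$channels
  c(diffusion_time = p$diffusion_time, firing_rate = p$firing_rate,
    repetition_time = p$repetition_time, D_parallel = p$D_parallel,
    anisotropy_ratio = p$anisotropy_ratio, D_perp = p$D_perp,
    D_free = p$D_free, water_fraction = p$water_fraction,
    tissue_density = p$tissue_density, duty_cycle = p$duty_cycle,
    rho_node = ch$rho_node, rho_unmyelinated = ch$rho_unmyelinated,
    ion_flux_per_channel = ch$ion_flux_per_channel,
    waters_per_na = ch$waters_per_na)
}

#' Predict diffusion-weighted signals from a fitted activation model
#'
#' Evaluates the Stejskal-Tanner signal for both model states, either along
#' a single gradient direction at given b-values or over a full
#' [gradient_scheme()].
#'
#' @param object An `"adti_model"`.
#' @param b Numeric b-values in s mm^-2 (ignored when `scheme` is given).
#' @param direction `"perpendicular"` or `"parallel"` to the fiber axis.
#' @param scheme Optional [gradient_scheme()]; overrides `b`/`direction`.
#' @param A0 Unweighted signal amplitude.
#' @param ... Unused.
#' @return A data frame with columns `b`, `signal_inactive`, `signal_active`
#'   and `rel_drop` (fractional signal decrease on activation).
#' @examples
#' predict(adti_model(), b = 600)
#' @export
predict.adti_model <- function(object, b = 600,
                               direction = c("perpendicular", "parallel"),
                               scheme = NULL, A0 = 1, ...) {
  if (is.null(scheme)) {
    direction <- match.arg(direction)
    g <- if (direction == "parallel") c(0, 0, 1) else c(1, 0, 0)
    scheme <- gradient_scheme_from_table(
      data.frame(bval = b, gx = g[1], gy = g[2], gz = g[3]))
  }
  s0 <- synthesize_signal(object$inactive, scheme, A0 = A0)
  s1 <- synthesize_signal(object$active, scheme, A0 = A0)
  data.frame(b = scheme$bval, signal_inactive = s0, signal_active = s1,
             rel_drop = ifelse(s0 > 0, (s0 - s1) / s0, 0))
}

#' Simulate noisy phantom realisations of a fitted activation model
#'
#' Wraps [run_phantom()]: embeds the model's inactive/active tensors in a
#' voxel-grid phantom, adds noise and refits tensors voxelwise.
#'
#' @param object An `"adti_model"`.
#' @param nsim Number of noise repetitions.
#' @param seed Master seed for reproducibility.
#' @param ... Passed to [phantom_config()] (e.g. `snr`, `grid`, `noise`).
#' @return A `"phantom_result"` object.
#' @export
simulate.adti_model <- function(object, nsim = 1, seed = 1L, ...) {
  cfg <- phantom_config(model = object, repetitions = nsim, seed = seed, ...)
  run_phantom(cfg)
}

#' Plot eigenvalue and anisotropy changes of an activation model
#'
#' Side-by-side eigenvalue bars for the inactive and active states with the
#' FA values annotated.
#'
#' @param x An `"adti_model"`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.adti_model <- function(x, ...) {
  m <- rbind(inactive = as.numeric(x$inactive),
             active = as.numeric(x$active))
  colnames(m) <- expression(lambda[1], lambda[2], lambda[3])
  mid <- graphics::barplot(m, beside = TRUE, ylab = "diffusivity (m^2/s)",
                           legend.text = rownames(m), ...)
  graphics::mtext(sprintf("FA %.3f -> %.3f (%+.1f%%)", x$FA, x$FA_star,
                          100 * x$rel_change_FA), side = 3, line = 0.5)
  invisible(mid)
}
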