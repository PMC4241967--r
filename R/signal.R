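# Gyromagnetic ratio of 1H, rad s^-1 T^-1
.GAMMA_1H <- 2.675e8

#' Pulsed-gradient spin-echo sequence parameters
#'
#' Either the b-value is given directly, or it is derived from the gradient
#' amplitude and timing via [b_value()].
#'
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1 (default: proton).
#' @param g_amplitude Diffusion-gradient amplitude, T m^-1.
#' @param delta Gradient pulse duration, ms.
#' @param Delta Separation of the gradient pulse rising edges, ms.
#' @param b Optional b-value in s mm^-2, overriding the timing parameters.
#' @return An object of class `"sequence_params"`.
#' @examples
#' sequence_params(g_amplitude = 30e-3, delta = 20, Delta = 35)
#' @export
sequence_params <- function(gamma = .GAMMA_1H, g_amplitude = NULL,
                            delta = NULL, Delta = NULL, b = NULL) {
  if (!is.null(b) && b < 0) stop("'b' must be non-negative", call. = FALSE)
  if (!is.null(delta) && !is.null(Delta)) {
    if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
    if (Delta < delta)
      stop("'Delta' must be at least 'delta'", call. = FALSE)
  }
  structure(list(gamma = gamma, g_amplitude = g_amplitude, delta = delta,
                 Delta = Delta, b = b), class = "sequence_params")
}

#' Diffusion weighting (b-value) of a pulsed-gradient sequence
#'
#' `b = (gamma * g * delta)^2 * (Delta - delta/3)`, reported in the
#' conventional unit s mm^-2.  If the sequence carries an explicit `b`, that
#' value is returned unchanged.
#'
#' @param seq A [sequence_params()] object.
#' @return b-value in s mm^-2.
#' @examples
#' b_value(sequence_params(g_amplitude = 30e-3, delta = 20, Delta = 35))
#' @export
b_value <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  if (!is.null(seq$b)) return(seq$b)
  if (is.null(seq$g_amplitude) || is.null(seq$delta) || is.null(seq$Delta))
    stop("need gamma, g_amplitude, delta and Delta (or an explicit b)",
         call. = FALSE)
  delta_s <- seq$delta * 1e-3
  Delta_s <- seq$Delta * 1e-3
  b_si <- (seq$gamma * seq$g_amplitude * delta_s)^2 * (Delta_s - delta_s / 3)
  b_si * 1e-6   # s m^-2 -> s mm^-2
}

#' Stejskal-Tanner echo attenuation
#'
#' `A = A0 * exp(-b * D)`, with the diffusivity converted from m^2 s^-1 to
#' mm^2 s^-1 to match the b-value unit.
#'
#' @param A0 Unweighted signal amplitude (>= 0).
#' @param b b-value in s mm^-2 (>= 0).
#' @param D Diffusivity in m^2 s^-1 (>= 0).
#' @return Attenuated signal amplitude.
#' @examples
#' echo_attenuation(1, 600, 2e-10)
#' @export
echo_attenuation <- function(A0, b, D) {
  if (any(A0 < 0) || any(b < 0) || any(D < 0))
    stop("'A0', 'b' and 'D' must be non-negative", call. = FALSE)
  A0 * exp(-b * D * 1e6)
}

#' Relative echo drop caused by a diffusivity increase
#'
#' `1 - exp(-b * (D_active - D_inactive))`: the fractional signal decrease
#' in the active state relative to the inactive state at the same b.
#'
#' @param b b-value in s mm^-2.
#' @param D_inactive,D_active Perpendicular diffusivities, m^2 s^-1.
#' @return Fractional signal drop (positive when diffusivity increases).
#' @examples
#' relative_signal_drop(600, 2.00e-10, 2.13e-10)   # about 0.77%
#' @export
relative_signal_drop <- function(b, D_inactive, D_active) {
  1 - exp(-b * (D_active - D_inactive) * 1e6)
}

#' Is a signal drop detectable at a given SNR?
#'
#' A fractional signal change is called detectable when it exceeds `z` noise
#' standard deviations of the normalised signal, i.e. `drop >= z / snr`.
#'
#' @param drop Fractional signal drop.
#' @param snr Signal-to-noise ratio of the unweighted image (> 0).
#' @param z Detection threshold in units of noise standard deviations.
#' @return A list with `detectable` (logical), `margin` (`drop - z/snr`) and
#'   `threshold` (`z/snr`).
#' @examples
#' detectable(0.0077, snr = 400)
#' @export
detectable <- function(drop, snr, z = 3) {
  if (snr <= 0) stop("'snr' must be positive", call. = FALSE)
  thr <- z / snr
  list(detectable = drop >= thr, margin = drop - thr, threshold = thr)
}

#' Diffusion gradient scheme
#'
#' A table of b-values and unit gradient directions, with at least one b = 0
#' entry so that tensors can be fitted.  The default scheme spreads `n_dirs`
#' directions approximately uniformly over the sphere with a deterministic
#' golden-angle (Fibonacci) spiral.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param b b-value of the weighted volumes, s mm^-2.
#' @param n_b0 Number of unweighted (b = 0) volumes, prepended.
#' @return An object of class `"gradient_scheme"`: a data frame with columns
#'   `bval`, `gx`, `gy`, `gz`.
#' @examples
#' gradient_scheme()
#' @export
gradient_scheme <- function(n_dirs = 30, b = 600, n_b0 = 1) {
  if (n_dirs < 1 || n_b0 < 1)
    stop("need at least one direction and one b = 0 volume", call. = FALSE)
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(gx = r * cos(phi), gy = r * sin(phi), gz = z)
  tab <- data.frame(bval = c(rep(0, n_b0), rep(b, n_dirs)),
                    rbind(matrix(0, n_b0, 3,
                                 dimnames = list(NULL, colnames(dirs))),
                          dirs))
  gradient_scheme_from_table(tab)
}

#' Build a gradient scheme from a b-value/direction table
#'
#' @param tab Data frame with columns `bval`, `gx`, `gy`, `gz`.  Directions
#'   of weighted volumes must be unit vectors (tolerance 1e-6); b = 0 rows
#'   may carry zero vectors.
#' @return A `"gradient_scheme"` object.
#' @export
gradient_scheme_from_table <- function(tab) {
  tab <- as.data.frame(tab)
  req <- c("bval", "gx", "gy", "gz")
  if (!all(req %in% names(tab)))
    stop("scheme table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(tab$bval < 0)) stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(tab$gx^2 + tab$gy^2 + tab$gz^2)
  bad <- tab$bval > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("gradient directions must be unit vectors (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  structure(tab[req], class = c("gradient_scheme", "data.frame"))
}

#' Read a gradient scheme from text files
#'
#' Supports the conventional two-file layout (a `bval` file with one row of
#' b-values and a `bvec` file with three rows of direction components) and a
#' single-file four-column layout (`bval gx gy gz`).
#'
#' @param bval_file Path to the b-value file, or to the four-column file when
#'   `bvec_file` is `NULL`.
#' @param bvec_file Optional path to the direction file.
#' @return A `"gradient_scheme"` object.
#' @export
read_gradient_scheme <- function(bval_file, bvec_file = NULL) {
  if (is.null(bvec_file)) {
    tab <- utils::read.table(bval_file, header = FALSE)
    if (ncol(tab) != 4)
      stop("single-file scheme must have 4 columns: bval gx gy gz",
           call. = FALSE)
    names(tab) <- c("bval", "gx", "gy", "gz")
    return(gradient_scheme_from_table(tab))
  }
  bvals <- scan(bval_file, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_file, header = FALSE))
  if (nrow(bvecs) != 3 || ncol(bvecs) != length(bvals))
    stop("bvec file must have 3 rows matching the number of b-values",
         call. = FALSE)
  gradient_scheme_from_table(data.frame(bval = bvals, gx = bvecs[1, ],
                                        gy = bvecs[2, ], gz = bvecs[3, ]))
}

#' Write a gradient scheme to text files
#'
#' @param scheme A `"gradient_scheme"`.
#' @param bval_file Output path for b-values (or the four-column file when
#'   `bvec_file` is `NULL`).
#' @param bvec_file Optional output path for the 3-row direction table.
#' @return Invisibly, the paths written.
#' @export
write_gradient_scheme <- function(scheme, bval_file, bvec_file = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (is.null(bvec_file)) {
    utils::write.table(scheme, bval_file, row.names = FALSE,
                       col.names = FALSE)
    return(invisible(bval_file))
  }
  writeLines(paste(scheme$bval, collapse = " "), bval_file)
  utils::write.table(t(as.matrix(scheme[c("gx", "gy", "gz")])), bvec_file,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bval_file, bvec_file))
}

# Build the 3x3 tensor (m^2/s) from eigenvalues and an orientation spec:
# either the principal axis (length-3) with an arbitrary orthonormal
# completion for the perpendicular eigenvectors, or a full 3x3 matrix whose
# columns are the eigenvectors of lambda1..lambda3.
.build_tensor <- function(state, axis) {
  l <- as.numeric(unclass(state))
  if (is.matrix(axis)) {
    V <- axis
    if (!all(dim(V) == c(3, 3)) ||
        max(abs(crossprod(V) - diag(3))) > 1e-6)
      stop("orientation matrix must be 3x3 orthonormal", call. = FALSE)
  } else {
    e1 <- axis / sqrt(sum(axis^2))
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    V <- cbind(e1, e2, e3)
  }
  V %*% diag(l) %*% t(V)
}

#' Synthesize diffusion-weighted signals from a tensor
#'
#' Generalised Stejskal-Tanner signal `A0 * exp(-b * g' D g)` for every entry
#' of a gradient scheme.  For a gradient along the principal axis this
#' reduces to [echo_attenuation()] with `lambda1`; perpendicular gradients
#' probe `lambda2`/`lambda3`.
#'
#' @param state A [tensor_state()].
#' @param scheme A [gradient_scheme()].
#' @param A0 Unweighted amplitude.
#' @param axis Principal-axis orientation: a length-3 vector (default:
#'   z-axis, the fiber-tract convention) or a 3x3 orthonormal matrix whose
#'   columns are the eigenvectors for `lambda1`, `lambda2`, `lambda3`.
#' @return Numeric vector of signals, one per scheme row.
#' @examples
#' s <- synthesize_signal(tensor_state(1e-9, 2e-10, 2e-10), gradient_scheme())
#' @export
synthesize_signal <- function(state, scheme, A0 = 1, axis = c(0, 0, 1)) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  D <- .build_tensor(state, axis) * 1e6   # -> mm^2/s
  G <- as.matrix(scheme[c("gx", "gy", "gz")])
  bd <- scheme$bval * rowSums((G %*% D) * G)
  unname(A0 * exp(-bd))
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Estimates a symmetric diffusion tensor from diffusion-weighted signals by
#' ordinary least squares on log-signals (no weighting, no positivity
#' constraint).  Requires at least six non-collinear weighted directions and
#' one b = 0 measurement; non-positive signals are masked with a warning.
#'
#' @param signals Numeric vector of signals, one per scheme row.
#' @param scheme A [gradient_scheme()].
#' @return An object of class `"dti_fit"`: list with `tensor` (3x3, m^2/s),
#'   `eigenvalues` (descending, m^2/s), `eigenvectors` (columns matching the
#'   eigenvalues), `A0`, `fa`, `md`.
#' @examples
#' sch <- gradient_scheme()
#' fit <- fit_tensor(synthesize_signal(tensor_state(1e-9, 2e-10, 2e-10), sch), sch)
#' fit$fa
#' @export
fit_tensor <- function(signals, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (length(signals) != nrow(scheme))
    stop("'signals' length must match the scheme", call. = FALSE)
  ok <- signals > 0
  if (!all(ok)) {
    warning("masking ", sum(!ok), " non-positive signal(s)")
    signals <- signals[ok]
    scheme <- scheme[ok, , drop = FALSE]
  }
  if (!any(scheme$bval == 0))
    stop("scheme must retain at least one b = 0 measurement", call. = FALSE)
  G <- as.matrix(scheme[c("gx", "gy", "gz")])
  b <- scheme$bval
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])
  if (qr(X)$rank < 7)
    stop("degenerate gradient scheme: need >= 6 non-collinear directions ",
         "and a b = 0 volume", call. = FALSE)
  beta <- qr.solve(X, log(signals))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3) * 1e-6  # -> m^2/s
  e <- eigen(D, symmetric = TRUE)
  lam <- e$values   # descending
  fa <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2) / sum(lam^2))
  structure(list(tensor = D, eigenvalues = lam, eigenvectors = e$vectors,
                 A0 = exp(beta[1]), fa = fa, md = mean(lam)),
            class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat("Diffusion tensor fit\n")
  cat(sprintf("  eigenvalues: (%.4g, %.4g, %.4g) m^2/s\n",
              x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  cat(sprintf("  MD = %.4g m^2/s, FA = %.4f, A0 = %.4g\n",
              x$md, x$fa, x$A0))
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) {
  c(object$eigenvalues, fa = object$fa, md = object$md, A0 = object$A0)
}
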