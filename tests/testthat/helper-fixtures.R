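# Shared fixtures and small utilities for the test suite.

# Single-class bundles for additivity/linearity checks.
one_class_bundle <- function(diameter = 3, count = 1, myelinated = FALSE,
                             geometry = bundle_geometry()) {
  axon_bundle(data.frame(diameter_um = diameter, count = count,
                         myelinated = myelinated), geometry)
}

# Random orthonormal 3x3 matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))))
}

# Axially symmetric FA closed form in D_parallel and D_perp.
fa_closed_form <- function(d_par, d_perp) {
  m <- (d_par + 2 * d_perp) / 3
  sqrt(1.5) * sqrt(((d_par - m)^2 + 2 * (d_perp - m)^2) /
                     (d_par^2 + 2 * d_perp^2))
}
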