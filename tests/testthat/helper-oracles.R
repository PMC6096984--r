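# Independent oracles used across the suite.

# Prolate-spheroid surface area by adaptive quadrature of the
# surface-of-revolution integral S = int 2 pi y sqrt(1 + y'^2) dx with
# y(x) = b sqrt(1 - x^2/a^2), independent of the closed form in the package.
spheroid_area_quadrature <- function(a, b, rel.tol = 1e-12) {
  f <- function(x) {
    y <- b * sqrt(pmax(1 - x^2 / a^2, 0))
    dy <- -b * x / (a^2 * sqrt(pmax(1 - x^2 / a^2, 1e-300)))
    2 * pi * y * sqrt(1 + dy^2)
  }
  stats::integrate(f, -a, a, rel.tol = rel.tol, subdivisions = 500L)$value
}

# Reduced volume of two equal unit spheres, analytic.
nu_equal_spheres <- 1 / sqrt(2)

# Neck-condition local curvature written out independently from the
# package's grouping (direct transcription of the adopted algebra).
neck_m_reference <- function(Ra, Rb, kr) {
  s2 <- Ra^2 + Rb^2
  0.5 * (1 / Ra + 1 / Rb) - pi * kr * (sqrt(s2) - Ra - Rb) / s2
}
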