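# Shared fixtures and independent oracles for the test suite.

# Independent quadratic least-squares oracle: brute-force normal equations
# solved with base solve(). Returns c(a, b, c).
quad_oracle <- function(x, y) {
  X <- cbind(x^2, x, 1)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Bent triatomic with water-like connectivity (O central, two H).
water_geometry <- function() {
  geometry(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(0.9572, 0, 0),
                 c(-0.2399872, 0.9266272, 0)),
           label = "water")
}

# Planar formaldehyde: trigonal carbon with 3 neighbors.
formaldehyde_geometry <- function() {
  geometry(c("C", "O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(0, 1.205, 0),
                 c(0.943, -0.587, 0),
                 c(-0.943, -0.587, 0)),
           label = "formaldehyde")
}

# A mode set over a single geometry from explicit raw vectors.
simple_mode_set <- function(geom, raw_vectors, freqs = NULL) {
  if (is.null(freqs)) freqs <- seq(100, by = 100, length.out = length(raw_vectors))
  mode_set(geom, freqs, raw_vectors)
}
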