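# Shared test fixtures, generated in code.

# uniform disc phantom-like object: `ne` channels of constant mu inside a
# disc of radius r_cm on an n x n grid with pixel size px_cm
disc_phantom <- function(n = 64, r_cm = 2, mu = 0.2, ne = 1, px_cm = 0.1) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- t(xs)
  ctr <- (n + 1) / 2
  inside <- ((xs - ctr)^2 + (ys - ctr)^2) * px_cm^2 <= r_cm^2
  lac <- array(0, c(ne, n, n))
  for (e in seq_len(ne)) lac[e, , ][inside] <- mu * e
  list(lac = lac, energies = seq_len(ne) * 10 + 10, inside = inside,
       px = px_cm)
}

# small fan-beam geometry for fast unit tests
test_geometry <- function(n_angles = 120, ndet = 48, pitch_mm = 2.4) {
  scan_geometry(57.50, 58.05, ndet, pitch_mm,
                seq(0, 360 - 360 / n_angles, by = 360 / n_angles))
}

# deterministic pseudo-random stack
random_stack <- function(ne = 6, n = 20, seed = 99) {
  set.seed(seed)
  spectral_image_stack(array(rnorm(ne * n * n), c(ne, n, n)),
                       seq_len(ne), "random")
}
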