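# shared fixtures, built in code

# deterministic random fingerprint matrix
rand_fps <- function(n, len = 64L, density = 0.3, seed = 1L) {
  set.seed(seed)
  m <- matrix(rbinom(n * len, 1L, density), nrow = n)
  m[rowSums(m) == 0L, 1L] <- 1L
  m
}

# small activity class with given potencies
toy_class <- function(potencies, len = 64L, seed = 1L, name = "toy") {
  n <- length(potencies)
  activity_class(name, sprintf("c%02d", seq_len(n)),
                 rand_fps(n, len, seed = seed), potencies)
}

# fingerprint with exactly the given on-bit positions
fp_bits <- function(on, len = 16L) {
  v <- integer(len)
  v[on] <- 1L
  v
}

# tiny rendered-image stand-in: gray matrix as al_image
gray_image <- function(m, encoding = "grayscale") {
  al_image(m, meta = list(encoding = encoding))
}

# quick surface for render tests
demo_surface <- function(n_peaks = 2L, grid = 32L, seed = 1L) {
  generate_surface_fixture(surface_fixture_spec(
    grid_size = grid, n_peaks = n_peaks, seed = seed
  ))
}
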