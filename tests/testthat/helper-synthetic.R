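# Shared fixtures, all built in code.

# Switch off the PSF and read noise so planted structure is an exact oracle.
noiseless <- function(params) {
  q <- unclass(params)
  q$noise_sd <- 0
  q$psf_sigma_px <- 0
  httscreen:::validate_culture_params(q)
}

as_layout <- function(df) httscreen:::validate_plate_layout(df)

# Minimal valid layout: n vehicle wells per genotype plus treated 138Q wells.
tiny_layout <- function(n_treatments = 2L, n_vehicle = 2L, duplicates = 2L) {
  screen_layout(n_treatments = n_treatments,
                n_vehicle_per_genotype = n_vehicle,
                duplicates = duplicates)
}

# Draw a filled disc of intensity `val` onto an integer matrix.
draw_disc <- function(m, ci, cj, r, val) {
  for (i in max(1, ci - r - 1):min(nrow(m), ci + r + 1)) {
    for (j in max(1, cj - r - 1):min(ncol(m), cj + r + 1)) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- val
    }
  }
  m
}

# A feature table of n synthetic per-field profiles (no imaging involved),
# for statistics-level tests.
random_feature_table <- function(n, shift = 0) {
  pct <- t(vapply(seq_len(n), function(i) {
    x <- runif(3)
    100 * x / sum(x)
  }, numeric(3)))
  pct2 <- t(vapply(seq_len(n), function(i) {
    x <- runif(3)
    100 * x / sum(x)
  }, numeric(3)))
  tibble::tibble(
    pct_small_neuromere = pct[, 1], pct_medium_neuromere = pct[, 2],
    pct_large_neuromere = pct[, 3],
    mean_neuromere_area = rnorm(n, 180 + shift, 20),
    pct_short_neurite = pct2[, 1], pct_medium_neurite = pct2[, 2],
    pct_long_neurite = pct2[, 3],
    mean_neurite_length = rnorm(n, 60 + shift, 8)
  )
}
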