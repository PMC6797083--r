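# Shared fixture builders. Oracles here are deliberately independent
# reimplementations (plain vectorized R) of what the package computes in
# compiled code.

# Analytic spherocylinder membership on the pixel-center grid: the oracle
# for rasterization and for constructing morphometry fixtures.
sphero_mask <- function(nr, nc, x_um, y_um, theta, length_um, width_um, px) {
  xs <- ((seq_len(nc)) - 0.5) * px
  ys <- ((seq_len(nr)) - 0.5) * px
  X <- matrix(xs, nr, nc, byrow = TRUE) - x_um
  Y <- matrix(ys, nr, nc) - y_um
  hx <- (length_um - width_um) / 2
  ux <- cos(theta); uy <- sin(theta)
  t <- pmin(pmax(X * ux + Y * uy, -hx), hx)
  sqrt((X - t * ux)^2 + (Y - t * uy)^2) < width_um / 2
}

# A clean scene: fixed-width cells, no PSF, no noise, generous separation.
clean_scene_spec <- function(n = 10L, width = 1.0, width_sd = 0,
                             len = 3, len_sd = 0, shape = c(512L, 512L),
                             sep = 6, psf = 0, expansion = 1) {
  scene_spec(shape, 0.1,
             list(species_spec("sp", width, width_sd, len, len_sd,
                               expansion_factor = expansion)),
             counts = n, gel_factor = max(4, expansion),
             min_separation_um = sep, background_level = 0,
             psf_sigma_um = psf, noise = list(shot_scale = 0, read_sd = 0))
}

noisy_scene_spec <- function(n = 10L, width = 0.8, width_sd = 0.05,
                             len = 3, len_sd = 0.4, shape = c(512L, 512L),
                             sep = 6, expansion = 1) {
  scene_spec(shape, 0.1,
             list(species_spec("sp", width, width_sd, len, len_sd,
                               expansion_factor = expansion)),
             counts = n, gel_factor = max(4, expansion),
             min_separation_um = sep, background_level = 0.02,
             psf_sigma_um = 0.1, noise = list(shot_scale = 200, read_sd = 0.01))
}

# Label centroids straight from the label matrix (oracle for segmentation
# accuracy, independent of measure_cells).
label_centroids_um <- function(labels, px) {
  L <- labels$labels
  idx <- which(L > 0L)
  rr <- (idx - 1L) %% nrow(L) + 1L
  cc <- (idx - 1L) %/% nrow(L) + 1L
  x <- tapply((cc - 0.5) * px, L[idx], mean)
  y <- tapply((rr - 0.5) * px, L[idx], mean)
  data.frame(label = as.integer(names(x)), x_um = as.numeric(x),
             y_um = as.numeric(y))
}

# Greedy nearest matching of measured centroids to truth (scenes here are
# well separated, so matching is unambiguous).
match_to_truth <- function(truth, cent) {
  stopifnot(nrow(truth) == nrow(cent))
  m <- vapply(seq_len(nrow(truth)), function(i)
    which.min((cent$x_um - truth$x_um[i])^2 + (cent$y_um - truth$y_um[i])^2),
    integer(1))
  expect_equal(sort(m), seq_len(nrow(cent)))
  m
}
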