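#' Species specification for synthetic scenes
#'
#' Describes one bacterial species for the synthetic micrograph generator:
#' pre-expansion width/length distributions (sampled as truncated normals)
#' and the species-specific expansion factor, i.e. how much the cell body
#' itself expands when the surrounding hydrogel expands. A fully digested
#' wall expands with the gel (factor ~4), an intact gram-positive wall
#' hardly at all (factor ~1).
#'
#' @param name Species label.
#' @param width_mean_um,width_sd_um Pre-expansion cell width distribution (um).
#' @param length_mean_um,length_sd_um Pre-expansion cell length distribution (um).
#' @param expansion_factor Cell-body linear expansion factor, >= 1.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, width_mean_um, width_sd_um = 0,
                         length_mean_um, length_sd_um = 0,
                         expansion_factor = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (width_mean_um <= 0 || width_sd_um < 0 || length_sd_um < 0)
    stop("width_mean_um must be > 0 and sds >= 0", call. = FALSE)
  if (length_mean_um < width_mean_um)
    stop("length_mean_um must be >= width_mean_um (rod-shaped cell)", call. = FALSE)
  if (expansion_factor < 1)
    stop("expansion_factor must be >= 1", call. = FALSE)
  structure(list(name = name, width_mean_um = width_mean_um,
                 width_sd_um = width_sd_um, length_mean_um = length_mean_um,
                 length_sd_um = length_sd_um,
                 expansion_factor = expansion_factor),
            class = "species_spec")
}

#' Scene specification for the synthetic micrograph generator
#'
#' @param image_shape_px Integer `(rows, cols)` of the pre-expansion frame.
#' @param pixel_size_um Pixel size in um/px (default 0.1, a typical confocal
#'   sampling for a 63x/1.4 objective).
#' @param species List of [species_spec()] objects.
#' @param counts Integer vector of per-species cell counts (same length as
#'   `species`).
#' @param gel_factor Bulk hydrogel linear expansion factor `g >= 1`; acts on
#'   cell positions (and the frame) in post-expansion scenes.
#' @param min_separation_um Minimum pairwise centroid separation enforced by
#'   rejection placement.
#' @param background_level Constant background intensity added to the frame.
#' @param psf_sigma_um Isotropic Gaussian PSF sigma (um); 0 disables blur.
#' @param noise List `(shot_scale, read_sd)`: shot noise is scaled Poisson
#'   with `shot_scale` photons per intensity unit (0 disables), read noise is
#'   additive Gaussian with sd `read_sd` (0 disables).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape_px = c(512L, 512L), pixel_size_um = 0.1,
                       species, counts, gel_factor = 4,
                       min_separation_um = 4, background_level = 0.02,
                       psf_sigma_um = 0.1,
                       noise = list(shot_scale = 200, read_sd = 0.01)) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (length(image_shape_px) != 2L || any(image_shape_px < 1))
    stop("image_shape_px must be (rows, cols) >= 1", call. = FALSE)
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "species_spec")))
  counts <- as.integer(counts)
  if (length(counts) != length(species) || any(counts < 0))
    stop("counts must be nonnegative, one per species", call. = FALSE)
  if (gel_factor < 1) stop("gel_factor must be >= 1", call. = FALSE)
  if (min_separation_um < 0 || psf_sigma_um < 0 || background_level < 0)
    stop("lengths and background must be nonnegative", call. = FALSE)
  stopifnot(is.list(noise), noise$shot_scale >= 0, noise$read_sd >= 0)
  structure(list(image_shape_px = as.integer(image_shape_px),
                 pixel_size_um = pixel_size_um, species = species,
                 counts = counts, gel_factor = gel_factor,
                 min_separation_um = min_separation_um,
                 background_level = background_level,
                 psf_sigma_um = psf_sigma_um, noise = noise),
            class = "scene_spec")
}

# Deterministic per-cell substream seed, kept below 2^31 - 1.
.substream <- function(seed, i) {
  # modulo in double precision first; result always fits a 32-bit integer
  as.integer(((abs(seed) %% 2147483647) * 48271 + i * 9973) %% 2147483562)
}

.rtruncnorm1 <- function(mean, sd, lower = 0) {
  if (sd == 0) return(max(mean, lower))
  lo <- max(lower, mean - 4 * sd)
  hi <- mean + 4 * sd
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  mean
}

# Sample per-cell geometry (width/length/orientation + phenotype draw) from
# the cell's own substream; placement also draws from that substream.
.sample_cells <- function(spec, seed) {
  n_total <- sum(spec$counts)
  if (n_total == 0L) {
    return(data.frame(id = integer(), species = character(),
                      x_um = numeric(), y_um = numeric(),
                      orientation_rad = numeric(), length_um = numeric(),
                      width_um = numeric(), phen_u = numeric()))
  }
  sp_idx <- rep(seq_along(spec$species), spec$counts)
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sp <- spec$species[[sp_idx[i]]]
    set.seed(.substream(seed, i))
    w <- .rtruncnorm1(sp$width_mean_um, sp$width_sd_um, lower = 1e-6)
    l <- .rtruncnorm1(sp$length_mean_um, sp$length_sd_um, lower = w)
    l <- max(l, w)
    th <- stats::runif(1, 0, pi)
    u <- stats::runif(1) # phenotype draw, used only by halo scenes
    out[[i]] <- data.frame(id = i, species = sp$name, x_um = NA_real_,
                           y_um = NA_real_, orientation_rad = th,
                           length_um = l, width_um = w, phen_u = u)
  }
  do.call(rbind, out)
}

# Rejection placement: positions uniform in the frame inset by half the cell
# length; pairwise centroid separation >= min_separation_um; 10,000 attempts
# per cell before giving up.
.place_cells <- function(cells, spec, seed) {
  n <- nrow(cells)
  if (n == 0L) return(cells)
  h_um <- spec$image_shape_px[1] * spec$pixel_size_um
  w_um <- spec$image_shape_px[2] * spec$pixel_size_um
  area <- (cells$length_um - cells$width_um) * cells$width_um +
    pi * (cells$width_um / 2)^2
  if (sum(area) > 0.3 * h_um * w_um)
    stop("scene too crowded: total cell area exceeds 30% of the frame",
         call. = FALSE)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.substream(seed, i) + 1L)
    inset <- cells$length_um[i] / 2
    if (2 * inset >= w_um || 2 * inset >= h_um)
      stop("cell longer than the frame", call. = FALSE)
    ok <- FALSE
    for (att in seq_len(10000L)) {
      x <- stats::runif(1, inset, w_um - inset)
      y <- stats::runif(1, inset, h_um - inset)
      if (i == 1L ||
          all((x - xs[seq_len(i - 1)])^2 + (y - ys[seq_len(i - 1)])^2 >=
              spec$min_separation_um^2)) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("scene too crowded: placement failed after 10000 attempts",
           call. = FALSE)
  }
  cells$x_um <- xs
  cells$y_um <- ys
  cells
}

# Add one spherocylinder to `img` (pixel (r, c) center at
# ((c - 0.5) px, (r - 0.5) px); a pixel is interior iff its center-to-axis
# distance is strictly < the radius). Delegates to compiled code that
# modifies the matrix in place for speed; callers reassign the return value
# so the R-level semantics stay value-like.
.paint_cell <- function(img, x, y, theta, length_um, width_um, px,
                        amplitude = 1, halo = NULL) {
  if (is.null(halo)) {
    cpp_paint_cell(img, x, y, theta, length_um, width_um, px, amplitude,
                   0L, 0, 0, 0, 0, 0)
  } else {
    cpp_paint_cell(img, x, y, theta, length_um, width_um, px, amplitude,
                   1L, halo$r_in, halo$r_out, halo$sigma, halo$core_floor,
                   halo$pad_um)
  }
  img
}

.apply_optics_noise <- function(img, spec, noise_seed) {
  px <- spec$pixel_size_um
  img <- img + spec$background_level
  if (spec$psf_sigma_um > 0)
    img <- cpp_gaussian_blur(img, spec$psf_sigma_um / px)
  set.seed(noise_seed)
  if (spec$noise$shot_scale > 0) {
    n <- length(img)
    img[] <- stats::rpois(n, pmax(img, 0) * spec$noise$shot_scale) /
      spec$noise$shot_scale
  }
  if (spec$noise$read_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise$read_sd),
                        nrow(img))
  attr(img, "pixel_size_um") <- px
  img
}

.finish_truth <- function(cells) {
  cells$phenotype <- if (nrow(cells)) "normal" else character()
  cells$halo_width_um <- if (nrow(cells)) NA_real_ else numeric()
  cells$phen_u <- NULL
  cells
}

#' Render a synthetic fluorescence micrograph
#'
#' Draws per-cell geometry from the species distributions, places cells by
#' rejection sampling, rasterizes each as a constant-intensity spherocylinder
#' (rectangle of length `L - W` capped by half-disks of diameter `W`),
#' convolves with a Gaussian PSF and applies scaled-Poisson shot noise plus
#' Gaussian read noise. Fully deterministic given `(spec, seed)`.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; drives all sampling via per-cell substreams.
#' @return List with `image` (matrix, `pixel_size_um` attribute) and `truth`
#'   (data.frame: id, species, x_um, y_um, orientation_rad, length_um,
#'   width_um, phenotype, halo_width_um).
#' @export
render_scene <- function(spec, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  cells <- .place_cells(.sample_cells(spec, seed), spec, seed)
  img <- matrix(0, spec$image_shape_px[1], spec$image_shape_px[2])
  px <- spec$pixel_size_um
  for (i in seq_len(nrow(cells)))
    img <- .paint_cell(img, cells$x_um[i], cells$y_um[i],
                       cells$orientation_rad[i], cells$length_um[i],
                       cells$width_um[i], px)
  img <- .apply_optics_noise(img, spec, .substream(seed, 0L))
  list(image = img, truth = .finish_truth(cells))
}

#' Render a matched pre/post expansion image pair
#'
#' The pre-expansion scene is sampled and placed as in [render_scene()]. The
#' post-expansion scene reuses the same cells: centroids are scaled by the
#' gel factor `g` (the bulk hydrogel expansion, which acts on inter-cell
#' distances regardless of wall digestion) while each cell's width and
#' length are scaled by its species' `expansion_factor` (wall-limited). The
#' post frame is `g` times larger at the same pixel size, mirroring the
#' convention of rescaling scale bars rather than images.
#'
#' @inheritParams render_scene
#' @return List `pre_image`, `post_image`, `pre_truth`, `post_truth`.
#' @export
render_expansion_pair <- function(spec, seed) {
  stopifnot(inherits(spec, "scene_spec"))
  rho <- vapply(spec$species, `[[`, numeric(1), "expansion_factor")
  if (spec$gel_factor < max(c(1, rho)))
    stop("gel_factor must be >= every species expansion_factor", call. = FALSE)
  pre <- render_scene(spec, seed)
  cells <- .place_cells(.sample_cells(spec, seed), spec, seed)
  g <- spec$gel_factor
  names(rho) <- vapply(spec$species, `[[`, character(1), "name")
  post_cells <- cells
  post_cells$x_um <- cells$x_um * g
  post_cells$y_um <- cells$y_um * g
  f <- rho[cells$species]
  post_cells$width_um <- cells$width_um * f
  post_cells$length_um <- cells$length_um * f
  post_spec <- spec
  post_spec$image_shape_px <- as.integer(round(spec$image_shape_px * g))
  img <- matrix(0, post_spec$image_shape_px[1], post_spec$image_shape_px[2])
  for (i in seq_len(nrow(post_cells)))
    img <- .paint_cell(img, post_cells$x_um[i], post_cells$y_um[i],
                       post_cells$orientation_rad[i], post_cells$length_um[i],
                       post_cells$width_um[i], spec$pixel_size_um)
  img <- .apply_optics_noise(img, post_spec, .substream(seed, -1L) + 7L)
  list(pre_image = pre$image, post_image = img,
       pre_truth = pre$truth, post_truth = .finish_truth(post_cells))
}

#' Render a two-channel DNA-halo scene
#'
#' Emulates the DNA-translocation phenotype seen after expansion of cells
#' with a damaged wall: the cytoplasm stays at its unexpanded width while
#' the chromosome escapes through wall pores and forms a concentric DNA
#' cloud several times wider. Every cell appears in the cytoplasm channel at
#' its unexpanded size; each cell is independently a halo cell with
#' probability `halo_fraction`. Halo cells render, in the DNA channel, an
#' annular (edge-bright) cloud of outer width `halo_factor * width_um` with
#' Gaussian falloff at the rims and a dim core; non-halo cells render DNA
#' colocalized with the cytoplasm at amplitude `dna_amplitude`.
#'
#' The radial profile of the halo is not constrained by any measurement, so
#' it is configurable: amplitude 1 on the annulus `[0.5, 1] * r_out`,
#' Gaussian shoulders of sigma `0.05 * r_out`, core floor 0.35.
#'
#' @inheritParams render_scene
#' @param halo_fraction Probability that a cell is a halo cell, in `[0, 1]`.
#' @param halo_factor Ratio of DNA-cloud width to cell width, > 1 (the
#'   wall-damage phenotype shows ~4).
#' @param dna_amplitude Amplitude of the DNA channel (halo amplitude is
#'   `0.5 * dna_amplitude` to keep the cloud dimmer than the cytoplasm core).
#' @return List `cyto_image`, `dna_image` (registered channels) and `truth`
#'   with per-cell `phenotype` and `halo_width_um`.
#' @export
render_halo_scene <- function(spec, halo_fraction, halo_factor = 4, seed,
                              dna_amplitude = 0.8) {
  stopifnot(inherits(spec, "scene_spec"))
  if (halo_fraction < 0 || halo_fraction > 1)
    stop("halo_fraction must be in [0, 1]", call. = FALSE)
  if (halo_factor <= 1)
    stop("halo_factor must be > 1", call. = FALSE)
  cells <- .place_cells(.sample_cells(spec, seed), spec, seed)
  px <- spec$pixel_size_um
  sh <- spec$image_shape_px
  cyto <- matrix(0, sh[1], sh[2])
  dna <- matrix(0, sh[1], sh[2])
  is_halo <- cells$phen_u < halo_fraction
  for (i in seq_len(nrow(cells))) {
    cyto <- .paint_cell(cyto, cells$x_um[i], cells$y_um[i],
                        cells$orientation_rad[i], cells$length_um[i],
                        cells$width_um[i], px)
    if (is_halo[i]) {
      r_out <- halo_factor * cells$width_um[i] / 2
      sig <- 0.05 * r_out
      halo_len <- cells$length_um[i] + (halo_factor - 1) * cells$width_um[i]
      dna <- .paint_cell(dna, cells$x_um[i], cells$y_um[i],
                         cells$orientation_rad[i], halo_len,
                         2 * r_out, px, amplitude = 0.5 * dna_amplitude,
                         halo = list(r_in = 0.5 * r_out, r_out = r_out,
                                     sigma = sig, core_floor = 0.35,
                                     pad_um = 4 * sig))
    } else {
      dna <- .paint_cell(dna, cells$x_um[i], cells$y_um[i],
                         cells$orientation_rad[i], cells$length_um[i],
                         cells$width_um[i], px, amplitude = dna_amplitude)
    }
  }
  cyto <- .apply_optics_noise(cyto, spec, .substream(seed, 0L))
  dna <- .apply_optics_noise(dna, spec, .substream(seed, 0L) + 13L)
  truth <- .finish_truth(cells)
  truth$phenotype <- ifelse(is_halo, "halo", "normal")
  truth$halo_width_um <- ifelse(is_halo, halo_factor * truth$width_um, NA_real_)
  list(cyto_image = cyto, dna_image = dna, truth = truth)
}
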