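#' Principal (long) axis of a labelled region
#'
#' Orientation is the direction of the principal eigenvector of the
#' covariance of pixel-center coordinates, mapped to `[0, pi)`; the length is
#' the extent of pixel projections onto that direction plus one pixel (so a
#' 40-pixel-long axis-aligned rectangle reports 40 px).
#'
#' @param rows,cols Integer pixel coordinates of the region (1-based).
#' @param pixel_size_um Pixel size in um/px.
#' @return List `orientation_rad`, `length_um`, `minor_extent_um`,
#'   `centroid_um` (x, y with x along columns), `endpoints_um` (2x2 matrix).
#' @export
long_axis <- function(rows, cols, pixel_size_um = 1) {
  n <- length(rows)
  if (n < 1L) stop("empty region", call. = FALSE)
  x <- (cols - 0.5) * pixel_size_um
  y <- (rows - 0.5) * pixel_size_um
  cx <- mean(x); cy <- mean(y)
  if (n < 5L) {
    warning("region too small for a stable axis; using 1-px fallback")
    return(list(orientation_rad = 0, length_um = pixel_size_um * n,
                minor_extent_um = pixel_size_um,
                centroid_um = c(cx, cy),
                endpoints_um = rbind(c(cx, cy), c(cx, cy))))
  }
  cov2 <- stats::cov(cbind(x, y))
  eig <- eigen(cov2, symmetric = TRUE)
  v <- eig$vectors[, 1]
  theta <- atan2(v[2], v[1]) %% pi
  u <- c(cos(theta), sin(theta))
  w <- c(-sin(theta), cos(theta))
  t_major <- (x - cx) * u[1] + (y - cy) * u[2]
  t_minor <- (x - cx) * w[1] + (y - cy) * w[2]
  len <- diff(range(t_major)) + pixel_size_um
  minor <- diff(range(t_minor)) + pixel_size_um
  p0 <- c(cx, cy) + min(t_major) * u
  p1 <- c(cx, cy) + max(t_major) * u
  list(orientation_rad = theta, length_um = len, minor_extent_um = minor,
       centroid_um = c(cx, cy), endpoints_um = rbind(p0, p1))
}

# Bilinear sample of a binary mask at fractional pixel-center coordinates
# (x along columns, y along rows, in pixels with centers at 0.5, 1.5, ...).
# Outside the matrix the mask is 0.
.bilinear_mask <- function(mask, xs, ys) {
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- xs - 0.5; cy <- ys - 0.5 # continuous 0-based pixel-center coords
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0; fy <- cy - r0
  val <- function(r, cc) {
    ok <- r >= 0 & r < nr & cc >= 0 & cc < nc
    out <- numeric(length(r))
    out[ok] <- mask[cbind(r[ok] + 1L, cc[ok] + 1L)]
    out
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1L)
  v10 <- val(r0 + 1L, c0); v11 <- val(r0 + 1L, c0 + 1L)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Five-station width profile of a region
#'
#' Measures the chord length of the region mask perpendicular to its long
#' axis at `n_positions` stations placed at fractions `(2i - 1) / (2n)` of
#' the axis extent (10%, 30%, 50%, 70%, 90% for n = 5), the centered layout
#' avoiding the degenerate zero-width chords at the cell poles. Each chord
#' is traced by bilinear sampling of the binary mask at 0.25-px steps,
#' marching outward from the station until the interpolated mask drops below
#' 0.5 (the half-maximum edge, which lands half a pixel beyond the last
#' foreground pixel center, so a 10-px-wide rectangle reads 10 px). Empty
#' chords (mask gaps) are interpolated from neighboring stations and
#' flagged.
#'
#' @param mask Logical/numeric matrix of the single-cell mask.
#' @param axis Result of [long_axis()] for the same region.
#' @param pixel_size_um Pixel size in um/px.
#' @param n_positions Number of stations (default 5).
#' @return Numeric vector of widths in um with attribute `interpolated`
#'   (logical vector flagging stations recovered from neighbors).
#' @export
width_profile <- function(mask, axis, pixel_size_um = 1, n_positions = 5L) {
  u <- c(cos(axis$orientation_rad), sin(axis$orientation_rad))
  w <- c(-u[2], u[1])
  # physical long-axis span: half a pixel beyond the extreme pixel centers
  p0 <- axis$endpoints_um[1, ] - 0.5 * pixel_size_um * u
  ext <- axis$length_um
  step <- 0.25 # px
  max_r <- ceiling(sqrt(sum(dim(mask)^2)) / 2 / step) + 8L
  tgrid <- step * (1:max_r)
  fr <- (2 * seq_len(n_positions) - 1) / (2 * n_positions)
  widths <- numeric(n_positions)
  interp <- logical(n_positions)
  for (i in seq_len(n_positions)) {
    # station on the axis, in pixel units
    st <- (p0 + fr[i] * ext * u) / pixel_size_um
    if (.bilinear_mask(mask, st[1], st[2]) < 0.5) {
      widths[i] <- NA_real_
      interp[i] <- TRUE
      next
    }
    # integrate the half-max indicator along the full perpendicular line:
    # counting samples (rather than stopping at the first sub-0.5 sample)
    # is insensitive to the dithered edges a noisy threshold mask has
    tall <- c(-rev(tgrid), 0, tgrid)
    vals <- .bilinear_mask(mask, st[1] + tall * w[1], st[2] + tall * w[2])
    widths[i] <- sum(vals >= 0.5) * step * pixel_size_um
  }
  if (anyNA(widths)) {
    if (all(is.na(widths))) {
      warning("all stations empty; width set to 1 px")
      widths[] <- pixel_size_um
    } else if (sum(!is.na(widths)) == 1L) {
      widths[is.na(widths)] <- widths[!is.na(widths)]
      warning("empty width station(s) filled from the single valid station")
    } else {
      widths[is.na(widths)] <- stats::approx(
        fr[!is.na(widths)], widths[!is.na(widths)], xout = fr[is.na(widths)],
        rule = 2)$y
      warning("empty width station(s) interpolated from neighbors")
    }
  }
  attr(widths, "interpolated") <- interp
  widths
}

#' Per-cell morphometry of a label image
#'
#' For every label: principal-axis orientation and length, the five-station
#' width profile, their mean (the cell width) and the aspect ratio
#' (ratio of the projected extents along the major and minor principal
#' axes).
#'
#' @param labels A `label_image` (from [segment_cells()] or [label_image()]).
#' @param n_positions Number of width stations (default 5).
#' @return A data.frame with one row per label: `label`, `width_um`,
#'   `widths_1_um` .. `widths_<n>_um`, `length_um`, `aspect_ratio`,
#'   `orientation_rad`, `centroid_x_um`, `centroid_y_um`, `area_px`.
#' @export
measure_cells <- function(labels, n_positions = 5L) {
  stopifnot(inherits(labels, "label_image"))
  px <- labels$pixel_size_um
  L <- labels$labels
  wcols <- paste0("widths_", seq_len(n_positions), "_um")
  if (labels$n == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, 8 + n_positions))
    names(out) <- c("label", "width_um", wcols, "length_um", "aspect_ratio",
                    "orientation_rad", "centroid_x_um", "centroid_y_um",
                    "area_px")
    return(out)
  }
  idx <- which(L > 0L)
  lab <- L[idx]
  rr <- (idx - 1L) %% nrow(L) + 1L
  cc <- (idx - 1L) %/% nrow(L) + 1L
  ord <- order(lab)
  lab <- lab[ord]; rr <- rr[ord]; cc <- cc[ord]
  bounds <- c(0L, cumsum(tabulate(lab, labels$n)))
  rows_out <- vector("list", labels$n)
  for (k in seq_len(labels$n)) {
    sel <- (bounds[k] + 1L):bounds[k + 1L]
    r <- rr[sel]; c2 <- cc[sel]
    ax <- long_axis(r, c2, px)
    # crop to the bounding box for cheap chord sampling
    r0 <- min(r) - 2L; c0 <- min(c2) - 2L
    sub <- matrix(0, max(r) - r0 + 3L, max(c2) - c0 + 3L)
    sub[cbind(r - r0, c2 - c0)] <- 1
    ax_sub <- ax
    off <- c(c0, r0) * px # (x, y) offset of the crop
    ax_sub$endpoints_um <- sweep(ax$endpoints_um, 2, off)
    wp <- width_profile(sub, ax_sub, px, n_positions)
    wmean <- mean(wp)
    row <- data.frame(label = k, width_um = wmean)
    row[wcols] <- as.list(wp)
    row$length_um <- ax$length_um
    # projected extents along the principal axes: stays ~1 for isotropic
    # shapes, where the mean five-station chord underestimates the diameter
    row$aspect_ratio <- ax$length_um / ax$minor_extent_um
    row$orientation_rad <- ax$orientation_rad
    row$centroid_x_um <- ax$centroid_um[1]
    row$centroid_y_um <- ax$centroid_um[2]
    row$area_px <- length(r)
    rows_out[[k]] <- row
  }
  do.call(rbind, rows_out)
}
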