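#' Parameters of a confined DNA chain
#'
#' Bundles the physical parameters of the confined-Gaussian-chain model of
#' DNA translocation through a cell-wall pore: the genome size, the helical
#' rise per base pair, the Kuhn length, the confinement (cell) radius and the
#' cross-sectional radius of the double helix.
#'
#' @param genome_bp Genome size in base pairs. Default 4.7e6 (E. coli).
#' @param rise_nm_per_bp Contour length per base pair in nm. Default 0.34.
#' @param kuhn_nm Kuhn length \eqn{l_K} in nm. Default 100 (double-stranded DNA).
#' @param cell_radius_nm Confinement radius \eqn{R} in nm. Default 1000.
#' @param cross_radius_nm Radius of the DNA cross section in nm. Default 1.
#' @return An object of class `chain_params`.
#' @seealso [chain_quantities()], [barrier()], [critical_potential()]
#' @export
#' @examples
#' chain_params()
chain_params <- function(genome_bp = 4.7e6, rise_nm_per_bp = 0.34,
                         kuhn_nm = 100, cell_radius_nm = 1000,
                         cross_radius_nm = 1) {
  for (v in c(genome_bp = genome_bp, rise_nm_per_bp = rise_nm_per_bp,
              kuhn_nm = kuhn_nm, cell_radius_nm = cell_radius_nm,
              cross_radius_nm = cross_radius_nm)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all chain parameters must be positive finite scalars", call. = FALSE)
  }
  if (kuhn_nm < rise_nm_per_bp)
    stop("kuhn_nm must be at least the rise per base pair", call. = FALSE)
  structure(list(genome_bp = genome_bp, rise_nm_per_bp = rise_nm_per_bp,
                 kuhn_nm = kuhn_nm, cell_radius_nm = cell_radius_nm,
                 cross_radius_nm = cross_radius_nm),
            class = "chain_params")
}

#' Derived quantities of the confined chain
#'
#' Computes the contour length \eqn{L = genome\_bp \times rise},
#' the number of Kuhn segments \eqn{N = L / l_K}, the ideal-chain radius of
#' gyration \eqn{R_g = \sqrt{N/6}\, l_K}, the confinement ratio \eqn{R/R_g}
#' and the volume fraction of DNA inside the cell
#' \eqn{\pi a^2 L / (\frac{4}{3}\pi R^3)}.
#'
#' With the defaults (4.7 Mbp, 0.34 nm/bp, \eqn{l_K} = 100 nm, R = 1 um)
#' this gives N = 15,980, \eqn{R_g \approx 5.2} um, \eqn{R/R_g \approx 0.19}
#' and a volume fraction of about 0.1%: the chromosome is strongly confined
#' but the cell is far from densely packed with DNA.
#'
#' @param p A [chain_params()] object.
#' @return An object of class `derived_chain`: list with `contour_nm`,
#'   `n_kuhn`, `rg_nm`, `confinement_ratio`, `volume_fraction`, plus the
#'   input parameters under `$params`.
#' @export
#' @examples
#' chain_quantities(chain_params())$n_kuhn   # 15980
chain_quantities <- function(p = chain_params()) {
  stopifnot(inherits(p, "chain_params"))
  contour_nm <- p$genome_bp * p$rise_nm_per_bp
  n_kuhn <- contour_nm / p$kuhn_nm
  rg_nm <- sqrt(n_kuhn / 6) * p$kuhn_nm
  vol_frac <- (pi * p$cross_radius_nm^2 * contour_nm) /
    (4 / 3 * pi * p$cell_radius_nm^3)
  if (vol_frac >= 1)
    stop("DNA volume exceeds cell volume; check parameters", call. = FALSE)
  structure(list(contour_nm = contour_nm, n_kuhn = n_kuhn, rg_nm = rg_nm,
                 confinement_ratio = p$cell_radius_nm / rg_nm,
                 volume_fraction = vol_frac, params = p),
            class = "derived_chain")
}

# Dimensionless confinement parameter z_c = sqrt(6/pi) * R / l_K.
# In terms of z_c the free energy per kT reduces to
#   F(m) = -ln(1 + z_c / sqrt(m)) + pi * (N - m) / z_c^2 + m * dmu
.zc <- function(chain) {
  p <- chain$params
  sqrt(6 / pi) * p$cell_radius_nm / p$kuhn_nm
}

.as_chain <- function(chain) {
  if (inherits(chain, "chain_params")) chain <- chain_quantities(chain)
  stopifnot(inherits(chain, "derived_chain"))
  chain
}

#' Translocation free energy F(m)
#'
#' Free energy (in units of \eqn{k_B T}) of a confined Gaussian chain with
#' segment `m` held at the cell-wall pore, under the ground-state-dominance
#' approximation for strong confinement:
#' \deqn{F(m) = -\ln\left[1 + \frac{R}{R_g}\sqrt{\frac{N}{\pi m}}\right]
#'   + \pi^2 \frac{N - m}{N}\left(\frac{R_g}{R}\right)^2 + m\,\Delta\mu}
#' The first term is the conformational entropy of the escaped half-chain
#' (m segments outside), the second that of the confined half-chain, and the
#' third the chemical-potential preference of the escaped segments for the
#' low-density gel cavity outside the wall (`dmu_kT` < 0 favours escape).
#'
#' @param m Continuous segment index, in `[1, N - 1]`. Vectorized.
#' @param chain A [chain_quantities()] or [chain_params()] object.
#' @param dmu_kT Per-segment chemical potential difference (outside minus
#'   inside) in units of \eqn{k_B T}. Default 0.
#' @return A data.frame with one row per `m`: columns `m`, `dmu_kT`, `f_kT`,
#'   `df_kT` (\eqn{\Delta F(m) = F(m) - F(1)}), and the individual terms
#'   `entropy_out_kT`, `entropy_in_kT`, `potential_kT`.
#' @export
#' @examples
#' free_energy(23, chain_quantities(chain_params()))$df_kT  # about 0.98
free_energy <- function(m, chain, dmu_kT = 0) {
  chain <- .as_chain(chain)
  N <- chain$n_kuhn
  if (any(!is.finite(m)) || any(m < 1) || any(m > N - 1))
    stop("m must lie in [1, N - 1]", call. = FALSE)
  zc <- .zc(chain)
  f_of <- function(mm) {
    out_term <- -log(1 + zc / sqrt(mm))
    in_term <- pi * (N - mm) / zc^2
    pot <- mm * dmu_kT
    cbind(out_term, in_term, pot)
  }
  terms <- f_of(m)
  f <- rowSums(terms)
  f1 <- sum(f_of(1))
  data.frame(m = m, dmu_kT = dmu_kT, f_kT = f, df_kT = f - f1,
             entropy_out_kT = terms[, 1], entropy_in_kT = terms[, 2],
             potential_kT = terms[, 3])
}

#' Entropic barrier of the translocation free energy
#'
#' Locates the interior maximum \eqn{m^*} of F(m). Setting
#' \eqn{dF/dm = 0} and substituting \eqn{x = \sqrt{m}} yields the cubic
#' \deqn{2c\,x^3 + 2c\,z_c\,x^2 - z_c = 0,\qquad
#'   c = \pi/z_c^2 - \Delta\mu,\quad z_c = \sqrt{6/\pi}\,R/l_K,}
#' whose unique positive root is independent of the chain length N.
#' The root is found by bracketed bisection to relative tolerance 1e-10.
#'
#' A barrier exists only while the slope of F at m = 1 is positive, i.e.
#' while `dmu_kT` exceeds the critical potential [critical_potential()];
#' below it the profile is downhill from the first segment and translocation
#' is spontaneous (`exists = FALSE`, `m_star = 1`, `df_star_kT = 0`).
#'
#' @inheritParams free_energy
#' @return An object of class `barrier_result`: list with `m_star`
#'   (continuous), `m_star_int` (rounded half away from zero), `df_star_kT`
#'   and `exists`.
#' @export
#' @examples
#' barrier(chain_quantities(chain_params()))$m_star_int  # 23
barrier <- function(chain, dmu_kT = 0) {
  chain <- .as_chain(chain)
  zc <- .zc(chain)
  cc <- pi / zc^2 - dmu_kT
  if (cc <= 0)
    stop("dmu_kT >= pi/z_c^2: free energy increases without an interior ",
         "barrier; translocation never proceeds at this potential",
         call. = FALSE)
  crit <- pi / zc^2 - zc / (2 * (1 + zc))
  if (dmu_kT <= crit) {
    res <- list(m_star = 1, m_star_int = 1L, df_star_kT = 0, exists = FALSE)
    class(res) <- "barrier_result"
    return(res)
  }
  g <- function(x) 2 * cc * x^3 + 2 * cc * zc * x^2 - zc
  # g(1) < 0 iff slope of F at m=1 is positive (barrier beyond m=1)
  lo <- 1
  hi <- 2
  while (g(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-10 * hi) break
  }
  x <- (lo + hi) / 2
  m_star <- x^2
  if (m_star > chain$n_kuhn - 1)
    stop("internal inconsistency: barrier root beyond chain length", call. = FALSE)
  df_star <- free_energy(m_star, chain, dmu_kT)$df_kT
  res <- list(m_star = m_star,
              m_star_int = as.integer(floor(m_star + 0.5)),
              df_star_kT = df_star, exists = TRUE)
  class(res) <- "barrier_result"
  res
}

#' Critical chemical potential for spontaneous translocation
#'
#' The per-segment chemical potential difference at which the entropic
#' barrier vanishes, obtained by setting \eqn{m^* = 1} in the stationarity
#' condition:
#' \deqn{\Delta\mu_c = \frac{\pi}{z_c^2} - \frac{z_c}{2(1 + z_c)},\qquad
#'   z_c = \sqrt{6/\pi}\, R/l_K.}
#' For \eqn{R/l_K = 10} this gives \eqn{-0.45\,k_B T}; in the limit of very
#' strong confinement (\eqn{R/l_K \to \infty}) it tends to \eqn{-0.5\,k_B T}.
#' Below \eqn{\Delta\mu_c} the free energy is downhill from the first segment
#' and the chain escapes spontaneously.
#'
#' @inheritParams free_energy
#' @return An object of class `critical_potential`: list with `dmu_c_kT` and
#'   `z_c`.
#' @export
#' @examples
#' critical_potential(chain_params())$dmu_c_kT  # about -0.45
critical_potential <- function(chain) {
  chain <- .as_chain(chain)
  zc <- .zc(chain)
  structure(list(dmu_c_kT = pi / zc^2 - zc / (2 * (1 + zc)), z_c = zc),
            class = "critical_potential")
}

#' Convert Kuhn segments to base pairs
#'
#' @param m Number of Kuhn segments (>= 0). Vectorized.
#' @param p A [chain_params()] object.
#' @return Base pairs, `m * kuhn_nm / rise_nm_per_bp`.
#' @export
#' @examples
#' segments_to_bp(23, chain_params())  # about 6765
segments_to_bp <- function(m, p = chain_params()) {
  stopifnot(inherits(p, "chain_params"))
  if (any(m < 0)) stop("m must be nonnegative", call. = FALSE)
  m * p$kuhn_nm / p$rise_nm_per_bp
}

#' Free-energy profile over a grid of segment indices
#'
#' Vectorized [free_energy()] over `m_grid`, suitable for plotting
#' \eqn{\Delta F(m)} curves for several chemical potentials.
#'
#' @inheritParams free_energy
#' @param m_grid Numeric vector of segment indices within `[1, N - 1]`.
#' @return A data.frame as from [free_energy()], one row per grid point.
#' @export
energy_profile <- function(chain, dmu_kT = 0, m_grid) {
  free_energy(m_grid, chain, dmu_kT)
}

#' @export
print.barrier_result <- function(x, ...) {
  if (x$exists)
    cat(sprintf("Entropic barrier at m* = %.3f (~%d Kuhn segments), dF* = %.3f kT\n",
                x$m_star, x$m_star_int, x$df_star_kT))
  else
    cat("No entropic barrier: translocation is downhill from the first segment\n")
  invisible(x)
}

#' @export
print.critical_potential <- function(x, ...) {
  cat(sprintf("Critical potential dmu_c = %.4f kT (z_c = %.3f)\n",
              x$dmu_c_kT, x$z_c))
  invisible(x)
}
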