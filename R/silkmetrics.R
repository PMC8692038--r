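#' Mechanical summary of a stress-strain curve
#'
#' Computes the tensile-test quantities reported for silk fibres: toughness
#' as the trapezoidal integral of stress over strain converted from
#' GPa x (unit strain) to MJ m^-3 (factor 1000), tensile strength as the
#' maximum stress, strain at break as the final strain in percent (the
#' break point is the last sample), and Young's modulus as the least-squares
#' slope of stress versus strain over the initial region
#' strain <= \code{modulus_strain_cap}.
#'
#' @param strain nondecreasing dimensionless strain values (0 =
#'   unstretched); alternatively a data.frame with columns \code{strain}
#'   and \code{stress}.
#' @param stress stress values in GPa.
#' @param modulus_strain_cap strain cap for the modulus fit (default 0.02,
#'   the initial linear region).
#' @return object of class \code{mechanical_summary}: \code{toughness_MJ_m3},
#'   \code{tensile_strength_GPa}, \code{strain_at_break_pct},
#'   \code{youngs_modulus_GPa}.
#' @export
mechanics_summary <- function(strain, stress = NULL,
                              modulus_strain_cap = 0.02) {
  if (is.data.frame(strain)) {
    stress <- strain$stress
    strain <- strain$strain
  }
  stopifnot(length(strain) == length(stress))
  if (length(strain) < 3L) stop("need at least 3 curve points")
  if (any(diff(strain) < 0)) stop("strain must be nondecreasing")
  if (strain[1] < 0) stop("strain must start at or above 0")
  toughness <- trapz(strain, stress) * 1000   # 1 GPa * strain == 1000 MJ/m^3
  idx <- which(strain <= modulus_strain_cap)
  if (length(idx) < 2L) idx <- 1:2
  modulus <- unname(coef(lm(stress[idx] ~ strain[idx]))[2])
  structure(list(toughness_MJ_m3 = toughness,
                 tensile_strength_GPa = max(stress),
                 strain_at_break_pct = 100 * strain[length(strain)],
                 youngs_modulus_GPa = modulus),
            class = "mechanical_summary")
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf(paste0("<mechanical_summary> toughness %.1f MJ/m^3 | ",
                     "strength %.3f GPa | strain at break %.1f%% | ",
                     "modulus %.2f GPa\n"),
              x$toughness_MJ_m3, x$tensile_strength_GPa,
              x$strain_at_break_pct, x$youngs_modulus_GPa))
  invisible(x)
}

gauss <- function(q, A, c, w) A * exp(-(q - c)^2 / (2 * w^2))

#' Simulate a 1-D WAXS radial profile
#'
#' Sum of narrow crystal-peak Gaussians and one broad amorphous-halo
#' Gaussian, with optional additive Gaussian noise (sd expressed as a
#' fraction of the maximum intensity). Used as the ground-truth generator
#' for crystallinity recovery studies.
#'
#' @param q scattering-vector grid (nm^-1), strictly increasing.
#' @param peaks data.frame with columns \code{center}, \code{width},
#'   \code{area} for the crystal peaks.
#' @param halo list/row with \code{center}, \code{width}, \code{area}.
#' @param noise_frac additive noise sd as a fraction of max intensity.
#' @param seed integer seed.
#' @return data.frame with columns \code{q}, \code{intensity}; true
#'   crystallinity attached as attribute \code{"crystallinity"}.
#' @export
simulate_waxs_profile <- function(q, peaks, halo, noise_frac = 0,
                                  seed = 1L) {
  amp <- function(area, w) area / (w * sqrt(2 * pi))
  I <- gauss(q, amp(halo$area, halo$width), halo$center, halo$width)
  for (i in seq_len(nrow(peaks)))
    I <- I + gauss(q, amp(peaks$area[i], peaks$width[i]), peaks$center[i],
                   peaks$width[i])
  if (noise_frac > 0)
    I <- with_seed(seed, I + rnorm(length(q), 0, noise_frac * max(I)))
  out <- data.frame(q = q, intensity = I)
  attr(out, "crystallinity") <- sum(peaks$area) /
    (sum(peaks$area) + halo$area)
  out
}

#' Crystallinity from a 1-D WAXS profile by Gaussian decomposition
#'
#' Fits \code{n_peaks} crystal-peak Gaussians plus one broad amorphous-halo
#' Gaussian to a background-subtracted radial profile by nonlinear least
#' squares, and reports the degree of crystallinity as the crystal peak
#' area divided by the total area of crystal peaks and amorphous halo. To
#' keep the decomposition identifiable the halo is initialised wide and its
#' width is bounded below at three times the largest initial peak width;
#' amplitudes are bounded at zero.
#'
#' @param profile data.frame with columns \code{q} (strictly increasing)
#'   and \code{intensity}.
#' @param n_peaks number of crystal peaks (>= 1); silk profiles typically
#'   use the (120)/(200)/(211) reflections.
#' @param init list with \code{peak_centers} (required, length
#'   \code{n_peaks}) and optionally \code{peak_widths}, \code{halo_center},
#'   \code{halo_width}.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return object of class \code{crystallinity_fit}: \code{peaks}
#'   (data.frame center/width/area), \code{halo}, \code{crystallinity},
#'   \code{residual_norm}.
#' @export
fit_crystallinity <- function(profile, n_peaks, init, max_iter = 200L) {
  q <- profile$q; I <- profile$intensity
  stopifnot(n_peaks >= 1L, all(diff(q) > 0))
  pc <- init$peak_centers
  if (length(pc) != n_peaks) stop("init$peak_centers must have n_peaks entries")
  if (any(pc < min(q)) || any(pc > max(q)))
    stop("profile must cover all initialized centers")
  span <- diff(range(q))
  pw <- if (!is.null(init$peak_widths)) init$peak_widths
        else rep(span / 50, n_peaks)
  hc <- if (!is.null(init$halo_center)) init$halo_center
        else sum(q * pmax(I, 0)) / max(sum(pmax(I, 0)), 1e-12)
  hw <- if (!is.null(init$halo_width)) max(init$halo_width, 3 * max(pw))
        else max(span / 4, 3 * max(pw))
  at_c <- vapply(pc, function(c0) I[which.min(abs(q - c0))], numeric(1))
  par0 <- c(A = pmax(at_c * 0.5, 1e-3), c = pc, w = pw,
            Ah = max(I) * 0.8, ch = hc, wh = hw)
  lower <- c(rep(0, n_peaks), rep(min(q), n_peaks), rep(span / 500, n_peaks),
             0, min(q), 3 * max(pw))
  upper <- c(rep(Inf, n_peaks), rep(max(q), n_peaks), rep(span / 4, n_peaks),
             Inf, max(q), span)
  resid_fn <- function(p) {
    A <- p[1:n_peaks]; cc <- p[(n_peaks + 1):(2 * n_peaks)]
    w <- p[(2 * n_peaks + 1):(3 * n_peaks)]
    model <- gauss(q, p[3 * n_peaks + 1], p[3 * n_peaks + 2],
                   p[3 * n_peaks + 3])
    for (i in seq_len(n_peaks)) model <- model + gauss(q, A[i], cc[i], w[i])
    I - model
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  if (fit$info == 0L || fit$info == 5L)
    stop("crystallinity fit did not converge (info = ", fit$info,
         ", residual norm = ", sqrt(fit$deviance), ")")
  p <- fit$par
  A <- p[1:n_peaks]; cc <- p[(n_peaks + 1):(2 * n_peaks)]
  w <- p[(2 * n_peaks + 1):(3 * n_peaks)]
  areas <- A * w * sqrt(2 * pi)
  halo_area <- p[3 * n_peaks + 1] * p[3 * n_peaks + 3] * sqrt(2 * pi)
  structure(list(
    peaks = data.frame(center = unname(cc), width = unname(w),
                       area = unname(areas)),
    halo = list(center = unname(p[3 * n_peaks + 2]),
                width = unname(p[3 * n_peaks + 3]), area = unname(halo_area)),
    crystallinity = unname(sum(areas) / (sum(areas) + halo_area)),
    residual_norm = sqrt(fit$deviance)), class = "crystallinity_fit")
}

#' @export
print.crystallinity_fit <- function(x, ...) {
  cat(sprintf("<crystallinity_fit> crystallinity %.3f (%d peaks, residual %.3g)\n",
              x$crystallinity, nrow(x$peaks), x$residual_norm))
  invisible(x)
}
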