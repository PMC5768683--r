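# 15N spin-relaxation analysis: mono-exponential T1/T2 decay fitting
# (downhill-simplex least squares), per-residue T1/T2 ratio profiles,
# core/appendage segmentation, and inversion of the rigid isotropic
# tumbling model for the rotational correlation time.

#' Standard relaxation delay grids (ms)
#'
#' The conventional sampling schedules for amide 15N relaxation series:
#' T1 delays 0, 10, 100, 300, 500, 700, 900, 1200, 1700 ms and T2 delays
#' 8.1 to 64.8 ms in steps of 8.1 ms.
#' @param kind `"T1"` or `"T2"`.
#' @export
default_delays <- function(kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  if (kind == "T1") c(0, 10, 100, 300, 500, 700, 900, 1200, 1700)
  else seq(8.1, 64.8, by = 8.1)
}

#' Build a decay curve
#' @param residue residue number (native-extended numbering).
#' @param kind `"T1"` or `"T2"`.
#' @param delays_ms delay times, ms (at least 3, non-negative).
#' @param intensities signal intensities, arbitrary units.
#' @export
decay_curve <- function(residue, kind, delays_ms, intensities) {
  kind <- match.arg(kind, c("T1", "T2"))
  stopifnot(length(delays_ms) == length(intensities), length(delays_ms) >= 3L,
            all(delays_ms >= 0))
  structure(list(residue = as.integer(residue), kind = kind,
                 delays_ms = as.numeric(delays_ms),
                 intensities = as.numeric(intensities)),
            class = "DecayCurve")
}

#' Fit a mono-exponential decay I(t) = I0 exp(-t / T)
#'
#' Unweighted least squares by the derivative-free downhill-simplex
#' (Nelder-Mead) method, restarted once from its own optimum to tighten
#' convergence.  Default initialization: I0 = max intensity, T = the
#' delay whose intensity is nearest I0/e.
#'
#' @param curve a [decay_curve()].
#' @param init optional `c(I0, T_ms)` starting point.
#' @return List of class `RelaxationFit`: `I0`, `T_ms`, `rss`, `n_iter`,
#'   `converged`.
#' @export
fit_decay <- function(curve, init = NULL) {
  t <- curve$delays_ms; y <- curve$intensities
  if (length(unique(t)) < 3L) stop("need at least 3 distinct delays")
  if (diff(range(y)) == 0) stop("all intensities equal; decay time undetermined")
  if (is.null(init)) {
    I0 <- max(y)
    Tg <- t[which.min(abs(y - I0 / exp(1)))]
    if (Tg <= 0) Tg <- max(t[t > 0]) / 2
    init <- c(I0, Tg)
  }
  obj <- function(p) {
    if (p[2] <= 0) return(1e300)
    sum((y - p[1] * exp(-t / p[2]))^2)
  }
  ctrl <- list(reltol = 1e-14, maxit = 20000L)
  f1 <- optim(init, obj, method = "Nelder-Mead", control = ctrl)
  f2 <- optim(f1$par, obj, method = "Nelder-Mead", control = ctrl)
  if (f2$convergence != 0)
    warning("simplex fit did not converge for residue ", curve$residue)
  structure(list(I0 = f2$par[1], T_ms = f2$par[2], rss = f2$value,
                 n_iter = unname(f1$counts[1] + f2$counts[1]),
                 converged = f2$convergence == 0,
                 residue = curve$residue, kind = curve$kind),
            class = "RelaxationFit")
}

#' Per-residue T1/T2 ratio profile
#'
#' Inner-joins the two fit sets on residue number; residues missing
#' either fit are dropped with a message.
#'
#' @param t1_fits,t2_fits lists of `RelaxationFit` objects (kinds T1 and
#'   T2 respectively).
#' @return data.frame of class `RatioProfile` with columns `resid`,
#'   `t1_ms`, `t2_ms`, `ratio`.
#' @export
ratio_profile <- function(t1_fits, t2_fits) {
  r1 <- vapply(t1_fits, `[[`, integer(1), "residue")
  r2 <- vapply(t2_fits, `[[`, integer(1), "residue")
  shared <- sort(intersect(r1, r2))
  if (!length(shared)) stop("no residues common to the T1 and T2 fit sets")
  dropped <- setdiff(union(r1, r2), shared)
  if (length(dropped))
    message("omitting residues lacking one fit: ", paste(dropped, collapse = ", "))
  t1 <- vapply(t1_fits[match(shared, r1)], `[[`, numeric(1), "T_ms")
  t2 <- vapply(t2_fits[match(shared, r2)], `[[`, numeric(1), "T_ms")
  out <- data.frame(resid = shared, t1_ms = t1, t2_ms = t2, ratio = t1 / t2)
  class(out) <- c("RatioProfile", class(out))
  out
}

#' Segment a ratio profile into appendage and core means
#'
#' In native-extended numbering the appendage occupies negative residue
#' numbers, so the default boundary of 1 splits appendage (residue <
#' boundary) from catalytic core (residue >= boundary).
#'
#' @param profile RatioProfile.
#' @param boundary first residue of the core segment, default 1.
#' @return Named numeric vector `c(appendage = ..., core = ...)` of mean
#'   T1/T2 ratios.
#' @export
segment_regions <- function(profile, boundary = 1L) {
  lo <- profile$ratio[profile$resid < boundary]
  hi <- profile$ratio[profile$resid >= boundary]
  if (!length(lo) || !length(hi)) stop("segmentation leaves an empty segment")
  c(appendage = mean(lo), core = mean(hi))
}

# --- rigid isotropic tumbling forward model ------------------------------
# J(w) = (2/5) tau / (1 + (w tau)^2)   (Lipari-Szabo limit, S^2 = 1)
# R1 = d2/4 [J(wH - wN) + 3 J(wN) + 6 J(wH + wN)] + c2 J(wN)
# R2 = d2/8 [4 J(0) + J(wH - wN) + 3 J(wN) + 6 J(wH) + 6 J(wH + wN)]
#      + c2/6 [4 J(0) + 3 J(wN)]
# d = mu0 hbar gH gN / (4 pi rNH^3),  c = wN * CSA / sqrt(3)

relax_constants <- function(r_nh_m = 1.02e-10, csa_ppm = -160) {
  mu0 <- 4e-7 * pi
  hbar <- 1.054571817e-34
  gH <- 2.6752218744e8
  gN <- -2.7126e7
  list(d = mu0 * hbar * gH * gN / (4 * pi * r_nh_m^3),
       csa = csa_ppm * 1e-6, gH = gH, gN = gN)
}

#' T1/T2 ratio predicted by rigid isotropic tumbling
#'
#' 15N relaxation from dipolar (N-H, r = 1.02 A) plus CSA (-160 ppm)
#' mechanisms with a single-Lorentzian spectral density (order parameter
#' 1).  All physical constants are exposed for sensitivity checks.
#'
#' @param tau_c_ns rotational correlation time, ns.
#' @param field_MHz_1H proton Larmor frequency of the spectrometer, MHz.
#' @param r_nh_m N-H bond length in meters.
#' @param csa_ppm 15N chemical-shift anisotropy.
#' @return Dimensionless T1/T2 (= R2/R1).
#' @export
t1t2_ratio <- function(tau_c_ns, field_MHz_1H, r_nh_m = 1.02e-10,
                       csa_ppm = -160) {
  k <- relax_constants(r_nh_m, csa_ppm)
  wH <- 2 * pi * field_MHz_1H * 1e6
  wN <- wH * k$gN / k$gH            # negative gyromagnetic ratio
  tau <- tau_c_ns * 1e-9
  J <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  d2 <- k$d^2
  c2 <- (wN * k$csa)^2 / 3
  R1 <- d2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                    6 * J(wH + wN)) + c2 / 6 * (4 * J(0) + 3 * J(wN))
  R2 / R1
}

#' Rotational correlation time from a mean T1/T2 ratio
#'
#' Inverts the [t1t2_ratio()] forward model (strictly increasing in tau_c
#' over the search interval) by monotone root finding.
#'
#' @param mean_ratio observed mean T1/T2, must exceed the model value at
#'   the lower search bound.
#' @param field_MHz_1H proton Larmor frequency, MHz.
#' @param interval_ns search interval, default `c(1, 100)` ns.
#' @param ... passed through to [t1t2_ratio()].
#' @return tau_c in ns.
#' @export
estimate_tau_c <- function(mean_ratio, field_MHz_1H,
                           interval_ns = c(1, 100), ...) {
  if (mean_ratio <= 1) stop("T1/T2 ratio must exceed 1")
  f <- function(tau) t1t2_ratio(tau, field_MHz_1H, ...) - mean_ratio
  lo <- f(interval_ns[1]); hi <- f(interval_ns[2])
  if (lo > 0 || hi < 0)
    stop(sprintf("ratio %.3g not invertible within [%g, %g] ns at %g MHz",
                 mean_ratio, interval_ns[1], interval_ns[2], field_MHz_1H))
  uniroot(f, interval_ns, tol = 1e-9)$root
}
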