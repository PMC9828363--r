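# CODATA 2018 physical constants (SI)
KB_SI <- 1.380649e-23        # Boltzmann constant, J/K
HBAR_SI <- 1.054571817e-34   # reduced Planck constant, J s
GAMMA_1H <- 2.6752218744e8   # 1H gyromagnetic ratio, rad s^-1 T^-1

# Complex concentration [ML] for the 1:1 equilibrium, via the
# cancellation-free root of the mass-balance quadratic:
# ML^2 - (L + M + Kd) ML + L M = 0, smaller root written as 2LM/(b + sqrt(D)).
complex_concentration <- function(ligand_total, metal_total, kd) {
  if (any(c(ligand_total, metal_total, kd) < 0)) {
    abort("concentrations and kd must be >= 0")
  }
  b <- ligand_total + metal_total + kd
  disc <- b^2 - 4 * ligand_total * metal_total
  disc <- max(disc, 0)
  if (b + sqrt(disc) == 0) return(0)
  2 * ligand_total * metal_total / (b + sqrt(disc))
}

#' Fraction of metal bound in a 1:1 equilibrium
#'
#' Closed-form solution of the 1:1 binding mass balance,
#' `L + M <-> LM` with `Kd = [L][M]/[LM]`, in a numerically stable
#' formulation (no catastrophic cancellation for tight binding). Returns
#' the fraction of total **metal** in the complex; use
#' [bound_fraction_ligand()] for the ligand-side fraction.
#'
#' @param ligand_total,metal_total Total concentrations, molar.
#' @param kd Dissociation constant, molar.
#' @return Fraction in [0, 1].
#' @examples
#' bound_fraction(700e-6, 700e-6, 300e-9)  # ~0.98
#' @export
bound_fraction <- function(ligand_total, metal_total, kd) {
  if (metal_total <= 0) abort("metal_total must be > 0")
  ml <- complex_concentration(ligand_total, metal_total, kd)
  min(1, ml / metal_total)
}

#' @rdname bound_fraction
#' @export
bound_fraction_ligand <- function(ligand_total, metal_total, kd) {
  if (ligand_total <= 0) abort("ligand_total must be > 0")
  ml <- complex_concentration(ligand_total, metal_total, kd)
  min(1, ml / ligand_total)
}

#' Fit a 1:1 Kd to titration data
#'
#' Nonlinear least squares of
#' `signal = s_free + (s_bound - s_free) * f_bound(ligand)`, where
#' `f_bound` is the exact closed-form 1:1 bound fraction of the ligand
#' (the spectral response reports on the oligonucleotide's conformation).
#' `kd` is fitted on a log scale for positivity; the confidence interval
#' comes from the residual covariance of the fit.
#'
#' @param points Data frame with columns `metal_total` (molar) and
#'   `signal` (>= 4 points spanning sub- and super-stoichiometric metal).
#' @param ligand_total Ligand concentration, molar.
#' @param kd_start Starting value for the optimiser, molar.
#' @param conf_level Confidence level of the reported interval.
#' @return A `kd_fit` list: `kd`, `kd_ci` (2-vector), `s_free`, `s_bound`,
#'   the underlying `nls` fit, and the prediction table. An identifiability
#'   warning is raised when the data do not constrain the Kd (all points
#'   saturated, metal >= 100 Kd everywhere).
#' @export
fit_kd_titration <- function(points, ligand_total, kd_start = NULL,
                             conf_level = 0.95) {
  points <- as_tibble(points)
  if (!all(c("metal_total", "signal") %in% names(points))) {
    abort("`points` needs columns metal_total and signal")
  }
  if (nrow(points) < 4) abort("need >= 4 titration points")
  kd_start <- kd_start %||% max(ligand_total / 10, 1e-12)
  model_fn <- function(log_kd, s_free, s_bound, metal_total) {
    kd <- exp(log_kd)
    fb <- vapply(metal_total, function(m) {
      bound_fraction_ligand(ligand_total, max(m, 0), kd)
    }, 0)
    s_free + (s_bound - s_free) * fb
  }
  fit <- minpack.lm::nlsLM(
    signal ~ model_fn(log_kd, s_free, s_bound, metal_total),
    data = points,
    start = list(log_kd = log(kd_start),
                 s_free = points$signal[which.min(points$metal_total)],
                 s_bound = points$signal[which.max(points$metal_total)]),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  est <- coef(fit)
  kd <- exp(est[["log_kd"]])
  se_log <- tryCatch(sqrt(vcov(fit)["log_kd", "log_kd"]), error = function(e) Inf)
  zc <- qt(1 - (1 - conf_level) / 2, df = max(1, nrow(points) - 3))
  ci <- kd * exp(c(-1, 1) * zc * se_log)
  if (all(points$metal_total >= 100 * kd) || !is.finite(se_log) || se_log > 2) {
    warn("Kd is poorly identified by these points (saturation regime or flat response); the confidence interval is very wide",
         class = "parashift_identifiability_warning")
  }
  preds <- points
  preds$fitted <- model_fn(est[["log_kd"]], est[["s_free"]], est[["s_bound"]],
                           points$metal_total)
  structure(list(kd = kd, kd_ci = ci,
                 s_free = est[["s_free"]], s_bound = est[["s_bound"]],
                 fit = fit, ligand_total = ligand_total, predictions = preds),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> 1:1 model, ligand_total = %.3g M\n", x$ligand_total))
  cat(sprintf("  Kd = %.4g M  (CI %.3g - %.3g)\n", x$kd, x$kd_ci[1], x$kd_ci[2]))
  cat(sprintf("  s_free = %.4g, s_bound = %.4g\n", x$s_free, x$s_bound))
  invisible(x)
}

#' @export
tidy.kd_fit <- function(x, ...) {
  tibble(term = c("kd", "s_free", "s_bound"),
         estimate = c(x$kd, x$s_free, x$s_bound),
         conf.low = c(x$kd_ci[1], NA, NA),
         conf.high = c(x$kd_ci[2], NA, NA))
}

#' @export
glance.kd_fit <- function(x, ...) {
  tibble(kd = x$kd, n = nrow(x$predictions),
         sigma = sqrt(mean((x$predictions$signal - x$predictions$fitted)^2)))
}

#' Titration fit plot
#'
#' @param object A `kd_fit`.
#' @param ... Unused.
#' @export
autoplot.kd_fit <- function(object, ...) {
  curve <- tibble(metal_total = seq(0, max(object$predictions$metal_total),
                                    length.out = 200))
  curve$signal <- object$s_free + (object$s_bound - object$s_free) *
    vapply(curve$metal_total, function(m) {
      bound_fraction_ligand(object$ligand_total, m, object$kd)
    }, 0)
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$metal_total, y = .data$signal)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "total metal (M)", y = "signal",
                  title = sprintf("1:1 fit: Kd = %.3g M", object$kd)) +
    ggplot2::theme_minimal()
}

#' Maximal self-alignment RDC predicted from a delta-chi tensor
#'
#' Magnitude of the residual dipolar coupling between two nuclei induced by
#' partial self-alignment of the paramagnetic molecule in the field:
#'
#' \deqn{D(\theta,\Omega) = -\frac{B_0^2}{15 k_B T}\,
#'   \frac{\gamma_a \gamma_b \hbar}{8\pi^2 r^3}
#'   \left[\Delta\chi_{ax}(3\cos^2\theta - 1)
#'   + \tfrac{3}{2}\Delta\chi_{rh}\sin^2\theta\cos 2\Omega\right]}
#'
#' The maximum of `|D|` over internuclear-vector orientations is attained
#' on a principal axis and equals `3 |lambda|_max` times the prefactor,
#' with `|lambda|_max` the largest-magnitude tensor eigenvalue.
#'
#' @param tensor A [dchi_tensor] (units 1e-32 m^3).
#' @param r Internuclear distance, Angstrom (> 0.5).
#' @param B0 Field strength, tesla (16.44 T is a 700 MHz magnet).
#' @param temperature Kelvin (default 298).
#' @param gamma_a,gamma_b Gyromagnetic ratios, rad s^-1 T^-1 (default 1H).
#' @return Maximum |D| in Hz.
#' @export
max_rdc <- function(tensor, r, B0, temperature = 298,
                    gamma_a = GAMMA_1H, gamma_b = GAMMA_1H) {
  stopifnot(is_dchi_tensor(tensor))
  if (r < 0.5) abort("r must be >= 0.5 Angstrom")
  if (B0 <= 0 || temperature <= 0) abort("B0 and temperature must be > 0")
  lam_max <- max(abs(eigen(tensor$M, symmetric = TRUE, only.values = TRUE)$values))
  prefac <- B0^2 / (15 * KB_SI * temperature) *
    gamma_a * gamma_b * HBAR_SI / (8 * pi^2 * (r * 1e-10)^3)
  prefac * 3 * lam_max * 1e-32
}
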