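#' Thermodynamic conversions for binding constants
#'
#' Conversions between association constant, dissociation constant, Gibbs
#' energy, enthalpy and entropy via
#' \eqn{\Delta G = -RT \ln K_a} and \eqn{\Delta G = \Delta H - T\Delta S},
#' with \eqn{R = 1.9872} cal/mol/K and \eqn{T = 298} K by default (the
#' conventions used throughout the package's ITC reporting).
#'
#' @param ka association constant, M^-1 (> 0).
#' @param T temperature in K (default 298, used exactly).
#' @return `delta_g`: Gibbs energy change in cal/mol.
#' @examples
#' delta_g(1.71e7)                    # -9863 cal/mol
#' delta_s(-3730, delta_g(1.71e7))    # +20.6 cal/mol/K
#' kd(1.71e7) * 1e9                   # 58.5 nM
#' @export
delta_g <- function(ka, T = 298) {
  if (any(ka <= 0)) stop("ka must be > 0", call. = FALSE)
  -GAS_CONSTANT_CAL * T * log(ka)
}

#' @rdname delta_g
#' @param dh enthalpy change, cal/mol.
#' @param dg Gibbs energy change, cal/mol.
#' @return `delta_s`: entropy change in cal/mol/K.
#' @export
delta_s <- function(dh, dg, T = 298) {
  if (any(T <= 0)) stop("T must be > 0", call. = FALSE)
  (dh - dg) / T
}

#' @rdname delta_g
#' @return `kd`: dissociation constant in M.
#' @export
kd <- function(ka) {
  if (any(ka <= 0)) stop("ka must be > 0", call. = FALSE)
  1 / ka
}

# gas constant in cal/mol/K, as used for all conversions
GAS_CONSTANT_CAL <- 1.9872

#' Summarize the thermodynamics of one binding step
#'
#' @param ka association constant (M^-1).
#' @param dh enthalpy change (cal/mol).
#' @param T temperature (K), default 298.
#' @return object of class `thermo_summary`: list with `ka`, `kd` (M),
#'   `dg`, `dh` (cal/mol), `ds` (cal/mol/K) and `T`.
#' @examples
#' thermo_summary(ka = 6.08e3, dh = -8520)
#' @export
thermo_summary <- function(ka, dh, T = 298) {
  dg <- delta_g(ka, T)
  structure(list(ka = ka, kd = kd(ka), dg = dg, dh = dh,
                 ds = delta_s(dh, dg, T), T = T),
            class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat(sprintf("Ka = %.3g M^-1   Kd = %s\n", x$ka, format_conc(x$kd)))
  cat(sprintf("dG = %.0f cal/mol   dH = %.0f cal/mol   dS = %.3g cal/mol/K   (T = %g K)\n",
              x$dg, x$dh, x$ds, x$T))
  invisible(x)
}

# pretty-print a molar concentration with a sensible SI prefix
format_conc <- function(x) {
  if (x >= 1e-3) sprintf("%.3g mM", x * 1e3)
  else if (x >= 1e-6) sprintf("%.3g uM", x * 1e6)
  else sprintf("%.3g nM", x * 1e9)
}

#' Round a value to reporting precision
#'
#' Reporting convention for derived thermodynamic quantities: a fixed
#' number of significant figures (dissociation constants are usually
#' quoted to 2-3 significant figures, entropies to 3).
#'
#' @param x numeric value(s).
#' @param digits significant figures (default 3).
#' @return rounded value(s).
#' @export
report_signif <- function(x, digits = 3) signif(x, digits)
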