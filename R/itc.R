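#' Define an ITC titration protocol
#'
#' Describes a perfusion-cell titration: a stirred cell of fixed active
#' volume `V0` whose contents are displaced by each syringe injection.
#' Defaults correspond to a standard VP-ITC setup: 1.4 mL cell and 25
#' injections of 10 uL.  Concentrations are in molar; convert from uM/mM
#' at the boundary (see [umol()], [mmol()]).
#'
#' @param cell named numeric vector of initial cell concentrations (M).
#' @param syringe named numeric vector of syringe concentrations (M); must
#'   contain at least one species.
#' @param cell_volume active cell volume V0 in litres (default `1.4e-3`).
#' @param injections numeric vector of injection volumes in litres
#'   (default 25 injections of `10e-6`), or a single count `n` combined
#'   with `inj_volume`.
#' @param inj_volume per-injection volume in litres when `injections` is a
#'   count (default `10e-6`).
#' @param temperature temperature in K (default 298).
#' @param discard_first logical; if `TRUE` the first injection is simulated
#'   and reported but flagged excluded from fitting, the usual treatment of
#'   the small priming injection (default `FALSE`).
#' @return an object of class `titration_protocol`.
#' @examples
#' titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
#' @export
titration_protocol <- function(cell, syringe, cell_volume = 1.4e-3,
                               injections = 25L, inj_volume = 10e-6,
                               temperature = 298, discard_first = FALSE) {
  if (length(injections) == 1L && injections == round(injections) &&
      injections >= 1)
    injections <- rep(inj_volume, injections)
  stopifnot(cell_volume > 0, all(injections > 0), temperature > 0,
            length(syringe) >= 1L, !is.null(names(syringe)),
            !is.null(names(cell)))
  if (any(injections >= 0.25 * cell_volume))
    stop("injection volumes must be small relative to the cell volume",
         call. = FALSE)
  structure(list(cell = cell, syringe = syringe, cell_volume = cell_volume,
                 injections = injections, temperature = temperature,
                 discard_first = isTRUE(discard_first)),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat("ITC titration protocol\n")
  cat("  cell   (", format(x$cell_volume * 1e3), "mL):",
      paste(sprintf("%s=%.4g uM", names(x$cell), x$cell * 1e6),
            collapse = ", "), "\n")
  cat("  syringe:",
      paste(sprintf("%s=%.4g uM", names(x$syringe), x$syringe * 1e6),
            collapse = ", "), "\n")
  cat("  ", length(x$injections), "injections, ",
      format(mean(x$injections) * 1e6, digits = 3), "uL mean, T =",
      x$temperature, "K\n")
  if (x$discard_first) cat("  first injection flagged excluded\n")
  invisible(x)
}

#' Convenience unit conversions to molar
#'
#' @param x concentration value(s) in micromolar (`umol`) or millimolar
#'   (`mmol`).
#' @return value(s) in molar.
#' @export
umol <- function(x) x * 1e-6

#' @rdname umol
#' @export
mmol <- function(x) x * 1e-3

#' Update cell totals after one injection
#'
#' Perfusion-cell displacement bookkeeping: each injection of volume
#' `dV` replaces a fraction `dV/V0` of the cell contents with syringe
#' solution, so for every species
#' \deqn{C \leftarrow C (1 - dV/V_0) + C_{syr} (dV/V_0).}
#'
#' @param state_totals named vector of current cell totals (M).
#' @param protocol a [titration_protocol()].
#' @param i injection index.
#' @return updated named vector of totals (M).
#' @export
dilute_after_injection <- function(state_totals, protocol, i) {
  if (i < 1L || i > length(protocol$injections))
    stop("injection index ", i, " out of range 1..",
         length(protocol$injections), call. = FALSE)
  dv <- protocol$injections[i]
  f <- dv / protocol$cell_volume
  syr <- protocol$syringe[names(state_totals)]
  syr[is.na(syr)] <- 0
  state_totals * (1 - f) + syr * f
}

# identify the injectant: the syringe species used for molar normalization
injectant_species <- function(protocol, injectant = NULL) {
  if (!is.null(injectant)) {
    if (!injectant %in% names(protocol$syringe) ||
        protocol$syringe[injectant] <= 0)
      stop("injectant '", injectant, "' not present in the syringe",
           call. = FALSE)
    return(injectant)
  }
  pos <- names(protocol$syringe)[protocol$syringe > 0]
  if (length(pos) == 0L)
    stop("syringe contains no injectant; molar normalization undefined",
         call. = FALSE)
  pos[which.max(protocol$syringe[pos])]
}

# cell totals trajectory: row 0 = initial, rows 1..n after each injection
totals_trajectory <- function(scheme, protocol, r_m = 1) {
  sp <- scheme$species
  tot <- setNames(numeric(length(sp)), sp)
  cell <- protocol$cell[sp]
  cell[is.na(cell)] <- 0
  tot[] <- cell
  recep <- sp[1]
  tot[recep] <- tot[recep] * r_m
  n <- length(protocol$injections)
  out <- matrix(0, nrow = n + 1L, ncol = length(sp),
                dimnames = list(NULL, sp))
  out[1L, ] <- tot
  for (i in seq_len(n)) {
    tot <- dilute_after_injection(tot, protocol, i)
    out[i + 1L, ] <- tot
  }
  out
}

#' Simulate an ITC binding isotherm
#'
#' Computes the theoretical per-injection heats for a binding scheme under
#' a titration protocol.  After each injection the cell totals are updated
#' by the perfusion-cell dilution rule and the equilibrium speciation is
#' solved; with the heat-content density
#' \eqn{H_i = \sum_c \Delta H_c [c]_i} (cal/L, cumulative complex
#' enthalpies), the heat of injection \eqn{i} is
#' \deqn{q_i = V_0 (H_i - H_{i-1}) + dV_i (H_i + H_{i-1})/2 +
#'   Q_{dil} C_{syr} dV_i,}
#' where the middle term is the midpoint correction for the displaced
#' volume and the last the heat-of-dilution offset per mole of injectant.
#' Heats are reported per mole of injectant added,
#' \eqn{q_i / (C_{syr} dV_i)}.
#'
#' The nominal cell receptor concentration (the scheme's first species) is
#' scaled by `r_m` before the first injection.
#'
#' @param scheme a [binding_scheme()].
#' @param ka named stepwise association constants (M^-1).
#' @param dh named step enthalpies (cal/mol).
#' @param protocol a [titration_protocol()].
#' @param r_m dimensionless scale on the nominal cell receptor
#'   concentration (default 1).
#' @param q_dil heat of dilution, cal per mole of injectant (default 0).
#' @param injectant syringe species used for molar normalization; default
#'   is the most concentrated syringe species.
#' @param noise_sd if > 0, i.i.d. Gaussian noise of this standard deviation
#'   (cal/mol) is added to the molar heats (used by the synthetic-data
#'   generator; requires a seeded RNG for reproducibility).
#' @return an object of class `itc_isotherm`: a data.frame with columns
#'   `injection`, `dV` (L), `ratio` (cumulative injectant / receptor molar
#'   ratio in the cell), `q` (cal), `q_molar` (cal per mol injectant) and
#'   `excluded` (logical).
#' @examples
#' pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
#' iso <- simulate_isotherm(binding_scheme("S1"),
#'                          ka = c(K1 = 1.71e7, K2 = 2.31e4),
#'                          dh = c(K1 = -3730, K2 = -4600), pro)
#' head(iso)
#' @export
simulate_isotherm <- function(scheme, ka, dh, protocol, r_m = 1,
                              q_dil = 0, injectant = NULL, noise_sd = 0) {
  stopifnot(inherits(scheme, "binding_scheme"),
            inherits(protocol, "titration_protocol"), r_m > 0)
  recep <- scheme$species[1]
  cell_r <- protocol$cell[recep]
  if (is.na(cell_r) || cell_r <= 0)
    stop("receptor species '", recep, "' absent from the cell",
         call. = FALSE)
  inj <- injectant_species(protocol, injectant)
  if (!inj %in% scheme$species)
    stop("injectant '", inj, "' is not a species of scheme '",
         scheme$name, "'", call. = FALSE)
  c_syr <- protocol$syringe[[inj]]
  dhc <- cumulative_dh(scheme, dh)

  tot <- totals_trajectory(scheme, protocol, r_m)
  n <- length(protocol$injections)
  v0 <- protocol$cell_volume
  h <- numeric(n + 1L)
  cum_inj <- numeric(n + 1L)
  for (i in seq_len(n + 1L)) {
    st <- solve_speciation(scheme, ka, tot[i, ])
    h[i] <- sum(dhc * st$complexes[names(dhc)])
    cum_inj[i] <- if (inj %in% colnames(tot)) tot[i, inj] else 0
  }
  dv <- protocol$injections
  moles_inj <- c_syr * dv
  q <- v0 * diff(h) + dv * (h[-1] + h[-(n + 1L)]) / 2 + q_dil * moles_inj
  q_molar <- q / moles_inj
  if (noise_sd > 0) {
    q_molar <- q_molar + stats::rnorm(n, 0, noise_sd)
    q <- q_molar * moles_inj
  }
  ratio <- cum_inj[-1L] / tot[-1L, recep]
  excl <- rep(FALSE, n)
  if (protocol$discard_first) excl[1L] <- TRUE
  new_isotherm(data.frame(injection = seq_len(n), dV = dv, ratio = ratio,
                          q = q, q_molar = q_molar, excluded = excl))
}

new_isotherm <- function(df) {
  stopifnot(all(c("injection", "ratio", "q_molar", "excluded") %in%
                  names(df)))
  class(df) <- c("itc_isotherm", "data.frame")
  df
}

#' Molar-ratio axis of a titration
#'
#' Cumulative diluted injectant total over diluted receptor total in the
#' cell after each injection, the x-axis of a binding isotherm.
#'
#' @inheritParams simulate_isotherm
#' @return numeric vector, one ratio per injection, strictly increasing.
#' @export
molar_ratio_axis <- function(scheme, protocol, r_m = 1, injectant = NULL) {
  recep <- scheme$species[1]
  if (is.na(protocol$cell[recep]) || protocol$cell[recep] <= 0)
    stop("receptor species '", recep, "' absent from the cell",
         call. = FALSE)
  inj <- injectant_species(protocol, injectant)
  tot <- totals_trajectory(scheme, protocol, r_m)
  as.numeric(tot[-1L, inj] / tot[-1L, recep])
}

#' Count inflection points of a binding isotherm
#'
#' Smooths the molar heats with a centred moving average and counts sign
#' changes of the second derivative with respect to the molar ratio
#' (finite differences on the, generally non-uniform, ratio grid).  Used
#' to characterize isotherm shape: a single 1:1 binding event yields one
#' interior inflection; well-separated multiple events yield more.
#'
#' @param isotherm an `itc_isotherm`.
#' @param window moving-average window width (odd, default 3).
#' @return integer number of sign changes of the smoothed second
#'   derivative.
#' @export
count_inflections <- function(isotherm, window = 3L) {
  q <- isotherm$q_molar
  r <- isotherm$ratio
  sm <- stats::filter(q, rep(1 / window, window))
  ok <- which(is.finite(sm))
  q <- as.numeric(sm[ok])
  r <- r[ok]
  n <- length(q)
  if (n < 3L) stop("too few points after smoothing", call. = FALSE)
  d2 <- numeric(n - 2L)
  for (i in 2:(n - 1L)) {
    h1 <- r[i] - r[i - 1L]
    h2 <- r[i + 1L] - r[i]
    d2[i - 1L] <- 2 * (h1 * q[i + 1L] - (h1 + h2) * q[i] + h2 * q[i - 1L]) /
      (h1 * h2 * (h1 + h2))
  }
  sum(diff(sign(d2)) != 0)
}

#' @export
plot.itc_isotherm <- function(x, ..., xlab = "molar ratio",
                              ylab = "q (cal/mol injectant)") {
  pch <- ifelse(x$excluded, 1L, 16L)
  graphics::plot(x$ratio, x$q_molar, pch = pch, xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}
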