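#' Combined amide chemical-shift perturbation
#'
#' Weighted combination of the 1H and 15N amide chemical shift changes,
#' \deqn{CSP = \sqrt{\left(\Delta\delta_H^2 +
#'   (w \, \Delta\delta_N)^2\right) / d},}
#' with nitrogen weight `w = 0.14` and normalization divisor `d = 2` by
#' default.  Both the divisor-2 and divisor-1 conventions are in use; `d`
#' is configurable.
#'
#' @param ddh 1H shift change(s), ppm.
#' @param ddn 15N shift change(s), ppm.
#' @param w nitrogen scaling weight (default 0.14).
#' @param d normalization divisor (default 2; must be > 0).
#' @return combined CSP(s), ppm (non-negative).
#' @examples
#' combined_csp(0.10, 0.50)          # 0.0863
#' combined_csp(0.10, 0.50, d = 1)   # 0.1221
#' @export
combined_csp <- function(ddh, ddn, w = 0.14, d = 2) {
  if (d <= 0) stop("divisor d must be > 0", call. = FALSE)
  sqrt((ddh^2 + (w * ddn)^2) / d)
}

#' Construct an NMR peak list
#'
#' @param residue integer residue numbers (unique).
#' @param h_ppm 1H amide shifts (ppm); `NA` marks a missing peak.
#' @param n_ppm 15N amide shifts (ppm); `NA` marks a missing peak.
#' @param label optional titration-point label (e.g. a peptide:protein
#'   ratio).
#' @return a data.frame of class `peak_list`.
#' @export
peak_list <- function(residue, h_ppm, n_ppm, label = NULL) {
  residue <- as.integer(residue)
  if (anyDuplicated(residue))
    stop("duplicate residue numbers in peak list", call. = FALSE)
  df <- data.frame(residue = residue, h_ppm = as.numeric(h_ppm),
                   n_ppm = as.numeric(n_ppm))
  if (any(is.infinite(df$h_ppm), na.rm = TRUE) ||
      any(is.infinite(df$n_ppm), na.rm = TRUE))
    stop("shifts must be finite where present", call. = FALSE)
  attr(df, "label") <- label
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Chemical-shift-perturbation profile between two titration points
#'
#' Matches residues between a reference (apo) and a bound-state peak list,
#' computes per-residue combined CSPs and flags residues whose CSP exceeds
#' the mean plus `k` standard deviations (strictly) of the observed CSPs.
#' Residues missing in either list (e.g. broadened beyond detection in
#' slow/intermediate exchange) are carried with `NA` and excluded from the
#' mean/SD statistics.
#'
#' @param apo,bound [peak_list()] objects (or data.frames with columns
#'   `residue`, `h_ppm`, `n_ppm`).
#' @param w nitrogen weight (default 0.14).
#' @param d normalization divisor (default 2).
#' @param k threshold multiplier on the SD (default 1: the
#'   mean-plus-one-SD rule).
#' @return data.frame of class `csp_profile`: columns `residue`, `dd_h`,
#'   `dd_n`, `csp`, `significant`; attributes `csp_mean`, `csp_sd`,
#'   `threshold`, `w`, `d`, `k`.
#' @export
csp_profile <- function(apo, bound, w = 0.14, d = 2, k = 1) {
  need <- c("residue", "h_ppm", "n_ppm")
  stopifnot(all(need %in% names(apo)), all(need %in% names(bound)))
  common <- intersect(apo$residue, bound$residue)
  all_res <- sort(union(apo$residue, bound$residue))
  ia <- match(all_res, apo$residue)
  ib <- match(all_res, bound$residue)
  dd_h <- bound$h_ppm[ib] - apo$h_ppm[ia]
  dd_n <- bound$n_ppm[ib] - apo$n_ppm[ia]
  csp <- combined_csp(dd_h, dd_n, w = w, d = d)
  if (!any(is.finite(csp)))
    stop("no residues matched between the two peak lists", call. = FALSE)
  obs <- is.finite(csp)
  m <- mean(csp[obs])
  s <- stats::sd(csp[obs])
  if (sum(obs) < 2L) s <- 0
  thr <- m + k * s
  sig <- obs & csp > thr
  out <- data.frame(residue = all_res, dd_h = dd_h, dd_n = dd_n,
                    csp = csp, significant = sig)
  attr(out, "csp_mean") <- m
  attr(out, "csp_sd") <- s
  attr(out, "threshold") <- thr
  attr(out, "w") <- w
  attr(out, "d") <- d
  attr(out, "k") <- k
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' @export
print.csp_profile <- function(x, ...) {
  cat("CSP profile:", nrow(x), "residues,",
      sum(is.finite(x$csp)), "observed,",
      sum(x$significant), "significant (CSP > mean + ",
      attr(x, "k"), "SD = ", format(attr(x, "threshold"), digits = 4),
      "ppm)\n")
  invisible(x)
}

#' @export
plot.csp_profile <- function(x, ..., xlab = "residue",
                             ylab = "combined CSP (ppm)") {
  col <- ifelse(x$significant, "firebrick", "grey40")
  graphics::plot(x$residue, x$csp, type = "h", col = col, lwd = 2,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2, col = "grey50")
  invisible(x)
}

#' Aggregate CSPs by protein lobe
#'
#' Sums combined CSPs over residue ranges, by default the calmodulin
#' N-terminal lobe (residues 1-76) and C-terminal lobe (81-148), leaving
#' the interdomain linker (77-80) unassigned.  Ranges must not overlap.
#'
#' @param profile a [csp_profile()].
#' @param lobes named list of integer residue vectors.
#' @return named numeric vector of per-lobe CSP sums (ppm; `NA` CSPs are
#'   dropped).
#' @export
lobe_sums <- function(profile,
                      lobes = list(N = 1:76, C = 81:148)) {
  all_r <- unlist(lobes, use.names = FALSE)
  if (anyDuplicated(all_r))
    stop("lobe residue ranges overlap", call. = FALSE)
  vapply(lobes, function(rr) {
    v <- profile$csp[profile$residue %in% rr]
    sum(v[is.finite(v)])
  }, numeric(1))
}
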