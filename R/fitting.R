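#' Bundle an isotherm with its binding model for fitting
#'
#' @param isotherm an `itc_isotherm` (from [simulate_isotherm()],
#'   [gen_itc()] or [read_isotherm_csv()]).
#' @param scheme the [binding_scheme()] assumed to generate it.
#' @param protocol the [titration_protocol()] used.
#' @param injectant syringe species for molar normalization (default: the
#'   most concentrated syringe species).
#' @param name dataset label; used to name the per-dataset nuisance
#'   parameters `r_m_<name>` and `q_dil_<name>`.
#' @return a list of class `itc_dataset`.
#' @export
itc_dataset <- function(isotherm, scheme, protocol, injectant = NULL,
                        name = "d1") {
  stopifnot(inherits(scheme, "binding_scheme"),
            inherits(protocol, "titration_protocol"))
  structure(list(isotherm = isotherm, scheme = scheme, protocol = protocol,
                 injectant = injectant, name = name),
            class = "itc_dataset")
}

#' Fit binding parameters to one or several ITC isotherms
#'
#' Estimates stepwise association constants and enthalpies (plus the
#' nuisance parameters `r_m`, the scale on the nominal cell receptor
#' concentration, and `q_dil`, the per-mole heat of dilution) by bounded
#' Levenberg-Marquardt least squares on the per-injection molar heats.
#' With several datasets this is a global fit: step parameters are shared
#' across datasets through their step labels (`ka_K1`, `dh_K1`, ...),
#' while `r_m` and `q_dil` are per dataset (`r_m_<name>`, `q_dil_<name>`).
#'
#' Association constants are optimized as log10(Ka) internally, with
#' default bounds log10(Ka) in `[0, 12]` and `r_m` in `[0.5, 2]`.
#' Injections flagged `excluded` (e.g. the discarded first injection)
#' never enter the sum of squares.
#'
#' @param data an `itc_dataset` or list of them.
#' @param start named numeric vector of starting values on the natural
#'   scale: `ka_<step>` (M^-1) and `dh_<step>` (cal/mol) entries are
#'   required for every step of every scheme; `r_m_<name>` and
#'   `q_dil_<name>` default to 1 and 0.
#' @param fixed named numeric vector of parameters held fixed at the given
#'   values (e.g. `c(r_m_d1 = 1)`).
#' @param lower,upper optional named bounds on the natural scale;
#'   defaults: Ka in `[1, 1e12]`, `r_m` in `[0.5, 2]`, `dh` and `q_dil`
#'   in `[-1e6, 1e6]`.
#' @param control list passed to [minpack.lm::nls.lm.control()]
#'   (default `maxiter = 200`).
#' @return an object of class `itc_fit`; see [summary.itc_fit()].
#'   Components include `coefficients` (natural scale), `se`, `ssr`,
#'   `gof` (overall %), `gof_by_dataset`, `residuals` (list per dataset),
#'   `fitted` (list per dataset), `converged`, `degenerate`,
#'   `max_correlation`, `cov` (covariance of the internal parameters),
#'   `df_residual`.
#' @examples
#' pro <- titration_protocol(cell = c(M = 40e-6), syringe = c(A = 0.8e-3))
#' s2 <- binding_scheme("S2")
#' iso <- simulate_isotherm(s2, c(K1 = 3.6e5), c(K1 = -3260), pro)
#' fit <- itc_fit(itc_dataset(iso, s2, pro),
#'                start = c(ka_K1 = 1e5, dh_K1 = -2000),
#'                fixed = c(r_m_d1 = 1, q_dil_d1 = 0))
#' coef(fit)["ka_K1"]
#' @export
itc_fit <- function(data, start, fixed = NULL, lower = NULL, upper = NULL,
                    control = list()) {
  if (inherits(data, "itc_dataset")) data <- list(data)
  stopifnot(length(data) >= 1L,
            all(vapply(data, inherits, TRUE, "itc_dataset")))
  nm <- vapply(data, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("dataset names must be unique", call. = FALSE)

  # ---- parameter table -------------------------------------------------
  steps <- unique(unlist(lapply(data, function(d) d$scheme$steps)))
  pnames <- c(paste0("ka_", steps), paste0("dh_", steps),
              paste0("r_m_", nm), paste0("q_dil_", nm))
  ptype <- c(rep("ka", length(steps)), rep("dh", length(steps)),
             rep("r_m", length(nm)), rep("q_dil", length(nm)))
  names(ptype) <- pnames

  full <- setNames(rep(NA_real_, length(pnames)), pnames)
  full[ptype == "r_m"] <- 1
  full[ptype == "q_dil"] <- 0
  start <- unlist(start)
  bad <- setdiff(names(start), pnames)
  if (length(bad))
    stop("unknown start parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full[names(start)] <- start
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pnames)
    if (length(bad))
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    full[names(fixed)] <- fixed  # fixed values override start
  }
  if (any(is.na(full)))
    stop("no starting value for: ",
         paste(names(full)[is.na(full)], collapse = ", "), call. = FALSE)
  free <- setdiff(pnames, names(fixed))

  # ---- internal scale and bounds ---------------------------------------
  to_int <- function(p) {
    i <- ptype[names(p)] == "ka"
    p[i] <- log10(p[i])
    p
  }
  to_nat <- function(p) {
    i <- ptype[names(p)] == "ka"
    p[i] <- 10^p[i]
    p
  }
  lo <- c(ka = 0, dh = -1e6, r_m = 0.5, q_dil = -1e6)
  hi <- c(ka = 12, dh = 1e6, r_m = 2, q_dil = 1e6)
  lower_i <- setNames(lo[ptype[free]], free)
  upper_i <- setNames(hi[ptype[free]], free)
  if (!is.null(lower)) {
    li <- to_int(lower[intersect(names(lower), free)])
    lower_i[names(li)] <- li
  }
  if (!is.null(upper)) {
    ui <- to_int(upper[intersect(names(upper), free)])
    upper_i[names(ui)] <- ui
  }

  # ---- data vectors ----------------------------------------------------
  obs <- lapply(data, function(d) {
    keep <- !d$isotherm$excluded
    d$isotherm$q_molar[keep]
  })
  n_eff <- vapply(obs, length, 1L)
  for (j in seq_along(data)) {
    relevant <- sum(ptype[free] %in% c("ka", "dh") &
                      sub("^(ka|dh)_", "", free) %in% data[[j]]$scheme$steps |
                    free %in% paste0(c("r_m_", "q_dil_"), nm[j]))
    if (n_eff[j] < relevant + 1L)
      stop("dataset '", nm[j], "' is under-determined: ", n_eff[j],
           " usable points for ", relevant, " free parameters",
           call. = FALSE)
  }

  model_q <- function(par_nat, d) {
    ka <- par_nat[paste0("ka_", d$scheme$steps)]
    names(ka) <- d$scheme$steps
    dh <- par_nat[paste0("dh_", d$scheme$steps)]
    names(dh) <- d$scheme$steps
    iso <- simulate_isotherm(d$scheme, ka, dh, d$protocol,
                             r_m = par_nat[[paste0("r_m_", d$name)]],
                             q_dil = par_nat[[paste0("q_dil_", d$name)]],
                             injectant = d$injectant)
    iso$q_molar[!d$isotherm$excluded]
  }
  resid_fun <- function(theta) {
    par <- full
    par[free] <- to_nat(setNames(theta, free))
    unlist(lapply(seq_along(data), function(j)
      obs[[j]] - model_q(par, data[[j]])))
  }

  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200), control))
  theta0 <- to_int(full[free])
  fit <- minpack.lm::nls.lm(par = theta0, lower = lower_i,
                            upper = upper_i, fn = resid_fun,
                            control = ctrl)
  theta <- setNames(fit$par, free)
  par_hat <- full
  par_hat[free] <- to_nat(theta)

  # ---- diagnostics -----------------------------------------------------
  r_all <- resid_fun(theta)
  ssr <- sum(r_all^2)
  npt <- sum(n_eff)
  dfres <- npt - length(free)
  sigma2 <- if (dfres > 0) ssr / dfres else NA_real_
  hess <- fit$hessian
  cov_i <- tryCatch(sigma2 * solve(hess), error = function(e) NULL)
  se_int <- if (!is.null(cov_i)) sqrt(pmax(diag(cov_i), 0)) else
    rep(NA_real_, length(free))
  names(se_int) <- free
  # delta method: SE(ka) = ln(10) * ka * SE(log10 ka)
  se_nat <- se_int
  is_ka <- ptype[free] == "ka"
  se_nat[is_ka] <- log(10) * par_hat[free][is_ka] * se_int[is_ka]
  max_cor <- NA_real_
  if (!is.null(cov_i) && length(free) > 1L) {
    dd <- sqrt(pmax(diag(cov_i), 0))
    ok <- dd > 0
    if (sum(ok) > 1L) {
      cc <- cov_i[ok, ok] / tcrossprod(dd[ok])
      max_cor <- max(abs(cc[upper.tri(cc)]))
    }
  }
  all_obs <- unlist(obs)
  sst <- sum((all_obs - mean(all_obs))^2)
  degenerate <- is.null(cov_i) || sst < .Machine$double.eps ||
    max(abs(all_obs)) < 1e-12 ||
    (is.finite(max_cor) && max_cor > 0.999)

  per_gof <- vapply(seq_along(data), function(j) {
    r <- obs[[j]] - model_q(par_hat, data[[j]])
    goodness_of_fit(r, obs[[j]])
  }, numeric(1))
  names(per_gof) <- nm

  structure(list(
    coefficients = par_hat, se = se_nat, free = free, fixed = fixed,
    ssr = ssr, gof = goodness_of_fit(r_all, all_obs),
    gof_by_dataset = per_gof,
    residuals = split(r_all, rep(nm, n_eff)),
    fitted = lapply(seq_along(data), function(j) model_q(par_hat,
                                                         data[[j]])),
    converged = fit$info %in% 1:4, info = fit$info,
    message = fit$message, niter = fit$niter,
    degenerate = degenerate, max_correlation = max_cor,
    cov = cov_i, df_residual = dfres, n_points = npt,
    data = data, ptype = ptype),
    class = "itc_fit")
}

#' Goodness-of-fit percentage
#'
#' `GoF = 100 * sqrt(max(0, 1 - SSR/SST))` with
#' `SST = sum((q - mean(q))^2)`: 100% for a perfect fit, 0% for a model no
#' better than the data mean.  Undefined (`NA`, with a warning) for
#' constant data.
#'
#' @param residuals numeric vector of fit residuals.
#' @param observed the observed values the residuals refer to (>= 2).
#' @return percentage in `[0, 100]`, or `NA` if SST is zero.
#' @examples
#' goodness_of_fit(c(0, 0), c(3, 1))    # 100
#' goodness_of_fit(c(1, -1), c(3, 1))   # 0
#' @export
goodness_of_fit <- function(residuals, observed) {
  if (length(observed) < 2L)
    stop("need at least two points", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) {
    warning("constant data: goodness of fit undefined")
    return(NA_real_)
  }
  100 * sqrt(max(0, 1 - sum(residuals^2) / sst))
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
vcov.itc_fit <- function(object, ...) object$cov

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC ", if (length(x$data) > 1L) "global " else "",
      "fit: ", length(x$data), " dataset(s), schemes ",
      paste(unique(vapply(x$data, function(d) d$scheme$name, "")),
            collapse = "+"), "\n", sep = "")
  est <- x$coefficients[x$free]
  cat("Estimates:\n")
  print(signif(est, 4))
  cat(sprintf("SSR = %.4g   GoF = %.1f%%   (%d points, %d free par.)\n",
              x$ssr, x$gof, x$n_points, length(x$free)))
  if (!x$converged) cat("WARNING: optimizer did not converge (info ",
                        x$info, ": ", x$message, ")\n", sep = "")
  if (x$degenerate)
    cat("NOTE: fit flagged degenerate (no signal or extreme parameter",
        "correlation)\n")
  invisible(x)
}

#' Summarize an ITC fit
#'
#' @param object an `itc_fit`.
#' @param T temperature (K) for the derived dG/dS values (default 298).
#' @param ... unused.
#' @return object of class `summary.itc_fit`: the fit plus a coefficient
#'   table and a per-step thermodynamic table (Ka, Kd, dG, dH, dS).
#' @export
summary.itc_fit <- function(object, T = 298, ...) {
  est <- object$coefficients[object$free]
  tab <- cbind(estimate = est, std_error = object$se[object$free])
  steps <- sub("^ka_", "", grep("^ka_", names(object$coefficients),
                                value = TRUE))
  thermo <- do.call(rbind, lapply(steps, function(s) {
    ka <- object$coefficients[[paste0("ka_", s)]]
    dh <- object$coefficients[[paste0("dh_", s)]]
    ts <- thermo_summary(ka, dh, T = T)
    data.frame(step = s, ka = ka, kd = ts$kd, dg = ts$dg, dh = dh,
               ds = ts$ds)
  }))
  structure(list(fit = object, coef_table = tab, thermo = thermo, T = T),
            class = "summary.itc_fit")
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (free parameters):\n")
  print(signif(x$coef_table, 4))
  cat("\nPer-step thermodynamics (T =", x$T, "K; cal, mol, M):\n")
  print(format(x$thermo, digits = 4), row.names = FALSE)
  if (is.finite(x$fit$max_correlation))
    cat(sprintf("\nMax |parameter correlation| = %.3f\n",
                x$fit$max_correlation))
  cat("GoF by dataset:",
      paste(sprintf("%s: %.1f%%", names(x$fit$gof_by_dataset),
                    x$fit$gof_by_dataset), collapse = ", "), "\n")
  invisible(x)
}

#' Predicted isotherm(s) at the fitted parameters
#'
#' @param object an `itc_fit`.
#' @param newdata optionally an `itc_dataset` (or list of them) to predict
#'   for; defaults to the fitted datasets.
#' @param ... unused.
#' @return a list of `itc_isotherm` objects (one per dataset), or a single
#'   isotherm if only one dataset is involved.
#' @export
predict.itc_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else
    if (inherits(newdata, "itc_dataset")) list(newdata) else newdata
  par <- object$coefficients
  out <- lapply(data, function(d) {
    ka <- setNames(par[paste0("ka_", d$scheme$steps)], d$scheme$steps)
    dh <- setNames(par[paste0("dh_", d$scheme$steps)], d$scheme$steps)
    rmn <- paste0("r_m_", d$name)
    qdn <- paste0("q_dil_", d$name)
    simulate_isotherm(d$scheme, ka, dh, d$protocol,
                      r_m = if (rmn %in% names(par)) par[[rmn]] else 1,
                      q_dil = if (qdn %in% names(par)) par[[qdn]] else 0,
                      injectant = d$injectant)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Simulate new isotherms from a fitted model
#'
#' Parametric simulation: the fitted model heats plus Gaussian noise with
#' the residual standard deviation of the fit.
#'
#' @param object an `itc_fit`.
#' @param nsim number of replicate sets (default 1).
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return a list of length `nsim`; each element is a list of
#'   `itc_isotherm` objects, one per fitted dataset.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdres <- sqrt(object$ssr / max(object$df_residual, 1))
  base <- predict(object)
  if (inherits(base, "itc_isotherm")) base <- list(base)
  lapply(seq_len(nsim), function(k)
    lapply(base, function(iso) {
      moles <- iso$q / iso$q_molar
      iso$q_molar <- iso$q_molar + stats::rnorm(nrow(iso), 0, sdres)
      iso$q <- iso$q_molar * moles
      iso
    }))
}

#' @export
plot.itc_fit <- function(x, which = seq_along(x$data), ...) {
  for (j in which) {
    d <- x$data[[j]]
    pred <- predict(x, newdata = d)
    plot(d$isotherm, main = d$name, ...)
    graphics::lines(pred$ratio, pred$q_molar, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
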