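#' Solve coupled mass-balance equilibria for a binding scheme
#'
#' Given total (analytical) concentrations of every free species and the
#' stepwise association constants, computes the free and complex
#' concentrations satisfying mass action,
#' \deqn{[c] = \beta_c \prod_s [s]^{\nu_{cs}},}
#' and mass balance,
#' \deqn{T_s = [s] + \sum_c \nu_{cs} [c],}
#' for every species \eqn{s}.
#'
#' The solver works in log-free-concentration space with damped Newton
#' iterations, which guarantees positivity and handles cumulative constants
#' spanning many orders of magnitude.  If Newton stalls, a nested-bisection
#' fallback is used for schemes in which every complex contains exactly one
#' receptor (true for all bundled schemes).  The result is deterministic:
#' it does not depend on a user-supplied starting guess.
#'
#' @param scheme a [binding_scheme()].
#' @param ka named numeric vector of stepwise association constants (M^-1).
#' @param totals named numeric vector of total concentrations (M), one per
#'   scheme species; non-negative.
#' @param tol maximum relative mass-balance residual accepted
#'   (default `1e-10`).
#' @param max_iter Newton iteration cap (default 200).
#' @return an object of class `speciation_state`: list with `totals`,
#'   `free` (named, M), `complexes` (named, M), and `residual`, the worst
#'   relative mass-balance residual.
#' @examples
#' s2 <- binding_scheme("S2")
#' st <- solve_speciation(s2, c(K1 = 1e6), c(M = 1e-6, A = 1e-6))
#' st$complexes[["MA"]]   # 3.8197e-7, the (-1+sqrt(5))/2e6 quadratic root
#' @export
solve_speciation <- function(scheme, ka, totals, tol = 1e-10,
                             max_iter = 200L) {
  stopifnot(inherits(scheme, "binding_scheme"))
  totals <- check_totals(scheme, totals)
  beta <- cumulative_beta(scheme, ka)
  nu <- scheme$nu

  active <- totals > 0
  free <- numeric(length(totals))
  names(free) <- names(totals)

  if (!any(active)) {
    cplx <- setNames(numeric(nrow(nu)), rownames(nu))
    return(new_speciation_state(totals, free, cplx, 0))
  }

  # complexes needing an absent species, or with beta = 0, have zero
  # concentration; drop them so the reduced problem is solved exactly as
  # the corresponding smaller scheme would be
  live_cplx <- apply(nu[, !active, drop = FALSE] > 0, 1, sum) == 0 &
    beta > 0
  nu_a <- nu[live_cplx, active, drop = FALSE]
  beta_a <- beta[live_cplx]
  t_a <- totals[active]

  sol <- speciate_newton(nu_a, beta_a, t_a, tol, max_iter)
  if (is.null(sol)) {
    sol <- speciate_bisect(nu_a, beta_a, t_a, tol)
    if (is.null(sol))
      stop("speciation solver failed to converge for scheme '", scheme$name,
           "' (worst relative residual ",
           format(attr(speciate_newton(nu_a, beta_a, t_a, tol, max_iter,
                                       give_up = TRUE), "residual"),
                  digits = 3), ")", call. = FALSE)
  }

  free[active] <- sol
  cplx <- setNames(numeric(nrow(nu)), rownames(nu))
  if (nrow(nu_a)) {
    cplx[rownames(nu_a)] <- if (all(sol > 0))
      beta_a * exp(as.numeric(nu_a %*% log(sol)))
    else
      beta_a * apply(nu_a, 1, function(v) prod(sol^v))
  }
  resid <- worst_residual(nu, cplx, free, totals)
  new_speciation_state(totals, free, cplx, resid)
}

new_speciation_state <- function(totals, free, complexes, residual) {
  structure(list(totals = totals, free = free, complexes = complexes,
                 residual = residual),
            class = "speciation_state")
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("Speciation state (concentrations in M)\n")
  df <- data.frame(total = x$totals, free = x$free)
  print(format(df, digits = 5))
  if (length(x$complexes)) {
    cat("complexes:\n")
    print(format(x$complexes, digits = 5))
  }
  cat("worst relative mass-balance residual:",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

check_totals <- function(scheme, totals) {
  if (is.null(names(totals)))
    stop("`totals` must be named by species", call. = FALSE)
  missing <- setdiff(scheme$species, names(totals))
  if (length(missing))
    stop("missing totals for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  totals <- totals[scheme$species]
  if (any(totals < 0) || any(!is.finite(totals)))
    stop("totals must be finite and >= 0", call. = FALSE)
  totals
}

worst_residual <- function(nu, cplx, free, totals) {
  bound <- if (nrow(nu)) as.numeric(crossprod(nu, cplx)) else
    numeric(ncol(nu))
  names(bound) <- colnames(nu)
  err <- abs(free[names(bound)] + bound - totals[names(bound)])
  denom <- pmax(totals[names(bound)], .Machine$double.xmin)
  max(c(0, err / denom))
}

# Damped Newton in x = log(free).  Residual g_s = log1p-free formulation is
# not needed; we minimize the scaled balance residual directly.
speciate_newton <- function(nu, beta, totals, tol, max_iter,
                            give_up = FALSE) {
  ns <- length(totals)
  if (nrow(nu) == 0L) return(totals)  # no feasible complexes
  x <- log(totals)  # start at free = total
  fres <- function(x) {
    f <- exp(x)
    c_ <- beta * exp(as.numeric(nu %*% x))
    bal <- f + as.numeric(crossprod(nu, c_)) - totals
    list(f = f, c = c_, bal = bal, scaled = bal / totals)
  }
  st <- fres(x)
  best <- max(abs(st$scaled))
  for (it in seq_len(max_iter)) {
    if (best < tol) return(st$f)
    # Jacobian wrt x_t: delta_st * f_s + sum_c nu_cs nu_ct [c]
    J <- diag(st$f, ns, ns) +
      t(nu) %*% (nu * st$c)  # (nu' diag(c) nu)_{st}
    Js <- J / totals  # scale rows like the residual
    step <- tryCatch(solve(Js, st$scaled), error = function(e) NULL)
    if (is.null(step)) break
    # damp: cap step length in log space, then backtrack on residual norm
    step <- pmin(pmax(step, -5), 5)
    lam <- 1
    improved <- FALSE
    for (k in 1:30) {
      cand <- fres(x - lam * step)
      if (max(abs(cand$scaled)) < best) {
        x <- x - lam * step
        st <- cand
        best <- max(abs(st$scaled))
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (best < tol) return(st$f)
  if (give_up) return(structure(NULL, residual = best))
  NULL
}

# Nested bisection for schemes where every complex has exactly one receptor
# (first species).  Free receptor is then linear given ligand frees, and
# each ligand balance is monotone in its own free concentration.
speciate_bisect <- function(nu, beta, totals, tol) {
  sp <- colnames(nu)
  if (nrow(nu) == 0L) return(totals)
  if (any(nu[, 1] != 1L)) return(NULL)  # fallback unavailable
  recep <- sp[1]
  ligs <- sp[-1]
  if (length(ligs) > 2L) return(NULL)

  free_m <- function(flig) {
    # denom = 1 + sum_c beta_c prod_lig flig^nu
    denom <- 1 + sum(beta * apply(nu[, ligs, drop = FALSE], 1, function(v)
      prod(flig^v)))
    totals[recep] / denom
  }
  cplx_at <- function(fm, flig) {
    beta * fm * apply(nu[, ligs, drop = FALSE], 1, function(v) prod(flig^v))
  }
  lig_balance <- function(l, flig) {
    fm <- free_m(flig)
    c_ <- cplx_at(fm, flig)
    flig[l] + sum(nu[, l] * c_) - totals[l]
  }
  bisect <- function(fun, lo, hi, n = 200L) {
    flo <- fun(lo)
    if (flo > 0) return(lo)
    for (i in seq_len(n)) {
      mid <- (lo + hi) / 2
      if (fun(mid) <= 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  solve_b <- function(fa) {
    # returns full ligand free vector given free A (first ligand)
    if (length(ligs) == 1L) return(setNames(fa, ligs))
    fb <- bisect(function(b) lig_balance(ligs[2],
                                         setNames(c(fa, b), ligs)),
                 0, totals[ligs[2]])
    setNames(c(fa, fb), ligs)
  }
  fa <- bisect(function(a) lig_balance(ligs[1], solve_b(a)),
               0, totals[ligs[1]])
  flig <- solve_b(fa)
  fm <- free_m(flig)
  out <- setNames(c(fm, flig), c(recep, ligs))[sp]
  c_ <- cplx_at(fm, flig)
  res <- max(abs(out + as.numeric(crossprod(nu, c_)) - totals) /
               pmax(totals, .Machine$double.xmin))
  if (res > 1e3 * tol) return(NULL)
  out
}

#' Species distribution along a titration trajectory
#'
#' Solves the speciation at each point of a trajectory of total
#' concentrations and tabulates the complex concentrations, as used for
#' concentration-distribution plots of the CaM complexes formed during a
#' competition titration.
#'
#' @param scheme a [binding_scheme()].
#' @param ka named stepwise association constants (M^-1).
#' @param totals_trajectory a data.frame or matrix of total concentrations
#'   (M), one column per scheme species, one row per titration point; or a
#'   list of named vectors.
#' @param tol,max_iter passed to [solve_speciation()].
#' @return a data.frame with one row per point: free-species columns
#'   (`free_<species>`) and one column per complex (M).
#' @export
species_distribution <- function(scheme, ka, totals_trajectory,
                                 tol = 1e-10, max_iter = 200L) {
  if (is.list(totals_trajectory) && !is.data.frame(totals_trajectory))
    totals_trajectory <- do.call(rbind, totals_trajectory)
  tt <- as.matrix(totals_trajectory)
  if (nrow(tt) == 0L) stop("empty trajectory", call. = FALSE)
  rows <- vector("list", nrow(tt))
  for (i in seq_len(nrow(tt))) {
    st <- tryCatch(
      solve_speciation(scheme, ka, tt[i, , drop = TRUE],
                       tol = tol, max_iter = max_iter),
      error = function(e)
        stop("speciation failed at trajectory point ", i, ": ",
             conditionMessage(e), call. = FALSE))
    rows[[i]] <- c(setNames(st$free, paste0("free_", names(st$free))),
                   st$complexes)
  }
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
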