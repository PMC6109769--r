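#' Construct a binding scheme
#'
#' A binding scheme is a declarative reaction network over a receptor and one
#' or two ligand species.  Each complex is reached along an ordered path of
#' elementary association steps; its cumulative formation constant
#' \eqn{\beta} is the product of the stepwise association constants along
#' that path, and its cumulative enthalpy is the sum of the step enthalpies.
#'
#' Five schemes covering the CaM / dCRY / INAD titration designs are
#' bundled (species `M` = calmodulin, `A` = dCRY peptide, `B` = INAD
#' peptide):
#'
#' * `"S1"` sequential two-site dCRY binding:
#'   `M + A <-> MA` (`K1`, high-affinity site), `MA + A <-> MA2`
#'   (`K2`, low-affinity site).
#' * `"S2"` single-site dCRY binding (apo-CaM): `M + A <-> MA` (`K1`).
#' * `"S3"` single-site INAD binding: `M + B <-> MB` (`KB`).
#' * `"S4"` competition of INAD and dCRY for the high-affinity site with
#'   subsequent dCRY binding to the low-affinity site of the CaM-dCRY
#'   complex: the `S1` steps plus `M + B <-> MB` (`KB`); no ternary complex.
#' * `"S5"` as `S4` plus dCRY binding to the low-affinity site of the
#'   CaM-INAD complex: `MB + A <-> MAB` (`K3`), the CaM-INAD-dCRY ternary
#'   complex.
#'
#' Stepwise constants are macroscopic stoichiometric constants; no
#' statistical-factor conversion to microscopic site constants is applied.
#'
#' @param scheme_id one of `"S1"`, `"S2"`, `"S3"`, `"S4"`, `"S5"`
#'   (case-insensitive).
#' @return an object of class `binding_scheme`: a list with elements
#'   `name`, `species` (character, receptor first), `steps` (character
#'   vector of step labels), `complexes` (named list; each element has
#'   integer `stoich` named by species and `path`, the step labels whose
#'   constants multiply to the cumulative constant).
#' @seealso [make_scheme()] for custom networks, [solve_speciation()].
#' @examples
#' s5 <- binding_scheme("S5")
#' names(s5$complexes)   # "MA" "MA2" "MB" "MAB"
#' @export
binding_scheme <- function(scheme_id) {
  valid <- c("S1", "S2", "S3", "S4", "S5")
  id <- toupper(as.character(scheme_id)[1])
  if (!id %in% valid)
    stop("unknown scheme id '", scheme_id, "'; valid ids: ",
         paste(valid, collapse = ", "), call. = FALSE)
  cx <- function(stoich, path) list(stoich = stoich, path = path)
  switch(id,
    S1 = make_scheme("S1", species = c("M", "A"),
      steps = c("K1", "K2"),
      complexes = list(
        MA  = cx(c(M = 1L, A = 1L), "K1"),
        MA2 = cx(c(M = 1L, A = 2L), c("K1", "K2")))),
    S2 = make_scheme("S2", species = c("M", "A"),
      steps = "K1",
      complexes = list(MA = cx(c(M = 1L, A = 1L), "K1"))),
    S3 = make_scheme("S3", species = c("M", "B"),
      steps = "KB",
      complexes = list(MB = cx(c(M = 1L, B = 1L), "KB"))),
    S4 = make_scheme("S4", species = c("M", "A", "B"),
      steps = c("K1", "K2", "KB"),
      complexes = list(
        MA  = cx(c(M = 1L, A = 1L), "K1"),
        MA2 = cx(c(M = 1L, A = 2L), c("K1", "K2")),
        MB  = cx(c(M = 1L, B = 1L), "KB"))),
    S5 = make_scheme("S5", species = c("M", "A", "B"),
      steps = c("K1", "K2", "KB", "K3"),
      complexes = list(
        MA  = cx(c(M = 1L, A = 1L), "K1"),
        MA2 = cx(c(M = 1L, A = 2L), c("K1", "K2")),
        MB  = cx(c(M = 1L, B = 1L), "KB"),
        MAB = cx(c(M = 1L, A = 1L, B = 1L), c("KB", "K3")))))
}

#' Define a custom binding scheme
#'
#' @param name scheme label.
#' @param species character vector of free-species labels; the first entry
#'   is the receptor.
#' @param steps character vector of step labels; each step carries one
#'   stepwise association constant in fits and simulations.
#' @param complexes named list; each element is `list(stoich = , path = )`
#'   with `stoich` a named non-negative integer vector over `species` and
#'   `path` an ordered character vector of step labels.
#' @return a `binding_scheme` object.
#' @export
make_scheme <- function(name, species, steps, complexes) {
  stopifnot(is.character(species), length(species) >= 1L,
            is.character(steps), length(steps) >= 1L,
            is.list(complexes), length(complexes) >= 1L,
            !is.null(names(complexes)))
  for (lab in names(complexes)) {
    cc <- complexes[[lab]]
    if (!all(names(cc$stoich) %in% species))
      stop("complex '", lab, "' references unknown species", call. = FALSE)
    if (any(cc$stoich < 0) || any(cc$stoich != round(cc$stoich)))
      stop("complex '", lab, "' has non-integer or negative stoichiometry",
           call. = FALSE)
    if (!all(cc$path %in% steps))
      stop("complex '", lab, "' has a path step not in `steps`",
           call. = FALSE)
  }
  # stoichiometry matrix: complexes x species, zero-filled
  nu <- matrix(0L, nrow = length(complexes), ncol = length(species),
               dimnames = list(names(complexes), species))
  for (lab in names(complexes))
    nu[lab, names(complexes[[lab]]$stoich)] <- complexes[[lab]]$stoich
  structure(list(name = name, species = species, steps = steps,
                 complexes = complexes, nu = nu),
            class = "binding_scheme")
}

#' @export
print.binding_scheme <- function(x, ...) {
  cat("Binding scheme '", x$name, "'\n", sep = "")
  cat("  species  :", paste(x$species, collapse = ", "),
      "(receptor:", x$species[1], ")\n")
  cat("  steps    :", paste(x$steps, collapse = ", "), "\n")
  cat("  complexes:\n")
  for (lab in names(x$complexes)) {
    cc <- x$complexes[[lab]]
    st <- cc$stoich[cc$stoich > 0]
    cat("    ", lab, " = ",
        paste(ifelse(st > 1, paste0(st, "x", names(st)), names(st)),
              collapse = " + "),
        "   beta = ", paste(cc$path, collapse = " * "), "\n", sep = "")
  }
  invisible(x)
}

#' Cumulative formation constants of a scheme's complexes
#'
#' Multiplies the stepwise association constants along each complex's
#' formation path.
#'
#' @param scheme a `binding_scheme`.
#' @param ka named numeric vector of stepwise association constants
#'   (M^-1), names matching `scheme$steps`.
#' @return named numeric vector of cumulative constants, one per complex.
#' @export
cumulative_beta <- function(scheme, ka) {
  ka <- check_step_values(scheme, ka, "ka")
  # ka = 0 is admissible: it removes the complexes formed through that step
  if (any(ka < 0) || any(!is.finite(ka)))
    stop("all stepwise ka must be finite and >= 0", call. = FALSE)
  vapply(scheme$complexes, function(cc) prod(ka[cc$path]), numeric(1))
}

#' Cumulative enthalpies of a scheme's complexes
#'
#' Sums the step enthalpies along each complex's formation path.
#'
#' @param scheme a `binding_scheme`.
#' @param dh named numeric vector of step enthalpies (cal/mol), names
#'   matching `scheme$steps`.
#' @return named numeric vector, one per complex.
#' @export
cumulative_dh <- function(scheme, dh) {
  dh <- check_step_values(scheme, dh, "dh")
  if (any(!is.finite(dh))) stop("all step dh must be finite", call. = FALSE)
  vapply(scheme$complexes, function(cc) sum(dh[cc$path]), numeric(1))
}

check_step_values <- function(scheme, x, what) {
  if (is.null(names(x)) && length(x) == length(scheme$steps))
    names(x) <- scheme$steps
  missing <- setdiff(scheme$steps, names(x))
  if (length(missing))
    stop("missing ", what, " for step(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x[scheme$steps]
}
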