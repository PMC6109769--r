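#' Read an integrated-heat isotherm from CSV
#'
#' Expected columns: `injection`, `dV_uL`, `q_molar_cal_per_mol`, `ratio`
#' and optionally `excluded` (0/1 or logical).  A
#' `q_molar_ucal_per_mol` column is accepted instead of the cal/mol one
#' and converted.  Validation failures report the offending line.
#'
#' @param path CSV file path.
#' @return an `itc_isotherm`.
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  ucal <- "q_molar_ucal_per_mol" %in% names(df)
  qcol <- if (ucal) "q_molar_ucal_per_mol" else "q_molar_cal_per_mol"
  need <- c("injection", "dV_uL", qcol, "ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cc in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop("non-numeric value in column '", cc, "' at data line ",
           bad[1], call. = FALSE)
    df[[cc]] <- as.numeric(df[[cc]])
  }
  dup <- which(duplicated(df$injection))
  if (length(dup))
    stop("duplicate injection index at data line ", dup[1], call. = FALSE)
  nd <- which(diff(df$ratio) <= 0)
  if (length(nd))
    stop("molar ratio not strictly increasing at data line ", nd[1] + 1L,
         call. = FALSE)
  excl <- if ("excluded" %in% names(df)) as.logical(df$excluded) else
    rep(FALSE, nrow(df))
  q_molar <- df[[qcol]] * if (ucal) 1e-6 else 1
  new_isotherm(data.frame(injection = df$injection, dV = df$dV_uL * 1e-6,
                          ratio = df$ratio, q = NA_real_,
                          q_molar = q_molar, excluded = excl))
}

#' Write an isotherm to CSV
#'
#' Writes the standard isotherm columns (`injection`, `dV_uL`,
#' `q_molar_cal_per_mol`, `ratio`, `excluded`) at full float precision so
#' that [read_isotherm_csv()] round-trips losslessly.
#'
#' @param isotherm an `itc_isotherm`.
#' @param path output path.
#' @param overwrite allow overwriting an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(isotherm, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path,
         " (use overwrite = TRUE)", call. = FALSE)
  df <- data.frame(injection = isotherm$injection,
                   dV_uL = format(isotherm$dV * 1e6, digits = 17),
                   q_molar_cal_per_mol = format(isotherm$q_molar,
                                                digits = 17),
                   ratio = format(isotherm$ratio, digits = 17),
                   excluded = as.integer(isotherm$excluded))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an NMR peak list
#'
#' Two dialects: `"csv"` expects columns `residue`, `h_ppm` (or `1H_ppm`)
#' and `n_ppm` (or `15N_ppm`); `"sparky"` expects whitespace-separated
#' lines `assignment w1 w2` where the assignment is like `M109N-H`
#' (residue letter, number, `N-H`), `w1` the 15N shift and `w2` the 1H
#' shift.  Blank lines and lines starting with `#` (or a Sparky
#' `Assignment` header) are ignored; unparseable Sparky assignments are
#' skipped with a warning.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"sparky"`.
#' @return a [peak_list()].
#' @export
read_peaklist <- function(path, dialect = c("csv", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    names(df)[names(df) %in% c("1H_ppm", "H_ppm")] <- "h_ppm"
    names(df)[names(df) %in% c("15N_ppm", "N_ppm")] <- "n_ppm"
    need <- c("residue", "h_ppm", "n_ppm")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing peak-list column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (nrow(df) == 0L) stop("empty peak list: ", path, call. = FALSE)
    return(peak_list(df$residue, df$h_ppm, df$n_ppm))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !grepl("^Assignment", lines)]
  res <- integer(0); n <- numeric(0); h <- numeric(0)
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    m <- regmatches(parts[1],
                    regexec("^[A-Za-z]([0-9]+)N-?H$", parts[1]))[[1]]
    w <- suppressWarnings(as.numeric(parts[2:3]))
    if (length(m) < 2L || length(parts) < 3L || any(!is.finite(w))) {
      skipped <- skipped + 1L
      next
    }
    res <- c(res, as.integer(m[2]))
    n <- c(n, w[1])
    h <- c(h, w[2])
  }
  if (skipped > 0L)
    warning(skipped, " unparseable line(s) skipped in ", path)
  if (length(res) == 0L)
    stop("no parseable peaks in ", path, call. = FALSE)
  peak_list(res, h, n)
}

#' Write a CSP profile to CSV
#'
#' @param profile a [csp_profile()].
#' @param path output path.
#' @param overwrite allow overwriting (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_csp_csv <- function(profile, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path,
         " (use overwrite = TRUE)", call. = FALSE)
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write fit results to JSON
#'
#' Serializes an [itc_fit()] to JSON: free-parameter estimates and
#' standard errors, SSR, GoF, convergence flags and per-step
#' thermodynamic summaries (Kd, dG, dS at 298 K).
#'
#' @param fit an `itc_fit`.
#' @param path output path.
#' @param overwrite allow overwriting (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path,
         " (use overwrite = TRUE)", call. = FALSE)
  sm <- summary(fit)
  out <- list(
    parameters = as.list(fit$coefficients[fit$free]),
    std_errors = as.list(fit$se[fit$free]),
    fixed = as.list(fit$fixed),
    ssr = fit$ssr, gof_percent = fit$gof,
    gof_by_dataset = as.list(fit$gof_by_dataset),
    converged = fit$converged, degenerate = fit$degenerate,
    max_correlation = fit$max_correlation,
    thermodynamics = sm$thermo)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
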