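.case_columns <- c(
  "case_id", "pump_type", "afterload",
  "P_b_in", "P_b_out", "P_d_in", "P_d_out",
  "Q_b_in", "Q_b_out", "Q_d_in", "Q_d_out", "UF", "blood_type"
)
.case_numeric <- c(
  "P_b_in", "P_b_out", "P_d_in", "P_d_out",
  "Q_b_in", "Q_b_out", "Q_d_in", "Q_d_out", "UF"
)
.conc_columns <- c("case_id", "solute", "C_b_in", "C_b_out", "C_d_in", "C_d_out")

#' Read a table of dialyzer operating cases
#'
#' Reads a comma-delimited bench table of per-case operating conditions:
#' port pressures (mmHg), port flows (ml/min), net ultrafiltration
#' (ml/min), pump type (`WAK` or `roller_centrifugal`), an afterload flag
#' and the working fluid (`saline` or `porcine`). Values stay in bench
#' units in the returned table; solvers convert to SI on entry. An empty
#' file (header only) yields an empty table with a warning.
#'
#' @param path path to a CSV file with the columns listed above.
#' @return a `data.frame` of class `dialyzer_cases`.
#' @seealso [bench_cases()] for the packaged M60 bench table,
#'   [mass_balance_report()] for the `Q_b_in - Q_b_out - UF` diagnostic.
#' @export
load_case_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.case_columns, names(x))
  if (length(missing_cols)) {
    stop("case table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, .case_columns]
  for (col in .case_numeric) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(x[[col]])))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' in column %s, case row '%s'",
        x[[col]][bad[1]], col, x$case_id[bad[1]]
      ))
    }
    x[[col]] <- v
  }
  x$afterload <- as.logical(x$afterload)
  bad_pump <- setdiff(unique(x$pump_type), c("WAK", "roller_centrifugal"))
  if (length(bad_pump) && nrow(x)) {
    stop("unknown pump_type value(s): ", paste(bad_pump, collapse = ", "))
  }
  if (!nrow(x)) warning("case table ", path, " contains no rows")
  if (anyDuplicated(x$case_id)) stop("duplicated case_id in ", path)
  class(x) <- c("dialyzer_cases", "data.frame")
  x
}

#' Write a table of operating cases
#'
#' Serializes in exactly the dialect [load_case_table()] reads, so that a
#' load/write round trip is byte-identical for tables holding bench-unit
#' values at table precision.
#'
#' @param cases a `dialyzer_cases` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(cases, path) {
  x <- as.data.frame(cases)[, .case_columns]
  for (col in .case_numeric) x[[col]] <- vapply(x[[col]], .format_num, "")
  x$afterload <- ifelse(x$afterload, "TRUE", "FALSE")
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.format_num <- function(v) {
  format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Read a table of measured port concentrations
#'
#' One row per case and solute, holding the four port concentrations in
#' mg/dL: blood inlet/outlet and dialysate inlet/outlet.
#'
#' @param path path to a CSV file with columns
#'   `case_id,solute,C_b_in,C_b_out,C_d_in,C_d_out`.
#' @return a `data.frame` of class `dialyzer_concentrations`.
#' @export
load_concentration_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.conc_columns, names(x))
  if (length(missing_cols)) {
    stop("concentration table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, .conc_columns]
  for (col in .conc_columns[3:6]) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(x[[col]])))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' in column %s, case row '%s'",
        x[[col]][bad[1]], col, x$case_id[bad[1]]
      ))
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative concentration in column ", col)
    }
    x[[col]] <- v
  }
  class(x) <- c("dialyzer_concentrations", "data.frame")
  x
}

#' Packaged M60 bench characterization tables
#'
#' Bench measurements of a Multiflow M60 dialyzer operated with either a
#' counter-phased dual-ventricle pulsatile (WAK) pump driving both blood
#' and dialysate, or a roller blood pump plus centrifugal dialysate pump.
#' `bench_cases()` returns mean operating conditions (29 cases; pressures
#' in mmHg, flows in ml/min); `bench_concentrations()` urea and creatinine
#' port concentrations (mg/dL) for the saline cases sampled for clearance;
#' `bench_clearances()` the corresponding measured (`K_exp`) and
#' model-computed (`K_num`) clearances in ml/min. Measured rows carry
#' about 1 ml/min / 1 mmHg rounding.
#'
#' @return a data frame (see [load_case_table()],
#'   [load_concentration_table()] for the schemas).
#' @export
bench_cases <- function() {
  load_case_table(system.file("extdata", "bench_cases.csv",
    package = "hfdialyzer", mustWork = TRUE
  ))
}

#' @rdname bench_cases
#' @export
bench_concentrations <- function() {
  load_concentration_table(system.file("extdata", "bench_concentrations.csv",
    package = "hfdialyzer", mustWork = TRUE
  ))
}

#' @rdname bench_cases
#' @export
bench_clearances <- function() {
  x <- utils::read.csv(
    system.file("extdata", "bench_clearances.csv",
      package = "hfdialyzer", mustWork = TRUE
    ),
    stringsAsFactors = FALSE
  )
  x$case_id <- as.character(x$case_id)
  x
}

#' Select one operating case by id
#'
#' @param cases a `dialyzer_cases` data frame.
#' @param case_id case identifier (matched as character).
#' @return the one-row `dialyzer_cases` data frame for that case.
#' @export
get_case <- function(cases, case_id) {
  i <- match(as.character(case_id), as.character(cases$case_id))
  if (is.na(i)) stop("no case with id '", case_id, "'")
  cases[i, , drop = FALSE]
}

#' Port concentrations for one case and solute
#'
#' @param concentrations a `dialyzer_concentrations` data frame.
#' @param case_id case identifier.
#' @param solute solute name.
#' @return one-row data frame with the four port concentrations, mg/dL.
#' @export
get_concentrations <- function(concentrations, case_id, solute) {
  i <- which(as.character(concentrations$case_id) == as.character(case_id) &
    concentrations$solute == solute)
  if (!length(i)) {
    stop("no concentrations for case '", case_id, "', solute '", solute, "'")
  }
  concentrations[i[1], , drop = FALSE]
}

#' Blood-side volumetric mass-balance diagnostic
#'
#' Measured rows are rounded to table precision, so the identity
#' `Q_b_in = Q_b_out + UF` holds only to about 1 ml/min. This reports the
#' signed imbalance `Q_b_in - Q_b_out - UF` per case and optionally flags
#' rows whose imbalance exceeds a tolerance.
#'
#' @param cases a `dialyzer_cases` data frame (one or more rows).
#' @param tol flag threshold, ml/min.
#' @return data frame with columns `case_id`, `imbalance` (ml/min) and
#'   `flagged`.
#' @export
mass_balance_report <- function(cases, tol = 2) {
  imb <- cases$Q_b_in - cases$Q_b_out - cases$UF
  out <- data.frame(
    case_id = as.character(cases$case_id),
    imbalance = imb,
    flagged = abs(imb) > tol,
    stringsAsFactors = FALSE
  )
  if (any(out$flagged)) {
    warning(
      "blood-side mass imbalance above ", tol, " ml/min for case(s): ",
      paste(out$case_id[out$flagged], collapse = ", ")
    )
  }
  out
}

# SI view of a one-row case: pressures in Pa, flows in m^3/s
.case_si <- function(case) {
  list(
    case_id = as.character(case$case_id),
    P_b_in = mmhg_to_pa(case$P_b_in), P_b_out = mmhg_to_pa(case$P_b_out),
    P_d_in = mmhg_to_pa(case$P_d_in), P_d_out = mmhg_to_pa(case$P_d_out),
    Q_b_in = mlmin_to_m3s(case$Q_b_in), Q_b_out = mlmin_to_m3s(case$Q_b_out),
    Q_d_in = mlmin_to_m3s(case$Q_d_in), Q_d_out = mlmin_to_m3s(case$Q_d_out),
    UF = mlmin_to_m3s(case$UF)
  )
}
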