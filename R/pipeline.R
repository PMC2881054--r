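#' Pipeline run configuration
#'
#' Collects the inputs and options of [run_pipeline()]. `config` may
#' also be given as a YAML file path (requires the `yaml` package), whose
#' entries override these defaults.
#'
#' @param case_table path to the operating-case CSV (default: the
#'   packaged bench table).
#' @param concentration_table path to the port-concentration CSV.
#' @param clearance_table path to the measured-clearance CSV, used for
#'   the reproduction report (`NULL` to skip).
#' @param output_dir directory for report files (`NULL`: no files).
#' @param reference_case case id for the diffusivity fits.
#' @param forward_cases case ids run through the full 2-D forward model.
#' @param solute solute used in the forward runs.
#' @param mesh_Nz,mesh_nr axial cell count and radial counts
#'   (lumen/membrane/shell) of the production mesh.
#' @param calibrate fit the membrane parameters (otherwise metrics only).
#' @param make_plots write diagnostic plots (PDF) to `output_dir`.
#' @param seed integer seed (reserved for stochastic stages).
#' @return a list of class `run_config`.
#' @export
run_config <- function(case_table = NULL, concentration_table = NULL,
                       clearance_table = NULL, output_dir = NULL,
                       reference_case = "23",
                       forward_cases = c("23", "32"),
                       solute = "urea",
                       mesh_Nz = 200, mesh_nr = c(24, 8, 16),
                       calibrate = TRUE, make_plots = TRUE, seed = 1L) {
  cfg <- list(
    case_table = case_table, concentration_table = concentration_table,
    clearance_table = clearance_table, output_dir = output_dir,
    reference_case = reference_case, forward_cases = forward_cases,
    solute = solute, mesh_Nz = mesh_Nz, mesh_nr = mesh_nr,
    calibrate = calibrate, make_plots = make_plots, seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package")
    }
    user <- yaml::read_yaml(config)
    cfg <- run_config()
    for (nm in names(user)) cfg[[nm]] <- user[[nm]]
    return(cfg)
  }
  if (!inherits(config, "run_config")) stop("config must be a run_config or a YAML path")
  config
}

#' Run the full characterization pipeline
#'
#' Load the bench tables, compute per-case performance metrics (TMP,
#' K_UF, mass balance), fit the UF-TMP quadratic, calibrate the membrane
#' permeability per case and the solute diffusivities to the reference
#' case, run the 2-D forward model for selected cases, and assemble a
#' reproduction table comparing computed clearances with the measured
#' ones. Reports are written with [report_render()] when an output
#' directory is configured.
#'
#' @param config a [run_config()] or a YAML file path.
#' @return object of class `dialyzer_report`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- .load_config(config)

  paths <- list(
    cases = cfg$case_table %||% system.file("extdata", "bench_cases.csv",
      package = "hfdialyzer", mustWork = TRUE
    ),
    conc = cfg$concentration_table %||% system.file("extdata",
      "bench_concentrations.csv",
      package = "hfdialyzer", mustWork = TRUE
    ),
    clear = cfg$clearance_table %||% system.file("extdata",
      "bench_clearances.csv",
      package = "hfdialyzer", mustWork = TRUE
    )
  )
  for (p in paths[c("cases", "conc")]) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }

  message("stage load: reading case and concentration tables")
  cases <- load_case_table(paths$cases)
  conc <- load_concentration_table(paths$conc)
  clear <- if (!is.null(paths$clear) && file.exists(paths$clear)) {
    utils::read.csv(paths$clear, stringsAsFactors = FALSE,
      colClasses = c(case_id = "character"))
  }

  message("stage metrics: TMP, K_UF, mass balance")
  metrics_tab <- data.frame(
    case_id = as.character(cases$case_id),
    pump_type = cases$pump_type,
    TMP = tmp(cases),
    UF = cases$UF,
    K_UF = ifelse(tmp(cases) != 0, 60 * cases$UF / tmp(cases), NA_real_),
    imbalance = suppressWarnings(mass_balance_report(cases))$imbalance,
    stringsAsFactors = FALSE
  )
  # the UF-TMP characteristic is a saline-bench property; porcine rows
  # carry osmotic backfiltration outside the protein-free Starling model
  sal <- if ("blood_type" %in% names(cases)) {
    cases[cases$blood_type == "saline", , drop = FALSE]
  } else {
    cases
  }
  uf_fit <- fit_uf_tmp(if (nrow(sal) >= 4) sal else cases)

  fit <- NULL
  forward <- NULL
  if (cfg$calibrate) {
    message("stage calibrate: per-case Lp and reference-case diffusivities")
    fit <- dialyzer_fit(cases, conc, reference_case = cfg$reference_case)
    mesh <- build_mesh(fit$geometry,
      Nz = cfg$mesh_Nz, nr_lumen = cfg$mesh_nr[1],
      nr_membrane = cfg$mesh_nr[2], nr_shell = cfg$mesh_nr[3]
    )
    message("stage forward: 2-D model for cases ",
      paste(cfg$forward_cases, collapse = ", "))
    forward <- predict(fit,
      case_ids = cfg$forward_cases, solute = cfg$solute, mesh = mesh
    )
  }

  # reproduction table: Eq.-type clearances recomputed from the measured
  # tables, next to the recorded measured/model values
  message("stage reproduce: clearances from measured tables")
  rep_rows <- list()
  for (i in seq_len(nrow(conc))) {
    id <- as.character(conc$case_id[i])
    if (!id %in% metrics_tab$case_id) next
    case <- get_case(cases, id)
    K <- clearance(case, conc[i, , drop = FALSE])
    ref <- if (!is.null(clear)) {
      clear[clear$case_id == id & clear$solute == conc$solute[i], ]
    }
    rep_rows[[length(rep_rows) + 1]] <- data.frame(
      case_id = id, solute = conc$solute[i],
      K_computed = K,
      K_measured = if (!is.null(ref) && nrow(ref)) ref$K_exp else NA_real_,
      K_model_recorded = if (!is.null(ref) && nrow(ref)) ref$K_num else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  reproduction <- do.call(rbind, rep_rows)

  report <- structure(
    list(
      config = cfg, metrics = metrics_tab, uf_tmp = uf_fit,
      fit = fit, forward = forward, reproduction = reproduction
    ),
    class = "dialyzer_report"
  )
  if (!is.null(cfg$output_dir)) report_render(report, cfg$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dialyzer_report <- function(x, ...) {
  cat("Dialyzer characterization report\n")
  cat(sprintf("  %d cases; UF-TMP quadratic R^2 = %.4f\n",
    nrow(x$metrics), x$uf_tmp$r_squared))
  if (!is.null(x$forward)) {
    cat("  forward model:\n")
    print(format(x$forward, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$reproduction)) {
    ure <- x$reproduction[x$reproduction$solute == "urea", ]
    ok <- sum(abs(ure$K_computed - ure$K_measured) <= 1, na.rm = TRUE)
    cat(sprintf(
      "  urea clearance reproduction: %d/%d cases within 1 ml/min of the measured value\n",
      ok, sum(is.finite(ure$K_measured))
    ))
  }
  invisible(x)
}

#' Write pipeline report files
#'
#' Emits the per-case metrics, calibration, forward-model and
#' reproduction tables as CSV, a plain-text summary, and (optionally)
#' diagnostic plots as PDF.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return invisible character vector of the files written.
#' @export
report_render <- function(report, dir) {
  stopifnot(inherits(report, "dialyzer_report"))
  if (is.null(report$metrics) || !nrow(report$metrics)) {
    stop("empty metrics; nothing to render")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = ",", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(report$metrics, "metrics.csv")
  if (!is.null(report$fit)) wr(report$fit$calibration, "calibration.csv")
  if (!is.null(report$forward)) wr(report$forward, "forward_model.csv")
  if (!is.null(report$reproduction)) wr(report$reproduction, "reproduction.csv")

  sp <- file.path(dir, "summary.txt")
  con <- file(sp, "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  if (!is.null(report$fit)) print(summary(report$fit))
  sink(); close(con); on.exit()
  files <- c(files, sp)

  if (isTRUE(report$config$make_plots)) {
    pp <- file.path(dir, "uf_tmp_fit.pdf")
    grDevices::pdf(pp, width = 6, height = 5)
    plot(report$uf_tmp)
    grDevices::dev.off()
    files <- c(files, pp)
    if (!is.null(report$fit)) {
      pk <- file.path(dir, "kuf_lp.pdf")
      grDevices::pdf(pk, width = 6, height = 5)
      plot(report$fit, which = "kuf_lp")
      grDevices::dev.off()
      files <- c(files, pk)
    }
  }
  invisible(files)
}
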