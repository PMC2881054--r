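#' Ground truth for synthetic bench cases
#'
#' Defines the membrane and solute parameters the synthetic generator
#' treats as physical truth, together with the operating envelope the
#' sampled cases cover. The default envelope mirrors the pulsatile-pump
#' bench cases: blood inflow 10-77 ml/min, dialysate inflow 30-42 ml/min,
#' blood outlet pressure 5-33 mmHg and dialysate outlet pressure -32 to
#' -25 mmHg, which spans trans-membrane pressures of roughly 27-64 mmHg.
#'
#' @param Lp membrane hydraulic permeability, m/s/Pa.
#' @param solutes named list of [solute_properties()] (used when
#'   concentration tables are generated).
#' @param sigma reflection coefficient.
#' @param envelope named list of length-2 ranges for `Q_b_in`, `Q_d_in`
#'   (ml/min), `P_b_out`, `P_d_out` (mmHg).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(Lp = 5e-11, solutes = default_solutes(), sigma = 0,
                         envelope = list(
                           Q_b_in = c(10, 77), Q_d_in = c(30, 42),
                           P_b_out = c(5, 33), P_d_out = c(-32, -25)
                         )) {
  stopifnot(Lp > 0, sigma >= 0, sigma <= 1)
  needed <- c("Q_b_in", "Q_d_in", "P_b_out", "P_d_out")
  stopifnot(all(needed %in% names(envelope)))
  structure(
    list(Lp = Lp, solutes = solutes, sigma = sigma, envelope = envelope),
    class = "ground_truth"
  )
}

#' Measurement-noise model for the synthetic generator
#'
#' Relative measurement errors of the bench instrumentation: about 7-10%
#' for flows, 10-15% for pressures and 5-7% for concentrations; the
#' defaults take the midpoints. Noise is multiplicative Gaussian,
#' truncated at three standard deviations. `quantize` additionally rounds
#' the emitted values to table precision (integer mmHg and ml/min, one
#' decimal for UF and concentrations), emulating how bench tables are
#' reported; it is part of the measurement corruption and can be disabled
#' to study the noise-free limit.
#'
#' @param flow,pressure,concentration relative error fractions in
#'   `[0, 0.5]`.
#' @param quantize round emitted values to table precision.
#' @param seed integer seed driving all sampling in the generator.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(flow = 0.085, pressure = 0.125,
                        concentration = 0.06, quantize = TRUE, seed = 1L) {
  for (f in c(flow, pressure, concentration)) {
    if (f < 0 || f > 0.5) stop("noise fractions must lie in [0, 0.5]")
  }
  structure(
    list(
      flow = flow, pressure = pressure, concentration = concentration,
      quantize = quantize, seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

# run expr with a local RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# multiplicative Gaussian relative noise, truncated at +-3 sd
.perturb <- function(x, frac) {
  if (frac == 0) return(x)
  eps <- stats::rnorm(length(x))
  eps <- pmin(pmax(eps, -3), 3)
  x * (1 + frac * eps)
}

#' Generate one synthetic bench case from ground truth
#'
#' Runs the forward flow model (and, when solute properties are
#' requested, the 2-D solute solver) at a given operating point with the
#' ground-truth parameters, then corrupts every measured quantity with
#' independent multiplicative noise and optional table-precision
#' rounding. The exact (noise-free) forward results are retained
#' alongside the emitted measurements.
#'
#' @param truth a [ground_truth()] object.
#' @param operating_point list with `Q_b_in`, `Q_d_in` (ml/min),
#'   `P_b_out`, `P_d_out` (mmHg); must lie within the truth envelope.
#' @param noise a [noise_model()]; its seed is used unless `seed` is
#'   given.
#' @param case_id identifier for the emitted row.
#' @param geometry,fluid device description.
#' @param solutes `FALSE` for flow-only cases, `TRUE` to simulate the
#'   truth's solutes and emit port concentrations, or a named list of
#'   [solute_properties()].
#' @param inlet_concentrations named vector of blood-inlet concentrations
#'   (mg/dL) per solute when solutes are simulated.
#' @param mesh mesh for the solute forward solve.
#' @param seed overrides `noise$seed`.
#' @return list with `case` (one-row `dialyzer_cases`), `concentrations`
#'   (or `NULL`) and `truth_case` (the exact forward results).
#' @export
generate_case <- function(truth, operating_point, noise = noise_model(),
                          case_id = "S1",
                          geometry = m60_geometry(),
                          fluid = saline_properties(),
                          solutes = FALSE,
                          inlet_concentrations = c(urea = 118, creatinine = 4.5),
                          mesh = NULL, seed = NULL) {
  op <- operating_point
  for (nm in c("Q_b_in", "Q_d_in", "P_b_out", "P_d_out")) {
    rng <- truth$envelope[[nm]]
    if (op[[nm]] < rng[1] - 1e-9 || op[[nm]] > rng[2] + 1e-9) {
      stop("operating point ", nm, " = ", op[[nm]], " outside the envelope [",
        rng[1], ", ", rng[2], "]")
    }
  }
  membrane <- membrane_properties(Lp = truth$Lp, sigma = truth$sigma)
  bc <- flow_bc(op$Q_b_in, op$Q_d_in, op$P_b_out, op$P_d_out)
  rf <- solve_flow_reduced(geometry, fluid, membrane, bc)

  sol_list <- NULL
  if (isTRUE(solutes)) sol_list <- truth$solutes
  if (is.list(solutes)) sol_list <- solutes
  conc_true <- NULL
  if (!is.null(sol_list)) {
    if (is.null(mesh)) {
      mesh <- build_mesh(geometry, Nz = 80, nr_lumen = 12, nr_membrane = 6,
        nr_shell = 10)
    }
    flow2 <- solve_flow(mesh, fluid, membrane, bc)
    conc_true <- do.call(rbind, lapply(names(sol_list), function(nm) {
      cin <- inlet_concentrations[[nm]]
      cf <- solve_solute(flow2, sol_list[[nm]], membrane, solute_bc(cin, 0))
      data.frame(
        case_id = case_id, solute = nm, C_b_in = cin,
        C_b_out = cf$C_b_out, C_d_in = 0, C_d_out = cf$C_d_out,
        stringsAsFactors = FALSE
      )
    }))
  }

  truth_case <- data.frame(
    case_id = case_id, pump_type = "WAK", afterload = TRUE,
    P_b_in = rf$ports$P_b_in, P_b_out = rf$ports$P_b_out,
    P_d_in = rf$ports$P_d_in, P_d_out = rf$ports$P_d_out,
    Q_b_in = rf$ports$Q_b_in, Q_b_out = rf$ports$Q_b_out,
    Q_d_in = rf$ports$Q_d_in, Q_d_out = rf$ports$Q_d_out,
    UF = rf$UF, blood_type = "saline", stringsAsFactors = FALSE
  )

  emit <- .with_seed(if (is.null(seed)) noise$seed else seed, {
    meas <- truth_case
    for (col in c("P_b_in", "P_b_out", "P_d_in", "P_d_out")) {
      meas[[col]] <- .perturb(meas[[col]], noise$pressure)
    }
    for (col in c("Q_b_in", "Q_b_out", "Q_d_in", "Q_d_out", "UF")) {
      meas[[col]] <- .perturb(meas[[col]], noise$flow)
    }
    conc <- conc_true
    if (!is.null(conc)) {
      for (col in c("C_b_out", "C_d_out")) {
        conc[[col]] <- .perturb(conc[[col]], noise$concentration)
      }
    }
    if (noise$quantize) {
      for (col in c("P_b_in", "P_b_out", "P_d_in", "P_d_out",
        "Q_b_in", "Q_b_out", "Q_d_in", "Q_d_out")) {
        meas[[col]] <- round(meas[[col]])
      }
      meas$UF <- round(meas$UF, 1)
      if (!is.null(conc)) {
        for (col in c("C_b_in", "C_b_out", "C_d_in", "C_d_out")) {
          conc[[col]] <- round(conc[[col]], 1)
        }
      }
    }
    list(meas = meas, conc = conc)
  })

  case <- emit$meas
  class(case) <- c("dialyzer_cases", "data.frame")
  if (!is.null(emit$conc)) {
    class(emit$conc) <- c("dialyzer_concentrations", "data.frame")
  }
  list(case = case, concentrations = emit$conc, truth_case = truth_case)
}

#' Generate a synthetic bench table
#'
#' Samples operating points uniformly over the truth envelope and builds
#' a case table (plus, optionally, a concentration table) in exactly the
#' dialect [load_case_table()] reads, together with a ground-truth
#' sidecar. When `dir` is given the three tables are written there as
#' CSV files.
#'
#' @inheritParams generate_case
#' @param n_cases number of cases to generate.
#' @param dir optional output directory.
#' @return list with `cases`, `concentrations` (or `NULL`),
#'   `truth_cases` (exact forward results per case), `truth_parameters`
#'   (data frame of the ground-truth parameters), and `paths` when files
#'   were written.
#' @export
generate_table <- function(truth, n_cases, noise = noise_model(),
                           geometry = m60_geometry(),
                           fluid = saline_properties(),
                           solutes = FALSE,
                           inlet_concentrations = c(urea = 118, creatinine = 4.5),
                           mesh = NULL, dir = NULL) {
  stopifnot(n_cases >= 1)
  env <- truth$envelope
  draws <- .with_seed(noise$seed, {
    data.frame(
      Q_b_in = stats::runif(n_cases, env$Q_b_in[1], env$Q_b_in[2]),
      Q_d_in = stats::runif(n_cases, env$Q_d_in[1], env$Q_d_in[2]),
      P_b_out = stats::runif(n_cases, env$P_b_out[1], env$P_b_out[2]),
      P_d_out = stats::runif(n_cases, env$P_d_out[1], env$P_d_out[2]),
      sub_seed = sample.int(2^30, n_cases)
    )
  })
  out_cases <- vector("list", n_cases)
  out_conc <- vector("list", n_cases)
  out_truth <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    g <- generate_case(
      truth,
      list(
        Q_b_in = draws$Q_b_in[i], Q_d_in = draws$Q_d_in[i],
        P_b_out = draws$P_b_out[i], P_d_out = draws$P_d_out[i]
      ),
      noise = noise, case_id = sprintf("S%02d", i),
      geometry = geometry, fluid = fluid, solutes = solutes,
      inlet_concentrations = inlet_concentrations, mesh = mesh,
      seed = draws$sub_seed[i]
    )
    out_cases[[i]] <- g$case
    out_conc[[i]] <- g$concentrations
    out_truth[[i]] <- g$truth_case
  }
  cases <- do.call(rbind, out_cases)
  class(cases) <- c("dialyzer_cases", "data.frame")
  conc <- if (!is.null(out_conc[[1]])) {
    x <- do.call(rbind, out_conc)
    class(x) <- c("dialyzer_concentrations", "data.frame")
    x
  }
  truth_cases <- do.call(rbind, out_truth)

  truth_parameters <- data.frame(
    parameter = c(
      "Lp", "sigma",
      unlist(lapply(names(truth$solutes), function(nm) {
        paste0(nm, c("_D_free", "_D_membrane"))
      }))
    ),
    value = c(
      truth$Lp, truth$sigma,
      unlist(lapply(truth$solutes, function(s) c(s$D_free, s$D_membrane)))
    ),
    stringsAsFactors = FALSE
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      cases = file.path(dir, "synthetic_cases.csv"),
      concentrations = file.path(dir, "synthetic_concentrations.csv"),
      truth = file.path(dir, "synthetic_truth.csv")
    )
    write_case_table(cases, paths$cases)
    if (!is.null(conc)) {
      utils::write.table(conc, paths$concentrations,
        sep = ",", quote = FALSE, row.names = FALSE
      )
    } else {
      paths$concentrations <- NULL
    }
    tp <- truth_parameters
    tp$value <- sprintf("%.17g", tp$value)
    utils::write.table(tp, paths$truth, sep = ",", quote = FALSE, row.names = FALSE)
  }

  list(
    cases = cases, concentrations = conc, truth_cases = truth_cases,
    truth_parameters = truth_parameters, paths = paths
  )
}
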