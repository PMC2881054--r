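#' Fit the dialyzer transport model to bench data
#'
#' The central estimation interface of the package. Given a table of
#' operating cases (and optionally measured port concentrations), it
#' calibrates the membrane hydraulic permeability \eqn{L_p} case by case
#' against the measured ultrafiltration, fits solute diffusivities to the
#' port concentrations of a reference case, and returns a fitted-model
#' object with the usual accessor methods (`print`, `summary`, `coef`,
#' `predict`, `residuals`, `plot`, `simulate`).
#'
#' Cases whose measured UF opposes the model trans-membrane pressure
#' admit no Starling-consistent permeability (osmotic effects of real
#' blood, which the protein-free model excludes, are the plausible
#' cause); they are reported with `status = "infeasible"` and excluded
#' from the coefficient table.
#'
#' @param cases a `dialyzer_cases` data frame (see [load_case_table()]).
#' @param concentrations optional `dialyzer_concentrations` data frame.
#' @param geometry,fluid device description.
#' @param reference_case case id used for the diffusivity fits.
#' @param tol UF tolerance of the permeability calibration, ml/min.
#' @param engine calibration engine passed to [calibrate_lp()].
#' @param fit_mesh mesh used inside the diffusivity fits.
#' @param solutes character vector of solute names to fit (default: all
#'   present for the reference case).
#' @return object of class `dialyzer_fit`.
#' @examples
#' \donttest{
#' fit <- dialyzer_fit(bench_cases(), bench_concentrations())
#' summary(fit)
#' coef(fit)
#' }
#' @export
dialyzer_fit <- function(cases, concentrations = NULL,
                         geometry = m60_geometry(),
                         fluid = saline_properties(),
                         reference_case = "23",
                         tol = 0.05,
                         engine = c("reduced", "full"),
                         fit_mesh = NULL,
                         solutes = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(cases, "data.frame"), nrow(cases) >= 1)

  ids <- as.character(cases$case_id)
  n <- nrow(cases)
  cal_tab <- data.frame(
    case_id = ids,
    TMP = tmp(cases),
    K_UF = NA_real_,
    UF = cases$UF,
    Lp = NA_real_,
    K_UF_model = NA_real_,
    residual = NA_real_,
    iterations = NA_integer_,
    status = "ok",
    stringsAsFactors = FALSE
  )
  cal_tab$K_UF <- ifelse(cal_tab$TMP != 0, 60 * cases$UF / cal_tab$TMP, NA_real_)

  for (i in seq_len(n)) {
    res <- tryCatch(
      calibrate_lp(cases[i, , drop = FALSE],
        geometry = geometry, fluid = fluid, tol = tol, engine = engine
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      cal_tab$status[i] <- "infeasible"
    } else {
      cal_tab$Lp[i] <- res$estimate
      cal_tab$K_UF_model[i] <- res$K_UF
      cal_tab$residual[i] <- res$residual
      cal_tab$iterations[i] <- res$iterations
    }
  }

  diff_fits <- list()
  if (!is.null(concentrations)) {
    ref <- as.character(reference_case)
    if (!ref %in% ids) stop("reference case '", ref, "' not in the case table")
    lp_ref <- cal_tab$Lp[match(ref, ids)]
    if (!is.finite(lp_ref)) stop("reference case did not calibrate; cannot fit diffusivities")
    if (is.null(solutes)) {
      solutes <- unique(concentrations$solute[
        as.character(concentrations$case_id) == ref
      ])
    }
    if (is.null(fit_mesh)) {
      fit_mesh <- build_mesh(geometry,
        Nz = 100, nr_lumen = 16,
        nr_membrane = 6, nr_shell = 12
      )
    }
    for (s in solutes) {
      diff_fits[[s]] <- calibrate_diffusivities(
        get_case(cases, ref),
        get_concentrations(concentrations, ref, s),
        Lp = lp_ref, solute_name = s,
        geometry = geometry, fluid = fluid, mesh = fit_mesh
      )
    }
  }

  structure(
    list(
      cases = cases, concentrations = concentrations,
      calibration = cal_tab, diffusivity_fits = diff_fits,
      geometry = geometry, fluid = fluid,
      reference_case = as.character(reference_case),
      uf_tmp = {
        sal <- if ("blood_type" %in% names(cases)) {
          cases[cases$blood_type == "saline", , drop = FALSE]
        } else {
          cases
        }
        if (nrow(sal) < 4) sal <- cases
        if (length(unique(tmp(sal))) >= 4) fit_uf_tmp(sal) else NULL
      },
      engine = engine, tol = tol
    ),
    class = "dialyzer_fit"
  )
}

#' @export
print.dialyzer_fit <- function(x, ...) {
  ok <- sum(x$calibration$status == "ok")
  cat("Hollow-fiber dialyzer model fit\n")
  cat(sprintf(
    "  %d operating cases, %d with calibrated Lp (%d infeasible)\n",
    nrow(x$calibration), ok, nrow(x$calibration) - ok
  ))
  if (length(x$diffusivity_fits)) {
    for (s in names(x$diffusivity_fits)) {
      f <- x$diffusivity_fits[[s]]
      cat(sprintf(
        "  %s: D_free %.3g, D_membrane %.3g m^2/s (reference case %s)\n",
        s, f$solute$D_free, f$solute$D_membrane, x$reference_case
      ))
    }
  }
  if (!is.null(x$uf_tmp)) {
    cat(sprintf("  UF-TMP quadratic: R^2 = %.4f\n", x$uf_tmp$r_squared))
  }
  invisible(x)
}

#' @export
summary.dialyzer_fit <- function(object, ...) {
  out <- list(
    calibration = object$calibration,
    diffusivities = if (length(object$diffusivity_fits)) {
      do.call(rbind, lapply(names(object$diffusivity_fits), function(s) {
        f <- object$diffusivity_fits[[s]]
        data.frame(
          solute = s, D_free = f$solute$D_free,
          D_membrane = f$solute$D_membrane,
          objective = f$objective,
          C_b_out_model = unname(f$model_outlets[1]),
          C_b_out_measured = unname(f$target_outlets[1]),
          C_d_out_model = unname(f$model_outlets[2]),
          C_d_out_measured = unname(f$target_outlets[2]),
          stringsAsFactors = FALSE
        )
      }))
    },
    uf_tmp = object$uf_tmp
  )
  class(out) <- "summary.dialyzer_fit"
  out
}

#' @export
print.summary.dialyzer_fit <- function(x, ...) {
  cat("Per-case calibration:\n")
  print(format(x$calibration, digits = 4), row.names = FALSE)
  if (!is.null(x$diffusivities)) {
    cat("\nDiffusivity fits:\n")
    print(format(x$diffusivities, digits = 4), row.names = FALSE)
  }
  if (!is.null(x$uf_tmp)) {
    cat("\nUF-TMP quadratic fit: ")
    print(x$uf_tmp)
  }
  invisible(x)
}

#' @export
coef.dialyzer_fit <- function(object, ...) {
  lp <- object$calibration$Lp
  names(lp) <- paste0("Lp.", object$calibration$case_id)
  dv <- unlist(lapply(object$diffusivity_fits, function(f) {
    c(f$solute$D_free, f$solute$D_membrane)
  }))
  if (length(object$diffusivity_fits)) {
    names(dv) <- unlist(lapply(names(object$diffusivity_fits), function(s) {
      paste0(s, c(".D_free", ".D_membrane"))
    }))
  }
  c(lp[is.finite(lp)], dv)
}

#' @export
residuals.dialyzer_fit <- function(object, ...) {
  r <- object$calibration$residual
  names(r) <- object$calibration$case_id
  r
}

#' Forward predictions from a fitted dialyzer model
#'
#' Runs the 2-D forward model for the requested cases with their
#' calibrated permeabilities and the fitted solute diffusivities, and
#' reports UF, model TMP, mixing-cup outlet concentrations, generalized
#' clearance and the convective transfer fraction.
#'
#' @param object a [dialyzer_fit()] object.
#' @param case_ids cases to predict (default: the reference case).
#' @param solute solute name (must have a diffusivity fit; when none
#'   exist, concentration outputs are omitted).
#' @param mesh production mesh (default [build_mesh()] at the standard
#'   resolution).
#' @param surface decomposition surface, see [flux_decomposition()].
#' @param ... unused.
#' @return data frame with one row per case.
#' @export
predict.dialyzer_fit <- function(object, case_ids = object$reference_case,
                                 solute = names(object$diffusivity_fits)[1],
                                 mesh = NULL, surface = "blood", ...) {
  if (is.null(mesh)) mesh <- build_mesh(object$geometry)
  cal <- object$calibration
  out <- vector("list", length(case_ids))
  for (k in seq_along(case_ids)) {
    id <- as.character(case_ids[k])
    i <- match(id, cal$case_id)
    if (is.na(i)) stop("case '", id, "' not in the fit")
    if (!is.finite(cal$Lp[i])) stop("case '", id, "' has no calibrated Lp")
    membrane <- membrane_properties(Lp = cal$Lp[i])
    case <- get_case(object$cases, id)
    flow <- solve_flow(mesh, object$fluid, membrane, case_flow_bc(case))
    row <- data.frame(
      case_id = id, UF = flow$UF,
      TMP_model = (flow$ports$P_b_in + flow$ports$P_b_out) / 2 -
        (flow$ports$P_d_in + flow$ports$P_d_out) / 2,
      stringsAsFactors = FALSE
    )
    if (!is.null(solute) && length(object$diffusivity_fits) &&
      solute %in% names(object$diffusivity_fits)) {
      sp <- object$diffusivity_fits[[solute]]$solute
      cc <- get_concentrations(object$concentrations, id, solute)
      cf <- solve_solute(flow, sp, membrane, solute_bc(cc$C_b_in, cc$C_d_in))
      dec <- flux_decomposition(cf, surface = surface)
      row$solute <- solute
      row$C_b_out <- cf$C_b_out
      row$C_d_out <- cf$C_d_out
      row$clearance <- (case$Q_b_in * cc$C_b_in -
        flow$ports$Q_b_out * cf$C_b_out) / cc$C_b_in
      row$convective_fraction <- dec$convective_fraction
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' @export
plot.dialyzer_fit <- function(x, which = c("uf_tmp", "kuf_lp"), ...) {
  which <- match.arg(which)
  if (which == "uf_tmp") {
    if (is.null(x$uf_tmp)) stop("no UF-TMP fit available")
    plot(x$uf_tmp, ...)
  } else {
    cal <- x$calibration[x$calibration$status == "ok", ]
    graphics::plot(cal$K_UF, cal$Lp,
      xlab = "K_UF (ml/hr/mmHg)", ylab = "calibrated Lp (m/s/Pa)",
      main = "Hydraulic permeability vs ultrafiltration coefficient", ...
    )
    kk <- seq(0, max(cal$K_UF, na.rm = TRUE) * 1.05, length.out = 100)
    graphics::lines(kk, lp_from_kuf(kk, x$geometry$A), col = "red3", lwd = 2)
    graphics::legend("topleft",
      legend = c("calibrated cases", "Starling device law Lp = K_UF/A"),
      pch = c(1, NA), lty = c(NA, 1), col = c("black", "red3"), cex = 0.8
    )
  }
  invisible(x)
}

#' Simulate synthetic bench tables from a fitted model
#'
#' Uses the fitted permeability (median over the calibrated cases, or a
#' chosen case) and the fitted diffusivities as ground truth for the
#' synthetic-case generator.
#'
#' @param object a [dialyzer_fit()] object.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param n_cases cases per table.
#' @param noise a [noise_model()].
#' @param ... passed to [generate_table()].
#' @return a [generate_table()] result (or a list of them when
#'   `nsim > 1`).
#' @export
simulate.dialyzer_fit <- function(object, nsim = 1, seed = 1L,
                                  n_cases = 10, noise = NULL, ...) {
  lp <- stats::median(object$calibration$Lp, na.rm = TRUE)
  sol <- lapply(object$diffusivity_fits, function(f) f$solute)
  if (!length(sol)) sol <- default_solutes()
  truth <- ground_truth(Lp = lp, solutes = sol)
  out <- lapply(seq_len(nsim), function(k) {
    generate_table(
      truth, n_cases,
      noise = if (is.null(noise)) noise_model(seed = seed + k - 1) else noise,
      geometry = object$geometry, fluid = object$fluid, ...
    )
  })
  if (nsim == 1) out[[1]] else out
}
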