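.report_num <- function(x) {
  # 12 significant digits keeps JSON reports byte-identical across runs of
  # the same seed while preserving full practical precision
  rapply(x, function(v) if (is.numeric(v)) signif(v, 12) else v, how = "replace")
}

#' Run one analysis stage end to end
#'
#' Thin driver binding the pipeline stages together: it reads the stage's
#' inputs, runs the corresponding package functions, and writes a
#' machine-readable JSON report plus a manifest (configuration, seed,
#' package version) into the output directory.  Stages:
#'
#' * `"fit-ensemble"`: ensemble titration CSV -> quenching curve ->
#'   Stern-Volmer and two-state fits ([compare_models]).
#' * `"fit-bh"`: absorbance titration CSV -> [bh_fit].
#' * `"analyze-traces"`: one or more trace CSVs -> [analyze_traces].
#' * `"forster"`: donor emission + acceptor extinction CSVs ->
#'   [overlap_integral] + [forster_radius].
#' * `"simulate-ensemble"`: generate a titration CSV with
#'   [gen_ensemble_titration].
#'
#' @param config Named list.  Common fields: `stage` (above), `out_dir`
#'   (created if absent), `seed` (integer, default 1), `units` (`"uM"` or
#'   `"M"`, default `"uM"`).  Stage fields: `input` (path or vector of
#'   paths), `model` (`"approx"` or `"precise"`), `L0_uM`, `d_cm`, `A0`,
#'   `logK`, `f`, `noise_frac`, `kappa2`, `n_medium`, `phi_d`, `nbins`.
#' @return The report (named list), invisibly; `report.json` and
#'   `manifest.json` are written to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$stage)) stop("config$stage is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  units <- config$units %||% "uM"
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- config$stage

  report <- tryCatch(switch(
    stage,
    "fit-ensemble" = {
      series <- read_titration_csv(config$input, units = units)
      curve <- build_quench_curve(series)
      use_precise <- identical(config$model, "precise")
      L0 <- if (!is.null(config$L0_uM)) config$L0_uM * 1e-6 else NULL
      cmp <- compare_models(curve, use_precise = use_precise, L0 = L0)
      ts <- cmp$fits[[which(names(cmp$fits) == "two_state")]]
      sv <- cmp$fits[[which(names(cmp$fits) == "stern_volmer")]]
      if (!ts$converged) stop("two-state fit did not converge")
      list(stage = stage,
           two_state = list(logK = ts$logK, f = ts$f, se_logK = ts$se_logK,
                            se_f = ts$se_f, chi2_red = ts$chi2_red,
                            model_tag = ts$model_tag),
           stern_volmer = list(ksv = sv$ksv, se_ksv = sv$se_ksv,
                               chi2_red = sv$chi2_red),
           best_model = cmp$ranking[1], n_points = ts$n_points)
    },
    "fit-bh" = {
      titr <- read_absorbance_csv(config$input, L0 = config$L0_uM * 1e-6,
                                  d = config$d_cm, A0 = config$A0,
                                  units = units)
      fit <- bh_fit(titr, min_delta_A = config$min_delta_A %||% 0)
      if (!fit$ok) stop("BH fit flagged: non-physical intercept")
      list(stage = stage, logK = fit$logK, se_logK = fit$se_logK, K = fit$K,
           r2 = fit$r2, curvature = fit$curvature, n_points = fit$n)
    },
    "analyze-traces" = {
      traces <- lapply(config$input, read_trace_csv)
      res <- analyze_traces(traces, nbins = config$nbins %||% "auto")
      list(stage = stage, f_mean = res$aggregate$f_mean,
           f_sd = res$aggregate$f_sd, n_traces = res$aggregate$n_traces,
           n_excluded = res$aggregate$n_excluded,
           per_trace = as.numeric(res$per_trace))
    },
    "forster" = {
      em <- read_spectrum_csv(config$input[1], kind = "emission")
      ex <- read_spectrum_csv(config$input[2], kind = "extinction")
      J <- overlap_integral(em, ex)
      fr <- forster_radius(J, kappa2 = config$kappa2 %||% 2/3,
                           n = config$n_medium %||% 1.33,
                           phi_d = config$phi_d %||% 0.1)
      list(stage = stage, J = fr$J, R0_nm = fr$R0, params = fr$params)
    },
    "simulate-ensemble" = {
      params <- two_state_params(logK = config$logK, f = config$f)
      series <- gen_ensemble_titration(params,
                                       noise_frac = config$noise_frac %||% 0.02,
                                       seed = seed)
      out_csv <- file.path(config$out_dir, "titration.csv")
      write_titration_csv(series, out_csv, units = units)
      list(stage = stage, output = out_csv, logK = config$logK, f = config$f,
           n_series = length(series))
    },
    stop("unknown stage: ", stage)
  ), error = function(e) stop("stage '", stage, "': ", conditionMessage(e),
                              call. = FALSE))

  jsonlite::write_json(.report_num(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "quenchfit",
    version = as.character(utils::packageVersion("quenchfit")),
    schema = 1L, seed = seed,
    config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(.report_num(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
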