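# CSV readers/writers, run configuration, and the command-line front-end.
# All files are UTF-8, LF, '.' decimal; times are hours from surgery onset.

#' Write / read a clinical series set as CSV
#'
#' Schema: `branch, observable, time_h, median, mae`. The writer emits
#' one row per point in deterministic order (branch, observable, time);
#' the reader validates the schema and every row, reporting offending
#' line numbers.
#'
#' @param series_set List of [clinical_series()].
#' @param path File path.
#' @return `write_clinical_series` returns `path` invisibly;
#'   `read_clinical_series` returns a named list of [clinical_series()].
#' @export
write_clinical_series <- function(series_set, path) {
  rows <- do.call(rbind, lapply(series_set, function(s) {
    data.frame(branch = s$branch, observable = s$observable,
               time_h = s$time_h, median = s$median, mae = s$mae)
  }))
  rows <- rows[order(rows$branch, rows$observable, rows$time_h), ]
  rows$time_h <- sprintf("%.10g", rows$time_h)
  rows$median <- sprintf("%.10g", rows$median)
  rows$mae <- sprintf("%.10g", rows$mae)
  utils::write.table(rows, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_clinical_series
#' @export
read_clinical_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("branch", "observable", "time_h", "median", "mae")
  if (!identical(names(df), need)) {
    stop("header must be exactly: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty series file: ", path, call. = FALSE)
  line <- seq_len(nrow(df)) + 1  # header is line 1
  bad <- !df$branch %in% c("placebo", "bIAP")
  if (any(bad)) {
    stop("unknown branch at line(s) ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$observable %in% c("AP", "IL6", "IL10")
  if (any(bad)) {
    stop("unknown observable at line(s) ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(df$time_h) | df$time_h < 0
  if (any(bad)) {
    stop("invalid time at line(s) ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(df$median) | df$median < 0
  if (any(bad)) {
    stop("negative or missing median at line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(df$mae) | df$mae <= 0
  if (any(bad)) {
    stop("mae must be > 0 at line(s) ", paste(line[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (br in unique(df$branch)) {
    for (ob in unique(df$observable[df$branch == br])) {
      sub <- df[df$branch == br & df$observable == ob, ]
      if (any(diff(sub$time_h) <= 0)) {
        stop("times not strictly increasing for ", br, "/", ob,
             call. = FALSE)
      }
      out[[paste(br, ob, sep = "_")]] <-
        clinical_series(br, ob, sub$time_h, sub$median, sub$mae)
    }
  }
  out
}

#' Write / read a trajectory as long-format CSV
#'
#' Schema: `time_h, variable, value_internal, value_clinical`, floats at
#' 10 significant digits, rows ordered by variable then time. The
#' clinical column carries IU/L for blood AP pools and pg/mL for
#' cytokines; other variables have no clinical unit (empty field).
#'
#' @param trajectory A `trajectory` from [integrate_model()].
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the long data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  uc <- unit_constants()
  clin_factor <- function(vn) {
    if (vn %in% c("ap_endo_blood", "ap_supp_blood", "itm_ap_blood",
                  "ap_endo_tissue", "ap_supp_tissue")) {
      1 / uc$ap_iu_per_l_to_molec_mm3
    } else if (vn %in% c("ch", "ach")) {
      1 / uc$cytokine_pg_ml_to_molec_mm3
    } else {
      NA_real_
    }
  }
  rows <- do.call(rbind, lapply(colnames(trajectory$states), function(vn) {
    val <- trajectory$states[, vn]
    fac <- clin_factor(vn)
    data.frame(time_h = sprintf("%.10g", trajectory$times),
               variable = vn,
               value_internal = sprintf("%.10g", val),
               value_clinical = ifelse(rep(is.na(fac), length(val)), "",
                                       sprintf("%.10g", val * fac)))
  }))
  utils::write.table(rows, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "character", "numeric",
                                       "numeric"))
  need <- c("time_h", "variable", "value_internal", "value_clinical")
  if (!identical(names(df), need)) {
    stop("header must be exactly: ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df
}

# Documented defaults of the run configuration.
.config_defaults <- function() {
  list(
    parameters_file = NULL,
    protocol = list(bolus_iu = 1000, infusion_total_iu = 8000,
                    infusion_duration_h = 8, scale = 1),
    horizon_h = 36,
    seed = 42,
    free = c("r_induce_peak", "r_induce", "t_ap_delay"),
    n_global = 150,
    n_local = 100,
    noise_fraction = 0.25,
    insult_multiple = 1,
    insult_center_h = 6,
    insult_width_h = 1,
    scales = c(1, 2, 3),
    sensitivity_vary = c("r_induce_peak", "t_liver_recovery",
                         "k_aps_deg_blood", "k_bind"),
    n_samples = 64)
}

#' Load and validate a run configuration
#'
#' YAML configuration with documented defaults; unknown keys are
#' rejected (all offenders listed), and the effective configuration is
#' echoed to the log.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the configuration echo.
#' @return Named list of effective settings.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      proto <- user$protocol
      if (!is.null(proto)) {
        bad <- setdiff(names(proto), names(cfg$protocol))
        if (length(bad)) {
          stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
               call. = FALSE)
        }
        cfg$protocol[names(proto)] <- proto
        user$protocol <- NULL
      }
      cfg[names(user)] <- user
    }
  }
  if (!quiet) {
    message("effective configuration:")
    message(paste(" ", utils::capture.output(utils::str(cfg, give.attr = FALSE)),
                  collapse = "\n"))
  }
  cfg
}

.cfg_protocol <- function(cfg) {
  do.call(treatment_protocol, cfg$protocol)
}

.cfg_params <- function(cfg) {
  if (is.null(cfg$parameters_file)) model_parameters()
  else read_parameters(cfg$parameters_file)
}

.cli_usage <- function() {
  paste(
    "usage: apsirs <command> [--config FILE] [--seed N] [--out DIR] [options]",
    "commands:",
    "  simulate    [--horizon H] [--placebo]   write a trajectory CSV",
    "  synth                                   generate pseudo-clinical series",
    "  calibrate   [--data FILE]               fit free parameters to series",
    "  experiment  {branch|ablation|excess-itm|dose-scaling}",
    "  sensitivity                             Sobol global sensitivity",
    sep = "\n")
}

# Minimal long-option parser: --key value or --flag.
.cli_opts <- function(args) {
  opts <- list(positional = character())
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[[i + 1]], "--")) {
        opts[[key]] <- args[[i + 1]]
        i <- i + 2
      } else {
        opts[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1
    }
  }
  opts
}

.write_manifest <- function(cfg, seed, out_dir) {
  manifest <- list(
    package = "apsirs",
    version = as.character(utils::packageVersion("apsirs")),
    seed = seed,
    config = cfg[!vapply(cfg, is.null, logical(1))],
    config_hash = config_hash(cfg[!vapply(cfg, is.null, logical(1))]))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `synth`, `calibrate`,
#' `experiment {branch|ablation|excess-itm|dose-scaling}` and
#' `sensitivity`, each accepting `--config`, `--seed` and `--out`.
#' Outputs (trajectory/series CSVs, JSON assertion reports, fitted
#' parameter files) and a run manifest are written under `--out`
#' (default `.`). Returns the exit code (0 on success) rather than
#' calling `quit()`, so it can be driven in-process; the shipped
#' `inst/cli/apsirs` script forwards `commandArgs()` and exits with the
#' returned code.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(args)) {
      message(.cli_usage())
      return(invisible(2L))
    }
    cmd <- args[[1]]
    opts <- .cli_opts(args[-1])
    cfg <- load_config(opts$config, quiet = FALSE)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    out_dir <- if (is.null(opts$out)) "." else opts$out
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    params <- .cfg_params(cfg)
    protocol <- .cfg_protocol(cfg)
    horizon <- if (is.null(opts$horizon)) cfg$horizon_h
               else as.numeric(opts$horizon)

    scfg <- synth_config(params = params,
                         protocols = list(placebo = placebo_protocol(),
                                          bIAP = protocol),
                         noise_fraction = cfg$noise_fraction,
                         seed = cfg$seed,
                         insult_multiple = cfg$insult_multiple,
                         insult_center_h = cfg$insult_center_h,
                         insult_width_h = cfg$insult_width_h)

    switch(cmd,
      simulate = {
        proto <- if (isTRUE(opts$placebo)) placebo_protocol() else protocol
        tr <- integrate_model(params, proto, horizon = horizon)
        write_trajectory(tr, file.path(out_dir, "trajectory.csv"))
        message("wrote ", file.path(out_dir, "trajectory.csv"))
      },
      synth = {
        series <- generate_clinical_series(scfg)
        write_clinical_series(series,
                              file.path(out_dir, "clinical_series.csv"))
        message("wrote ", file.path(out_dir, "clinical_series.csv"))
      },
      calibrate = {
        data_path <- if (is.null(opts$data)) {
          file.path(out_dir, "clinical_series.csv")
        } else {
          opts$data
        }
        series <- read_clinical_series(data_path)
        bIAP <- series[grep("^bIAP_", names(series))]
        fit <- fit_parameters(params, bIAP, protocol, free = cfg$free,
                              seed = cfg$seed, n_global = cfg$n_global,
                              n_local = cfg$n_local)
        write_parameters(fit$params,
                         file.path(out_dir, "fitted_parameters.tsv"))
        jsonlite::write_json(
          list(loss = fit$loss, residuals = as.list(fit$residuals),
               free = fit$free,
               estimates = as.list(fit$params$values[fit$free]),
               seed = fit$seed),
          file.path(out_dir, "fit_report.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        message("fit loss: ", signif(fit$loss, 6))
      },
      experiment = {
        sub <- opts$positional[1]
        if (is.na(sub) || is.null(sub)) {
          stop("experiment requires a subcommand: ",
               "branch|ablation|excess-itm|dose-scaling", call. = FALSE)
        }
        insult <- generate_secondary_insult(scfg)
        rep <- switch(sub,
          branch = {
            r <- run_branch_comparison(params,
                                       list(placebo = placebo_protocol(),
                                            bIAP = protocol))
            write_trajectory(r$placebo,
                             file.path(out_dir, "branch_placebo.csv"))
            write_trajectory(r$bIAP, file.path(out_dir, "branch_bIAP.csv"))
            list(experiment = "branch_comparison",
                 orderings = r$orderings, config_hash = r$config_hash)
          },
          ablation = {
            data_path <- if (is.null(opts$data)) {
              file.path(out_dir, "clinical_series.csv")
            } else {
              opts$data
            }
            series <- read_clinical_series(data_path)
            r <- run_ablation_study(series,
                                    list(placebo = placebo_protocol(),
                                         bIAP = protocol),
                                    params, seed = cfg$seed,
                                    n_global = cfg$n_global,
                                    n_local = cfg$n_local)
            list(experiment = "induction_ablation",
                 full_bIAP_ap_residual = r$full_bIAP_ap_residual,
                 ablated_bIAP_ap_residual = r$ablated_bIAP_ap_residual,
                 ablated_over_full = r$ablated_over_full,
                 config_hash = r$config_hash)
          },
          `excess-itm` = {
            r <- run_excess_itm_experiment(params,
                                           list(placebo = placebo_protocol(),
                                                bIAP = protocol), insult)
            list(experiment = "excess_itm", orderings = r$orderings,
                 config_hash = r$config_hash)
          },
          `dose-scaling` = {
            r <- run_dose_scaling(params, protocol, scales = cfg$scales,
                                  insult = insult)
            list(experiment = "dose_scaling",
                 monotonicity = r$monotonicity,
                 config_hash = r$config_hash)
          },
          stop("unknown experiment: ", sub, call. = FALSE))
        jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows")
        message("wrote ", file.path(out_dir, "report.json"))
      },
      sensitivity = {
        res <- sensitivity_analysis(params, vary = cfg$sensitivity_vary,
                                    protocol = protocol,
                                    n_samples = cfg$n_samples,
                                    seed = cfg$seed, horizon = horizon)
        jsonlite::write_json(res, file.path(out_dir, "sensitivity.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows")
        message("wrote ", file.path(out_dir, "sensitivity.json"))
      },
      {
        message(.cli_usage())
        return(invisible(2L))
      })
    .write_manifest(cfg, cfg$seed, out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
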