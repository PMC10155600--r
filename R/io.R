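#' @name cli_io
#' @title Delimited-text formats and provenance
#' @description
#' All tabular data move through comma-separated text with a declared header
#' row and `#` comment lines; unit-bearing columns carry their unit as a name
#' suffix (`_K`, `_per_s`, `_Pa`, `_pct`, `_rad_s`, `_s`, `_au`). Every file
#' written by the package embeds the package version, the seed, and a hash of
#' the generating configuration in its comment header.
NULL

curve_schemas <- list(
  buildup = c("tau_s", "amplitude_au", "filter_kind", "temperature_K",
              "shear_rate_per_s", "snr"),
  flow = c("temperature_K", "replicate", "shear_rate_per_s", "stress_Pa"),
  sweep = c("axis_kind", "axis_value", "G_prime_Pa", "G_doubleprime_Pa",
            "strain_pct", "frequency_rad_s", "temperature_K")
)

# 32-bit FNV-1a over the deparsed object; cheap content hash for provenance.
# Arithmetic is done on 16-bit halves so every intermediate stays exactly
# representable in a double.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Write curves as commented delimited text
#'
#' @param x Data frame to write.
#' @param path Output file path.
#' @param config Optional configuration object; hashed into the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_curves <- function(x, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rheomqf %s",
                     as.character(utils::packageVersion("rheomqf"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config)) writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate delimited curve files
#'
#' Reads a comma-separated file with `#` comments, checks that the declared
#' schema's columns are present, that numeric columns contain numbers, and
#' that the relevant axis is strictly increasing within each curve (tau
#' within a build-up curve, shear rate within a flow replicate). Violations
#' are reported with the offending column or row.
#'
#' @param path File path.
#' @param schema One of `"buildup"`, `"flow"`, `"sweep"`.
#' @return Validated data frame.
#' @export
read_curves <- function(path, schema = c("buildup", "flow", "sweep")) {
  schema <- match.arg(schema)
  need <- curve_schemas[[schema]]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_curves: ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  char_ok <- c("filter_kind", "axis_kind")
  for (col in need) {
    if (col %in% char_ok) next
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
    } else vn <- v
    bad <- which(!is.finite(vn) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("read_curves: non-numeric value in column '", col, "' at row ",
           bad[1], call. = FALSE)
    }
    df[[col]] <- vn
  }
  if (schema == "buildup") {
    key <- interaction(df$filter_kind, df$temperature_K, df$shear_rate_per_s,
                       drop = TRUE)
    for (g in split(seq_len(nrow(df)), key)) {
      if (any(diff(df$tau_s[g]) <= 0)) {
        stop("read_curves: tau_s not strictly increasing within curve starting at row ",
             g[1], call. = FALSE)
      }
    }
  }
  if (schema == "flow") {
    key <- interaction(df$temperature_K, df$replicate, drop = TRUE)
    for (g in split(seq_len(nrow(df)), key)) {
      if (any(diff(df$shear_rate_per_s[g]) <= 0)) {
        stop("read_curves: shear_rate_per_s not strictly increasing within replicate starting at row ",
             g[1], call. = FALSE)
      }
    }
  }
  df
}

buildup_to_df <- function(curve) {
  data.frame(tau_s = curve$tau, amplitude_au = curve$amplitude,
             filter_kind = curve$filter_kind,
             temperature_K = curve$temperature_K,
             shear_rate_per_s = curve$shear_rate_per_s, snr = curve$snr)
}

df_to_buildup <- function(df) {
  structure(list(tau = df$tau_s, amplitude = df$amplitude_au,
                 filter_kind = df$filter_kind[1],
                 temperature_K = df$temperature_K[1],
                 shear_rate_per_s = df$shear_rate_per_s[1],
                 snr = df$snr[1],
                 noise_sigma = NA_real_, seed = NA_integer_, truth = NULL),
            class = "buildup_curve")
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for data files and reports.
#' @param seed Master seed; all stage seeds derive from it.
#' @param snr Build-up curve signal-to-noise ratio.
#' @param temperature_list,shear_rate_list MQF study conditions.
#' @param flow_temperatures Temperatures of the constitutive selection study.
#' @param n_replicates Flow replicates per temperature.
#' @param presence_k Detection threshold (noise SDs).
#' @param newtonian_gate,band_fraction,lvr_fraction Cascade and detector
#'   thresholds.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("rheomqf-run-"), seed = 1L,
                            snr = 20, temperature_list = c(288, 295, 303, 313),
                            shear_rate_list = c(0, 11.6, 29, 58, 87),
                            flow_temperatures = c(283, 288, 295, 303, 313),
                            n_replicates = 20L, presence_k = 3,
                            newtonian_gate = 0.1, band_fraction = 0.15,
                            lvr_fraction = 0.05) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), snr = snr,
                 temperature_list = temperature_list,
                 shear_rate_list = shear_rate_list,
                 flow_temperatures = flow_temperatures,
                 n_replicates = as.integer(n_replicates),
                 presence_k = presence_k, newtonian_gate = newtonian_gate,
                 band_fraction = band_fraction, lvr_fraction = lvr_fraction),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields of [pipeline_config()].
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates the workflow in the order of the original study: simulate the
#' synthetic fluid (flow curves, oscillatory sweeps, MQF build-up curves
#' across the condition grid), fit the constitutive models and run the
#' selection cascade per temperature, run the sequential MQF fits where a
#' signal is detected, and derive the shear-dependence and Arrhenius
#' analyses. Emits the simulated data as commented CSV and a JSON report
#' shaped like the study's three parameter tables. Identical configurations
#' produce byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly; written to
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hc <- helix_coil_model()
  # hash covers the scientific settings, not the output location
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])

  ## stage 1: rheometry - selection cascade per temperature
  flow_reports <- lapply(config$flow_temperatures, function(T) {
    rep <- tryCatch(
      run_selection_study(T, seed = config$seed + round(T),
                          n_replicates = config$n_replicates),
      error = function(e) stop("stage 'rheometry' failed at ", T, " K: ",
                               conditionMessage(e), call. = FALSE))
    list(temperature_K = T, chosen = rep$chosen, reasons = rep$reasons,
         sigma_y_sd_over_mean = rep$sigma_y_sd_over_mean,
         parameters = lapply(rep$tried, function(a)
           list(mean = as.list(a$mean), sd = as.list(a$sd))))
  })

  ## stage 2: oscillatory characterisation
  tsweep <- generate_temperature_sweep(hc, seed = config$seed + 7)
  cross <- detect_crossover(tsweep$sweep)
  amp <- generate_amplitude_sweep(hc, seed = config$seed + 8)
  lvr <- lvr_extent(amp, fraction = config$lvr_fraction)
  cm <- lapply(c(288, 295, 303, 308), function(T) {
    fs <- derive_visco(generate_frequency_sweep(hc, T, seed = config$seed + 9))
    sv <- generate_steady_viscosity(hc, T, seed = config$seed + 10)
    chk <- cox_merz_check(fs, sv)
    list(temperature_K = T, holds = chk$holds,
         max_rel_deviation = chk$max_rel_deviation)
  })
  write_curves(tsweep$sweep, file.path(config$out_dir, "temperature_sweep.csv"),
               config = config, seed = config$seed)
  write_curves(amp, file.path(config$out_dir, "amplitude_sweep.csv"),
               config = config, seed = config$seed)

  ## stage 3: MQF build-up simulation + sequential fits
  cond <- generate_mqf_condition_table(hc, config$temperature_list,
                                       config$shear_rate_list)
  grid <- tau_grid()
  mqf_rows <- list()
  buildup_df <- list()
  for (i in seq_len(nrow(cond))) {
    p <- mqf_params(C0 = cond$C0[i], C1 = cond$C1[i],
                    nu_eff = cond$nu_eff_Hz[i], R2fast = cond$R2fast_per_s[i],
                    R2slow = cond$R2slow_per_s[i])
    sd_curve <- generate_buildup_curve(p, grid, "DQF_MA", snr = config$snr,
                                       seed = config$seed * 1000L + 2L * i,
                                       temperature_K = cond$temperature_K[i],
                                       shear_rate_per_s = cond$shear_rate_per_s[i])
    st_curve <- generate_buildup_curve(p, grid, "TQF", snr = config$snr,
                                       seed = config$seed * 1000L + 2L * i + 1L,
                                       temperature_K = cond$temperature_K[i],
                                       shear_rate_per_s = cond$shear_rate_per_s[i])
    buildup_df[[length(buildup_df) + 1L]] <- rbind(buildup_to_df(sd_curve),
                                                   buildup_to_df(st_curve))
    pres <- detect_mqf_presence(sd_curve, k = config$presence_k)
    row <- list(temperature_K = cond$temperature_K[i],
                shear_rate_per_s = cond$shear_rate_per_s[i],
                signal = pres$signal)
    if (pres$signal) {
      pair <- fit_mqf_pair(sd_curve, st_curve)
      if (pair$dqf$status == "ok") {
        row$nu_eff_Hz <- pair$dqf$params[["nu_eff"]]
        row$nu_eff_se_Hz <- pair$dqf$se[["nu_eff"]]
        row$R2fast_per_s <- pair$dqf$params[["R2fast"]]
        row$R2fast_se_per_s <- pair$dqf$se[["R2fast"]]
        if (!is.null(pair$tqf) && pair$tqf$status == "ok") {
          row$R2slow_per_s <- pair$tqf$params[["R2slow"]]
          row$R2slow_se_per_s <- pair$tqf$se[["R2slow"]]
        }
      }
    }
    mqf_rows[[length(mqf_rows) + 1L]] <- row
  }
  write_curves(do.call(rbind, buildup_df),
               file.path(config$out_dir, "buildup_curves.csv"),
               config = config, seed = config$seed)

  ## stage 4: downstream series analyses on the fitted conditions
  fitted <- Filter(function(r) isTRUE(r$signal) && !is.null(r$R2slow_per_s),
                   mqf_rows)
  fitted_df <- do.call(rbind, lapply(fitted, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  shear <- NULL
  arr <- NULL
  if (!is.null(fitted_df)) {
    at288 <- fitted_df[fitted_df$temperature_K == 288 &
                         fitted_df$shear_rate_per_s > 0, ]
    if (nrow(at288) >= 3) {
      sd_fit <- fit_shear_dependence(at288)
      shear <- list(nu_slope_Hz_s = sd_fit$nu_slope,
                    nu_intercept_Hz = sd_fit$nu_intercept,
                    r2slow_flatness_p = sd_fit$r2slow_flatness_p)
    }
    at58 <- fitted_df[fitted_df$shear_rate_per_s == 58, ]
    if (nrow(at58) >= 3) {
      ar <- arrhenius_analysis(at58)
      arr <- lapply(ar, function(a) list(slope_K = a$slope,
                                         intercept = a$intercept,
                                         slope_error = a$slope_error))
    }
  }

  report <- list(
    meta = list(package = "rheomqf",
                version = as.character(utils::packageVersion("rheomqf")),
                seed = config$seed, config_hash = hash),
    flow_models = flow_reports,
    oscillatory = list(crossover_K = cross$temperature_K,
                       gamma_lvr_pct = lvr$gamma_lvr_pct,
                       cox_merz = cm),
    mqf_conditions = mqf_rows,
    shear_dependence_288K = shear,
    arrhenius_58s = arr)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
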