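#' Monte-Carlo recovery study of the sequential MQF pipeline
#'
#' Generates seeded DQF-MA / TQF curve pairs from a generating parameter set,
#' runs the sequential pipeline (DQF first, then TQF with frozen
#' coefficients) on every pair, and summarises the recovered parameters.
#' This is the package's acceptance exercise for the fitting pipeline: with
#' no public instrument data, recovery of the reported parameter values from
#' synthetic curves generated at those values is the testable claim.
#'
#' @param params Generating [mqf_params()].
#' @param n_seeds Number of Monte-Carlo repetitions (seeds `offset + 1 ...
#'   offset + n_seeds`).
#' @param snr Per-curve signal-to-noise ratio.
#' @param grid A [tau_grid()].
#' @param seed_offset Added to each repetition index to form the curve seeds.
#' @return List with `estimates` (data frame of per-seed `nu_eff_Hz`,
#'   `R2fast_per_s`, `R2slow_per_s`, `C0`, `C1`), `mean`, `sd` and
#'   `mc_se` (Monte-Carlo standard error of each mean), and `truth`.
#' @export
mqf_recovery_study <- function(params, n_seeds = 50L, snr = 20,
                               grid = tau_grid(), seed_offset = 0L) {
  params <- as_mqf_params(params)
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- as.integer(seed_offset) + i
    dq <- generate_buildup_curve(params, grid, "DQF_MA", snr = snr,
                                 seed = 2L * s)
    tq <- generate_buildup_curve(params, grid, "TQF", snr = snr,
                                 seed = 2L * s + 1L)
    pair <- fit_mqf_pair(dq, tq)
    data.frame(
      seed = s,
      nu_eff_Hz = pair$dqf$params[["nu_eff"]],
      R2fast_per_s = pair$dqf$params[["R2fast"]],
      C0 = pair$dqf$params[["C0"]],
      R2slow_per_s = if (!is.null(pair$tqf)) pair$tqf$params[["R2slow"]] else NA_real_,
      C1 = if (!is.null(pair$tqf)) pair$tqf$params[["C1"]] else NA_real_,
      dqf_ok = pair$dqf$status == "ok",
      tqf_ok = !is.null(pair$tqf) && pair$tqf$status == "ok")
  })
  est <- do.call(rbind, rows)
  num <- c("nu_eff_Hz", "R2fast_per_s", "R2slow_per_s", "C0", "C1")
  mean_ <- colMeans(est[num], na.rm = TRUE)
  sd_ <- vapply(est[num], stats::sd, numeric(1), na.rm = TRUE)
  list(estimates = est, mean = mean_, sd = sd_,
       mc_se = sd_ / sqrt(colSums(!is.na(est[num]))),
       truth = c(nu_eff_Hz = params$nu_eff, R2fast_per_s = params$R2fast,
                 R2slow_per_s = params$R2slow, C0 = params$C0, C1 = params$C1))
}

#' Monte-Carlo recovery study of replicate constitutive fits
#'
#' For each of `n_seeds` seeds, generates `n_replicates` flow curves from a
#' reference constitutive row (that row's reported standard deviations as
#' replicate dispersion, multiplicative stress noise), fits the requested
#' model to every replicate, aggregates, and optionally runs the selection
#' cascade.
#'
#' @param temperature_K Reference temperature (row of [kc_flow_models()]).
#' @param kind Model generated and fitted (`"HB"`, `"PL"`, `"N"`).
#' @param n_seeds Number of Monte-Carlo repetitions.
#' @param n_replicates Replicates per repetition.
#' @param noise_cv Multiplicative stress noise.
#' @param rate_grid Shear-rate grid.
#' @param select Also run the HB/PL selection cascade per seed.
#' @param seed_offset Added to the repetition index to form seeds.
#' @return List with `per_seed` (data frame of aggregated means per seed,
#'   plus `chosen` when `select`), `mean`, `mc_se`, `truth`, and
#'   `selection_rate` (named proportions, when `select`).
#' @export
flow_recovery_study <- function(temperature_K, kind, n_seeds = 100L,
                                n_replicates = 10L, noise_cv = 0.02,
                                rate_grid = default_rate_grid(),
                                select = FALSE, seed_offset = 0L) {
  ref <- kc_flow_row(temperature_K, kind)
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- as.integer(seed_offset) + i
    curves <- generate_flow_curve(list(kind = ref$kind, pars = ref$pars),
                                  rate_grid = rate_grid, noise_cv = noise_cv,
                                  replicate_dispersion = ref$sds,
                                  n_replicates = n_replicates,
                                  temperature_K = temperature_K, seed = s)
    fits <- lapply(curves, fit_constitutive, kind = kind)
    agg <- aggregate_replicates(fits)
    out <- as.list(agg$mean)
    names(out) <- paste0(names(out), "_mean")
    if (select) {
      hb <- if (kind == "HB") fits else lapply(curves, fit_constitutive, kind = "HB")
      pl <- if (kind == "PL") fits else lapply(curves, fit_constitutive, kind = "PL")
      sel <- select_model(list(HB = aggregate_replicates(hb),
                               PL = aggregate_replicates(pl)), curves)
      out$chosen <- sel$chosen
    }
    out$seed <- s
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  per_seed <- do.call(rbind, rows)
  num <- setdiff(names(per_seed), c("seed", "chosen"))
  mean_ <- colMeans(per_seed[num])
  mc_se <- vapply(per_seed[num], stats::sd, numeric(1)) / sqrt(n_seeds)
  out <- list(per_seed = per_seed, mean = mean_, mc_se = mc_se,
              truth = ref$pars)
  if (select) {
    out$selection_rate <- prop.table(table(per_seed$chosen))
  }
  out
}
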