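#' Configuration for the synthetic case-study generator
#'
#' The generator emulates the structure of the wet-granulation /
#' compaction case study: raw-material lots described by two latent
#' factors (a filling/dimension factor driving densities, particle
#' sizes and, inversely, specific surface area; and a flowability
#' factor driving angle of repose, Hausner ratio and span), granule
#' properties driven by binder amount and the material factors, and
#' tablet responses generated from the packaged response-surface models
#' plus a granule-size perturbation and Gaussian noise.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_lots Number of raw-material lots (>= 3; default 11, the
#'   case-study count).
#' @param material_noise Idiosyncratic noise sd on the standardized
#'   material variables (latent factor effects have sd 1).
#' @param granule_noise Noise sd on the standardized granule variables.
#' @param y_noise Noise sd on the tablet responses, in response units
#'   (MPa for TS, min for DT).
#' @param beta_binder Effect of coded binder amount (-1..1 over the
#'   designed range) on the standardized granule size/density
#'   variables.
#' @param beta_lot Effect of material factor 1 on the standardized
#'   granule size/density variables.
#' @param beta_lot2 Effect of material factor 2 on the standardized
#'   granule MC/AOR/HR/Span variables.
#' @param gamma_ts Granule-size perturbation coefficient on tensile
#'   strength (MPa per unit size score; negative — larger granules
#'   compact into weaker tablets).
#' @param gamma_dt Granule-size perturbation on disintegration time
#'   (min per unit size score; negative — larger granules disintegrate
#'   faster).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_lots = 11L,
                             material_noise = 0.3,
                             granule_noise = 0.35,
                             y_noise = c(TS = 0.35, DT = 0.55),
                             beta_binder = 1.0, beta_lot = 0.6,
                             beta_lot2 = 1.0,
                             gamma_ts = -0.25, gamma_dt = -0.15) {
  stopifnot(n_lots >= 3L, material_noise >= 0, granule_noise >= 0,
            all(y_noise >= 0))
  if (is.null(names(y_noise))) names(y_noise) <- c("TS", "DT")
  structure(list(seed = as.integer(seed), n_lots = as.integer(n_lots),
                 material_noise = material_noise,
                 granule_noise = granule_noise, y_noise = y_noise,
                 beta_binder = beta_binder, beta_lot = beta_lot,
                 beta_lot2 = beta_lot2, gamma_ts = gamma_ts,
                 gamma_dt = gamma_dt),
            class = "generator_config")
}

# Units/centers/scales used to map standardized material variables to
# plausible physical values (densities g/mL, sizes um, SSA m2/g, AOR
# degrees). Modeling autoscales everything, so these affect only
# readability of the generated tables.
material_var_map <- function() {
  data.frame(
    var = c("D_bm", "D_tm", "D_10m", "D_50m", "D_90m", "SSA_m",
            "AOR_m", "HR_m", "Span_m"),
    center = c(0.38, 0.48, 12, 55, 120, 1.1, 38, 1.25, 2.0),
    scale = c(0.04, 0.05, 3, 12, 25, 0.25, 3.5, 0.08, 0.3),
    f1 = c(1, 1, 1, 1, 1, -1, 0, 0, 0),
    f2 = c(0, 0, 0, 0, 0, 0, 1, 1, 1))
}

#' Generate a synthetic raw-material block
#'
#' Draws `n_lots` lots from the two-factor structure described in
#' [generator_config()]: factor 1 loads positively on bulk/tapped
#' density and the particle sizes and negatively on specific surface
#' area; factor 2 loads on angle of repose, Hausner ratio and span.
#'
#' @param config A [generator_config()].
#' @param lot_labels Optional lot labels (default `L01`..; the
#'   case-study generator passes the 11 canonical labels).
#' @return List with `block` (an `n_lots x 9` [data_block()] whose
#'   run ids are the lot labels) and `truth` (latent factors and the
#'   loading map).
#' @export
generate_material_block <- function(config = generator_config(),
                                    lot_labels = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_lots
  if (is.null(lot_labels)) {
    lot_labels <- sprintf("L%02d", seq_len(n))
  }
  stopifnot(length(lot_labels) == n)
  f1 <- stats::rnorm(n)
  f2 <- stats::rnorm(n)
  vm <- material_var_map()
  Z <- sapply(seq_len(nrow(vm)), function(j) {
    vm$f1[j] * f1 + vm$f2[j] * f2 +
      config$material_noise * stats::rnorm(n)
  })
  vals <- sweep(sweep(Z, 2L, vm$scale, "*"), 2L, vm$center, "+")
  colnames(vals) <- vm$var
  rownames(vals) <- lot_labels
  block <- data_block(vals, name = "M", role = "predictor",
                      run_ids = lot_labels)
  truth <- list(factors = cbind(f1 = f1, f2 = f2), loading_map = vm)
  list(block = block, truth = truth)
}

#' Generate a full synthetic case study
#'
#' Produces the five blocks of the case-study layout with known ground
#' truth. The granulation parameters (`P1`), compaction parameters
#' (`X3`) and lot assignment come verbatim from the packaged 52-run
#' design; the material block (`M`), granule properties (`X2`) and
#' tablet responses (`Y`) are simulated:
#'
#' * granule size/density variables (`D_b`, `D_t`, `D_10`, `D_50`,
#'   `D_90`) respond positively to binder amount (coded) and to the
#'   lot's filling/dimension factor;
#' * granule `MC`, `AOR`, `HR`, `Span` carry the lot's flowability
#'   factor;
#' * `TS` and `DT` are the packaged response-surface models evaluated
#'   at each run's (binder, lubrication, distance) plus a granule-size
#'   perturbation (negative on both) and Gaussian noise, so the
#'   response truly routes through the granule (`X2`) and compaction
#'   (`X3`) blocks.
#'
#' @param config A [generator_config()].
#' @return List with `blocks` (named list `M` (11 x 9, per lot),
#'   `M_expanded` (52 x 9, per run), `P1`, `X2`, `X3`, `Y`) and `truth`
#'   (`drivers` per response, lot factors, generating coefficients).
#' @export
generate_case_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_lots != 11L) {
    stop("the packaged design assigns 11 lots; set n_lots = 11")
  }
  dsn <- design_blocks()
  lots <- sort(unique(unname(dsn$lot_of_run)))
  al <- lot_aliases()
  lots <- sort(unique(ifelse(lots %in% names(al), al[lots], lots)))
  mat <- generate_material_block(config, lot_labels = lots)
  # rng state continues past the material draw; everything below is a
  # deterministic continuation of the same seed
  M_exp <- expand_lot_block(mat$block, dsn$lot_of_run)
  n <- nrow(M_exp$values)
  run_ids <- M_exp$run_ids
  lot_idx <- match(ifelse(dsn$lot_of_run %in% names(al),
                          al[dsn$lot_of_run], dsn$lot_of_run), lots)
  f1r <- mat$truth$factors[lot_idx, "f1"]
  f2r <- mat$truth$factors[lot_idx, "f2"]

  C <- dsn$P1$values[, "C"]
  Ft <- dsn$X3$values[, "F"]
  G <- dsn$X3$values[, "G"]
  c_coded <- (C - 22) / 2

  size_vars <- c("D_b", "D_t", "D_10", "D_50", "D_90")
  flow_vars <- c("MC", "AOR", "HR", "Span")
  g_center <- c(D_b = 0.45, D_t = 0.55, D_10 = 80, D_50 = 250,
                D_90 = 550, MC = 2.5, AOR = 35, HR = 1.2, Span = 1.9)
  g_scale <- c(D_b = 0.05, D_t = 0.06, D_10 = 20, D_50 = 60,
               D_90 = 120, MC = 0.5, AOR = 3, HR = 0.07, Span = 0.25)
  Zsize <- sapply(size_vars, function(v) {
    config$beta_binder * c_coded + config$beta_lot * f1r +
      config$granule_noise * stats::rnorm(n)
  })
  Zflow <- sapply(flow_vars, function(v) {
    config$beta_lot2 * f2r + config$granule_noise * stats::rnorm(n)
  })
  size_score <- rowMeans(Zsize)
  Z <- cbind(Zsize, Zflow)[, c("D_b", "D_t", "AOR", "HR", "MC",
                               "D_10", "D_50", "D_90", "Span")]
  X2_vals <- sweep(sweep(Z, 2L, g_scale[colnames(Z)], "*"),
                   2L, g_center[colnames(Z)], "+")
  rownames(X2_vals) <- run_ids
  X2 <- data_block(X2_vals, name = "X2", role = "predictor",
                   run_ids = run_ids)

  base <- evaluate_printed_models(C, Ft, G)
  TS <- base[, "TS"] + config$gamma_ts * size_score +
    config$y_noise[["TS"]] * stats::rnorm(n)
  DT <- base[, "DT"] + config$gamma_dt * size_score +
    config$y_noise[["DT"]] * stats::rnorm(n)
  Y <- data_block(cbind(TS = TS, DT = DT), name = "Y",
                  role = "predictee", run_ids = run_ids)

  truth <- list(
    drivers = list(
      TS = c("C", "F", "G", size_vars),
      DT = c("C", "F", "G", size_vars)),
    critical_blocks = c("X2", "X3"),
    critical_vars = c("C", "F", "G"),
    lot_factors = mat$truth$factors,
    coefficients = list(beta_binder = config$beta_binder,
                        beta_lot = config$beta_lot,
                        beta_lot2 = config$beta_lot2,
                        gamma_ts = config$gamma_ts,
                        gamma_dt = config$gamma_dt),
    size_score = size_score)
  list(blocks = list(M = mat$block, M_expanded = M_exp, P1 = dsn$P1,
                     X2 = X2, X3 = dsn$X3, Y = Y),
       truth = truth)
}

#' Criticality-recovery experiment over seeded replicates
#'
#' For each replicate: generate a synthetic case study, assemble
#' `X1 = [M_expanded, P1]`, fit the path model, compute the
#' [criticality()] calls, and record whether they match the generator's
#' ground truth — a block hit when the critical blocks are exactly
#' `{X2, X3}`, a variable hit when the critical variables include
#' binder amount (`C`), lubrication time (`F`) and minimal punch tip
#' separation distance (`G`).
#'
#' @param config Base [generator_config()]; replicate `i` uses
#'   `seed + i - 1`.
#' @param n_replicates Number of replicates (>= 10).
#' @param n_lvs Latent variables for the fitted path model.
#' @return List with `summary` (data frame: `bip_hit_rate`,
#'   `vip_hit_rate`, `mean_r2y`, `n_replicates`) and `per_replicate`
#'   (data frame of per-replicate outcomes).
#' @export
recovery_experiment <- function(config = generator_config(),
                                n_replicates = 100L, n_lvs = 3L) {
  stopifnot(n_replicates >= 10L)
  res <- lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    cs <- generate_case_study(cfg)
    X1 <- concat_blocks(list(cs$blocks$M_expanded, cs$blocks$P1),
                        name = "X1")
    fit <- fit_mbplspm(X1, cs$blocks$X2, cs$blocks$X3, cs$blocks$Y,
                       n_lvs = n_lvs)
    cr <- criticality(fit)
    data.frame(
      seed = cfg$seed,
      bip_hit = identical(sort(cr$critical_blocks),
                          sort(cs$truth$critical_blocks)),
      vip_hit = all(cs$truth$critical_vars %in% cr$critical_vars),
      r2y = fit$r2y_cum[n_lvs],
      r2x = fit$r2x_cum[n_lvs],
      iterations = max(fit$iterations))
  })
  per <- do.call(rbind, res)
  list(summary = data.frame(bip_hit_rate = mean(per$bip_hit),
                            vip_hit_rate = mean(per$vip_hit),
                            mean_r2y = mean(per$r2y),
                            mean_r2x = mean(per$r2x),
                            n_replicates = n_replicates),
       per_replicate = per)
}
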