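#' Subtract background fluorescence from a plate-reader series
#'
#' Removes cell autofluorescence per channel and cycle, using the matched
#' series of a reporter-free strain grown and treated identically. Series
#' are aligned on cycle number.
#'
#' @param series data.frame with columns `cycle`, `time_min`, `F400`,
#'   `F485` (fluorescence at 400 nm / 485 nm excitation, a.u.).
#' @param background same columns, reporter-free strain; must cover the
#'   same cycles.
#' @return `series` with `F400`/`F485` background-corrected; warns when any
#'   corrected value is <= 0.
#' @export
subtract_background <- function(series, background) {
  need <- c("cycle", "F400", "F485")
  for (nm in c("series", "background")) {
    df <- get(nm)
    miss <- setdiff(need, names(df))
    if (length(miss)) stopf("`%s` lacks column(s): %s", nm,
                            paste(miss, collapse = ", "))
  }
  bg <- background[match(series$cycle, background$cycle), ]
  if (any(is.na(bg$cycle)) || nrow(bg) != nrow(series)) {
    stopf("channel length mismatch: background does not cover all cycles")
  }
  out <- series
  out$F400 <- series$F400 - bg$F400
  out$F485 <- series$F485 - bg$F485
  if (any(out$F400 <= 0 | out$F485 <= 0)) {
    warnf("background-corrected fluorescence <= 0 in %d cycle(s)",
          sum(out$F400 <= 0 | out$F485 <= 0))
  }
  out
}

#' Degree of oxidation of a ratiometric probe
#'
#' Converts an excitation ratio `R = F485 / F400` to the fraction of probe
#' molecules oxidised, given the ratios of the fully reduced (DTT-treated)
#' and fully oxidised (H2O2-treated) calibration wells:
#' \deqn{OxD = \frac{R - R_{red}}{F_{corr} (R_{ox} - R) + (R - R_{red})}}
#' With `F_corr = 1` this is linear interpolation between the calibration
#' ratios; `F_corr` corrects for instrument-dependent differences in the
#' channel response between the two redox states. Values outside `[0, 1]`
#' (ratios beyond the calibration range) are clamped and flagged.
#'
#' @param R excitation ratio(s) `F485 / F400`.
#' @param R_red,R_ox calibration ratios of the fully reduced / oxidised
#'   probe; must differ.
#' @param F_corr instrument correction factor (> 0; default 1).
#' @param clamp clamp results to `[0, 1]`.
#' @return Numeric vector of OxD values; logical attribute
#'   `"out_of_range"` marks entries clamped (or outside `[0, 1]` when
#'   `clamp = FALSE`).
#' @export
oxd <- function(R, R_red, R_ox, F_corr = 1, clamp = TRUE) {
  stopifnot(is.numeric(R), is_number(R_red), is_number(R_ox))
  if (R_red == R_ox) stopf("R_red equals R_ox: no calibration dynamic range")
  if (!is_number(F_corr) || F_corr <= 0) stopf("`F_corr` must be positive")
  raw <- (R - R_red) / (F_corr * (R_ox - R) + (R - R_red))
  oor <- !is.finite(raw) | raw < 0 | raw > 1
  out <- if (clamp) pmin(1, pmax(0, raw)) else raw
  out[!is.finite(raw)] <- NA_real_
  attr(out, "out_of_range") <- oor
  out
}

# ratio producing a given OxD under the same calibration (used by the
# synthetic series generator)
inverse_oxd <- function(oxd_value, R_red, R_ox, F_corr = 1) {
  stopifnot(all(oxd_value >= 0 & oxd_value <= 1))
  (R_red * (1 - oxd_value) + oxd_value * F_corr * R_ox) /
    (1 - oxd_value + oxd_value * F_corr)
}

#' Calibration ratio from a control well
#'
#' Median excitation ratio over the post-treatment plateau cycles of a
#' fully reduced or fully oxidised control well; the median is robust to
#' the injection transient.
#'
#' @param series data.frame with `cycle`, `F400`, `F485` (background
#'   corrected).
#' @param baseline_cycles number of pre-treatment cycles; only cycles after
#'   these enter the median.
#' @return Scalar calibration ratio.
#' @export
calibration_ratio <- function(series, baseline_cycles = 4) {
  stopifnot(all(c("cycle", "F400", "F485") %in% names(series)))
  post <- series[series$cycle > baseline_cycles, , drop = FALSE]
  if (nrow(post) == 0L) stopf("no post-treatment cycles for calibration")
  median(post$F485 / post$F400)
}

#' Baseline degree of oxidation
#'
#' Mean OxD over the pre-treatment cycles — the steady-state oxidation of
#' the probe before any H2O2 challenge.
#'
#' @param oxd_trajectory OxD values in cycle order.
#' @param n_baseline_cycles number of pre-treatment cycles (default 4,
#'   matching ~2-min cycles before injection).
#' @return Mean OxD over the first `n_baseline_cycles` values.
#' @export
oxd0 <- function(oxd_trajectory, n_baseline_cycles = 4) {
  stopifnot(is.numeric(oxd_trajectory), is_count(n_baseline_cycles))
  if (length(oxd_trajectory) < n_baseline_cycles) {
    stopf("trajectory has fewer cycles (%d) than the baseline window (%d)",
          length(oxd_trajectory), n_baseline_cycles)
  }
  base::mean(oxd_trajectory[seq_len(n_baseline_cycles)])
}

#' Degree-of-oxidation pipeline for one plate
#'
#' Full OxD computation from a long-format dual-excitation plate-reader
#' table: averages the background wells per cycle and subtracts them from
#' every reporter well, derives the calibration ratios from the fully
#' reduced and fully oxidised control wells, converts each sample well's
#' ratio trajectory to OxD, and summarises the pre-treatment baseline OxD0.
#'
#' @param plate data.frame with columns `well`, `condition` (one of
#'   `"sample"`, `"reduced_control"`, `"oxidized_control"`,
#'   `"background"`), `cycle`, `time_min`, `F400`, `F485`.
#' @param baseline_cycles pre-treatment cycles (default 4).
#' @param F_corr instrument correction factor passed to [oxd()].
#' @return List: `oxd` (`data.table`: `well`, `condition`, `cycle`,
#'   `time_min`, `R`, `OxD`, `out_of_range`), `summary` (`data.table`:
#'   `well`, `OxD0` for sample wells), `calibration` (list `R_red`, `R_ox`,
#'   `F_corr`).
#' @export
oxd_plate <- function(plate, baseline_cycles = 4, F_corr = 1) {
  plate <- as.data.frame(plate)
  need <- c("well", "condition", "cycle", "time_min", "F400", "F485")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stopf("`plate` lacks column(s): %s", paste(miss, collapse = ", "))
  conds <- c("sample", "reduced_control", "oxidized_control", "background")
  bad <- setdiff(unique(plate$condition), conds)
  if (length(bad)) stopf("unknown condition(s): %s", paste(bad, collapse = ", "))
  for (cc in c("reduced_control", "oxidized_control")) {
    if (!any(plate$condition == cc)) stopf("no %s well on the plate", cc)
  }
  bg <- plate[plate$condition == "background", , drop = FALSE]
  if (nrow(bg)) {
    bgm <- aggregate(bg[c("F400", "F485")], by = list(cycle = bg$cycle), FUN = base::mean)
  } else {
    bgm <- NULL
  }
  fg <- plate[plate$condition != "background", , drop = FALSE]
  per_well <- lapply(split(fg, fg$well), function(sw) {
    sw <- sw[order(sw$cycle), , drop = FALSE]
    corr <- if (is.null(bgm)) sw else
      suppressWarnings(subtract_background(sw, bgm))
    corr
  })
  ratio <- function(sw) sw$F485 / sw$F400
  red <- do.call(rbind, per_well[vapply(per_well, function(s)
    s$condition[1] == "reduced_control", TRUE)])
  ox <- do.call(rbind, per_well[vapply(per_well, function(s)
    s$condition[1] == "oxidized_control", TRUE)])
  R_red <- calibration_ratio(red, baseline_cycles)
  R_ox <- calibration_ratio(ox, baseline_cycles)
  traj <- rbindlist(lapply(per_well, function(sw) {
    Rv <- ratio(sw)
    ox_v <- oxd(Rv, R_red, R_ox, F_corr = F_corr)
    data.table(well = sw$well, condition = sw$condition, cycle = sw$cycle,
               time_min = sw$time_min, R = Rv, OxD = as.numeric(ox_v),
               out_of_range = attr(ox_v, "out_of_range"))
  }))
  setorder(traj, well, cycle)
  summ <- traj[condition == "sample",
               .(OxD0 = oxd0(OxD, baseline_cycles)), by = well]
  list(oxd = traj[], summary = summ[],
       calibration = list(R_red = R_red, R_ox = R_ox, F_corr = F_corr))
}

#' Simulate a dual-excitation HyPer7 plate
#'
#' Generates a synthetic plate-reader table with known ground truth for
#' validating the OxD pipeline: one or more sample wells at a given
#' baseline oxidation (optionally stepping to a post-treatment level),
#' fully reduced and fully oxidised calibration wells, and a background
#' well. Noise of standard deviation `noise_sd` is applied on the OxD scale
#' and mapped back to ratios, and a constant background offset is added to
#' both channels.
#'
#' @param oxd0_true true baseline degree of oxidation of the sample wells.
#' @param oxd_post post-treatment OxD plateau (default: same as baseline).
#' @param n_cycles total cycles.
#' @param baseline_cycles pre-treatment cycles.
#' @param cycle_min minutes per cycle.
#' @param n_sample_wells number of sample wells.
#' @param R_red,R_ox true calibration ratios.
#' @param F400_level clean 400-nm-excitation fluorescence level (a.u.).
#' @param bg400,bg485 constant background offsets per channel.
#' @param noise_sd noise standard deviation on the OxD scale.
#' @param seed seed for reproducibility.
#' @return data.frame in [oxd_plate()] input format; true parameters in
#'   attribute `"truth"`.
#' @export
simulate_hyper7_plate <- function(oxd0_true = 0.4, oxd_post = oxd0_true,
                                  n_cycles = 20, baseline_cycles = 4,
                                  cycle_min = 2, n_sample_wells = 1,
                                  R_red = 0.4, R_ox = 2.4, F400_level = 1000,
                                  bg400 = 50, bg485 = 30, noise_sd = 0.01,
                                  seed = 1) {
  stopifnot(oxd0_true >= 0, oxd0_true <= 1, oxd_post >= 0, oxd_post <= 1,
            is_count(n_cycles), is_count(baseline_cycles),
            n_cycles > baseline_cycles, is_count(n_sample_wells))
  with_preserved_rng({
    set.seed(seed)
    cyc <- seq_len(n_cycles)
    tmin <- (cyc - 1) * cycle_min
    mk_well <- function(well, cond, oxd_traj) {
      oxd_noisy <- pmin(1, pmax(0, oxd_traj + rnorm(n_cycles, 0, noise_sd)))
      Rv <- inverse_oxd(oxd_noisy, R_red, R_ox)
      data.frame(well = well, condition = cond, cycle = cyc,
                 time_min = tmin,
                 F400 = F400_level + bg400, F485 = Rv * F400_level + bg485,
                 stringsAsFactors = FALSE)
    }
    traj_sample <- c(rep(oxd0_true, baseline_cycles),
                     rep(oxd_post, n_cycles - baseline_cycles))
    wells <- lapply(seq_len(n_sample_wells), function(i) {
      mk_well(sprintf("S%02d", i), "sample", traj_sample)
    })
    wells[[length(wells) + 1L]] <- mk_well("RED", "reduced_control",
                                           rep(0, n_cycles))
    wells[[length(wells) + 1L]] <- mk_well("OX", "oxidized_control",
                                           rep(1, n_cycles))
    bg <- data.frame(well = "BG", condition = "background", cycle = cyc,
                     time_min = tmin, F400 = rep(bg400, n_cycles),
                     F485 = rep(bg485, n_cycles), stringsAsFactors = FALSE)
    out <- do.call(rbind, c(wells, list(bg)))
    rownames(out) <- NULL
    attr(out, "truth") <- list(oxd0 = oxd0_true, oxd_post = oxd_post,
                               R_red = R_red, R_ox = R_ox)
    out
  })
}
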