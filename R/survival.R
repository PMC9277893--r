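#' Normalise one replicate's viability into a survival curve
#'
#' Survival is expressed relative to the logarithmic-growth sample (day 0),
#' which is taken as 100% viable: `survival(t) = 100 * f(t) / f(0)`. Values
#' above 100% (measurement noise) are retained and flagged, not clamped —
#' clamping would bias areas downward asymmetrically.
#'
#' @param day observation days; must contain 0 (the log sample).
#' @param fraction viable fractions in `[0, 1]`, one per day.
#' @return `data.frame` with `day` (sorted), `survival_pct` and `flagged`
#'   (TRUE where survival exceeds 100%).
#' @export
normalize_curve <- function(day, fraction) {
  stopifnot(is.numeric(day), is.numeric(fraction),
            length(day) == length(fraction))
  if (anyDuplicated(day)) stopf("duplicate days in one replicate")
  ord <- order(day)
  day <- day[ord]; fraction <- fraction[ord]
  if (day[1] != 0) stopf("no day-0 (log) sample: cannot anchor survival at 100%%")
  f0 <- fraction[1]
  if (!is.finite(f0) || f0 <= 0) {
    stopf("day-0 viable fraction is zero: strain unusable (no growth)")
  }
  surv <- 100 * fraction / f0
  data.frame(day = day, survival_pct = surv, flagged = surv > 100)
}

#' Assemble survival curves from a gated viability table
#'
#' Drops QC-failed samples (they become missing timepoints), then normalises
#' every (strain, plate, well) replicate that retains a usable day-0 point.
#' Replicates without a day-0 point, with day-0 viability of zero, or with
#' fewer than two usable points are excluded and logged.
#'
#' @param viability table from [gate_screen()] (columns `plate`, `well`,
#'   `strain`, `day`, `fraction_viable`, `n_events`, `qc_pass`).
#' @return `data.table` of curves: `strain`, `replicate` (plate:well),
#'   `plate`, `well`, `day`, `survival_pct`, `flagged`; excluded replicates
#'   are attached as attribute `"excluded"` (`strain`, `replicate`,
#'   `reason`).
#' @export
build_curves <- function(viability) {
  viab <- as.data.table(viability)
  need <- c("plate", "well", "strain", "day", "fraction_viable", "qc_pass")
  miss <- setdiff(need, names(viab))
  if (length(miss)) stopf("`viability` lacks column(s): %s", paste(miss, collapse = ", "))
  viab <- viab[qc_pass == TRUE]
  out <- vector("list", 0L)
  excluded <- vector("list", 0L)
  groups <- split(viab, by = c("strain", "plate", "well"), drop = TRUE)
  for (g in groups) {
    rep_id <- paste0(g$plate[1], ":", g$well[1])
    reason <- NULL
    if (!any(g$day == 0)) {
      reason <- "no day-0 sample passed QC"
    } else if (g[day == 0, fraction_viable][1] <= 0) {
      reason <- "no growth (day-0 viability zero)"
    } else if (nrow(g) < 2L) {
      reason <- "fewer than 2 usable timepoints"
    }
    if (!is.null(reason)) {
      excluded[[length(excluded) + 1L]] <- data.table(
        strain = g$strain[1], replicate = rep_id, reason = reason)
      next
    }
    nc <- normalize_curve(g$day, g$fraction_viable)
    out[[length(out) + 1L]] <- data.table(
      strain = g$strain[1], replicate = rep_id,
      plate = g$plate[1], well = g$well[1],
      day = nc$day, survival_pct = nc$survival_pct, flagged = nc$flagged)
  }
  curves <- if (length(out)) rbindlist(out) else
    data.table(strain = character(), replicate = character(),
               plate = integer(), well = character(), day = numeric(),
               survival_pct = numeric(), flagged = logical())
  setorder(curves, strain, plate, well, day)
  setattr(curves, "excluded",
          if (length(excluded)) rbindlist(excluded) else
            data.table(strain = character(), replicate = character(),
                       reason = character()))
  curves[]
}

#' Area under a survival curve
#'
#' Trapezoidal rule over the observed days; the longevity score of the
#' screen, in units of percent x days. Only the observed span is integrated:
#' no days are fabricated for missing timepoints (interior gaps are bridged
#' linearly by the trapezoid itself).
#'
#' @param day observation days (>= 2, strictly increasing after sorting).
#' @param survival survival percentages, one per day.
#' @return Area in % * days.
#' @export
auc <- function(day, survival) {
  stopifnot(is.numeric(day), is.numeric(survival),
            length(day) == length(survival))
  if (length(day) < 2L) stopf("need at least 2 points to integrate")
  ord <- order(day)
  day <- day[ord]; survival <- survival[ord]
  if (any(diff(day) <= 0)) stopf("duplicate days in curve")
  sum(diff(day) * (head(survival, -1L) + tail(survival, -1L)) / 2)
}

#' Longevity areas for every replicate curve
#'
#' @param curves curve table from [build_curves()].
#' @param normalize_span divide each area by its observed span, giving a
#'   per-day mean survival — makes strains with different spans comparable.
#'   Default `FALSE`; a warning is issued if spans differ across replicates.
#' @return `data.table`: `strain`, `replicate`, `area`, `span_start`,
#'   `span_end`.
#' @export
curve_areas <- function(curves, normalize_span = FALSE) {
  curves <- as.data.table(curves)
  need <- c("strain", "replicate", "day", "survival_pct")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stopf("`curves` lacks column(s): %s", paste(miss, collapse = ", "))
  areas <- curves[, .(area = auc(day, survival_pct),
                      span_start = min(day), span_end = max(day)),
                  by = .(strain, replicate)]
  if (normalize_span) {
    areas[, area := area / (span_end - span_start)]
  } else if (length(unique(areas$span_end - areas$span_start)) > 1L) {
    warnf(paste("curves have unequal observed spans; raw areas are not",
                "directly comparable (consider `normalize_span = TRUE`)"))
  }
  areas[]
}

#' Local-regression average survival curve with 95% band
#'
#' Pools the (day, survival) points of all replicates of one strain and fits
#' a locally weighted regression (tricube weights). The pointwise 95% band
#' is `fit +/- 1.96 * SE(fit)`; with identical replicates the band has zero
#' width.
#'
#' @param curves curve table for a single strain with >= 2 replicates.
#' @param span loess span (fraction of points in each local window).
#' @param degree local polynomial degree (1 or 2).
#' @param grid days at which to evaluate the fit; default 81 equally spaced
#'   points over the observed day range.
#' @return `data.frame`: `day`, `fit`, `lower`, `upper`; number of
#'   replicates in attribute `"n_replicates"`.
#' @export
average_curve <- function(curves, span = 0.75, degree = 2, grid = NULL) {
  curves <- as.data.table(curves)
  need <- c("strain", "replicate", "day", "survival_pct")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stopf("`curves` lacks column(s): %s", paste(miss, collapse = ", "))
  if (length(unique(curves$strain)) != 1L) {
    stopf("`average_curve()` expects curves of a single strain")
  }
  n_rep <- length(unique(curves$replicate))
  if (n_rep < 2L) stopf("need >= 2 replicates for an average curve with a band")
  stopifnot(is_number(span), span > 0, degree %in% c(0, 1, 2))
  if (is.null(grid)) {
    grid <- seq(min(curves$day), max(curves$day), length.out = 81L)
  }
  # screens sample few distinct days with many tied replicates; loess then
  # warns about locally singular quadratic designs it resolves by
  # pseudoinverse — expected here, so those numerics notices are muffled
  muffle <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("pseudoinverse|singularit|neighborhood radius|condition number",
              conditionMessage(w))) invokeRestart("muffleWarning")
  })
  fit <- muffle(loess(survival_pct ~ day, data = curves, span = span,
                      degree = degree, family = "gaussian"))
  pr <- muffle(predict(fit, newdata = data.frame(day = grid), se = TRUE))
  se <- pr$se.fit
  se[!is.finite(se)] <- 0
  out <- data.frame(day = grid, fit = as.numeric(pr$fit),
                    lower = as.numeric(pr$fit) - 1.96 * se,
                    upper = as.numeric(pr$fit) + 1.96 * se)
  attr(out, "n_replicates") <- n_rep
  out
}

#' Apply the screen's strain-exclusion rules
#'
#' Strains that never grew or never regrew in stationary phase are removed
#' before classification: a strain is excluded when it has no day-0 sample
#' with positive viability passing QC ("no growth"), when all of its
#' post-day-0 samples failed QC ("no stationary-phase data"), or when it is
#' flagged by the caller (e.g. external regrowth checks).
#'
#' @param viability gated viability table from [gate_screen()].
#' @param growth_flags optional data.frame (`strain`, `reason`) of strains
#'   to exclude for reasons outside the table (e.g. no regrowth on spots).
#' @return List: `retained` (character vector of strains) and `excluded`
#'   (`data.table`: `strain`, `reason`).
#' @export
exclude_strains <- function(viability, growth_flags = NULL) {
  viab <- as.data.table(viability)
  need <- c("strain", "day", "fraction_viable", "qc_pass")
  miss <- setdiff(need, names(viab))
  if (length(miss)) stopf("`viability` lacks column(s): %s", paste(miss, collapse = ", "))
  excl <- vector("list", 0L)
  if (!is.null(growth_flags)) {
    gf <- as.data.frame(growth_flags)
    stopifnot(all(c("strain", "reason") %in% names(gf)))
    excl[[length(excl) + 1L]] <- data.table(strain = as.character(gf$strain),
                                            reason = as.character(gf$reason))
  }
  by_strain <- viab[, .(
    has_growth = any(day == 0 & qc_pass & fraction_viable > 0),
    has_stationary = any(day > 0 & qc_pass)
  ), by = strain]
  ng <- by_strain[has_growth == FALSE, strain]
  if (length(ng)) excl[[length(excl) + 1L]] <-
    data.table(strain = ng, reason = "no growth")
  ns <- by_strain[has_growth == TRUE & has_stationary == FALSE, strain]
  if (length(ns)) excl[[length(excl) + 1L]] <-
    data.table(strain = ns, reason = "no stationary-phase data")
  excluded <- if (length(excl)) unique(rbindlist(excl), by = "strain") else
    data.table(strain = character(), reason = character())
  list(retained = setdiff(unique(viab$strain), excluded$strain),
       excluded = excluded)
}
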