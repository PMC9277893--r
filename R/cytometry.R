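#' Estimate a PI gating threshold
#'
#' Separates PI-negative (live) from PI-positive (dead) events. The default
#' method applies Otsu's criterion — maximising between-class variance — to a
#' histogram of log10 intensities pooled across samples, which keeps fully
#' dead or fully live samples (a single population) gateable under a shared
#' plate-batch threshold. A user-supplied fixed threshold bypasses
#' estimation.
#'
#' @param intensities positive PI intensities (linear a.u.), pooled over the
#'   samples to be gated.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param value the threshold to echo back when `method = "fixed"`.
#' @param bins histogram bin count for the Otsu scan.
#' @return Threshold in linear intensity units, strictly between the minimum
#'   and maximum observed intensity (for `"otsu"`).
#' @export
gate_threshold <- function(intensities, method = c("otsu", "fixed"),
                           value = NULL, bins = 512L) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (!is_number(value) || value <= 0) {
      stopf("`value` must be a positive number when method = \"fixed\"")
    }
    return(value)
  }
  stopifnot(is.numeric(intensities), length(intensities) >= 2L)
  if (any(!is.finite(intensities)) || any(intensities <= 0)) {
    stopf("intensities must be positive and finite (log10 gating domain)")
  }
  x <- log10(intensities)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stopf("constant intensities: no separable populations to gate")
  }
  stopifnot(is_count(bins, min = 2))
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  mids <- (head(br, -1L) + tail(br, -1L)) / 2
  n <- sum(cnt)
  w <- cumsum(cnt) / n               # class-0 weight up to split t
  mu <- cumsum(cnt * mids) / n       # unnormalised class-0 mean
  mu_t <- mu[bins]
  ok <- w > 0 & w < 1
  # between-class variance at each candidate split (cut after bin t)
  sigma_b <- rep(-Inf, bins)
  sigma_b[ok] <- (mu_t * w[ok] - mu[ok])^2 / (w[ok] * (1 - w[ok]))
  t_best <- which.max(sigma_b)
  10^br[t_best + 1L]
}

#' Viable fraction of one event sample
#'
#' The proportion of events with PI intensity strictly below the gating
#' threshold: PI only stains cells with compromised membranes, so sub-gate
#' events are counted as viable.
#'
#' @param intensities PI intensities of one sample (linear a.u.).
#' @param threshold gating threshold (finite).
#' @return Proportion in `[0, 1]`.
#' @export
fraction_viable <- function(intensities, threshold) {
  if (length(intensities) == 0L) stopf("empty sample: no events to gate")
  stopifnot(is.numeric(intensities))
  if (!is_number(threshold)) stopf("`threshold` must be a finite number")
  mean(intensities < threshold)
}

#' Sample-level QC on event count
#'
#' Flags samples that recorded fewer events than required; failing samples
#' propagate downstream as missing timepoints (never as imputed zeros).
#'
#' @param n_events events recorded for the sample.
#' @param min_events minimum acceptable event count.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_sample <- function(n_events, min_events) {
  stopifnot(is.numeric(n_events), is_number(min_events))
  n_events >= min_events
}

#' Gate a whole screen's event table
#'
#' Estimates (or accepts) a global gating threshold, then computes the
#' per-sample viable fraction and QC flag for every (plate, well, strain,
#' day) sample in a long-format event table.
#'
#' @param events `data.table`/data.frame with columns `plate`, `well`,
#'   `strain`, `day`, `pi_intensity` (e.g. from [simulate_screen()] or
#'   [read_events_tsv()]).
#' @param threshold `"auto"` for a pooled Otsu threshold, or a fixed
#'   numeric value.
#' @param min_events QC minimum event count per sample.
#' @param bins histogram bins for the Otsu scan.
#' @return `data.table` with one row per sample: `plate`, `well`, `strain`,
#'   `day`, `fraction_viable`, `n_events`, `qc_pass`; the threshold used is
#'   attached as attribute `"threshold"`.
#' @export
gate_screen <- function(events, threshold = "auto", min_events = 1000L,
                        bins = 512L) {
  events <- as.data.table(events)
  need <- c("plate", "well", "strain", "day", "pi_intensity")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("`events` lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(events) == 0L) stopf("empty event table")
  thr <- if (identical(threshold, "auto")) {
    gate_threshold(events$pi_intensity, bins = bins)
  } else {
    gate_threshold(events$pi_intensity, method = "fixed", value = threshold)
  }
  viab <- events[, .(fraction_viable = mean(pi_intensity < thr),
                     n_events = .N),
                 by = .(plate, well, strain, day)]
  viab[, qc_pass := qc_sample(n_events, min_events)]
  setattr(viab, "threshold", thr)
  viab[]
}
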