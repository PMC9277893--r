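# Long-format TSV interchange for every pipeline stage (data.table fast
# readers/writers; events files can run to tens of millions of rows).

EVENT_COLS <- c("plate", "well", "strain", "day", "event_index", "pi_intensity")

#' Write / read event tables
#'
#' Long-format TSV with header `plate`, `well`, `strain`, `day`,
#' `event_index`, `pi_intensity`. Non-positive intensities are rejected at
#' parse time (the gate operates on log10 intensity).
#'
#' @param events event table (e.g. `simulate_screen()$events`).
#' @param path file path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns a `data.table`.
#' @export
write_events_tsv <- function(events, path) {
  events <- as.data.table(events)
  miss <- setdiff(EVENT_COLS, names(events))
  if (length(miss)) stopf("`events` lacks column(s): %s", paste(miss, collapse = ", "))
  fwrite(events[, ..EVENT_COLS], path, sep = "\t")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- fread(path, sep = "\t")
  miss <- setdiff(EVENT_COLS, names(ev))
  if (length(miss)) stopf("event file lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(ev$pi_intensity)) || any(ev$pi_intensity <= 0)) {
    stopf("event file contains non-positive PI intensities (rejected: log gating domain)")
  }
  ev
}

#' Write / read ground-truth tables
#'
#' TSV with one row per simulated replicate: `strain`, `archetype`,
#' `plate`, `well`, `tau_r`.
#'
#' @param truth truth table (`simulate_screen()$truth`).
#' @param path file path.
#' @return `write_truth_tsv()` returns `path` invisibly;
#'   `read_truth_tsv()` a `data.table`.
#' @export
write_truth_tsv <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) fread(path, sep = "\t")

#' Write / read per-sample viability tables
#'
#' TSV with columns `plate`, `well`, `strain`, `day`, `fraction_viable`,
#' `n_events`, `qc_pass` (the [gate_screen()] output).
#'
#' @param viability viability table.
#' @param path file path.
#' @return `write_viability_tsv()` returns `path` invisibly;
#'   `read_viability_tsv()` a `data.table`.
#' @export
write_viability_tsv <- function(viability, path) {
  fwrite(as.data.table(viability), path, sep = "\t")
  invisible(path)
}

#' @rdname write_viability_tsv
#' @export
read_viability_tsv <- function(path) fread(path, sep = "\t")

#' Write survival-curve and area tables
#'
#' Curves: `strain`, `replicate`, `day`, `survival_pct` (+ `flagged`).
#' Areas: `strain`, `replicate`, `area`, `span_start`, `span_end`.
#'
#' @param curves,areas tables from [build_curves()] / [curve_areas()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curves_tsv <- function(curves, path) {
  fwrite(as.data.table(curves), path, sep = "\t")
  invisible(path)
}

#' @rdname write_curves_tsv
#' @export
write_areas_tsv <- function(areas, path) {
  fwrite(as.data.table(areas), path, sep = "\t")
  invisible(path)
}
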