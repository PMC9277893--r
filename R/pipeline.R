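#' Run the full screen pipeline on an event table
#'
#' Gate -> exclude -> curves -> areas -> control fit -> classify, the
#' standard analysis path from a long-format event table (real or
#' simulated) to per-strain longevity calls.
#'
#' @param events event table (`plate`, `well`, `strain`, `day`,
#'   `pi_intensity`).
#' @param controls named character vector mapping class labels to the
#'   control strain names present on every plate.
#' @param threshold `"auto"` (pooled Otsu) or a fixed numeric gate.
#' @param min_events per-sample QC minimum (default: a tenth of the median
#'   recorded event count).
#' @param priors prior class probabilities (default equal).
#' @param form classification likelihood form, see [class_likelihood()].
#' @param growth_flags optional externally flagged strains, see
#'   [exclude_strains()].
#' @return List of class `"cls_screen_result"`: `threshold`, `viability`,
#'   `excluded`, `curves`, `areas`, `controls` (fitted
#'   [control_distribution()]s), `classification`, `counts`.
#' @export
screen_pipeline <- function(events, controls = c(average = "666",
                                                 short_lived = "sty1d",
                                                 long_lived = "pka1d"),
                            threshold = "auto", min_events = NULL,
                            priors = NULL, form = "t",
                            growth_flags = NULL) {
  events <- as.data.table(events)
  if (is.null(min_events)) {
    med <- stats::median(events[, .N, by = .(plate, well, day)]$N)
    min_events <- max(1, floor(med / 10))
  }
  viab <- gate_screen(events, threshold = threshold, min_events = min_events)
  thr <- attr(viab, "threshold")
  excl <- exclude_strains(viab, growth_flags = growth_flags)
  curves <- build_curves(viab[strain %in% excl$retained])
  rep_excl <- attr(curves, "excluded")
  areas <- curve_areas(curves)
  ctrl_areas <- areas[strain %in% controls]
  if (nrow(ctrl_areas) == 0L) stopf("no control strain areas found")
  lab_of <- setNames(names(controls), controls)
  dists <- fit_controls(ctrl_areas$area, lab_of[ctrl_areas$strain],
                        classes = names(controls))
  mut_areas <- areas[!strain %in% controls]
  classification <- if (nrow(mut_areas)) {
    classify_screen(mut_areas, dists, priors = priors, form = form)
  } else NULL
  structure(
    list(threshold = thr, viability = viab, excluded = excl$excluded,
         replicate_exclusions = rep_excl, curves = curves, areas = areas,
         controls = dists, classification = classification,
         counts = if (!is.null(classification)) attr(classification, "counts")),
    class = "cls_screen_result"
  )
}

#' @export
print.cls_screen_result <- function(x, ...) {
  cat("<cls_screen_result>\n")
  cat(sprintf("  gate threshold: %.1f a.u.\n", x$threshold))
  cat(sprintf("  samples gated: %d (%d strains excluded)\n",
              nrow(x$viability), nrow(x$excluded)))
  for (d in x$controls) {
    cat(sprintf("  control %-12s n = %d, area %.1f +/- %.1f %%*days\n",
                d$label, d$n, d$mean, d$sd))
  }
  if (!is.null(x$counts)) {
    cat("  classified mutants:",
        paste(sprintf("%s = %d", names(x$counts), x$counts), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Compare screen calls with simulation ground truth
#'
#' @param classification classification table from [classify_screen()] (or
#'   a `cls_screen_result`).
#' @param truth truth table from [simulate_screen()] (`strain`,
#'   `archetype`).
#' @return List: `confusion` (truth x called contingency table over mutant
#'   strains), `recovery` (fraction of strains whose call matches their
#'   archetype), `n`.
#' @export
label_recovery <- function(classification, truth) {
  if (inherits(classification, "cls_screen_result")) {
    classification <- classification$classification
  }
  cls <- as.data.table(classification)
  tr <- unique(as.data.table(truth)[, .(strain, archetype)])
  m <- merge(cls[, .(strain, label)], tr, by = "strain")
  if (nrow(m) == 0L) stopf("no strains shared between classification and truth")
  lev <- union(unique(m$archetype), unique(m$label))
  conf <- table(truth = factor(m$archetype, lev), called = factor(m$label, lev))
  list(confusion = conf, recovery = base::mean(m$archetype == m$label),
       n = nrow(m))
}

#' Plot average survival curves per strain
#'
#' Convenience ggplot of local-regression average curves with their 95%
#' bands, one colour per strain (requires ggplot2).
#'
#' @param curves curve table from [build_curves()] covering one or more
#'   strains with >= 2 replicates each.
#' @param span,degree smoothing parameters passed to [average_curve()].
#' @return A ggplot object.
#' @export
plot_average_curves <- function(curves, span = 0.75, degree = 2) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_average_curves() requires the ggplot2 package")
  }
  curves <- as.data.table(curves)
  strains <- unique(curves$strain)
  fits <- rbindlist(lapply(strains, function(s) {
    av <- average_curve(curves[strain == s], span = span, degree = degree)
    data.table(strain = s, av)
  }))
  ggplot2::ggplot(fits, ggplot2::aes(x = day, y = fit, colour = strain,
                                     fill = strain)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Days in stationary phase", y = "Survival (%)") +
    ggplot2::theme_minimal()
}
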