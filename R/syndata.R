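#' Strain archetype for synthetic survival decay
#'
#' An archetype describes how one longevity class loses viability during
#' stationary phase. True viability follows a Weibull decay
#' \deqn{v(t) = \exp(-(t/\tau_r)^k)}
#' with realised time-scale \eqn{\tau_r = \tau \exp(\epsilon_{plate} +
#' \epsilon_{rep})}; plate and replicate effects act multiplicatively on the
#' time-scale so viability stays in `[0, 1]` by construction.
#'
#' @param label class label, e.g. `"average"`, `"short_lived"`,
#'   `"long_lived"`, or any custom name.
#' @param tau survival time-scale in days (> 0); the day at which viability
#'   has dropped to `exp(-1)` for a noise-free replicate.
#' @param k_shape Weibull shape (> 0); values > 1 give a shoulder followed by
#'   accelerating death, values < 1 a fast early decline.
#' @param plate_sd standard deviation of the plate effect on `log(tau)`.
#' @param rep_sd standard deviation of the replicate (well) effect on
#'   `log(tau)`.
#' @return An object of class `"archetype_spec"`.
#' @seealso [control_archetypes()], [simulate_viability()]
#' @export
archetype_spec <- function(label, tau, k_shape = 1.6, plate_sd = 0.02,
                           rep_sd = 0.05) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is_number(tau) || tau <= 0) stopf("`tau` must be a positive number")
  if (!is_number(k_shape) || k_shape <= 0) {
    stopf("`k_shape` must be a positive number")
  }
  if (!is_number(plate_sd) || plate_sd < 0) stopf("`plate_sd` must be >= 0")
  if (!is_number(rep_sd) || rep_sd < 0) stopf("`rep_sd` must be >= 0")
  structure(
    list(label = label, tau = tau, k_shape = k_shape,
         plate_sd = plate_sd, rep_sd = rep_sd),
    class = "archetype_spec"
  )
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<archetype '%s'> tau = %g d, shape = %g, plate_sd = %g, rep_sd = %g\n",
              x$label, x$tau, x$k_shape, x$plate_sd, x$rep_sd))
  invisible(x)
}

#' Default control-strain archetypes
#'
#' The three reference longevity classes carried on every plate of the
#' screen: an average-lifespan wild type, a short-lived mutant and a
#' long-lived mutant (in the real screen: strain 666, sty1-del and pka1-del).
#' Default time-scales were chosen so the three classes produce clearly
#' separated area-under-curve distributions on the day {0, 2, 4, 6, 8}
#' sampling grid, mimicking control survival curves that are distinguishable
#' by eye.
#'
#' @param tau_average,tau_short,tau_long Weibull time-scales (days) for the
#'   three classes.
#' @param k_shape shared Weibull shape.
#' @param plate_sd,rep_sd shared noise scales on `log(tau)`.
#' @return Named list of three [archetype_spec()] objects with names
#'   `average`, `short_lived`, `long_lived`.
#' @export
control_archetypes <- function(tau_average = 4.5, tau_short = 2.2,
                               tau_long = 8.5, k_shape = 1.6,
                               plate_sd = 0.02, rep_sd = 0.05) {
  list(
    average     = archetype_spec("average", tau_average, k_shape, plate_sd, rep_sd),
    short_lived = archetype_spec("short_lived", tau_short, k_shape, plate_sd, rep_sd),
    long_lived  = archetype_spec("long_lived", tau_long, k_shape, plate_sd, rep_sd)
  )
}

#' PI fluorescence intensity model
#'
#' Two-component log-normal model of propidium-iodide fluorescence on a
#' PE-A-like channel: PI-negative (live, membrane-intact) events form a dim
#' component and PI-positive (dead, permeable) events a bright one.
#' Locations and scales are given on the log10-intensity axis; emitted
#' intensities are in linear arbitrary units.
#'
#' @param live_mu,live_sigma log10-intensity location/scale of live events.
#' @param dead_mu,dead_sigma log10-intensity location/scale of dead events;
#'   `dead_mu` must exceed `live_mu`.
#' @return An object of class `"fluor_model"`.
#' @export
fluor_model <- function(live_mu = 2.0, live_sigma = 0.25,
                        dead_mu = 3.5, dead_sigma = 0.3) {
  stopifnot(is_number(live_mu), is_number(dead_mu),
            is_number(live_sigma), is_number(dead_sigma))
  if (dead_mu <= live_mu) stopf("`dead_mu` must exceed `live_mu`")
  if (live_sigma <= 0 || dead_sigma <= 0) stopf("sigmas must be positive")
  structure(
    list(live_mu = live_mu, live_sigma = live_sigma,
         dead_mu = dead_mu, dead_sigma = dead_sigma),
    class = "fluor_model"
  )
}

#' Screen design
#'
#' Sampling design of a (synthetic) CLS screen: the day grid, the number of
#' flow-cytometry events recorded per sample, and the plate layout. Day 0 is
#' the logarithmic-growth sample that anchors survival at 100%; the real
#' screen sampled days 2, 4, 6 and 8 of stationary phase at 10,000 events
#' per sample and carried the three control strains on every 96-well plate.
#'
#' @param timepoints strictly increasing day grid; first element must be 0
#'   (the log sample).
#' @param events_per_sample events recorded per well and timepoint (>= 1).
#' @param plates number of plates.
#' @param wells_per_plate wells per plate (>= number of controls).
#' @param seed master seed; all simulation randomness derives from it via
#'   [substream_seed()].
#' @param controls named character vector mapping archetype labels to control
#'   strain names; every plate carries one well per control.
#' @return An object of class `"screen_design"`.
#' @export
screen_design <- function(timepoints = c(0, 2, 4, 6, 8),
                          events_per_sample = 10000,
                          plates = 1L, wells_per_plate = 96L, seed = 1L,
                          controls = c(average = "666",
                                       short_lived = "sty1d",
                                       long_lived = "pka1d")) {
  if (length(timepoints) < 2L || timepoints[1] != 0) {
    stopf("`timepoints` must start at day 0 (the log sample)")
  }
  if (any(diff(timepoints) <= 0)) stopf("`timepoints` must be strictly increasing")
  if (!is_count(events_per_sample)) stopf("`events_per_sample` must be >= 1")
  if (!is_count(plates)) stopf("`plates` must be a positive integer")
  if (!is_count(wells_per_plate, min = length(controls))) {
    stopf("`wells_per_plate` must fit at least the %d control wells",
          length(controls))
  }
  if (is.null(names(controls)) || any(!nzchar(names(controls))) ||
      anyDuplicated(names(controls)) || anyDuplicated(controls)) {
    stopf("`controls` must be uniquely named archetype -> strain mapping")
  }
  if (!is_number(seed) || seed != floor(seed)) stopf("`seed` must be an integer")
  structure(
    list(timepoints = as.numeric(timepoints),
         events_per_sample = as.integer(events_per_sample),
         plates = as.integer(plates),
         wells_per_plate = as.integer(wells_per_plate),
         seed = as.integer(seed),
         controls = controls),
    class = "screen_design"
  )
}

#' Noise-free Weibull survival
#'
#' @param t days (vector).
#' @param tau time-scale in days (> 0).
#' @param k_shape Weibull shape (> 0).
#' @return Viability in `[0, 1]` at each `t`.
#' @export
weibull_survival <- function(t, tau, k_shape) {
  if (!is_number(tau) || tau <= 0) stopf("`tau` must be a positive number")
  if (!is_number(k_shape) || k_shape <= 0) stopf("`k_shape` must be positive")
  stopifnot(is.numeric(t), all(t >= 0))
  exp(-(t / tau)^k_shape)
}

#' Simulate one replicate's true viability trajectory
#'
#' Draws the plate and replicate effects for one well from their dedicated
#' sub-streams of the design's master seed and evaluates the Weibull decay
#' on the design's day grid. The plate-level standard normal draw is shared
#' by all wells of a plate (each archetype scales it by its own `plate_sd`),
#' so strains co-housed on a plate experience a common plate shift.
#'
#' @param arch an [archetype_spec()].
#' @param design a [screen_design()].
#' @param plate plate index (>= 1).
#' @param replicate replicate (well) index within the plate (>= 1).
#' @return List with `day`, `viability` (same length) and `tau_r`, the
#'   realised time-scale.
#' @export
simulate_viability <- function(arch, design, plate = 1L, replicate = 1L) {
  stopifnot(inherits(arch, "archetype_spec"), inherits(design, "screen_design"),
            is_count(plate), is_count(replicate))
  z <- plate_rep_effects(design$seed, plate, replicate)
  tau_r <- arch$tau * exp(arch$plate_sd * z$z_plate + arch$rep_sd * z$z_rep)
  list(day = design$timepoints,
       viability = weibull_survival(design$timepoints, tau_r, arch$k_shape),
       tau_r = tau_r)
}

# shared standard-normal draws for plate and replicate effects
plate_rep_effects <- function(seed, plate, replicate) {
  with_preserved_rng({
    set.seed(substream_seed(seed, 101L, plate))
    z_plate <- rnorm(1)
    set.seed(substream_seed(seed, 202L, plate, replicate))
    z_rep <- rnorm(1)
    list(z_plate = z_plate, z_rep = z_rep)
  })
}

#' Emit flow-cytometry events for one sample
#'
#' Given a true viability, draws the number of dead events from
#' `Binomial(n_events, 1 - v)` and the PI intensities of live and dead
#' events from the two log-normal components of the fluorescence model.
#'
#' @param v true viability in `[0, 1]`.
#' @param fluor a [fluor_model()].
#' @param n_events number of events to emit.
#' @param seed optional seed applied before drawing (caller RNG preserved).
#' @return `data.table` with `n_events` rows: `event_index`, `pi_intensity`
#'   (linear a.u.) and `component` (`"live"`/`"dead"`, the ground truth).
#' @export
emit_events <- function(v, fluor, n_events, seed = NULL) {
  if (!is_number(v) || v < 0 || v > 1) stopf("`v` must lie in [0, 1]")
  stopifnot(inherits(fluor, "fluor_model"), is_count(n_events))
  draw <- function() {
    n_dead <- rbinom(1L, n_events, 1 - v)
    n_live <- n_events - n_dead
    data.table(
      event_index = seq_len(n_events),
      pi_intensity = c(10^rnorm(n_live, fluor$live_mu, fluor$live_sigma),
                       10^rnorm(n_dead, fluor$dead_mu, fluor$dead_sigma)),
      component = rep(c("live", "dead"), c(n_live, n_dead))
    )
  }
  if (is.null(seed)) draw() else with_preserved_rng({ set.seed(seed); draw() })
}

#' Simulate a full CLS screen with known ground truth
#'
#' Lays out the control strains (first wells of every plate) and the mutant
#' strains (filling the remaining wells plate by plate, one replicate per
#' mutant, controls replicated once per plate), simulates each well's true
#' Weibull survival trajectory, and emits PI-intensity events for every
#' well x timepoint. All randomness derives from per-(plate, well,
#' timepoint) sub-streams of `design$seed`, so results are reproducible and
#' stable under design extension.
#'
#' @param design a [screen_design()].
#' @param strain_map named character vector: mutant strain name ->
#'   archetype label (must exist in `archetypes`). `NULL` simulates a
#'   controls-only screen.
#' @param archetypes named list of [archetype_spec()] covering the control
#'   labels (names of `design$controls`) and every label used in
#'   `strain_map`.
#' @param fluor a [fluor_model()].
#' @param keep_component keep the per-event live/dead ground-truth column
#'   (memory-costly on large screens).
#' @return List of class `"cls_screen_sim"`: `events` (data.table: plate,
#'   well, strain, day, event_index, pi_intensity[, component]), `truth`
#'   (strain, archetype, plate, well, tau_r — one row per replicate),
#'   `truth_curves` (strain, plate, well, day, viability), and `design`.
#' @export
simulate_screen <- function(design, strain_map = NULL,
                            archetypes = control_archetypes(),
                            fluor = fluor_model(),
                            keep_component = FALSE) {
  stopifnot(inherits(design, "screen_design"), inherits(fluor, "fluor_model"))
  ctrl_labels <- names(design$controls)
  need <- unique(c(ctrl_labels, unname(strain_map)))
  missing_arch <- setdiff(need, names(archetypes))
  if (length(missing_arch)) {
    stopf("no archetype defined for label(s): %s",
          paste(missing_arch, collapse = ", "))
  }
  mutants <- names(strain_map)
  if (!is.null(strain_map)) {
    if (is.null(mutants) || any(!nzchar(mutants))) {
      stopf("`strain_map` must be a named character vector (strain -> label)")
    }
    if (anyDuplicated(mutants)) {
      stopf("duplicate strain in plate layout: %s",
            paste(unique(mutants[duplicated(mutants)]), collapse = ", "))
    }
    clash <- intersect(mutants, design$controls)
    if (length(clash)) {
      stopf("strain(s) %s collide with control strain names",
            paste(clash, collapse = ", "))
    }
  }
  n_ctrl <- length(design$controls)
  slots <- design$wells_per_plate - n_ctrl
  if (length(mutants) > slots * design$plates) {
    stopf("%d mutants do not fit %d plates x %d free wells",
          length(mutants), design$plates, slots)
  }
  wells <- well_ids(design$wells_per_plate)
  days <- design$timepoints

  events_list <- vector("list", 0L)
  truth_list <- vector("list", 0L)
  curve_list <- vector("list", 0L)
  for (p in seq_len(design$plates)) {
    mut_idx <- seq.int(from = (p - 1L) * slots + 1L,
                       length.out = min(slots, max(0L, length(mutants) - (p - 1L) * slots)))
    plate_strains <- c(unname(design$controls),
                       if (length(mut_idx)) mutants[mut_idx])
    plate_labels <- c(ctrl_labels,
                      if (length(mut_idx)) unname(strain_map[mut_idx]))
    for (w in seq_along(plate_strains)) {
      arch <- archetypes[[plate_labels[w]]]
      traj <- simulate_viability(arch, design, plate = p, replicate = w)
      truth_list[[length(truth_list) + 1L]] <- data.table(
        strain = plate_strains[w], archetype = plate_labels[w],
        plate = p, well = wells[w], tau_r = traj$tau_r
      )
      curve_list[[length(curve_list) + 1L]] <- data.table(
        strain = plate_strains[w], plate = p, well = wells[w],
        day = days, viability = traj$viability
      )
      for (ti in seq_along(days)) {
        es <- emit_events(traj$viability[ti], fluor, design$events_per_sample,
                          seed = substream_seed(design$seed, 303L, p, w, ti))
        if (!keep_component) es[, component := NULL]
        es[, `:=`(plate = p, well = wells[w], strain = plate_strains[w],
                  day = days[ti])]
        events_list[[length(events_list) + 1L]] <- es
      }
    }
  }
  events <- rbindlist(events_list)
  first_cols <- c("plate", "well", "strain", "day", "event_index", "pi_intensity")
  setcolorder(events, c(first_cols, setdiff(names(events), first_cols)))
  structure(
    list(events = events,
         truth = rbindlist(truth_list),
         truth_curves = rbindlist(curve_list),
         design = design),
    class = "cls_screen_sim"
  )
}

#' @export
print.cls_screen_sim <- function(x, ...) {
  cat(sprintf(
    "<cls_screen_sim> %d plates x %d wells, days {%s}, %s events (%d strains)\n",
    x$design$plates, x$design$wells_per_plate,
    paste(x$design$timepoints, collapse = ", "),
    format(nrow(x$events), big.mark = ","),
    length(unique(x$truth$strain))
  ))
  invisible(x)
}
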