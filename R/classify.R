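CLASS_LABELS <- c("average", "short_lived", "long_lived")

#' Control-strain area distribution
#'
#' Summary of the area-under-curve distribution of one control class, used
#' as the reference for posterior classification. The class-conditional
#' likelihood of a new area is the Bayesian predictive density for a fresh
#' observation from a normal population with unknown mean and variance: a
#' location-scale Student-t with `df = n - 1`, location `mean` and scale
#' `sd * sqrt(1 + 1/n)`.
#'
#' @param label one of `"average"`, `"short_lived"`, `"long_lived"` (or a
#'   custom class name).
#' @param n number of control replicates (>= 2).
#' @param mean sample mean area (% * days).
#' @param sd sample standard deviation of the areas (> 0, n - 1 denominator).
#' @return Object of class `"control_distribution"` with fields `label`,
#'   `n`, `mean`, `sd`, `df`.
#' @export
control_distribution <- function(label, n, mean, sd) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is_count(n, min = 2)) stopf("`n` must be an integer >= 2")
  if (!is_number(mean)) stopf("`mean` must be finite")
  if (!is_number(sd) || sd <= 0) {
    stopf("`sd` must be positive: degenerate control distribution")
  }
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd,
                 df = as.integer(n) - 1L),
            class = "control_distribution")
}

#' @export
print.control_distribution <- function(x, ...) {
  cat(sprintf("<control '%s'> n = %d, mean = %.1f, sd = %.2f (df = %d)\n",
              x$label, x$n, x$mean, x$sd, x$df))
  invisible(x)
}

#' Fit the three control area distributions
#'
#' Computes the sample mean and standard deviation (n - 1 denominator) of
#' the replicate areas of each control class.
#'
#' @param areas numeric vector of control areas.
#' @param labels class label per area; every class in `classes` must appear
#'   with >= 2 replicates and non-zero spread.
#' @param classes the class labels to fit (default the three screen
#'   classes).
#' @return Named list of [control_distribution()] objects, in `classes`
#'   order.
#' @export
fit_controls <- function(areas, labels, classes = CLASS_LABELS) {
  stopifnot(is.numeric(areas), length(areas) == length(labels))
  labels <- as.character(labels)
  miss <- setdiff(classes, unique(labels))
  if (length(miss)) stopf("no areas for class(es): %s", paste(miss, collapse = ", "))
  out <- lapply(classes, function(cl) {
    a <- areas[labels == cl]
    if (length(a) < 2L) stopf("class '%s' has fewer than 2 replicate areas", cl)
    s <- sd(a)
    if (!is.finite(s) || s == 0) {
      stopf("class '%s' has zero spread: degenerate distribution", cl)
    }
    control_distribution(cl, length(a), base::mean(a), s)
  })
  setNames(out, classes)
}

#' Class-conditional likelihood of an area
#'
#' Evaluates the predictive density of a control class at the given area(s).
#' The default Student-t predictive (df = n - 1, location = mean, scale =
#' sd * sqrt(1 + 1/n)) accounts for the finite control sample; the
#' `"normal"` form is a plain Gaussian with the fitted mean and sd, kept for
#' sensitivity analysis.
#'
#' @param area numeric vector of areas (% * days).
#' @param dist a [control_distribution()].
#' @param log return log-density.
#' @param form `"t"` (default) or `"normal"`.
#' @return Density (or log-density) values, strictly positive for finite
#'   input.
#' @export
class_likelihood <- function(area, dist, log = FALSE, form = c("t", "normal")) {
  stopifnot(inherits(dist, "control_distribution"), is.numeric(area))
  form <- match.arg(form)
  if (form == "t") {
    scale <- dist$sd * sqrt(1 + 1 / dist$n)
    ld <- stats::dt((area - dist$mean) / scale, df = dist$df, log = TRUE) -
      base::log(scale)
  } else {
    ld <- stats::dnorm(area, dist$mean, dist$sd, log = TRUE)
  }
  if (log) ld else exp(ld)
}

#' Posterior class membership of areas
#'
#' Combines the class-conditional predictive likelihoods with prior class
#' probabilities (equal by default) and normalises:
#' `posterior_k = prior_k * L_k / sum_j prior_j * L_j`. All density work is
#' done in log space, so extreme areas far outside every control
#' distribution still classify stably. Each area is assigned the label with
#' maximal posterior; when the top two posteriors differ by less than
#' `tie_epsilon` the call is flagged ambiguous and conservatively assigned
#' to the first class in `dists` (by default `"average"`, i.e. not a hit).
#'
#' @param area numeric vector of areas.
#' @param dists named list of [control_distribution()] objects (classes in
#'   decision order; first = conservative fallback).
#' @param priors prior probabilities, same length/order as `dists`;
#'   non-negative, summing to 1.
#' @param form likelihood form, see [class_likelihood()].
#' @param tie_epsilon posterior gap below which a call is ambiguous.
#' @return `data.frame`: `area`, one `p_<label>` column per class, `label`,
#'   `ambiguous`.
#' @export
posterior_class <- function(area, dists, priors = NULL, form = "t",
                            tie_epsilon = 1e-6) {
  stopifnot(is.numeric(area), length(area) >= 1L, is.list(dists))
  lapply(dists, function(d) stopifnot(inherits(d, "control_distribution")))
  k <- length(dists)
  labels <- vapply(dists, `[[`, "", "label")
  if (is.null(priors)) priors <- rep(1 / k, k)
  stopifnot(length(priors) == k)
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
    stopf("`priors` must be non-negative and sum to 1")
  }
  ll <- vapply(dists, function(d) class_likelihood(area, d, log = TRUE, form = form),
               numeric(length(area)))
  ll <- matrix(ll, nrow = length(area), ncol = k)
  lp <- sweep(ll, 2L, base::log(priors), `+`)
  mx <- apply(lp, 1L, max)
  if (any(!is.finite(mx))) {
    stopf("posterior degenerate: all classes have zero prior x likelihood")
  }
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  ord <- t(apply(post, 1L, sort, decreasing = TRUE))
  gap <- ord[, 1L] - ord[, 2L]
  ambiguous <- gap < tie_epsilon
  idx <- max.col(post, ties.method = "first")
  idx[ambiguous] <- 1L
  out <- data.frame(area = area, post, labels[idx], ambiguous,
                    stringsAsFactors = FALSE)
  names(out) <- c("area", paste0("p_", labels), "label", "ambiguous")
  rownames(out) <- NULL
  out
}

#' Classify every strain of a screen
#'
#' Summarises each strain's replicate areas by their mean (the screen
#' classifies one area per mutant), evaluates its posterior over the control
#' classes and assigns the maximum-posterior label. A `per_replicate` mode
#' classifies each replicate separately and takes a majority vote (posterior
#' means break ties), logged as non-default.
#'
#' @param areas area table from [curve_areas()] (columns `strain`,
#'   `replicate`, `area`).
#' @param dists named list of [control_distribution()]s, see
#'   [posterior_class()].
#' @param priors prior probabilities (default equal).
#' @param form likelihood form, see [class_likelihood()].
#' @param tie_epsilon ambiguity threshold on the posterior gap.
#' @param per_replicate majority-vote over per-replicate calls instead of
#'   classifying the mean area.
#' @return `data.table`: `strain`, `n_reps`, `area_mean`, one `p_<label>`
#'   column per class, `label`, `ambiguous`; class counts in attribute
#'   `"counts"`.
#' @export
classify_screen <- function(areas, dists, priors = NULL, form = "t",
                            tie_epsilon = 1e-6, per_replicate = FALSE) {
  areas <- as.data.table(areas)
  need <- c("strain", "area")
  miss <- setdiff(need, names(areas))
  if (length(miss)) stopf("`areas` lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(areas) == 0L) stopf("empty area table: nothing to classify")
  labels <- vapply(dists, `[[`, "", "label")
  summ <- areas[, .(n_reps = .N, area_mean = base::mean(area)), by = strain]
  if (!per_replicate) {
    pc <- posterior_class(summ$area_mean, dists, priors, form, tie_epsilon)
    res <- cbind(summ, as.data.table(pc)[, !"area"])
  } else {
    pr <- posterior_class(areas$area, dists, priors, form, tie_epsilon)
    prdt <- cbind(areas[, .(strain)], as.data.table(pr)[, !"area"])
    pcols <- paste0("p_", labels)
    vote <- prdt[, c(.(n_votes = .N),
                     lapply(.SD, base::mean),
                     .(label = {
                       tab <- sort(table(label), decreasing = TRUE)
                       if (length(tab) > 1L && tab[1] == tab[2]) NA_character_
                       else names(tab)[1]
                     }),
                     .(ambiguous = base::mean(ambiguous) > 0.5)),
                 by = strain, .SDcols = pcols]
    # break vote ties by the mean posterior
    tied <- which(is.na(vote$label))
    if (length(tied)) {
      pm <- as.matrix(vote[tied, ..pcols])
      vote$label[tied] <- labels[max.col(pm, ties.method = "first")]
    }
    res <- merge(summ, vote[, !"n_votes"], by = "strain")
  }
  setorder(res, strain)
  counts <- table(factor(res$label, levels = labels))
  setattr(res, "counts", setNames(as.integer(counts), names(counts)))
  res[]
}
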