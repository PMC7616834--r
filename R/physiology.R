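#' Read a two-ROI fluorescence trace
#'
#' A paired recording of the neurogenic zone (`roi1`) and myogenic zone
#' (`roi2`) of the esophageal ring musculature, as a CSV time series.
#'
#' @param path CSV with header `t`, `roi1`, `roi2` (seconds, arbitrary
#'   fluorescence units).
#' @return List of class `two_roi_trace` with `t`, `roi1`, `roi2` and the
#'   inferred `sampling_rate` (Hz, median reciprocal time step).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "roi1", "roi2")
  if (!all(need %in% names(df)))
    abort_parse(paste0("trace CSV must have header columns: ",
                       paste(need, collapse = ", ")))
  two_roi_trace(df$t, df$roi1, df$roi2)
}

#' @rdname read_trace
#' @param t Time stamps in seconds, strictly increasing.
#' @param roi1,roi2 Fluorescence samples, same length as `t`.
#' @export
two_roi_trace <- function(t, roi1, roi2) {
  if (length(t) != length(roi1) || length(t) != length(roi2))
    abort_validation("t, roi1, roi2 must have equal length")
  if (any(diff(t) <= 0))
    abort_validation("time stamps must be strictly increasing")
  structure(list(t = t, roi1 = roi1, roi2 = roi2,
                 sampling_rate = 1 / stats::median(diff(t))),
            class = "two_roi_trace")
}

#' @export
print.two_roi_trace <- function(x, ...) {
  cat(sprintf("two_roi_trace: %d samples, %.3f-%.3f s, %.1f Hz\n",
              length(x$t), min(x$t), max(x$t), x$sampling_rate))
  invisible(x)
}

#' Detect fluorescence events (peaks) in one channel
#'
#' A sample is an event peak when it is a local maximum exceeding the
#' baseline (channel median) by `threshold_k` median absolute deviations,
#' with topographic prominence of at least `min_prominence` times the
#' signal range, and no higher accepted peak within `min_interval`
#' seconds (peaks are accepted in order of decreasing height). All three
#' criteria are scale-free, so detection is invariant under affine
#' rescaling of the signal.
#'
#' @param x Numeric fluorescence samples (at least 10, all finite).
#' @param t Time stamps in seconds (same length as `x`).
#' @param threshold_k Threshold in MAD multiples above the median
#'   (default 3).
#' @param min_interval Refractory separation between events, seconds
#'   (default 1).
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   signal range (default 0.1).
#' @param smooth_s Width in seconds of the moving-average pre-filter
#'   applied before peak finding (default 0.25 s; 0 disables). Smoothing
#'   shrinks the prominence of single-sample noise excursions far below
#'   the prominence criterion while leaving genuine transients intact.
#' @return Sorted numeric vector of event times (at peak samples). A flat
#'   signal (MAD = 0) yields zero events with a warning.
#' @export
detect_events <- function(x, t, threshold_k = 3, min_interval = 1,
                          min_prominence = 0.1, smooth_s = 0.25) {
  if (length(x) < 10) abort_validation("need at least 10 samples")
  if (length(x) != length(t)) abort_validation("x and t lengths differ")
  if (!all(is.finite(x))) abort_validation("signal contains non-finite values")
  if (smooth_s > 0) {
    dt <- stats::median(diff(t))
    w <- max(1L, round(smooth_s / dt))
    if (w > 1L) {
      kern <- rep(1 / w, w)
      pad <- c(rep(x[1L], w), x, rep(x[length(x)], w))
      sm <- stats::filter(pad, kern, sides = 2L)
      x <- as.numeric(sm[(w + 1L):(w + length(x))])
    }
  }
  med <- stats::median(x)
  m <- stats::mad(x)
  if (m == 0) {
    warning("flat signal (MAD = 0): no events detected")
    return(numeric(0))
  }
  thr <- med + threshold_k * m
  n <- length(x)
  left <- c(-Inf, x[-n])
  right <- c(x[-1L], -Inf)
  cand <- which(x > thr & x > left & x >= right)
  if (!length(cand)) return(numeric(0))
  rng <- diff(range(x))
  prom_ok <- vapply(cand, function(i) {
    peak <- x[i]
    base <- -Inf
    for (dir in c(-1L, 1L)) {
      j <- i + dir
      lowest <- peak
      while (j >= 1L && j <= n && x[j] <= peak) {
        if (x[j] < lowest) lowest <- x[j]
        j <- j + dir
      }
      # boundary without higher terrain: this side does not limit prominence
      if (j >= 1L && j <= n) base <- max(base, lowest)
    }
    if (!is.finite(base)) base <- min(x)
    (peak - base) >= min_prominence * rng
  }, logical(1))
  cand <- cand[prom_ok]
  if (!length(cand)) return(numeric(0))
  # refractory rule: accept by decreasing height
  cand <- cand[order(-x[cand], t[cand])]
  accepted <- numeric(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(t[i] - accepted) >= min_interval))
      accepted <- c(accepted, t[i])
  }
  sort(accepted)
}

#' Pair trigger events with completed-wave events
#'
#' Implements the trigger/completion picture of foregut peristalsis: a
#' contraction in the neurogenic zone (an ROI1 event) is a trigger, and an
#' ROI2 event is the wave completing through the myogenic zone. Each ROI2
#' event is greedily assigned to the latest not-yet-consumed trigger in
#' the window `[t - window, t]`; ROI2 events with no available prior
#' trigger are orphans (reported, since empirically waves do not arise in
#' the myogenic zone without a neurogenic trigger).
#'
#' @param roi1_events,roi2_events Sorted event times, seconds.
#' @param window Pairing window in seconds (default 2).
#' @return List of class `event_pairing`: `trigger_times`,
#'   `completed_flags` (one per trigger), `orphan_roi2_events`.
#' @export
pair_events <- function(roi1_events, roi2_events, window = 2) {
  roi1_events <- sort(roi1_events)
  roi2_events <- sort(roi2_events)
  flags <- rep(FALSE, length(roi1_events))
  orphans <- numeric(0)
  for (ev in roi2_events) {
    ok <- which(!flags & roi1_events >= ev - window & roi1_events <= ev)
    if (length(ok)) flags[ok[length(ok)]] <- TRUE
    else orphans <- c(orphans, ev)
  }
  if (length(orphans))
    message(sprintf("%d myogenic event(s) without a prior trigger in window",
                    length(orphans)))
  structure(list(trigger_times = roi1_events, completed_flags = flags,
                 orphan_roi2_events = orphans),
            class = "event_pairing")
}

#' Peristalsis completion rate
#'
#' Percentage of triggered contraction waves that propagate into a
#' complete peristaltic wave.
#'
#' @param pairing An `event_pairing` from [pair_events].
#' @return Percent in \[0, 100\]; `NA` with a warning when there are no
#'   triggers.
#' @export
completion_rate <- function(pairing) {
  n <- length(pairing$trigger_times)
  if (n == 0) {
    warning("no triggers: completion rate undefined")
    return(NA_real_)
  }
  100 * sum(pairing$completed_flags) / n
}

#' Cycle frequency in events per minute
#'
#' @param events Event times (only their count is used).
#' @param duration Recording duration in seconds (> 0).
#' @return Events per minute.
#' @export
cycle_frequency <- function(events, duration) {
  if (duration <= 0) abort_validation("duration must be positive")
  60 * length(events) / duration
}

#' Per-animal mean of single-cell fluorescence ratios
#'
#' Computes each cell's channel ratio (for CaMPARI: red over green; for
#' Epac: cyan over yellow; for single-channel reporters such as cAMPr the
#' denominator is 1) and then the unweighted mean over cells within each
#' animal. Cells with a zero or negative denominator are excluded with a
#' warning.
#'
#' @param cells `data.frame` with columns `animal`, `cell`, `ch_num` and
#'   optionally `ch_den` (defaults to 1).
#' @return `data.frame` with columns `animal`, `n_cells`, `mean_ratio`.
#' @export
per_animal_ratio <- function(cells) {
  need <- c("animal", "cell", "ch_num")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    abort_validation(paste0("cell table missing column(s): ",
                            paste(miss, collapse = ", ")))
  if (is.null(cells$ch_den)) cells$ch_den <- 1
  bad <- !is.na(cells$ch_den) & cells$ch_den <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d cell(s) with non-positive denominator",
                    sum(bad)))
    cells <- cells[!bad, , drop = FALSE]
  }
  cells$ratio <- cells$ch_num / cells$ch_den
  agg <- stats::aggregate(list(mean_ratio = cells$ratio),
                          by = list(animal = cells$animal), FUN = mean)
  counts <- stats::aggregate(list(n_cells = cells$cell),
                             by = list(animal = cells$animal), FUN = length)
  out <- merge(counts, agg, by = "animal")
  out[order(out$animal), ]
}

#' Full analysis of one two-ROI trace
#'
#' Detects events in both channels, pairs triggers with completed waves,
#' and reports cycle frequencies (both for triggers and for completed
#' waves, since conventions differ) plus the completion rate.
#'
#' @param trace A `two_roi_trace`.
#' @param threshold_k,min_interval,min_prominence See [detect_events].
#' @param window Pairing window, seconds (see [pair_events]).
#' @return List with `roi1_events`, `roi2_events`, `pairing`,
#'   `cycle_freq_trigger_per_min`, `cycle_freq_wave_per_min`,
#'   `completion_rate_percent`, `duration_s`.
#' @export
analyze_trace <- function(trace, threshold_k = 3, min_interval = 1,
                          min_prominence = 0.1, window = 2) {
  e1 <- detect_events(trace$roi1, trace$t, threshold_k, min_interval,
                      min_prominence)
  e2 <- detect_events(trace$roi2, trace$t, threshold_k, min_interval,
                      min_prominence)
  pairing <- pair_events(e1, e2, window = window)
  dur <- max(trace$t) - min(trace$t)
  list(
    roi1_events = e1,
    roi2_events = e2,
    pairing = pairing,
    cycle_freq_trigger_per_min = cycle_frequency(e1, dur),
    cycle_freq_wave_per_min = cycle_frequency(e2, dur),
    completion_rate_percent = if (length(e1)) completion_rate(pairing)
                              else NA_real_,
    duration_s = dur
  )
}
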