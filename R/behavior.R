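# Detection and quantification of the egg-laying behavioural sequence:
# substrate assignment, search-period onset from locomotor speed,
# substrate transitions with de-rocking, choice/leaving statistics.

#' Assign each trajectory frame to a substrate
#'
#' A frame belongs to the half of the chamber containing the fly's
#' centroid: lower substrate when `y <= midline_y` (frames exactly on the
#' midline go to the lower side by convention), upper otherwise.  Frames
#' within `barrier_halfwidth` of the midline are additionally flagged as
#' on the plastic barrier strip; the flag is informational (used by the
#' simulator's no-egg-on-plastic rule) and does not affect assignment.
#'
#' @param trajectory Data frame with `t_s`, `x_mm`, `y_mm`.
#' @param chamber A [chamber_spec()].
#' @return Data frame `t_s, label, on_barrier`.
#' @export
assign_substrate <- function(trajectory, chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  x <- trajectory$x_mm; y <- trajectory$y_mm
  bad <- which(x < 0 | x > chamber$width | y < 0 | y > chamber$height)
  if (length(bad))
    stop("out-of-bounds coordinates at frame ", bad[1])
  data.frame(
    t_s = trajectory$t_s,
    label = ifelse(y <= chamber$midline_y,
                   chamber$labels[["lower"]], chamber$labels[["upper"]]),
    on_barrier = abs(y - chamber$midline_y) <= chamber$barrier_halfwidth,
    stringsAsFactors = FALSE)
}

#' Detect the start of the egg-laying search period
#'
#' The speed trace up to the deposition frame is smoothed with a centred
#' boxcar filter (default 18.5 s, truncated at the trace ends) and the
#' search start is the latest frame before deposition at which the
#' smoothed speed falls below `speed_thresh` - the end of the ovulation
#' standstill.  The returned search duration is never shorter than
#' `min_search_s`: if the latest sub-threshold frame is closer to
#' deposition than that, the start is clamped to `deposition_s -
#' min_search_s` (`clamped = TRUE`); if no sub-threshold frame exists in
#' the trace the same fallback is used (`fallback = TRUE`).
#'
#' @param speed Per-frame speed in mm/s.
#' @param t Frame times in seconds (uniform).
#' @param deposition_s Time of egg deposition.
#' @param boxcar_s Smoothing window in seconds.
#' @param speed_thresh Threshold in mm/s.
#' @param min_search_s Minimum search duration in seconds.
#' @return List with `search_start_s`, `duration_s`, `clamped`,
#'   `fallback`.
#' @export
detect_search_start <- function(speed, t, deposition_s,
                                boxcar_s = 18.5, speed_thresh = 0.1,
                                min_search_s = 9) {
  stopifnot(length(speed) == length(t), length(t) >= 2)
  dt <- t[2] - t[1]
  keep <- t <= deposition_s + 1e-9
  if (!any(keep)) stop("deposition precedes the speed trace")
  sm <- boxcar(speed[keep], boxcar_s, dt)
  tk <- t[keep]
  below <- which(sm < speed_thresh)
  fallback <- length(below) == 0
  start <- if (fallback) deposition_s - min_search_s else tk[max(below)]
  clamped <- FALSE
  if (deposition_s - start < min_search_s) {
    start <- deposition_s - min_search_s
    clamped <- !fallback
  }
  list(search_start_s = start, duration_s = deposition_s - start,
       clamped = clamped, fallback = fallback)
}

#' Detect substrate transitions with rocking removal
#'
#' Raw transitions occur at every change of the per-frame substrate
#' label.  A single de-rocking pass over the raw list (in original
#' order) then eliminates each transition i whose neighbours i-1 and
#' i+1 occurred within `derock_s` of each other, which removes spurious
#' transition triplets caused by the fly rocking on the boundary.
#'
#' @param labels Per-frame substrate labels.
#' @param t Frame times in seconds.
#' @param derock_s Rocking window in seconds.
#' @return Data frame `time_s, from_substrate, to_substrate` in time
#'   order.
#' @export
detect_transitions <- function(labels, t, derock_s = 4) {
  stopifnot(length(labels) == length(t))
  empty <- data.frame(time_s = numeric(0), from_substrate = character(0),
                      to_substrate = character(0), stringsAsFactors = FALSE)
  if (length(labels) < 2) return(empty)
  ch <- which(labels[-1] != labels[-length(labels)]) + 1L
  if (length(ch) == 0) return(empty)
  ev <- data.frame(time_s = t[ch],
                   from_substrate = labels[ch - 1L],
                   to_substrate = labels[ch],
                   stringsAsFactors = FALSE)
  m <- nrow(ev)
  if (m >= 3) {
    drop <- rep(FALSE, m)
    for (i in 2:(m - 1))
      if (ev$time_s[i + 1] - ev$time_s[i - 1] < derock_s) drop[i] <- TRUE
    ev <- ev[!drop, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Binomial fraction with exact (Clopper-Pearson) confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return One-row data frame `k, n, fraction, ci_lo, ci_hi` (fraction
#'   and bounds are `NA` when `n = 0`).
#' @export
fraction_with_ci <- function(k, n, level = 0.95) {
  if (n == 0)
    return(data.frame(k = k, n = 0L, fraction = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_))
  ci <- clopper_pearson(k, n, level)
  data.frame(k = k, n = n, fraction = k / n,
             ci_lo = ci[["lo"]], ci_hi = ci[["hi"]])
}

#' Choice and leaving statistics for a set of egg-laying searches
#'
#' For each substrate option, counts (with exact binomial 95% CIs):
#' eggs deposited on it; search periods that started on it; and, of the
#' searches starting on it, those in which the fly left the starting
#' substrate before deposition.
#'
#' @param eggs Data frame of egg events with `search_start_s`,
#'   `deposition_s` and `substrate` (substrate at deposition).
#' @param frame_labels Data frame `t_s, label` of per-frame substrate
#'   assignments (e.g. from [assign_substrate()]).
#' @param level Confidence level for the intervals.
#' @return Data frame with one row per (metric, option): columns
#'   `metric` (`eggs_on`, `search_started_on`, `left_start_substrate`),
#'   `option`, `k`, `n`, `fraction`, `ci_lo`, `ci_hi`.
#' @export
choice_and_leaving_stats <- function(eggs, frame_labels, level = 0.95) {
  opts <- sort(unique(frame_labels$label))
  n_eggs <- nrow(eggs)
  start_lab <- left <- character(0)
  if (n_eggs > 0) {
    idx0 <- findInterval(eggs$search_start_s, frame_labels$t_s)
    start_lab <- frame_labels$label[pmax(idx0, 1L)]
    left <- vapply(seq_len(n_eggs), function(i) {
      span <- frame_labels$t_s > eggs$search_start_s[i] &
        frame_labels$t_s <= eggs$deposition_s[i]
      any(frame_labels$label[span] != start_lab[i])
    }, logical(1))
  }
  rows <- list()
  for (o in opts) {
    rows[[length(rows) + 1L]] <- cbind(
      metric = "eggs_on", option = o,
      fraction_with_ci(sum(eggs$substrate == o), n_eggs, level))
    rows[[length(rows) + 1L]] <- cbind(
      metric = "search_started_on", option = o,
      fraction_with_ci(sum(start_lab == o), n_eggs, level))
    on_o <- start_lab == o
    rows[[length(rows) + 1L]] <- cbind(
      metric = "left_start_substrate", option = o,
      fraction_with_ci(sum(left[on_o]), sum(on_o), level))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-sum test on two binary (0/1) groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) two-sided p-value for comparing a
#' group of `n1` trials with `k1` events against a group of `n2` trials
#' with `k2` events, each trial coded 0/1.  With binary data the rank
#' statistic is a monotone function of the group-1 event count, so the
#' exact permutation distribution is hypergeometric and is used for
#' small samples; large samples use the normal approximation with the
#' tie correction (the convention behind published large-sample rank-sum
#' p-values on such counts).
#'
#' @param k1,n1 Events and trials in group 1.
#' @param k2,n2 Events and trials in group 2.
#' @param method `"auto"` (exact for `n1 + n2 <= 200`, else normal),
#'   `"exact"`, or `"normal"`.
#' @return Two-sided p-value.
#' @export
binary_group_ranksum <- function(k1, n1, k2, n2,
                                 method = c("auto", "exact", "normal")) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 > 0, n2 > 0)
  method <- match.arg(method)
  N <- n1 + n2
  m0 <- (n1 - k1) + (n2 - k2)  # zeros overall
  m1 <- k1 + k2                # ones overall
  if (m0 == N || m1 == N) return(1)  # both groups constant and equal
  if (method == "auto") method <- if (N <= 200) "exact" else "normal"
  if (method == "exact") {
    # |W - E W| is proportional to |K - E K| where K = group-1 event
    # count, K ~ Hypergeometric(m1 ones, m0 zeros, n1 draws)
    ks <- max(0, n1 - m0):min(n1, m1)
    ek <- n1 * m1 / N
    pk <- stats::dhyper(ks, m1, m0, n1)
    return(min(1, sum(pk[abs(ks - ek) >= abs(k1 - ek) - 1e-9])))
  }
  r0 <- (m0 + 1) / 2           # average rank of the zeros
  r1 <- m0 + (m1 + 1) / 2      # average rank of the ones
  W <- (n1 - k1) * r0 + k1 * r1      # rank sum of group 1
  mu <- n1 * (N + 1) / 2
  tie <- (m0^3 - m0) + (m1^3 - m1)
  v <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
  if (v <= 0) return(1)
  z <- (W - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Per-fly search-duration and walking summaries
#'
#' Restricted to flies that laid at least `min_eggs` eggs: reports the
#' median search duration, and the fraction of time spent walking during
#' non-egg-laying periods (frames more than `exclude_s` from any egg
#' deposition), walking being speed above `walk_thresh`.
#'
#' @param eggs Data frame with `fly`, `search_start_s`, `deposition_s`.
#' @param frames Data frame with `fly`, `t_s`, `speed` (mm/s).
#' @param min_eggs Minimum egg count for inclusion.
#' @param walk_thresh Walking speed threshold in mm/s.
#' @param exclude_s Half-width of the exclusion window around each
#'   deposition, in seconds.
#' @return Data frame `fly, n_eggs, median_search_s, walking_fraction`
#'   (empty when no fly qualifies).
#' @export
per_fly_search_summary <- function(eggs, frames = NULL, min_eggs = 5,
                                   walk_thresh = 1, exclude_s = 600) {
  counts <- table(eggs$fly)
  keep <- names(counts)[counts >= min_eggs]
  out <- data.frame(fly = character(0), n_eggs = integer(0),
                    median_search_s = numeric(0),
                    walking_fraction = numeric(0), stringsAsFactors = FALSE)
  for (f in keep) {
    e <- eggs[eggs$fly == f, , drop = FALSE]
    wf <- NA_real_
    if (!is.null(frames)) {
      fr <- frames[frames$fly == f, , drop = FALSE]
      if (nrow(fr)) {
        far <- rep(TRUE, nrow(fr))
        for (d in e$deposition_s) far <- far & abs(fr$t_s - d) > exclude_s
        if (any(far)) wf <- mean(fr$speed[far] > walk_thresh)
      }
    }
    out <- rbind(out, data.frame(
      fly = f, n_eggs = nrow(e),
      median_search_s = stats::median(e$deposition_s - e$search_start_s),
      walking_fraction = wf, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
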