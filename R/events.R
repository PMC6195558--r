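# Detachment-event detection: per-frame closed/open/transient classification
# of a centre-of-mass distance series, and annotation of the stepwise
# detachment mechanism from the hydrogen-bond count and key-pair occupancy.

#' Classify closed/open/transient states
#'
#' The baseline is the mean of the (smoothed) distance over the baseline
#' window; frames whose smoothed distance is at least `baseline + openOffset`
#' are labelled `open`. Sub-threshold excursions between two open segments
#' that last less than `dwellNs` are labelled `transient` (brief
#' re-attachment); longer ones revert to `closed`.
#'
#' @param comSeries data.frame `time_ns`, `value` from
#'   [comDistanceTimeSeries()]
#' @param baselineWindow numeric `c(startNs, endNs)` inside the series
#' @param openOffset offset above baseline in Angstrom (default 5)
#' @param smoothNs centred running-mean width in ns (default 10; 0 = raw)
#' @param dwellNs maximum duration of a transient excursion in ns (default 50)
#' @return an [EventTimeline-class] (no step annotations yet); attribute
#'   `baseline_A` records the baseline distance
#' @export
classifyStates <- function(comSeries, baselineWindow = NULL, openOffset = 5,
                           smoothNs = 10, dwellNs = 50) {
  stopifnot(is.data.frame(comSeries), openOffset > 0)
  t <- comSeries$time_ns
  v <- .runningMean(comSeries$value, t, smoothNs)
  if (is.null(baselineWindow)) baselineWindow <- c(t[1L], t[1L] + 100)
  inBase <- t >= baselineWindow[1L] - 1e-9 & t <= baselineWindow[2L] + 1e-9
  if (!any(inBase)) stop("configuration error: baseline window is empty")
  baseline <- mean(v[inBase])
  open <- v >= baseline + openOffset - 1e-9
  states <- ifelse(open, "open", "closed")
  # runs of closed frames strictly between open segments
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] != "closed" || k == 1L || k == length(r$values)) next
    dur <- t[ends[k]] - t[starts[k]]
    if (dur < dwellNs) states[starts[k]:ends[k]] <- "transient"
  }
  tl <- new("EventTimeline", times = t, states = states,
            steps = data.frame(step = integer(0), onset_ns = numeric(0),
                               signal = character(0), stringsAsFactors = FALSE))
  attr(tl, "baseline_A") <- baseline
  tl
}

# first sustained level drop in a count series: two-window mean comparison
.firstLevelDrop <- function(times, counts, windowNs, dropThreshold) {
  n <- length(times)
  if (n < 4L) return(NA_real_)
  stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    before <- counts[times >= times[i] - windowNs & times < times[i]]
    after <- counts[times >= times[i] & times < times[i] + windowNs]
    if (length(before) >= 2L && length(after) >= 2L)
      stat[i] <- mean(before) - mean(after)
  }
  hit <- which(stat >= dropThreshold)
  if (length(hit) == 0L) return(NA_real_)
  # onset = the maximum of the drop statistic within the first crossing run
  runEnd <- hit[1L]
  while (runEnd < n && !is.na(stat[runEnd + 1L]) && stat[runEnd + 1L] >= dropThreshold)
    runEnd <- runEnd + 1L
  seg <- hit[1L]:runEnd
  times[seg[which.max(stat[seg])]]
}

# occupancy of a pair label in the window containing time tt (NA if absent)
.pairFormedAt <- function(table, pairRow, tt) {
  w <- which(table@windows$start_ns - 1e-9 <= tt & tt <= table@windows$end_ns + 1e-9)
  if (length(w) == 0L) return(NA)
  table@occupancy[pairRow, w[1L]] >= 0.5
}

#' Annotate the stepwise detachment mechanism
#'
#' Adds Step 1-4 annotations to a timeline:
#' \itemize{
#'   \item Step 1: first sustained drop of the total inter-domain
#'     hydrogen-bond count (two-window mean comparison against
#'     `countDropThreshold`).
#'   \item Step 2: first open-state onset at which the designated critical
#'     pair (the last of `keyPairs`) is lost.
#'   \item Step 3: first re-attachment segment (transient, or closed between
#'     two opens) during which the critical pair is re-formed.
#'   \item Step 4: onset of the final open segment, with the pair absent.
#' }
#' Later steps are omitted when their condition never occurs, so annotated
#' steps are always strictly ordered in time. When the critical pair is
#' missing from the occupancy table, a warning is issued and Steps 2/4 are
#' reported from the state signal alone.
#'
#' @param timeline an [EventTimeline-class] from [classifyStates()]
#' @param hbondSeries data.frame `time_ns`, `value` from
#'   [interdomainHbondCount()] (same time base as the timeline)
#' @param pairTable an [OccupancyTable-class] from [pairOccupancy()]
#' @param keyPairs character vector of pair labels as in
#'   `pairTable@pairs$label`; the last entry is the critical pair (default:
#'   the nSH2-helical contact set around the mutation site, ending with
#'   R340-E542)
#' @param changeWindowNs window for the Step-1 change point (default 50)
#' @param countDropThreshold minimum drop in mean count (default 1.5)
#' @return the timeline with populated step annotations
#' @export
annotateSteps <- function(timeline, hbondSeries, pairTable,
                          keyPairs = c("A:LYS545--B:LEU380",
                                       "B:LYS382--A:GLN546",
                                       "B:ARG358--A:GLU542",
                                       "B:ARG340--A:GLU542"),
                          changeWindowNs = 50, countDropThreshold = 1.5) {
  stopifnot(is(timeline, "EventTimeline"), is(pairTable, "OccupancyTable"))
  t <- timeline@times
  states <- timeline@states
  critical <- keyPairs[length(keyPairs)]
  critRow <- match(critical, pairTable@pairs$label)
  haveCrit <- !is.na(critRow)
  if (!haveCrit)
    warning("key pair '", critical,
            "' absent from occupancy table; steps use the count/state signals only")
  steps <- list()
  # Step 1: sustained count drop
  t1 <- .firstLevelDrop(hbondSeries$time_ns, hbondSeries$value,
                        changeWindowNs, countDropThreshold)
  if (!is.na(t1))
    steps[[length(steps) + 1L]] <- data.frame(
      step = 1L, onset_ns = t1,
      signal = "sustained drop in total H-bond count", stringsAsFactors = FALSE)
  # segments
  r <- rle(states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  openSegs <- which(r$values == "open")
  if (length(openSegs)) {
    # Step 2: first open onset (critical pair lost there, if checkable)
    for (k in openSegs) {
      onset <- t[starts[k]]
      ok <- if (haveCrit) isFALSE(.pairFormedAt(pairTable, critRow, onset)) else TRUE
      if (isTRUE(ok) || is.na(ok)) {
        steps[[length(steps) + 1L]] <- data.frame(
          step = 2L, onset_ns = onset,
          signal = sprintf("open-state onset%s", if (haveCrit)
            sprintf(" with loss of %s", critical) else ""),
          stringsAsFactors = FALSE)
        break
      }
    }
    firstOpen <- openSegs[1L]
    lastOpen <- openSegs[length(openSegs)]
    # Step 3: re-attachment between opens with the critical pair re-formed
    if (lastOpen > firstOpen) {
      for (k in seq_along(r$values)) {
        if (k <= firstOpen || k >= lastOpen) next
        if (!r$values[k] %in% c("transient", "closed")) next
        onset <- t[starts[k]]
        mid <- t[starts[k] + (ends[k] - starts[k]) %/% 2L]
        formed <- if (haveCrit) {
          isTRUE(.pairFormedAt(pairTable, critRow, mid)) ||
            isTRUE(.pairFormedAt(pairTable, critRow, onset))
        } else TRUE
        if (formed) {
          steps[[length(steps) + 1L]] <- data.frame(
            step = 3L, onset_ns = onset,
            signal = sprintf("re-attachment%s", if (haveCrit)
              sprintf(" with %s re-formed", critical) else ""),
            stringsAsFactors = FALSE)
          break
        }
      }
    }
    # Step 4: final open onset after a step-3 re-attachment
    have3 <- any(vapply(steps, function(s) s$step == 3L, logical(1)))
    if (have3 && lastOpen > firstOpen) {
      onset <- t[starts[lastOpen]]
      steps[[length(steps) + 1L]] <- data.frame(
        step = 4L, onset_ns = onset,
        signal = sprintf("final open onset%s", if (haveCrit)
          sprintf(" with %s absent", critical) else ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(steps)) {
    sdf <- do.call(rbind, steps)
    sdf <- sdf[order(sdf$step), , drop = FALSE]
    # enforce strict temporal ordering: drop any step not later than its
    # predecessor (later steps omitted rather than reordered)
    keep <- rep(TRUE, nrow(sdf))
    last <- -Inf
    for (i in seq_len(nrow(sdf))) {
      if (sdf$onset_ns[i] <= last) keep[i] <- FALSE else last <- sdf$onset_ns[i]
    }
    sdf <- sdf[keep, , drop = FALSE]
    rownames(sdf) <- NULL
  } else {
    sdf <- timeline@steps
  }
  out <- new("EventTimeline", times = t, states = states, steps = sdf)
  attr(out, "baseline_A") <- attr(timeline, "baseline_A")
  out
}

#' Write an event timeline as JSON
#'
#' States are run-length encoded; steps are records.
#'
#' @param timeline an [EventTimeline-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeTimelineJSON <- function(timeline, path) {
  r <- rle(timeline@states)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- data.frame(state = r$values,
                     start_ns = timeline@times[starts],
                     end_ns = timeline@times[ends])
  jsonlite::write_json(list(segments = segs, steps = timeline@steps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
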