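#' @include metrics.R
NULL

.validateTimeline <- function(tl) {
  stopifnot(is.data.frame(tl),
            all(c("label", "start_s", "end_s") %in% names(tl)))
  if (anyDuplicated(tl$label)) stop("epoch labels must be unique")
  if (any(tl$end_s <= tl$start_s)) stop("epochs must have end_s > start_s")
  o <- order(tl$start_s)
  tl <- tl[o, , drop = FALSE]
  if (nrow(tl) > 1L &&
      any(tl$start_s[-1L] < tl$end_s[-nrow(tl)] - 1e-9)) {
    stop("overlapping epochs in timeline")
  }
  rownames(tl) <- NULL
  tl
}

#' Experimental timelines
#'
#' `protocolTimeline()` returns one of the three built-in epoch timelines
#' as a data.frame (`label`, `start_s`, `end_s`, `gas`) with a
#' `protocol_id` attribute; `makeTimeline()` builds a custom one. Epoch
#' intervals are half-open `[start_s, end_s)`.
#'
#' Built-in protocols:
#' \describe{
#'   \item{mouse_emg}{10-min baseline, vehicle (saline) with 20-min
#'     recording, then ligand with 90 min of recording split at the 30-,
#'     60- and 90-min time points.}
#'   \item{rat_pleth}{20-min pre-vehicle baseline, 30-min post-vehicle
#'     observation in 5-min bins, 20-min pre-ligand baseline, 30-min
#'     post-ligand observation in 5-min bins.}
#'   \item{rat_phrenic}{15-min baseline, 5-min hypoxic episode, recovery,
#'     15-min post-vehicle period, then ligand with recording split at the
#'     30-, 60- and 90-min time points.}
#' }
#'
#' @param id protocol preset id.
#' @param scale positive factor applied to all epoch times; `scale < 1`
#'   gives a structurally identical but shorter protocol (used for
#'   simulation studies).
#' @return data.frame timeline.
#' @examples
#' protocolTimeline("mouse_emg")
#' @export
protocolTimeline <- function(id = c("mouse_emg", "rat_pleth",
                                    "rat_phrenic"), scale = 1) {
  id <- match.arg(id)
  stopifnot(scale > 0)
  tl <- switch(id,
    mouse_emg = data.frame(
      label = c("BL", "SL", "J60_30", "J60_60", "J60_90"),
      start_s = c(0, 600, 1800, 3600, 5400),
      end_s = c(600, 1800, 3600, 5400, 7200),
      gas = "iso_O2"
    ),
    rat_pleth = {
      bins <- function(prefix, from) data.frame(
        label = sprintf("%s_%02d", prefix, seq_len(6L) * 5L),
        start_s = from + (seq_len(6L) - 1L) * 300,
        end_s = from + seq_len(6L) * 300,
        gas = "normoxia"
      )
      rbind(
        data.frame(label = "BL_SL", start_s = 0, end_s = 1200,
                   gas = "normoxia"),
        bins("SL", 1200),
        data.frame(label = "BL_J60", start_s = 3000, end_s = 4200,
                   gas = "normoxia"),
        bins("J60", 4200)
      )
    },
    rat_phrenic = data.frame(
      label = c("BL", "HX1", "REC", "SL", "J60_30", "J60_60", "J60_90"),
      start_s = c(0, 900, 1200, 2100, 3000, 4800, 6600),
      end_s = c(900, 1200, 2100, 3000, 4800, 6600, 8400),
      gas = c("O2_CO2", "hypoxia", "O2_CO2", "O2_CO2", "O2_CO2",
              "O2_CO2", "O2_CO2")
    )
  )
  tl$start_s <- tl$start_s * scale
  tl$end_s <- tl$end_s * scale
  tl <- .validateTimeline(tl)
  attr(tl, "protocol_id") <- id
  tl
}

#' @rdname protocolTimeline
#' @param labels,startS,endS,gas epoch definitions (equal lengths).
#' @param protocolId id stored in the `protocol_id` attribute.
#' @export
makeTimeline <- function(labels, startS, endS, gas = "air",
                         protocolId = "custom") {
  tl <- .validateTimeline(data.frame(label = labels, start_s = startS,
                                     end_s = endS, gas = gas))
  attr(tl, "protocol_id") <- protocolId
  tl
}

#' Assign events to timeline epochs
#'
#' Labels each event with the unique epoch whose half-open interval
#' `[start_s, end_s)` contains its onset. Events outside all epochs are
#' dropped, with the count reported via `message()`.
#'
#' @param timeline a timeline data.frame ([protocolTimeline()]).
#' @param events data.frame with an `onset_s` column.
#' @return `events` restricted to in-epoch rows, with `epoch` and
#'   `epoch_start_s` columns appended.
#' @export
assignEpochs <- function(timeline, events) {
  timeline <- .validateTimeline(timeline)
  lab <- rep(NA_character_, nrow(events))
  est <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(timeline))) {
    inEp <- events$onset_s >= timeline$start_s[i] &
      events$onset_s < timeline$end_s[i]
    lab[inEp] <- timeline$label[i]
    est[inEp] <- timeline$start_s[i]
  }
  dropped <- sum(is.na(lab))
  if (dropped > 0) {
    message(dropped, " event(s) outside all epochs dropped")
  }
  out <- events[!is.na(lab), , drop = FALSE]
  out$epoch <- lab[!is.na(lab)]
  out$epoch_start_s <- est[!is.na(lab)]
  rownames(out) <- NULL
  out
}

#' Per-epoch summary of event metrics
#'
#' Averages each metric over the events whose onsets fall in the final
#' `summaryWindowS` seconds of each epoch (steady-state sampling at the
#' labeled time point; set `summaryWindowS = Inf` to average whole
#' epochs). Also reports the event rate over the same window. Epochs with
#' no events in the window yield `NA` and are reported via `message()`.
#'
#' @param labeled epoch-labeled metrics from [assignEpochs()].
#' @param timeline the timeline used for labeling.
#' @param metrics character vector of metric column names to average.
#' @param summaryWindowS summary window, seconds (default 60).
#' @return long data.frame: `epoch`, `epoch_start_s`, `metric`, `value`,
#'   `n_events`; metrics include an `event_rate` row per epoch.
#' @export
summarizeEpoch <- function(labeled, timeline,
                           metrics = intersect(
                             c("pk_pk", "auc", "tonic", "peak_amp"),
                             names(labeled)),
                           summaryWindowS = 60) {
  timeline <- .validateTimeline(timeline)
  out <- list()
  for (i in seq_len(nrow(timeline))) {
    ep <- timeline$label[i]
    w0 <- max(timeline$start_s[i], timeline$end_s[i] - summaryWindowS)
    w1 <- timeline$end_s[i]
    rows <- labeled[labeled$epoch == ep & labeled$onset_s >= w0 &
                      labeled$onset_s < w1, , drop = FALSE]
    nEv <- nrow(rows)
    if (!nEv) {
      message("epoch ", ep, ": no events in summary window (missing cell)")
    }
    vals <- vapply(metrics, function(m) {
      if (nEv) mean(rows[[m]]) else NA_real_
    }, numeric(1))
    rate <- if (nEv >= 2L) eventRate(rows$onset_s, c(w0, w1)) else NA_real_
    out[[ep]] <- data.frame(
      epoch = ep, epoch_start_s = timeline$start_s[i],
      metric = c(metrics, "event_rate"), value = c(vals, rate),
      n_events = nEv
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize a value to its baseline mean
#'
#' @param value numeric value(s).
#' @param baselineMean baseline mean (> 0 for a defined result).
#' @return `100 * value / baselineMean` (percent of baseline);
#'   `NA_real_` where the baseline is missing or not positive.
#' @examples
#' normalizeToBaseline(2.5, 1)  # 250%
#' @export
normalizeToBaseline <- function(value, baselineMean) {
  ifelse(!is.na(baselineMean) & baselineMean > 0,
         100 * value / baselineMean, NA_real_)
}

#' Add percent-of-baseline column to a cohort table
#'
#' For each subject, side and metric, divides the value in every epoch by
#' that subject's own baseline-epoch value (the baseline of the baseline
#' is identically 100%).
#'
#' @param table long cohort table with columns `subject_id`, `epoch`,
#'   `metric`, `value` (and optionally `side`).
#' @param baselineLabel label of the baseline epoch.
#' @return `table` with a `value_pct_baseline` column appended.
#' @export
addBaselineNormalization <- function(table, baselineLabel = "BL") {
  side <- if ("side" %in% names(table)) table$side else ""
  key <- paste(table$subject_id, side, table$metric, sep = "\r")
  isBl <- table$epoch == baselineLabel
  blMap <- tapply(table$value[isBl], key[isBl], mean)
  bl <- as.numeric(blMap[key])
  table$value_pct_baseline <- normalizeToBaseline(table$value, bl)
  table
}

#' Censor a subject's data after death
#'
#' Removes, for the given subject, all cohort-table rows whose epoch
#' starts at or after the death time; earlier rows (the time points
#' preceding death) are retained. Other subjects' rows are untouched.
#'
#' @param record list or one-row data.frame with `subject_id` and
#'   `death_time_s` (`NA` or absent means the subject survived).
#' @param table cohort table with `subject_id` and `epoch_start_s`.
#' @return the censored table.
#' @export
censorDeath <- function(record, table) {
  dt <- record$death_time_s
  if (is.null(dt) || length(dt) == 0L || is.na(dt)) return(table)
  drop <- table$subject_id == record$subject_id &
    table$epoch_start_s >= dt
  if (any(drop)) {
    message("censoring ", sum(drop), " row(s) of subject ",
            record$subject_id, " at/after death (t = ", dt, " s)")
  }
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort survival contingency table
#'
#' Builds the 2x2 cohort-by-outcome table of survivors and deaths used in
#' the chi-squared comparison of survival proportions.
#'
#' @param records data.frame with columns `subject_id`, `cohort` and
#'   `death_time_s` (`NA` = survived).
#' @return 2x2 integer matrix, rows = cohorts (order of first
#'   appearance), columns = `survived`, `died`.
#' @examples
#' recs <- data.frame(
#'   subject_id = 1:20,
#'   cohort = rep(c("wild_type", "chat_cre"), c(11, 9)),
#'   death_time_s = c(rep(NA, 6), rep(3600, 5), rep(NA, 9)))
#' survivalTable(recs)
#' @export
survivalTable <- function(records) {
  cohorts <- unique(records$cohort)
  if (length(cohorts) != 2L) {
    stop("survivalTable needs exactly two cohorts (got ",
         length(cohorts), ")")
  }
  died <- !is.na(records$death_time_s)
  tab <- t(vapply(cohorts, function(co) {
    s <- records$cohort == co
    c(survived = sum(s & !died), died = sum(s & died))
  }, integer(2)))
  storage.mode(tab) <- "integer"
  tab
}

#' Tally histology quadrant scores
#'
#' Counts, per cohort, spinal segment (C3--C6) and quadrant (left/right x
#' dorsal/ventral), the number of animals scored positive for reporter
#' (mCherry) expression, and flags for exclusion any subject with no
#' positive cell anywhere in C3--C6.
#'
#' @param grids long data.frame with columns `subject_id`, `cohort`,
#'   `segment` (C3..C6), `quadrant` (left_dorsal, right_dorsal,
#'   left_ventral, right_ventral) and logical `positive`. Every subject
#'   must have all 16 segment-by-quadrant cells scored.
#' @return list with `counts` (data.frame cohort, segment, quadrant,
#'   n_positive) and `inclusion` (data.frame subject_id, cohort,
#'   histology_included).
#' @export
histologyTally <- function(grids) {
  segs <- c("C3", "C4", "C5", "C6")
  quads <- c("left_dorsal", "right_dorsal", "left_ventral",
             "right_ventral")
  need <- c("subject_id", "cohort", "segment", "quadrant", "positive")
  if (!all(need %in% names(grids))) {
    stop("grids must have columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(grids)) {
    return(list(
      counts = data.frame(cohort = character(), segment = character(),
                          quadrant = character(), n_positive = integer()),
      inclusion = data.frame(subject_id = character(), cohort = character(),
                             histology_included = logical())))
  }
  full <- expand.grid(segment = segs, quadrant = quads,
                      stringsAsFactors = FALSE)
  for (sid in unique(grids$subject_id)) {
    g <- grids[grids$subject_id == sid, , drop = FALSE]
    have <- paste(g$segment, g$quadrant)
    missing <- setdiff(paste(full$segment, full$quadrant), have)
    if (length(missing)) {
      stop("incomplete histology grid for subject ", sid, ": missing ",
           paste(missing, collapse = "; "))
    }
    if (anyDuplicated(have)) {
      stop("duplicated histology cells for subject ", sid)
    }
  }
  counts <- aggregate(positive ~ cohort + segment + quadrant,
                      data = grids, FUN = sum)
  names(counts)[names(counts) == "positive"] <- "n_positive"
  counts <- counts[order(counts$cohort, counts$segment,
                         counts$quadrant), , drop = FALSE]
  rownames(counts) <- NULL
  anyPos <- aggregate(positive ~ subject_id + cohort, data = grids,
                      FUN = any)
  inclusion <- data.frame(subject_id = anyPos$subject_id,
                          cohort = anyPos$cohort,
                          histology_included = anyPos$positive)
  list(counts = counts, inclusion = inclusion)
}
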