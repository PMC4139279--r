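#' Protocol phase labels
#'
#' Ordered labels of the UCO protocol phases: a resting baseline, three
#' escalating occlusion phases (partial to complete cord compression), and a
#' final recovery.
#' @export
PHASE_LEVELS <- c("BASELINE", "MILD", "MODERATE", "SEVERE", "RECOVERY")

#' Occlusion schedule
#'
#' Timed umbilical-cord occlusion events together with the protocol phase
#' boundaries.  Events must be non-overlapping, time-ordered, and each must
#' lie within exactly one phase; phases must be non-overlapping and ordered
#' BASELINE before RECOVERY.
#'
#' @param events data frame with columns `start_s`, `end_s`, `phase`.
#' @param phases data frame with columns `phase`, `start_s`, `end_s`.
#' @return An object of class `occlusion_schedule`.
#' @export
occlusion_schedule <- function(events, phases) {
  events <- as.data.frame(events)
  phases <- as.data.frame(phases)
  stopifnot(all(c("start_s", "end_s", "phase") %in% names(events)),
            all(c("phase", "start_s", "end_s") %in% names(phases)))
  sch <- structure(list(events = events, phases = phases),
                   class = "occlusion_schedule")
  validate_occlusion_schedule(sch)
}

#' Validate an occlusion schedule
#' @param sch an `occlusion_schedule`.
#' @return `sch`, invisibly (but also returned visibly by the constructor).
#' @export
validate_occlusion_schedule <- function(sch) {
  ev <- sch$events
  ph <- sch$phases
  if (!all(ph$phase %in% PHASE_LEVELS)) {
    stop("unknown phase label: ", setdiff(ph$phase, PHASE_LEVELS)[1])
  }
  if (anyDuplicated(ph$phase)) stop("duplicate phase label")
  if (any(ph$end_s <= ph$start_s)) stop("phase with non-positive duration")
  o <- order(match(ph$phase, PHASE_LEVELS))
  if (is.unsorted(ph$start_s[o])) stop("phases out of protocol order")
  pho <- ph[order(ph$start_s), ]
  if (nrow(pho) > 1L && any(pho$start_s[-1L] < pho$end_s[-nrow(pho)])) {
    stop("overlapping phases")
  }
  if (nrow(ev) > 0L) {
    if (!all(ev$phase %in% PHASE_LEVELS)) {
      stop("unknown phase label in events: ", setdiff(ev$phase, PHASE_LEVELS)[1])
    }
    if (any(ev$end_s <= ev$start_s)) stop("event with non-positive duration")
    if (is.unsorted(ev$start_s, strictly = TRUE)) stop("events not time-ordered")
    if (any(ev$start_s[-1L] < ev$end_s[-nrow(ev)])) stop("overlapping occlusion events")
    for (i in seq_len(nrow(ev))) {
      hit <- ph$phase[ev$start_s[i] >= ph$start_s & ev$end_s[i] <= ph$end_s]
      if (length(hit) != 1L) {
        stop("event ", i, " does not lie within exactly one phase")
      }
      if (hit != ev$phase[i]) {
        stop("event ", i, " labelled ", ev$phase[i], " but lies in ", hit)
      }
    }
  }
  invisible(sch)
}

#' @export
print.occlusion_schedule <- function(x, ...) {
  cat(sprintf("occlusion_schedule: %d events, %d phases (%s)\n",
              nrow(x$events), nrow(x$phases),
              paste(x$phases$phase, collapse = " > ")))
  invisible(x)
}

#' Phase boundaries of a schedule
#'
#' @param sch an `occlusion_schedule`.
#' @param phase a phase label.
#' @return numeric `c(start, end)` in seconds.
#' @export
phase_interval <- function(sch, phase) {
  row <- sch$phases[sch$phases$phase == phase, ]
  if (nrow(row) != 1L) stop("phase ", phase, " not in schedule")
  c(row$start_s, row$end_s)
}

#' Occlusion events of a phase
#' @param sch an `occlusion_schedule`.
#' @param phase a phase label.
#' @return data frame of events (possibly empty).
#' @export
phase_events <- function(sch, phase) {
  sch$events[sch$events$phase == phase, , drop = FALSE]
}
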