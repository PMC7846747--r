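#' Build a stimulation protocol table
#'
#' A protocol is an ordered set of non-overlapping epochs describing what the
#' islet preparation is exposed to over time: a low-glucose baseline, one or
#' more stimulatory glucose steps, a depolarising KCl pulse, or a chemogenetic
#' "silenced" period. Each epoch carries a drive level in [0, 1] controlling
#' how strongly cells are pushed towards the bursting state; it is used both
#' by the synthetic-islet simulator and by response-metric calculations.
#'
#' @param label character vector; each one of `"baseline"`, `"glucose"`,
#'   `"kcl"`, `"silenced"`.
#' @param start_s,end_s epoch boundaries in seconds; epochs must be ordered
#'   and non-overlapping with `start_s < end_s`.
#' @param drive_level numeric in `[0, 1]`; probability drive towards the ON
#'   (bursting) state during the epoch.
#' @return A `data.frame` of class `stim_protocol` with columns
#'   `label`, `start_s`, `end_s`, `drive_level`.
#' @examples
#' stim_protocol(c("baseline", "glucose"), c(0, 60), c(60, 180), c(0.1, 0.8))
#' @export
stim_protocol <- function(label, start_s, end_s, drive_level) {
  n <- length(label)
  if (length(start_s) != n || length(end_s) != n || length(drive_level) != n) {
    stop_config("protocol", "label, start_s, end_s, drive_level must have equal length")
  }
  ok <- label %in% c("baseline", "glucose", "kcl", "silenced")
  if (!all(ok)) stop_config("protocol$label", paste("unknown label:", label[!ok][1]))
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop_config("protocol", "epoch times must be finite")
  }
  if (any(end_s <= start_s)) stop_config("protocol", "start_s must be < end_s")
  if (n > 1 && any(start_s[-1] < end_s[-n])) {
    stop_config("protocol", "epochs must be ordered and non-overlapping")
  }
  if (any(drive_level < 0 | drive_level > 1)) {
    stop_config("protocol$drive_level", "must lie in [0, 1]")
  }
  out <- data.frame(label = label, start_s = start_s, end_s = end_s,
                    drive_level = drive_level, stringsAsFactors = FALSE)
  class(out) <- c("stim_protocol", "data.frame")
  out
}

#' Default two-step protocol: baseline then sustained glucose
#'
#' @param duration_s total recording length in seconds.
#' @param baseline_s length of the initial low-glucose baseline.
#' @param baseline_drive,glucose_drive drive levels of the two epochs.
#' @return A [stim_protocol()] table.
#' @export
default_protocol <- function(duration_s, baseline_s = min(60, duration_s / 3),
                             baseline_drive = 0.1, glucose_drive = 0.8) {
  stim_protocol(c("baseline", "glucose"),
                c(0, baseline_s), c(baseline_s, duration_s),
                c(baseline_drive, glucose_drive))
}

## Per-frame drive level / epoch label vectors for a frame grid.
epoch_frame_drive <- function(protocol, times_s) {
  drive <- rep(0, length(times_s))
  label <- rep(NA_character_, length(times_s))
  for (i in seq_len(nrow(protocol))) {
    sel <- times_s >= protocol$start_s[i] & times_s < protocol$end_s[i]
    drive[sel] <- protocol$drive_level[i]
    label[sel] <- protocol$label[i]
  }
  ## frames at/after the last epoch end inherit the final epoch
  tail_sel <- times_s >= protocol$end_s[nrow(protocol)]
  drive[tail_sel] <- protocol$drive_level[nrow(protocol)]
  label[tail_sel] <- protocol$label[nrow(protocol)]
  list(drive = drive, label = label)
}

epoch_frames <- function(protocol, label_want, times_s) {
  lab <- epoch_frame_drive(protocol, times_s)$label
  which(lab %in% label_want)
}
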