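#' Build a periodic oddball stimulation schedule
#'
#' In a frequency-tagged oddball design all stimuli update at the base rate
#' (e.g. 10 Hz) while every `items_per_deviant`-th item is a deviant, so the
#' deviant stream itself is periodic at `base_hz / items_per_deviant`
#' (e.g. 2 Hz). The schedule fixes the frequencies and the periodic item
#' sequence for one condition.
#'
#' @param base_hz Base stimulation rate in Hz (all items).
#' @param items_per_deviant Integer >= 2; a deviant appears once every this
#'   many item presentations. `items_per_deviant = 2` is the alternation mode.
#' @param trial_duration_s Trial length in seconds. Must hold a whole number
#'   of deviant cycles.
#' @param n_trials Number of trials per condition.
#' @return An object of class `ssvep_schedule` with fields `base_hz`,
#'   `deviant_hz`, `items_per_deviant`, `trial_duration_s`, `n_trials` and
#'   `item_labels` (character vector, `"deviant"`/`"base"`, one per item
#'   presentation in a trial; the first item of each cycle is the deviant).
#' @examples
#' sched <- make_schedule(10, 5, 12, 16)   # 2 Hz deviants in a 10 Hz stream
#' sched$deviant_hz                        # 2
#' table(sched$item_labels)                # 24 deviants, 96 base items
#' @export
make_schedule <- function(base_hz, items_per_deviant, trial_duration_s,
                          n_trials = 16L) {
  stopifnot(is.numeric(base_hz), length(base_hz) == 1L, base_hz > 0,
            is.numeric(trial_duration_s), trial_duration_s > 0,
            is.numeric(n_trials), n_trials >= 1)
  if (!is.numeric(items_per_deviant) || length(items_per_deviant) != 1L ||
      items_per_deviant != round(items_per_deviant) || items_per_deviant < 2) {
    stop("`items_per_deviant` must be an integer >= 2 (one deviant embedded ",
         "among base items; alternation mode is 2).")
  }
  items_per_deviant <- as.integer(items_per_deviant)
  deviant_hz <- base_hz / items_per_deviant
  n_items <- trial_duration_s * base_hz
  if (abs(n_items - round(n_items)) > 1e-9) {
    stop("trial_duration_s * base_hz must be an integer number of items.")
  }
  n_cycles <- trial_duration_s * deviant_hz
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("trial_duration_s * deviant_hz must be an integer: a trial must ",
         "contain whole deviant cycles (base_hz / items_per_deviant = ",
         deviant_hz, " Hz).")
  }
  n_items <- as.integer(round(n_items))
  labels <- rep(c("deviant", rep("base", items_per_deviant - 1L)),
                length.out = n_items)
  structure(
    list(base_hz = base_hz, deviant_hz = deviant_hz,
         items_per_deviant = items_per_deviant,
         trial_duration_s = trial_duration_s,
         n_trials = as.integer(n_trials),
         item_labels = labels),
    class = "ssvep_schedule")
}

#' @export
print.ssvep_schedule <- function(x, ...) {
  cat(sprintf(
    "SSVEP schedule: base %g Hz, deviant %g Hz (1 in %d items), %g-s trials, %d trials\n",
    x$base_hz, x$deviant_hz, x$items_per_deviant, x$trial_duration_s,
    x$n_trials))
  invisible(x)
}
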