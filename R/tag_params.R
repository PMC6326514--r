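#' Per-tag firmware and hardware parameters
#'
#' Builds the parameter table consumed by [emulate_tags()]: one row per tag
#' with its internal 32-bit id, clock offset (the wall-clock second of
#' battery insertion -- the tag-local counter reads wall minus offset),
#' battery life, restart behaviour, per-second miss/spurious detection
#' probabilities, flash memory capacity (in 16-byte event records) and the
#' washout gap that terminates a contact event.
#'
#' `default_tag_params()` draws study-like imperfections: insertion offsets
#' uniform on 0..300 s, battery lives centred shortly into the sixth day,
#' sporadic restarts and a small per-second miss probability.
#' `ideal_tag_params()` gives every tag a zero offset, effectively unlimited
#' battery and memory, no restarts and perfect sensing; it is the
#' configuration under which the pipeline should recover the simulated truth
#' exactly.
#'
#' @param tag_ids Character vector of tag ids.
#' @param seed Integer seed for the random per-tag draws.
#' @param clock_offset_s,battery_life_s,restart_rate_per_day,restart_gap_s,p_miss,p_spurious
#'   Optional scalar or per-tag overrides.
#' @param memory_capacity_events Flash capacity in event records
#'   (default [event_capacity()] of 8 MiB at 16 B/record = 524288).
#' @param washout_s Consecutive silent seconds that terminate a contact
#'   event (default 30).
#' @param battery_mean_s,battery_sd_s Normal battery-life draw used when
#'   `battery_life_s` is not supplied (defaults: mean 6.3 days, sd 10 h).
#' @return A `tag_params` data.frame, one row per tag.
#' @export
default_tag_params <- function(tag_ids, seed = 1L,
                               clock_offset_s = NULL,
                               battery_life_s = NULL,
                               restart_rate_per_day = 0.2,
                               restart_gap_s = 5L,
                               p_miss = 0.05,
                               p_spurious = 0,
                               memory_capacity_events = event_capacity(8 * 1024^2, 16),
                               washout_s = 30L,
                               battery_mean_s = 544320,
                               battery_sd_s = 36000) {
  n <- length(tag_ids)
  if (n == 0) stopf("tag_ids must be nonempty")
  with_local_seed(derive_seed(seed, 2L), {
    if (is.null(clock_offset_s)) clock_offset_s <- sample(0:300, n, replace = TRUE)
    if (is.null(battery_life_s)) {
      battery_life_s <- pmax(3600, round(stats::rnorm(n, battery_mean_s, battery_sd_s)))
    }
  })
  params <- data.frame(
    tag_id = tag_ids,
    internal_id = 305419896L + seq_len(n),   # arbitrary 32-bit id block
    external_id = tag_ids,
    clock_offset_s = as.integer(rep_len(clock_offset_s, n)),
    battery_life_s = as.numeric(rep_len(battery_life_s, n)),
    restart_rate_per_day = rep_len(restart_rate_per_day, n),
    restart_gap_s = as.integer(rep_len(restart_gap_s, n)),
    p_miss = rep_len(p_miss, n),
    p_spurious = rep_len(p_spurious, n),
    memory_capacity_events = rep_len(memory_capacity_events, n),
    washout_s = as.integer(rep_len(washout_s, n)),
    stringsAsFactors = FALSE
  )
  params$spurious_candidates <- replicate(n, character(), simplify = FALSE)
  validate_tag_params(params)
}

#' @rdname default_tag_params
#' @export
ideal_tag_params <- function(tag_ids) {
  default_tag_params(tag_ids, seed = 0L,
                     clock_offset_s = 0L, battery_life_s = 1e12,
                     restart_rate_per_day = 0, p_miss = 0, p_spurious = 0)
}

validate_tag_params <- function(params) {
  stopifnot(is.data.frame(params))
  if (anyDuplicated(params$tag_id)) stopf("duplicate tag_id in tag params")
  if (any(params$p_miss < 0 | params$p_miss > 1) ||
      any(params$p_spurious < 0 | params$p_spurious > 1)) {
    stopf("p_miss and p_spurious must lie in [0, 1]")
  }
  if (any(params$memory_capacity_events <= 0)) stopf("memory capacity must be positive")
  if (any(params$washout_s < 1)) stopf("washout_s must be >= 1")
  if (any(params$clock_offset_s < 0)) stopf("clock offsets must be >= 0")
  if (any(params$restart_gap_s < 1)) stopf("restart_gap_s must be >= 1")
  if (any(params$restart_rate_per_day < 0)) stopf("restart rate must be >= 0")
  class(params) <- c("tag_params", "data.frame")
  params
}

#' Flash event capacity
#'
#' Number of event records a tag's flash memory can hold: each record
#' occupies a fixed number of bytes, so capacity is the integer quotient.
#' An 8 MiB flash at 16 bytes per record holds 524,288 records.
#'
#' @param flash_bytes Flash size in bytes (> 0).
#' @param bytes_per_event Bytes per stored record (> 0).
#' @return Integer record capacity, `floor(flash_bytes / bytes_per_event)`.
#' @examples
#' event_capacity(8 * 1024^2, 16)  # 524288
#' @export
event_capacity <- function(flash_bytes, bytes_per_event) {
  if (!is.numeric(flash_bytes) || !is.numeric(bytes_per_event) ||
      flash_bytes <= 0 || bytes_per_event <= 0) {
    stopf("flash_bytes and bytes_per_event must be positive")
  }
  as.integer(flash_bytes %/% bytes_per_event)
}

#' Battery survival summary
#'
#' Counts tags whose last recorded activity reached at least `threshold_s`
#' wall-clock seconds into the deployment, i.e. whose batteries lasted the
#' distance. A tag with no stored records counts as failed.
#'
#' @param logs A `tag_logs` object from [emulate_tags()].
#' @param threshold_s Wall-clock second the last activity must reach.
#' @return A list with `n_survived`, `n_total` and `percent`
#'   (= 100 * n_survived / n_total, rounded to one decimal).
#' @export
battery_survival_summary <- function(logs, threshold_s) {
  stopifnot(inherits(logs, "tag_logs"))
  if (nrow(logs$tags) == 0) stopf("no tag logs supplied")
  last <- logs$tags$last_activity_wall_s
  n_surv <- sum(!is.na(last) & last >= threshold_s)
  n_tot <- nrow(logs$tags)
  list(n_survived = n_surv, n_total = n_tot,
       percent = round(100 * n_surv / n_tot, 1))
}
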