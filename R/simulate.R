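#' Simulate ground-truth proximity between tags
#'
#' Generates the per-second "within detection range" indicator stream for all
#' tag pairs implied by a facility scenario. The state model is entirely
#' schedule-driven:
#'
#' * Overnight (outside the turnout window) horses are in their stalls;
#'   same-aisle pairs come into range in alternating exponential on/off bouts.
#' * During turnout all halter tags of horses sharing a pasture hang together
#'   on the fence hook, so they are continuously mutually in range and in
#'   range of that pasture's static tag.
#' * Leaving for and returning from pasture puts each horse tag briefly in
#'   range of the barn door and its aisle tag (a fixed-length transit window);
#'   on weekend days horses also walk past the weekend pasture's tag.
#' * Training/grooming bouts put a horse in range of an arena, wash-stall,
#'   grooming-stall or cross-tie tag and of the handling person's tag.
#' * On-shift people make short entry/exit transits past static location tags;
#'   off-shift person tags sit with the bookkeeping tag and are continuously
#'   in range of it.
#'
#' The stream is the simulation's ground truth: it knows nothing of tag
#' batteries, clocks, missed detections or memory -- those belong to
#' [emulate_tags()].
#'
#' @param scenario A `scenario` from [build_scenario()].
#' @param seed Integer seed; identical seeds give identical streams.
#' @return A `proximity_stream`: a data.table with integer column `second`
#'   (wall-clock seconds since deployment start) and character columns
#'   `tag_a` < `tag_b` (the unordered in-range pair), one row per
#'   (second, pair), with attribute `total_seconds`.
#' @examples
#' sc <- default_scenario()
#' ps <- simulate_proximity(sc, seed = 1)
#' @export
simulate_proximity <- function(scenario, seed) {
  stopifnot(inherits(scenario, "scenario"))
  with_local_seed(derive_seed(seed, 1L), {
    iv <- rbind(
      turnout_intervals(scenario),
      transit_intervals(scenario),
      stall_intervals(scenario),
      training_intervals(scenario),
      person_transit_intervals(scenario),
      offshift_intervals(scenario)
    )
    op <- order_pair(iv$tag_a, iv$tag_b)
    iv$tag_a <- op$a
    iv$tag_b <- op$b
    total <- scenario$n_days * 86400L
    iv$start <- pmax(iv$start, 0L)
    iv$end <- pmin(iv$end, total)
    stream <- expand_intervals(merge_pair_intervals(iv))
  })
  setorder(stream, second)
  structure(stream, total_seconds = total,
            class = c("proximity_stream", class(stream)))
}

#' Construct a proximity stream from per-second samples
#'
#' Builds a `proximity_stream` from a data.frame of `(second, tag_a, tag_b)`
#' samples, canonicalising pair order and dropping duplicates. Useful for
#' feeding hand-built or externally recorded proximity data to
#' [emulate_tags()] or [truth_networks()].
#'
#' @param samples Data.frame with integer `second` and character `tag_a`,
#'   `tag_b` columns.
#' @param total_seconds Stream length; defaults to `max(second) + 1`.
#' @return A `proximity_stream`.
#' @export
as_proximity_stream <- function(samples, total_seconds = NULL) {
  dt <- as.data.table(as.data.frame(samples))[, .(second, tag_a, tag_b)]
  if (nrow(dt) > 0 && any(dt$tag_a == dt$tag_b)) {
    stopf("a tag cannot be in range of itself")
  }
  dt[, second := as.integer(second)]
  op <- order_pair(dt$tag_a, dt$tag_b)
  dt[, `:=`(tag_a = op$a, tag_b = op$b)]
  dt <- unique(dt, by = c("second", "tag_a", "tag_b"))
  setorder(dt, second)
  total <- as.integer(total_seconds %||%
                        (if (nrow(dt) > 0) max(dt$second) + 1L else 0L))
  structure(dt, total_seconds = total,
            class = c("proximity_stream", class(dt)))
}

# Union overlapping/touching intervals within each pair so the expanded
# stream has each (second, pair) at most once.
merge_pair_intervals <- function(iv) {
  dt <- as.data.table(iv)[end > start]
  if (nrow(dt) == 0) return(dt)
  setorder(dt, tag_a, tag_b, start, end)
  dt[, run := {
    prev_end <- shift(cummax(end), fill = NA)
    cumsum(is.na(prev_end) | start > prev_end)
  }, by = .(tag_a, tag_b)]
  dt[, .(start = min(start), end = max(end)), by = .(tag_a, tag_b, run)][
    , .(start, end, tag_a, tag_b)]
}

# Expand half-open intervals [start, end) into one row per second.
expand_intervals <- function(iv) {
  iv <- as.data.table(iv)
  if (nrow(iv) == 0) {
    return(data.table(second = integer(), tag_a = character(), tag_b = character()))
  }
  iv <- iv[end > start]
  n <- iv$end - iv$start
  data.table(
    second = as.integer(sequence(n, from = iv$start)),
    tag_a = rep(iv$tag_a, n),
    tag_b = rep(iv$tag_b, n)
  )
}

empty_iv <- function() {
  data.frame(start = integer(), end = integer(),
             tag_a = character(), tag_b = character())
}

iv_df <- function(start, end, tag_a, tag_b) {
  data.frame(start = as.integer(start), end = as.integer(end),
             tag_a = tag_a, tag_b = tag_b)
}

# Pasture assignment of each horse on a given study day (1-based).
pasture_on_day <- function(scenario, day) {
  h <- scenario$horses
  if (day %in% scenario$weekend_days) h$weekend_pasture else h$weekday_pasture
}

turnout_intervals <- function(sc) {
  out <- list()
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    s <- base + sc$turnout_start_s
    e <- base + sc$turnout_end_s
    pasture <- pasture_on_day(sc, day)
    for (p in unique(pasture)) {
      ids <- sc$horses$id[pasture == p]
      if (length(ids) >= 2) {
        pairs <- utils::combn(ids, 2)
        out[[length(out) + 1]] <- iv_df(s, e, pairs[1, ], pairs[2, ])
      }
      if (p %in% sc$static_tags$id) {
        out[[length(out) + 1]] <- iv_df(s, e, ids, p)
      }
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

transit_intervals <- function(sc) {
  tr <- sc$params$transit_s
  doors <- sc$static_tags$id[sc$static_tags$kind == "barn_door"]
  door <- if (length(doors) > 0) doors[1] else NULL
  out <- list()
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    for (leg_start in c(base + sc$turnout_start_s - tr, base + sc$turnout_end_s)) {
      for (i in seq_len(nrow(sc$horses))) {
        h <- sc$horses[i, ]
        aisle_tag <- sc$static_tags$id[sc$static_tags$kind == "aisle" &
                                       !is.na(sc$static_tags$link) &
                                       sc$static_tags$link == h$aisle]
        near <- c(door, aisle_tag)
        if (day %in% sc$weekend_days) {
          wk <- sc$static_tags$id[sc$static_tags$kind == "pasture" &
                                  sc$static_tags$id %in% sc$horses$weekend_pasture &
                                  !sc$static_tags$id %in% sc$horses$weekday_pasture]
          near <- c(near, wk)
        }
        if (length(near) > 0) {
          out[[length(out) + 1]] <- iv_df(leg_start, leg_start + tr, h$id, near)
        }
      }
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

# Alternating exponential off/on bouts over [block_start, block_end).
renewal_bouts <- function(block_start, block_end, mean_on, mean_off) {
  t <- block_start + rexp(1, 1 / mean_off)
  out <- list()
  while (t < block_end) {
    on <- rexp(1, 1 / mean_on)
    s <- floor(t)
    e <- min(ceiling(t + on), block_end)
    if (e > s) out[[length(out) + 1]] <- c(s, e)
    t <- t + on + rexp(1, 1 / mean_off)
  }
  out
}

# Contiguous non-turnout blocks over the whole study (evenings run across
# midnight into the next morning, so stall bouts can straddle day boundaries).
night_blocks <- function(sc) {
  total <- sc$n_days * 86400L
  bounds <- c(0L)
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    bounds <- c(bounds, base + sc$turnout_start_s, base + sc$turnout_end_s)
  }
  bounds <- c(bounds, total)
  m <- matrix(bounds, ncol = 2, byrow = TRUE)
  m[m[, 1] < m[, 2], , drop = FALSE]
}

stall_intervals <- function(sc) {
  h <- sc$horses
  blocks <- night_blocks(sc)
  out <- list()
  for (aisle in unique(h$aisle)) {
    ids <- h$id[h$aisle == aisle]
    if (length(ids) < 2) next
    pairs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(pairs))) {
      for (b in seq_len(nrow(blocks))) {
        bouts <- renewal_bouts(blocks[b, 1], blocks[b, 2],
                               sc$params$stall_bout_on_s,
                               sc$params$stall_bout_off_s)
        for (bt in bouts) {
          out[[length(out) + 1]] <- iv_df(bt[1], bt[2], pairs[1, k], pairs[2, k])
        }
      }
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

# People on shift during wall-second `s` of day `day`.
people_on_shift <- function(sc, day, s) {
  p <- sc$people
  keep <- vapply(seq_len(nrow(p)), function(i) {
    day %in% p$days[[i]] && s >= p$shift_start_s[i] && s < p$shift_end_s[i]
  }, logical(1))
  p$id[keep]
}

training_intervals <- function(sc) {
  kinds <- c("arena", "wash_stall", "grooming_stall", "cross_tie")
  spots <- sc$static_tags$id[sc$static_tags$kind %in% kinds]
  win <- sc$params$train_window_s
  out <- list()
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    for (hid in sc$horses$id) {
      if (runif(1) > sc$params$p_train) next
      s0 <- floor(runif(1, win[1], win[2]))
      dur <- max(60, ceiling(rexp(1, 1 / sc$params$train_mean_s)))
      e0 <- min(s0 + dur, 86400L)
      spot <- if (length(spots) > 0) sample(spots, 1) else NULL
      handler <- people_on_shift(sc, day, s0)
      handler <- if (length(handler) > 0) sample(handler, 1) else NULL
      for (other in c(spot, handler)) {
        out[[length(out) + 1]] <- iv_df(base + s0, base + e0, hid, other)
      }
      if (!is.null(spot) && !is.null(handler)) {
        out[[length(out) + 1]] <- iv_df(base + s0, base + e0, handler, spot)
      }
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

person_transit_intervals <- function(sc) {
  tr <- sc$params$transit_s
  k <- sc$params$person_transits_per_day
  spots <- sc$static_tags$id
  out <- list()
  if (length(spots) == 0 || k == 0) return(empty_iv())
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    for (i in seq_len(nrow(sc$people))) {
      p <- sc$people[i, ]
      if (!day %in% p$days[[1]]) next
      starts <- floor(runif(k, p$shift_start_s, max(p$shift_start_s + 1, p$shift_end_s - tr)))
      where <- sample(spots, k, replace = TRUE)
      out[[length(out) + 1]] <- iv_df(base + starts, base + starts + tr, p$id, where)
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

offshift_intervals <- function(sc) {
  bk <- sc$bookkeeping_tag_id
  out <- list()
  for (day in seq_len(sc$n_days)) {
    base <- (day - 1L) * 86400L
    for (i in seq_len(nrow(sc$people))) {
      p <- sc$people[i, ]
      if (day %in% p$days[[1]]) {
        out[[length(out) + 1]] <- iv_df(base, base + p$shift_start_s, p$id, bk)
        out[[length(out) + 1]] <- iv_df(base + p$shift_end_s, base + 86400L, p$id, bk)
      } else {
        out[[length(out) + 1]] <- iv_df(base, base + 86400L, p$id, bk)
      }
    }
  }
  do.call(rbind, c(out, list(empty_iv())))
}

#' Ground-truth daily networks from a proximity stream
#'
#' Bins a proximity stream into day-long undirected weighted edge lists.
#' With the defaults each in-range pair-second contributes 1/3600 h to the
#' day bin the second falls in (exact conservation). Setting `washout_s > 0`
#' first merges each pair's in-range seconds into contact bouts, closing a
#' bout only after `washout_s` consecutive silent seconds -- the same
#' segmentation rule the tags apply -- and `bin = "event_start"` credits a
#' bout's whole duration (last minus first in-range second) to the day of its
#' first second, mirroring the downstream aggregation convention. These
#' options exist so the truth can be expressed in the same currency as the
#' tag-derived networks when validating recovery.
#'
#' @param stream A `proximity_stream`.
#' @param day_length_s Seconds per day bin (default 86400).
#' @param washout_s 0 for raw per-second binning; otherwise the gap (s) that
#'   terminates a contact bout.
#' @param bin `"second"` (each in-range second credited to its own day) or
#'   `"event_start"` (whole bout credited to the day of its first second;
#'   only meaningful with `washout_s > 0`).
#' @return A `truth_network_set`: a list with one data.frame per day
#'   (`tag_a`, `tag_b`, `weight_hours`), plus attribute `n_days`.
#' @export
truth_networks <- function(stream, day_length_s = 86400L, washout_s = 0L,
                           bin = c("second", "event_start")) {
  bin <- match.arg(bin)
  stopifnot(day_length_s > 0)
  total <- attr(stream, "total_seconds") %||%
    (if (nrow(stream) > 0) max(stream$second) + 1L else 0L)
  n_days <- max(1L, as.integer(ceiling(total / day_length_s)))
  dt <- as.data.table(stream)
  if (nrow(dt) == 0) {
    return(empty_truth_set(n_days))
  }
  if (washout_s > 0) {
    setorder(dt, tag_a, tag_b, second)
    dt[, new_bout := {
      gap <- second - shift(second) - 1L
      is.na(gap) | gap >= washout_s
    }, by = .(tag_a, tag_b)]
    dt[, bout := cumsum(new_bout), by = .(tag_a, tag_b)]
    ev <- dt[, .(start = min(second), end = max(second)),
             by = .(tag_a, tag_b, bout)]
    if (bin == "event_start") {
      ev[, day := as.integer(start %/% day_length_s) + 1L]
      w <- ev[, .(weight_hours = sum(end - start) / 3600), by = .(day, tag_a, tag_b)]
    } else {
      # split each bout's duration-bearing seconds (start, end] across days
      secs <- ev[end > start,
                 .(second = as.integer(sequence(end - start, from = start + 1L))),
                 by = .(tag_a, tag_b, bout)]
      secs[, day := as.integer(second %/% day_length_s) + 1L]
      w <- secs[, .(weight_hours = .N / 3600), by = .(day, tag_a, tag_b)]
    }
  } else {
    dt[, day := as.integer(second %/% day_length_s) + 1L]
    w <- dt[, .(weight_hours = .N / 3600), by = .(day, tag_a, tag_b)]
  }
  out <- empty_truth_set(n_days)
  for (d in seq_len(n_days)) {
    wd <- w[day == d][order(tag_a, tag_b)]
    out[[d]] <- as.data.frame(wd[, .(tag_a, tag_b, weight_hours)])
  }
  out
}

empty_truth_set <- function(n_days) {
  out <- replicate(n_days, data.frame(tag_a = character(), tag_b = character(),
                                      weight_hours = numeric()),
                   simplify = FALSE)
  structure(out, n_days = n_days, class = "truth_network_set")
}

#' Export a proximity stream as CSV (diagnostic)
#'
#' @param stream A `proximity_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proximity_csv <- function(stream, path) {
  data.table::fwrite(as.data.table(stream)[, .(second, tag_a, tag_b)], path)
  invisible(path)
}

utils::globalVariables(c(
  "second", "tag_a", "tag_b", "new_bout", "bout", "day", "end", "start",
  "weight_hours", "run"
))
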