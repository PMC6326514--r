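#' Emulate flash-logging proximity tags over a ground-truth stream
#'
#' Replays a [simulate_proximity()] stream through a software model of the
#' tag firmware. Each second a powered tag senses the partners in range and
#' maintains one session per partner: the session opens (`BEGIN`) at the
#' first sensed second, emits an `ONGOING` record every `ongoing_every_s`
#' seconds while open, and closes (`END`) once the partner has been silent
#' for `washout_s` consecutive seconds -- the recorded end time is the last
#' sensed second, so silent gaps shorter than the washout are absorbed into
#' one event. Both participants record the session independently on their
#' own counter clocks (tag-local time = wall time minus the battery-insertion
#' offset).
#'
#' Hardware imperfections modelled per tag: sensing only while powered
#' (between battery insertion and depletion), sporadic restarts (during a
#' restart gap the tag neither senses nor is sensed; gaps shorter than the
#' washout are absorbed, longer ones split the event), per-second missed
#' detections (`p_miss`), spurious detections of configured non-proximal
#' partners (`p_spurious`), and a finite flash memory: once
#' `memory_capacity_events` records are stored the tag keeps sensing but
#' stores nothing further. Within one second a tag processes detected
#' partners sequentially in seeded-random order, which affects record
#' ordering only. An `END` record is only written if the tag is still
#' powered when the washout elapses; otherwise the session is left open in
#' the log (an orphan the cleaning stage closes and flags).
#'
#' @param stream A `proximity_stream`.
#' @param params A `tag_params` table covering every tag in the stream.
#' @param seed Integer seed for miss/spurious/restart draws.
#' @param trial_id Integer trial number stamped on every record.
#' @param ongoing_every_s Cadence of `ONGOING` records (default 60 s).
#' @return A `tag_logs` object: `$records` (one row per stored record:
#'   `tag_id`, `trial_id`, `source_internal_id`, `partner_internal_id`,
#'   `source_time_s`, `partner_time_s`, `status` 1=BEGIN/2=ONGOING/3=END, in
#'   storage order per tag) and `$tags` (per-tag `events_stored`,
#'   `truncated`, `last_activity_wall_s`), plus the `params` used.
#' @export
emulate_tags <- function(stream, params, seed = 1L, trial_id = 1L,
                         ongoing_every_s = 60L) {
  params <- validate_tag_params(as.data.frame(params))
  dt <- as.data.table(stream)
  tags_in_stream <- unique(c(dt$tag_a, dt$tag_b))
  missing <- setdiff(tags_in_stream, params$tag_id)
  if (length(missing) > 0) {
    stopf("no tag params for stream tag(s): %s", paste(missing, collapse = ", "))
  }
  total <- attr(stream, "total_seconds") %||%
    (if (nrow(dt) > 0) max(dt$second) + 1L else 0L)

  # integer tag codes for the heavy per-second operations
  lev <- params$tag_id
  offset <- params$clock_offset_s
  washout <- params$washout_s
  death <- params$clock_offset_s + params$battery_life_s
  cap <- params$memory_capacity_events
  ca <- match(dt$tag_a, lev)
  cb <- match(dt$tag_b, lev)

  with_local_seed(derive_seed(seed, 3L), {
    down <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      iv <- list()
      if (p$clock_offset_s > 0) iv[[length(iv) + 1]] <- c(0, p$clock_offset_s)
      d <- p$clock_offset_s + p$battery_life_s
      if (d < total) iv[[length(iv) + 1]] <- c(d, Inf)
      if (p$restart_rate_per_day > 0 && total > 0) {
        nr <- rpois(1, p$restart_rate_per_day * total / 86400)
        if (nr > 0) {
          rs <- sort(floor(runif(nr, 0, total)))
          for (r in rs) iv[[length(iv) + 1]] <- c(r, r + p$restart_gap_s)
        }
      }
      iv
    })
    names(down) <- params$tag_id

    sensed <- data.table(tag = c(ca, cb), partner = c(cb, ca),
                         second = rep(dt$second, 2L))

    # drop seconds where either endpoint is unpowered or restarting;
    # merged down intervals become sorted boundary vectors so membership is
    # a findInterval parity test
    bnd <- lapply(down, function(iv) {
      if (length(iv) == 0) return(NULL)
      m <- do.call(rbind, iv)
      m <- m[order(m[, 1]), , drop = FALSE]
      merged <- list(m[1, ])
      for (r in seq_len(nrow(m))[-1]) {
        last <- merged[[length(merged)]]
        if (m[r, 1] <= last[2]) {
          merged[[length(merged)]][2] <- max(last[2], m[r, 2])
        } else merged[[length(merged) + 1]] <- m[r, ]
      }
      as.numeric(t(do.call(rbind, merged)))
    })
    if (any(!vapply(bnd, is.null, logical(1)))) {
      sensed[, keep := TRUE]
      sensed[, keep := {
        b <- bnd[[.BY[[1]]]]
        if (is.null(b)) keep else findInterval(second, b) %% 2L == 0L
      }, by = tag]
      sensed[keep == TRUE, keep := {
        b <- bnd[[.BY[[1]]]]
        if (is.null(b)) keep else findInterval(second, b) %% 2L == 0L
      }, by = partner]
      sensed <- sensed[keep == TRUE][, keep := NULL]
    }

    # per-recorder missed detections
    pm <- params$p_miss
    if (any(pm > 0)) {
      sensed <- sensed[runif(.N) >= pm[tag]]
    }

    # spurious detections of configured candidates (one-sided)
    for (i in which(params$p_spurious > 0)) {
      cand <- match(params$spurious_candidates[[i]], lev)
      cand <- cand[!is.na(cand)]
      if (length(cand) == 0 || total == 0) next
      up <- up_seconds_sample(total, down[[i]], params$p_spurious[i])
      if (length(up) > 0) {
        sensed <- rbind(sensed, data.table(
          tag = i, partner = sample(cand, length(up), replace = TRUE),
          second = up
        ))
        sensed <- unique(sensed, by = c("tag", "partner", "second"))
      }
    }

    if (nrow(sensed) == 0) {
      return(empty_tag_logs(params, trial_id))
    }

    setorder(sensed, tag, partner, second)
    sensed[, new_ev := {
      gap <- second - shift(second) - 1L
      is.na(gap) | gap >= washout[.BY[[1]]]
    }, by = .(tag, partner)]
    sensed[, ev := cumsum(new_ev), by = .(tag, partner)]
    events <- sensed[, .(start = min(second), end = max(second)),
                     by = .(tag, partner, ev)]

    # expand events into BEGIN / ONGOING / END records with write times
    n_ong <- ifelse(events$end > events$start,
                    (events$end - events$start - 1L) %/% ongoing_every_s, 0L)
    beg <- events[, .(tag, partner, time = start, status = 1L, write = as.numeric(start))]
    ong <- events[rep(seq_len(.N), n_ong)]
    if (nrow(ong) > 0) {
      ong[, k := sequence(n_ong[n_ong > 0])]
      ong <- ong[, .(tag, partner, time = start + k * ongoing_every_s,
                     status = 2L, write = as.numeric(start + k * ongoing_every_s))]
    } else {
      ong <- beg[0]
    }
    fin <- events[end + washout[tag] < death[tag],
                  .(tag, partner, time = end, status = 3L,
                    write = as.numeric(end) + washout[tag])]
    recs <- rbindlist(list(beg, ong, fin))

    # storage order: write time, random tiebreak (one-partner-at-a-time);
    # an END detected in the same second as a new BEGIN is stored first so
    # the per-pair record stream stays well formed
    recs[, tie := runif(.N)]
    recs[, stprio := -status]
    setorder(recs, tag, write, stprio, tie)
    recs[, slot := seq_len(.N), by = tag]
    stored <- recs[slot <= cap[tag]]

    stored[, `:=`(
      trial_id = as.integer(trial_id),
      source_internal_id = params$internal_id[tag],
      partner_internal_id = params$internal_id[partner],
      source_time_s = pmax(0, time - offset[tag]),
      partner_time_s = pmax(0, time - offset[partner])
    )]

    tagsum <- stored[, .(events_stored = .N,
                         last_activity_wall_s = max(time)), by = .(code = tag)]
    tagsum <- merge(data.table(code = seq_along(lev)), tagsum,
                    by = "code", all.x = TRUE)
    tagsum[is.na(events_stored), events_stored := 0L]
    tagsum[, `:=`(tag_id = lev[code], truncated = events_stored >= cap[code])]

    structure(list(
      records = as.data.frame(stored[, .(
        tag_id = lev[tag], trial_id, source_internal_id, partner_internal_id,
        source_time_s = as.integer(source_time_s),
        partner_time_s = as.integer(partner_time_s), status
      )]),
      tags = as.data.frame(tagsum[, .(tag_id, events_stored,
                                      last_activity_wall_s, truncated)]),
      params = params,
      trial_id = as.integer(trial_id)
    ), class = "tag_logs")
  })
}

empty_tag_logs <- function(params, trial_id) {
  structure(list(
    records = data.frame(tag_id = character(), trial_id = integer(),
                         source_internal_id = integer(),
                         partner_internal_id = integer(),
                         source_time_s = integer(), partner_time_s = integer(),
                         status = integer()),
    tags = data.frame(tag_id = params$tag_id, events_stored = 0L,
                      last_activity_wall_s = NA_real_, truncated = FALSE),
    params = params,
    trial_id = as.integer(trial_id)
  ), class = "tag_logs")
}

# Bernoulli(p) draw over the powered seconds of [0, total), returned as the
# sampled second indices; used for spurious detections.
up_seconds_sample <- function(total, down_iv, p) {
  secs <- integer(0)
  if (p <= 0 || total <= 0) return(secs)
  n <- rbinom(1, total, p)
  if (n == 0) return(secs)
  draw <- unique(floor(runif(n, 0, total)))
  if (length(down_iv) > 0) {
    bad <- rep(FALSE, length(draw))
    for (b in down_iv) bad <- bad | (draw >= b[1] & draw < b[2])
    draw <- draw[!bad]
  }
  as.integer(draw)
}

#' @export
print.tag_logs <- function(x, ...) {
  cat(sprintf("<tag_logs> %d tags, %d stored records (trial %d)\n",
              nrow(x$tags), nrow(x$records), x$trial_id))
  invisible(x)
}

#' Write raw tag logs and the tag registry to CSV
#'
#' Writes one CSV per tag (`raw_<tag>.csv`) plus a combined
#' `raw_combined.csv`, with columns
#' `trial_id,source_internal_id,partner_internal_id,source_time_s,partner_time_s,status`,
#' and the registry as `registry.csv`. This is the interchange format the
#' cleaning stage consumes.
#'
#' @param logs A `tag_logs` object.
#' @param dir Output directory (created if needed).
#' @param registry Optional registry from [build_registry()]; written when
#'   supplied.
#' @return `dir`, invisibly.
#' @export
write_tag_logs <- function(logs, dir, registry = NULL) {
  stopifnot(inherits(logs, "tag_logs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("trial_id", "source_internal_id", "partner_internal_id",
            "source_time_s", "partner_time_s", "status")
  for (tg in logs$tags$tag_id) {
    sub <- logs$records[logs$records$tag_id == tg, cols]
    data.table::fwrite(sub, file.path(dir, sprintf("raw_%s.csv", tg)))
  }
  data.table::fwrite(logs$records[, cols], file.path(dir, "raw_combined.csv"))
  if (!is.null(registry)) {
    data.table::fwrite(as.data.frame(registry), file.path(dir, "registry.csv"))
  }
  invisible(dir)
}

utils::globalVariables(c(
  "tag", "partner", "w", "new_ev", "ev", "k", "tie", "slot", "time", "status",
  "source_time_s", "partner_time_s", "source_internal_id",
  "partner_internal_id", "events_stored", "tag_id", "truncated",
  "last_activity_wall_s", "write", "stprio", "ca", "cb", "keep", "code"
))
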