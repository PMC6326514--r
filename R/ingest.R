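#' Tag registry
#'
#' The registry maps each tag's external label to its internal 32-bit id,
#' carries its role (`horse`, `person`, `location`, `bookkeeping`) and the
#' wall-clock anchor of its battery insertion (the second at which its
#' counter clock started). The mapping must be one-to-one and every internal
#' id appearing in a raw log must resolve through it.
#'
#' @param params A `tag_params` table (supplies ids and anchors).
#' @param roles A data.frame with columns `id`, `role`, e.g.
#'   [scenario_tags()]; tags absent from it get role `"unknown"`.
#' @return A `tag_registry` data.frame with columns `external_id`,
#'   `internal_id`, `role`, `label`, `anchor_wall_s`.
#' @export
build_registry <- function(params, roles = NULL) {
  params <- as.data.frame(params)
  reg <- data.frame(
    external_id = params$tag_id,
    internal_id = params$internal_id,
    role = "unknown",
    label = params$tag_id,
    anchor_wall_s = params$clock_offset_s,
    stringsAsFactors = FALSE
  )
  if (!is.null(roles)) {
    m <- match(reg$external_id, roles$id)
    reg$role[!is.na(m)] <- roles$role[m[!is.na(m)]]
  }
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("external_id", "internal_id", "role", "anchor_wall_s")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0) stopf("registry lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$external_id) || anyDuplicated(reg$internal_id)) {
    stopf("registry mapping must be one-to-one (duplicate external or internal id)")
  }
  if (is.null(reg$label)) reg$label <- reg$external_id
  class(reg) <- c("tag_registry", "data.frame")
  reg
}

#' Read a registry CSV
#' @param path CSV with columns `external_id,internal_id,role,label,anchor_wall_s`.
#' @return A validated `tag_registry`.
#' @export
read_registry <- function(path) {
  validate_registry(as.data.frame(data.table::fread(path)))
}

registry_bookkeeping <- function(registry) {
  bk <- registry$external_id[registry$role == "bookkeeping"]
  if (length(bk) != 1) {
    stopf("registry must designate exactly one bookkeeping tag (found %d)", length(bk))
  }
  bk
}

#' Screen raw records against the registry
#'
#' Records whose source or partner internal id does not resolve through the
#' registry are rejected (not an error) with a reason code, mirroring the
#' aberrant-data check applied before any further processing.
#'
#' @param records Raw record data.frame (combined-log format from
#'   [emulate_tags()] / [write_tag_logs()]).
#' @param registry A `tag_registry`.
#' @return A list with `clean` and `rejected` data.frames; `rejected` has an
#'   extra `reason` column (`"unregistered_id"`).
#' @export
validate_ids <- function(records, registry) {
  registry <- validate_registry(as.data.frame(registry))
  records <- as.data.frame(records)
  known <- registry$internal_id
  ok <- records$source_internal_id %in% known &
    records$partner_internal_id %in% known
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- "unregistered_id"
  else rejected$reason <- character(0)
  list(clean = records[ok, , drop = FALSE], rejected = rejected)
}

#' Fold per-tag status records into contact events (tag-local clock)
#'
#' Replays each (recording tag, partner) record stream: a `BEGIN` opens a
#' session, `ONGOING` updates its last-seen time, `END` closes it. A session
#' left open when the log ends (battery death, restart, memory truncation)
#' is closed at its last `ONGOING` time -- or its `BEGIN` time if none was
#' seen -- and flagged `"orphan"`. A new `BEGIN` while a session is open
#' closes the previous session the same way. `END` or `ONGOING` records with
#' no open session are rejected with reason codes.
#'
#' @param records Validated raw records (from [validate_ids()]`$clean`).
#' @param registry A `tag_registry` used to translate internal ids.
#' @return A list with `events` (columns `recorder`, `partner`,
#'   `start_local_s`, `end_local_s`, `duration_s`, `flag`) and `rejected`.
#' @export
assemble_events <- function(records, registry) {
  registry <- validate_registry(as.data.frame(registry))
  dt <- as.data.table(records)
  if (nrow(dt) == 0) {
    return(list(events = empty_local_events(), rejected = as.data.frame(dt)))
  }
  ext <- setNames(registry$external_id, as.character(registry$internal_id))
  dt[, recorder := ext[as.character(source_internal_id)]]
  dt[, partner := ext[as.character(partner_internal_id)]]
  dt[, row0 := .I]  # preserve log (storage) order within each pair stream
  dt[, sid := cumsum(status == 1L), by = .(recorder, partner)]

  rejected <- dt[sid == 0L]
  if (nrow(rejected) > 0) {
    rejected[, reason := fifelse(status == 3L, "orphan_end", "orphan_ongoing")]
  } else {
    rejected[, reason := character(0)]
  }

  dt <- dt[sid > 0L]
  if (nrow(dt) == 0) {
    rej_cols <- intersect(c("tag_id", "trial_id", "source_internal_id",
                            "partner_internal_id", "source_time_s",
                            "partner_time_s", "status", "reason"),
                          names(rejected))
    return(list(events = empty_local_events(),
                rejected = as.data.frame(rejected[, ..rej_cols])))
  }
  ev <- dt[, {
    t <- source_time_s
    st <- status
    iend <- which(st == 3L)
    if (length(iend) >= 1) {
      keep <- seq_len(iend[1])
      extra <- .SD[-keep]
      list(start = t[1],
           end = t[iend[1]],
           flag = "",
           n_extra = nrow(extra))
    } else {
      seen <- t[st != 3L]
      list(start = t[1], end = max(seen), flag = "orphan", n_extra = 0L)
    }
  }, by = .(recorder, partner, sid)]

  # records trailing a closed session inside the same sid (no new BEGIN):
  # reject them individually
  extra_rej <- dt[, {
    iend <- which(status == 3L)
    if (length(iend) >= 1 && .N > iend[1]) .SD[(iend[1] + 1L):.N] else .SD[0]
  }, by = .(recorder, partner, sid)]
  if (nrow(extra_rej) > 0) {
    extra_rej[, reason := fifelse(status == 3L, "orphan_end", "orphan_ongoing")]
    rejected <- rbindlist(list(rejected, extra_rej), fill = TRUE)
  }

  events <- as.data.frame(ev[, .(
    recorder, partner,
    start_local_s = as.integer(start),
    end_local_s = as.integer(end),
    duration_s = as.integer(end - start),
    flag
  )])
  rej_cols <- intersect(c("tag_id", "trial_id", "source_internal_id",
                          "partner_internal_id", "source_time_s",
                          "partner_time_s", "status", "reason"),
                        names(rejected))
  list(events = events, rejected = as.data.frame(rejected[, ..rej_cols]))
}

empty_local_events <- function() {
  data.frame(recorder = character(), partner = character(),
             start_local_s = integer(), end_local_s = integer(),
             duration_s = integer(), flag = character())
}

#' Convert tag-local event times to the wall clock
#'
#' Each recording tag's counter started at its battery-insertion anchor, so
#' wall time = tag-local time + anchor.
#'
#' @param events Events from [assemble_events()].
#' @param registry A `tag_registry` with `anchor_wall_s` for every recorder.
#' @return Events with `start_wall_s`, `end_wall_s` replacing the local
#'   columns (recorder/partner and flags retained).
#' @export
to_wall_clock <- function(events, registry) {
  registry <- validate_registry(as.data.frame(registry))
  events <- as.data.frame(events)
  m <- match(events$recorder, registry$external_id)
  if (anyNA(m) || anyNA(registry$anchor_wall_s[m])) {
    stopf("missing battery-insertion anchor for recorder tag(s): %s",
          paste(unique(events$recorder[is.na(m)]), collapse = ", "))
  }
  anchor <- registry$anchor_wall_s[m]
  out <- events
  out$start_wall_s <- events$start_local_s + anchor
  out$end_wall_s <- events$end_local_s + anchor
  out$start_local_s <- NULL
  out$end_local_s <- NULL
  out$duration_s <- out$end_wall_s - out$start_wall_s
  out
}

#' Restrict events to the study window
#'
#' Drops events wholly outside the closed window `[start_wall, end_wall]`
#' and clips events straddling a boundary, recomputing their duration. This
#' implements the study-period filter that lets batteries be inserted and
#' removed away from the deployment site.
#'
#' @param events Wall-clock events.
#' @param start_wall,end_wall Window bounds in wall seconds (`start < end`).
#' @return Filtered (possibly clipped) events.
#' @export
filter_window <- function(events, start_wall, end_wall) {
  if (start_wall >= end_wall) stopf("window start must precede window end")
  events <- as.data.frame(events)
  keep <- events$end_wall_s >= start_wall & events$start_wall_s <= end_wall
  out <- events[keep, , drop = FALSE]
  out$start_wall_s <- pmax(out$start_wall_s, start_wall)
  out$end_wall_s <- pmin(out$end_wall_s, end_wall)
  out$duration_s <- out$end_wall_s - out$start_wall_s
  out
}

#' Delete contacts in the vicinity of the bookkeeping tag
#'
#' Removes (1) every event involving the bookkeeping tag itself and (2) for
#' each tag T, events of T with other tags that temporally overlap an
#' interval during which T was in contact with the bookkeeping tag --
#' operationalising "in the vicinity of the bookkeeping tag" as co-location
#' in time with a bookkeeping contact. Off-shift person tags stored next to
#' the bookkeeping tag therefore have their incidental mutual contacts
#' deleted, which is the purpose of deploying such a tag.
#'
#' @param events Wall-clock events.
#' @param registry A `tag_registry` designating exactly one bookkeeping tag.
#' @return Events with bookkeeping-vicinity contacts removed.
#' @export
remove_bookkeeping <- function(events, registry) {
  registry <- validate_registry(as.data.frame(registry))
  bk <- registry_bookkeeping(registry)
  events <- as.data.frame(events)
  if (nrow(events) == 0) return(events)
  involves_bk <- events$recorder == bk | events$partner == bk
  bk_iv <- events[involves_bk, , drop = FALSE]
  out <- events[!involves_bk, , drop = FALSE]
  if (nrow(bk_iv) == 0 || nrow(out) == 0) return(out)
  # per-tag bookkeeping intervals (from either side's recording)
  per_tag <- split(bk_iv, ifelse(bk_iv$recorder == bk, bk_iv$partner, bk_iv$recorder))
  drop <- rep(FALSE, nrow(out))
  for (tg in names(per_tag)) {
    iv <- per_tag[[tg]]
    sel <- which(out$recorder == tg | out$partner == tg)
    if (length(sel) == 0) next
    for (j in seq_len(nrow(iv))) {
      drop[sel] <- drop[sel] |
        (out$start_wall_s[sel] <= iv$end_wall_s[j] &
         out$end_wall_s[sel] >= iv$start_wall_s[j])
    }
  }
  out[!drop, , drop = FALSE]
}

#' Reconcile the two participants' recordings of each contact
#'
#' A physical contact is normally logged by both tags. Within each unordered
#' pair, events from the two recorders whose start times agree to within
#' `tolerance_s` are matched greedily in time order and collapsed to a single
#' event whose times come from the chosen policy: `"first_tag"` (default --
#' treat the pair's lexicographically first tag as the single source of
#' truth), `"mean"` (average the two recordings' start and end times) or
#' `"max"` (keep the longer recording). Unmatched one-sided events (e.g. the
#' partner restarted or its memory filled) are retained as recorded and
#' flagged `"one_sided"`.
#'
#' @param events Wall-clock events carrying recorder provenance.
#' @param policy Reconciliation policy; see above.
#' @param tolerance_s Maximum start-time discrepancy for a match (default
#'   300 s, the battery-insertion window bound).
#' @return One event per physical contact: columns `tag_a`, `tag_b`
#'   (sorted), `start_wall_s`, `end_wall_s`, `duration_s`, `provenance`,
#'   `flag`.
#' @export
reconcile_duplicates <- function(events, policy = c("first_tag", "mean", "max"),
                                 tolerance_s = 300) {
  policy <- match.arg(policy)
  events <- as.data.frame(events)
  if (nrow(events) == 0) return(empty_contact_events())
  op <- order_pair(events$recorder, events$partner)
  events$tag_a <- op$a
  events$tag_b <- op$b
  out <- list()
  for (key in unique(paste(events$tag_a, events$tag_b, sep = "\r"))) {
    pairids <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- events[events$tag_a == pairids[1] & events$tag_b == pairids[2], , drop = FALSE]
    a_ev <- sub[sub$recorder == pairids[1], , drop = FALSE]
    b_ev <- sub[sub$recorder == pairids[2], , drop = FALSE]
    a_ev <- a_ev[order(a_ev$start_wall_s), , drop = FALSE]
    b_ev <- b_ev[order(b_ev$start_wall_s), , drop = FALSE]
    i <- 1L; j <- 1L
    while (i <= nrow(a_ev) || j <= nrow(b_ev)) {
      if (i <= nrow(a_ev) && j <= nrow(b_ev) &&
          abs(a_ev$start_wall_s[i] - b_ev$start_wall_s[j]) <= tolerance_s) {
        out[[length(out) + 1]] <- merge_pair_events(
          a_ev[i, ], b_ev[j, ], pairids, policy)
        i <- i + 1L; j <- j + 1L
      } else if (j > nrow(b_ev) ||
                 (i <= nrow(a_ev) && a_ev$start_wall_s[i] < b_ev$start_wall_s[j])) {
        out[[length(out) + 1]] <- one_sided_event(a_ev[i, ], pairids)
        i <- i + 1L
      } else {
        out[[length(out) + 1]] <- one_sided_event(b_ev[j, ], pairids)
        j <- j + 1L
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_wall_s, res$tag_a, res$tag_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

merge_pair_events <- function(a, b, pairids, policy) {
  if (policy == "first_tag") {
    s <- a$start_wall_s; e <- a$end_wall_s; prov <- a$recorder
  } else if (policy == "mean") {
    s <- round((a$start_wall_s + b$start_wall_s) / 2)
    e <- round((a$end_wall_s + b$end_wall_s) / 2)
    prov <- "mean"
  } else {
    if ((a$end_wall_s - a$start_wall_s) >= (b$end_wall_s - b$start_wall_s)) {
      s <- a$start_wall_s; e <- a$end_wall_s; prov <- a$recorder
    } else {
      s <- b$start_wall_s; e <- b$end_wall_s; prov <- b$recorder
    }
  }
  flag <- paste(setdiff(unique(c(a$flag, b$flag)), ""), collapse = "+")
  data.frame(tag_a = pairids[1], tag_b = pairids[2],
             start_wall_s = s, end_wall_s = e, duration_s = e - s,
             provenance = prov, flag = flag, stringsAsFactors = FALSE)
}

one_sided_event <- function(a, pairids) {
  flag <- paste(c(setdiff(a$flag, ""), "one_sided"), collapse = "+")
  data.frame(tag_a = pairids[1], tag_b = pairids[2],
             start_wall_s = a$start_wall_s, end_wall_s = a$end_wall_s,
             duration_s = a$end_wall_s - a$start_wall_s,
             provenance = a$recorder, flag = flag, stringsAsFactors = FALSE)
}

empty_contact_events <- function() {
  data.frame(tag_a = character(), tag_b = character(),
             start_wall_s = numeric(), end_wall_s = numeric(),
             duration_s = numeric(), provenance = character(),
             flag = character())
}

#' Run the full cleaning pipeline on raw tag logs
#'
#' Convenience wrapper: registry screening, session folding, wall-clock
#' conversion, study-window filtering, bookkeeping-vicinity deletion and
#' duplicate reconciliation, in that order.
#'
#' @param logs A `tag_logs` object (or its combined records data.frame).
#' @param registry A `tag_registry`.
#' @param window Optional numeric length-2 wall-second study window.
#' @param policy,tolerance_s Passed to [reconcile_duplicates()].
#' @return Reconciled `ContactEvent` data.frame (see
#'   [reconcile_duplicates()]).
#' @export
clean_contacts <- function(logs, registry, window = NULL,
                           policy = "first_tag", tolerance_s = 300) {
  records <- if (inherits(logs, "tag_logs")) logs$records else as.data.frame(logs)
  v <- validate_ids(records, registry)
  a <- assemble_events(v$clean, registry)
  ev <- to_wall_clock(a$events, registry)
  if (!is.null(window)) ev <- filter_window(ev, window[1], window[2])
  ev <- remove_bookkeeping(ev, registry)
  reconcile_duplicates(ev, policy = policy, tolerance_s = tolerance_s)
}

#' Write / read reconciled contact events
#' @param events Contact events from [reconcile_duplicates()].
#' @param path CSV path.
#' @return `path` (write) or the events data.frame (read).
#' @export
write_events_csv <- function(events, path) {
  data.table::fwrite(as.data.frame(events)[, c(
    "tag_a", "tag_b", "start_wall_s", "end_wall_s", "duration_s", "flag")], path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

utils::globalVariables(c(
  "recorder", "sid", "row0", "reason", "..rej_cols", "flag"
))
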