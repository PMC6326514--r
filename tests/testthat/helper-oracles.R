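# Independent oracles and small fixture builders used across the suite.

# Brute-force washout segmentation: walk the sensed seconds one by one,
# counting consecutive silence; close the open bout once the silence reaches
# `washout` seconds. Returns one row per bout (start, end = last sensed).
oracle_washout_segment <- function(secs, washout) {
  secs <- sort(unique(as.integer(secs)))
  starts <- integer(0)
  ends <- integer(0)
  cur_start <- NA_integer_
  last <- NA_integer_
  for (s in secs) {
    if (is.na(cur_start)) {
      cur_start <- s
    } else if (s - last - 1L >= washout) {
      starts <- c(starts, cur_start)
      ends <- c(ends, last)
      cur_start <- s
    }
    last <- s
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start)
    ends <- c(ends, last)
  }
  data.frame(start = starts, end = ends)
}

# Exhaustive pair-enumeration classification oracle.
oracle_classify <- function(ids, gold_pairs, test_pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  gold <- if (nrow(gold_pairs)) key(gold_pairs[[1]], gold_pairs[[2]]) else character(0)
  test <- if (nrow(test_pairs)) key(test_pairs[[1]], test_pairs[[2]]) else character(0)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      k <- key(ids[i], ids[j])
      in_g <- k %in% gold
      in_t <- k %in% test
      if (in_g && in_t) tp <- tp + 1L
      else if (!in_g && in_t) fp <- fp + 1L
      else if (in_g && !in_t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  rt <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sn = rt(tp, tp + fn), sp = rt(tn, tn + fp),
       ppv = rt(tp, tp + fp), npv = rt(tn, tn + fn))
}

# Build a proximity stream from inclusive in-range runs:
# runs = data.frame(tag_a, tag_b, start, end) with seconds start..end sensed.
stream_from_runs <- function(runs, total_seconds = NULL) {
  rows <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    data.frame(second = runs$start[i]:runs$end[i],
               tag_a = runs$tag_a[i], tag_b = runs$tag_b[i])
  }))
  as_proximity_stream(rows, total_seconds)
}

# Extract (partner, start, end) events from one recorder's stored records by
# replaying BEGIN/END statuses directly (independent of assemble_events).
events_from_log <- function(logs, recorder) {
  recs <- logs$records[logs$records$tag_id == recorder, , drop = FALSE]
  out <- list()
  open <- list()
  for (i in seq_len(nrow(recs))) {
    p <- as.character(recs$partner_internal_id[i])
    if (recs$status[i] == 1) {
      open[[p]] <- recs$source_time_s[i]
    } else if (recs$status[i] == 3 && !is.null(open[[p]])) {
      out[[length(out) + 1]] <- data.frame(
        partner_internal_id = recs$partner_internal_id[i],
        start = open[[p]], end = recs$source_time_s[i])
      open[[p]] <- NULL
    }
  }
  if (length(out) == 0) {
    return(data.frame(partner_internal_id = integer(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$partner_internal_id, res$start), , drop = FALSE]
}

# A small two-aisle, two-pasture scenario that runs in well under a second.
mini_scenario <- function(n_days = 2L) {
  build_scenario(list(
    horses = list(
      list(id = "h1", stall = 1, aisle = "A", weekday_pasture = "pasture_1"),
      list(id = "h2", stall = 2, aisle = "A", weekday_pasture = "pasture_1"),
      list(id = "h3", stall = 3, aisle = "B", weekday_pasture = "pasture_2"),
      list(id = "h4", stall = 4, aisle = "B", weekday_pasture = "pasture_2")
    ),
    people = list(list(id = "p1", shift_start_s = 25200, shift_end_s = 57600)),
    static_tags = list(
      list(id = "pasture_1", kind = "pasture", link = "pasture_1"),
      list(id = "pasture_2", kind = "pasture", link = "pasture_2"),
      list(id = "barn_door_1", kind = "barn_door"),
      list(id = "aisle_A", kind = "aisle", link = "A"),
      list(id = "aisle_B", kind = "aisle", link = "B")
    ),
    bookkeeping_tag_id = "bk", n_days = n_days, day0_weekday = "Tuesday",
    weekend_days = integer(0)
  ))
}

# End-to-end pipeline on a scenario with given tag params.
run_pipeline <- function(sc, sim_seed = 1L, params = NULL, emu_seed = 1L,
                         policy = "first_tag") {
  ps <- simulate_proximity(sc, seed = sim_seed)
  roster <- scenario_tags(sc)
  if (is.null(params)) params <- ideal_tag_params(roster$id)
  logs <- emulate_tags(ps, params, seed = emu_seed)
  reg <- build_registry(params, roster)
  ev <- clean_contacts(logs, reg, window = c(0, sc$n_days * 86400),
                       policy = policy)
  list(stream = ps, logs = logs, registry = reg, events = ev,
       networks = aggregate_daily(ev, nodes = reg, n_days = sc$n_days))
}

contact_matrix_path <- function() {
  system.file("extdata", "horse_contact_matrix_9x9.csv", package = "equitag")
}
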