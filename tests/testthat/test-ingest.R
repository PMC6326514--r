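make_registry <- function(ids, roles = NULL, anchors = 0L) {
  p <- default_tag_params(ids, seed = 1, clock_offset_s = anchors,
                          battery_life_s = 1e9, p_miss = 0,
                          restart_rate_per_day = 0)
  r <- if (is.null(roles)) NULL else data.frame(id = ids, role = roles)
  build_registry(p, r)
}

test_that("validate_ids rejects unregistered internal ids with a reason", {
  reg <- make_registry(c("a", "b"))
  rec <- data.frame(tag_id = "a", trial_id = 1L,
                    source_internal_id = reg$internal_id[1],
                    partner_internal_id = c(reg$internal_id[2], 999L),
                    source_time_s = c(0L, 5L), partner_time_s = c(0L, 5L),
                    status = c(1L, 1L))
  v <- validate_ids(rec, reg)
  expect_equal(nrow(v$clean), 1)
  expect_equal(nrow(v$rejected), 1)
  expect_equal(v$rejected$reason, "unregistered_id")
  all_known <- validate_ids(rec[1, ], reg)
  expect_equal(nrow(all_known$rejected), 0)

  bad_reg <- as.data.frame(reg)
  bad_reg$internal_id <- bad_reg$internal_id[1]
  expect_error(validate_ids(rec, bad_reg), "one-to-one")
})

test_that("assemble_events folds status streams into events", {
  reg <- make_registry(c("a", "b", "c"))
  iid <- setNames(reg$internal_id, reg$external_id)
  rec <- function(partner, t, s) {
    data.frame(tag_id = "a", trial_id = 1L, source_internal_id = iid[["a"]],
               partner_internal_id = iid[[partner]], source_time_s = t,
               partner_time_s = t, status = s)
  }
  # BEGIN 10, ONGOING 70, END 130 -> one event of 120 s
  r1 <- rbind(rec("b", 10L, 1L), rec("b", 70L, 2L), rec("b", 130L, 3L))
  a1 <- assemble_events(r1, reg)
  expect_equal(nrow(a1$events), 1)
  expect_equal(a1$events$duration_s, 120L)
  expect_equal(a1$events$flag, "")

  # orphan BEGIN with no later records closes degenerately at the BEGIN time
  a2 <- assemble_events(rec("b", 10L, 1L), reg)
  expect_equal(a2$events$start_local_s, 10L)
  expect_equal(a2$events$end_local_s, 10L)
  expect_equal(a2$events$flag, "orphan")

  # orphan BEGIN with ONGOING closes at the last ONGOING
  a3 <- assemble_events(rbind(rec("b", 10L, 1L), rec("b", 70L, 2L)), reg)
  expect_equal(a3$events$end_local_s, 70L)
  expect_equal(a3$events$flag, "orphan")

  # END without BEGIN is rejected
  a4 <- assemble_events(rec("b", 99L, 3L), reg)
  expect_equal(nrow(a4$events), 0)
  expect_equal(a4$rejected$reason, "orphan_end")

  # interleaved sessions with two partners reconstruct independently;
  # oracle replay of the record stream gives the same answer
  r5 <- rbind(rec("b", 10L, 1L), rec("c", 20L, 1L), rec("b", 100L, 3L),
              rec("c", 250L, 3L))
  a5 <- assemble_events(r5, reg)
  expect_equal(nrow(a5$events), 2)
  got <- a5$events[order(a5$events$partner), c("start_local_s", "end_local_s")]
  expect_equal(got$start_local_s, c(10L, 20L))
  expect_equal(got$end_local_s, c(100L, 250L))
})

test_that("wall-clock conversion adds the recorder's insertion anchor", {
  reg <- make_registry(c("a", "b"), anchors = c(100L, 0L))
  ev <- data.frame(recorder = c("a", "b"), partner = c("b", "a"),
                   start_local_s = c(50L, 0L), end_local_s = c(80L, 10L),
                   duration_s = c(30L, 10L), flag = "")
  w <- to_wall_clock(ev, reg)
  expect_equal(w$start_wall_s, c(150L, 0L))
  expect_equal(w$end_wall_s, c(180L, 10L))
  ev_bad <- ev
  ev_bad$recorder <- c("a", "zz")
  expect_error(to_wall_clock(ev_bad, reg), "anchor")
})

test_that("window filter drops outside events and clips straddlers", {
  ev <- data.frame(recorder = "a", partner = "b",
                   start_wall_s = c(0L, 500L, 900L),
                   end_wall_s = c(90L, 600L, 1100L),
                   duration_s = c(90L, 100L, 200L), flag = "")
  f <- filter_window(ev, 100, 1000)
  expect_equal(nrow(f), 2)            # first event wholly before -> dropped
  expect_equal(f$start_wall_s, c(500L, 900L))
  expect_equal(f$end_wall_s, c(600L, 1000L))  # clipped by 100 s
  expect_equal(f$duration_s, c(100L, 100L))
  # idempotence
  expect_equal(filter_window(f, 100, 1000), f)
  expect_error(filter_window(ev, 10, 10), "precede")
})

test_that("bookkeeping-vicinity removal deletes co-located contacts", {
  reg <- make_registry(c("bk", "p3", "p4", "h1", "h2"),
                       roles = c("bookkeeping", "person", "person",
                                 "horse", "horse"))
  ev <- data.frame(
    recorder = c("bk", "p3", "p4", "h1"),
    partner = c("p3", "p4", "p3", "h2"),
    start_wall_s = c(0L, 100L, 5000L, 150L),
    end_wall_s = c(1000L, 200L, 5100L, 400L),
    duration_s = c(1000L, 100L, 100L, 250L), flag = "")
  out <- remove_bookkeeping(ev, reg)
  # direct bookkeeping event removed; p3-p4 contact inside p3's bookkeeping
  # interval removed; p3-p4 contact outside it retained; horses retained
  expect_equal(nrow(out), 2)
  expect_true(any(out$recorder == "p4" & out$start_wall_s == 5000))
  expect_true(any(out$recorder == "h1"))
  # idempotence
  expect_equal(remove_bookkeeping(out, reg), out)
  # a registry without a bookkeeping tag is a configuration error
  reg2 <- make_registry(c("x", "y"), roles = c("person", "person"))
  expect_error(remove_bookkeeping(ev, reg2), "bookkeeping")
})

test_that("reconciliation collapses two-sided recordings per policy", {
  base <- data.frame(
    recorder = c("a", "b"), partner = c("b", "a"),
    start_wall_s = c(1000L, 1003L), end_wall_s = c(1500L, 1509L),
    duration_s = c(500L, 506L), flag = "")
  first <- reconcile_duplicates(base, policy = "first_tag")
  expect_equal(nrow(first), 1)
  expect_equal(first$start_wall_s, 1000L)   # lexicographically first tag: a
  expect_equal(first$end_wall_s, 1500L)
  mn <- reconcile_duplicates(base, policy = "mean")
  expect_equal(mn$start_wall_s, round((1000 + 1003) / 2))
  expect_equal(mn$end_wall_s, round((1500 + 1509) / 2))
  mx <- reconcile_duplicates(base, policy = "max")
  expect_equal(mx$duration_s, 506L)
  # identical events collapse unchanged
  same <- base
  same$start_wall_s <- c(1000L, 1000L)
  same$end_wall_s <- c(1500L, 1500L)
  expect_equal(reconcile_duplicates(same)$duration_s, 500L)
  # one-sided events survive with a flag
  solo <- base[1, ]
  out <- reconcile_duplicates(solo)
  expect_match(out$flag, "one_sided")
  # conservation: reconciled total <= recorded total
  expect_lte(first$duration_s, sum(base$duration_s))
})

test_that("events lost on one side are retained and flagged one-sided", {
  # partner b's flash fills after the first contact's three records, so the
  # second contact exists only in a's log
  p <- default_tag_params(c("a", "b"), seed = 1, clock_offset_s = 0,
                          battery_life_s = 1e9, p_miss = 0,
                          restart_rate_per_day = 0,
                          memory_capacity_events = c(524288L, 3L))
  runs <- data.frame(tag_a = c("a", "a"), tag_b = c("b", "b"),
                     start = c(0L, 1000L), end = c(100L, 1100L))
  logs <- emulate_tags(stream_from_runs(runs, 86400L), p, seed = 1)
  expect_true(logs$tags$truncated[logs$tags$tag_id == "b"])
  reg <- build_registry(p, data.frame(id = c("a", "b"),
                                      role = c("horse", "horse")))
  v <- validate_ids(logs$records, reg)
  a <- assemble_events(v$clean, reg)
  ev <- reconcile_duplicates(to_wall_clock(a$events, reg))
  # first contact seen by both -> reconciled; second only by "a" -> one-sided
  expect_equal(nrow(ev), 2)
  expect_equal(ev$flag[ev$start_wall_s == 1000], "one_sided")
  expect_false(grepl("one_sided", ev$flag[ev$start_wall_s == 0]))
})

test_that("ideal end-to-end recovery matches washout-merged truth", {
  sc <- mini_scenario(2L)
  out <- run_pipeline(sc, sim_seed = 21)
  truth <- truth_networks(out$stream, washout_s = 30L, bin = "event_start")
  got <- out$networks
  for (d in seq_along(truth)) {
    td <- truth[[d]]
    gd <- got[[d]]$edges
    # drop bookkeeping-tag pairs from truth (deleted by the pipeline)
    keep <- !(td$tag_a == "bk" | td$tag_b == "bk")
    td <- td[keep, , drop = FALSE]
    m <- merge(td, gd, by = c("tag_a", "tag_b"),
               suffixes = c("_truth", "_got"), all = TRUE)
    m[is.na(m)] <- 0
    expect_true(all(abs(m$weight_hours_truth - m$weight_hours_got) < 1e-9),
                info = paste("day", d))
  }
})
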