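#' Facility scenario construction
#'
#' A *scenario* describes an equine boarding facility well enough to drive the
#' proximity simulator: the horses (stall, barn aisle, weekday and weekend
#' pasture assignments, primary use), the people and their daily shift
#' windows, the static location tags fixed around the facility, one
#' bookkeeping tag that sits with off-shift person tags, the study length and
#' the turnout schedule.
#'
#' `build_scenario()` validates a configuration list (typically read from a
#' YAML or JSON file with [read_scenario_config()]) and returns a `scenario`
#' object. `default_scenario()` returns the built-in one-week scenario: nine
#' horses in a single barn with three aisles, turned out 08:30-16:30 in three
#' pastures (one horse moved to a fourth pasture on the weekend days), six
#' people, seventeen static location tags and one bookkeeping tag -- 33 tags
#' in total.
#'
#' @param config A nested list describing the scenario. Recognised top-level
#'   fields: `horses`, `people`, `static_tags`, `bookkeeping_tag_id`,
#'   `n_days`, `day0_weekday`, `turnout_start_s`, `turnout_end_s`,
#'   `weekend_days`, `params`. See the package vignette for the full schema;
#'   a machine-readable copy ships as
#'   `system.file("extdata", "scenario-schema.json", package = "equitag")`.
#' @return An object of class `scenario`.
#' @examples
#' sc <- default_scenario()
#' nrow(scenario_tags(sc))  # 33 tags
#' @export
build_scenario <- function(config) {
  horses <- as.data.frame(
    data.table::rbindlist(lapply(config$horses, as.data.frame), fill = TRUE)
  )
  need <- c("id", "stall", "aisle", "weekday_pasture")
  miss <- setdiff(need, names(horses))
  if (length(miss) > 0 || anyNA(horses[intersect(need, names(horses))])) {
    stopf("every horse needs an id, a stall, an aisle and a weekday pasture (missing: %s)",
          paste(miss, collapse = ", "))
  }
  if (is.null(horses$weekend_pasture)) horses$weekend_pasture <- horses$weekday_pasture
  horses$weekend_pasture <- ifelse(is.na(horses$weekend_pasture),
                                   horses$weekday_pasture, horses$weekend_pasture)
  if (is.null(horses$use)) horses$use <- "boarding"
  if (anyDuplicated(horses$stall)) {
    stopf("duplicate stall assignment: two horses share stall %s",
          horses$stall[duplicated(horses$stall)][1])
  }

  people <- if (length(config$people) > 0) {
    as.data.frame(data.table::rbindlist(lapply(config$people, function(p) {
      data.frame(id = p$id,
                 shift_start_s = as.integer(p$shift_start_s %||% 25200L),
                 shift_end_s = as.integer(p$shift_end_s %||% 61200L),
                 days = I(list(as.integer(p$days %||% seq_len(config$n_days %||% 7L)))))
    })))
  } else {
    data.frame(id = character(), shift_start_s = integer(),
               shift_end_s = integer(), days = I(list()))
  }

  static_tags <- if (length(config$static_tags) > 0) {
    as.data.frame(data.table::rbindlist(lapply(config$static_tags, function(s) {
      data.frame(id = s$id, kind = s$kind %||% "other",
                 link = as.character(s$link %||% NA_character_),
                 stringsAsFactors = FALSE)
    })))
  } else {
    data.frame(id = character(), kind = character(), link = character())
  }

  bookkeeping <- config$bookkeeping_tag_id %||% "bookkeeping"
  n_days <- as.integer(config$n_days %||% 7L)
  if (n_days < 1L) stopf("n_days must be >= 1")
  day0 <- config$day0_weekday %||% "Tuesday"
  if (!day0 %in% WEEKDAYS) stopf("unknown weekday '%s'", day0)
  t0 <- as.integer(config$turnout_start_s %||% 30600L)  # 08:30
  t1 <- as.integer(config$turnout_end_s %||% 59400L)    # 16:30
  if (t0 >= t1) stopf("turnout start must precede turnout end")

  ids <- c(horses$id, people$id, static_tags$id, bookkeeping)
  if (anyDuplicated(ids)) {
    stopf("tag ids must be unique across horses, people, static tags and the bookkeeping tag (duplicate: %s)",
          ids[duplicated(ids)][1])
  }

  defaults <- list(
    stall_bout_on_s = 1800, stall_bout_off_s = 7200,
    transit_s = 60L,
    p_train = 0.8, train_mean_s = 2400, train_window_s = c(61200L, 72000L),
    person_transits_per_day = 4L
  )
  params <- utils::modifyList(defaults, config$params %||% list())

  sc <- structure(list(
    horses = horses, people = people, static_tags = static_tags,
    bookkeeping_tag_id = bookkeeping, n_days = n_days, day0_weekday = day0,
    turnout_start_s = t0, turnout_end_s = t1,
    weekend_days = as.integer(unlist(config$weekend_days %||% c(4L, 5L))),
    params = params
  ), class = "scenario")
  sc
}

#' @rdname build_scenario
#' @export
default_scenario <- function() {
  pasture_of <- rep(c("pasture_1", "pasture_2", "pasture_3"), times = 3)
  aisle_of <- rep(c("A", "B", "C"), each = 3)
  horses <- lapply(1:9, function(i) {
    list(id = sprintf("horse_%d", i), stall = i, aisle = aisle_of[i],
         weekday_pasture = pasture_of[i],
         # one horse moves to the weekend pasture by itself
         weekend_pasture = if (i == 9) "pasture_4" else pasture_of[i],
         use = if (i <= 4) "lessons" else "competition")
  })
  people <- list(
    list(id = "worker_1", shift_start_s = 23400L, shift_end_s = 54000L),
    list(id = "worker_2", shift_start_s = 23400L, shift_end_s = 54000L),
    list(id = "trainer_1", shift_start_s = 43200L, shift_end_s = 72000L),
    list(id = "trainer_2", shift_start_s = 43200L, shift_end_s = 72000L),
    list(id = "vet_1", shift_start_s = 36000L, shift_end_s = 45000L, days = c(2L, 6L)),
    list(id = "farrier_1", shift_start_s = 32400L, shift_end_s = 41400L, days = 3L)
  )
  static_tags <- c(
    lapply(1:4, function(i) list(id = sprintf("pasture_%d", i), kind = "pasture",
                                 link = sprintf("pasture_%d", i))),
    lapply(1:2, function(i) list(id = sprintf("barn_door_%d", i), kind = "barn_door")),
    list(list(id = "arena_indoor", kind = "arena"),
         list(id = "arena_outdoor", kind = "arena"),
         list(id = "wash_stall", kind = "wash_stall"),
         list(id = "grooming_stall", kind = "grooming_stall"),
         list(id = "cross_tie_1", kind = "cross_tie"),
         list(id = "cross_tie_2", kind = "cross_tie"),
         list(id = "tack_room", kind = "tack_room"),
         list(id = "feed_room", kind = "feed_room")),
    lapply(c("A", "B", "C"), function(a) list(id = sprintf("aisle_%s", a),
                                              kind = "aisle", link = a))
  )
  build_scenario(list(
    horses = horses, people = people, static_tags = static_tags,
    bookkeeping_tag_id = "bookkeeping", n_days = 7L, day0_weekday = "Tuesday",
    turnout_start_s = 30600L, turnout_end_s = 59400L, weekend_days = c(4L, 5L)
  ))
}

#' Read a scenario configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) scenario description and
#' returns the configuration list expected by [build_scenario()].
#'
#' @param path Path to the configuration file.
#' @return A configuration list.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stopf("unsupported config format '.%s' (use YAML or JSON)", ext)
  }
}

#' Tag roster of a scenario
#'
#' @param scenario A `scenario` object.
#' @return A data.frame with one row per deployed tag: `id` and `role`
#'   (`horse`, `person`, `location` or `bookkeeping`).
#' @export
scenario_tags <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  mk <- function(ids, role) {
    data.frame(id = as.character(ids), role = rep(role, length(ids)))
  }
  rbind(
    mk(scenario$horses$id, "horse"),
    mk(scenario$people$id, "person"),
    mk(scenario$static_tags$id, "location"),
    mk(scenario$bookkeeping_tag_id, "bookkeeping")
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d horses, %d people, %d static tags + bookkeeping; %d days starting %s\n",
              nrow(x$horses), nrow(x$people), nrow(x$static_tags),
              x$n_days, x$day0_weekday))
  cat(sprintf("  turnout %05.2f-%05.2f h, weekend pasture on days %s\n",
              x$turnout_start_s / 3600, x$turnout_end_s / 3600,
              paste(x$weekend_days, collapse = ",")))
  invisible(x)
}
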