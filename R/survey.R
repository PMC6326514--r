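#' Survey-predicted contact network
#'
#' Builds the unweighted network predicted from management information
#' alone: every pair of horses sharing a pasture class or a barn class is
#' assumed to have come in contact, so the edge set is the union of
#' complete graphs over each class. A horse turned out in several pastures
#' during the week is assigned the pasture it occupied the majority of
#' days.
#'
#' @param memberships Data.frame with columns `horse_id`, `pasture_class`,
#'   `barn_class`. A horse with multiple weekly pastures may instead carry
#'   per-day occupancy in `pasture_days`: a list-column of named integer
#'   vectors (pasture -> days occupied), from which the majority pasture is
#'   taken (ties broken by first name).
#' @return A `survey_network`: list with `nodes` (horse ids) and `edges`
#'   (tag_a, tag_b, sorted unordered pairs).
#' @examples
#' m <- data.frame(horse_id = c("h1", "h2", "h3", "h4"),
#'                 pasture_class = c("A", "A", "B", "B"),
#'                 barn_class = c("X", "X", "Y", "Y"))
#' build_survey_network(m)  # edges (h1,h2) and (h3,h4) only
#' @export
build_survey_network <- function(memberships) {
  m <- as.data.frame(memberships)
  if (!all(c("horse_id", "barn_class") %in% names(m))) {
    stopf("memberships need horse_id and barn_class columns")
  }
  if (!is.null(m$pasture_days)) {
    m$pasture_class <- vapply(seq_len(nrow(m)), function(i) {
      pd <- m$pasture_days[[i]]
      if (is.null(pd) || length(pd) == 0) {
        as.character(m$pasture_class[i])
      } else {
        names(pd)[which.max(pd)]
      }
    }, character(1))
  }
  if (is.null(m$pasture_class) || anyNA(m$pasture_class) || anyNA(m$barn_class)) {
    stopf("every horse needs a pasture class and a barn class")
  }
  if (anyDuplicated(m$horse_id)) stopf("duplicate horse_id in memberships")
  ids <- as.character(m$horse_id)
  edges <- list()
  for (cls in list(split(ids, m$pasture_class), split(ids, m$barn_class))) {
    for (members in cls) {
      if (length(members) >= 2) {
        pr <- utils::combn(sort(members), 2)
        edges[[length(edges) + 1]] <- data.frame(tag_a = pr[1, ], tag_b = pr[2, ])
      }
    }
  }
  ed <- if (length(edges) > 0) unique(do.call(rbind, edges)) else
    data.frame(tag_a = character(), tag_b = character())
  ed <- ed[order(ed$tag_a, ed$tag_b), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = ids, edges = ed), class = "survey_network")
}

#' Survey memberships implied by a scenario
#'
#' Derives the membership table [build_survey_network()] expects from a
#' simulation scenario: barn class = aisle, pasture occupancy counted over
#' the study days (weekday vs weekend pasture), majority rule applied
#' downstream.
#'
#' @param scenario A `scenario`.
#' @return A memberships data.frame with a `pasture_days` list-column.
#' @export
survey_from_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  n_wk <- sum(seq_len(scenario$n_days) %in% scenario$weekend_days)
  n_wd <- scenario$n_days - n_wk
  h <- scenario$horses
  pd <- lapply(seq_len(nrow(h)), function(i) {
    tab <- c(n_wd, n_wk)
    names(tab) <- c(h$weekday_pasture[i], h$weekend_pasture[i])
    tapply(tab, names(tab), sum)
  })
  data.frame(horse_id = h$id, barn_class = h$aisle,
             pasture_class = h$weekday_pasture,
             pasture_days = I(pd), stringsAsFactors = FALSE)
}

#' Week-long combined network
#'
#' Union of the daily networks: a pair is connected in the combined
#' (unweighted) network if it shares an edge on any day.
#'
#' @param networks List of `daily_network`s with consistent node sets.
#' @param restrict_to_type Optional node type restriction applied first.
#' @return A `daily_network` (day 0) whose edges carry the summed weight but
#'   whose edge *set* is the union; use it as the unweighted gold standard.
#' @export
weekly_combined <- function(networks, restrict_to_type = NULL) {
  stopifnot(length(networks) > 0)
  nodes <- networks[[1]]$nodes
  for (nw in networks) {
    if (!identical(sort(nw$nodes$id), sort(nodes$id))) {
      stopf("daily networks must share one node set")
    }
  }
  edges <- do.call(rbind, lapply(networks, function(nw) nw$edges))
  if (!is.null(restrict_to_type)) {
    nodes <- nodes[nodes$type %in% restrict_to_type, , drop = FALSE]
    edges <- edges[edges$tag_a %in% nodes$id & edges$tag_b %in% nodes$id, , drop = FALSE]
  }
  ed <- if (nrow(edges) > 0) {
    dt <- as.data.table(edges)
    as.data.frame(dt[, .(weight_hours = sum(weight_hours)), by = .(tag_a, tag_b)][
      order(tag_a, tag_b)])
  } else edges
  new_daily_network(0L, nodes, ed)
}

#' Classification table: survey-predicted vs tag-observed edges
#'
#' Compares a predictive (test) network against a gold-standard network
#' over all unordered node pairs: TP pairs connected in both, FP test-only,
#' FN gold-only, TN in neither. Reports sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, positive predictive value `tp/(tp+fp)` and
#' negative predictive value `tn/(tn+fn)`; an undefined ratio (0/0) is
#' reported as `NA`, never coerced to 0. Both networks are treated as
#' unweighted (a recorded weight-0 edge counts as an edge).
#'
#' @param gold A `daily_network` (daily or combined), the tag-observed gold
#'   standard.
#' @param test A `survey_network` or `daily_network`, the prediction.
#' @param restrict_to_type Optional node type to restrict `gold` to (e.g.
#'   `"horse"`) before comparison.
#' @return A `classification_table`: list with `tp`, `fp`, `tn`, `fn`,
#'   `sn`, `sp`, `ppv`, `npv`.
#' @export
classify_networks <- function(gold, test, restrict_to_type = NULL) {
  gold_nodes <- if (!is.null(restrict_to_type)) {
    gold$nodes$id[gold$nodes$type %in% restrict_to_type]
  } else gold$nodes$id
  test_nodes <- if (inherits(test, "survey_network")) test$nodes else test$nodes$id
  if (!identical(sort(as.character(gold_nodes)), sort(as.character(test_nodes)))) {
    stopf("gold and test networks must share the same node set")
  }
  ids <- sort(as.character(gold_nodes))
  pair_key <- function(edges) {
    edges <- edges[edges$tag_a %in% ids & edges$tag_b %in% ids, , drop = FALSE]
    op <- order_pair(as.character(edges$tag_a), as.character(edges$tag_b))
    unique(paste(op$a, op$b, sep = "\r"))
  }
  gold_e <- pair_key(gold$edges)
  test_e <- pair_key(test$edges)
  n <- length(ids)
  universe <- n * (n - 1) / 2
  tp <- length(intersect(gold_e, test_e))
  fp <- length(setdiff(test_e, gold_e))
  fn <- length(setdiff(gold_e, test_e))
  tn <- universe - tp - fp - fn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sn = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn)
  ), class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("<classification_table> tp=%d fp=%d tn=%d fn=%d | sn=%s sp=%s ppv=%s npv=%s\n",
              x$tp, x$fp, x$tn, x$fn,
              fmt_or_na(x$sn), fmt_or_na(x$sp), fmt_or_na(x$ppv), fmt_or_na(x$npv)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' Write per-day classification results
#'
#' @param tables Named list of `classification_table`s (names used as the
#'   `day` column, e.g. `"1"`..`"7"` and `"combined"`).
#' @param path CSV path; columns `day,tp,fp,tn,fn,sn,sp,ppv,npv`.
#' @return `path`, invisibly.
#' @export
write_classification_csv <- function(tables, path) {
  rows <- lapply(names(tables), function(nm) {
    x <- tables[[nm]]
    data.frame(day = nm, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
               sn = x$sn, sp = x$sp, ppv = x$ppv, npv = x$npv)
  })
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
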