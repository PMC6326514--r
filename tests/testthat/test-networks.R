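mk_events <- function(tag_a, tag_b, start, end) {
  data.frame(tag_a = tag_a, tag_b = tag_b, start_wall_s = start,
             end_wall_s = end, duration_s = end - start,
             provenance = tag_a, flag = rep("", length(tag_a)))
}

test_that("daily aggregation sums pair durations into hours by start date", {
  ev <- mk_events(c("1", "1"), c("2", "2"), c(100L, 50000L),
                  c(1900L, 51800L))
  nets <- aggregate_daily(ev, n_days = 2)
  expect_equal(length(nets), 2)
  expect_equal(nets[[1]]$edges$weight_hours, 1.0)  # 2 x 1800 s
  expect_equal(nrow(nets[[2]]$edges), 0)

  # event starting 1 s before midnight: whole 2 h credited to day 1
  late <- mk_events("1", "2", 86399L, 86399L + 7200L)
  n2 <- aggregate_daily(late, n_days = 2)
  expect_equal(n2[[1]]$edges$weight_hours, 2.0)
  expect_equal(nrow(n2[[2]]$edges), 0)

  # split-credit alternative apportions it across the boundary
  n3 <- aggregate_daily(late, n_days = 2, split_credit = TRUE)
  expect_equal(n3[[1]]$edges$weight_hours, 1 / 3600)
  expect_equal(n3[[2]]$edges$weight_hours, 7199 / 3600)
  # conservation in both conventions
  expect_equal(sum(n2[[1]]$edges$weight_hours, n2[[2]]$edges$weight_hours),
               sum(n3[[1]]$edges$weight_hours, n3[[2]]$edges$weight_hours))

  # no events -> one empty network per day
  n4 <- aggregate_daily(mk_events(character(0), character(0), integer(0),
                                  integer(0)), n_days = 3)
  expect_equal(length(n4), 3)
  expect_true(all(vapply(n4, function(x) nrow(x$edges) == 0, logical(1))))
})

test_that("daily CSV files round-trip", {
  dir <- withr::local_tempdir()
  ev <- mk_events(c("1", "3"), c("2", "4"), c(0L, 90000L), c(3600L, 93600L))
  nets <- aggregate_daily(ev, n_days = 2)
  paths <- write_daily_networks(nets, dir)
  expect_equal(length(list.files(dir, pattern = "^day_")), 2)
  back <- read_daily_network(file.path(dir, "day_1.csv"), day = 1)
  expect_equal(back$edges, nets[[1]]$edges)
  # an empty day yields a header-only file
  empty <- aggregate_daily(ev[0, ], n_days = 1)
  write_daily_networks(empty, dir)
  expect_equal(nrow(utils::read.csv(file.path(dir, "day_1.csv"))), 0)
})

test_that("the printed day-1 contact matrix parses to the documented graph", {
  nw <- load_contact_matrix(contact_matrix_path(), triangle = "lower")
  expect_equal(nrow(nw$nodes), 9)
  expect_equal(nrow(nw$edges), 27)
  w <- nw$edges$weight_hours[nw$edges$tag_a == "2" & nw$edges$tag_b == "8"]
  expect_equal(w, 15.75)
  # negligible-duration cells become weight-0 edges by default ...
  expect_true(any(nw$edges$weight_hours == 0))
  # ... and disappear under the drop policy
  nw_drop <- load_contact_matrix(contact_matrix_path(), triangle = "lower",
                                 below_detect = "drop")
  expect_lt(nrow(nw_drop$edges), 27)
  expect_false(any(nw_drop$edges$weight_hours == 0))

  cent <- centrality(nw, restrict_to_type = "horse")
  expect_equal(max(cent$degree), 8)
  expect_equal(cent$degree[cent$id == "1"], 8L)
  expect_equal(mean(cent$degree), 6.0)
  expect_equal(max(cent$strength), 32.09, tolerance = 1e-9)
  expect_equal(cent$id[which.max(cent$strength)], "8")
})

test_that("malformed matrix cells raise a parse error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",1,2", "1,,x", "2,0.5,"), path)
  expect_error(load_contact_matrix(path, triangle = "upper"), "unparseable")
  # lower triangle of the same file is fine
  expect_equal(load_contact_matrix(path, triangle = "lower")$edges$weight_hours,
               0.5)
})

test_that("centrality matches igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    ids <- as.character(seq_len(n))
    pairs <- t(utils::combn(ids, 2))
    sel <- runif(nrow(pairs)) < 0.5
    if (!any(sel)) next
    ed <- data.frame(tag_a = pairs[sel, 1], tag_b = pairs[sel, 2],
                     weight_hours = round(runif(sum(sel), 0.1, 20), 2))
    nw <- structure(list(day = 1L,
                         nodes = data.frame(id = ids, type = "horse"),
                         edges = ed), class = "daily_network")
    cent <- centrality(nw)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = data.frame(name = ids))
    expect_equal(cent$degree, unname(igraph::degree(g)))
    expect_equal(cent$strength,
                 unname(igraph::strength(g, weights = ed$weight_hours)))
    if (igraph::is_connected(g)) {
      ev <- igraph::eigen_centrality(g, weights = ed$weight_hours)$vector
      ev <- unname(ev) / sqrt(sum(ev^2))  # rescale to unit Euclidean norm
      expect_equal(cent$eigenvector, ev, tolerance = 1e-6)
    }
  }
})

test_that("eigenvector centrality is scale-invariant and in [0, 1]", {
  ed <- data.frame(tag_a = c("1", "2", "3"), tag_b = c("2", "3", "4"),
                   weight_hours = c(2, 4, 8))
  nw <- structure(list(day = 1L,
                       nodes = data.frame(id = as.character(1:4), type = "horse"),
                       edges = ed), class = "daily_network")
  c1 <- centrality(nw)
  ed2 <- ed
  ed2$weight_hours <- ed$weight_hours * 37.5
  nw2 <- nw
  nw2$edges <- ed2
  c2 <- centrality(nw2)
  expect_equal(c1$eigenvector, c2$eigenvector, tolerance = 1e-9)
  expect_true(all(c1$eigenvector >= 0 & c1$eigenvector <= 1))

  # single-edge graph: equal nonzero entries at the endpoints
  one <- structure(list(day = 1L,
                        nodes = data.frame(id = c("a", "b"), type = "horse"),
                        edges = data.frame(tag_a = "a", tag_b = "b",
                                           weight_hours = 3)),
                   class = "daily_network")
  co <- centrality(one)
  expect_equal(co$degree, c(1L, 1L))
  expect_equal(co$eigenvector[1], co$eigenvector[2])

  # disconnected graphs are flagged and computed per component
  disc <- structure(list(day = 1L,
                         nodes = data.frame(id = as.character(1:5), type = "horse"),
                         edges = data.frame(tag_a = c("1", "3"), tag_b = c("2", "4"),
                                            weight_hours = c(1, 2))),
                    class = "daily_network")
  cd <- centrality(disc)
  expect_true(attr(cd, "disconnected"))
  expect_equal(cd$eigenvector[cd$id == "5"], 0)
  expect_error(centrality(disc, restrict_to_type = "person"), "no nodes")
})

test_that("heat-map matrices aggregate by tag and tag type", {
  nodes <- data.frame(id = c("h1", "h2", "p1"),
                      type = c("horse", "horse", "person"))
  ed1 <- data.frame(tag_a = c("h1", "h1"), tag_b = c("h2", "p1"),
                    weight_hours = c(2, 1))
  ed2 <- data.frame(tag_a = "h1", tag_b = "h2", weight_hours = 3)
  d1 <- structure(list(day = 1L, nodes = nodes, edges = ed1),
                  class = "daily_network")
  d2 <- structure(list(day = 2L, nodes = nodes, edges = ed2),
                  class = "daily_network")
  m1 <- heatmap_matrix(d1)
  expect_true(isSymmetric(unclass(m1)))
  expect_equal(diag(unclass(m1)), setNames(rep(0, 3), rownames(m1)))
  expect_equal(m1["h1", "h2"], 2)

  mt <- heatmap_matrix(list(d1, d2), level = "tag_type")
  expect_equal(mt["horse", "horse"], 5)
  expect_equal(mt["horse", "person"], 1)
  # combined cell dominates any single day's cell
  expect_gte(mt["horse", "horse"], heatmap_matrix(d1, level = "tag_type")["horse", "horse"])
  # grouping must cover all nodes
  expect_error(heatmap_matrix(d1, grouping = c(h1 = "A")), "cover")
})

test_that("mixing summary separates homogeneous from block structure", {
  ids <- paste0("n", 1:6)
  grp <- setNames(rep(c("A", "B"), each = 3), ids)
  flat <- matrix(1, 6, 6, dimnames = list(ids, ids))
  diag(flat) <- 0
  flat <- structure(flat, level = "tag", grouping = grp,
                    class = c("heatmap_matrix", "matrix", "array"))
  ms <- mixing_summary(flat, grp)
  expect_equal(ms$ratio, 1.0)
  expect_true(ms$homogeneous)

  blocky <- matrix(0, 6, 6, dimnames = list(ids, ids))
  blocky[1:3, 1:3] <- 5
  blocky[4:6, 4:6] <- 5
  diag(blocky) <- 0
  blocky <- structure(blocky, level = "tag", grouping = grp,
                      class = c("heatmap_matrix", "matrix", "array"))
  mb <- mixing_summary(blocky, grp)
  expect_true(mb$between_zero)
  expect_equal(mb$ratio, Inf)
  expect_false(mb$homogeneous)
  expect_error(mixing_summary(flat, setNames(rep("A", 6), ids)), "single group")
})

test_that("unstructured random networks sit inside the homogeneity band", {
  # Monte-Carlo calibration: Erdos-Renyi weighted graphs on 50 nodes with an
  # arbitrary 2-group labelling should show no block structure
  n <- 50
  ids <- paste0("n", seq_len(n))
  grp <- setNames(rep(c("A", "B"), length.out = n), ids)
  pairs <- t(utils::combn(ids, 2))
  set.seed(2024)
  inside <- vapply(1:100, function(s) {
    sel <- runif(nrow(pairs)) < 0.5
    ed <- data.frame(tag_a = pairs[sel, 1], tag_b = pairs[sel, 2],
                     weight_hours = runif(sum(sel), 0, 2))
    nw <- structure(list(day = 1L,
                         nodes = data.frame(id = ids, type = "horse"),
                         edges = ed), class = "daily_network")
    ms <- mixing_summary(heatmap_matrix(nw, grouping = grp))
    ms$ratio >= 0.8 && ms$ratio <= 1.25
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})
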