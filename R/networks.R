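#' Daily weighted contact networks
#'
#' [aggregate_daily()] bins reconciled contact events into undirected
#' weighted graphs, one per 24-h period. By default an event's whole
#' duration is credited to the day bin its start time falls in (the
#' start-date convention used when the raw data are sorted into daily
#' files); `split_credit = TRUE` instead apportions an event's duration
#' across the day bins it spans, for sensitivity analysis. Edge weight is
#' total contact hours between the pair within the day.
#'
#' @param events Reconciled contact events (columns `tag_a`, `tag_b`,
#'   `start_wall_s`, `end_wall_s`).
#' @param nodes Optional data.frame of node `id` and `type` (e.g. a
#'   registry's `external_id`/`role`); defaults to the tags seen in
#'   `events`, typed `"unknown"`.
#' @param day_length_s Seconds per day bin (default 86400).
#' @param first_day_start Wall second at which day 1 begins (default 0).
#' @param n_days Number of day bins; inferred from the events if omitted.
#' @param split_credit Credit event duration to each day it overlaps rather
#'   than wholly to its start day.
#' @return A list of `daily_network` objects, one per day; each has `$day`,
#'   `$nodes` (id, type) and `$edges` (tag_a, tag_b, weight_hours).
#' @export
aggregate_daily <- function(events, nodes = NULL, day_length_s = 86400L,
                            first_day_start = 0L, n_days = NULL,
                            split_credit = FALSE) {
  events <- as.data.frame(events)
  nodes <- normalize_nodes(nodes, events)
  if (is.null(n_days)) {
    n_days <- if (nrow(events) == 0) 1L else
      max(1L, as.integer((max(events$start_wall_s) - first_day_start) %/% day_length_s) + 1L)
  }
  dt <- as.data.table(events)
  if (nrow(dt) > 0) {
    if (split_credit) {
      parts <- list()
      for (d in seq_len(n_days)) {
        lo <- first_day_start + (d - 1L) * day_length_s
        hi <- lo + day_length_s
        ov <- pmin(dt$end_wall_s, hi) - pmax(dt$start_wall_s, lo)
        sel <- ov > 0 | (dt$start_wall_s >= lo & dt$start_wall_s < hi & dt$duration_s == 0)
        if (any(sel)) {
          parts[[length(parts) + 1]] <- data.table(
            day = d, tag_a = dt$tag_a[sel], tag_b = dt$tag_b[sel],
            dur = pmax(0, ov[sel]))
        }
      }
      per <- rbindlist(parts)
    } else {
      per <- dt[, .(day = as.integer((start_wall_s - first_day_start) %/% day_length_s) + 1L,
                    tag_a, tag_b, dur = end_wall_s - start_wall_s)]
    }
    w <- per[day >= 1L & day <= n_days,
             .(weight_hours = sum(dur) / 3600), by = .(day, tag_a, tag_b)]
  } else {
    w <- data.table(day = integer(), tag_a = character(), tag_b = character(),
                    weight_hours = numeric())
  }
  lapply(seq_len(n_days), function(d) {
    ed <- as.data.frame(w[day == d][order(tag_a, tag_b),
                                    .(tag_a, tag_b, weight_hours)])
    new_daily_network(d, nodes, ed)
  })
}

normalize_nodes <- function(nodes, events) {
  if (is.null(nodes)) {
    ids <- sort(unique(c(events$tag_a, events$tag_b)))
    return(data.frame(id = ids, type = rep("unknown", length(ids))))
  }
  nodes <- as.data.frame(nodes)
  if ("external_id" %in% names(nodes)) {
    nodes <- data.frame(id = nodes$external_id, type = nodes$role)
  }
  stopifnot(all(c("id", "type") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  nodes[, c("id", "type")]
}

new_daily_network <- function(day, nodes, edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (any(edges$tag_a == edges$tag_b)) stopf("self-edges are not allowed")
    if (any(edges$weight_hours < 0)) stopf("negative edge weights")
    op <- order_pair(edges$tag_a, edges$tag_b)
    edges$tag_a <- op$a; edges$tag_b <- op$b
    unknown <- setdiff(unique(c(edges$tag_a, edges$tag_b)), nodes$id)
    if (length(unknown) > 0) {
      nodes <- rbind(nodes, data.frame(id = unknown, type = "unknown"))
    }
  }
  structure(list(day = as.integer(day), nodes = nodes, edges = edges),
            class = "daily_network")
}

#' @export
print.daily_network <- function(x, ...) {
  cat(sprintf("<daily_network> day %d: %d nodes, %d edges, %.2f total hours\n",
              x$day, nrow(x$nodes), nrow(x$edges), sum(x$edges$weight_hours)))
  invisible(x)
}

#' Write one edge-list CSV per day
#'
#' Columns `source_internal_id,partner_internal_id,weight_hours`, pairs
#' sorted; one file `day_<d>.csv` per network (an empty day yields a
#' header-only file).
#'
#' @param networks List of `daily_network`s.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_daily_networks <- function(networks, dir) {
  if (length(networks) == 0) stopf("no networks to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(networks, function(nw) {
    path <- file.path(dir, sprintf("day_%d.csv", nw$day))
    out <- nw$edges[order(nw$edges$tag_a, nw$edges$tag_b), , drop = FALSE]
    names(out) <- c("source_internal_id", "partner_internal_id", "weight_hours")
    data.table::fwrite(out, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a daily edge-list CSV back into a network
#' @param path CSV written by [write_daily_networks()].
#' @param nodes Optional node table (id, type).
#' @param day Day index to stamp on the network.
#' @return A `daily_network`.
#' @export
read_daily_network <- function(path, nodes = NULL, day = 1L) {
  ed <- as.data.frame(data.table::fread(path))
  names(ed) <- c("tag_a", "tag_b", "weight_hours")
  ed$tag_a <- as.character(ed$tag_a)
  ed$tag_b <- as.character(ed$tag_b)
  new_daily_network(day, normalize_nodes(nodes, ed), ed)
}

#' Parse a printed triangular contact-duration matrix
#'
#' Loads a labelled square matrix of pairwise contact hours -- the format in
#' which day-long horse-horse contact tables are printed -- and turns the
#' chosen triangle into a network. Cells may be empty (no recorded contact),
#' numeric (hours), or the token `"<0.00"` denoting a recorded contact of
#' negligible duration. Under the default policy `"edge_weight_zero"` such
#' cells become edges of weight 0 (they are recorded contacts and count
#' towards degree); `"drop"` discards them. Any other non-numeric cell is a
#' parse error.
#'
#' @param path CSV file: first column row labels, remaining columns the
#'   matrix with column labels in the header.
#' @param triangle Which triangle holds the day of interest (`"lower"` or
#'   `"upper"`).
#' @param below_detect Policy for `"<0.00"` cells; see above.
#' @param node_type Node type stamped on the parsed nodes (default
#'   `"horse"`).
#' @param day Day index for the resulting network.
#' @return A `daily_network`.
#' @export
load_contact_matrix <- function(path, triangle = c("lower", "upper"),
                                below_detect = c("edge_weight_zero", "drop"),
                                node_type = "horse", day = 1L) {
  triangle <- match.arg(triangle)
  below_detect <- match.arg(below_detect)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         row.names = 1)
  labels <- rownames(raw)
  if (!identical(labels, colnames(raw)) || nrow(raw) != ncol(raw)) {
    stopf("contact matrix must be square with matching row and column labels")
  }
  n <- length(labels)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      in_tri <- if (triangle == "lower") i > j else i < j
      if (!in_tri) next
      cell <- trimws(raw[i, j])
      if (is.na(cell) || cell == "") next
      if (cell == "<0.00") {
        if (below_detect == "drop") next
        wgt <- 0
      } else {
        wgt <- suppressWarnings(as.numeric(cell))
        if (is.na(wgt)) stopf("unparseable cell '%s' at (%s, %s)", cell,
                              labels[i], labels[j])
      }
      edges[[length(edges) + 1]] <- data.frame(
        tag_a = labels[min(i, j)], tag_b = labels[max(i, j)],
        weight_hours = wgt, stringsAsFactors = FALSE)
    }
  }
  ed <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(tag_a = character(), tag_b = character(), weight_hours = numeric())
  nodes <- data.frame(id = labels, type = rep(node_type, n))
  new_daily_network(day, nodes, ed)
}

#' Node centrality of a daily network
#'
#' Computes, per node: unweighted degree (number of incident edges,
#' 0..N-1), strength (sum of incident edge weights in hours; can exceed
#' 24 h) and eigenvector centrality (principal eigenvector of the weighted
#' adjacency matrix, entries nonnegative). The eigenvector is normalised to
#' unit Euclidean length, which keeps all entries in [0, 1]. On a
#' disconnected network the eigenvector is computed per connected component
#' (unit norm within each component, isolated nodes 0) and the report is
#' flagged via its `disconnected` attribute.
#'
#' @param network A `daily_network`.
#' @param restrict_to_type Optional node type (e.g. `"horse"`) to which the
#'   graph is restricted before computing centralities.
#' @return A `centrality_report` data.frame: `id`, `degree`, `strength`,
#'   `eigenvector`, with attribute `disconnected`.
#' @export
centrality <- function(network, restrict_to_type = NULL) {
  stopifnot(inherits(network, "daily_network"))
  nodes <- network$nodes
  edges <- network$edges
  if (!is.null(restrict_to_type)) {
    nodes <- nodes[nodes$type %in% restrict_to_type, , drop = FALSE]
    edges <- edges[edges$tag_a %in% nodes$id & edges$tag_b %in% nodes$id, , drop = FALSE]
  }
  if (nrow(nodes) == 0) stopf("no nodes left after type restriction")
  ids <- nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  P <- matrix(FALSE, n, n)  # edge presence (weight-0 edges count for degree)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$tag_a[k], ids); j <- match(edges$tag_b[k], ids)
    A[i, j] <- A[i, j] + edges$weight_hours[k]
    A[j, i] <- A[i, j]
    P[i, j] <- P[j, i] <- TRUE
  }
  degree <- rowSums(P)
  strength <- rowSums(A)
  comp <- graph_components(P)
  eig <- numeric(n)
  disconnected <- length(unique(comp)) > 1
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1) next
    sub <- A[idx, idx, drop = FALSE]
    if (all(sub == 0)) next
    es <- eigen(sub, symmetric = TRUE)
    v <- es$vectors[, 1]
    v <- abs(v) / sqrt(sum(v^2))
    eig[idx] <- v
  }
  structure(
    data.frame(id = ids, degree = as.integer(degree), strength = strength,
               eigenvector = eig, stringsAsFactors = FALSE),
    disconnected = disconnected, class = c("centrality_report", "data.frame"))
}

# connected components of a presence matrix (simple BFS)
graph_components <- function(P) {
  n <- nrow(P)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(P[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Contact heat-map matrix
#'
#' Builds the symmetric matrix of total contact hours underlying a contact
#' heat map, either between individual tags (`level = "tag"`, rows ordered
#' by an optional grouping annotation such as pasture or aisle) or between
#' tag types (`level = "tag_type"`: entry (X, Y) is the total hours between
#' all tags of type X and all of type Y). Accepts a single network or a
#' list of daily networks, which are summed -- the combined week-long map.
#'
#' @param networks A `daily_network` or list of them.
#' @param level `"tag"` or `"tag_type"`.
#' @param grouping Optional named vector mapping node id to group label;
#'   must cover every node when supplied.
#' @return A `heatmap_matrix`: symmetric numeric matrix with zero diagonal
#'   and attributes `level` and `grouping`.
#' @export
heatmap_matrix <- function(networks, level = c("tag", "tag_type"),
                           grouping = NULL) {
  level <- match.arg(level)
  if (inherits(networks, "daily_network")) networks <- list(networks)
  stopifnot(length(networks) > 0)
  nodes <- networks[[1]]$nodes
  edges <- do.call(rbind, lapply(networks, function(nw) nw$edges))
  if (level == "tag") {
    ids <- nodes$id
    if (!is.null(grouping)) {
      missing <- setdiff(ids, names(grouping))
      if (length(missing) > 0) {
        stopf("grouping does not cover node(s): %s", paste(missing, collapse = ", "))
      }
      ids <- ids[order(grouping[ids], ids)]
    }
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(edges))) {
      i <- match(edges$tag_a[k], ids); j <- match(edges$tag_b[k], ids)
      M[i, j] <- M[i, j] + edges$weight_hours[k]
      M[j, i] <- M[i, j]
    }
    grp <- if (!is.null(grouping)) grouping[ids] else NULL
  } else {
    type_of <- setNames(nodes$type, nodes$id)
    types <- sort(unique(nodes$type))
    M <- matrix(0, length(types), length(types), dimnames = list(types, types))
    for (k in seq_len(nrow(edges))) {
      ti <- type_of[[edges$tag_a[k]]]; tj <- type_of[[edges$tag_b[k]]]
      M[ti, tj] <- M[ti, tj] + edges$weight_hours[k]
      if (ti != tj) M[tj, ti] <- M[ti, tj]
    }
    grp <- NULL
  }
  structure(M, level = level, grouping = grp,
            class = c("heatmap_matrix", class(M)))
}

#' @export
plot.heatmap_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, rev(seq_len(n))],
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(x), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Within- vs between-group mixing summary
#'
#' Quantifies the visual block structure of a contact heat map: the mean of
#' off-diagonal cells within a group versus between groups, and their
#' ratio. Under homogeneous mixing the ratio is close to 1; a large ratio
#' indicates strongly assortative (blocky) contact. When the between-group
#' mean is zero the ratio is infinite and `between_zero` is flagged.
#'
#' @param mat A tag-level `heatmap_matrix`.
#' @param grouping Named vector id -> group; taken from the matrix attribute
#'   when omitted. Must cover all nodes and define at least two groups.
#' @param homogeneity_band Ratio band considered compatible with
#'   homogeneous mixing (default c(0.8, 1.25), the calibration band of
#'   unstructured random networks).
#' @return A list: `within_mean`, `between_mean`, `ratio`, `between_zero`,
#'   `homogeneous`.
#' @export
mixing_summary <- function(mat, grouping = NULL,
                           homogeneity_band = c(0.8, 1.25)) {
  stopifnot(inherits(mat, "heatmap_matrix"))
  grouping <- grouping %||% attr(mat, "grouping")
  if (is.null(grouping)) stopf("a node grouping is required")
  ids <- rownames(mat)
  missing <- setdiff(ids, names(grouping))
  if (length(missing) > 0) {
    stopf("grouping does not cover node(s): %s", paste(missing, collapse = ", "))
  }
  g <- grouping[ids]
  if (length(unique(g)) < 2) {
    stopf("between-group mixing is undefined with a single group")
  }
  same <- outer(g, g, "==")
  off <- !diag(TRUE, nrow(mat))
  within_mean <- mean(mat[same & off])
  between_mean <- mean(mat[!same])
  between_zero <- between_mean == 0
  ratio <- if (between_zero) Inf else within_mean / between_mean
  list(within_mean = within_mean, between_mean = between_mean, ratio = ratio,
       between_zero = between_zero,
       homogeneous = is.finite(ratio) &&
         ratio >= homogeneity_band[1] && ratio <= homogeneity_band[2])
}
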