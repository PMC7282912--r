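#' Dyadic co-occupancy durations within a time window
#'
#' Clips visit records to the window (half-open intervals `[entry, exit)`)
#' and computes, for every unordered dyad, the total number of seconds the
#' two individuals were inside the *same* box simultaneously, together with
#' each individual's total in-box time. Touching intervals overlap for 0
#' seconds; different boxes never count.
#'
#' @param events visit records (`individual_id`, `box_id`, `entry`, `exit`).
#' @param window one row of a [window_schedule()] (or any list with `start`
#'   and `end` in seconds).
#' @return A list with `dyads` (data.frame `id_i`, `id_j`, `seconds`, with
#'   `id_i < id_j`, only dyads with positive overlap) and `totals` (named
#'   vector of per-individual in-box seconds; individuals with at least one
#'   clipped visit appear, even with 0 overlap).
#' @export
cooccupancy_durations <- function(events, window) {
  bad <- which(!(events$exit > events$entry))
  if (length(bad)) {
    stop("visit record(s) with exit <= entry at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  dt <- data.table::as.data.table(events[, c("individual_id", "box_id",
                                             "entry", "exit")])
  dt[, entry := pmax(entry, window$start)]
  dt[, exit := pmin(exit, window$end)]
  dt <- dt[exit > entry]
  if (nrow(dt) == 0L) {
    return(list(dyads = data.frame(id_i = character(), id_j = character(),
                                   seconds = numeric(), stringsAsFactors = FALSE),
                totals = numeric()))
  }
  totals_dt <- dt[, .(seconds = sum(exit - entry)), by = individual_id]
  totals <- setNames(totals_dt$seconds, totals_dt$individual_id)

  data.table::setkey(dt, box_id, entry, exit)
  ov <- data.table::foverlaps(dt, dt, type = "any")
  ov <- ov[individual_id < i.individual_id]
  if (nrow(ov) > 0L) {
    ov[, overlap := pmin(exit, i.exit) - pmax(entry, i.entry)]
    ov <- ov[overlap > 0]
  }
  if (nrow(ov) == 0L) {
    dyads <- data.frame(id_i = character(), id_j = character(),
                        seconds = numeric(), stringsAsFactors = FALSE)
  } else {
    agg <- ov[, .(seconds = sum(overlap)),
              by = .(id_i = individual_id, id_j = i.individual_id)]
    dyads <- as.data.frame(agg)
    dyads <- dyads[order(dyads$id_i, dyads$id_j), , drop = FALSE]
    rownames(dyads) <- NULL
  }
  list(dyads = dyads, totals = totals)
}

#' Simple ratio index on co-occupancy durations
#'
#' The duration analogue of the simple ratio association index:
#' `SRI = x / (t_i + t_j - x)`, the proportion of the dyad's pooled in-box
#' time (union of the two individuals' observed box time) that they spent
#' together. Always in `[0, 1]`; 1 means the two were together whenever
#' either was in a box. The denominator convention is isolated here so an
#' alternative (e.g. `x / min(t_i, t_j)`) can be swapped in one place.
#'
#' @param x seconds together in the same box.
#' @param t_i,t_j each individual's total in-box seconds.
#' @return The index, vectorized; `NA` where `t_i + t_j` is 0.
#' @export
simple_ratio_index <- function(x, t_i, t_j) {
  denom <- t_i + t_j - x
  out <- ifelse(denom > 0, x / denom, NA_real_)
  if (any(!is.na(out) & (out < -1e-12 | out > 1 + 1e-12))) {
    stop("simple ratio index outside [0, 1]; check that x <= min(t_i, t_j)",
         call. = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

#' Build the association network for one window
#'
#' Nodes are the individuals with at least one (clipped, positive-length)
#' visit in the window; edges connect dyads with positive simple ratio index.
#' Node attributes `sex` and `fate` come from the roster;
#' `section_use` is the section holding the majority of the individual's
#' in-box time in this window.
#'
#' @inheritParams cooccupancy_durations
#' @param roster optional roster supplying `sex` and `fate`.
#' @return An undirected [igraph::graph] with edge attribute `weight`
#'   (the SRI) and graph attributes `window_index`, `window_start`,
#'   `window_end`.
#' @export
build_network <- function(events, window, roster = NULL) {
  cd <- cooccupancy_durations(events, window)
  ids <- sort(names(cd$totals))
  if (length(ids) == 0L) {
    warning("no visits fall inside the window; returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    d <- cd$dyads
    if (nrow(d) > 0L) {
      d$weight <- simple_ratio_index(d$seconds, cd$totals[d$id_i],
                                     cd$totals[d$id_j])
      d <- d[!is.na(d$weight) & d$weight > 0, c("id_i", "id_j", "weight")]
    } else {
      d <- data.frame(id_i = character(), id_j = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
    }
    g <- igraph::graph_from_data_frame(d, directed = FALSE,
                                       vertices = data.frame(name = ids))
  }
  if (length(ids) > 0L) {
    igraph::V(g)$section_use <- majority_section(events, window)[ids]
    if (!is.null(roster)) {
      m <- match(ids, roster$individual_id)
      igraph::V(g)$sex <- roster$sex[m]
      igraph::V(g)$fate <- roster$fate[m]
    }
  }
  g <- igraph::set_graph_attr(g, "window_index",
                              if (!is.null(window$index)) window$index else NA_integer_)
  g <- igraph::set_graph_attr(g, "window_start", window$start)
  igraph::set_graph_attr(g, "window_end", window$end)
}

majority_section <- function(events, window) {
  if (is.null(events$section)) {
    return(setNames(rep(NA_integer_, length(unique(events$individual_id))),
                    unique(events$individual_id)))
  }
  dt <- data.table::as.data.table(events)
  dt[, entry := pmax(entry, window$start)]
  dt[, exit := pmin(exit, window$end)]
  dt <- dt[exit > entry]
  agg <- dt[, .(seconds = sum(exit - entry)), by = .(individual_id, section)]
  data.table::setorder(agg, individual_id, -seconds, section)
  top <- agg[, .SD[1], by = individual_id]
  setNames(top$section, top$individual_id)
}

#' Build the full and survivor-restricted network stacks
#'
#' One association network per scheduled window. The *full* stack contains
#' every individual recorded in each window. The *survivor* stack is
#' restricted to the individuals present (at least one visit) in **every**
#' window; its networks are the full networks node-induced on that common
#' set, so retained edges keep their full-network SRI values exactly. The
#' last pre-event window is the change baseline.
#'
#' @param events visit records covering the whole schedule.
#' @param schedule a [window_schedule()].
#' @param roster optional roster for node attributes.
#' @param event_time event instant; must fall strictly between the last
#'   pre- and first post-event window (defaults to the schedule's own).
#' @return A list with `full` and `survivor`, each a `network_stack`: a list
#'   of networks (named by window index) plus the schedule, the restriction
#'   label and the baseline window index.
#' @export
make_stacks <- function(events, schedule, roster = NULL,
                        event_time = attr(schedule, "event_time")) {
  if (sum(schedule$phase == "pre") < 1 || sum(schedule$phase == "post") < 1) {
    stop("schedule needs at least one pre- and one post-event window",
         call. = FALSE)
  }
  if (!is.null(event_time) &&
      any(event_time > schedule$start & event_time < schedule$end)) {
    stop("event time falls inside an observation window; exclude the event gap",
         call. = FALSE)
  }
  nets <- lapply(seq_len(nrow(schedule)), function(i) {
    build_network(events, schedule[i, ], roster)
  })
  names(nets) <- as.character(schedule$index)
  baseline <- max(schedule$index[schedule$phase == "pre"])
  full <- structure(list(networks = nets, schedule = schedule,
                         restriction = "full", baseline_window = baseline),
                    class = "network_stack")
  common <- Reduce(intersect, lapply(nets, function(g) igraph::V(g)$name))
  surv_nets <- lapply(nets, function(g) {
    igraph::induced_subgraph(g, common)
  })
  survivor <- structure(list(networks = surv_nets, schedule = schedule,
                             restriction = "survivor_only",
                             baseline_window = baseline),
                        class = "network_stack")
  list(full = full, survivor = survivor)
}

#' @export
print.network_stack <- function(x, ...) {
  cat(sprintf("<network_stack: %s, %d windows, baseline window %d>\n",
              x$restriction, length(x$networks), x$baseline_window))
  for (nm in names(x$networks)) {
    g <- x$networks[[nm]]
    cat(sprintf("  window %s: %d nodes, %d edges\n", nm,
                igraph::vcount(g), igraph::ecount(g)))
  }
  invisible(x)
}

#' Node set shared by every window of a stack
#' @param stack a `network_stack`.
#' @return Character vector of individual ids.
#' @export
stack_nodes <- function(stack) igraph::V(stack$networks[[1]])$name

#' Pre-event sociality and proportion of association strength lost
#'
#' From the full pre-event network: each individual's pre-event sociality
#' (weighted degree, the sum of its SRI edge weights) and its loss
#' proportion — the summed edge strength to missing individuals divided by
#' its total edge strength. Individuals with zero pre-event strength have an
#' undefined loss proportion and are flagged.
#'
#' @param pre_network the full pre-event association network.
#' @param missing_ids ids of individuals that died or disappeared.
#' @return A data.frame per non-missing node: `individual_id`,
#'   `pre_event_sociality`, `loss_proportion` (`NA` when flagged),
#'   `zero_strength` flag, plus `sex`/`fate` when present on the network.
#' @export
loss_attributes <- function(pre_network, missing_ids) {
  ids <- igraph::V(pre_network)$name
  survivors <- setdiff(ids, missing_ids)
  s_all <- igraph::strength(pre_network, weights = igraph::E(pre_network)$weight)
  lost <- setNames(rep(0, length(survivors)), survivors)
  if (igraph::ecount(pre_network) > 0L) {
    el <- igraph::as_data_frame(pre_network, what = "edges")
    from_miss <- el$from %in% missing_ids
    to_miss <- el$to %in% missing_ids
    cross <- xor(from_miss, to_miss)
    if (any(cross)) {
      surv_end <- ifelse(from_miss[cross], el$to[cross], el$from[cross])
      add <- tapply(el$weight[cross], surv_end, sum)
      add <- add[names(add) %in% survivors]
      lost[names(add)] <- lost[names(add)] + as.numeric(add)
    }
  }
  s <- s_all[survivors]
  out <- data.frame(
    individual_id = survivors,
    pre_event_sociality = as.numeric(s),
    loss_proportion = ifelse(s > 0, as.numeric(lost) / as.numeric(s), NA_real_),
    zero_strength = s == 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(igraph::vertex_attr(pre_network, "sex"))) {
    m <- match(survivors, ids)
    out$sex <- igraph::V(pre_network)$sex[m]
    out$fate <- igraph::V(pre_network)$fate[m]
  }
  rownames(out) <- NULL
  out
}

#' Export a window's network as an edge list
#'
#' @param network an association network.
#' @return data.frame `id_i`, `id_j`, `sri`.
#' @export
edge_list <- function(network) {
  if (igraph::ecount(network) == 0L) {
    return(data.frame(id_i = character(), id_j = character(), sri = numeric(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_data_frame(network, what = "edges")
  data.frame(id_i = pmin(el$from, el$to), id_j = pmax(el$from, el$to),
             sri = el$weight, stringsAsFactors = FALSE)
}
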