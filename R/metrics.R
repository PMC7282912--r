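#' Per-node centrality metrics
#'
#' Degree (number of partners), strength (weighted degree: sum of incident
#' SRI weights) and betweenness centrality. Because a large SRI means a
#' *close* association, betweenness uses the inverted weights
#' `d_ij = 1 / w_ij` as shortest-path distances, so strong edges are short.
#' Betweenness is unnormalized; tied geodesics contribute fractionally
#' (Brandes accounting). Isolated nodes get 0 on all three.
#'
#' @param network an association network ([build_network()]).
#' @return data.frame `individual_id`, `degree`, `strength`, `betweenness`,
#'   plus the window index as column `window`.
#' @export
node_metrics <- function(network) {
  n <- igraph::vcount(network)
  win <- igraph::graph_attr(network, "window_index")
  if (n == 0L) {
    return(data.frame(individual_id = character(), window = integer(),
                      degree = integer(), strength = numeric(),
                      betweenness = numeric(), stringsAsFactors = FALSE))
  }
  w <- igraph::E(network)$weight
  btw <- if (igraph::ecount(network) > 0L) {
    igraph::betweenness(network, directed = FALSE, weights = 1 / w,
                        normalized = FALSE)
  } else {
    rep(0, n)
  }
  data.frame(
    individual_id = igraph::V(network)$name,
    window = if (is.null(win)) NA_integer_ else win,
    degree = as.integer(igraph::degree(network)),
    strength = as.numeric(igraph::strength(network, weights = w)),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE
  )
}

#' Change in centrality relative to the pre-event baseline
#'
#' For every window of a survivor stack except the baseline (the last
#' pre-event window), computes each individual's change in degree, strength
#' and betweenness relative to its value in the baseline window. With the
#' default two-pre/four-post layout this yields rows for windows
#' 1, 3, 4, 5, 6 — the earlier pre-event window serves as a pre-event
#' "control" timestep.
#'
#' @param stack a survivor `network_stack` from [make_stacks()].
#' @return data.frame `individual_id`, `window`, `d_degree`, `d_strength`,
#'   `d_betweenness` plus the raw metrics.
#' @export
delta_from_baseline <- function(stack) {
  metrics <- do.call(rbind, lapply(stack$networks, node_metrics))
  base <- metrics[metrics$window == stack$baseline_window, , drop = FALSE]
  others <- metrics[metrics$window != stack$baseline_window, , drop = FALSE]
  m <- match(others$individual_id, base$individual_id)
  if (anyNA(m)) {
    stop("internal consistency error: survivor stack member missing from the ",
         "baseline window", call. = FALSE)
  }
  others$d_degree <- others$degree - base$degree[m]
  others$d_strength <- others$strength - base$strength[m]
  others$d_betweenness <- others$betweenness - base$betweenness[m]
  rownames(others) <- NULL
  others
}

#' Edge density of an association network
#'
#' The proportion of realized dyads: edges with positive weight divided by
#' `n (n - 1) / 2`. Depends only on which dyads have positive weight, not on
#' the weights themselves.
#'
#' @param network an association network.
#' @return A single proportion; `NA` with a warning for fewer than 2 nodes.
#' @export
edge_density_sri <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2L) {
    warning("edge density undefined for fewer than 2 nodes")
    return(NA_real_)
  }
  igraph::ecount(network) / (n * (n - 1) / 2)
}

#' Weighted modularity of a partition
#'
#' Newman's weighted modularity
#' `Q = sum_c (W_c / W - (S_c / 2W)^2)` where `W` is the total edge weight,
#' `W_c` the weight inside community `c` and `S_c` the summed strength of its
#' members. A single-community partition always scores 0.
#'
#' @param network an association network.
#' @param partition a [community_partition()] or a membership vector named by
#'   individual id.
#' @return Modularity Q.
#' @export
network_modularity <- function(network, partition) {
  mem <- partition_membership(partition)
  ids <- igraph::V(network)$name
  if (!all(ids %in% names(mem))) {
    stop("partition does not cover every node of the network", call. = FALSE)
  }
  igraph::modularity(network, as.integer(factor(mem[ids])),
                     weights = igraph::E(network)$weight)
}

#' Community-level summary statistics
#'
#' For each community of a partition: its size, its within-community edge
#' density (realized positive-weight dyads among members over all member
#' dyads; undefined below 2 members), the proportion of its members missing,
#' and optionally its size in a baseline partition.
#'
#' @param network the window's association network.
#' @param partition community partition of that window.
#' @param missing_ids ids counted as missing.
#' @param baseline_partition optional partition whose community sizes are
#'   joined as `pre_size` (matched by community label).
#' @return data.frame `community`, `window`, `size`, `within_density`,
#'   `prop_missing`, and `pre_size` when a baseline is given.
#' @export
group_stats <- function(network, partition, missing_ids = character(),
                        baseline_partition = NULL) {
  mem <- partition_membership(partition)
  ids <- igraph::V(network)$name
  mem <- mem[names(mem) %in% ids]
  comms <- sort(unique(mem))
  win <- igraph::graph_attr(network, "window_index")
  el <- if (igraph::ecount(network) > 0L) {
    igraph::as_data_frame(network, what = "edges")
  } else {
    data.frame(from = character(), to = character())
  }
  rows <- lapply(comms, function(cc) {
    members <- names(mem)[mem == cc]
    nc <- length(members)
    within <- sum(el$from %in% members & el$to %in% members)
    dens <- if (nc >= 2) within / (nc * (nc - 1) / 2) else NA_real_
    data.frame(community = cc,
               window = if (is.null(win)) NA_integer_ else win,
               size = nc,
               within_density = dens,
               prop_missing = mean(members %in% missing_ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(baseline_partition)) {
    bmem <- partition_membership(baseline_partition)
    bsize <- table(bmem)
    out$pre_size <- as.integer(bsize[as.character(out$community)])
  }
  rownames(out) <- NULL
  out
}
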