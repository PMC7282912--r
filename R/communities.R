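#' Detect social communities in one window
#'
#' Partitions one window's association network into social groups by greedy
#' optimization of either the two-level map-equation codelength (Infomap,
#' the default) or weighted modularity (Louvain), with a fixed seed and
#' best-of-`restarts` tie-breaking. Isolated nodes become singleton
#' communities.
#'
#' @param network an association network.
#' @param objective `"map"` (map equation) or `"modularity"`.
#' @param restarts number of restarts; the best objective value wins.
#' @param seed RNG seed for the stochastic optimizer.
#' @return A `community_partition`: named membership vector (labels are
#'   window-local integers), the window index, the objective and its value
#'   (codelength for `"map"`, Q for `"modularity"`).
#' @export
detect_communities <- function(network, objective = c("map", "modularity"),
                               restarts = 10, seed = 1L) {
  objective <- match.arg(objective)
  n <- igraph::vcount(network)
  win <- igraph::graph_attr(network, "window_index")
  if (n == 0L) {
    return(structure(list(membership = setNames(integer(), character()),
                          window = win, objective = objective,
                          value = NA_real_),
                     class = "community_partition"))
  }
  w <- igraph::E(network)$weight
  res <- with_seed(derive_seed(seed, 811,
                               if (is.null(win) || is.na(win)) 0 else win), {
    if (objective == "map") {
      best <- NULL
      for (k in seq_len(restarts)) {
        cm <- igraph::cluster_infomap(network, e.weights = w, nb.trials = 1)
        cl <- igraph::code_len(cm)
        if (is.null(best) || (is.finite(cl) && cl < best$value)) {
          best <- list(mem = igraph::membership(cm),
                       value = if (is.finite(cl)) cl else NA_real_)
        }
      }
      best
    } else {
      best <- NULL
      for (k in seq_len(restarts)) {
        cm <- igraph::cluster_louvain(network, weights = w)
        q <- igraph::modularity(network, igraph::membership(cm), weights = w)
        if (is.null(best) || q > best$value) {
          best <- list(mem = igraph::membership(cm), value = q)
        }
      }
      best
    }
  })
  mem <- setNames(as.integer(res$mem), igraph::V(network)$name)
  structure(list(membership = mem, window = win, objective = objective,
                 value = res$value),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition: window %s, %d nodes, %d communities, %s = %.4g>\n",
              ifelse(is.null(x$window) || is.na(x$window), "?", x$window),
              length(x$membership), length(unique(x$membership)),
              ifelse(x$objective == "map", "codelength", "Q"), x$value))
  invisible(x)
}

partition_membership <- function(partition) {
  if (inherits(partition, "community_partition")) return(partition$membership)
  if (is.atomic(partition) && !is.null(names(partition))) return(partition)
  stop("expected a community_partition or a named membership vector",
       call. = FALSE)
}

#' Link window partitions into dynamic communities
#'
#' Tracks social groups through time by reciprocal majority identification:
#' community `X` at window `t` links to `Y` at window `t + 1` only when `Y`
#' contains a strict majority (> 50%) of `X`'s members *and* `X` contributes
#' a strict majority of `Y`'s members. Linked communities share a persistent
#' id; communities with no reciprocal match get a fresh id. With
#' `history = 2`, a community unmatched at `t` is also compared against
#' window `t - 1`, so a group that fragments for a single window can recover
#' its identity; the two pre-event windows thereby establish the initial
#' persistent identities. Ties (exactly 50%) break to no link.
#'
#' @param partitions list of `community_partition`s (or named membership
#'   vectors) in window order.
#' @param windows optional window indices (defaults to the partitions'
#'   recorded windows, else `1:T`).
#' @param node_sections optional list (one per window) of named vectors
#'   giving each individual's majority-use section, used to assign each
#'   community a section label (its members' modal section).
#' @param history how many previous windows to search for a reciprocal
#'   majority (default 2).
#' @return A `dynamic_community_map` with `assignments` (window,
#'   individual_id, community, persistent_id), `linkage` (one row per
#'   community per window: matched / new), and `sections` (window,
#'   persistent_id, section) when `node_sections` is given.
#' @export
link_windows <- function(partitions, windows = NULL, node_sections = NULL,
                         history = 2) {
  if (length(partitions) < 2L) {
    stop("need at least two windows to link", call. = FALSE)
  }
  mems <- lapply(partitions, partition_membership)
  for (m in mems) {
    if (anyDuplicated(names(m))) {
      stop("duplicate individual in a window's partition", call. = FALSE)
    }
  }
  if (is.null(windows)) {
    windows <- vapply(seq_along(partitions), function(i) {
      w <- if (inherits(partitions[[i]], "community_partition")) {
        partitions[[i]]$window
      } else NULL
      if (is.null(w) || is.na(w)) i else as.integer(w)
    }, integer(1))
  }
  T <- length(mems)
  pid_counter <- 0L
  new_pid <- function() {
    pid_counter <<- pid_counter + 1L
    sprintf("D%02d", pid_counter)
  }
  # pid_maps[[t]]: named map community label -> persistent id
  pid_maps <- vector("list", T)
  comms1 <- sort(unique(mems[[1]]))
  pid_maps[[1]] <- setNames(vapply(comms1, function(x) new_pid(), character(1)),
                            as.character(comms1))
  linkage <- list()
  for (t in 2:T) {
    cur <- mems[[t]]
    comms <- sort(unique(cur))
    assigned <- setNames(rep(NA_character_, length(comms)), as.character(comms))
    used <- character()
    for (back in seq_len(min(history, t - 1))) {
      prev <- mems[[t - back]]
      prev_map <- pid_maps[[t - back]]
      for (cc in comms) {
        key <- as.character(cc)
        if (!is.na(assigned[key])) next
        members_y <- names(cur)[cur == cc]
        shared <- intersect(members_y, names(prev))
        if (length(shared) == 0L) next
        cand <- table(prev[shared])
        cand <- sort(cand, decreasing = TRUE)
        x_lab <- names(cand)[1]
        o <- as.integer(cand[1])
        size_x <- sum(prev == as.integer(x_lab))
        size_y <- length(members_y)
        pid <- prev_map[[x_lab]]
        if (o > size_x / 2 && o > size_y / 2 && !(pid %in% used)) {
          assigned[key] <- pid
          used <- c(used, pid)
        }
      }
    }
    for (key in names(assigned)) {
      if (is.na(assigned[key])) assigned[key] <- new_pid()
    }
    pid_maps[[t]] <- assigned
    linkage[[t - 1]] <- data.frame(
      window = windows[t], community = as.integer(names(assigned)),
      persistent_id = unname(assigned),
      type = ifelse(assigned %in% used, "matched", "new"),
      stringsAsFactors = FALSE
    )
  }
  assignments <- do.call(rbind, lapply(seq_len(T), function(t) {
    m <- mems[[t]]
    data.frame(window = windows[t], individual_id = names(m),
               community = as.integer(m),
               persistent_id = unname(pid_maps[[t]][as.character(m)]),
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  sections <- NULL
  if (!is.null(node_sections)) {
    sections <- do.call(rbind, lapply(seq_len(T), function(t) {
      a <- assignments[assignments$window == windows[t], , drop = FALSE]
      sec <- node_sections[[t]][a$individual_id]
      agg <- tapply(sec, a$persistent_id, modal_value)
      data.frame(window = windows[t], persistent_id = names(agg),
                 section = as.vector(agg), stringsAsFactors = FALSE)
    }))
    rownames(sections) <- NULL
  }
  structure(list(assignments = assignments,
                 linkage = do.call(rbind, linkage),
                 sections = sections, windows = windows),
            class = "dynamic_community_map")
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1]
}

#' @export
print.dynamic_community_map <- function(x, ...) {
  npid <- length(unique(x$assignments$persistent_id))
  cat(sprintf("<dynamic_community_map: %d windows, %d persistent communities>\n",
              length(x$windows), npid))
  invisible(x)
}

#' Movement events between dynamic communities
#'
#' A movement event is one or more individuals leaving the same persistent
#' community for the same other persistent community between two consecutive
#' windows. Events are counted per (source, destination) pair; the
#' `cross_section` flag marks events whose source and destination communities
#' have different majority sections (when the map carries sections).
#'
#' @param map a [link_windows()] result.
#' @param window_pair optional length-2 vector `c(from, to)` restricting the
#'   count to one consecutive pair; default: all consecutive pairs.
#' @return A list with `events` (data.frame window_from, window_to,
#'   source_pid, dest_pid, n_movers, cross_section, mover ids collapsed with
#'   `;`), `n_events`, `mover_range`, `n_cross_section`.
#' @export
movement_events <- function(map, window_pair = NULL) {
  w <- map$windows
  pairs <- if (is.null(window_pair)) {
    lapply(seq_len(length(w) - 1L), function(i) c(w[i], w[i + 1L]))
  } else {
    list(window_pair)
  }
  a <- map$assignments
  out <- list()
  for (p in pairs) {
    a1 <- a[a$window == p[1], c("individual_id", "persistent_id")]
    a2 <- a[a$window == p[2], c("individual_id", "persistent_id")]
    m <- merge(a1, a2, by = "individual_id", suffixes = c("_from", "_to"))
    movers <- m[m$persistent_id_from != m$persistent_id_to, , drop = FALSE]
    if (nrow(movers) == 0L) next
    key <- paste(movers$persistent_id_from, movers$persistent_id_to, sep = "->")
    for (k in unique(key)) {
      sub <- movers[key == k, , drop = FALSE]
      src <- sub$persistent_id_from[1]
      dst <- sub$persistent_id_to[1]
      cross <- NA
      if (!is.null(map$sections)) {
        s1 <- map$sections$section[map$sections$window == p[1] &
                                     map$sections$persistent_id == src]
        s2 <- map$sections$section[map$sections$window == p[2] &
                                     map$sections$persistent_id == dst]
        if (length(s1) == 1 && length(s2) == 1) cross <- !identical(s1, s2)
      }
      out[[length(out) + 1L]] <- data.frame(
        window_from = p[1], window_to = p[2],
        source_pid = src, dest_pid = dst,
        n_movers = nrow(sub), cross_section = cross,
        movers = paste(sub$individual_id, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  events <- if (length(out)) do.call(rbind, out) else {
    data.frame(window_from = integer(), window_to = integer(),
               source_pid = character(), dest_pid = character(),
               n_movers = integer(), cross_section = logical(),
               movers = character(), stringsAsFactors = FALSE)
  }
  rownames(events) <- NULL
  list(events = events,
       n_events = nrow(events),
       mover_range = if (nrow(events)) range(events$n_movers) else c(0L, 0L),
       n_cross_section = sum(events$cross_section %in% TRUE))
}

#' Count communities of at least a minimum size
#'
#' @param partition a partition or named membership vector.
#' @param min_size minimum community size (default 3, the convention for a
#'   "group" rather than a pair or singleton).
#' @return Integer count.
#' @export
count_groups <- function(partition, min_size = 3) {
  mem <- partition_membership(partition)
  sum(table(mem) >= min_size)
}

#' Alluvial flow table of a dynamic community map
#'
#' Long-format flows between consecutive windows: how many individuals went
#' from each persistent community to each (including staying put), enough to
#' draw an alluvial diagram. Flows out of a community sum to its membership
#' among individuals present in both windows.
#'
#' @param map a [link_windows()] result.
#' @return data.frame `window_from`, `window_to`, `source_pid`, `dest_pid`,
#'   `n`.
#' @export
alluvial_table <- function(map) {
  w <- map$windows
  a <- map$assignments
  out <- list()
  for (i in seq_len(length(w) - 1L)) {
    a1 <- a[a$window == w[i], c("individual_id", "persistent_id")]
    a2 <- a[a$window == w[i + 1L], c("individual_id", "persistent_id")]
    m <- merge(a1, a2, by = "individual_id", suffixes = c("_from", "_to"))
    if (nrow(m) == 0L) next
    tb <- as.data.frame(table(m$persistent_id_from, m$persistent_id_to),
                        stringsAsFactors = FALSE)
    tb <- tb[tb$Freq > 0, , drop = FALSE]
    out[[i]] <- data.frame(window_from = w[i], window_to = w[i + 1L],
                           source_pid = tb$Var1, dest_pid = tb$Var2,
                           n = tb$Freq, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(window_from = integer(), window_to = integer(),
               source_pid = character(), dest_pid = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Detect and link communities across a whole stack
#'
#' Convenience wrapper: runs [detect_communities()] on every window of a
#' stack and links the partitions with [link_windows()], feeding each
#' window's majority-use sections through for the cross-section flags.
#'
#' @param stack a `network_stack`.
#' @inheritParams detect_communities
#' @inheritParams link_windows
#' @return A list with `partitions` (per window) and `map`
#'   (a `dynamic_community_map`).
#' @export
dynamic_communities <- function(stack, objective = c("map", "modularity"),
                                restarts = 10, seed = 1L, history = 2) {
  objective <- match.arg(objective)
  partitions <- lapply(stack$networks, detect_communities,
                       objective = objective, restarts = restarts, seed = seed)
  sections <- lapply(stack$networks, function(g) {
    s <- igraph::vertex_attr(g, "section_use")
    if (is.null(s)) NULL else setNames(s, igraph::V(g)$name)
  })
  if (any(vapply(sections, is.null, logical(1)))) sections <- NULL
  map <- link_windows(partitions, windows = stack$schedule$index,
                      node_sections = sections, history = history)
  list(partitions = partitions, map = map)
}
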