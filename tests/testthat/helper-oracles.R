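# Independent brute-force oracles used to validate the fast implementations.

# Per-second discretization of dyadic co-occupancy: counts seconds (grid of
# 1 s) during which two individuals sit in the same box. O(n * T), only for
# short logs.
oracle_cooccupancy <- function(events, window) {
  ids <- sort(unique(events$individual_id))
  secs <- seq(floor(window$start), ceiling(window$end) - 1)
  occ <- lapply(ids, function(i) {
    sub <- events[events$individual_id == i, , drop = FALSE]
    box <- rep(NA_character_, length(secs))
    for (k in seq_len(nrow(sub))) {
      lo <- max(ceiling(sub$entry[k]), window$start)
      hi <- min(floor(sub$exit[k]) - 1, window$end - 1)
      if (hi >= lo) box[(lo - secs[1] + 1):(hi - secs[1] + 1)] <- sub$box_id[k]
    }
    box
  })
  names(occ) <- ids
  totals <- vapply(occ, function(b) sum(!is.na(b)), numeric(1))
  dyads <- list()
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        x <- sum(!is.na(occ[[a]]) & occ[[a]] == occ[[b]], na.rm = TRUE)
        if (x > 0) {
          dyads[[length(dyads) + 1L]] <- data.frame(
            id_i = ids[a], id_j = ids[b], seconds = x,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(dyads = if (length(dyads)) do.call(rbind, dyads) else
         data.frame(id_i = character(), id_j = character(), seconds = numeric()),
       totals = totals)
}

# Brute-force betweenness by enumerating every simple path between every
# pair, with edge distance 1/w; tied geodesics contribute fractionally.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  btw <- setNames(rep(0, n), igraph::V(g)$name)
  if (n < 3) return(btw)
  dmat <- 1 / igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- suppressWarnings(
        igraph::all_simple_paths(g, from = s, to = t))
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p) {
        p <- as.integer(p)
        sum(dmat[cbind(p[-length(p)], p[-1])])
      }, numeric(1))
      dmin <- min(lens)
      short <- paths[lens <= dmin + 1e-9]
      for (p in short) {
        inner <- setdiff(as.integer(p), c(s, t))
        for (v in inner) {
          btw[v] <- btw[v] + 1 / length(short)
        }
      }
    }
  }
  btw
}

# Random connected weighted graph on n nodes for oracle comparisons.
random_weighted_graph <- function(n, p = 0.5) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.05, 1), 3)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# Compose a chain's transpositions one at a time (independent of the
# vectorized bookkeeping in generate_swap_chain).
oracle_permutation <- function(chain, emission) {
  k <- chain$burn_in + emission * chain$swaps_per_emission
  perm <- seq_along(chain$pool)
  for (i in seq_len(k)) {
    a <- chain$swaps[i, 1]; b <- chain$swaps[i, 2]
    tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
  }
  setNames(chain$pool[perm], chain$pool)
}

# Hand-built visit record helper.
visits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r[[1]], box_id = r[[2]],
               entry = as.numeric(r[[3]]), exit = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
  df$section <- as.integer(sub("^s(\\d+).*", "\\1", df$box_id))
  df
}

win <- function(start, end, index = 1L, phase = "pre") {
  data.frame(index = index, start = start, end = end, phase = phase,
             stringsAsFactors = FALSE)
}

# Small simulated scenario shared across tests (built once per file).
small_scenario <- function(seed = 42, ...) {
  cfg <- scenario_config(n_individuals = 40, n_groups = 4, n_sections = 2,
                         boxes_per_section = 8, seed = seed, ...)
  simulate_scenario(cfg)
}

# Scripted community-change table: high-loss communities shrink by exactly
# their loss count (plus unit noise); used by the community-model checks.
scripted_community_table <- function(seed, nc = 12) {
  set.seed(seed)
  pre <- sample(6:30, nc, replace = TRUE)
  loss <- runif(nc, 0.05, 0.8)
  tab <- do.call(rbind, lapply(1:4, function(w) {
    data.frame(persistent_id = sprintf("D%02d", 1:nc),
               window = w + 2,
               d_size = -round(pre * loss) + rnorm(nc, 0, 1),
               d_density = rnorm(nc, 0, 0.05),
               pre_size = pre, prop_missing = loss, prop_killed = loss,
               stringsAsFactors = FALSE)
  }))
  tab$pre_size_std <- (tab$pre_size - mean(tab$pre_size)) / sd(tab$pre_size)
  tab$missing_std <- (tab$prop_missing - mean(tab$prop_missing)) /
    sd(tab$prop_missing)
  tab$killed_std <- tab$missing_std
  tab$timestep <- factor(tab$window)
  tab
}
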