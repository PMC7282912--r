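#' Generate a population roster
#'
#' Draws the tagged population: unique individual ids, sex, a home social
#' group (each group living in exactly one barn section), and a positive,
#' right-skewed `sociality_trait` (Gamma with mean 1) that scales how much
#' time an individual spends inside nest-boxes and hence its expected
#' association strength. Group sizes are drawn from a Dirichlet-multinomial
#' so that small and large groups coexist; every group is non-empty.
#'
#' @param config a [scenario_config()].
#' @return A data.frame with columns `individual_id`, `sex`, `home_group`,
#'   `home_section`, `sociality_trait`, `fate` (all `"survivor"` until
#'   [apply_catastrophe()] runs).
#' @export
generate_roster <- function(config) {
  validate_scenario_config(config)
  n <- config$n_individuals
  g <- config$n_groups
  if (n < g) stop("need at least one individual per group", call. = FALSE)
  with_seed(derive_seed(config$seed, 101), {
    conc <- config$group_size_dispersion * 5
    w <- rgamma(g, shape = conc, rate = 1)
    w <- w / sum(w)
    extra <- if (n > g) as.vector(stats::rmultinom(1, n - g, prob = w)) else rep(0L, g)
    sizes <- 1L + extra
    group <- rep(sprintf("g%02d", seq_len(g)), times = sizes)
    section <- group_sections(g, config$n_sections)[as.integer(factor(group))]
    roster <- data.frame(
      individual_id = sprintf("m%04d", seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      home_group = group,
      home_section = section,
      sociality_trait = rgamma(n, shape = config$sociality_shape,
                               rate = config$sociality_shape),
      fate = "survivor",
      stringsAsFactors = FALSE
    )
    roster
  })
}

# Deterministic group -> section map (round robin), and group -> home box
# cluster (disjoint clusters within a section as long as boxes allow).
group_sections <- function(n_groups, n_sections) {
  ((seq_len(n_groups) - 1L) %% n_sections) + 1L
}

box_ids <- function(section, boxes_per_section) {
  sprintf("s%db%02d", rep(section, each = boxes_per_section),
          rep(seq_len(boxes_per_section), length(section)))
}

box_section_map <- function(config) {
  data.frame(
    box_id = box_ids(seq_len(config$n_sections), config$boxes_per_section),
    section = rep(seq_len(config$n_sections), each = config$boxes_per_section),
    stringsAsFactors = FALSE
  )
}

# Home clusters are laid out over boxes 1..(B-1) of the group's section; the
# last box of every section belongs to no cluster and is visited only during
# exploration.
group_box_cluster <- function(group_index, config) {
  secs <- group_sections(config$n_groups, config$n_sections)
  sec <- secs[group_index]
  rank_in_sec <- sum(secs[seq_len(group_index)] == sec)
  b <- config$boxes_per_section - 1L
  k <- config$boxes_per_group
  offset <- ((rank_in_sec - 1L) * k) %% b
  idx <- ((offset + seq_len(k) - 1L) %% b) + 1L
  sprintf("s%db%02d", sec, idx)
}

# Per-individual box-choice weights (named by box id). Cluster boxes carry a
# popularity gradient (`popularity_decay`): the first box is the group's main
# nest, later boxes are progressively quieter. `prune` in [0, 1) is the
# box-choice side of the insularity response: it sharpens preference for the
# main nest (exponent grows with prune) and cuts exploratory visits to
# non-home boxes quadratically, so weak incidental ties are dropped first.
# Parameterized so that equal within and between rates give uniform box
# choice at prune 0.
box_weights <- function(home_cluster, config, prune = 0) {
  boxes <- box_section_map(config)$box_id
  wb <- config$between_group_overlap_rate
  ww <- config$within_group_overlap_rate
  dec <- config$popularity_decay
  k <- length(home_cluster)
  pref <- dec^((seq_len(k) - 1) * (1 + 2 * prune))
  w <- rep(wb * (1 - prune)^2, length(boxes))
  names(w) <- boxes
  w[home_cluster] <- wb * (1 - prune)^2 + (ww - wb) * pref
  if (sum(w) <= 0 || any(w < 0)) {
    w[] <- pmax(w, 0)
    if (sum(w) <= 0) w[home_cluster[1]] <- 1
  }
  w
}

# Alternating renewal bout process for one individual over [start, end):
# out-of-box gaps ~ Exp(mean_gap / sociality), in-box visits ~ Exp(mean_visit),
# box drawn from `weights`. Visits are sequential, so an individual is never
# in two boxes at once; the final visit is clipped to the window end.
simulate_bouts <- function(id, start, end, mean_visit_s, mean_gap_s, weights) {
  span <- end - start
  n_max <- max(8L, ceiling(3 * span / (mean_visit_s + mean_gap_s)) + 8L)
  out <- vector("list", 4L)
  oi <- 0L
  t <- start
  boxes <- names(weights)
  p <- weights / sum(weights)
  repeat {
    gaps <- rexp(n_max, rate = 1 / mean_gap_s)
    durs <- rexp(n_max, rate = 1 / mean_visit_s)
    entries <- t + cumsum(gaps) + c(0, cumsum(durs[-n_max]))
    exits <- entries + durs
    live <- entries < end
    if (!any(live)) break
    oi <- oi + 1L
    out[[oi]] <- data.frame(
      individual_id = id,
      box_id = sample(boxes, sum(live), replace = TRUE, prob = p),
      entry = entries[live],
      exit = pmin(exits[live], end),
      stringsAsFactors = FALSE
    )
    if (all(live)) {
      t <- exits[n_max]
    } else {
      break
    }
  }
  if (oi == 0L) return(NULL)
  do.call(rbind, out[seq_len(oi)])
}

#' Simulate one observation window of nest-box visits
#'
#' Every listed individual follows an alternating in-box/out-of-box bout
#' process. Box choice is biased towards the home group's box cluster by the
#' ratio of `within_group_overlap_rate` to `between_group_overlap_rate`, which
#' plants higher expected co-occupancy among group mates than between groups.
#'
#' @param roster output of [generate_roster()].
#' @param window_index index of a window in `schedule`.
#' @param config the [scenario_config()].
#' @param schedule a [window_schedule()]; defaults to the one implied by
#'   `config`.
#' @param ids individuals to simulate (default: all of `roster`).
#' @return A data.frame of visit records: `individual_id`, `box_id`,
#'   `section`, `entry`, `exit` (epoch seconds), sorted by entry time.
#' @export
simulate_window <- function(roster, window_index, config,
                            schedule = scenario_schedule(config),
                            ids = roster$individual_id) {
  win <- window_row(schedule, window_index)
  bmap <- box_section_map(config)
  group_idx <- as.integer(sub("^g", "", roster$home_group))
  rows <- match(ids, roster$individual_id)
  if (anyNA(rows)) stop("unknown individual id in `ids`", call. = FALSE)
  mean_visit_s <- config$mean_visit_minutes * 60
  res <- with_seed(derive_seed(config$seed, 211, window_index), {
    pieces <- lapply(rows, function(r) {
      w <- box_weights(group_box_cluster(group_idx[r], config), config)
      gap <- config$mean_gap_hours * 3600 / max(roster$sociality_trait[r], 1e-3)
      simulate_bouts(roster$individual_id[r], win$start, win$end,
                     mean_visit_s, gap, w)
    })
    do.call(rbind, pieces)
  })
  finalize_events(res, bmap)
}

finalize_events <- function(events, bmap) {
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(individual_id = character(), box_id = character(),
                      section = integer(), entry = numeric(), exit = numeric(),
                      stringsAsFactors = FALSE))
  }
  events$section <- bmap$section[match(events$box_id, bmap$box_id)]
  events <- events[order(events$entry, events$individual_id, events$box_id),
                   c("individual_id", "box_id", "section", "entry", "exit")]
  rownames(events) <- NULL
  events
}

#' Schedule implied by a scenario configuration
#' @param config a [scenario_config()].
#' @return A [window_schedule()].
#' @export
scenario_schedule <- function(config) {
  window_schedule(config$n_pre_windows, config$n_post_windows,
                  config$window_length_days, config$gap_days)
}

#' Apply the catastrophic removal to a roster
#'
#' Assigns fate `dead` to `round(mortality_fraction * N)` individuals and
#' `disappeared` to `round(disappearance_fraction * N)` of the remainder
#' (rounding half away from zero, so printed fractions give exact counts).
#' Sampling weights are proportional to `loss_group_bias` for each
#' individual's group, so losses can be spread evenly or concentrated until
#' some groups are nearly wiped out. Dead and disappeared individuals are
#' treated identically downstream ("missing"): both stop emitting visits at
#' the event.
#'
#' @param roster output of [generate_roster()].
#' @param config the [scenario_config()].
#' @return The roster with its `fate` column filled in.
#' @export
apply_catastrophe <- function(roster, config) {
  n <- nrow(roster)
  n_dead <- as.integer(round_half_away(config$mortality_fraction * n))
  n_gone <- as.integer(round_half_away(config$disappearance_fraction * n))
  if (n_dead + n_gone > n) {
    stop("loss fractions exceed the population size", call. = FALSE)
  }
  bias <- config$loss_group_bias
  if (is.null(bias)) bias <- rep(1, config$n_groups)
  w <- bias[as.integer(sub("^g", "", roster$home_group))]
  if (all(w == 0)) w <- rep(1, n)
  roster$fate <- "survivor"
  with_seed(derive_seed(config$seed, 307), {
    dead <- if (n_dead > 0) sample(n, n_dead, prob = w) else integer()
    pool <- setdiff(seq_len(n), dead)
    wp <- w[pool]
    if (all(wp == 0)) wp <- rep(1, length(pool))
    gone <- if (n_gone > 0) pool[sample(length(pool), n_gone, prob = wp)] else integer()
    roster$fate[dead] <- "dead"
    roster$fate[gone] <- "disappeared"
  })
  roster
}

#' Simulate a post-event window with behavioural responses
#'
#' Only survivors emit visits. On top of the baseline bout process two
#' response mechanisms act, each scaled by the proportion of pre-event
#' association strength the survivor lost:
#'
#' * weak-tie formation: survivors of *low* pre-event sociality add extra
#'   short visits to other groups' home boxes, at an expected per-window rate
#'   `response_effect_low_social * loss * (1 - sociality quantile)`. These
#'   bouts create many weak new edges (degree rises, strength barely moves).
#' * partner pruning: survivors of *high* pre-event sociality concentrate
#'   their in-box time on fewer boxes, with intensity
#'   `response_effect_high_social * loss * sociality quantile`, shrinking the
#'   number of distinct partners while keeping total in-box time similar.
#'
#' With both effects zero, post-event behaviour is the pre-event process
#' restricted to survivors (the null scenario).
#'
#' @param roster roster after [apply_catastrophe()].
#' @param sociality named vector of baseline sociality per individual
#'   (typically pre-event weighted degree); ranks are used, so any
#'   monotone measure works. Defaults to the roster's latent trait.
#' @param loss named vector of loss proportions in `[0, 1]` per survivor
#'   (see [loss_attributes()]); missing entries are treated as 0.
#' @param window_index index of a post-event window.
#' @inheritParams simulate_window
#' @return Visit records for the window, survivors only.
#' @export
simulate_post_event_response <- function(roster, window_index, config,
                                         sociality = NULL, loss = NULL,
                                         schedule = scenario_schedule(config)) {
  if (all(roster$fate == "survivor") &&
      (config$mortality_fraction > 0 || config$disappearance_fraction > 0)) {
    stop("apply_catastrophe() must run before simulating post-event windows",
         call. = FALSE)
  }
  win <- window_row(schedule, window_index)
  if (win$phase != "post") {
    stop("window ", window_index, " is not a post-event window", call. = FALSE)
  }
  surv <- roster[roster$fate == "survivor", , drop = FALSE]
  if (nrow(surv) == 0L) return(finalize_events(NULL, box_section_map(config)))

  if (is.null(sociality)) {
    sociality <- setNames(roster$sociality_trait, roster$individual_id)
  }
  soc <- sociality[surv$individual_id]
  soc[is.na(soc)] <- 0
  q <- (rank(soc, ties.method = "average") - 0.5) / length(soc)
  lv <- rep(0, nrow(surv))
  if (!is.null(loss)) {
    lv <- loss[surv$individual_id]
    lv[is.na(lv)] <- 0
  }
  lv <- pmin(pmax(lv, 0), 1)

  # responses build up over the post-event period: linear ramp from the
  # first (1/m) to the last (1) post-event window
  post_idx <- schedule$index[schedule$phase == "post"]
  ramp <- match(window_index, post_idx) / length(post_idx)
  prune <- pmin(config$response_effect_high_social * lv * q * ramp, 0.9)
  extra_rate <- config$response_effect_low_social * lv * (1 - q) * ramp

  bmap <- box_section_map(config)
  group_idx <- as.integer(sub("^g", "", surv$home_group))
  mean_visit_s <- config$mean_visit_minutes * 60
  res <- with_seed(derive_seed(config$seed, 211, window_index), {
    pieces <- lapply(seq_len(nrow(surv)), function(r) {
      cluster <- group_box_cluster(group_idx[r], config)
      w <- box_weights(cluster, config, prune = prune[r])
      # insular survivors also reduce overall box attendance, shedding the
      # weak incidental ties while long-overlap groupmate ties persist
      gap <- config$mean_gap_hours * 3600 /
        max(surv$sociality_trait[r], 1e-3) / (1 - prune[r])
      base <- simulate_bouts(surv$individual_id[r], win$start, win$end,
                             mean_visit_s, gap, w)
      extra <- extra_bouts(surv$individual_id[r], group_idx[r], win, config,
                           extra_rate[r], base)
      rbind(base, extra)
    })
    do.call(rbind, pieces)
  })
  finalize_events(res, bmap)
}

# Short prospecting visits to other groups' home boxes; bouts overlapping the
# individual's own baseline visits are dropped so intervals stay disjoint.
extra_bouts <- function(id, own_group, win, config, rate, base) {
  if (rate <= 0) return(NULL)
  n <- rpois(1, rate)
  if (n == 0L) return(NULL)
  other <- setdiff(seq_len(config$n_groups), own_group)
  if (length(other) == 0L) return(NULL)
  target <- other[sample.int(length(other), n, replace = TRUE)]
  # prospectors head for the busy boxes, where new associates are found
  pop <- config$popularity_decay^(seq_len(config$boxes_per_group) - 1)
  boxes <- vapply(target, function(gi) {
    cl <- group_box_cluster(gi, config)
    cl[sample.int(length(cl), 1, prob = pop)]
  }, character(1))
  dur <- runif(n, 120, 600)
  entry <- win$start + runif(n) * (win$end - win$start - max(dur))
  exit <- entry + dur
  keep <- rep(TRUE, n)
  if (!is.null(base) && nrow(base) > 0) {
    for (i in seq_len(n)) {
      keep[i] <- !any(entry[i] < base$exit & exit[i] > base$entry)
    }
  }
  if (n > 1) {
    ord <- order(entry)
    last_exit <- -Inf
    for (i in ord) {
      if (keep[i] && entry[i] < last_exit) keep[i] <- FALSE
      if (keep[i]) last_exit <- exit[i]
    }
  }
  if (!any(keep)) return(NULL)
  data.frame(individual_id = id, box_id = boxes[keep],
             entry = entry[keep], exit = exit[keep], stringsAsFactors = FALSE)
}

#' Simulate a complete turnover scenario
#'
#' Runs the whole generative pipeline: roster, pre-event windows for the full
#' population, the catastrophic removal, pre-event full-network sociality and
#' loss attributes, then post-event windows for survivors with the configured
#' behavioural responses. This is the entry point the tests and the worked
#' examples use.
#'
#' @param config a [scenario_config()].
#' @return A list with `events` (all visit records, all windows), `roster`
#'   (with fates), `schedule`, `config`, and `attributes` (per-survivor
#'   pre-event sociality and loss proportion; `NULL` when no loss occurred).
#' @export
simulate_scenario <- function(config) {
  roster <- generate_roster(config)
  schedule <- scenario_schedule(config)
  pre_idx <- schedule$index[schedule$phase == "pre"]
  post_idx <- schedule$index[schedule$phase == "post"]
  pre <- lapply(pre_idx, function(i) simulate_window(roster, i, config, schedule))
  roster <- apply_catastrophe(roster, config)

  pre_events <- do.call(rbind, pre)
  last_pre <- window_row(schedule, max(pre_idx))
  full_pre <- build_network(pre_events, last_pre, roster)
  missing_ids <- roster$individual_id[roster$fate != "survivor"]
  attrs <- loss_attributes(full_pre, missing_ids)
  soc <- setNames(attrs$pre_event_sociality, attrs$individual_id)
  loss <- setNames(attrs$loss_proportion, attrs$individual_id)
  loss[is.na(loss)] <- 0

  post <- lapply(post_idx, function(i) {
    simulate_post_event_response(roster, i, config,
                                 sociality = soc, loss = loss,
                                 schedule = schedule)
  })
  events <- rbind(pre_events, do.call(rbind, post))
  rownames(events) <- NULL
  list(events = events, roster = roster, schedule = schedule,
       config = config, attributes = attrs)
}

#' Read and write visit-event logs and rosters
#'
#' Plain-CSV interchange formats: event logs carry `individual_id`, `box_id`,
#' `section`, `entry`, `exit` (epoch seconds); rosters carry the columns of
#' [generate_roster()].
#'
#' @param events,roster data frames to write.
#' @param path file path.
#' @return The read data.frame, or (invisibly) the path written.
#' @export
write_event_log <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "box_id", "entry", "exit")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("event log is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ev
}

#' @rdname write_event_log
#' @export
write_roster <- function(roster, path) {
  write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_roster <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
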