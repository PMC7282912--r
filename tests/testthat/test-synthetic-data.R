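test_that("roster generation partitions individuals into non-empty groups", {
  cfg <- scenario_config(n_individuals = 12, n_groups = 3, n_sections = 2,
                         seed = 1)
  roster <- generate_roster(cfg)
  expect_equal(nrow(roster), 12)
  expect_equal(anyDuplicated(roster$individual_id), 0L)
  expect_setequal(unique(roster$home_group), c("g01", "g02", "g03"))
  expect_true(all(table(roster$home_group) >= 1))
  # each group maps to exactly one section
  sec_per_group <- tapply(roster$home_section, roster$home_group,
                          function(s) length(unique(s)))
  expect_true(all(sec_per_group == 1))
  # degenerate single group
  cfg1 <- scenario_config(n_individuals = 5, n_groups = 1, seed = 1)
  r1 <- generate_roster(cfg1)
  expect_equal(unique(r1$home_group), "g01")
  expect_equal(unique(r1$home_section), 1L)
})

test_that("identical configuration reproduces identical rosters and event logs", {
  cfg <- scenario_config(n_individuals = 20, n_groups = 2, seed = 99)
  expect_identical(generate_roster(cfg), generate_roster(cfg))
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$roster, s2$roster)
})

test_that("visit intervals stay inside the window and never self-overlap", {
  scen <- small_scenario(seed = 5)
  sched <- scen$schedule
  ev <- scen$events
  expect_true(all(ev$exit > ev$entry))
  for (i in seq_len(nrow(sched))) {
    sub <- ev[ev$entry >= sched$start[i] & ev$exit <= sched$end[i], ]
    expect_gt(nrow(sub), 0)
  }
  # no record crosses the event gap
  gap_lo <- max(sched$end[sched$phase == "pre"])
  gap_hi <- min(sched$start[sched$phase == "post"])
  expect_false(any(ev$entry < gap_hi & ev$exit > gap_lo))
  # per-individual intervals pairwise disjoint
  sp <- split(ev[, c("entry", "exit")], ev$individual_id)
  overlaps <- vapply(sp, function(d) {
    o <- order(d$entry)
    any(d$entry[o][-1] < d$exit[o][-length(o)])
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("zero between-group rate plants perfectly separated groups", {
  cfg <- scenario_config(n_individuals = 24, n_groups = 3, n_sections = 3,
                         between_group_overlap_rate = 0, seed = 3)
  roster <- generate_roster(cfg)
  sched <- scenario_schedule(cfg)
  ev <- simulate_window(roster, 1, cfg, sched)
  cd <- cooccupancy_durations(ev, sched[1, ])
  grp <- setNames(roster$home_group, roster$individual_id)
  if (nrow(cd$dyads) > 0) {
    expect_true(all(grp[cd$dyads$id_i] == grp[cd$dyads$id_j]))
  }
  # single individual emits only its own records, no dyads
  ev1 <- simulate_window(roster, 1, cfg, sched, ids = roster$individual_id[1])
  expect_equal(unique(ev1$individual_id), roster$individual_id[1])
  cd1 <- cooccupancy_durations(ev1, sched[1, ])
  expect_equal(nrow(cd1$dyads), 0L)
})

test_that("equal within/between rates give within:between overlap ratio 1", {
  # Monte-Carlo over many seeds: expected per-dyad overlap should not differ
  # between within-group and between-group dyads when box choice is uniform
  tot_w <- 0; tot_b <- 0; nw <- 0; nb <- 0
  for (seed in 1:200) {
    cfg <- scenario_config(n_individuals = 10, n_groups = 2, n_sections = 2,
                           boxes_per_section = 3, boxes_per_group = 2,
                           within_group_overlap_rate = 0.5,
                           between_group_overlap_rate = 0.5,
                           window_length_days = 1, seed = seed)
    roster <- generate_roster(cfg)
    sched <- scenario_schedule(cfg)
    ev <- simulate_window(roster, 1, cfg, sched)
    cd <- cooccupancy_durations(ev, sched[1, ])
    grp <- setNames(roster$home_group, roster$individual_id)
    ids <- roster$individual_id
    for (a in 1:(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        x <- cd$dyads$seconds[cd$dyads$id_i == min(ids[a], ids[b]) &
                                cd$dyads$id_j == max(ids[a], ids[b])]
        x <- if (length(x)) x else 0
        if (grp[ids[a]] == grp[ids[b]]) { tot_w <- tot_w + x; nw <- nw + 1 }
        else { tot_b <- tot_b + x; nb <- nb + 1 }
      }
    }
  }
  ratio <- (tot_w / nw) / (tot_b / nb)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.18)
})

test_that("planted contrast: within-group overlap exceeds between-group overlap", {
  scen <- small_scenario(seed = 8)
  sched <- scen$schedule
  cd <- cooccupancy_durations(scen$events, sched[1, ])
  grp <- setNames(scen$roster$home_group, scen$roster$individual_id)
  same <- grp[cd$dyads$id_i] == grp[cd$dyads$id_j]
  expect_gt(sum(cd$dyads$seconds[same]) / sum(same),
            sum(cd$dyads$seconds[!same]) / sum(!same))
})

test_that("catastrophe fate counts follow the rounding rule and group bias", {
  cfg <- scenario_config(n_individuals = 100, n_groups = 5,
                         mortality_fraction = 0.18,
                         disappearance_fraction = 0.22, seed = 2)
  roster <- apply_catastrophe(generate_roster(cfg), cfg)
  expect_equal(sum(roster$fate == "dead"), 18)
  expect_equal(sum(roster$fate == "disappeared"), 22)
  expect_equal(sum(roster$fate == "survivor"), 60)

  # zero fractions: everyone survives
  cfg0 <- scenario_config(n_individuals = 30, n_groups = 3,
                          mortality_fraction = 0, disappearance_fraction = 0,
                          seed = 2)
  r0 <- apply_catastrophe(generate_roster(cfg0), cfg0)
  expect_true(all(r0$fate == "survivor"))

  # heavy bias on group 1 concentrates the loss there
  cfgb <- scenario_config(n_individuals = 100, n_groups = 5,
                          mortality_fraction = 0.15,
                          disappearance_fraction = 0.15,
                          loss_group_bias = c(50, 1, 1, 1, 1), seed = 4)
  rb <- apply_catastrophe(generate_roster(cfgb), cfgb)
  loss_by_group <- tapply(rb$fate != "survivor", rb$home_group, mean)
  expect_equal(names(which.max(loss_by_group)), "g01")
})

test_that("dead and disappeared individuals emit no post-event visits", {
  cfg <- scenario_config(n_individuals = 30, n_groups = 3,
                         mortality_fraction = 0.2,
                         disappearance_fraction = 0.2, seed = 6)
  scen <- simulate_scenario(cfg)
  post_idx <- scen$schedule$index[scen$schedule$phase == "post"]
  post <- scen$events[scen$events$entry >=
                        min(scen$schedule$start[scen$schedule$index %in% post_idx]), ]
  missing_ids <- scen$roster$individual_id[scen$roster$fate != "survivor"]
  expect_length(intersect(unique(post$individual_id), missing_ids), 0)
})

test_that("post-event simulation requires the catastrophe and a post window", {
  cfg <- scenario_config(n_individuals = 10, n_groups = 2,
                         mortality_fraction = 0.2,
                         disappearance_fraction = 0.1, seed = 1)
  roster <- generate_roster(cfg)
  expect_error(simulate_post_event_response(roster, 3, cfg),
               "apply_catastrophe")
  roster <- apply_catastrophe(roster, cfg)
  expect_error(simulate_post_event_response(roster, 1, cfg), "post-event")
  expect_error(simulate_window(roster, 99, cfg), "outside the schedule")
})

test_that("null scenario leaves survivor behaviour unchanged in expectation", {
  # with both response effects zero, survivor-restricted within/between
  # overlap ratios match between pre- and post-event windows (Monte Carlo)
  rat <- matrix(NA_real_, 200, 2)
  for (seed in 1:200) {
    cfg <- scenario_config(n_individuals = 12, n_groups = 2, n_sections = 2,
                           boxes_per_section = 4, boxes_per_group = 2,
                           window_length_days = 1, n_post_windows = 1,
                           mortality_fraction = 0.25,
                           disappearance_fraction = 0, seed = seed)
    scen <- simulate_scenario(cfg)
    surv_ids <- scen$roster$individual_id[scen$roster$fate == "survivor"]
    grp <- setNames(scen$roster$home_group, scen$roster$individual_id)
    for (k in 1:2) {
      wrow <- scen$schedule[scen$schedule$index == c(2, 3)[k], ]
      cd <- cooccupancy_durations(scen$events, wrow)
      d <- cd$dyads[cd$dyads$id_i %in% surv_ids &
                      cd$dyads$id_j %in% surv_ids, , drop = FALSE]
      if (nrow(d) == 0) next
      same <- grp[d$id_i] == grp[d$id_j]
      rat[seed, k] <- sum(d$seconds[same]) / max(sum(d$seconds), 1)
    }
  }
  ok <- complete.cases(rat)
  expect_gt(sum(ok), 150)
  expect_lt(abs(mean(rat[ok, 1]) - mean(rat[ok, 2])), 0.05)
})

test_that("low-sociality high-loss survivors gain partners under the weak-tie response", {
  gains <- vapply(1:12, function(seed) {
    cfg <- scenario_config(n_individuals = 60, n_groups = 4, n_sections = 2,
                           response_effect_low_social = 10,
                           response_effect_high_social = 0, seed = seed)
    scen <- simulate_scenario(cfg)
    surv <- make_stacks(scen$events, scen$schedule, scen$roster)$survivor
    a <- scen$attributes
    a <- a[!is.na(a$loss_proportion), ]
    foc <- a$individual_id[
      a$pre_event_sociality <= quantile(a$pre_event_sociality, 0.25) &
        a$loss_proportion >= quantile(a$loss_proportion, 0.75)]
    foc <- intersect(foc, stack_nodes(surv))
    if (length(foc) == 0) return(NA_real_)
    last_w <- as.character(max(surv$schedule$index))
    base_w <- as.character(surv$baseline_window)
    mean(igraph::degree(surv$networks[[last_w]])[foc]) -
      mean(igraph::degree(surv$networks[[base_w]])[foc])
  }, numeric(1))
  expect_gt(mean(gains, na.rm = TRUE), 0.5)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(n_individuals = 0), "positive count")
  expect_error(scenario_config(mortality_fraction = 1.2), "\\[0, 1\\)")
  expect_error(scenario_config(mortality_fraction = 0.6,
                               disappearance_fraction = 0.5), "< 1")
  expect_error(scenario_config(within_group_overlap_rate = 0), "positive")
  expect_error(scenario_config(boxes_per_group = 10, boxes_per_section = 10),
               "refuge")
  expect_error(scenario_config(loss_group_bias = c(1, 2)), "one non-negative")
})

test_that("event logs and rosters round-trip through CSV", {
  scen <- small_scenario(seed = 13)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_event_log(scen$events, f1)
  write_roster(scen$roster, f2)
  ev <- read_event_log(f1)
  ro <- read_roster(f2)
  expect_equal(nrow(ev), nrow(scen$events))
  expect_equal(ro$individual_id, scen$roster$individual_id)
  expect_equal(ev$entry, scen$events$entry, tolerance = 1e-6)
  expect_error(read_event_log(f2), "missing columns")
  unlink(c(f1, f2))
})
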