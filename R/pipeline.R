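#' Read a pipeline configuration file
#'
#' YAML or JSON. Recognized fields: `scenario` (arguments for
#' [scenario_config()], used when `simulate` is true), `simulate` (logical),
#' `events`, `roster` (paths, used when `simulate` is false), `out_dir`,
#' `seed`, `randomization` (`burn_in`, `swaps_per_emission`, `n_emissions`),
#' `communities` (`objective`, `restarts`), `models` (`responses`,
#' `variants`), `permutation_test` (logical).
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Validate an event log against a roster and schedule
#'
#' Report-only checks: required columns, `exit > entry`, ids present in the
#' roster (unknown ids are flagged as untagged and would be excluded from
#' network analysis), visits overlapping the excluded event gap, and
#' per-individual self-overlapping intervals.
#'
#' @param events visit records.
#' @param roster population roster.
#' @param schedule a [window_schedule()].
#' @return A data.frame of `check`, `n_flagged`, `detail`.
#' @export
validate_inputs <- function(events, roster, schedule) {
  flags <- list()
  add <- function(check, n, detail = "") {
    flags[[length(flags) + 1L]] <<- data.frame(
      check = check, n_flagged = n, detail = detail, stringsAsFactors = FALSE)
  }
  need <- c("individual_id", "box_id", "entry", "exit")
  miss <- setdiff(need, names(events))
  add("schema", length(miss), paste(miss, collapse = ", "))
  if (length(miss) == 0L) {
    bad <- which(!(events$exit > events$entry))
    add("exit_after_entry", length(bad),
        if (length(bad)) paste("rows", paste(head(bad, 5), collapse = ",")) else "")
    unknown <- setdiff(unique(events$individual_id), roster$individual_id)
    add("untagged_ids", length(unknown), paste(head(unknown, 5), collapse = ","))
    in_gap <- sum(!vapply(seq_len(nrow(events)), function(i) {
      any(pmax(events$entry[i], schedule$start) <
            pmin(events$exit[i], schedule$end))
    }, logical(1)))
    add("outside_windows", in_gap, "records wholly in the event gap or off-schedule")
    self_ov <- 0L
    sp <- split(events[, c("entry", "exit")], events$individual_id)
    for (d in sp) {
      o <- order(d$entry)
      if (any(d$entry[o][-1] < d$exit[o][-length(o)])) self_ov <- self_ov + 1L
    }
    add("self_overlap_individuals", self_ov, "")
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage: (optionally) simulate a scenario, build the
#' full and survivor network stacks, compute metrics and baseline deltas,
#' pre-event loss attributes, dynamic communities and movement events,
#' the individual- and community-level models, and (optionally) the
#' synchronized node-swap permutation test. Deterministic given the seed.
#'
#' @param config a list as returned by [read_pipeline_config()], or a
#'   [scenario_config()] (then all defaults apply).
#' @param out_dir optional output directory; when given, stage outputs are
#'   written as CSV/JSON.
#' @return A `pipeline_report` list: `summary` (per-window node/edge counts,
#'   edge density, modularity, group counts), `movements`, `model_fits`,
#'   `pvalues` (when the permutation test ran), `provenance`, and the
#'   intermediate objects (`stacks`, `communities`, `tables`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "scenario_config")) {
    config <- list(scenario = unclass(config), simulate = TRUE)
  }
  seed <- if (!is.null(config$seed)) config$seed else
    if (!is.null(config$scenario$seed)) config$scenario$seed else 1L
  simulate <- isTRUE(config$simulate) || is.null(config$events)

  if (simulate) {
    sc_args <- config$scenario
    if (is.null(sc_args)) sc_args <- list()
    if (is.null(sc_args$seed)) sc_args$seed <- seed
    scen_cfg <- do.call(scenario_config, sc_args)
    scen <- simulate_scenario(scen_cfg)
    events <- scen$events
    roster <- scen$roster
    schedule <- scen$schedule
  } else {
    if (is.null(config$events) || !file.exists(config$events)) {
      stop("pipeline config: no event log path and simulation disabled",
           call. = FALSE)
    }
    events <- read_event_log(config$events)
    roster <- read_roster(config$roster)
    sch <- config$schedule
    schedule <- window_schedule(sch$n_pre, sch$n_post, sch$window_length_days,
                                sch$gap_days, origin = sch$origin %||% 0)
  }
  validation <- validate_inputs(events, roster, schedule)
  events <- events[events$individual_id %in% roster$individual_id, , drop = FALSE]

  stacks <- make_stacks(events, schedule, roster)
  missing_ids <- roster$individual_id[roster$fate != "survivor"]
  killed_ids <- roster$individual_id[roster$fate == "dead"]
  pre_w <- max(schedule$index[schedule$phase == "pre"])
  full_pre <- stacks$full$networks[[as.character(pre_w)]]
  attributes <- loss_attributes(full_pre, missing_ids)

  comm_cfg <- config$communities %||% list()
  comm <- dynamic_communities(stacks$full,
                              objective = comm_cfg$objective %||% "map",
                              restarts = comm_cfg$restarts %||% 10,
                              seed = seed)
  mov <- movement_events(comm$map)

  summary_tab <- do.call(rbind, lapply(names(stacks$full$networks), function(nm) {
    g <- stacks$full$networks[[nm]]
    part <- comm$partitions[[nm]]
    data.frame(
      window = as.integer(nm),
      phase = schedule$phase[schedule$index == as.integer(nm)],
      nodes = igraph::vcount(g),
      edges = igraph::ecount(g),
      edge_density = edge_density_sri(g),
      survivor_edge_density =
        edge_density_sri(stacks$survivor$networks[[nm]]),
      modularity = network_modularity(g, part),
      groups_3plus = count_groups(part),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary_tab) <- NULL

  delta <- delta_from_baseline(stacks$survivor)
  table <- build_response_table(delta, attributes)

  model_cfg <- config$models %||% list()
  responses <- model_cfg$responses %||% c("d_degree", "d_strength")
  variants <- model_cfg$variants %||% "interaction"
  fits <- list()
  for (resp in responses) {
    for (v in variants) {
      fits[[paste(resp, v, sep = ".")]] <-
        fit_response_model(table, resp, v)
    }
  }
  comm_tab <- community_change_table(stacks$full, comm$map, missing_ids,
                                     killed_ids)
  for (resp in c("d_size", "d_density")) {
    fits[[paste0("community.", resp)]] <- tryCatch(
      suppressWarnings(fit_community_model(comm_tab, resp)),
      error = function(e) {
        warning("community model for ", resp, " could not be fitted: ",
                conditionMessage(e))
        NULL
      })
  }

  pvalues <- NULL
  if (isTRUE(config$permutation_test)) {
    rcfg <- config$randomization %||% list()
    chain <- generate_swap_chain(
      stack_nodes(stacks$survivor),
      burn_in = rcfg$burn_in %||% 1000,
      swaps_per_emission = rcfg$swaps_per_emission %||% 10,
      n_emissions = rcfg$n_emissions %||% 1000,
      seed = derive_seed(seed, 977)
    )
    pt <- permutation_effect_test(stacks$survivor, attributes, chain,
                                  response = responses[1],
                                  variant = variants[1])
    pvalues <- pt$pvalues
  }

  report <- list(
    summary = summary_tab,
    movements = mov,
    model_fits = fits,
    pvalues = pvalues,
    validation = validation,
    provenance = list(seed = seed, simulate = simulate,
                      n_individuals = nrow(roster),
                      n_missing = length(missing_ids),
                      package_version = as.character(utils::packageVersion("turnovernet"))),
    stacks = stacks, communities = comm,
    tables = list(delta = delta, response = table, community = comm_tab,
                  attributes = attributes)
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("movement events: %d (%d cross-section)\n",
              x$movements$n_events, x$movements$n_cross_section))
  cat(sprintf("models fitted: %s\n", paste(names(x$model_fits), collapse = ", ")))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$summary, file.path(out_dir, "window_summary.csv"),
            row.names = FALSE)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (nm in names(report$stacks$full$networks)) {
    g <- report$stacks$full$networks[[nm]]
    write.csv(edge_list(g),
              file.path(net_dir, sprintf("window_%s_edges.csv", nm)),
              row.names = FALSE)
    igraph::write_graph(g,
                        file.path(net_dir, sprintf("window_%s.graphml", nm)),
                        format = "graphml")
  }
  sched <- report$stacks$full$schedule
  jsonlite::write_json(
    list(windows = as.data.frame(sched),
         event_time = attr(sched, "event_time")),
    file.path(out_dir, "window_schedule.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  write.csv(report$movements$events, file.path(out_dir, "movement_events.csv"),
            row.names = FALSE)
  write.csv(report$communities$map$assignments,
            file.path(out_dir, "community_assignments.csv"), row.names = FALSE)
  write.csv(alluvial_table(report$communities$map),
            file.path(out_dir, "alluvial_flows.csv"), row.names = FALSE)
  write.csv(report$tables$community,
            file.path(out_dir, "community_change.csv"), row.names = FALSE)
  write.csv(report$tables$delta, file.path(out_dir, "delta_table.csv"),
            row.names = FALSE)
  write.csv(report$tables$attributes, file.path(out_dir, "attributes.csv"),
            row.names = FALSE)
  keep <- !vapply(report$model_fits, is.null, logical(1))
  coefs <- do.call(rbind, lapply(names(report$model_fits)[keep], function(nm) {
    f <- report$model_fits[[nm]]
    cbind(model = nm, rbind(cbind(part = "mean", f$beta),
                            cbind(part = "scale", f$gamma)))
  }))
  write.csv(coefs, file.path(out_dir, "model_coefficients.csv"),
            row.names = FALSE)
  if (!is.null(report$pvalues)) {
    write.csv(report$pvalues, file.path(out_dir, "permutation_pvalues.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
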