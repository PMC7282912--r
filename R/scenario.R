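#' Scenario configuration for the visit-stream simulator
#'
#' Bundles every parameter of the generative model: population and group
#' structure, nest-box geometry, the observation window schedule, the
#' catastrophic-removal step, and the post-event behavioural response
#' effects. The defaults describe a barn population observed through
#' RFID-equipped nest-boxes: four sections of ten boxes each, spatially
#' clustered social groups, 5-day observation windows with two windows before
#' and four after a single removal event, and roughly 40% of adults lost
#' (dead plus disappeared).
#'
#' @param n_individuals number of tagged adults.
#' @param n_groups number of social groups.
#' @param n_sections number of barn sections; each group has one home section.
#' @param boxes_per_section nest-boxes per section.
#' @param boxes_per_group size of a group's home box cluster.
#' @param window_length_days length of one observation window.
#' @param n_pre_windows,n_post_windows number of windows before/after the event.
#' @param gap_days excluded gap (the event itself) between the last pre- and
#'   first post-event window.
#' @param mortality_fraction,disappearance_fraction proportions of the tagged
#'   population assigned fate `dead` / `disappeared` by [apply_catastrophe()];
#'   must sum to less than 1.
#' @param within_group_overlap_rate,between_group_overlap_rate relative
#'   box-choice weights for boxes in an individual's home cluster versus all
#'   other boxes. Their ratio controls how much more within-group dyads
#'   co-occupy boxes than between-group dyads; `between_group_overlap_rate = 0`
#'   plants perfectly separated groups.
#' @param response_effect_low_social expected number of extra short
#'   cross-group visits per post-event window, per unit of (loss proportion
#'   x low-sociality weight). Models weakly social survivors that lost many
#'   associates forming many new weak ties.
#' @param response_effect_high_social partner-pruning intensity per unit of
#'   (loss proportion x high-sociality weight). Models highly social
#'   survivors that lost many associates concentrating on fewer boxes and
#'   partners. Both response effects default to 0: the null scenario in which
#'   post-event behaviour is statistically identical to pre-event behaviour.
#' @param mean_visit_minutes mean in-box bout duration (exponential).
#' @param mean_gap_hours mean out-of-box interval for an individual of
#'   sociality 1; the realized mean is `mean_gap_hours / sociality_trait`, so
#'   more social individuals are inside boxes a larger fraction of the time.
#' @param sociality_shape shape of the Gamma distribution (mean 1) from which
#'   `sociality_trait` is drawn; small values give a strongly right-skewed
#'   trait.
#' @param popularity_decay geometric decay of box popularity within a group's
#'   cluster: the first box is the main nest, later boxes are quieter. Must
#'   be in (0, 1].
#' @param group_size_dispersion Dirichlet concentration scaling for group
#'   sizes; values below 1 mix small and large groups.
#' @param loss_group_bias optional vector of per-group relative weights used
#'   when sampling which individuals die or disappear; default equal weights.
#'   A heavily skewed vector concentrates the loss in some groups (realized
#'   per-group losses can then range from mild to near-total).
#' @param seed integer seed; every stochastic step derives its stream from it,
#'   so an identical configuration yields byte-identical event logs.
#'
#' @return A validated `scenario_config` object (a named list).
#' @export
scenario_config <- function(n_individuals = 478,
                            n_groups = 17,
                            n_sections = 4,
                            boxes_per_section = 10,
                            boxes_per_group = 3,
                            window_length_days = 5,
                            n_pre_windows = 2,
                            n_post_windows = 4,
                            gap_days = 2,
                            mortality_fraction = 0.18,
                            disappearance_fraction = 0.22,
                            within_group_overlap_rate = 1,
                            between_group_overlap_rate = 0.015,
                            response_effect_low_social = 0,
                            response_effect_high_social = 0,
                            mean_visit_minutes = 30,
                            mean_gap_hours = 6,
                            sociality_shape = 2,
                            popularity_decay = 0.6,
                            group_size_dispersion = 1,
                            loss_group_bias = NULL,
                            seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_groups = as.integer(n_groups),
    n_sections = as.integer(n_sections),
    boxes_per_section = as.integer(boxes_per_section),
    boxes_per_group = as.integer(boxes_per_group),
    window_length_days = window_length_days,
    n_pre_windows = as.integer(n_pre_windows),
    n_post_windows = as.integer(n_post_windows),
    gap_days = gap_days,
    mortality_fraction = mortality_fraction,
    disappearance_fraction = disappearance_fraction,
    within_group_overlap_rate = within_group_overlap_rate,
    between_group_overlap_rate = between_group_overlap_rate,
    response_effect_low_social = response_effect_low_social,
    response_effect_high_social = response_effect_high_social,
    mean_visit_minutes = mean_visit_minutes,
    mean_gap_hours = mean_gap_hours,
    sociality_shape = sociality_shape,
    popularity_decay = popularity_decay,
    group_size_dispersion = group_size_dispersion,
    loss_group_bias = loss_group_bias,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  counts <- c("n_individuals", "n_groups", "n_sections", "boxes_per_section",
              "boxes_per_group", "n_pre_windows", "n_post_windows")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("scenario_config: `", nm, "` must be a positive count", call. = FALSE)
    }
  }
  for (nm in c("mortality_fraction", "disappearance_fraction")) {
    f <- cfg[[nm]]
    if (!is.finite(f) || f < 0 || f >= 1) {
      stop("scenario_config: `", nm, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  if (cfg$mortality_fraction + cfg$disappearance_fraction >= 1) {
    stop("scenario_config: mortality_fraction + disappearance_fraction must be < 1",
         call. = FALSE)
  }
  if (cfg$within_group_overlap_rate <= 0) {
    stop("scenario_config: within_group_overlap_rate must be positive", call. = FALSE)
  }
  if (cfg$between_group_overlap_rate < 0) {
    stop("scenario_config: between_group_overlap_rate must be non-negative",
         call. = FALSE)
  }
  if (cfg$window_length_days <= 0 || cfg$gap_days < 0) {
    stop("scenario_config: window/gap lengths invalid", call. = FALSE)
  }
  if (cfg$popularity_decay <= 0 || cfg$popularity_decay > 1) {
    stop("scenario_config: popularity_decay must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$boxes_per_group > cfg$boxes_per_section - 1L) {
    stop("scenario_config: boxes_per_group must leave at least one refuge box ",
         "per section (boxes_per_group <= boxes_per_section - 1)", call. = FALSE)
  }
  if (!is.null(cfg$loss_group_bias) &&
      (length(cfg$loss_group_bias) != cfg$n_groups || any(cfg$loss_group_bias < 0))) {
    stop("scenario_config: loss_group_bias must give one non-negative weight per group",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d individuals in %d groups across %d sections (%d boxes each)\n",
              x$n_individuals, x$n_groups, x$n_sections, x$boxes_per_section))
  cat(sprintf("  windows: %d pre + %d post x %g days, %g-day event gap\n",
              x$n_pre_windows, x$n_post_windows, x$window_length_days, x$gap_days))
  cat(sprintf("  losses: %.0f%% dead + %.0f%% disappeared\n",
              100 * x$mortality_fraction, 100 * x$disappearance_fraction))
  cat(sprintf("  response effects: low-social %.2f, high-social %.2f; seed %d\n",
              x$response_effect_low_social, x$response_effect_high_social, x$seed))
  invisible(x)
}

#' Observation window schedule
#'
#' Lays out non-overlapping observation windows on a seconds axis, with an
#' excluded gap (the event) strictly between the last pre-event and the first
#' post-event window. Window indices count 1, 2, ... for pre-event windows and
#' continue across the gap, so with two pre-event windows the post-event
#' windows are 3, 4, ... (the convention used throughout: window 2 is the
#' last pre-event window and the change baseline).
#'
#' @param n_pre,n_post numbers of pre-/post-event windows.
#' @param window_length_days window length in days.
#' @param gap_days length of the excluded event gap in days.
#' @param origin epoch second at which the first window starts.
#' @return A data.frame with columns `index`, `start`, `end`, `phase`
#'   (`"pre"`/`"post"`), carrying the event time (midpoint of the gap) as
#'   attribute `event_time`.
#' @export
window_schedule <- function(n_pre = 2, n_post = 4, window_length_days = 5,
                            gap_days = 2, origin = 0) {
  stopifnot(n_pre >= 1, n_post >= 1, window_length_days > 0, gap_days >= 0)
  wlen <- window_length_days * 86400
  gap <- gap_days * 86400
  idx <- seq_len(n_pre + n_post)
  start <- origin + (idx - 1) * wlen + ifelse(idx > n_pre, gap, 0)
  sched <- data.frame(
    index = idx,
    start = start,
    end = start + wlen,
    phase = ifelse(idx <= n_pre, "pre", "post"),
    stringsAsFactors = FALSE
  )
  attr(sched, "event_time") <- origin + n_pre * wlen + gap / 2
  class(sched) <- c("window_schedule", "data.frame")
  sched
}

window_row <- function(schedule, window_index) {
  i <- match(window_index, schedule$index)
  if (is.na(i)) {
    stop("window index ", window_index, " is outside the schedule", call. = FALSE)
  }
  schedule[i, , drop = FALSE]
}

# Derived, reproducible sub-seed for one stochastic stage. Keeps everything
# inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  salt <- c(...)
  x <- (as.double(seed) %% 599999L) * 3001 + 7
  for (s in salt) x <- (x * 131 + (as.double(s) %% 65521L) + 17) %% 2147483629
  as.integer(x %% 2147483629) + 1L
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero (so fate counts from fractions are exact and
# documented, unlike banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
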