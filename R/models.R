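#' Assemble the model-ready response table
#'
#' Joins per-window centrality changes with the pre-event node attributes,
#' standardizes sociality and loss (mean 0, sd 1), and encodes the window as
#' a categorical `timestep` whose reference level is the first post-event
#' window. Rows whose loss proportion is undefined (zero pre-event strength)
#' are dropped and counted.
#'
#' @param delta a [delta_from_baseline()] table.
#' @param attributes a [loss_attributes()] table.
#' @param first_post_window index of the first post-event window (reference
#'   level for `timestep`); defaults to the smallest window index above the
#'   baseline windows present.
#' @return data.frame with columns `individual_id`, `timestep` (factor),
#'   `d_degree`, `d_strength`, `d_betweenness`, `sociality_std`, `loss_std`
#'   (and `sex` when available), plus attributes `n_dropped` (rows lost to
#'   undefined loss) and `scaling` (centres/sds used).
#' @export
build_response_table <- function(delta, attributes, first_post_window = NULL) {
  tab <- merge(delta, attributes, by = "individual_id")
  if (nrow(tab) == 0L) stop("empty response table", call. = FALSE)
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$loss_proportion), , drop = FALSE]
  n_dropped <- n0 - nrow(tab)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped: undefined loss proportion ",
            "(zero pre-event strength)")
  }
  if (nrow(tab) == 0L) stop("empty response table", call. = FALSE)
  soc <- standardize(tab$pre_event_sociality)
  los <- standardize(tab$loss_proportion)
  tab$sociality_std <- soc$x
  tab$loss_std <- los$x
  wins <- sort(unique(tab$window))
  if (is.null(first_post_window)) {
    first_post_window <- if (any(wins > 2)) min(wins[wins > 2]) else wins[1]
  }
  lev <- c(first_post_window, setdiff(wins, first_post_window))
  tab$timestep <- factor(tab$window, levels = lev)
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  attr(tab, "scaling") <- list(sociality = soc[c("center", "scale")],
                               loss = los[c("center", "scale")])
  tab
}

standardize <- function(x) {
  ctr <- mean(x)
  scl <- sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  list(x = (x - ctr) / scl, center = ctr, scale = scl)
}

response_model_formulas <- function(variant = c("interaction", "additive", "sex")) {
  variant <- match.arg(variant)
  switch(variant,
    interaction = list(mean = ~ timestep * sociality_std * loss_std,
                       scale = ~ sociality_std * loss_std),
    additive = list(mean = ~ timestep + sociality_std * loss_std,
                    scale = ~ sociality_std * loss_std),
    sex = list(mean = ~ timestep * sex * loss_std,
               scale = ~ sex * loss_std)
  )
}

#' Fit an individual-level response model
#'
#' The main analysis model: a location-scale regression of one centrality
#' change on `timestep x sociality x loss` (full three-way interaction by
#' default), with the residual log-sd following `sociality x loss` and a
#' random intercept per individual. Variants: `"additive"` (timestep enters
#' additively, testing an overall per-window shift rather than
#' type-by-timestep slopes) and `"sex"` (sex replaces sociality).
#'
#' @param table a [build_response_table()] result.
#' @param response `"d_degree"`, `"d_strength"` or `"d_betweenness"`.
#' @param variant model variant (see above).
#' @param se,start passed to [fit_location_scale()].
#' @return A `locscale_fit`.
#' @export
fit_response_model <- function(table,
                               response = c("d_degree", "d_strength",
                                            "d_betweenness"),
                               variant = c("interaction", "additive", "sex"),
                               se = TRUE, start = NULL) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  ff <- response_model_formulas(variant)
  if (variant == "sex" && !"sex" %in% names(table)) {
    stop("sex variant requires a `sex` column in the table", call. = FALSE)
  }
  fit <- fit_location_scale(table, response, mean_formula = ff$mean,
                            scale_formula = ff$scale, group = "individual_id",
                            se = se, start = start)
  if (!fit$converged) {
    warning("model for ", response, " (", variant, ") did not converge")
  }
  fit$variant <- variant
  fit
}

#' Permutation test of model effects against synchronized node swaps
#'
#' Refits the response model on each randomized version of the survivor
#' stack and compares observed coefficients with the randomized coefficient
#' distribution via two-sided add-one empirical p-values. A synchronized
#' node swap relabels identities while leaving every window's topology
#' untouched, so identity `i`'s metrics in each randomized stack equal the
#' observed metrics of the identity whose position it took; the randomized
#' response tables are therefore built exactly by reindexing the observed
#' per-window responses through each emission's permutation, while
#' attributes (sociality, loss, sex) stay with the identity. This is
#' algebraically identical to rebuilding every randomized network and is
#' what makes 1000 refits affordable.
#'
#' @param stack observed survivor `network_stack`.
#' @param attributes [loss_attributes()] for the stack's individuals.
#' @param chain a [generate_swap_chain()] over the stack's node set.
#' @param response,variant as in [fit_response_model()].
#' @param n_emissions number of randomized stacks to use (default: all in
#'   the chain).
#' @return A list with `observed` (the observed `locscale_fit`), `pvalues`
#'   (data.frame term, estimate, empirical_p for every mean- and scale-model
#'   coefficient), `randomized_beta` / `randomized_gamma` (matrices of
#'   randomized estimates), and `effective_R` (randomized fits that
#'   converged).
#' @export
permutation_effect_test <- function(stack, attributes, chain,
                                    response = c("d_degree", "d_strength",
                                                 "d_betweenness"),
                                    variant = c("interaction", "additive", "sex"),
                                    n_emissions = chain$n_emissions) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  if (n_emissions < 1) stop("need at least one randomized emission", call. = FALSE)
  delta <- delta_from_baseline(stack)
  table <- build_response_table(delta, attributes)
  observed <- fit_response_model(table, response, variant, se = TRUE)
  start <- list(gamma = observed$theta[seq_len(nrow(observed$gamma))],
                log_tau = observed$theta[nrow(observed$gamma) + 1L])

  # per-(identity, window) lookup of the response column, over the full
  # survivor stack (swap targets may include rows absent from the model
  # table). The design matrices depend only on identity attributes, which
  # the swaps never move, so they are prepared once and every refit swaps
  # only the response vector.
  lookup <- setNames(delta[[response]],
                     paste(delta$individual_id, delta$window))
  ff <- response_model_formulas(variant)
  X <- suppressWarnings(drop_aliased(stats::model.matrix(ff$mean, table), "mean"))
  Z <- suppressWarnings(drop_aliased(stats::model.matrix(ff$scale, table), "scale"))
  gi <- as.integer(factor(table$individual_id))

  bet <- matrix(NA_real_, nrow = n_emissions, ncol = nrow(observed$beta),
                dimnames = list(NULL, observed$beta$term))
  gam <- matrix(NA_real_, nrow = n_emissions, ncol = nrow(observed$gamma),
                dimnames = list(NULL, observed$gamma$term))
  ok <- logical(n_emissions)
  base_key <- paste0(" ", table$window)
  for (r in seq_len(n_emissions)) {
    perm <- emission_permutation(chain, r)
    y_r <- unname(lookup[paste0(perm[table$individual_id], base_key)])
    fit <- tryCatch(locscale_ml(y_r, X, Z, gi, se = FALSE, start = start),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      bet[r, ] <- fit$beta$estimate
      gam[r, ] <- fit$gamma$estimate
      ok[r] <- TRUE
    }
  }
  if (!any(ok)) stop("no randomized fit converged", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " randomized fit(s) failed/non-converged and were dropped")
  }
  pv_beta <- vapply(seq_len(ncol(bet)), function(j) {
    empirical_pvalue(observed$beta$estimate[j], bet[ok, j])
  }, numeric(1))
  pv_gamma <- vapply(seq_len(ncol(gam)), function(j) {
    empirical_pvalue(observed$gamma$estimate[j], gam[ok, j])
  }, numeric(1))
  pvalues <- rbind(
    data.frame(model = "mean", term = observed$beta$term,
               estimate = observed$beta$estimate, empirical_p = pv_beta,
               stringsAsFactors = FALSE),
    data.frame(model = "scale", term = observed$gamma$term,
               estimate = observed$gamma$estimate, empirical_p = pv_gamma,
               stringsAsFactors = FALSE)
  )
  rownames(pvalues) <- NULL
  list(observed = observed, pvalues = pvalues,
       randomized_beta = bet[ok, , drop = FALSE],
       randomized_gamma = gam[ok, , drop = FALSE],
       effective_R = sum(ok))
}

#' Community-level change table
#'
#' One row per persistent community per non-baseline window of a stack:
#' change in community size and within-community edge density relative to
#' the baseline window, the community's pre-event (baseline) size and the
#' proportion of its baseline members missing (and, separately, killed).
#'
#' @param stack a `network_stack`.
#' @param map a [link_windows()] map over the same windows.
#' @param missing_ids ids that died or disappeared.
#' @param killed_ids optional subset of `missing_ids` found dead (for the
#'   killed-only robustness variant).
#' @return data.frame `persistent_id`, `window`, `timestep`, `d_size`,
#'   `d_density`, `pre_size_std`, `missing_std`, `killed_std` plus raw
#'   columns.
#' @export
community_change_table <- function(stack, map, missing_ids,
                                   killed_ids = missing_ids) {
  base_w <- stack$baseline_window
  a <- map$assignments
  stats_by_window <- lapply(names(stack$networks), function(nm) {
    w <- as.integer(nm)
    part <- a[a$window == w, , drop = FALSE]
    mem <- setNames(part$persistent_id, part$individual_id)
    if (length(mem) == 0L) return(NULL)
    gs <- group_stats(stack$networks[[nm]], mem, missing_ids = missing_ids)
    gs$prop_killed <- vapply(gs$community, function(cc) {
      members <- names(mem)[mem == cc]
      mean(members %in% killed_ids)
    }, numeric(1))
    gs$window <- w
    gs
  })
  all_gs <- do.call(rbind, stats_by_window)
  base <- all_gs[all_gs$window == base_w, , drop = FALSE]
  oth <- all_gs[all_gs$window != base_w, , drop = FALSE]
  m <- match(oth$community, base$community)
  oth <- oth[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  out <- data.frame(
    persistent_id = oth$community,
    window = oth$window,
    d_size = oth$size - base$size[m],
    d_density = oth$within_density - base$within_density[m],
    pre_size = base$size[m],
    prop_missing = base$prop_missing[m],
    prop_killed = base$prop_killed[m],
    stringsAsFactors = FALSE
  )
  out$pre_size_std <- standardize(out$pre_size)$x
  out$missing_std <- standardize(out$prop_missing)$x
  out$killed_std <- standardize(out$prop_killed)$x
  wins <- sort(unique(out$window))
  first_post <- if (any(wins > base_w)) min(wins[wins > base_w]) else wins[1]
  out$timestep <- factor(out$window, levels = c(first_post,
                                                setdiff(wins, first_post)))
  rownames(out) <- NULL
  out
}

#' Fit a community-level response model
#'
#' Location-scale regression of the change in community size or
#' within-community density on `timestep x pre-event size x proportion
#' missing`, with a random intercept per persistent community. With a single
#' community the random effect is degenerate and the model falls back to no
#' grouping, with a warning. Setting `loss = "killed"` uses the proportion
#' found dead instead of the proportion missing.
#'
#' @param table a [community_change_table()].
#' @param response `"d_size"` or `"d_density"`.
#' @param loss `"missing"` or `"killed"`.
#' @param se passed on.
#' @return A `locscale_fit`.
#' @export
fit_community_model <- function(table, response = c("d_size", "d_density"),
                                loss = c("missing", "killed"), se = TRUE) {
  response <- match.arg(response)
  loss <- match.arg(loss)
  loss_col <- if (loss == "missing") "missing_std" else "killed_std"
  table$loss_term <- table[[loss_col]]
  mean_f <- ~ timestep * pre_size_std * loss_term
  scale_f <- ~ pre_size_std * loss_term
  # full three-way interaction needs 4 x timestep levels worth of rows;
  # small community sets get the additive mean model instead
  p_full <- 4 * length(unique(table$timestep))
  if (nrow(table) < p_full + 4) {
    warning("too few community-window rows for the full interaction; ",
            "fitting the additive mean model")
    mean_f <- ~ timestep + pre_size_std * loss_term
  }
  group <- "persistent_id"
  if (length(unique(table$persistent_id)) < 2L) {
    warning("single community: fitting without a random effect")
    group <- NULL
  }
  fit <- fit_location_scale(table, response, mean_formula = mean_f,
                            scale_formula = scale_f, group = group, se = se)
  fit$loss_variant <- loss
  fit
}
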