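# data generated from the assumed location-scale random-intercept model
gen_locscale <- function(n_groups, n_per, beta, gamma, tau, seed) {
  set.seed(seed)
  n <- n_groups * n_per
  g <- rep(sprintf("g%03d", seq_len(n_groups)), each = n_per)
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(1, x1, x2, x1 * x2)
  Z <- cbind(1, x1)
  u <- rnorm(n_groups, 0, tau)
  sigma <- exp(as.vector(Z %*% gamma))
  y <- as.vector(X %*% beta) + u[as.integer(factor(g))] + rnorm(n, 0, sigma)
  data.frame(y = y, x1 = x1, x2 = x2, g = g, stringsAsFactors = FALSE)
}

test_that("intercept-only ungrouped fit returns the sample mean", {
  set.seed(1)
  d <- data.frame(y = rnorm(50, 3, 2))
  f <- fit_location_scale(d, "y", ~ 1, ~ 1)
  expect_equal(f$beta$estimate, mean(d$y), tolerance = 1e-6)
  expect_equal(exp(f$gamma$estimate), sd(d$y) * sqrt(49 / 50), tolerance = 1e-4)
  expect_equal(f$tau, 0)
})

test_that("constant-scale fits reduce to an ordinary random-intercept model", {
  skip_if_not_installed("lme4")
  d <- gen_locscale(40, 8, beta = c(1, 2, -1, 0.5), gamma = c(0.3, 0),
                    tau = 1.2, seed = 5)
  mine <- fit_location_scale(d, "y", ~ x1 * x2, ~ 1, group = "g")
  ref <- lme4::lmer(y ~ x1 * x2 + (1 | g), data = d, REML = FALSE)
  expect_equal(mine$beta$estimate, unname(lme4::fixef(ref)), tolerance = 1e-4)
  expect_equal(mine$tau, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-4)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("the full location-scale likelihood matches an independent implementation", {
  skip_if_not_installed("glmmTMB")
  d <- gen_locscale(50, 8, beta = c(1, 2, -1, 0.5), gamma = c(0.2, 0.4),
                    tau = 1.5, seed = 7)
  mine <- fit_location_scale(d, "y", ~ x1 * x2, ~ x1, group = "g")
  ref <- suppressWarnings(
    glmmTMB::glmmTMB(y ~ x1 * x2 + (1 | g), dispformula = ~ x1, data = d,
                     REML = FALSE))
  expect_equal(mine$beta$estimate, unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  # glmmTMB's gaussian dispformula is also on the log residual-sd scale
  expect_equal(mine$gamma$estimate, unname(glmmTMB::fixef(ref)$disp),
               tolerance = 1e-3)
  expect_equal(mine$tau,
               sqrt(unname(glmmTMB::VarCorr(ref)$cond$g[1])), tolerance = 1e-3)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("estimates recover the generating parameters within 3 SE", {
  beta <- c(0.5, 1.5, -0.8, 0.6)
  gamma <- c(0.1, 0.3)
  hits <- vapply(1:40, function(seed) {
    d <- gen_locscale(80, 8, beta, gamma, tau = 1, seed = seed)
    f <- fit_location_scale(d, "y", ~ x1 * x2, ~ x1, group = "g")
    all(abs(f$beta$estimate - beta) <= 3 * f$beta$se)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("interval coverage of a null interaction is near nominal", {
  beta <- c(0.5, 1, -0.5, 0)  # interaction truly zero
  cover <- vapply(1:60, function(seed) {
    d <- gen_locscale(60, 6, beta, c(0.1, 0.25), tau = 0.8, seed = 1000 + seed)
    f <- fit_location_scale(d, "y", ~ x1 * x2, ~ x1, group = "g")
    r <- f$beta[f$beta$term == "x1:x2", ]
    r$lower <= 0 && r$upper >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.89)
  expect_lte(mean(cover), 0.995)
})

test_that("response tables standardize predictors and drop undefined loss", {
  scen <- small_scenario(seed = 81, mortality_fraction = 0.2,
                         disappearance_fraction = 0.15)
  surv <- make_stacks(scen$events, scen$schedule, scen$roster)$survivor
  delta <- delta_from_baseline(surv)
  attrs <- scen$attributes
  # force one undefined-loss survivor into the join
  attrs$loss_proportion[1] <- NA
  expect_message(tab <- build_response_table(delta, attrs), "dropped")
  expect_equal(mean(tab$sociality_std), 0, tolerance = 1e-9)
  expect_equal(sd(tab$sociality_std), 1, tolerance = 1e-9)
  expect_equal(mean(tab$loss_std), 0, tolerance = 1e-9)
  expect_false(attrs$individual_id[1] %in% tab$individual_id)
  expect_gte(attr(tab, "n_dropped"), 1)
  # one row per retained individual per non-baseline window
  n_windows <- length(setdiff(scen$schedule$index, surv$baseline_window))
  expect_lte(nrow(tab), length(stack_nodes(surv)) * n_windows)
  # reference level of timestep is the first post-event window
  expect_equal(levels(tab$timestep)[1], "3")
  # standardizing an already standardized column is a no-op
  tab2 <- tab
  s <- turnovernet:::standardize(tab2$sociality_std)
  expect_equal(s$x, tab2$sociality_std, tolerance = 1e-12)
})

test_that("response-model variants expose the expected terms", {
  scen <- small_scenario(seed = 82, mortality_fraction = 0.2,
                         disappearance_fraction = 0.1)
  surv <- make_stacks(scen$events, scen$schedule, scen$roster)$survivor
  tab <- suppressMessages(build_response_table(delta_from_baseline(surv),
                                               scen$attributes))
  f1 <- fit_response_model(tab, "d_degree", "interaction")
  expect_true("timestep4:sociality_std:loss_std" %in% f1$beta$term)
  expect_true("sociality_std:loss_std" %in% f1$gamma$term)
  f2 <- fit_response_model(tab, "d_strength", "additive")
  expect_false(any(grepl("timestep.*:", f2$beta$term)))
  expect_true("sociality_std:loss_std" %in% f2$beta$term)
  f3 <- fit_response_model(tab, "d_degree", "sex")
  expect_true(any(grepl("sexM", f3$beta$term)))
  expect_true(f1$converged)
})

test_that("permutation effect tests are internally consistent and reproducible", {
  scen <- small_scenario(seed = 83, mortality_fraction = 0.2,
                         disappearance_fraction = 0.1)
  surv <- make_stacks(scen$events, scen$schedule, scen$roster)$survivor
  chain <- generate_swap_chain(stack_nodes(surv), burn_in = 50,
                               swaps_per_emission = 10, n_emissions = 19,
                               seed = 4)
  pt <- suppressMessages(
    permutation_effect_test(surv, scen$attributes, chain, "d_degree",
                            "additive"))
  expect_equal(pt$effective_R, 19)
  expect_true(all(pt$pvalues$empirical_p > 0 & pt$pvalues$empirical_p <= 1))
  expect_true(all(pt$pvalues$empirical_p >= 1 / 20))
  # reported p equals recounting from the stored randomized estimates
  for (j in seq_len(ncol(pt$randomized_beta))) {
    term <- colnames(pt$randomized_beta)[j]
    row <- pt$pvalues[pt$pvalues$model == "mean" & pt$pvalues$term == term, ]
    expect_equal(row$empirical_p,
                 empirical_pvalue(row$estimate, pt$randomized_beta[, j]))
  }
  # deterministic given the same chain
  pt2 <- suppressMessages(
    permutation_effect_test(surv, scen$attributes, chain, "d_degree",
                            "additive"))
  expect_identical(pt$pvalues, pt2$pvalues)
})

test_that("randomized-table shortcut matches refitting from permuted stacks", {
  scen <- small_scenario(seed = 84, mortality_fraction = 0.2,
                         disappearance_fraction = 0.1)
  surv <- make_stacks(scen$events, scen$schedule, scen$roster)$survivor
  chain <- generate_swap_chain(stack_nodes(surv), burn_in = 30,
                               swaps_per_emission = 7, n_emissions = 3,
                               seed = 12)
  pt <- suppressMessages(
    permutation_effect_test(surv, scen$attributes, chain, "d_degree",
                            "additive"))
  for (r in 1:3) {
    rs <- apply_swaps_synchronized(surv, chain, r)
    tab_r <- suppressMessages(
      build_response_table(delta_from_baseline(rs), scen$attributes))
    fit_r <- fit_response_model(tab_r, "d_degree", "additive", se = FALSE)
    # agreement up to optimizer precision (different starting values)
    expect_equal(unname(pt$randomized_beta[r, ]), fit_r$beta$estimate,
                 tolerance = 1e-4)
  }
})


test_that("community models recover a scripted loss slope and match killed variant", {
  # scripted: high-loss communities shrink by exactly their loss count
  sign_hits <- vapply(1:100, function(seed) {
    f <- suppressWarnings(fit_community_model(scripted_community_table(seed),
                                              "d_size"))
    coef(f)[["loss_term"]] < 0
  }, logical(1))
  expect_gte(mean(sign_hits), 0.95)
  tab <- scripted_community_table(100)

  # identical killed and missing sets give identical fits (same predictor)
  f_m <- suppressWarnings(fit_community_model(tab, "d_size", loss = "missing"))
  f_k <- suppressWarnings(fit_community_model(tab, "d_size", loss = "killed"))
  expect_equal(f_m$beta$estimate, f_k$beta$estimate, tolerance = 1e-8)

  # community change table carries the expected structure on simulated data
  scen <- small_scenario(seed = 85, mortality_fraction = 0.25,
                         disappearance_fraction = 0)
  stacks <- make_stacks(scen$events, scen$schedule, scen$roster)
  dc <- dynamic_communities(stacks$full, seed = 2)
  missing_ids <- scen$roster$individual_id[scen$roster$fate != "survivor"]
  ct <- community_change_table(stacks$full, dc$map, missing_ids,
                               killed_ids = missing_ids)
  expect_true(all(c("persistent_id", "d_size", "d_density", "pre_size",
                    "prop_missing", "missing_std", "timestep") %in% names(ct)))
  expect_true(all(ct$window != stacks$full$baseline_window))
  expect_equal(ct$prop_killed, ct$prop_missing)

  # all-unchanged scripted scenario: slopes at zero
  tab0 <- data.frame(persistent_id = rep(sprintf("D%02d", 1:8), 3),
                     window = rep(3:5, each = 8),
                     d_size = 0, d_density = 0,
                     pre_size = rep(5:12, 3),
                     prop_missing = rep(seq(0.1, 0.8, length.out = 8), 3),
                     prop_killed = rep(seq(0.1, 0.8, length.out = 8), 3),
                     stringsAsFactors = FALSE)
  tab0$pre_size_std <- (tab0$pre_size - mean(tab0$pre_size)) / sd(tab0$pre_size)
  tab0$missing_std <- (tab0$prop_missing - mean(tab0$prop_missing)) /
    sd(tab0$prop_missing)
  tab0$killed_std <- tab0$missing_std
  tab0$timestep <- factor(tab0$window)
  f0 <- suppressWarnings(fit_community_model(tab0, "d_size"))
  expect_lt(max(abs(f0$beta$estimate)), 1e-4)
})

test_that("degenerate groupings fall back gracefully", {
  set.seed(9)
  tab <- data.frame(persistent_id = "D01", window = rep(3:5, each = 10),
                    d_size = rnorm(30), d_density = rnorm(30, 0, 0.1),
                    pre_size = 10, prop_missing = runif(30),
                    prop_killed = runif(30), stringsAsFactors = FALSE)
  tab$pre_size_std <- 0
  tab$missing_std <- (tab$prop_missing - mean(tab$prop_missing)) /
    sd(tab$prop_missing)
  tab$killed_std <- tab$missing_std
  tab$timestep <- factor(tab$window)
  ws <- character()
  f <- withCallingHandlers(
    fit_community_model(tab, "d_size"),
    warning = function(w) {
      ws <<- c(ws, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("single community", ws)))
  expect_s3_class(f, "locscale_fit")
})
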