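#' Generate a chain of node-identity swaps
#'
#' Builds the randomization schedule used by the synchronized node-swap null:
#' a single Markov chain of transpositions over the id pool. The first
#' `burn_in` swaps decorrelate the chain from the observed labelling; after
#' that, one randomized labelling is emitted every `swaps_per_emission`
#' swaps. The chain is cumulative: emission `r` is the permutation after
#' `burn_in + r * swaps_per_emission` transpositions. The defaults (1000
#' burn-in, 10 swaps per emission, 1000 emissions) give 11 000 swaps in
#' total. Pairs are drawn uniformly, without replacement within a pair, and
#' may repeat across the chain.
#'
#' @param pool character vector of ids (the survivor-stack node set).
#' @param burn_in,swaps_per_emission,n_emissions chain schedule.
#' @param seed integer seed; the chain is reproducible.
#' @return A `swap_chain`: the pool, the schedule, the full swap list (two
#'   columns of pool indices) and the cumulative permutation at every
#'   emission (matrix `n_emissions x length(pool)`; row `r` entry `i` is the
#'   index of the id whose network position id `i` occupies at emission `r`).
#' @export
generate_swap_chain <- function(pool, burn_in = 1000, swaps_per_emission = 10,
                                n_emissions = 1000, seed = 1L) {
  n <- length(pool)
  if (n < 2L) stop("swap pool needs at least 2 ids", call. = FALSE)
  if (anyDuplicated(pool)) stop("swap pool ids must be unique", call. = FALSE)
  burn_in <- as.integer(burn_in)
  swaps_per_emission <- as.integer(swaps_per_emission)
  n_emissions <- as.integer(n_emissions)
  stopifnot(burn_in >= 0, swaps_per_emission >= 1, n_emissions >= 1)
  total <- burn_in + swaps_per_emission * n_emissions
  swaps <- with_seed(seed, {
    m <- matrix(0L, nrow = total, ncol = 2)
    for (k in seq_len(total)) m[k, ] <- sample.int(n, 2L, replace = FALSE)
    m
  })
  perm <- seq_len(n)
  states <- matrix(0L, nrow = n_emissions, ncol = n)
  r <- 0L
  next_emit <- burn_in + swaps_per_emission
  for (k in seq_len(total)) {
    a <- swaps[k, 1]; b <- swaps[k, 2]
    tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
    if (k == next_emit) {
      r <- r + 1L
      states[r, ] <- perm
      next_emit <- next_emit + swaps_per_emission
    }
  }
  structure(list(pool = pool, burn_in = burn_in,
                 swaps_per_emission = swaps_per_emission,
                 n_emissions = n_emissions, seed = as.integer(seed),
                 swaps = swaps, states = states),
            class = "swap_chain")
}

#' @export
print.swap_chain <- function(x, ...) {
  cat(sprintf(paste0("<swap_chain: %d ids, %d burn-in + %d x %d swaps ",
                     "= %d total, seed %d>\n"),
              length(x$pool), x$burn_in, x$swaps_per_emission, x$n_emissions,
              nrow(x$swaps), x$seed))
  invisible(x)
}

#' Cumulative permutation at one emission
#'
#' @param chain a [generate_swap_chain()] result.
#' @param emission emission index in `1:n_emissions`.
#' @return Named character vector: for each identity, the id of the network
#'   position it occupies at this emission (identity `i`'s edges are those
#'   formerly incident to `emission_permutation(chain, r)[i]`).
#' @export
emission_permutation <- function(chain, emission) {
  if (emission < 1 || emission > chain$n_emissions) {
    stop("emission out of range", call. = FALSE)
  }
  setNames(chain$pool[chain$states[emission, ]], chain$pool)
}

#' Apply a synchronized node swap to every window of a stack
#'
#' Produces one randomized stack: in every window, identity `i` takes over
#' the edges formerly incident to `pi(i)` under the chain's cumulative
#' permutation at the given emission. The same permutation is applied to
#' every window, so a pair swapped in one timestep is swapped in all.
#' Graph topology and weights are untouched — only the identity-position
#' mapping changes — and identity attributes (`sex`, `fate`) travel with the
#' identity, not the position.
#'
#' @param stack a survivor `network_stack` whose common node set equals the
#'   chain's pool.
#' @param chain a [generate_swap_chain()] over the stack's node set.
#' @param emission emission index.
#' @return A `network_stack` with fields `emission` and `chain_seed` recording
#'   provenance.
#' @export
apply_swaps_synchronized <- function(stack, chain, emission) {
  pool <- chain$pool
  nodes <- stack_nodes(stack)
  if (!setequal(pool, nodes) || length(pool) != length(nodes)) {
    stop("chain pool and stack node set differ", call. = FALSE)
  }
  perm <- emission_permutation(chain, emission)
  id_attrs <- NULL
  g1 <- stack$networks[[1]]
  if (!is.null(igraph::vertex_attr(g1, "sex"))) {
    id_attrs <- data.frame(individual_id = igraph::V(g1)$name,
                           sex = igraph::V(g1)$sex,
                           fate = igraph::V(g1)$fate,
                           stringsAsFactors = FALSE)
  }
  inv <- setNames(names(perm), perm)  # position id -> identity now holding it
  nets <- lapply(stack$networks, function(g) {
    vn <- igraph::V(g)$name
    g2 <- igraph::set_vertex_attr(g, "name", value = unname(inv[vn]))
    if (!is.null(id_attrs)) {
      m <- match(igraph::V(g2)$name, id_attrs$individual_id)
      g2 <- igraph::set_vertex_attr(g2, "sex", value = id_attrs$sex[m])
      g2 <- igraph::set_vertex_attr(g2, "fate", value = id_attrs$fate[m])
    }
    g2
  })
  structure(list(networks = nets, schedule = stack$schedule,
                 restriction = stack$restriction,
                 baseline_window = stack$baseline_window,
                 emission = emission, chain_seed = chain$seed),
            class = "network_stack")
}

#' Long-format permutation table of a swap chain
#'
#' Compact representation of the randomized stacks: one row per emission and
#' identity giving the network position the identity occupies, instead of
#' materializing hundreds of relabelled graph copies.
#'
#' @param chain a [generate_swap_chain()] result.
#' @param emissions emissions to include (default all).
#' @return data.frame `emission`, `identity`, `position`.
#' @export
permutation_table <- function(chain, emissions = seq_len(chain$n_emissions)) {
  do.call(rbind, lapply(emissions, function(r) {
    perm <- emission_permutation(chain, r)
    data.frame(emission = r, identity = names(perm), position = unname(perm),
               stringsAsFactors = FALSE)
  }))
}

#' Empirical p-value against a randomized distribution
#'
#' Add-one empirical p-value with the observed statistic included in the
#' reference set: two-sided (default)
#' `p = (1 + #\{r: |beta_r| >= |beta_obs|\}) / (1 + R)`. Never 0, always in
#' `(0, 1]`, valid at finite R.
#'
#' @param observed observed statistic.
#' @param randomized vector of statistics from randomized fits.
#' @param sided `"two.sided"`, `"greater"` or `"less"`.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(observed, randomized,
                             sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  randomized <- randomized[is.finite(randomized)]
  if (length(randomized) == 0L) {
    stop("no randomized values to compare against", call. = FALSE)
  }
  hits <- switch(sided,
    two.sided = sum(abs(randomized) >= abs(observed)),
    greater = sum(randomized >= observed),
    less = sum(randomized <= observed)
  )
  (1 + hits) / (1 + length(randomized))
}
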