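#' Configuration for the improved binary glowworm swarm optimizer
#'
#' Defaults follow the standard parameterization of the algorithm:
#' luciferin decay `rho = 0.4`, luciferin gain `gamma = 0.6`, decision-domain
#' update rate `radius_gain = 0.08`, neighbour threshold `n_t = 5`,
#' `t_max = 300` iterations and move-branch thresholds `p1 = 0.15`,
#' `p2 = 0.85`. The swarm searches the binary subset space under Hamming
#' distance; `sensing_radius` defaults to the mask length M so the initial
#' neighbourhood is global, and the initial decision radius equals the
#' sensing radius.
#'
#' @param population swarm size g.
#' @param rho luciferin decay in (0, 1).
#' @param gamma luciferin gain.
#' @param radius_gain decision-domain update rate (the rate often written
#'   beta in the swarm literature; distinct from ELM output weights).
#' @param n_t desired neighbour count threshold.
#' @param sensing_radius maximal decision radius, in Hamming units
#'   (`NULL` = M, set when the run starts).
#' @param step continuous-move step size; unused by the binary move rule and
#'   retained only so configurations for the continuous algorithm can be
#'   carried through unchanged.
#' @param t_max iteration cap.
#' @param p1,p2 bit-move branch thresholds, `0 <= p1 < p2 <= 1`: a uniform
#'   draw r per bit keeps the current bit when `r <= p1`, copies the target
#'   bit when `p1 < r < p2`, and draws a random bit when `r >= p2`.
#' @param omega fitness weight in (0, 1), slightly below 1, trading training
#'   accuracy against subset size.
#' @param l0 initial luciferin.
#' @param rd0 initial decision radius (`NULL` = `sensing_radius`).
#' @param radius_mode `"standard"` (cumulative update
#'   `rd + radius_gain * (n_t - |N|)`, clamped to `[0, r_s]`) or
#'   `"as_printed"` (memoryless `radius_gain * (n_t - |N|)`, clamped).
#' @param seed RNG seed.
#' @return an object of class `ibgso_config`.
#' @export
ibgso_config <- function(population = 30, rho = 0.4, gamma = 0.6,
                         radius_gain = 0.08, n_t = 5, sensing_radius = NULL,
                         step = 0.03, t_max = 300, p1 = 0.15, p2 = 0.85,
                         omega = 0.95, l0 = 5, rd0 = NULL,
                         radius_mode = "standard", seed = 1) {
  if (!(rho > 0 && rho < 1)) stop_glowsel("rho must lie in (0, 1)")
  if (!(p1 >= 0 && p2 <= 1 && p1 < p2)) stop_glowsel("need 0 <= p1 < p2 <= 1")
  if (!(omega > 0 && omega < 1)) stop_glowsel("omega must lie in (0, 1)")
  if (!is_count(population, 2L)) stop_glowsel("population must be >= 2")
  if (!is_count(t_max)) stop_glowsel("t_max must be a positive integer")
  if (!radius_mode %in% c("standard", "as_printed"))
    stop_glowsel("unknown radius_mode '%s'", radius_mode)
  structure(list(population = as.integer(population), rho = rho,
                 gamma = gamma, radius_gain = radius_gain, n_t = n_t,
                 sensing_radius = sensing_radius, step = step,
                 t_max = as.integer(t_max), p1 = p1, p2 = p2, omega = omega,
                 l0 = l0, rd0 = rd0, radius_mode = radius_mode,
                 seed = as.integer(seed)),
            class = "ibgso_config")
}

#' Subset-selection fitness: accuracy traded against ensemble size
#'
#' `fitness = omega * A_tr - (1 - omega) * m / M`, where `A_tr` is the
#' training accuracy of the fused masked ensemble, `m` the number of
#' selected members and `M` the pool size. Higher is better; at equal
#' accuracy the smaller subset wins.
#'
#' @param mask binary vector, or the selected count m directly.
#' @param training_accuracy fused training accuracy in `[0, 1]`.
#' @param omega accuracy weight, slightly below 1.
#' @param M pool size (defaults to `length(mask)` when a mask is given).
#' @return the scalar fitness.
#' @export
subset_fitness <- function(mask, training_accuracy, omega = 0.95, M = NULL) {
  if (length(mask) > 1L) {
    m <- sum(mask == 1L)
    if (is.null(M)) M <- length(mask)
  } else {
    m <- as.integer(mask)
    if (is.null(M)) stop_glowsel("M must be supplied when mask is a count")
  }
  if (m < 1L || m > M) stop_glowsel("need 0 < m <= M (got m = %d, M = %d)", m, M)
  if (!is_prob(training_accuracy)) stop_glowsel("training_accuracy must lie in [0, 1]")
  omega * training_accuracy - (1 - omega) * m / M
}

#' Luciferin update
#'
#' `l(t) = (1 - rho) * l(t-1) + gamma * J`, where J is the current fitness.
#'
#' @param l_prev previous luciferin value.
#' @param fitness_value current fitness J.
#' @param rho decay constant in (0, 1].
#' @param gamma gain constant.
#' @return updated luciferin.
#' @export
luciferin_update <- function(l_prev, fitness_value, rho = 0.4, gamma = 0.6) {
  (1 - rho) * l_prev + gamma * fitness_value
}

#' Hamming distance between binary vectors
#' @param a,b equal-length binary vectors.
#' @return number of differing bits.
#' @export
hamming <- function(a, b) sum(a != b)

#' Neighbour set of a glowworm
#'
#' Members strictly brighter than worm `i` and strictly within its decision
#' radius under Hamming distance: `{j : l_j > l_i, d(x_i, x_j) < rd_i}`.
#'
#' @param positions population x M binary matrix.
#' @param luciferin luciferin vector.
#' @param i worm index.
#' @param radius decision radius of worm i.
#' @return integer vector of neighbour indices (possibly empty).
#' @export
neighbor_set <- function(positions, luciferin, i, radius) {
  d <- colSums(t(positions) != positions[i, ])
  which(luciferin > luciferin[i] & d < radius & seq_along(luciferin) != i)
}

#' Attraction probabilities over a neighbour set
#'
#' `p_ij = (l_j - l_i) / sum_k (l_k - l_i)` over the neighbours k of i.
#'
#' @param luciferin luciferin vector of the swarm.
#' @param i worm index.
#' @param neighbors non-empty neighbour index vector.
#' @return probability vector (sums to 1) aligned with `neighbors`.
#' @export
move_probability <- function(luciferin, i, neighbors) {
  if (!length(neighbors)) stop_glowsel("empty neighbor set: no move target")
  excess <- luciferin[neighbors] - luciferin[i]
  excess / sum(excess)
}

#' Probabilistic bit-wise move toward a target position
#'
#' For each bit k a fresh uniform draw r decides the outcome: keep the
#' current bit (`r <= p1`), copy the target's bit (`p1 < r < p2`) or take a
#' fresh random bit (`r >= p2`).
#'
#' @param x_i current binary position.
#' @param x_j target binary position (same length).
#' @param p1,p2 branch thresholds, `p1 < p2`.
#' @return new binary vector.
#' @export
binary_move <- function(x_i, x_j, p1 = 0.15, p2 = 0.85) {
  if (length(x_i) != length(x_j)) stop_glowsel("positions differ in length")
  n <- length(x_i)
  r <- runif(n)
  r0 <- as.integer(runif(n) < 0.5)
  out <- x_i
  out[r > p1 & r < p2] <- x_j[r > p1 & r < p2]
  out[r >= p2] <- r0[r >= p2]
  out
}

#' Decaying mutation rate
#'
#' `R(t) = (1 - t / t_max)^2`: strong global search early, little late.
#'
#' @param t current iteration, `0 <= t <= t_max`.
#' @param t_max iteration cap.
#' @return mutation probability in `[0, 1]`.
#' @export
mutation_rate <- function(t, t_max) {
  if (t < 0 || t > t_max) stop_glowsel("t must lie in [0, t_max]")
  (1 - t / t_max)^2
}

#' Bit-flip mutation
#'
#' Each bit is flipped independently with probability R.
#'
#' @param x binary vector.
#' @param R mutation probability in `[0, 1]`.
#' @return mutated binary vector.
#' @export
mutate_bits <- function(x, R) {
  if (!is_prob(R)) stop_glowsel("R must lie in [0, 1]")
  flip <- runif(length(x)) <= R
  x[flip] <- 1L - x[flip]
  x
}

#' Decision-radius update
#'
#' Standard (cumulative) form:
#' `min(r_s, max(0, rd + radius_gain * (n_t - n_neighbors)))`. The
#' `"as_printed"` form drops the previous radius term,
#' `min(r_s, max(0, radius_gain * (n_t - n_neighbors)))`, which with the
#' default gain caps the radius at `radius_gain * n_t` and in Hamming space
#' empties every neighbourhood; it is kept selectable for comparison.
#'
#' @param rd current radius.
#' @param n_neighbors neighbour count this iteration.
#' @param radius_gain update rate.
#' @param n_t neighbour threshold.
#' @param r_s sensing radius (upper clamp).
#' @param mode `"standard"` or `"as_printed"`.
#' @return updated radius in `[0, r_s]`.
#' @export
decision_radius_update <- function(rd, n_neighbors, radius_gain = 0.08,
                                   n_t = 5, r_s = Inf, mode = "standard") {
  base <- switch(mode,
    standard = rd + radius_gain * (n_t - n_neighbors),
    as_printed = radius_gain * (n_t - n_neighbors),
    stop_glowsel("unknown radius mode '%s'", mode))
  min(r_s, max(0, base))
}

#' Composite three-candidate search move
#'
#' Generates up to three candidates by [binary_move()] toward (a) the
#' bulletin-board best position, (b) the brightest neighbour in the decision
#' domain and (c) a uniformly random neighbour, and adopts the candidate
#' with the highest fitness; ties are resolved in that order (exploitation
#' first). With an empty neighbour set only the bulletin candidate and the
#' current position compete.
#'
#' @param x_i current position.
#' @param luciferin swarm luciferin vector.
#' @param positions population x M binary matrix.
#' @param neighbors neighbour indices of worm i (possibly empty).
#' @param bulletin_best bulletin-board best position.
#' @param fitness_fn function(mask) -> scalar fitness (must tolerate an
#'   all-zero mask, e.g. by returning `-Inf`).
#' @param current_fitness fitness of `x_i`, used when no neighbour exists.
#' @param p1,p2 move thresholds.
#' @return new binary position.
#' @export
composite_move <- function(x_i, luciferin, positions, neighbors,
                           bulletin_best, fitness_fn, current_fitness,
                           p1 = 0.15, p2 = 0.85) {
  cand_bulletin <- binary_move(x_i, bulletin_best, p1, p2)
  if (length(neighbors)) {
    best_nb <- neighbors[which.max(luciferin[neighbors])]
    rand_nb <- neighbors[sample.int(length(neighbors), 1L)]
    cands <- list(cand_bulletin,
                  binary_move(x_i, positions[best_nb, ], p1, p2),
                  binary_move(x_i, positions[rand_nb, ], p1, p2))
    fits <- vapply(cands, fitness_fn, numeric(1))
    cands[[which.max(fits)]]        # which.max keeps the earliest on ties
  } else {
    if (fitness_fn(cand_bulletin) >= current_fitness) cand_bulletin else x_i
  }
}

#' Run the improved binary glowworm swarm subset search
#'
#' Maximizes a black-box fitness over non-empty binary masks of length M.
#' Each iteration evaluates the swarm, updates luciferin, posts the best
#' position to the bulletin board (which never forgets: elitism lives in
#' the board, not the swarm), then moves every worm by the composite
#' three-candidate search, applies bit-flip mutation at the decaying rate
#' `(1 - t/t_max)^2`, repairs all-zero masks by setting one random bit, and
#' adapts every decision radius. Fitness evaluations are memoized by mask.
#'
#' @param fitness_fn function(mask) returning either a scalar fitness or a
#'   list with elements `fitness` and `accuracy` (training accuracy of the
#'   masked ensemble, reported in the result).
#' @param M mask length (number of pool members / sensors).
#' @param config an [ibgso_config()].
#' @return object of class `selection_result`: list with `mask`, `fitness`,
#'   `training_accuracy`, `selected` (ids of set bits), `selected_count`,
#'   `trace` (bulletin best fitness per iteration, non-decreasing), `omega`,
#'   `seed`, `config`.
#' @export
run_ibgso <- function(fitness_fn, M, config = ibgso_config()) {
  if (!is_count(M)) stop_glowsel("M must be a positive integer")
  if (!inherits(config, "ibgso_config")) stop_glowsel("config must be an ibgso_config")
  r_s <- config$sensing_radius %||% M
  rd0 <- config$rd0 %||% r_s
  g <- config$population

  memo <- new.env(parent = emptyenv())
  eval_mask <- function(mask) {
    if (!any(mask == 1L)) return(list(fitness = -Inf, accuracy = NA_real_))
    key <- paste(mask, collapse = "")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- fitness_fn(mask)
    if (!is.list(res)) res <- list(fitness = res, accuracy = NA_real_)
    if (!is.finite(res$fitness))
      stop_glowsel("fitness callback returned a non-finite value for mask %s", key)
    memo[[key]] <- res
    res
  }
  fit_only <- function(mask) eval_mask(mask)$fitness

  with_seed(config$seed, {
    positions <- matrix(as.integer(runif(g * M) < 0.5), nrow = g)
    for (i in seq_len(g)) {
      if (!any(positions[i, ] == 1L))
        positions[i, sample.int(M, 1L)] <- 1L
    }
    luciferin <- rep(config$l0, g)
    radius <- rep(min(rd0, r_s), g)
    best_mask <- NULL
    best_fitness <- -Inf
    trace <- numeric(config$t_max)

    for (t in seq_len(config$t_max)) {
      evals <- lapply(seq_len(g), function(i) eval_mask(positions[i, ]))
      fitness <- vapply(evals, `[[`, numeric(1), "fitness")
      luciferin <- luciferin_update(luciferin, fitness, config$rho, config$gamma)

      top <- which.max(fitness)
      if (fitness[top] > best_fitness) {
        best_fitness <- fitness[top]
        best_mask <- positions[top, ]
      }
      trace[t] <- best_fitness

      R <- mutation_rate(t, config$t_max)
      new_positions <- positions
      for (i in seq_len(g)) {
        nb <- neighbor_set(positions, luciferin, i, radius[i])
        moved <- composite_move(positions[i, ], luciferin, positions, nb,
                                best_mask, fit_only, fitness[i],
                                config$p1, config$p2)
        moved <- mutate_bits(moved, R)
        if (!any(moved == 1L)) moved[sample.int(M, 1L)] <- 1L
        new_positions[i, ] <- moved
        radius[i] <- decision_radius_update(radius[i], length(nb),
                                            config$radius_gain, config$n_t,
                                            r_s, config$radius_mode)
      }
      positions <- new_positions
    }
  })

  best <- eval_mask(best_mask)
  structure(list(mask = best_mask, fitness = best_fitness,
                 training_accuracy = best$accuracy,
                 selected = which(best_mask == 1L),
                 selected_count = sum(best_mask),
                 trace = trace, omega = config$omega, seed = config$seed,
                 config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("subset selection: %d member(s) {%s}, fitness %.5f%s\n",
              x$selected_count, paste(x$selected, collapse = ","), x$fitness,
              if (is.na(x$training_accuracy)) ""
              else sprintf(", training accuracy %.4f", x$training_accuracy)))
  invisible(x)
}

#' Exhaustive oracle over all non-empty masks
#'
#' Enumerates all `2^M - 1` non-empty subsets and returns the fitness
#' argmax. Ties go to the mask whose selected-index sequence is
#' lexicographically smallest (so among singletons, sensor 1 wins). Guarded
#' to `M <= 20`.
#'
#' @param fitness_fn function(mask) -> scalar fitness (or a list with a
#'   `fitness` element).
#' @param M mask length.
#' @return list with `mask` and `fitness`.
#' @export
exhaustive_oracle <- function(fitness_fn, M) {
  if (!is_count(M) || M > 20) stop_glowsel("exhaustive search is limited to M <= 20")
  best_fit <- -Inf
  best_mask <- NULL
  best_key <- NULL
  for (j in seq_len(2^M - 1)) {
    mask <- as.integer(intToBits(j)[seq_len(M)])
    res <- fitness_fn(mask)
    if (is.list(res)) res <- res$fitness
    key <- paste(sprintf("%02d", which(mask == 1L)), collapse = ",")
    if (res > best_fit ||
        (res == best_fit && !is.null(best_key) && key < best_key)) {
      best_fit <- res
      best_mask <- mask
      best_key <- key
    }
  }
  list(mask = best_mask, fitness = best_fit)
}

#' Write a fitness trace as CSV (iteration, best_fitness)
#'
#' @param result a `selection_result`.
#' @param path file path.
#' @export
write_trace_csv <- function(result, path) {
  write.csv(data.frame(iteration = seq_along(result$trace),
                       best_fitness = result$trace),
            path, row.names = FALSE)
  invisible(path)
}
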