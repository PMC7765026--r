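test_that("the size-penalized fitness matches hand evaluation and is monotone", {
  expect_equal(subset_fitness(9, 0.9, omega = 0.95, M = 45), 0.845)
  expect_equal(subset_fitness(45, 1, omega = 0.95, M = 45), 0.90)
  mask <- c(1L, 0L, 1L)
  expect_equal(subset_fitness(mask, 0.5, omega = 0.9),
               0.9 * 0.5 - 0.1 * 2 / 3)
  # strictly decreasing in m at fixed accuracy; increasing in accuracy at fixed m
  f_m <- vapply(1:10, subset_fitness, numeric(1), training_accuracy = 0.8, M = 10)
  expect_true(all(diff(f_m) < 0))
  f_a <- vapply(seq(0, 1, 0.1), function(a) subset_fitness(3, a, M = 10), numeric(1))
  expect_true(all(diff(f_a) > 0))
  expect_error(subset_fitness(0, 1, M = 10), "0 < m")
  expect_error(subset_fitness(rep(0L, 5), 1), "0 < m")
})

test_that("luciferin update matches its closed form", {
  expect_equal(luciferin_update(5, 0.9, rho = 0.4, gamma = 0.6), 3.54)
  # memoryless limit: full decay forgets the previous value
  expect_equal(luciferin_update(123, 0.7, rho = 1 - 1e-15, gamma = 0.6),
               0.6 * 0.7, tolerance = 1e-10)
  expect_equal(luciferin_update(0, 0, 0.4, 0.6), 0)
})

test_that("neighbour sets contain only strictly brighter worms strictly in radius", {
  pos <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_length(neighbor_set(pos, c(2, 2, 2), 1, radius = 3), 0)
  expect_length(neighbor_set(pos, c(1, 2, 3), 1, radius = 0), 0)
  # pairwise Hamming 2, radius just above -> brighter worms 2 and 3
  expect_identical(neighbor_set(pos, c(1, 2, 3), 1, radius = 2.5), c(2L, 3L))
  # brute-force check of the definition on random swarms
  set.seed(90)
  for (i in 1:10) {
    P <- matrix(sample(0:1, 40, TRUE), nrow = 8)
    l <- runif(8)
    rd <- runif(1, 0, 5)
    got <- neighbor_set(P, l, 3, rd)
    want <- Filter(function(j) j != 3 && l[j] > l[3] && hamming(P[3, ], P[j, ]) < rd,
                   1:8)
    expect_identical(got, as.integer(want))
  }
})

test_that("attraction probabilities are a proper distribution over the neighbours", {
  expect_equal(move_probability(c(1, 5), 1, 2L), 1)
  expect_equal(move_probability(c(1, 3, 3), 1, c(2L, 3L)), c(0.5, 0.5))
  expect_equal(move_probability(c(1, 2, 4), 1, c(2L, 3L)), c(1 / 4, 3 / 4))
  expect_error(move_probability(c(1, 2), 1, integer(0)), "empty")
  set.seed(14)
  for (i in 1:10) {
    l <- runif(6)
    i0 <- which.min(l)
    nb <- setdiff(which(l > l[i0]), i0)
    p <- move_probability(l, i0, nb)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("the probabilistic bit move obeys its branch structure", {
  x <- rep(c(0L, 1L), 10)
  y <- 1L - x
  set.seed(2)
  expect_identical(binary_move(x, y, p1 = 1, p2 = 1 + 1e-9), x)   # keep branch forced
  expect_identical(binary_move(x, y, p1 = 0, p2 = 1), y)          # copy branch forced
  # with x_i == x_j only the random branch can flip: rate (1 - p2) * 0.5
  set.seed(3)
  n <- 1e5
  x_long <- sample(0:1, n, TRUE)
  moved <- binary_move(x_long, x_long, p1 = 0.15, p2 = 0.85)
  frac <- mean(moved != x_long)
  sd3 <- 3 * sqrt(0.075 * (1 - 0.075) / n)
  expect_lt(abs(frac - 0.075), sd3)
  expect_error(binary_move(c(0, 1), c(1, 0, 0)), "length")
})

test_that("the mutation schedule decays quadratically from 1 to 0", {
  expect_equal(mutation_rate(0, 300), 1)
  expect_equal(mutation_rate(300, 300), 0)
  expect_equal(mutation_rate(150, 300), 0.25)
  rates <- vapply(0:300, mutation_rate, numeric(1), t_max = 300)
  expect_true(all(diff(rates) <= 0))
  expect_error(mutation_rate(301, 300), "t_max")
})

test_that("bit-flip mutation hits the requested rate", {
  x <- rep(c(0L, 1L), 8)
  set.seed(4)
  expect_identical(mutate_bits(x, 0), x)
  expect_identical(mutate_bits(x, 1), 1L - x)
  set.seed(5)
  flips <- sum(mutate_bits(rep(0L, 1e4), 0.3))
  expect_lt(abs(flips - 3000), 3 * sqrt(1e4 * 0.3 * 0.7))
})

test_that("the decision radius updates and clamps in both modes", {
  expect_equal(decision_radius_update(2.2, 5, 0.08, 5, r_s = 10, "standard"), 2.2)
  expect_equal(decision_radius_update(2.2, 0, 0.08, 5, r_s = 10, "as_printed"), 0.4)
  expect_equal(decision_radius_update(1, 500, 0.08, 5, r_s = 10, "standard"), 0)
  expect_equal(decision_radius_update(9.9, 0, 1, 5, r_s = 10, "standard"), 10)
  expect_error(decision_radius_update(1, 1, mode = "bogus"), "mode")
})

test_that("the composite search adopts the best of its candidates", {
  fitness <- function(mask) {
    if (!any(mask == 1L)) return(-Inf)
    sum(mask * c(5, 1, 1, 1))
  }
  pos <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1))
  l <- c(1, 2, 3)
  # degenerate thresholds p1=0, p2=1 force every candidate to equal its target
  set.seed(6)
  out <- composite_move(pos[1, ], l, pos, neighbors = c(2L, 3L),
                        bulletin_best = c(1, 1, 1, 1), fitness_fn = fitness,
                        current_fitness = fitness(pos[1, ]), p1 = 0, p2 = 1)
  # candidates are exactly (1,1,1,1), (0,0,1,1), random neighbour's position;
  # the bulletin candidate has the highest fitness
  expect_identical(out, c(1, 1, 1, 1))

  # all candidates identical: that position is returned
  set.seed(7)
  same <- composite_move(pos[2, ], l, rbind(pos[2, ], pos[2, ], pos[2, ]),
                         neighbors = c(1L, 3L), bulletin_best = pos[2, ],
                         fitness_fn = fitness, current_fitness = fitness(pos[2, ]),
                         p1 = 0, p2 = 1)
  expect_identical(same, pos[2, ])

  # empty neighbour set: bulletin candidate or current, whichever is fitter
  set.seed(8)
  stay <- composite_move(pos[1, ], l, pos, neighbors = integer(0),
                         bulletin_best = c(0, 1, 0, 0), fitness_fn = fitness,
                         current_fitness = fitness(pos[1, ]), p1 = 0, p2 = 1)
  expect_identical(stay, pos[1, ])
})

test_that("the exhaustive oracle agrees with an independent enumeration", {
  # forced tie among singletons: selected-index lexicographic rule gives {1}
  expect_identical(exhaustive_oracle(function(m) -sum(m) / 3, 3)$mask,
                   c(1L, 0L, 0L))
  expect_identical(exhaustive_oracle(function(m) sum(m), 1)$mask, 1L)
  expect_error(exhaustive_oracle(function(m) 0, 25), "M <= 20")
  for (s in 1:3) {
    fit <- lookup_fitness(8, seed = 700 + s)
    a <- exhaustive_oracle(fit, 8)
    b <- enumerate_best_recursive(fit, 8)
    expect_equal(a$fitness, b$fitness)
    expect_identical(a$mask, b$mask)
  }
})

test_that("the swarm run is reproducible, monotone, and memoizes its callback", {
  calls <- new.env(); calls$n <- 0L; calls$seen <- character(0)
  counting <- function(mask) {
    calls$n <- calls$n + 1L
    calls$seen <- union(calls$seen, paste(mask, collapse = ""))
    sum(mask * seq_along(mask)) / 100
  }
  cfg <- ibgso_config(population = 10, t_max = 25, seed = 42)
  r1 <- run_ibgso(counting, 6, cfg)
  expect_identical(calls$n, length(calls$seen))   # one call per distinct mask
  r2 <- run_ibgso(counting, 6, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) >= 0))
  expect_equal(r1$fitness, max(r1$trace))

  # M = 1: the only legal subset
  r <- run_ibgso(function(m) 1, 1, ibgso_config(population = 2, t_max = 3, seed = 1))
  expect_identical(r$mask, 1L)
  expect_error(run_ibgso(function(m) 1, 0, cfg), "positive")
})

test_that("the swarm finds exhaustive optima on small rugged landscapes", {
  hits <- 0L
  for (s in 1:5) {
    fit <- lookup_fitness(8, seed = 50 + s)
    want <- exhaustive_oracle(fit, 8)$fitness
    got <- run_ibgso(fit, 8, ibgso_config(population = 20, t_max = 80,
                                          seed = 900 + s))$fitness
    hits <- hits + (abs(got - want) < 1e-12)
  }
  expect_gte(hits, 4L)
})

test_that("constant-accuracy fitness drives selection to a singleton", {
  const <- function(mask) list(
    fitness = subset_fitness(mask, 1, omega = 0.95), accuracy = 1)
  r <- run_ibgso(const, 8, ibgso_config(population = 15, t_max = 60, seed = 3))
  expect_identical(r$selected_count, 1L)
  expect_equal(r$training_accuracy, 1)
  expect_equal(r$fitness, 0.95 - 0.05 / 8)
})

test_that("fitness traces serialize as iteration/best-fitness CSV", {
  r <- run_ibgso(function(m) sum(m), 4,
                 ibgso_config(population = 5, t_max = 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(r, path)
  back <- read.csv(path)
  expect_identical(back$iteration, 1:10)
  expect_equal(back$best_fitness, r$trace)
})
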