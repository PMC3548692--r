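# Threshold / filtering / confusion arithmetic, the GA operators and the
# LOOCV grid driver.

test_that("the relative threshold and the strict filter behave as defined", {
  expect_equal(score_threshold(c(2.0, 1.0), 0.3), 0.6)
  expect_equal(score_threshold(c(2.0, 1.0), 0.3, sigma_max = 4), 1.2)
  expect_error(score_threshold(numeric(0), 0.5), class = "snpprio_usage_error")
  expect_error(score_threshold(1, 0), class = "snpprio_usage_error")
  expect_warning(t0 <- score_threshold(c(0, 0), 0.5), "degenerate")
  expect_equal(t0, 0)
  # epsilon grid of the optimizer: 10 steps from 0.1 to 1.0
  expect_length(seq(0.1, 1.0, by = 0.1), 10)

  sig <- c(a = 0.9, b = 0.6, c = 0.2)
  expect_equal(high_scoring_set(sig, 0.6), "a")        # strict >
  expect_setequal(high_scoring_set(sig, 0), c("a", "b", "c"))
  expect_length(high_scoring_set(numeric(0), 0), 0)
  # at epsilon = 1 with the observed-max reference, Y is empty
  expect_length(high_scoring_set(sig, score_threshold(sig, 1.0)), 0)
})

test_that("confusion counts match a brute-force set tally", {
  b <- disease_benchmark("d", "g", S = paste0("s", 1:10), A = paste0("s", 1:4))
  Y <- c(paste0("s", 1:3), "s5", "s6")   # 3 of A plus 2 others
  cc <- confusion(Y, b)
  expect_equal(cc$sensitivity, 0.75)
  expect_equal(cc$specificity, 4 / 6)
  expect_equal(cc$accuracy, 0.7)
  expect_equal(confusion(b$S, b)$sensitivity, 1)     # Y = S
  expect_equal(confusion(b$S, b)$specificity, 0)
  expect_equal(confusion(character(0), b)$sensitivity, 0)
  expect_equal(confusion(character(0), b)$specificity, 1)
  # random fixtures against the oracle; counts always partition S
  set.seed(5)
  for (i in 1:20) {
    S <- paste0("s", 1:30)
    A <- sample(S, 6)
    bi <- disease_benchmark("r", "g", S, A)
    Yi <- sample(S, sample(0:30, 1))
    got <- confusion(Yi, bi)
    want <- bf_confusion(Yi, S, A)
    expect_equal(got[c("P", "N", "FP", "TN")], want)
    expect_equal(got$P + got$N, length(A))
    expect_equal(got$P + got$N + got$FP + got$TN, length(S))
    expect_equal(got$sensitivity + got$N / length(A), 1)
  }
})

test_that("benchmarks enforce A within S and load from files", {
  expect_warning(
    b <- disease_benchmark("d", "g", S = c("s1", "s2"), A = c("s1", "zz")),
    "outside S")
  expect_equal(b$A, "s1")
  expect_equal(b$n_dropped_certified, 1)
  expect_error(disease_benchmark("d", "g", character(0), "a"),
               class = "snpprio_integrity_error")
  sim <- shared_sim()
  for (b in sim$benchmarks) {
    expect_true(all(b$A %in% b$S))
    expect_gt(length(b$A), 0)
  }
})

test_that("fitness rewards sensitivity and penalizes weak filtering", {
  # two hand-built diseases: 3 features, scores are sums of planted columns
  F1 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, 0, 0), 4, 3,
               dimnames = list(paste0("a", 1:4), c("f1", "f2", "f3")))
  F2 <- matrix(c(1, 1, 0, 0,
                 0, 0, 0, 0,
                 0, 0, 0, 0), 4, 3,
               dimnames = list(paste0("b", 1:4), c("f1", "f2", "f3")))
  data <- list(list(disease_id = "d1", F = F1,
                    certified = c(TRUE, TRUE, FALSE, FALSE)),
               list(disease_id = "d2", F = F2,
                    certified = c(TRUE, TRUE, FALSE, FALSE)))
  w <- c(1, 1, 0)
  # T = 0.3 * sum(w) = 0.6; d1: Y = {a1, a2} both certified; d2: Y = {b1, b2}
  expect_equal(ga_fitness(w, data, 0.3, Tr = 0.9), 0)   # perfect sensitivity
  # |Y|/|S| = 0.5 >= Tr = 0.5 -> sentinel penalty
  expect_equal(ga_fitness(w, data, 0.3, Tr = 0.5), 2.0)
  w2 <- c(0, 1, 0)   # d1: Y = {a2} (1 of 2 certified); d2: Y = {} -> sens 0
  expect_equal(ga_fitness(w2, data, 0.3, Tr = 0.9), 0.75)
  # sensitivities 0.5 (d1: T = 0.42 keeps a1 only) and 1.0 (d2) -> 0.25
  expect_equal(ga_fitness(c(1, 0.4, 0), data, 0.3, Tr = 0.9), 0.25)
  # pooled aggregation: w2 finds 1 of the 4 certified SNPs overall
  expect_equal(ga_fitness(w2, data, 0.3, Tr = 0.9, aggregate = "pooled"),
               1 - 1 / 4)
})

test_that("population initialization is uniform, sized and seeded", {
  set.seed(1); p1 <- init_population(31, 120)
  set.seed(1); p2 <- init_population(31, 120)
  expect_equal(dim(p1), c(120, 31))
  expect_identical(p1, p2)
  expect_error(init_population(5, 0), class = "snpprio_usage_error")
  set.seed(2)
  draws <- init_population(100, 100)   # 10^4 coefficients
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("recombination is uniform crossover with bounded mutation", {
  p <- runif(20)
  set.seed(9)
  expect_equal(recombine(p, p, mut_prob = 0), p)   # identical parents
  set.seed(10); c1 <- recombine(p, rev(p))
  set.seed(10); c2 <- recombine(p, rev(p))
  expect_identical(c1, c2)                         # seeded reproducibility
  # children stay within [min - 0.3, max + 0.3] intersected with [0, 1]
  set.seed(11)
  for (i in 1:50) {
    a <- runif(10); b <- runif(10)
    child <- recombine(a, b, mut_prob = 0.5, mut_sd = 0.05)
    expect_true(all(child >= pmax(pmin(a, b) - 0.3, 0)))
    expect_true(all(child <= pmin(pmax(a, b) + 0.3, 1)))
  }
})

test_that("generation turnover keeps the schedule and elitism", {
  cfg <- ga_config(seed = 4)
  set.seed(4)
  pop <- init_population(31, cfg$population)
  fitness <- runif(cfg$population)
  nx <- next_generation(pop, fitness, cfg)
  expect_equal(nrow(nx$pop), 120)
  expect_equal(as.vector(table(nx$provenance)[c("random", "elite",
                                                "recombinant")]),
               c(10, 10, 100))
  # the carried individuals are the 10 best of the previous generation
  best10 <- pop[order(fitness)[1:10], ]
  expect_equal(nx$pop[nx$provenance == "elite", ], best10)
  # all-equal fitness: deterministic index tie-break
  nx2 <- next_generation(pop, rep(0.5, 120), cfg)
  expect_equal(nx2$pop[nx2$provenance == "elite", ], pop[1:10, ])
  expect_error(next_generation(pop[1:30, ], fitness[1:30],
                               ga_config(population = 30, elite_pool = 50,
                                         n_random = 5, n_elite = 5,
                                         n_recombinant = 20)),
               class = "snpprio_usage_error")
  expect_error(ga_config(population = 100), class = "snpprio_usage_error")
})

test_that("the GA run is seeded, elitist and recovers planted signal", {
  sim <- shared_sim()
  cfg <- ga_config_scaled(population = 30, generations = 12, epsilon = 0.3,
                          Tr = 0.25, seed = 21)
  res1 <- run_ga(sim$data, cfg)
  res2 <- run_ga(sim$data, cfg)
  expect_identical(res1$best, res2$best)           # determinism
  expect_length(res1$trajectory, 12)
  expect_true(all(diff(res1$trajectory) <= 0))     # non-increasing
  expect_lt(res1$best_fitness, 1)                  # feasible solution found
  w <- stats::setNames(res1$best, sim$st$registry$name)
  inf <- sim$store$informative
  expect_gt(mean(w[inf]), mean(w[setdiff(names(w), inf)]))
})

test_that("the LOOCV driver validates each disease once per cell", {
  sim <- shared_sim()
  stub <- function(train_data, epsilon, Tr, seed) rep(0.5, 31)
  rep1 <- loocv_grid(sim$data, epsilon_grid = 0.3, tr_grid = 0.25,
                     config = ga_config(seed = 1), train_fn = stub)
  expect_equal(nrow(rep1$runs), length(sim$data))
  expect_setequal(rep1$runs$disease,
                  vapply(sim$data, `[[`, "", "disease_id"))
  # per-cell means equal the hand-computed mean of the per-disease values
  expect_equal(rep1$cells$mean_sensitivity, mean(rep1$runs$sensitivity))
  expect_equal(rep1$cells$mean_accuracy, mean(rep1$runs$accuracy))
  expect_equal(rep1$cells$n_runs, length(sim$data))
  # 2 diseases x 1 x 1 -> 2 runs
  rep2 <- loocv_grid(sim$data[1:2], epsilon_grid = 0.5, tr_grid = 1.0,
                     config = ga_config(seed = 1), train_fn = stub)
  expect_equal(nrow(rep2$runs), 2)
  expect_error(loocv_grid(sim$data[1], train_fn = stub),
               class = "snpprio_usage_error")
})
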