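test_that("uniform crossover mixes genes and nothing else", {
  a <- c(m_l = 3, c_r = 10, p_k = 0.5)
  b <- c(m_l = 7, c_r = -20, p_k = 2)

  expect_equal(uniform_crossover(a, a)$child_a, a)

  forced <- uniform_crossover(a, b, swap = rep(TRUE, 3))
  expect_equal(forced$child_a, b)
  expect_equal(forced$child_b, a)

  set.seed(40)
  for (i in 1:200) {
    kids <- uniform_crossover(a, b)
    for (g in names(a)) {
      expect_true(kids$child_a[[g]] %in% c(a[[g]], b[[g]]))
      # the pair of children always carries both parental genes
      expect_equal(sort(c(kids$child_a[[g]], kids$child_b[[g]])),
                   sort(c(a[[g]], b[[g]])))
    }
  }
})

test_that("random-reset mutation respects probability, bounds and typing", {
  bounds <- list(m_l = c(1, 9), c_r = c(-5, 5), p_k = c(0.1, 2))
  chrom <- c(m_l = 4, c_r = 0, p_k = 1)

  expect_equal(random_reset_mutation(chrom, 0, bounds), chrom)

  set.seed(41)
  draws <- t(replicate(1000, random_reset_mutation(chrom, 1, bounds)))
  expect_true(all(draws[, "m_l"] == round(draws[, "m_l"])))
  expect_true(all(draws[, "m_l"] >= 1 & draws[, "m_l"] <= 9))
  expect_true(all(draws[, "c_r"] >= -5 & draws[, "c_r"] <= 5))
  expect_true(all(draws[, "p_k"] >= 0.1 & draws[, "p_k"] <= 2))
  # means approach bound midpoints within 5% of the ranges
  expect_lt(abs(mean(draws[, "m_l"]) - 5), 0.05 * 8)
  expect_lt(abs(mean(draws[, "c_r"]) - 0), 0.05 * 10)
  expect_lt(abs(mean(draws[, "p_k"]) - 1.05), 0.05 * 1.9)
})

test_that("ga recovers the optimum of a convex fitness", {
  cfg <- ga_config(population_size = 30,
                   bounds = list(c_r = c(0, 10), p_k = c(0, 10)),
                   integer_genes = character(),
                   max_generations = 50, seed = 42)
  res <- ga_optimize(function(g) (g[["c_r"]] - 3)^2 + (g[["p_k"]] - 2)^2, cfg)
  expect_lt(abs(res$best[["c_r"]] - 3), 0.1)
  expect_lt(abs(res$best[["p_k"]] - 2), 0.1)
  expect_lte(nrow(res$history), 50)
})

test_that("ga terminates immediately on a constant fitness", {
  cfg <- ga_config(population_size = 10,
                   bounds = list(c_r = c(0, 1), p_k = c(0, 1)),
                   integer_genes = character(), max_generations = 20, seed = 1)
  res <- ga_optimize(function(g) 0.5, cfg)
  expect_equal(nrow(res$history), 1L) # best equals mean at generation 1
})

test_that("ga runs are reproducible and monotone under elitism", {
  cfg <- ga_config(population_size = 12,
                   bounds = list(m_l = c(1, 20), c_r = c(-10, 10),
                                 p_k = c(0.01, 5)),
                   max_generations = 15, seed = 7)
  noisy <- function(g) sin(g[["c_r"]]) + (g[["p_k"]] - 1)^2 + g[["m_l"]] / 20
  r1 <- ga_optimize(noisy, cfg)
  r2 <- ga_optimize(noisy, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
  expect_true(all(diff(r1$history$best) <= 1e-12))
})

test_that("a fitness error scores as worst and the run survives", {
  cfg <- ga_config(population_size = 8,
                   bounds = list(c_r = c(0, 10), p_k = c(0, 10)),
                   integer_genes = character(), max_generations = 10, seed = 3)
  hostile <- function(g) {
    if (g[["c_r"]] > 5) stop("boom")
    g[["p_k"]]
  }
  warnings <- capture_warnings(res <- ga_optimize(hostile, cfg))
  expect_true(any(grepl("scored as worst", warnings)))
  expect_lte(res$best[["c_r"]], 5)
  expect_true(is.finite(res$best_fitness))
})

test_that("config invariants are enforced", {
  expect_error(ga_config(population_size = 1), class = "ecgkelm_invalid_argument")
  expect_error(ga_config(elitism_count = 20, population_size = 20),
               class = "ecgkelm_invalid_argument")
  expect_error(ga_config(bounds = list(m_l = c(5, 1))),
               class = "ecgkelm_invalid_argument")
})
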