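# Genetic algorithm over (m_l, c_r, p_k).
#
# Minimises a user-supplied fitness (classification error rate in the
# pipeline) with tournament selection, uniform crossover, random-reset
# mutation and elitism. Termination: a generation cap, or the best fitness
# meeting the population mean within a tolerance.

#' Genetic-algorithm configuration
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param bounds Named list of `c(lower, upper)` per gene. The default covers
#'   the three tuned pipeline parameters: the maximum cumulant lag `m_l`
#'   (integer), the KELM regularisation coefficient `c_r` (may be negative),
#'   and the RBF kernel parameter `p_k`.
#' @param integer_genes Character vector of genes constrained to integers.
#' @param crossover_probability Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_probability Per-gene probability of a random reset.
#' @param max_generations Generation cap.
#' @param elitism_count Best chromosomes copied unchanged into the next
#'   generation (must be < `population_size`).
#' @param tournament_size Tournament size for parent selection.
#' @param termination_tolerance Stop once `|best - mean|` of a generation's
#'   fitness falls to this value or below.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L,
                      bounds = list(m_l = c(1, 50), c_r = c(-100, 200),
                                    p_k = c(1e-4, 10)),
                      integer_genes = "m_l",
                      crossover_probability = 0.9,
                      mutation_probability = 0.1,
                      max_generations = 30L,
                      elitism_count = 1L,
                      tournament_size = 3L,
                      termination_tolerance = 0,
                      seed = 1L) {
  if (population_size < 2L) stop_invalid("population_size must be >= 2")
  if (elitism_count >= population_size) {
    stop_invalid("elitism_count must be smaller than population_size")
  }
  if (tournament_size < 1L) stop_invalid("tournament_size must be >= 1")
  if (max_generations < 1L) stop_invalid("max_generations must be >= 1")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || b[1L] > b[2L]) {
      stop_invalid("bounds for gene '%s' must be c(lower, upper)", nm)
    }
  }
  structure(
    list(population_size = as.integer(population_size), bounds = bounds,
         integer_genes = integer_genes,
         crossover_probability = crossover_probability,
         mutation_probability = mutation_probability,
         max_generations = as.integer(max_generations),
         elitism_count = as.integer(elitism_count),
         tournament_size = as.integer(tournament_size),
         termination_tolerance = termination_tolerance,
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

random_chromosome <- function(bounds, integer_genes) {
  genes <- vapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (nm %in% integer_genes) {
      as.numeric(sample(seq(ceiling(b[1L]), floor(b[2L])), 1L))
    } else {
      runif(1L, b[1L], b[2L])
    }
  }, numeric(1))
  names(genes) <- names(bounds)
  genes
}

#' Uniform crossover of two chromosomes
#'
#' Each gene is treated separately: with probability 1/2 the children swap
#' that gene, otherwise they inherit it unswapped.
#'
#' @param parent_a,parent_b Named numeric gene vectors of equal layout.
#' @param swap Optional logical vector (one entry per gene) forcing the swap
#'   pattern; when `NULL` the pattern is drawn from the current RNG stream.
#' @return A list with elements `child_a` and `child_b`.
#' @export
uniform_crossover <- function(parent_a, parent_b, swap = NULL) {
  if (!identical(names(parent_a), names(parent_b))) {
    stop_invalid("parents must share gene layout")
  }
  if (is.null(swap)) swap <- runif(length(parent_a)) < 0.5
  child_a <- ifelse(swap, parent_b, parent_a)
  child_b <- ifelse(swap, parent_a, parent_b)
  names(child_a) <- names(child_b) <- names(parent_a)
  list(child_a = child_a, child_b = child_b)
}

#' Random-reset mutation
#'
#' Each gene is independently replaced, with the given probability, by a
#' uniform draw from its bound interval; integer genes are drawn uniformly
#' over the integer range.
#'
#' @param chromosome Named numeric gene vector.
#' @param mutation_probability Per-gene reset probability in `[0, 1]`.
#' @param bounds Named list of `c(lower, upper)` per gene.
#' @param integer_genes Character vector of integer-constrained genes.
#' @param reset Optional logical mask forcing which genes reset.
#' @return The mutated chromosome (within bounds).
#' @export
random_reset_mutation <- function(chromosome, mutation_probability, bounds,
                                  integer_genes = "m_l", reset = NULL) {
  if (is.null(reset)) reset <- runif(length(chromosome)) < mutation_probability
  for (i in which(reset)) {
    nm <- names(chromosome)[i]
    b <- bounds[[nm]]
    chromosome[i] <- if (nm %in% integer_genes) {
      as.numeric(sample(seq(ceiling(b[1L]), floor(b[2L])), 1L))
    } else {
      runif(1L, b[1L], b[2L])
    }
  }
  chromosome
}

#' Minimise a fitness function with a genetic algorithm
#'
#' Runs tournament selection, uniform crossover, random-reset mutation and
#' elitism until the generation cap is reached or the generation's best
#' fitness equals its mean within `termination_tolerance`. Fitness values are
#' memoised per chromosome; a fitness that errors or returns a non-finite
#' value scores as worst and the run continues.
#'
#' @param fitness Function taking a named gene vector, returning a single
#'   number to minimise.
#' @param config A [ga_config()].
#' @return A list with `best` (named gene vector), `best_fitness`, and
#'   `history` (tibble with one row per generation: best and mean fitness).
#' @examples
#' cfg <- ga_config(bounds = list(c_r = c(0, 10), p_k = c(0, 10)),
#'                  integer_genes = character(), seed = 42)
#' res <- ga_optimize(function(g) (g[["c_r"]] - 3)^2 + (g[["p_k"]] - 2)^2, cfg)
#' res$best
#' @export
ga_optimize <- function(fitness, config = ga_config()) {
  if (!inherits(config, "ga_config")) stop_invalid("`config` must be a ga_config()")
  set.seed(config$seed)
  bounds <- config$bounds
  int_genes <- config$integer_genes

  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- paste(signif(chrom, 12), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(fitness(chrom), error = function(e) {
      warn(sprintf("fitness error for (%s): %s; scored as worst",
                   paste(signif(chrom, 4), collapse = ", "),
                   conditionMessage(e)))
      Inf
    })
    if (!is.finite(val)) val <- Inf
    cache[[key]] <- val
    val
  }

  pop <- replicate(config$population_size,
                   random_chromosome(bounds, int_genes), simplify = FALSE)
  fit <- vapply(pop, evaluate, numeric(1))
  best_idx <- which.min(fit)
  best <- pop[[best_idx]]
  best_fit <- fit[best_idx]
  history <- list()

  for (gen in seq_len(config$max_generations)) {
    history[[gen]] <- tibble(generation = gen, best = min(fit),
                             mean = mean(fit))
    if (abs(min(fit) - mean(fit)) <= config$termination_tolerance) break
    if (gen == config$max_generations) break

    elite <- pop[order(fit)][seq_len(config$elitism_count)]
    children <- list()
    while (length(children) < config$population_size - config$elitism_count) {
      pick <- function() {
        contenders <- sample(config$population_size, config$tournament_size,
                             replace = TRUE)
        pop[[contenders[which.min(fit[contenders])]]]
      }
      pa <- pick(); pb <- pick()
      if (runif(1) < config$crossover_probability) {
        kids <- uniform_crossover(pa, pb)
      } else {
        kids <- list(child_a = pa, child_b = pb)
      }
      for (kid in kids) {
        kid <- random_reset_mutation(kid, config$mutation_probability,
                                     bounds, int_genes)
        children[[length(children) + 1L]] <- kid
        if (length(children) == config$population_size - config$elitism_count) break
      }
    }
    pop <- c(elite, children)
    fit <- vapply(pop, evaluate, numeric(1))
    gen_best <- which.min(fit)
    if (fit[gen_best] < best_fit) {
      best_fit <- fit[gen_best]
      best <- pop[[gen_best]]
    }
  }

  list(best = best, best_fitness = best_fit,
       history = dplyr::bind_rows(history))
}
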