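## Genetic algorithm over 15-bit architecture genomes -------------------------

#' Genetic-algorithm parameters
#'
#' Defaults follow the published search set-up: population `z = 15`, at most
#' `G = 20` generations, patience 15, crossover probability 0.9, initial
#' mutation probability 0.2 decayed by 30% every five generations down to a
#' floor of 0.01, two elites.
#'
#' @param z Population size (>= 3, required by tournament-of-two selection).
#' @param max_generations Maximum number of generations `G`.
#' @param patience Consecutive non-improving generations before stopping.
#' @param crossover_prob Probability an offspring comes from crossover
#'   rather than tournament cloning.
#' @param m0 Initial per-bit mutation probability.
#' @param m_decay Multiplier applied to the mutation probability every
#'   `m_every` generations.
#' @param m_every Generations between decay steps.
#' @param m_min Mutation probability floor.
#' @param n_elites Number of elites carried over unchanged.
#' @param n_bits Genome length.
#' @param seed Integer seed.
#' @return A `ga_params` list.
#' @export
ga_params <- function(z = 15, max_generations = 20, patience = 15,
                      crossover_prob = 0.9, m0 = 0.2, m_decay = 0.7,
                      m_every = 5, m_min = 0.01, n_elites = 2, n_bits = 15,
                      seed = 1L) {
  if (z < 3) stopf("tournament-of-two selection requires z >= 3")
  if (n_elites >= z) stopf("n_elites must be smaller than z")
  structure(list(z = as.integer(z), max_generations = as.integer(max_generations),
                 patience = as.integer(patience), crossover_prob = crossover_prob,
                 m0 = m0, m_decay = m_decay, m_every = as.integer(m_every),
                 m_min = m_min, n_elites = as.integer(n_elites),
                 n_bits = as.integer(n_bits), seed = as.integer(seed)),
            class = "ga_params")
}

#' Scheduled mutation probability
#'
#' `m(g) = max(m_min, m0 * m_decay^floor((g - 1) / m_every))`: 0.2 for the
#' first five generations, then shrinking 30% every five generations until
#' the 1% floor.
#'
#' @param g Generation index (1-based).
#' @param params A [ga_params()].
#' @return Mutation probability.
#' @export
#' @examples
#' mutation_prob(1)   # 0.2
#' mutation_prob(6)   # 0.14
mutation_prob <- function(g, params = ga_params()) {
  stopifnot(g >= 1)
  pmax(params$m_min, params$m0 * params$m_decay^(floor((g - 1) / params$m_every)))
}

#' Expected number of mutated bits per generation
#'
#' `m(g) * (z - 2) * n_bits`: the two elite slots are exempt from mutation,
#' so only `z - 2` offspring are mutated.
#'
#' @inheritParams mutation_prob
#' @return Expected count of bit flips in generation `g`.
#' @export
#' @examples
#' expected_mutations(1)  # 0.2 * 13 * 15 = 39
expected_mutations <- function(g, params = ga_params()) {
  mutation_prob(g, params) * (params$z - 2) * params$n_bits
}

#' Tournament-of-two selection
#'
#' Draws two distinct members uniformly at random (so each member enters a
#' given tournament with marginal probability `2/z`) and returns the index
#' of the fitter one; exact fitness ties are broken uniformly.
#'
#' @param fitness Numeric fitness vector of the population (higher better).
#' @param details If `TRUE`, return a list with the drawn `pair` and the
#'   `winner` instead of just the winner's index.
#' @return Index of the selected member (or a list when `details = TRUE`).
#' @export
tournament_select <- function(fitness, details = FALSE) {
  z <- length(fitness)
  if (z < 3) stopf("tournament selection requires a population of >= 3")
  pair <- sample.int(z, 2)
  winner <- if (fitness[pair[1]] == fitness[pair[2]]) pair[sample.int(2, 1)]
            else pair[which.max(fitness[pair])]
  if (details) list(pair = pair, winner = winner) else winner
}

#' Two-point crossover
#'
#' Picks two cut points `0 < i < j < n_bits` uniformly and returns the single
#' offspring `a[1:i] + b[(i+1):j] + a[(j+1):n]`.
#'
#' @param a,b Parent genomes (distinct population members).
#' @return One offspring genome.
#' @export
two_point_crossover <- function(a, b) {
  a <- check_bits(a); b <- check_bits(b)
  cuts <- sort(sample(seq_len(14), 2))   # i in 1..13, j > i (0 < i < j < 15)
  off <- a
  off[(cuts[1] + 1):cuts[2]] <- b[(cuts[1] + 1):cuts[2]]
  off
}

mutate_bits <- function(bits, m) {
  flip <- runif(length(bits)) < m
  bits[flip] <- 1L - bits[flip]
  bits
}

## one crossover-or-clone offspring from population `pop`
make_offspring <- function(pop, fitness, crossover_prob) {
  if (runif(1) < crossover_prob) {
    i <- tournament_select(fitness)
    repeat {
      j <- tournament_select(fitness)
      if (j != i) break
    }
    two_point_crossover(pop[[i]], pop[[j]])
  } else {
    pop[[tournament_select(fitness)]]
  }
}

new_trace <- function() {
  data.frame(round = integer(0), best_fitness = numeric(0),
             diversity = numeric(0), evaluations = integer(0))
}

eval_genomes <- function(fitness_fn, genomes) {
  vapply(genomes, function(g) {
    f <- fitness_fn(g)
    if (!is.finite(f))
      stopf("fitness function returned a non-finite value for genome %s",
            paste(g, collapse = ""))
    f
  }, 0)
}

#' Run the genetic algorithm
#'
#' Generation 1 is a random valid population of `z`, evaluated once. Every
#' later generation builds an offspring set `Q` of size `z`: the two elites
#' are cloned into it unchanged (and re-evaluated -- no memoization, so each
#' generation costs exactly `z` fitness calls), and the remaining `z - 2`
#' members are produced by two-point crossover (probability
#' `crossover_prob`, parents from two tournaments with distinct winners) or
#' tournament cloning, then bit-flip mutation at the scheduled rate, then
#' repair of empty channel masks. Survivors are the best `z - 2` of the old
#' population (elites removed) pooled with the mutated offspring, plus the
#' two elites. The run stops at `max_generations` or after `patience`
#' generations without strict improvement of the best fitness.
#'
#' @param fitness_fn Function mapping a 15-bit genome to a finite scalar
#'   fitness (higher is better); for architecture search this is the mean
#'   two-fold cross-validated AUC, see [make_tfcv_fitness()].
#' @param params A [ga_params()].
#' @return List with `best` (genome), `best_fitness`, `trace` (data.frame
#'   with round, best_fitness, diversity, evaluations) and `population`.
#' @export
#' @examples
#' onemax <- function(bits) sum(bits)
#' run_ga(onemax, ga_params(seed = 1))$best_fitness
run_ga <- function(fitness_fn, params = ga_params()) {
  with_seed(params$seed, {
    z <- params$z
    pop <- replicate(z, random_genome(), simplify = FALSE)
    fit <- eval_genomes(fitness_fn, pop)
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord]; fit <- fit[ord]
    evals <- z
    trace <- data.frame(round = 1L, best_fitness = fit[1],
                        diversity = hamming_diversity(pop),
                        evaluations = evals)
    best_fit <- fit[1]; pa <- 0L
    g <- 1L
    while (g < params$max_generations && pa < params$patience) {
      g <- g + 1L
      m <- mutation_prob(g, params)
      elites <- pop[seq_len(params$n_elites)]
      elite_fit <- fit[seq_len(params$n_elites)]
      # elite clones occupy 2 of the z offspring slots, exempt from mutation;
      # they are re-evaluated (their calls count) but not pooled twice
      evals <- evals + length(elites)
      invisible(eval_genomes(fitness_fn, elites))
      q <- vector("list", z - params$n_elites)
      for (k in seq_along(q)) {
        off <- make_offspring(pop, fit, params$crossover_prob)
        q[[k]] <- repair_genome(mutate_bits(off, m))
      }
      qfit <- eval_genomes(fitness_fn, q)
      evals <- evals + length(q)
      pool <- c(pop[-seq_len(params$n_elites)], q)
      pool_fit <- c(fit[-seq_len(params$n_elites)], qfit)
      keep <- order(pool_fit, decreasing = TRUE)[seq_len(z - params$n_elites)]
      pop <- c(elites, pool[keep])
      fit <- c(elite_fit, pool_fit[keep])
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord]; fit <- fit[ord]
      if (fit[1] > best_fit) {
        best_fit <- fit[1]; pa <- 0L
      } else pa <- pa + 1L
      trace <- rbind(trace, data.frame(round = g, best_fitness = best_fit,
                                       diversity = hamming_diversity(pop),
                                       evaluations = evals))
    }
    list(best = pop[[1]], best_fitness = best_fit, trace = trace,
         population = pop)
  })
}
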