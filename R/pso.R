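## Discrete binary particle swarm optimization --------------------------------

#' Binary-PSO parameters
#'
#' Defaults follow the published search set-up: swarm of 15 particles,
#' cognitive weight `c1 = 0.6`, social weight `c2 = 0.3`, inertia starting
#' at 0.9 and decaying 9% every five iterations down to 0.4, ring topology,
#' at most 20 iterations with patience 15. The velocity clamp `v_max = 6`
#' keeps the sigmoid position probabilities away from hard 0/1 saturation.
#'
#' @param swarm_size Number of particles (>= 3 for a ring).
#' @param c1,c2 Cognitive and social acceleration weights.
#' @param w0 Initial inertia weight.
#' @param w_min Inertia floor.
#' @param w_decay Multiplier applied every `w_every` iterations.
#' @param w_every Iterations between inertia decay steps.
#' @param max_iterations Maximum number of iterations.
#' @param patience Consecutive iterations without global improvement before
#'   stopping.
#' @param v_max Per-dimension velocity clamp.
#' @param n_bits Genome length.
#' @param seed Integer seed.
#' @return A `pso_params` list.
#' @export
pso_params <- function(swarm_size = 15, c1 = 0.6, c2 = 0.3, w0 = 0.9,
                       w_min = 0.4, w_decay = 0.91, w_every = 5,
                       max_iterations = 20, patience = 15, v_max = 6,
                       n_bits = 15, seed = 1L) {
  if (swarm_size < 3) stopf("a ring topology requires >= 3 particles")
  stopifnot(c1 >= 0, c2 >= 0, w0 >= w_min)
  structure(list(swarm_size = as.integer(swarm_size), c1 = c1, c2 = c2,
                 w0 = w0, w_min = w_min, w_decay = w_decay,
                 w_every = as.integer(w_every),
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience), v_max = v_max,
                 n_bits = as.integer(n_bits), seed = as.integer(seed)),
            class = "pso_params")
}

#' Time-varying inertia weight
#'
#' `w(i) = max(w_min, w0 * w_decay^floor((i - 1) / w_every))`: 0.9 for the
#' first five iterations, decreased 9% every five iterations until the 0.4
#' floor.
#'
#' @param i Iteration index (1-based).
#' @param params A [pso_params()].
#' @return Inertia weight.
#' @export
#' @examples
#' inertia(1)  # 0.9
#' inertia(6)  # 0.819
inertia <- function(i, params = pso_params()) {
  stopifnot(i >= 1)
  pmax(params$w_min, params$w0 * params$w_decay^(floor((i - 1) / params$w_every)))
}

#' Ring-topology neighbors
#'
#' Each particle shares information only with its two immediate neighbors
#' on a cycle.
#'
#' @param index Particle index (1-based).
#' @param swarm_size Number of particles (>= 3).
#' @return Integer pair of neighbor indices.
#' @export
#' @examples
#' ring_neighbors(1, 15)  # 15 2
ring_neighbors <- function(index, swarm_size) {
  if (swarm_size < 3) stopf("a ring topology requires >= 3 particles")
  as.integer(c((index - 2) %% swarm_size + 1, index %% swarm_size + 1))
}

#' Velocity update of binary PSO
#'
#' `v' = w v + c1 r1 (p - x) + c2 r2 (l - x)` per dimension with fresh
#' uniform `r1, r2`, clamped to `[-v_max, v_max]`.
#'
#' @param v Current velocity vector.
#' @param x Current bit position.
#' @param p Personal best position.
#' @param l Neighborhood (local) best position.
#' @param w Inertia weight.
#' @param c1,c2 Acceleration weights.
#' @param v_max Clamp.
#' @return Updated velocity vector.
#' @export
update_velocity <- function(v, x, p, l, w, c1 = 0.6, c2 = 0.3, v_max = 6) {
  r1 <- runif(length(v)); r2 <- runif(length(v))
  vn <- w * v + c1 * r1 * (p - x) + c2 * r2 * (l - x)
  pmin(pmax(vn, -v_max), v_max)
}

#' Sigmoid position sampling of binary PSO
#'
#' Each bit becomes 1 with probability `sigma(v_d) = 1 / (1 + exp(-v_d))`.
#'
#' @param v Velocity vector.
#' @return Sampled bit vector.
#' @export
update_position <- function(v) {
  as.integer(runif(length(v)) < sigmoid(v))
}

#' Run discrete binary PSO
#'
#' A random valid swarm is evaluated first (round 1, costing `swarm_size`
#' fitness calls); every iteration then updates each particle's velocity
#' from its personal best and the best personal best in its ring
#' neighborhood (self included), samples a new bit position through the
#' sigmoid, repairs empty channel masks, evaluates, and updates personal
#' and global bests. Stops at `max_iterations` or after `patience`
#' iterations without strict global improvement.
#'
#' @param fitness_fn As in [run_ga()] -- genome to finite scalar, higher
#'   better.
#' @param params A [pso_params()].
#' @return List with `best`, `best_fitness`, `trace`, `swarm` (positions).
#' @export
#' @examples
#' run_pso(function(bits) sum(bits), pso_params(seed = 1))$best_fitness
run_pso <- function(fitness_fn, params = pso_params()) {
  with_seed(params$seed, {
    z <- params$swarm_size
    nb <- params$n_bits
    x <- replicate(z, random_genome(), simplify = FALSE)
    v <- replicate(z, runif(nb, -1, 1), simplify = FALSE)
    fit <- eval_genomes(fitness_fn, x)
    pbest <- x; pbest_fit <- fit
    evals <- z
    gb <- which.max(pbest_fit)
    best <- pbest[[gb]]; best_fit <- pbest_fit[gb]
    trace <- data.frame(round = 1L, best_fitness = best_fit,
                        diversity = hamming_diversity(x), evaluations = evals)
    pa <- 0L; it <- 1L
    while (it < params$max_iterations && pa < params$patience) {
      it <- it + 1L
      w <- inertia(it, params)
      for (k in seq_len(z)) {
        nbrs <- c(k, ring_neighbors(k, z))
        l <- pbest[[nbrs[which.max(pbest_fit[nbrs])]]]
        v[[k]] <- update_velocity(v[[k]], x[[k]], pbest[[k]], l, w,
                                  params$c1, params$c2, params$v_max)
        x[[k]] <- repair_genome(update_position(v[[k]]))
      }
      fit <- eval_genomes(fitness_fn, x)
      evals <- evals + z
      improved <- fit > pbest_fit
      pbest[improved] <- x[improved]
      pbest_fit[improved] <- fit[improved]
      gb <- which.max(pbest_fit)
      if (pbest_fit[gb] > best_fit) {
        best <- pbest[[gb]]; best_fit <- pbest_fit[gb]; pa <- 0L
      } else pa <- pa + 1L
      trace <- rbind(trace, data.frame(round = it, best_fitness = best_fit,
                                       diversity = hamming_diversity(x),
                                       evaluations = evals))
    }
    list(best = best, best_fitness = best_fit, trace = trace, swarm = x)
  })
}
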