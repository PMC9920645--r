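#' Grasshopper optimizer parameters
#'
#' Collects the knobs of the binary grasshopper optimizer and its
#' k-tournament variant. The exploration--exploitation coefficient decays
#' linearly from `c_max` to `c_min`; `f_intensity` and `l_scale` are the
#' social-force constants of the original grasshopper algorithm.
#'
#' @param pop_size Population size `P >= 2`.
#' @param max_iter Number of repositioning iterations (`0` evaluates only the
#'   initial population).
#' @param c_max,c_min Bounds of the linear coefficient schedule,
#'   `c_max > c_min > 0`.
#' @param f_intensity Attraction intensity of the social force (default 0.5).
#' @param l_scale Attractive length scale of the social force (default 1.5).
#' @param k Tournament size, `1 <= k <= pop_size` (default 3).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A list of class `goa_params`.
#' @export
goa_params <- function(pop_size = 30, max_iter = 100, c_max = 1,
                       c_min = 0.00004, f_intensity = 0.5, l_scale = 1.5,
                       k = 3, seed = 1) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (!(c_max > c_min && c_min > 0)) stop("need c_max > c_min > 0")
  if (k < 1 || k > pop_size) stop("k must satisfy 1 <= k <= pop_size")
  if (max_iter < 0) stop("max_iter must be >= 0")
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         c_max = c_max, c_min = c_min, f_intensity = f_intensity,
         l_scale = l_scale, k = as.integer(k), seed = as.integer(seed)),
    class = "goa_params"
  )
}

#' Grasshopper social force
#'
#' `s(r) = f * exp(-r / l) - exp(-r)`: short-range repulsion, mid-range
#' attraction, vanishing at large distance.
#'
#' @param r Non-negative distance (vectorized).
#' @param f_intensity Attraction intensity.
#' @param l_scale Attractive length scale.
#' @return `s(r)`, same shape as `r`.
#' @export
social_force <- function(r, f_intensity = 0.5, l_scale = 1.5) {
  if (any(r < 0)) stop("distance r must be >= 0")
  f_intensity * exp(-r / l_scale) - exp(-r)
}

#' Linear exploration--exploitation coefficient schedule
#'
#' `c = c_max - iteration * (c_max - c_min) / max_iter`, strictly decreasing
#' in the iteration and reaching `c_min` at the final iteration.
#'
#' @param iteration Iteration index in `1..max_iter`.
#' @param params A [goa_params()] object.
#' @return The coefficient `c` for this iteration.
#' @export
coefficient_schedule <- function(iteration, params) {
  if (iteration < 1 || iteration > params$max_iter)
    stop("iteration out of range 1..max_iter")
  params$c_max - iteration * (params$c_max - params$c_min) / params$max_iter
}

#' k-tournament selection
#'
#' Draws `k` distinct indices uniformly without replacement and returns the
#' index of the maximum fitness among them, ties broken toward the lowest
#' index. With `k = length(fitnesses)` this is exactly the population best;
#' with `k = 1` it is a uniform draw.
#'
#' @param fitnesses Numeric fitness vector.
#' @param k Tournament size.
#' @return The winning index. Consumes the global RNG stream.
#' @export
tournament_select <- function(fitnesses, k) {
  P <- length(fitnesses)
  if (k < 1 || k > P) stop("k must satisfy 1 <= k <= length(fitnesses)")
  idx <- sort(sample.int(P, k))
  idx[which.max(fitnesses[idx])]
}

# Pairwise Euclidean distances between binary positions, linearly rescaled
# into [1, 4] (the social force's informative range). If all off-diagonal
# distances are equal the rescaling is skipped. Returns both raw and scaled.
scaled_distances <- function(positions) {
  Draw <- as.matrix(stats::dist(positions))
  off <- Draw[upper.tri(Draw)]
  if (length(off) && max(off) > min(off)) {
    Dsc <- 1 + 3 * (Draw - min(off)) / (max(off) - min(off))
  } else {
    Dsc <- Draw
  }
  # zero-distance pairs (incl. the diagonal) are masked out downstream; give
  # them a harmless positive placeholder so s() stays well defined
  Dsc[Draw == 0] <- 1
  list(raw = Draw, scaled = Dsc)
}

# Social displacement term for all agents at once:
#   soc[i, ] = sum_{j != i} c^2/2 * s(d_ij) * (x_j - x_i) / d_ij
# with d_ij the scaled distance; zero raw-distance pairs contribute zero.
social_matrix <- function(positions, c, params) {
  dd <- scaled_distances(positions)
  S <- (c^2 / 2) * social_force(dd$scaled, params$f_intensity, params$l_scale) / dd$scaled
  S[dd$raw == 0] <- 0        # coincident agents (and the diagonal) drop out
  unname(S %*% positions - rowSums(S) * positions)
}

#' Continuous grasshopper displacement for one agent
#'
#' Computes the pre-binarization displacement
#' `v_i = c * sum_{j != i} [ c (ub - lb)/2 * s(d_ij) * (x_j - x_i)/d_ij ] +
#' attractor` with `ub = 1`, `lb = 0`, and pairwise distances rescaled into
#' `[1, 4]` before entering the social force. Coincident agents contribute
#' zero, so the result is always finite.
#'
#' @param state List with element `positions` (`P x D` binary matrix).
#' @param agent Row index of the agent to move.
#' @param attractor Bit vector of length `D` the agent is drawn toward.
#' @param c Current exploration--exploitation coefficient.
#' @param params A [goa_params()] object (social-force constants).
#' @return Numeric displacement vector of length `D`.
#' @export
goa_displacement <- function(state, agent, attractor, c, params = goa_params()) {
  positions <- state$positions
  if (length(attractor) != ncol(positions)) stop("attractor has wrong length")
  soc <- social_matrix(positions, c, params)
  soc[agent, ] + attractor
}

#' S-shaped binarization
#'
#' Maps a continuous displacement to bits with the logistic transfer
#' function: `bit[d] = 1` with probability `Tf(v[d]) = 1/(1 + exp(-v[d]))`
#' (probabilistic set rule, not a flip rule).
#'
#' @param v Numeric vector.
#' @return Integer 0/1 vector of the same length. Consumes the RNG stream.
#' @export
binarize <- function(v) {
  as.integer(stats::runif(length(v)) < stats::plogis(v))
}

#' Binary grasshopper optimization over fixed-length bit vectors
#'
#' Maximizes `fitness_fn` over `{0,1}^D`. Each iteration evaluates the
#' population, updates the elitist best, chooses a per-agent attractor
#' (variant `"bgoa"`: the current population best, i.e. a whole-population
#' tournament; variant `"ktgoa"`: an independent k-tournament winner per
#' agent), applies the continuous grasshopper displacement, and re-binarizes
#' through the S-shaped transfer function. The initial population is i.i.d.
#' Bernoulli(0.5) except agent 1, which is the all-ones vector, so the
#' unpruned/full solution is always in the initial pool.
#'
#' @param fitness_fn Function from a 0/1 vector of length `D` to a scalar
#'   fitness (higher is better). Must be total on `{0,1}^D`.
#' @param D Number of bits, `>= 1`.
#' @param params A [goa_params()] object.
#' @param variant `"ktgoa"` (default) or `"bgoa"`.
#' @param tie_break `"none"` (strict improvement only, default) or
#'   `"sparser"`: on exact fitness ties prefer the candidate with fewer set
#'   bits (used by the feature-selection wrapper).
#' @return List with `best_position`, `best_fitness`, and `history`, a data
#'   frame with one row per iteration (iteration 0 = initial population)
#'   holding `iteration`, `best_fitness` (elitist, non-decreasing),
#'   `mean_fitness`, and `n_active_bits_best`.
#' @export
goa_optimize <- function(fitness_fn, D, params = goa_params(),
                         variant = c("ktgoa", "bgoa"),
                         tie_break = c("none", "sparser")) {
  variant <- match.arg(variant)
  tie_break <- match.arg(tie_break)
  if (D < 1) stop("D must be >= 1")
  P <- params$pop_size
  k_eff <- if (variant == "bgoa") P else params$k

  eval_pop <- function(positions) {
    vapply(seq_len(nrow(positions)), function(i) {
      f <- tryCatch(fitness_fn(positions[i, ]), error = function(e)
        stop(sprintf("fitness_fn failed for agent %d: %s", i, conditionMessage(e))))
      as.numeric(f)
    }, numeric(1))
  }

  with_seed(params$seed, {
    positions <- matrix(stats::rbinom(P * D, 1L, 0.5), nrow = P, ncol = D)
    positions[1L, ] <- 1L

    best_position <- NULL
    best_fitness <- -Inf
    consider <- function(pos, fit) {
      better <- fit > best_fitness ||
        (tie_break == "sparser" && fit == best_fitness &&
           !is.null(best_position) && sum(pos) < sum(best_position))
      if (better) {
        best_position <<- pos
        best_fitness <<- fit
      }
    }

    history <- vector("list", params$max_iter + 1L)
    fitnesses <- eval_pop(positions)
    # stable order: on plain ties the earliest agent (the all-ones elite) wins
    for (i in order(fitnesses, decreasing = TRUE)) consider(positions[i, ], fitnesses[i])
    history[[1L]] <- data.frame(
      iteration = 0L, best_fitness = best_fitness,
      mean_fitness = mean(fitnesses), n_active_bits_best = sum(best_position)
    )

    for (it in seq_len(params$max_iter)) {
      c_it <- coefficient_schedule(it, params)
      soc <- social_matrix(positions, c_it, params)
      new_positions <- positions
      for (i in seq_len(P)) {
        att_idx <- tournament_select(fitnesses, k_eff)
        v <- soc[i, ] + positions[att_idx, ]
        new_positions[i, ] <- binarize(v)
      }
      positions <- new_positions
      fitnesses <- eval_pop(positions)
      for (i in seq_len(P)) consider(positions[i, ], fitnesses[i])
      history[[it + 1L]] <- data.frame(
        iteration = it, best_fitness = best_fitness,
        mean_fitness = mean(fitnesses), n_active_bits_best = sum(best_position)
      )
    }

    list(
      best_position = best_position,
      best_fitness = best_fitness,
      history = do.call(rbind, history)
    )
  })
}

#' Write an optimizer trace to CSV
#'
#' @param history History data frame from [goa_optimize()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
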