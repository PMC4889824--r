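#' Mixed integer/real search space
#'
#' Describes the box the Cuckoo Search explores. Integer dimensions (kernel
#' family index, polynomial degree) live on the real line internally and are
#' decoded by rounding after clipping; real dimensions may be linear or
#' log10-scaled (the optimizer then works uniformly in log space, which is
#' the natural parameterisation for SVM cost and kernel width).
#'
#' @param integer_dims List of `list(name, low, high)` inclusive integer
#'   ranges, or `NULL`.
#' @param real_dims List of `list(name, low, high, scale)` with
#'   `scale` in `c("linear", "log10")`, or `NULL`. Log-scaled bounds must be
#'   positive.
#' @return Object of class `search_space`.
#' @examples
#' search_space(
#'   integer_dims = list(list(name = "kernel", low = 0, high = 2)),
#'   real_dims = list(list(name = "cost", low = 2^-5, high = 2^15, scale = "log10"))
#' )
#' @export
search_space <- function(integer_dims = NULL, real_dims = NULL) {
  dims <- list()
  for (d in integer_dims) {
    stopifnot(is.character(d$name), d$low < d$high)
    dims[[length(dims) + 1L]] <- list(
      name = d$name, type = "integer",
      low = as.numeric(d$low), high = as.numeric(d$high),
      ilow = as.numeric(d$low), ihigh = as.numeric(d$high)
    )
  }
  for (d in real_dims) {
    scale <- if (is.null(d$scale)) "linear" else match.arg(d$scale, c("linear", "log10"))
    stopifnot(is.character(d$name), d$low < d$high)
    if (scale == "log10" && d$low <= 0) stop("log10-scaled dimension needs low > 0")
    dims[[length(dims) + 1L]] <- list(
      name = d$name, type = "real", scale = scale,
      low = as.numeric(d$low), high = as.numeric(d$high),
      ilow = if (scale == "log10") log10(d$low) else as.numeric(d$low),
      ihigh = if (scale == "log10") log10(d$high) else as.numeric(d$high)
    )
  }
  if (length(dims) == 0L) stop("search space needs at least one dimension")
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(names(dims))) stop("dimension names must be unique")
  structure(list(dims = dims), class = "search_space")
}

space_dim <- function(space) length(space$dims)

# 2 x d matrix of internal lower/upper bounds.
space_bounds <- function(space) {
  vapply(space$dims, function(d) c(d$ilow, d$ihigh), numeric(2))
}

clip_position <- function(position, space) {
  b <- space_bounds(space)
  pmin(pmax(position, b[1L, ]), b[2L, ])
}

#' Decode an internal position into named parameters
#'
#' Integer dimensions are rounded to the nearest in-range integer; log10
#' dimensions are exponentiated back to their natural scale.
#'
#' @param position Numeric vector in the space's internal representation.
#' @param space A [search_space()].
#' @return Named list of parameter values.
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "search_space"), length(position) == space_dim(space))
  position <- unname(clip_position(position, space))
  out <- vector("list", space_dim(space))
  names(out) <- names(space$dims)
  for (i in seq_along(space$dims)) {
    d <- space$dims[[i]]
    out[[i]] <- if (d$type == "integer") {
      as.integer(min(max(round(position[i]), d$low), d$high))
    } else if (d$scale == "log10") {
      10^position[i]
    } else {
      position[i]
    }
  }
  out
}

#' @rdname decode_position
#' @param params Named list (or vector) of parameter values on their natural
#'   scale.
#' @return `encode_position()` returns the internal numeric vector;
#'   `decode_position(encode_position(p))` is the identity on valid
#'   parameter settings.
#' @export
encode_position <- function(params, space) {
  stopifnot(inherits(space, "search_space"))
  vapply(space$dims, function(d) {
    v <- params[[d$name]]
    if (is.null(v)) stop("missing parameter: ", d$name)
    v <- as.numeric(v)
    if (d$type == "real" && d$scale == "log10") log10(v) else v
  }, numeric(1))
}

#' Cuckoo Search configuration
#'
#' Defaults follow the canonical Cuckoo Search description: a fixed
#' population of 25 nests, abandonment probability 0.25, Levy exponent 1.5
#' and step scale 0.01.
#'
#' @param n_nests Population size (>= 2).
#' @param pa_abandon Per-iteration probability that a non-elite nest is
#'   abandoned and rebuilt, in (0, 1) — the endpoints are admitted for the
#'   degenerate no-abandonment / always-abandon settings.
#' @param max_iterations Number of iterations (>= 1).
#' @param levy_alpha Levy stability exponent in (1, 2].
#' @param step_scale Positive scale of the Levy proposal step.
#' @param rng_seed Integer seed, or `NULL` to continue the current RNG
#'   stream (useful when the caller manages seeding).
#' @return Object of class `cs_config`.
#' @export
cs_config <- function(n_nests = 25L, pa_abandon = 0.25, max_iterations = 50L,
                      levy_alpha = 1.5, step_scale = 0.01, rng_seed = NULL) {
  n_nests <- as.integer(n_nests)
  max_iterations <- as.integer(max_iterations)
  stopifnot(n_nests >= 2L, max_iterations >= 1L,
            pa_abandon >= 0, pa_abandon <= 1,
            levy_alpha > 1, levy_alpha <= 2,
            step_scale > 0)
  structure(
    list(n_nests = n_nests, pa_abandon = pa_abandon,
         max_iterations = max_iterations, levy_alpha = levy_alpha,
         step_scale = step_scale, rng_seed = rng_seed),
    class = "cs_config"
  )
}

#' Mantegna scale constant for Levy-stable step generation
#'
#' `sigma_u(alpha) = [Gamma(1+alpha) sin(pi alpha / 2) /
#' (Gamma((1+alpha)/2) alpha 2^((alpha-1)/2))]^(1/alpha)`.
#'
#' @param alpha Stability exponent in (1, 2].
#' @return Positive scalar.
#' @export
levy_sigma_u <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1 || alpha > 2) {
    stop("`alpha` must be a single number in (1, 2]")
  }
  (gamma(1 + alpha) * sin(pi * alpha / 2) /
     (gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2)))^(1 / alpha)
}

#' Draw a Levy-flight step by Mantegna's algorithm
#'
#' Each component is `u / |v|^(1/alpha)` with `u ~ N(0, sigma_u^2)` and
#' `v ~ N(0, 1)`, giving a heavy-tailed symmetric step whose occasional long
#' jumps provide the global-exploration component of Cuckoo Search. At
#' `alpha = 2` the distribution degenerates to a Gaussian.
#'
#' @param alpha Stability exponent in (1, 2].
#' @param d Number of components.
#' @return Numeric vector of length `d`. Uses (and advances) R's global RNG
#'   stream.
#' @export
levy_step <- function(alpha, d) {
  sigma <- levy_sigma_u(alpha)
  u <- stats::rnorm(d, sd = sigma)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / alpha)
}

#' Propose a new nest position by a Levy flight toward the current best
#'
#' `new = position + step_scale * levy * (position - best_position)`,
#' componentwise, clipped to the search-space bounds. The displacement is
#' proportional to the distance from the current best, so steps shrink as a
#' nest closes in on the incumbent optimum while the heavy-tailed Levy
#' factor still fires occasional long exploratory jumps. The elite nest
#' itself has a zero displacement term and re-proposes its own position.
#'
#' @param position Current internal position.
#' @param best_position Internal position of the current best nest.
#' @param cfg A [cs_config()].
#' @param space A [search_space()].
#' @return Proposed internal position (within bounds).
#' @export
propose_cuckoo <- function(position, best_position, cfg, space) {
  step <- cfg$step_scale * levy_step(cfg$levy_alpha, space_dim(space)) *
    (position - best_position)
  clip_position(position + unname(step), space)
}

new_nest <- function(position) {
  list(position = position, primary = NA_real_, secondary = NA_real_)
}

nest_evaluated <- function(nest) is.finite(nest$primary)

#' Lexicographic fitness comparison with support-vector tie-break
#'
#' Higher primary fitness (cross-validated classification rate, percent)
#' wins; on an exact primary tie the lower secondary value (total
#' support-vector count) wins; on a full tie the incumbent `a` is retained.
#'
#' @param a Incumbent nest (list with `primary`, `secondary`).
#' @param b Challenger nest.
#' @return The better of the two nests.
#' @export
compare_fitness <- function(a, b) {
  if (!nest_evaluated(a) || !nest_evaluated(b)) {
    stop("cannot compare unevaluated nests")
  }
  if (b$primary > a$primary) return(b)
  if (b$primary < a$primary) return(a)
  if (b$secondary < a$secondary) return(b)
  a
}

#' Abandon and rebuild part of the population
#'
#' Each non-elite nest is independently abandoned with probability `pa` and
#' rebuilt by a biased random walk: `position + U(0,1) * (perm1 - perm2)`
#' componentwise, where `perm1`/`perm2` are the positions of two randomly
#' permuted population members, clipped to bounds. The elite (best) nest is
#' never abandoned. Rebuilt nests have their fitness invalidated; the
#' attribute `"replaced"` marks which nests were rebuilt.
#'
#' @param population List of nests (with evaluated fitness).
#' @param pa Abandonment probability in `[0, 1]`.
#' @param space A [search_space()].
#' @return The population with rebuilt positions and attribute `"replaced"`.
#' @export
abandon_and_rebuild <- function(population, pa, space) {
  n <- length(population)
  elite <- best_index(population)
  p1 <- sample.int(n)
  p2 <- sample.int(n)
  replaced <- logical(n)
  d <- space_dim(space)
  for (i in seq_len(n)) {
    if (i == elite) next
    if (stats::runif(1) < pa) {
      step <- stats::runif(d) *
        (population[[p1[i]]]$position - population[[p2[i]]]$position)
      population[[i]] <- new_nest(clip_position(population[[i]]$position + step, space))
      replaced[i] <- TRUE
    }
  }
  attr(population, "replaced") <- replaced
  population
}

best_index <- function(population) {
  best <- 1L
  for (i in seq_along(population)[-1L]) {
    if (!identical(compare_fitness(population[[best]], population[[i]]),
                   population[[best]])) {
      best <- i
    }
  }
  best
}

#' Cuckoo Search optimisation
#'
#' Maximises a (possibly stochastic) fitness function over a mixed
#' integer/real box. The initial population is uniform over the internal
#' bounds (log-scaled dimensions uniform in log space). Each iteration, every
#' nest proposes a Levy-flight cuckoo which is compared against a randomly
#' chosen nest and replaces it if better; then a fraction `pa_abandon` of
#' the non-elite nests is rebuilt by a biased random walk. The global best is
#' updated against every evaluation with [compare_fitness()], so the
#' best-so-far trace is monotone non-decreasing in primary fitness and,
#' within a primary tie, non-increasing in the secondary objective.
#'
#' @param fitness_fn Function taking the decoded named parameter list and
#'   returning `c(primary, secondary)` (or a list with those names):
#'   primary is maximised, secondary (e.g. support-vector count) is
#'   minimised on primary ties. A scalar return is treated as
#'   `secondary = 0`.
#' @param space A [search_space()].
#' @param cfg A [cs_config()]. When `cfg$rng_seed` is non-`NULL` the run is
#'   fully reproducible from that seed.
#' @return Object of class `cs_result`: list with `best` (elements
#'   `position`, `params`, `primary`, `secondary`), `trace` (data frame with
#'   `iteration`, `best_primary`, `best_secondary`; iteration 0 is the
#'   initial population) and `n_evaluations`.
#' @examples
#' sp <- search_space(real_dims = list(
#'   list(name = "x", low = -5, high = 5, scale = "linear"),
#'   list(name = "y", low = -5, high = 5, scale = "linear")))
#' res <- cs_optimize(function(p) -(p$x^2 + p$y^2), sp,
#'                    cs_config(n_nests = 15, max_iterations = 50, rng_seed = 1))
#' res$best$params
#' @export
cs_optimize <- function(fitness_fn, space, cfg = cs_config()) {
  stopifnot(inherits(space, "search_space"), inherits(cfg, "cs_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  d <- space_dim(space)
  b <- space_bounds(space)
  n_evals <- 0L
  evaluate <- function(nest) {
    res <- fitness_fn(decode_position(nest$position, space))
    if (is.list(res)) res <- c(res$primary, res$secondary)
    if (length(res) == 1L) res <- c(res, 0)
    if (!is.numeric(res) || length(res) != 2L || !is.finite(res[1L])) {
      stop("fitness_fn must return finite c(primary, secondary); got ",
           paste(format(res), collapse = ", "),
           " at ", paste(format(nest$position), collapse = ", "))
    }
    nest$primary <- res[1L]
    nest$secondary <- res[2L]
    n_evals <<- n_evals + 1L
    nest
  }

  population <- lapply(seq_len(cfg$n_nests), function(i) {
    evaluate(new_nest(stats::runif(d, b[1L, ], b[2L, ])))
  })
  best <- population[[best_index(population)]]
  trace <- data.frame(iteration = 0L, best_primary = best$primary,
                      best_secondary = best$secondary)

  for (it in seq_len(cfg$max_iterations)) {
    for (i in seq_len(cfg$n_nests)) {
      prop <- evaluate(new_nest(propose_cuckoo(
        population[[i]]$position, best$position, cfg, space)))
      best <- compare_fitness(best, prop)
      j <- sample.int(cfg$n_nests, 1L)
      population[[j]] <- compare_fitness(population[[j]], prop)
    }
    population <- abandon_and_rebuild(population, cfg$pa_abandon, space)
    for (i in seq_len(cfg$n_nests)) {
      if (!nest_evaluated(population[[i]])) {
        population[[i]] <- evaluate(population[[i]])
        best <- compare_fitness(best, population[[i]])
      }
    }
    trace <- rbind(trace, data.frame(iteration = it, best_primary = best$primary,
                                     best_secondary = best$secondary))
  }

  structure(
    list(best = list(position = best$position,
                     params = decode_position(best$position, space),
                     primary = best$primary, secondary = best$secondary),
         trace = trace, n_evaluations = n_evals),
    class = "cs_result"
  )
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("cs_result: best primary %.4f (secondary %g) after %d evaluations\n",
              x$best$primary, x$best$secondary, x$n_evaluations))
  cat("  params:", paste(names(x$best$params),
                         vapply(x$best$params, function(v) format(v, digits = 4), ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
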