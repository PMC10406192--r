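## Constraint handling --------------------------------------------------------

#' Validate a constraint table for the event-timing search
#'
#' A constraint table has one row per event with columns `event`,
#' `start_time` (earliest allowed onset, s), `end_time` (latest allowed
#' offset, s) and optional `min_duration` / `max_duration` (s). Every
#' candidate solution in the search keeps each event inside
#' `[start_time, end_time]` with a duration inside the stated bounds.
#'
#' @param constraints Data frame of per-event constraints.
#' @param min_duration_floor Duration floor applied where `min_duration` is
#'   absent or `NA`; [optimize_events()] uses one high-resolution sample,
#'   `tr / f`.
#' @return A validated tibble with columns `event`, `start_time`,
#'   `end_time`, `min_duration`, `max_duration` (bounds filled in).
#' @export
as_constraints <- function(constraints, min_duration_floor = 1e-3) {
  if (!is.data.frame(constraints)) abort("`constraints` must be a data frame.")
  .require_columns(constraints, c("event", "start_time", "end_time"),
                   "`constraints`")
  .assert_scalar_num(min_duration_floor, "min_duration_floor", positive = TRUE)
  out <- tibble(
    event = as.character(constraints$event),
    start_time = as.numeric(constraints$start_time),
    end_time = as.numeric(constraints$end_time),
    min_duration = if ("min_duration" %in% names(constraints))
      as.numeric(constraints$min_duration) else NA_real_,
    max_duration = if ("max_duration" %in% names(constraints))
      as.numeric(constraints$max_duration) else NA_real_
  )
  if (nrow(out) == 0) abort("`constraints` must contain at least one event.")
  if (anyDuplicated(out$event)) abort("`constraints` has duplicated event names.")
  if (any(!is.finite(out$start_time)) || any(!is.finite(out$end_time))) {
    abort("`constraints`: start_time and end_time must be finite.")
  }
  bad <- out$start_time >= out$end_time
  if (any(bad)) {
    abort(sprintf("`constraints`: start_time must be < end_time (violated for %s).",
                  paste(out$event[bad], collapse = ", ")))
  }
  window <- out$end_time - out$start_time
  out$min_duration <- ifelse(is.na(out$min_duration),
                             pmin(min_duration_floor, window),
                             out$min_duration)
  out$max_duration <- ifelse(is.na(out$max_duration), window, out$max_duration)
  if (any(out$min_duration < 0)) abort("`constraints`: min_duration must be >= 0.")
  infeasible <- out$min_duration > out$max_duration |
    out$max_duration > window + 1e-12 | out$min_duration > window + 1e-12
  if (any(infeasible)) {
    abort(sprintf("infeasible constraint(s) for %s: need min_duration <= max_duration <= end_time - start_time.",
                  paste(out$event[infeasible], collapse = ", ")))
  }
  out
}

.check_satisfies <- function(model, cs, tol = 1e-9) {
  on <- model$start_time
  off <- model$start_time + model$duration
  all(on >= cs$start_time - tol, off <= cs$end_time + tol,
      model$duration >= cs$min_duration - tol,
      model$duration <= cs$max_duration + tol)
}

## GA primitives --------------------------------------------------------------

#' Draw a random population of constraint-satisfying event models
#'
#' For each event an onset is drawn uniformly from the feasible onset range
#' and a duration uniformly from the feasible duration range given that
#' onset, so every drawn model satisfies the constraints exactly. Uses the
#' current RNG state; seed it (e.g. with [withr::with_seed()]) for
#' reproducibility.
#'
#' @param constraints Constraint table (see [as_constraints()]).
#' @param size Number of models to draw.
#' @param min_duration_floor Passed to [as_constraints()].
#' @return A list of `size` event-model tibbles.
#' @export
init_population <- function(constraints, size, min_duration_floor = 1e-3) {
  cs <- as_constraints(constraints, min_duration_floor)
  size <- .assert_count(size, "size", min = 1L)
  lapply(seq_len(size), function(i) {
    onset <- runif(nrow(cs), cs$start_time, cs$end_time - cs$min_duration)
    dmax <- pmin(cs$max_duration, cs$end_time - onset)
    duration <- runif(nrow(cs), cs$min_duration, dmax)
    tibble(event = cs$event, start_time = onset, duration = duration)
  })
}

#' Roulette-wheel parent selection
#'
#' Returns one index with probability proportional to `max(fitness, 0)`.
#' If no fitness is positive, selection falls back to uniform (weighted
#' R-squared can be non-positive on residualised data).
#'
#' @param fitnesses Numeric vector of fitness values.
#' @return A single index into `fitnesses`.
#' @export
select_parent <- function(fitnesses) {
  if (!is.numeric(fitnesses) || length(fitnesses) == 0) {
    abort("`fitnesses` must be a nonempty numeric vector.")
  }
  w <- pmax(fitnesses, 0)
  if (sum(w) <= 0) w <- rep(1, length(w))
  sample.int(length(w), 1L, prob = w)
}

#' Single-point crossover on the event list
#'
#' The child takes the first `ceiling(n / 2)` events (their onset and
#' duration) from the first parent and the remaining events from the second
#' parent, so with an odd number of events the extra event comes from the
#' first parent.
#'
#' @param p1,p2 Event-model data frames with identical event names in
#'   identical order.
#' @return The child event-model tibble.
#' @export
crossover <- function(p1, p2) {
  p1 <- .as_event_model(p1, "p1")
  p2 <- .as_event_model(p2, "p2")
  if (!identical(p1$event, p2$event)) {
    abort("`p1` and `p2` must share the same events in the same order.")
  }
  n <- nrow(p1)
  k <- ceiling(n / 2)
  dplyr::bind_rows(p1[seq_len(k), ], p2[setdiff(seq_len(n), seq_len(k)), ])
}

#' Mutate event onsets and offsets within their constraints
#'
#' Each event's onset and offset is independently perturbed with probability
#' `rate` by a Gaussian step whose standard deviation is `sd_frac` times the
#' width of that event's constraint window. Perturbed endpoints are clipped
#' to the window; if a duration bound is violated, the endpoint that was not
#' mutated is shifted minimally to restore feasibility, so the result always
#' satisfies the constraints. Uses the current RNG state.
#'
#' @param model Event-model data frame satisfying `constraints`.
#' @param constraints Constraint table (see [as_constraints()]).
#' @param rate Per-endpoint mutation probability in `[0, 1]`.
#' @param sd_frac Gaussian step SD as a fraction of the constraint window.
#' @param min_duration_floor Passed to [as_constraints()].
#' @return The mutated event-model tibble.
#' @export
mutate_model <- function(model, constraints, rate, sd_frac = 0.1,
                         min_duration_floor = 1e-3) {
  model <- .as_event_model(model)
  cs <- as_constraints(constraints, min_duration_floor)
  if (!identical(model$event, cs$event)) {
    abort("`model` and `constraints` must share the same events in the same order.")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    abort("`rate` must be a probability in [0, 1].")
  }
  .assert_scalar_num(sd_frac, "sd_frac", positive = TRUE)
  if (rate == 0) return(model)

  on <- model$start_time
  off <- model$start_time + model$duration
  for (e in seq_len(nrow(model))) {
    w <- cs$end_time[e] - cs$start_time[e]
    mut_on <- runif(1) < rate
    mut_off <- runif(1) < rate
    if (mut_on) {
      on[e] <- min(max(on[e] + rnorm(1, 0, sd_frac * w), cs$start_time[e]),
                   cs$end_time[e])
    }
    if (mut_off) {
      off[e] <- min(max(off[e] + rnorm(1, 0, sd_frac * w), cs$start_time[e]),
                    cs$end_time[e])
    }
    fixed <- .repair_interval(on[e], off[e], mut_on, mut_off, cs[e, ])
    on[e] <- fixed[1]
    off[e] <- fixed[2]
  }
  tibble(event = model$event, start_time = on, duration = off - on)
}

## Restore onset < offset and the duration bounds, moving the endpoint that
## was not mutated (ties resolved toward moving the offset).
.repair_interval <- function(on, off, mut_on, mut_off, c1) {
  move_off <- !(mut_off && !mut_on)
  d <- off - on
  if (d < c1$min_duration) {
    if (move_off) {
      off <- on + c1$min_duration
      if (off > c1$end_time) {
        off <- c1$end_time
        on <- off - c1$min_duration
      }
    } else {
      on <- off - c1$min_duration
      if (on < c1$start_time) {
        on <- c1$start_time
        off <- on + c1$min_duration
      }
    }
  } else if (d > c1$max_duration) {
    if (move_off) off <- on + c1$max_duration else on <- off - c1$max_duration
  }
  c(on, off)
}

## Search driver --------------------------------------------------------------

#' Search for event timings that maximise weighted model fit
#'
#' Runs an elitist genetic algorithm over event onsets and durations. Each
#' candidate solution assigns every event an onset and offset inside its
#' constraint window; fitness is the ROI-weight-averaged R-squared of the
#' corresponding GLM (see [evaluate_model()]). Each iteration evaluates the
#' population, copies the top `elitism` fraction unchanged into the next
#' generation, and fills the remainder with children produced by
#' fitness-proportional parent selection, [crossover()] and
#' [mutate_model()]. One search is run independently per constraint set.
#'
#' @inheritParams evaluate_model
#' @param constraints A constraint data frame (columns `event`,
#'   `start_time`, `end_time`, optional `min_duration`, `max_duration`) or a
#'   list of such data frames, one search per set.
#' @param population Population size (>= 2).
#' @param iter Number of iterations.
#' @param mutation_rate Per-endpoint mutation probability.
#' @param elitism Fraction of best solutions copied unchanged each
#'   iteration, in `[0, 1]`; any positive value guarantees a nondecreasing
#'   best-fitness trace.
#' @param mutation_sd_frac Gaussian mutation step SD as a fraction of each
#'   event's constraint window.
#' @param seed Integer seed making the whole search reproducible; `NULL`
#'   uses (and advances) the current RNG state.
#' @param resume An `event_search` from a previous run with the same
#'   constraint sets; the search continues from its final populations and
#'   appends to its fitness traces.
#' @param initial_models Optional list (parallel to the constraint sets) of
#'   event-model data frames injected into the corresponding initial
#'   population, e.g. a theoretical model to guarantee the search never
#'   returns anything worse.
#' @return An object of class `event_search`: per constraint set the best
#'   model, its fitness, the per-iteration best-fitness trace and the final
#'   population, plus the full configuration (including the seed). Use
#'   [get_best_models()], [tidy()], [glance()], [autoplot()] /
#'   [plot_fitness()].
#' @examples
#' model <- data.frame(event = "on", start_time = 1, duration = 4)
#' amps <- data.frame(roi = c("r1", "r2", "r3"), on = c(1, 0.6, 0.3))
#' bold <- simulate_bold(simulation_spec(model, amps, tr = 1, n_frames = 16))
#' cs <- data.frame(event = "on", start_time = 0, end_time = 8)
#' res <- optimize_events(bold, cs, tr = 1, population = 10, iter = 5, seed = 1)
#' get_best_models(res)
#' @export
optimize_events <- function(bold, constraints, tr, hrf = hrf_spec(tr = tr),
                            roi_weights = NULL, population = 100, iter = 100,
                            mutation_rate = 0.1, elitism = 0.1,
                            mutation_sd_frac = 0.1, seed = NULL,
                            resume = NULL, initial_models = NULL) {
  population <- .assert_count(population, "population", min = 2L)
  iter <- .assert_count(iter, "iter", min = 1L)
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1) {
    abort("`mutation_rate` must be a probability in [0, 1].")
  }
  if (!is.numeric(elitism) || elitism < 0 || elitism > 1) {
    abort("`elitism` must be in [0, 1].")
  }
  if (is.data.frame(constraints)) constraints <- list(constraints)
  if (!is.list(constraints) || length(constraints) == 0) {
    abort("`constraints` must be a data frame or a nonempty list of data frames.")
  }
  set_names <- names(constraints)
  if (is.null(set_names) || any(set_names == "")) {
    set_names <- paste0("set_", seq_along(constraints))
  }
  floor_dur <- tr / hrf$f
  cs_list <- lapply(constraints, as_constraints, min_duration_floor = floor_dur)

  bm <- .as_bold_matrix(bold, tr)
  weights <- .resolve_weights(bm$rois, roi_weights)
  ctx <- .eval_ctx(bm, hrf, weights)

  if (!is.null(resume)) {
    if (!inherits(resume, "event_search")) {
      abort("`resume` must be an event_search object.")
    }
    if (length(resume$results) != length(cs_list)) {
      abort("`resume` has a different number of constraint sets.")
    }
    for (k in seq_along(cs_list)) {
      if (!identical(resume$results[[k]]$constraints$event, cs_list[[k]]$event)) {
        abort(sprintf("`resume` constraint set %d has different events.", k))
      }
    }
  }
  if (!is.null(initial_models) && length(initial_models) != length(cs_list)) {
    abort("`initial_models` must have one entry (or NULL) per constraint set.")
  }

  run_all <- function() {
    purrr::map(seq_along(cs_list), function(k) {
      .ga_one_set(
        cs = cs_list[[k]], ctx = ctx, population = population, iter = iter,
        mutation_rate = mutation_rate, elitism = elitism,
        mutation_sd_frac = mutation_sd_frac, floor_dur = floor_dur,
        start_population = if (!is.null(resume))
          resume$results[[k]]$population else NULL,
        seed_model = if (!is.null(initial_models)) initial_models[[k]] else NULL
      )
    })
  }
  results <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  for (k in seq_along(results)) {
    if (!is.null(resume)) {
      results[[k]]$trace <- c(resume$results[[k]]$trace, results[[k]]$trace)
    }
    results[[k]]$set <- set_names[k]
  }
  names(results) <- set_names

  structure(
    list(
      results = results,
      config = list(population = population, iter = iter,
                    mutation_rate = mutation_rate, elitism = elitism,
                    mutation_sd_frac = mutation_sd_frac, seed = seed,
                    tr = tr, hrf = hrf, resumed = !is.null(resume)),
      weights = weights
    ),
    class = "event_search"
  )
}

## One GA run for a single constraint set. Solutions are carried as onset and
## offset vectors; identical candidates within a run are evaluated once.
.ga_one_set <- function(cs, ctx, population, iter, mutation_rate, elitism,
                        mutation_sd_frac, floor_dur, start_population = NULL,
                        seed_model = NULL) {
  n_ev <- nrow(cs)
  cache <- new.env(parent = emptyenv())

  eval_one <- function(sol) {
    key <- paste(signif(sol, 12), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    on <- sol[seq_len(n_ev)]
    off <- sol[n_ev + seq_len(n_ev)]
    R <- .ctx_regressors(ctx, on, off - on, cs$event)
    val <- .ctx_weighted_r2(ctx, R)
    cache[[key]] <- val
    val
  }

  as_sol <- function(model) c(model$start_time,
                              model$start_time + model$duration)
  as_model <- function(sol) tibble(
    event = cs$event, start_time = sol[seq_len(n_ev)],
    duration = sol[n_ev + seq_len(n_ev)] - sol[seq_len(n_ev)]
  )

  pop <- if (!is.null(start_population)) {
    if (length(start_population) != population) {
      abort("`resume` population size differs from `population`.")
    }
    lapply(start_population, as_sol)
  } else {
    lapply(init_population(cs, population, floor_dur), as_sol)
  }
  if (!is.null(seed_model)) {
    m <- .as_event_model(seed_model, "initial_models")
    if (!identical(m$event, cs$event)) {
      abort("`initial_models` events must match the constraint set.")
    }
    if (!.check_satisfies(m, cs)) {
      abort("`initial_models` entry violates its constraint set.")
    }
    pop[[1]] <- as_sol(m)
  }

  fit <- vapply(pop, eval_one, numeric(1))
  n_elite <- if (elitism > 0) max(1L, floor(elitism * population)) else 0L
  trace <- numeric(iter)

  for (i in seq_len(iter)) {
    ord <- order(fit, decreasing = TRUE)   # stable: ties broken by index
    new_pop <- pop[ord[seq_len(n_elite)]]
    while (length(new_pop) < population) {
      i1 <- select_parent(fit)
      i2 <- select_parent(fit)
      child_on <- c(pop[[i1]][seq_len(ceiling(n_ev / 2))],
                    pop[[i2]][setdiff(seq_len(n_ev), seq_len(ceiling(n_ev / 2)))])
      child_off <- c(pop[[i1]][n_ev + seq_len(ceiling(n_ev / 2))],
                     pop[[i2]][n_ev + setdiff(seq_len(n_ev), seq_len(ceiling(n_ev / 2)))])
      child <- .mutate_sol(child_on, child_off, cs, mutation_rate,
                           mutation_sd_frac)
      new_pop[[length(new_pop) + 1L]] <- child
    }
    pop <- new_pop
    fit <- vapply(pop, eval_one, numeric(1))
    trace[i] <- max(fit)
  }

  best <- which.max(fit)
  list(
    constraints = cs,
    best_model = as_model(pop[[best]]),
    best_fitness = fit[best],
    trace = trace,
    population = lapply(pop, as_model),
    population_fitness = fit
  )
}

## vectorless mutate on the (onset, offset) encoding; mirrors mutate_model()
.mutate_sol <- function(on, off, cs, rate, sd_frac) {
  if (rate > 0) {
    for (e in seq_along(on)) {
      w <- cs$end_time[e] - cs$start_time[e]
      mut_on <- runif(1) < rate
      mut_off <- runif(1) < rate
      if (mut_on) {
        on[e] <- min(max(on[e] + rnorm(1, 0, sd_frac * w), cs$start_time[e]),
                     cs$end_time[e])
      }
      if (mut_off) {
        off[e] <- min(max(off[e] + rnorm(1, 0, sd_frac * w), cs$start_time[e]),
                      cs$end_time[e])
      }
      if (mut_on || mut_off || off[e] - on[e] < cs$min_duration[e] ||
          off[e] - on[e] > cs$max_duration[e]) {
        fixed <- .repair_interval(on[e], off[e], mut_on, mut_off, cs[e, ])
        on[e] <- fixed[1]
        off[e] <- fixed[2]
      }
    }
  }
  c(on, off)
}

#' Extract the best models (or their fitness) from a search
#'
#' @param res An `event_search` from [optimize_events()].
#' @param return_fitness If `TRUE`, return the best weighted R-squared per
#'   constraint set instead of the models.
#' @return A named list of event-model tibbles, or a named numeric vector
#'   of fitness values.
#' @export
get_best_models <- function(res, return_fitness = FALSE) {
  if (!inherits(res, "event_search")) abort("`res` must be an event_search object.")
  if (return_fitness) {
    vapply(res$results, function(r) r$best_fitness, numeric(1))
  } else {
    lapply(res$results, function(r) r$best_model)
  }
}

#' @export
print.event_search <- function(x, ...) {
  cat(sprintf("<event_search> %d constraint set(s), population %d, %d iteration(s)%s\n",
              length(x$results), x$config$population, x$config$iter,
              if (isTRUE(x$config$resumed)) " (resumed)" else ""))
  for (r in x$results) {
    cat(sprintf("  %s: best weighted R2 = %.4f\n", r$set, r$best_fitness))
  }
  invisible(x)
}

#' @rdname optimize_events
#' @param x,object An `event_search`.
#' @param ... Unused.
#' @method tidy event_search
#' @export
tidy.event_search <- function(x, ...) {
  purrr::map_dfr(x$results, function(r) {
    dplyr::mutate(r$best_model, constraint_set = r$set,
                  fitness = r$best_fitness, .before = 1)
  })
}

#' @rdname optimize_events
#' @method glance event_search
#' @export
glance.event_search <- function(x, ...) {
  fits <- vapply(x$results, function(r) r$best_fitness, numeric(1))
  tibble(
    n_constraint_sets = length(x$results),
    best_fitness = max(fits),
    population = x$config$population,
    iterations = length(x$results[[1]]$trace),
    seed = if (is.null(x$config$seed)) NA_integer_ else x$config$seed
  )
}

#' Per-iteration best-fitness trace of a search
#'
#' Convergence diagnostic: the best weighted R-squared in the population at
#' each iteration, per constraint set. With any elitism the trace is
#' nondecreasing; a flat tail suggests the search has converged.
#'
#' @param res An `event_search`.
#' @return A tibble with columns `constraint_set`, `iteration`, `fitness`.
#' @seealso [plot_fitness()]
#' @export
fitness_trace <- function(res) {
  if (!inherits(res, "event_search")) abort("`res` must be an event_search object.")
  purrr::map_dfr(res$results, function(r) {
    tibble(constraint_set = r$set,
           iteration = seq_along(r$trace),
           fitness = r$trace)
  })
}
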