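test_that("constraint validation fills bounds and rejects infeasible windows", {
  cs <- as_constraints(data.frame(event = "a", start_time = 0, end_time = 4),
                       min_duration_floor = 0.01)
  expect_equal(cs$min_duration, 0.01)
  expect_equal(cs$max_duration, 4)

  expect_error(as_constraints(data.frame(event = "a", start_time = 3,
                                         end_time = 2)), "start_time")
  expect_error(as_constraints(data.frame(event = "a", start_time = 0,
                                         end_time = 2, min_duration = 3)),
               "infeasible")
  expect_error(as_constraints(data.frame(event = "a", start_time = 0,
                                         end_time = 2, min_duration = 1.5,
                                         max_duration = 1)), "infeasible")
})

test_that("initial populations satisfy their constraints exactly", {
  cs <- data.frame(
    event = c("a", "b"), start_time = c(0, 5), end_time = c(10, 9),
    min_duration = c(1, NA), max_duration = c(4, NA)
  )
  withr::with_seed(2, {
    pop <- init_population(cs, 1000, min_duration_floor = 0.01)
    expect_length(pop, 1000)
    vcs <- as_constraints(cs, 0.01)
    ok <- vapply(pop, fmrievents:::.check_satisfies, logical(1), cs = vcs)
    expect_true(all(ok))
    # onsets and offsets fill their windows but never leave them
    on_a <- vapply(pop, function(m) m$start_time[1], numeric(1))
    off_a <- on_a + vapply(pop, function(m) m$duration[1], numeric(1))
    expect_gte(min(on_a), 0)
    expect_lte(max(off_a), 10)
  })

  # degenerate window forces the unique solution
  deg <- data.frame(event = "a", start_time = 0, end_time = 2.5,
                    min_duration = 2.5)
  withr::with_seed(3, {
    pop <- init_population(deg, 50)
    expect_true(all(vapply(pop, function(m)
      m$start_time == 0 && m$duration == 2.5, logical(1))))
  })
})

test_that("roulette-wheel selection is fitness-proportional", {
  withr::with_seed(4, {
    expect_true(all(replicate(50, select_parent(c(1, 0))) == 1))
    draws <- replicate(1e5, select_parent(c(0.25, 0.75)))
    expect_equal(mean(draws == 2), 0.75, tolerance = 0.01)
    # equal fitness -> uniform; all non-positive -> uniform fallback
    u <- replicate(1e4, select_parent(c(0.5, 0.5)))
    expect_equal(mean(u == 1), 0.5, tolerance = 0.03)
    neg <- replicate(1e4, select_parent(c(-0.2, -0.9)))
    expect_equal(mean(neg == 1), 0.5, tolerance = 0.03)
  })
})

test_that("crossover takes the first half (+1 when odd) from the first parent", {
  p1 <- data.frame(event = c("a", "b", "c"), start_time = c(0, 3, 10),
                   duration = c(2.5, 9.5, 3))
  p2 <- data.frame(event = c("a", "b", "c"), start_time = c(1, 4, 11),
                   duration = c(1, 8, 2))
  child <- crossover(p1, p2)
  expect_equal(child$start_time, c(0, 3, 11))
  expect_equal(child$duration, c(2.5, 9.5, 2))

  # even number of events: exactly half from each parent
  child2 <- crossover(p1[1:2, ], p2[1:2, ])
  expect_equal(child2$start_time, c(0, 4))

  # identical parents reproduce themselves
  expect_equal(crossover(p1, p1)$start_time, p1$start_time)
  expect_error(crossover(p1, p2[c(2, 1, 3), ]), "same events")
})

test_that("mutation is an identity at rate 0 and preserves feasibility at rate 1", {
  cs <- data.frame(event = c("a", "b"), start_time = c(0, 5),
                   end_time = c(4, 15), min_duration = c(0.5, 2),
                   max_duration = c(3, 8))
  vcs <- as_constraints(cs, 0.01)
  m <- data.frame(event = c("a", "b"), start_time = c(1, 6),
                  duration = c(2, 5))
  expect_equal(mutate_model(m, cs, rate = 0), fmrievents:::.as_event_model(m))

  withr::with_seed(6, {
    changed <- 0
    for (i in 1:500) {
      mm <- mutate_model(m, cs, rate = 1)
      expect_true(fmrievents:::.check_satisfies(mm, vcs))
      expect_true(all(mm$duration > 0))
      if (!isTRUE(all.equal(mm, fmrievents:::.as_event_model(m)))) {
        changed <- changed + 1
      }
    }
    expect_gt(changed, 490) # overwhelmingly different from the input
  })
})

test_that("a triggered offset mutation can shorten an event within its window", {
  cs <- data.frame(event = "e2", start_time = 10, end_time = 15)
  m <- data.frame(event = "e2", start_time = 10, duration = 2.5)
  withr::with_seed(8, {
    shorter <- FALSE
    for (i in 1:200) {
      mm <- mutate_model(m, cs, rate = 1)
      if (mm$start_time == 10 && mm$duration < 2.5) shorter <- TRUE
    }
    expect_true(shorter)
  })
})

test_that("the search honours its contracts: monotone trace, feasibility, determinism, fixed point", {
  bold <- fix_bold(noise_sd = 0.1, seed = 13)
  cs <- fix_constraints()
  res <- optimize_events(bold, cs, tr = 1, population = 20, iter = 10,
                         seed = 99)
  r <- res$results[[1]]

  # population size constant; every individual feasible
  expect_length(r$population, 20)
  vcs <- as_constraints(cs, 0.01)
  expect_true(all(vapply(r$population, fmrievents:::.check_satisfies,
                         logical(1), cs = vcs)))

  # elitist trace is nondecreasing and the best model is feasible
  expect_true(all(diff(r$trace) >= -1e-12))
  expect_true(fmrievents:::.check_satisfies(r$best_model, vcs))

  # fixed seed reproduces the whole result
  res2 <- optimize_events(bold, cs, tr = 1, population = 20, iter = 10,
                          seed = 99)
  expect_equal(get_best_models(res), get_best_models(res2))
  expect_equal(fitness_trace(res), fitness_trace(res2))

  # zero mutation + full elitism leaves the population a fixed point
  fixed <- optimize_events(bold, cs, tr = 1, population = 10, iter = 5,
                           mutation_rate = 0, elitism = 1, seed = 7)
  fr <- fixed$results[[1]]
  expect_equal(length(unique(fr$trace)), 1L)
  first_gen <- withr::with_seed(7, init_population(as_constraints(cs, 0.01), 10))
  sort_pop <- function(p) p[order(vapply(p, function(m) m$start_time[1],
                                         numeric(1)))]
  expect_equal(sort_pop(fr$population), sort_pop(first_gen),
               tolerance = 1e-12)
})

test_that("fitness delegates to evaluate_model's weighted R2", {
  bold <- fix_bold(noise_sd = 0)
  expect_equal(fitness(fix_model(), bold, tr = 1), 1, tolerance = 1e-9)
  # uniform weights: fitness equals the mean R2
  noisy <- fix_bold(noise_sd = 0.2, seed = 17)
  fit <- evaluate_model(noisy, fix_model(), tr = 1)
  expect_equal(fitness(fix_model(), noisy, tr = 1), glance(fit)$r2_mean,
               tolerance = 1e-12)
})

test_that("a seeded-in generating model is never beaten downward", {
  bold <- fix_bold(noise_sd = 0)
  res <- optimize_events(bold, fix_constraints(), tr = 1, population = 12,
                         iter = 5, seed = 31,
                         initial_models = list(fix_model()))
  truth_fit <- fitness(fix_model(), bold, tr = 1)
  expect_gte(get_best_models(res, return_fitness = TRUE)[[1]],
             truth_fit - 1e-6)
})

test_that("resuming continues from the final population and appends the trace", {
  bold <- fix_bold(noise_sd = 0.1, seed = 23)
  cs <- fix_constraints()
  first <- optimize_events(bold, cs, tr = 1, population = 15, iter = 4,
                           seed = 5)
  second <- optimize_events(bold, cs, tr = 1, population = 15, iter = 3,
                            seed = 6, resume = first)
  expect_length(second$results[[1]]$trace, 7L)
  expect_equal(second$results[[1]]$trace[1:4], first$results[[1]]$trace)
  # elitism keeps the resumed trace monotone across the boundary
  expect_true(all(diff(second$results[[1]]$trace) >= -1e-12))
  expect_error(optimize_events(bold, list(cs, cs), tr = 1, population = 15,
                               iter = 2, resume = first), "number of constraint")
})

test_that("get_best_models returns one entry per constraint set", {
  bold <- fix_bold(noise_sd = 0.1, seed = 29)
  loose <- data.frame(event = c("encoding", "delay", "response"),
                      start_time = c(0, 1, 9), end_time = c(2.5, 11, 14))
  res <- optimize_events(bold, list(strict = fix_constraints(), loose = loose),
                         tr = 1, population = 12, iter = 4, seed = 41)
  models <- get_best_models(res)
  expect_named(models, c("strict", "loose"))
  fits <- get_best_models(res, return_fitness = TRUE)
  expect_equal(unname(fits),
               vapply(res$results, function(r) r$trace[length(r$trace)],
                      numeric(1), USE.NAMES = FALSE))
  t <- tidy(res)
  expect_equal(nrow(t), 6L)
  expect_equal(glance(res)$n_constraint_sets, 2L)
})
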