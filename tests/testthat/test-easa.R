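# Self-adaptive evolution strategy and constraint filtering.

# Always-feasible stub statistics around an arbitrary fitness value.
stub_stats <- function(fit) {
  yield_stats(c(fit, fit), c(0.5, 0.5))
}

test_that("initial parents include the cultivar exactly once", {
  ranges <- default_trait_ranges()
  cv <- default_cultivar()
  p1 <- sample_initial_parents(ranges, 1, cv, seed = 3)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$genome, cv$traits)

  p25 <- sample_initial_parents(ranges, 25, cv, seed = 3)
  expect_length(p25, 25)
  expect_equal(p25[[1]]$genome, cv$traits)
  for (p in p25) {
    expect_true(all(p$genome >= ranges$lower & p$genome <= ranges$upper))
    expect_equal(unname(p$step_sizes),
                 0.1 * (ranges$upper - ranges$lower))
  }
  expect_identical(p25, sample_initial_parents(ranges, 25, cv, seed = 3))
  other <- sample_initial_parents(ranges, 25, cv, seed = 4)
  expect_equal(other[[1]]$genome, p25[[1]]$genome)
  expect_false(identical(other[[2]]$genome, p25[[2]]$genome))

  out <- cv
  out$traits[["P_h"]] <- 500
  expect_error(sample_initial_parents(ranges, 5, out, seed = 1), "ranges")
})

test_that("mutation respects bounds, adapts steps, and is reproducible", {
  ranges <- default_trait_ranges()
  cv <- default_cultivar()
  # start from a corner so reflection is exercised hard
  parent <- sample_initial_parents(ranges, 1, cv, seed = 1)[[1]]
  parent$genome[] <- ranges$upper
  parent$step_sizes[] <- 0.5 * (ranges$upper - ranges$lower)
  set.seed(99)
  for (i in 1:10000) {
    child <- mutate_candidate(parent, ranges)
    if (i <= 50) {
      expect_true(all(child$genome >= ranges$lower &
                        child$genome <= ranges$upper))
      expect_true(all(child$step_sizes > 0))
    }
  }
  set.seed(99)
  all_in <- TRUE
  for (i in 1:10000) {
    child <- mutate_candidate(parent, ranges)
    all_in <- all_in && all(child$genome >= ranges$lower &
                              child$genome <= ranges$upper)
  }
  expect_true(all_in)

  # vanishing step sizes leave the genome essentially unchanged
  parent$step_sizes[] <- 1e-12
  set.seed(5)
  near <- mutate_candidate(parent, ranges)
  expect_equal(near$genome, parent$genome, tolerance = 1e-9)

  set.seed(7); a <- mutate_candidate(parent, ranges)
  set.seed(7); b <- mutate_candidate(parent, ranges)
  expect_identical(a, b)
})

test_that("the feasibility filter enforces CV <= 10 and HI <= 0.64", {
  expect_false(constraint_filter(yield_stats(c(9, 11), c(0.5, 0.5))))  # cv 10.5
  expect_false(constraint_filter(yield_stats(c(10, 10.1), c(0.65, 0.65))))
  expect_true(constraint_filter(yield_stats(c(10, 10.1), c(0.5, 0.5))))
  # boundary: cv exactly 10 and hi exactly 0.64 are kept
  expect_true(constraint_filter(structure(
    list(mean_yield = 10, cv = 10, mean_hi = 0.64), class = "yield_stats")))
})

test_that("a generation keeps the parent when every candidate is infeasible", {
  ranges <- default_trait_ranges()
  parent <- sample_initial_parents(ranges, 1, default_cultivar(), 1)[[1]]
  parent$stats <- stub_stats(5)
  parent$feasible <- TRUE
  infeasible <- function(genome) yield_stats(c(5, 15), c(0.5, 0.5))  # cv 50
  set.seed(1)
  out <- easa_generation(parent, infeasible, ranges)
  expect_identical(out$genome, parent$genome)

  # selection never returns a feasible candidate worse than the parent
  sphere <- function(genome) stub_stats(-sum((genome - 1)^2))
  parent$stats <- sphere(parent$genome)
  set.seed(2)
  for (i in 1:5) {
    nxt <- easa_generation(parent, sphere, ranges)
    expect_gte(nxt$stats$mean_yield, parent$stats$mean_yield)
    parent <- nxt
  }

  # an evaluation failure is treated as infeasible, not fatal
  boom <- function(genome) stop("solver blew up")
  parent$feasible <- TRUE
  set.seed(3)
  expect_identical(easa_generation(parent, boom, ranges)$genome,
                   parent$genome)
})

test_that("EASA recovers known optima of separable concave fitness", {
  ranges <- default_trait_ranges()
  lo <- ranges$lower; hi <- ranges$upper
  center <- lo + c(0.3, 0.62, 0.45, 0.8, 0.25, 0.55, 0.7) * (hi - lo)
  scale <- hi - lo
  concave <- function(genome) {
    stub_stats(10 - sum(((genome - center) / scale)^2))
  }
  # coarse grid oracle: separable, so the grid argmax is per-dimension
  grid_n <- 9
  grid_best <- vapply(seq_along(lo), function(j) {
    g <- seq(lo[j], hi[j], length.out = grid_n)
    g[which.min((g - center[j])^2)]
  }, numeric(1))
  spacing <- (hi - lo) / (grid_n - 1)
  expect_true(all(abs(grid_best - center) <= spacing + 1e-9))  # sanity

  for (seed in c(1, 2, 3)) {
    parents <- sample_initial_parents(ranges, 4, default_cultivar(),
                                      split_seed(seed, "p"))
    res <- wheatgap:::easa_optimize(concave, parents, ranges, seed,
                                    patience = 15, max_gen = 120,
                                    tol = 1e-9)
    expect_true(all(abs(res$best$genome - grid_best) <= spacing))
    # per-start feasible trace fitness is non-decreasing
    tr <- res$trace[res$trace$feasible, ]
    for (s in unique(tr$start)) {
      expect_true(all(diff(tr$mean_yield[tr$start == s]) >= -1e-12))
    }
  }
})

test_that("full ideotype optimization is deterministic and beats its parent", {
  cache <- reduced_optimization()
  opt <- cache$opt
  # determinism on a smaller rerun
  site <- site_preset("cold_NE")
  w <- generate_weather(site, 4, seed = 2)
  mgmt <- management_for_site(site)
  args <- list(w, soil_profile(), mgmt, default_cultivar(),
               stress_mode = "iT", seed = 17, n_starts = 2, patience = 3,
               max_gen = 6)
  a <- do.call(optimize_ideotype, args)
  b <- do.call(optimize_ideotype, args)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best$genome, b$best$genome)

  # the best equals the top final parent recorded in the trace
  finals <- do.call(rbind, lapply(split(opt$trace, opt$trace$start),
                                  function(d) d[nrow(d), ]))
  expect_equal(opt$best$stats$mean_yield,
               max(finals$mean_yield[finals$feasible]))

  # never below the cultivar evaluated with the ideotype LUE
  ideo_cv <- default_cultivar()
  ideo_cv$lue_multiplier <- 1.10
  base_yield <- simulate_multi_year(ideo_cv, cache$series, soil_profile(),
                                    cache$mgmt)$mean_yield
  expect_gte(opt$best$stats$mean_yield, base_yield)
})
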