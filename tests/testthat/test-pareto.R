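op <- function(...) objective_point(list(), c(...), "minimize")

test_that("dominance requires at-least-as-good everywhere plus one strict", {
  expect_false(dominates(op(1, 2), op(1, 2)))
  expect_true(dominates(op(1, 1), op(2, 2)))
  expect_true(dominates(op(1, 2), op(1, 3)))
  expect_false(dominates(op(1, 3), op(2, 2)))
  expect_false(dominates(op(2, 2), op(1, 3)))

  pmax1 <- objective_point(list(), c(3, 3), "maximize")
  pmax2 <- objective_point(list(), c(2, 2), "maximize")
  expect_true(dominates(pmax1, pmax2))
  expect_error(dominates(pmax1, op(1, 2)), "directions")
})

test_that("pareto_front equals the all-pairs brute-force filter", {
  pts <- list(op(1, 2), op(2, 1), op(2, 2))
  front <- pareto_front(pts)
  expect_length(front, 2)
  expect_identical(front, pts[1:2])

  single <- list(op(5, 5))
  expect_identical(pareto_front(single), single)

  # duplicates of one objective vector are all retained
  dup <- list(op(1, 1), op(1, 1), op(3, 0))
  expect_length(pareto_front(dup), 3)

  for (seed in 1:20) {
    n <- 20 + (seed * 7) %% 80
    m <- 2 + seed %% 3
    pts <- rand_points(n, m, seed)
    expect_identical(pareto_front(pts), front_oracle(pts))
  }

  # permutation invariance (as a set) and positive-scale invariance
  pts <- rand_points(40, 3, 99)
  perm <- withr::with_seed(1, sample(40))
  ids <- function(l) sort(vapply(l, function(p) p$params$id, numeric(1)))
  expect_identical(ids(pareto_front(pts[perm])), ids(pareto_front(pts)))
  scaled <- lapply(pts, function(p)
    objective_point(p$params, p$objectives * 17, p$directions))
  expect_identical(ids(pareto_front(scaled)), ids(pareto_front(pts)))

  expect_error(pareto_front(list()), "at least one")
})

test_that("scalarization normalizes objectives before weighting", {
  pts <- list(op(0.1, 5e6), op(0.5, 1e6), op(0.9, 2e5))
  s_loss <- scalarize(pts, 1, 0)
  expect_identical(order(s_loss),
                   order(vapply(pts, function(p) p$objectives[1],
                                numeric(1))))
  # symmetric points under equal weights score equally
  sym <- list(op(0, 1), op(1, 0))
  s <- scalarize(sym, 0.5, 0.5)
  expect_equal(s[1], s[2])
  # constant objective contributes nothing
  const <- list(op(0.2, 7), op(0.8, 7))
  expect_equal(scalarize(const, 0.3, 0.7), c(0, 0.3))

  expect_error(scalarize(pts, 0, 0), "both zero")
  expect_error(scalarize(list(op(1, 2, 3)), 1, 1), "two")
})

test_that("select_config is the front-restricted scalarized argmin", {
  single <- list(op(1, 2))
  expect_identical(select_config(single, 0.7, 0.3), single[[1]])

  # a dominated point with the best raw score cannot win
  pts <- list(op(0, 1), op(1, 0), op(0.4, 0.45), op(0.41, 0.46))
  sel <- select_config(pts, 0.5, 0.5)
  expect_identical(sel, pts[[3]])

  for (seed in 1:10) {
    pts <- rand_points(50, 2, 200 + seed)
    alpha <- 0.7; beta <- 0.3
    sel <- select_config(pts, alpha, beta)
    front <- front_oracle(pts)
    scores <- scalarize(pts, alpha, beta)
    front_ids <- vapply(front, function(p) p$params$id, numeric(1))
    all_ids <- vapply(pts, function(p) p$params$id, numeric(1))
    best <- min(scores[all_ids %in% front_ids])
    expect_true(sel$params$id %in% front_ids)
    expect_equal(scores[all_ids == sel$params$id], best)
  }
})

test_that("candidate lists round-trip through JSON", {
  pts <- list(objective_point(list(tap_block = 1, mode = "mean"),
                              c(0.2, 1e5), "minimize"),
              objective_point(list(tap_block = 5, mode = "sum"),
                              c(0.1, 9e6), "minimize"))
  tmp <- tempfile(fileext = ".json")
  write_candidates(pts, tmp)
  back <- read_candidates(tmp)
  expect_equal(back[[1]]$objectives, pts[[1]]$objectives)
  expect_equal(back[[2]]$params$tap_block, 5)
  expect_identical(back[[1]]$directions, pts[[1]]$directions)
})
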