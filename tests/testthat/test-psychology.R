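make_agents <- function(xy, cats = NULL) {
  data.frame(
    id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
    self_category = cats %||% rep("COOPERATIVE", nrow(xy)),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("perception returns exactly the closed-ball neighbourhood", {
  # lone agent
  ags <- make_agents(rbind(c(0, 0)))
  p <- perceive(list(id = 1, x = 0, y = 0), ags, r = 1)
  expect_length(p$neighbour_ids, 0)

  # neighbour at distance exactly r is included (closed ball)
  ags <- make_agents(rbind(c(0, 0), c(1, 0), c(1.0000001, 1)))
  p <- perceive(list(id = 1, x = 0, y = 0), ags, r = 1)
  expect_identical(p$neighbour_ids, 2L)

  # scattered agents: membership and order equal the brute-force filter
  set.seed(5)
  for (rep in 1:10) {
    xy <- cbind(runif(6, 0, 2), runif(6, 0, 2))
    ags <- make_agents(xy)
    me <- list(id = 3, x = xy[3, 1], y = xy[3, 2])
    p <- perceive(me, ags, r = 1)
    expect_identical(p$neighbour_ids, as.integer(brute_neighbours(me, ags, 1)))
    expect_true(all(p$distances <= 1))
  }
})

test_that("cognition switches to cooperative on collapse and reverts on recovery", {
  params <- model_params(v_threshold = 0.05, n_history = 3)
  pct <- structure(list(neighbour_ids = integer(0)), class = "ccoop_percept")
  walker <- list(role = "walker", self_category = "TARGET_ORIENTED",
                 speed_history = c(0, 0, 0))
  expect_identical(update_cognition(walker, pct, params), "COOPERATIVE")

  # a walker moving at free-flow speed reverts to target-oriented
  walker$self_category <- "COOPERATIVE"
  walker$speed_history <- c(1.3, 1.3, 1.3)
  expect_identical(update_cognition(walker, pct, params), "TARGET_ORIENTED")

  # a waiter reverts to WAIT instead
  waiter <- list(role = "waiter", self_category = "COOPERATIVE",
                 speed_history = c(1.3, 1.3, 1.3))
  expect_identical(update_cognition(waiter, pct, params), "WAIT")

  # insufficient history: no transition
  walker$speed_history <- c(0, 0)
  walker$self_category <- "TARGET_ORIENTED"
  expect_identical(update_cognition(walker, pct, params), "TARGET_ORIENTED")

  # intermediate regime (not all below, mean below): category unchanged
  mixed <- list(role = "walker", self_category = "COOPERATIVE",
                speed_history = c(0, 0.1, 0))
  expect_identical(update_cognition(mixed, pct, model_params(v_threshold = 0.05)),
                   "COOPERATIVE")
})

test_that("only the three self-categories are reachable from any state", {
  params <- model_params(v_threshold = 0.2)
  pct <- structure(list(neighbour_ids = integer(0)), class = "ccoop_percept")
  hists <- list(c(0, 0, 0), c(1, 1, 1), c(0, 0.3, 0), c(0.1, 0.1, 0.1), numeric(0))
  for (role in c("walker", "waiter")) {
    for (cat in SELF_CATEGORIES) {
      for (h in hists) {
        out <- update_cognition(list(role = role, self_category = cat,
                                     speed_history = h), pct, params)
        expect_true(out %in% SELF_CATEGORIES)
        # from the states a role can actually occupy, cognition never produces
        # the other role's default
        if (length(h) >= 3 && role == "waiter" && cat != "TARGET_ORIENTED") {
          expect_false(out == "TARGET_ORIENTED")
        }
        if (length(h) >= 3 && role == "walker" && cat != "WAIT") {
          expect_false(out == "WAIT")
        }
      }
    }
  }
})

test_that("swap-candidate selection prefers the neighbour closest to the target", {
  target <- region_rect(0, 10, 2, 11)
  me <- list(id = 1, x = 1, y = 5, self_category = "COOPERATIVE")
  # no cooperative neighbour -> none
  ags <- make_agents(rbind(c(1, 5), c(1, 6)), cats = c("COOPERATIVE", "WAIT"))
  pct <- perceive(me, ags, r = 2)
  expect_true(is.na(find_swap_candidate(me, pct, ags, target)))

  # two cooperative neighbours at target distances 1.2 and 0.8 -> the closer one
  ags <- make_agents(rbind(c(1, 5), c(1, 8.8), c(1, 9.2)))
  pct <- perceive(me, ags, r = 5)
  expect_identical(find_swap_candidate(me, pct, ags, target), 3L)

  # equal target distance -> smaller id, against the brute-force rule
  ags <- make_agents(rbind(c(1, 5), c(0.6, 5.5), c(1.4, 5.5)))
  pct <- perceive(me, ags, r = 2)
  expect_identical(find_swap_candidate(me, pct, ags, target), 2L)
  expect_identical(find_swap_candidate(me, pct, ags, target),
                   brute_swap_candidate(me, ags, target, 2, Inf))

  # candidates beyond max_reach are not eligible
  expect_true(is.na(find_swap_candidate(me, pct, ags, target, max_reach = 0.3)))

  # randomized cross-check against the brute-force enumeration
  set.seed(31)
  for (rep in 1:15) {
    xy <- cbind(runif(6, 0, 2), runif(6, 4, 7))
    cats <- sample(c("COOPERATIVE", "WAIT"), 6, replace = TRUE)
    ags <- make_agents(xy, cats)
    me <- list(id = 1, x = xy[1, 1], y = xy[1, 2], self_category = "COOPERATIVE")
    pct <- perceive(me, ags, r = 1.5)
    got <- find_swap_candidate(me, pct, ags, target, max_reach = 1.0)
    want <- brute_swap_candidate(me, ags, target, 1.5, 1.0)
    expect_identical(got, want)
  }
})

test_that("swap execution exchanges positions exactly and conserves the configuration", {
  a <- list(id = 1L, x = 0.25, y = 1.1, self_category = "COOPERATIVE")
  b <- list(id = 2L, x = 0.5, y = 1.4, self_category = "COOPERATIVE")
  res <- execute_swap(a, b, r = 1, dt = 0.5)
  expect_true(res$swapped)
  # bitwise position exchange
  expect_identical(c(res$a$x, res$a$y), c(0.5, 1.4))
  expect_identical(c(res$b$x, res$b$y), c(0.25, 1.1))
  expect_equal(res$speed, sqrt(0.25^2 + 0.3^2) / 0.5)
  expect_identical(res$a$swap_cooldown, 1L)
  # ids and count conserved
  expect_identical(sort(c(res$a$id, res$b$id)), c(1L, 2L))
  # double swap restores the original configuration
  res2 <- execute_swap(res$a, res$b, r = 1, dt = 0.5)
  expect_identical(c(res2$a$x, res2$a$y), c(0.25, 1.1))
  expect_identical(c(res2$b$x, res2$b$y), c(0.5, 1.4))

  # precondition violations reject the swap without changing state
  b_far <- list(id = 2L, x = 5, y = 5, self_category = "COOPERATIVE")
  res3 <- execute_swap(a, b_far, r = 1, dt = 0.5)
  expect_false(res3$swapped)
  expect_identical(res3$a, a)
  b_wait <- list(id = 2, x = 0.5, y = 1.4, self_category = "WAIT")
  expect_false(execute_swap(a, b_wait, r = 1, dt = 0.5)$swapped)
})
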