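test_that("design invariants are enforced", {
  pp <- parameter_set(5, phiA = 0.9, p = list(intercept = 1))
  expect_error(simulation_design(5, c(0, 0, 0, 0, 10), c(0, 0, 0, 0, 0), pp),
               "last occasion")
  expect_error(simulation_design(5, integer(5), integer(5), pp), "positive")
  expect_error(simulation_design(5, c(-1, 0, 0, 0, 0), c(5, 0, 0, 0, 0), pp),
               "nonnegative")
  expect_error(simulation_design(4, integer(4), 10, parameter_set(5)), "T == T")
})

test_that("degenerate detection and survival give the expected histories", {
  T <- 6
  # detection 0: nothing after first capture
  pp0 <- parameter_set(T, phiA = 0.9, a = c(A = 0.5, B = 0.5),
                       phiJ = list(intercept = 1),
                       p = list(intercept = -15))
  d <- simulation_design(T, c(30, 0, 0, 0, 0, 0), c(30, 0, 0, 0, 0, 0), pp0, 1)
  h <- simulate_histories(d)
  expect_true(all(rowSums(h$events != 0) == 1))
  # adult survival 1 and detection 1, adults only: all-ones histories
  pp1 <- parameter_set(T, phiA = 1, p = list(intercept = 15))
  d1 <- simulation_design(T, integer(T), c(10, 10, 0, 0, 0, 0), pp1, 1)
  h1 <- simulate_histories(d1)
  for (i in seq_len(nrow(h1$events))) {
    fo <- h1$first_occasion[i]
    expect_identical(h1$events[i, fo:T], rep(1L, T - fo + 1L))
  }
})

test_that("identical seed and design reproduce the output exactly", {
  fx1 <- make_fixture("tiny", seed = 5)
  fx2 <- make_fixture("tiny", seed = 5)
  expect_identical(fx1$histories$events, fx2$histories$events)
  expect_identical(fx1$params, fx2$params)
  expect_false(identical(fx1$histories$events,
                         make_fixture("tiny", seed = 6)$histories$events))
})

test_that("first-year survival of a mixed cohort matches the binomial mixture", {
  T <- 3
  pp <- parameter_set(T, piA = 0.5,
                      phiJ = list(intercept = qlogis(0.73),
                                  groupB = qlogis(0.73) - qlogis(0.50)),
                      phiA = 0.85, a = c(A = 0.5, B = 0.5),
                      p = list(intercept = 1))
  d <- simulation_design(T, c(10000, 0, 0), integer(T), pp, 42)
  h <- simulate_histories(d, keep_latent = TRUE)
  st <- attr(h, "latent_states")
  alive2 <- mean(st[, 2] %in% 3:8)
  p_mix <- 0.5 * (0.73 + 0.50)
  se <- sqrt(p_mix * (1 - p_mix) / 10000)
  expect_lt(abs(alive2 - p_mix), 3 * se)      # 0.615 within binomial error
  # groups die at their own rates
  grp <- attr(h, "latent_group")
  sA <- mean(st[grp == 1, 2] %in% 3:8)
  sB <- mean(st[grp == 2, 2] %in% 3:8)
  expect_lt(abs(sA - 0.73), 3 * sqrt(0.73 * 0.27 / sum(grp == 1)))
  expect_lt(abs(sB - 0.50), 3 * sqrt(0.25 / sum(grp == 2)))
})

test_that("empirical transition frequencies converge to the kernel", {
  T <- 6
  pp <- parameter_set(T, piA = 0.6,
                      phiJ = list(intercept = qlogis(0.7), groupB = 0.8),
                      phiA = 0.85, a = c(A = 0.5, B = 0.3),
                      p = list(intercept = qlogis(0.8), groupB = 0.5))
  d <- simulation_design(T, c(50000, 0, 0, 0, 0, 0), c(50000, 0, 0, 0, 0, 0),
                         pp, 2024)
  h <- simulate_histories(d, keep_latent = TRUE)
  st <- attr(h, "latent_states")
  M <- build_transition(pp, 2)   # constant in this parameterisation
  for (from in c(3, 5, 7, 8)) {  # PB1_A, PB2_A, BR_A, BR_B
    for (t in 2:(T - 1)) {
      at <- st[, t] == from
      if (sum(at) < 500) next
      to <- st[at, t + 1]
      to[to == 0] <- 9L         # recorded once, then absorbed
      emp <- tabulate(to, 9) / sum(at)
      p <- M[from, ]
      se <- sqrt(pmax(p * (1 - p), 1e-12) / sum(at))
      expect_true(all(abs(emp - p) <= 3 * se + 1e-9),
                  info = sprintf("state %d, occasion %d", from, t))
    }
  }
})

test_that("simulated histories always satisfy the structural invariants", {
  for (s in 1:3) {
    fx <- make_fixture("paper_like", seed = s, n_HY = 400, n_ASY = 300)
    expect_silent(validate_histories(fx$histories))
    # one-year-olds never encountered
    hy <- fx$histories$entry_class == "HY"
    fo <- fx$histories$first_occasion[hy]
    ok <- fo + 1L <= fx$histories$T
    expect_true(all(fx$histories$events[cbind(which(hy)[ok], fo[ok] + 1L)] == 0L))
  }
})

test_that("fixtures honour their contracts", {
  tiny <- make_fixture("tiny", seed = 1)
  expect_lte(sum(tiny$histories$count), 200)
  expect_lte(tiny$histories$T, 6)
  pl <- make_fixture("paper_like", seed = 7, n_HY = 600, n_ASY = 400)
  expect_identical(sum(pl$histories$count), 1000L)
  # mean-year generating values are the reported point estimates
  expect_equal(natural_scale(pl$params, "phiA"), 0.85)
  expect_equal(unname(pl$params$a), c(0.54, 0.31))
  expect_equal(mean(plogis(pl$params$phiJ$intercept + pl$params$phiJ$year)),
               0.73, tolerance = 0.01)
  hom <- make_fixture("homogeneous", seed = 2)
  expect_identical(hom$params$phiJ$groupB, 0)
  expect_identical(unname(diff(hom$params$a)), 0)
  expect_false(hom$spec$heterogeneous)
})

test_that("breeder detections track the generating detection schedule", {
  fx <- make_fixture("paper_like", seed = 7, n_HY = 2000, n_ASY = 2000)
  h <- simulate_histories(fx$design, keep_latent = TRUE)
  st <- attr(h, "latent_states")
  grp <- attr(h, "latent_group")
  pp <- fx$params
  for (t in c(5, 10, 15)) {
    for (g in 1:2) {
      br <- st[, t] == 6L + g & h$first_occasion < t
      if (sum(br) < 200) next
      pdet <- natural_scale(pp, "p", t, c("A", "B")[g])
      emp <- mean(h$events[br, t] == 1L)
      expect_lt(abs(emp - pdet), 3 * sqrt(pdet * (1 - pdet) / sum(br)))
    }
  }
})
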