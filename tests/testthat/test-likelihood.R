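test_that("transition kernels are proper and match hand-computed products", {
  pp <- parameter_set(6, phiA = 0.85, a = c(A = 0.54, B = 0.31),
                      phiJ = list(intercept = qlogis(0.7), groupB = 1))
  M <- build_transition(pp, 2)
  expect_equal(M["PB2_A", c("BR_A", "PB2_A", "DEAD")],
               c(BR_A = 0.459, PB2_A = 0.391, DEAD = 0.15))
  expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
  # dead is absorbing, breeding is permanent, class is fixed for life
  expect_identical(unname(M["DEAD", ]), c(rep(0, 8), 1))
  expect_identical(unname(M["BR_A", c("PB1_A", "PB2_A")]), c(0, 0))
  A_states <- grep("_A$", brant_states())
  B_states <- grep("_B$", brant_states())
  expect_true(all(M[A_states, B_states] == 0) && all(M[B_states, A_states] == 0))
  # zero juvenile survival sends goslings straight to dead
  pp0 <- parameter_set(6, phiJ = list(intercept = -Inf))
  M0 <- build_transition(pp0, 1)
  expect_identical(unname(M0["GOS_A", "DEAD"]), 1)
  expect_error(build_transition(pp, 6), "1..T-1")
})

test_that("kernel rows sum to one for random parameter draws", {
  set.seed(11)
  for (k in 1:200) {
    pp <- random_params(5)
    t <- sample(4, 1)
    expect_true(max(abs(rowSums(build_transition(pp, t)) - 1)) < 1e-12)
    E <- build_emission(pp, t)
    expect_true(max(abs(rowSums(E) - 1)) < 1e-12)
    expect_true(all(E[-c(7, 8), "e1"] == 0))
  }
})

test_that("closed-form histories match the forward recursion", {
  T <- 5
  pp <- parameter_set(T, piA = 0.5, phiA = 0.8,
                      p = list(intercept = qlogis(0.7)),
                      a = c(A = 0.4, B = 0.4))
  # released at the last occasion: empty future, probability one
  h_last <- encounter_histories(rbind(c(0, 0, 0, 0, 1)))
  expect_identical(history_loglik(h_last, pp), 0)
  # released at T-1, not seen at T: 1 - phiA * p
  h_gap <- encounter_histories(rbind(c(0, 0, 0, 1, 0)))
  expect_equal(history_loglik(h_gap, pp), log(1 - 0.8 * 0.7), tolerance = 1e-12)
  # seen at both: phiA * p
  h_both <- encounter_histories(rbind(c(0, 0, 0, 1, 1)))
  expect_equal(history_loglik(h_both, pp), log(0.8 * 0.7), tolerance = 1e-12)
})

test_that("forward likelihood equals brute-force path enumeration", {
  fx <- make_fixture("tiny", seed = 2)
  h <- collapse_histories(fx$histories)
  set.seed(21)
  for (k in 1:10) {
    pp <- random_params(h$T)
    ll <- history_loglik(h, pp)
    for (i in sample(nrow(h$events), 3)) {
      expect_equal(ll[i],
                   oracle_loglik(h$events[i, ], h$first_occasion[i],
                                 h$entry_class[i], pp),
                   tolerance = 1e-10)
    }
  }
})

test_that("event-sequence probabilities marginalise to one", {
  T <- 4
  set.seed(33)
  pp <- random_params(T)
  # ASY released at 1: all 2^3 continuations
  seqs <- expand.grid(rep(list(0:1), T - 1))
  tot <- sum(vapply(seq_len(nrow(seqs)), function(i) {
    ev <- c(1L, as.integer(seqs[i, ]))
    exp(history_loglik(encounter_histories(rbind(ev), validate = FALSE), pp))
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-8)
  # HY released at 1: age-1 occasion is structurally 0
  seqs2 <- expand.grid(rep(list(0:1), T - 2))
  tot2 <- sum(vapply(seq_len(nrow(seqs2)), function(i) {
    ev <- c(2L, 0L, as.integer(seqs2[i, ]))
    exp(history_loglik(encounter_histories(rbind(ev), validate = FALSE), pp))
  }, numeric(1)))
  expect_equal(tot2, 1, tolerance = 1e-8)
})

test_that("with no class contrasts the likelihood ignores the class split", {
  T <- 5
  base <- list(phiJ = list(intercept = 0.5), phiA = 0.85,
               a = c(A = 0.4, B = 0.4), p = list(intercept = 1))
  fx <- make_fixture("tiny", seed = 4)
  h <- collapse_histories(fx$histories)
  ll <- function(piA) {
    pp <- do.call(parameter_set, c(list(T = T, piA = piA), base))
    dataset_loglik(h, pp)$loglik
  }
  expect_equal(ll(0.1), ll(0.9), tolerance = 1e-10)
  expect_equal(ll(0.5), ll(1.0), tolerance = 1e-10)
})

test_that("dataset likelihood weights counts and caching is exact", {
  fx <- make_fixture("tiny", seed = 6)
  h <- fx$histories
  pp <- fx$params
  ll <- dataset_loglik(h, pp)
  expect_lte(ll$loglik, 0)
  expect_equal(ll$deviance, -2 * ll$loglik)
  # duplicating a history with count 2 equals listing it twice
  ev1 <- h$events[1, , drop = FALSE]
  twice <- encounter_histories(rbind(ev1, ev1))
  once2 <- encounter_histories(ev1, count = 2L)
  expect_equal(dataset_loglik(twice, pp)$loglik,
               dataset_loglik(once2, pp)$loglik, tolerance = 1e-12)
  # collapsed and uncollapsed evaluation agree
  expect_equal(dataset_loglik(collapse_histories(h), pp)$loglik, ll$loglik,
               tolerance = 1e-12)
  expect_error(dataset_loglik(h[integer(0)], pp), "empty")
})

test_that("no underflow on long histories with high detection", {
  T <- 50
  pp <- parameter_set(T, phiA = 0.95, p = list(intercept = qlogis(0.9)),
                      a = c(A = 0.5, B = 0.5))
  ev <- matrix(0L, 2, T)
  ev[1, ] <- 1L                      # seen every year
  ev[2, 1] <- 1L                     # never seen again
  h <- encounter_histories(ev)
  ll <- history_loglik(h, pp)
  expect_true(all(is.finite(ll)))
  expect_equal(ll[1], 49 * log(0.95 * 0.9), tolerance = 1e-9)
})

test_that("adjoint gradient matches numerical differentiation", {
  fx <- make_fixture("tiny", seed = 8)
  x <- collapse_histories(fx$histories)
  spec <- fx$spec
  layout <- brantmix:::.par_layout(spec, sort(unique(x$first_occasion)))
  fn <- function(p) {
    nat <- brantmix:::.nat_arrays(brantmix:::.par_to_params(layout, p))
    -sum(x$count * brantmix:::.forward_pass(x, nat)$loglik)
  }
  gr <- function(p) {
    pp <- brantmix:::.par_to_params(layout, p)
    nat <- brantmix:::.nat_arrays(pp)
    fp <- brantmix:::.forward_pass(x, nat, grad = TRUE)
    -brantmix:::.grad_to_par(layout, p, nat, fp$grad)
  }
  set.seed(13)
  for (k in 1:3) {
    par <- brantmix:::.random_start(layout)
    g1 <- gr(par)
    g2 <- vapply(seq_along(par), function(j) {
      e <- 1e-6; p1 <- par; p2 <- par
      p1[j] <- p1[j] + e; p2[j] <- p2[j] - e
      (fn(p1) - fn(p2)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g1 - g2)), 1e-5)
  }
})
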