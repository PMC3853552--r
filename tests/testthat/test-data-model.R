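test_that("free initial-state parameter count follows T x (n_states - 1)", {
  expect_identical(count_free_initial_params(25, 4), 75L)
  expect_identical(count_free_initial_params(1, 2), 1L)
  expect_identical(count_free_initial_params(10, 4), 30L)
  expect_error(count_free_initial_params(0, 4), "T >= 1")
  expect_error(count_free_initial_params(10, 1), "n_states >= 2")
})

test_that("natural_scale assembles the logit-linear predictor", {
  T <- 8
  pp <- parameter_set(T, piA = 0.4,
                      phiJ = list(intercept = 0.3, year = seq(-0.3, 0.4, length.out = T - 1),
                                  groupB = 0.9),
                      phiA = 0.85, a = c(A = 0.54, B = 0.31),
                      p = list(intercept = 1.2, year = rep(0.1, T), groupB = -0.5))
  # constant families are flat in occasion and group
  for (occ in c(1, 4, 7)) for (g in c("A", "B"))
    expect_identical(natural_scale(pp, "phiA", occ, g), 0.85)
  expect_identical(natural_scale(pp, "a", 3, "B"), 0.31)
  # independent re-evaluation of the linear predictor
  set.seed(41)
  for (k in 1:25) {
    mu <- runif(1, -3, 3); dl <- runif(1, -2, 2); yr <- runif(T - 1, -1, 1)
    q <- parameter_set(T, phiJ = list(intercept = mu, year = yr, groupB = dl))
    occ <- sample(T - 1, 1)
    expect_equal(natural_scale(q, "phiJ", occ, "A"), 1 / (1 + exp(-(mu + yr[occ]))))
    expect_equal(natural_scale(q, "phiJ", occ, "B"), 1 / (1 + exp(-(mu + yr[occ] - dl))))
  }
  # logistic saturation: the class gap shrinks as the intercept grows
  gap <- function(mu) {
    q <- parameter_set(T, phiJ = list(intercept = mu, groupB = 1))
    natural_scale(q, "phiJ", 1, "A") - natural_scale(q, "phiJ", 1, "B")
  }
  expect_true(gap(8) < gap(2) && gap(2) < gap(0))
  expect_true(gap(-8) < gap(-2))
  expect_error(natural_scale(pp, "phiJ", T, "A"), "out of range")
  expect_error(natural_scale(pp, "nope", 1, "A"), "unknown parameter family")
})

test_that("natural-scale values stay inside [0, 1] for any finite coefficients", {
  set.seed(7)
  for (k in 1:50) {
    pp <- parameter_set(6,
      phiJ = list(intercept = runif(1, -40, 40), year = runif(5, -20, 20),
                  groupB = runif(1, -30, 30)),
      p = list(intercept = runif(1, -40, 40)))
    v <- c(natural_scale(pp, "phiJ", sample(5, 1), "A"),
           natural_scale(pp, "phiJ", sample(5, 1), "B"),
           natural_scale(pp, "p", sample(6, 1), "B"))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("encounter history invariants are enforced", {
  ev <- rbind(c(0, 2, 0, 0, 1), c(1, 0, 1, 0, 0))
  h <- encounter_histories(ev)
  expect_identical(h$entry_class, c("HY", "ASY"))
  expect_identical(h$first_occasion, c(2L, 1L))
  # a one-year-old encounter is structurally impossible
  expect_error(encounter_histories(rbind(c(2, 1, 0, 0, 0))), "age 1")
  # the gosling code only at first capture
  expect_error(encounter_histories(rbind(c(2, 0, 2, 0, 0))), "event 2")
  expect_error(encounter_histories(rbind(c(1, 0, 2, 0, 0))), "event 2")
  # declared entry class must match the event codes
  expect_error(encounter_histories(ev, entry_class = c("ASY", "ASY")),
               "open with event 1")
  expect_error(encounter_histories(ev, count = c(0, 1)), "count")
  expect_error(encounter_histories(matrix(0L, 1, 5)), "no events")
})

test_that("collapsing duplicates preserves totals and subsetting works", {
  ev <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(1, 0, 1))
  h <- encounter_histories(ev, count = c(2L, 3L, 1L, 1L))
  hc <- collapse_histories(h)
  expect_identical(nrow(hc$events), 2L)
  expect_identical(sum(hc$count), sum(h$count))
  expect_identical(hc$count[1L], 6L)
  h2 <- h[2:3]
  expect_identical(h2$count, c(3L, 1L))
})

test_that("boundary flags mark coefficients at the logit bound", {
  pp <- parameter_set(4, phiJ = list(intercept = 15), phiA = 0.85,
                      p = list(intercept = 2))
  fl <- boundary_flags(pp)
  expect_true(fl[["phiJ.intercept"]])
  expect_false(fl[["p.intercept"]])
  expect_false(fl[["phiA"]])
})

test_that("model structures parse and reject inconsistent factor sets", {
  sp <- model_spec(20)
  expect_true(sp$heterogeneous)
  expect_true(sp$families$phiJ$year)
  expect_identical(sp$families$p$relation, "additive")
  expect_identical(model_spec(10, p = "year*group")$families$p$relation,
                   "interactive")
  hom <- model_spec(10, pi = "constant", phiJ = "constant", a = "constant",
                    p = "constant")
  expect_false(hom$heterogeneous)
  expect_error(model_spec(10, phiJ = "year+trend"), "trend")
  expect_error(model_spec(10, phiJ = "season"), "unknown term")
  expect_error(model_spec(10, c_hat = 0), "c_hat")
})
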