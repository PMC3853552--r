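ref_matrix <- function(C = c(5, 3), d = 0.8) {
  r <- demographic_rates(C_A = C[1], C_B = C[2], d = d)
  r$s0 <- calibrate_s0(demographic_rates(), 1.058)
  build_matrix(r)
}

test_that("uniform vulnerability reduces to uniform harvest", {
  M <- ref_matrix()
  w <- stable_structure(M)
  sc <- harvest_scenario(1, 1, h_grid = c(0, 0.05, 0.1))
  h <- class_harvest_rates(sc, w, 0.1)
  expect_equal(unname(h), rep(0.1, 6), tolerance = 1e-12)
  expect_equal(compensation_index(w, reproductive_values(M), h), 1,
               tolerance = 1e-12)
  # scaling a matrix scales its spectrum
  expect_equal(lambda_harvested(M, h), lambda_dominant(M) * 0.9,
               tolerance = 1e-10)
  # all three curves coincide under column scaling
  res <- run_scenario(M, sc, gosling_first_fall = FALSE)
  expect_equal(res$table$lambda_direct, res$table$lambda_uniform,
               tolerance = 1e-9)
  expect_equal(res$table$lambda_sensitivity, res$table$lambda_uniform,
               tolerance = 1e-9)
})

test_that("class rates satisfy the overall-proportion constraint", {
  M <- ref_matrix()
  w <- stable_structure(M)
  sc <- harvest_scenario(0.3, 3)
  for (h in c(0.02, 0.1, 0.18)) {
    hi <- class_harvest_rates(sc, w, h)
    expect_equal(sum(w * hi), h, tolerance = 1e-12)
    expect_true(all(hi >= 0 & hi < 1))
  }
  expect_equal(unname(class_harvest_rates(sc, w, 0)), rep(0, 6))
  expect_error(class_harvest_rates(sc, w, 0.5), "infeasible")
  expect_error(class_harvest_rates(sc, w / 2, 0.1), "sum to 1")
})

test_that("compensation index is scale invariant and direction sensitive", {
  M <- ref_matrix()
  w <- stable_structure(M); v <- reproductive_values(M)
  sc <- harvest_scenario(0.3, 3)
  h1 <- class_harvest_rates(sc, w, 0.02)
  h2 <- class_harvest_rates(sc, w, 0.12)
  expect_equal(compensation_index(w, v, h1), compensation_index(w, v, h2),
               tolerance = 1e-10)
  # harvest aimed at the lowest-value class compensates (b < 1), at the
  # highest-value class it overshoots (b > 1)
  lo <- which.min(v); hi <- which.max(v)
  h_lo <- h_hi <- rep(0, 6); h_lo[lo] <- 0.2; h_hi[hi] <- 0.2
  expect_lt(compensation_index(w, v, h_lo), 1)
  expect_gt(compensation_index(w, v, h_hi), 1)
  expect_error(compensation_index(w, v, rep(0, 6)), "undefined")
})

test_that("growth-rate responses order correctly for a compensated scenario", {
  M <- ref_matrix()
  lam0 <- lambda_dominant(M)
  w <- stable_structure(M)
  sc <- harvest_scenario(0.3, 3)
  b <- compensation_index(w, reproductive_values(M),
                          class_harvest_rates(sc, w, 0.05))
  expect_lt(b, 1)
  for (h in c(0.02, 0.05)) {
    hi <- class_harvest_rates(sc, w, h)
    ld <- lambda_harvested(M, hi)
    ls <- lambda_sensitivity(lam0, b, h)
    lu <- lambda_uniform(lam0, h)
    expect_gte(ld, ls - 1e-9)
    expect_gte(ls, lu)
  }
  # first-order agreement at vanishing harvest
  h <- 1e-4
  hi <- class_harvest_rates(sc, w, h)
  slope <- (lam0 - lambda_harvested(M, hi)) / h
  expect_lt(abs(slope - b * lam0), 1e-3)
})

test_that("harvest depresses growth below one across the reference scenarios", {
  s0 <- calibrate_s0(demographic_rates(), 1.058)
  defs <- list(list(C = c(4, 4), rq = 0.5, rs = 2),
               list(C = c(5, 3), rq = 0.5, rs = 2),
               list(C = c(5, 3), rq = 0.3, rs = 3))
  for (df in defs) {
    r <- demographic_rates(C_A = df$C[1], C_B = df$C[2], d = 0.8, s0 = s0)
    M <- build_matrix(r)
    w <- stable_structure(M)
    sc <- harvest_scenario(df$rq, df$rs)
    lam_prev <- Inf
    for (h in c(0.04, 0.08, 0.12, 0.16)) {
      lam <- lambda_harvested(M, class_harvest_rates(sc, w, h),
                              gosling_first_fall = TRUE)
      expect_lt(lam, lam_prev)      # strictly decreasing in h
      lam_prev <- lam
    }
    expect_lt(lam_prev, 1)
    for (h in c(0.12, 0.16))
      expect_lt(lambda_harvested(M, class_harvest_rates(sc, w, h),
                                 gosling_first_fall = TRUE), 1)
  }
})

test_that("population survival responds only through heterogeneous classes", {
  M <- ref_matrix()
  w <- stable_structure(M)
  r <- attr(M, "rates")
  surv <- brantmix:::.class_survivals(r)
  # no harvest: the two summaries coincide at mean survival
  s0 <- population_survival(w, surv, rep(0, 6))
  expect_equal(s0[["with_heterogeneity"]], s0[["homogeneous"]])
  expect_equal(s0[["with_heterogeneity"]], sum(w * surv))
  # uniform harvest: still coincide
  su <- population_survival(w, surv, rep(0.1, 6), 0.1)
  expect_equal(su[["with_heterogeneity"]], su[["homogeneous"]], tolerance = 1e-12)
  # reference scenario 3: survival response is tiny relative to the
  # growth-rate response (breeders dominate and share one survival)
  sc <- harvest_scenario(0.3, 3)
  res <- run_scenario(M, sc)
  tab <- res$table
  at10 <- tab[abs(tab$h - 0.1) < 1e-9, ]
  dS <- abs(at10$S_with_het - at10$S_homogeneous)
  dLam <- abs(at10$lambda_direct - at10$lambda_uniform)
  expect_lt(dS, 0.5 * dLam)
})

test_that("scenario evaluation respects its grid and degenerate cases", {
  M <- ref_matrix()
  res0 <- run_scenario(M, harvest_scenario(0.3, 3, h_grid = numeric(0)))
  expect_identical(nrow(res0$table), 0L)
  expect_true(is.finite(res0$b))
  res <- run_scenario(M, harvest_scenario(0.3, 3, h_grid = c(0, 0.1)))
  expect_equal(res$table$lambda_direct[1], res$table$lambda_uniform[1],
               tolerance = 1e-10)   # lambda_direct(0) = lambda(0)
  expect_error(harvest_scenario(0, 2), "positive")
  expect_error(harvest_scenario(1, 1, h_grid = c(0.5, 1)), "\\[0, 1\\)")
})
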