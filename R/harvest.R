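# Class-structured harvest scenarios on the two-quality projection model.
#
# A scenario fixes relative vulnerabilities: the high/low quality ratio and
# the prebreeder/breeder stage ratio (goslings take the prebreeder rate by
# default).  For a requested overall proportion h of the population in the
# harvest, class rates h_i are the common multiplier pattern scaled so that
# the stable-structure-weighted mean equals h.  The compensation index
# b = (sum w_i v_i h_i / sum w_i v_i) / (sum w_i h_i) is the ratio of the
# reproductive-value-weighted to the unweighted harvest proportion: b < 1
# means the harvest falls disproportionately on low-value classes and its
# growth-rate cost is partially compensated.

#' Define a harvest scenario
#'
#' @param ratio_quality Harvest-rate ratio high-quality / low-quality (> 0).
#' @param ratio_stage Harvest-rate ratio prebreeder / breeder (> 0).
#' @param gosling_rule Which stage rate goslings receive: `"prebreeder"`
#'   (default) or `"breeder"`.
#' @param h_grid Overall harvest proportions to evaluate, each in `[0, 1)`.
#' @return An object of class `harvest_scenario`.
#' @export
harvest_scenario <- function(ratio_quality, ratio_stage,
                             gosling_rule = c("prebreeder", "breeder"),
                             h_grid = seq(0, 0.20, by = 0.01)) {
  gosling_rule <- match.arg(gosling_rule)
  if (ratio_quality <= 0 || ratio_stage <= 0)
    stop("harvest ratios must be positive", call. = FALSE)
  if (any(h_grid < 0 | h_grid >= 1))
    stop("overall harvest proportions must be in [0, 1)", call. = FALSE)
  structure(list(ratio_quality = ratio_quality, ratio_stage = ratio_stage,
                 gosling_rule = gosling_rule, h_grid = h_grid),
            class = "harvest_scenario")
}

.harvest_multipliers <- function(scenario) {
  rs <- scenario$ratio_stage
  rg <- if (scenario$gosling_rule == "prebreeder") rs else 1
  m <- c(GOS_A = rg, PB_A = rs, BR_A = 1, GOS_B = rg, PB_B = rs, BR_B = 1)
  m[1:3] <- m[1:3] * scenario$ratio_quality
  m
}

#' Class-specific harvest rates for an overall proportion
#'
#' Scales the scenario's vulnerability multipliers so the stable-structure-
#' weighted mean rate equals `h_total`: `h_i = c m_i` with
#' `sum(w_i h_i) = h_total`.
#'
#' @param scenario A `harvest_scenario`.
#' @param w Stable structure (6-vector summing to 1).
#' @param h_total Overall proportion of the population in the harvest.
#' @return 6-vector of class rates, each in `[0, 1)`.
#' @export
class_harvest_rates <- function(scenario, w, h_total) {
  stopifnot(inherits(scenario, "harvest_scenario"))
  if (h_total < 0 || h_total >= 1)
    stop("h_total must be in [0, 1)", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8) stop("w must sum to 1", call. = FALSE)
  m <- .harvest_multipliers(scenario)
  if (h_total == 0) return(m * 0)
  h <- h_total / sum(w * m) * m
  if (any(h >= 1))
    stop(sprintf("infeasible scenario: class rate %.3f >= 1 at h_total = %g",
                 max(h), h_total), call. = FALSE)
  h
}

#' Compensation index b
#'
#' Ratio of the reproductive-value-weighted harvest proportion to the
#' unweighted one; scale-invariant in the rates, below 1 when harvest is
#' concentrated in classes of low reproductive value.
#'
#' @param w Stable structure (sums to 1).
#' @param v Reproductive values (sums to 1).
#' @param h_rates Class-specific harvest rates.
#' @return The index b.
#' @export
compensation_index <- function(w, v, h_rates) {
  if (any(w < 0) || any(v < 0)) stop("w and v must be nonnegative", call. = FALSE)
  h <- sum(w * h_rates)
  if (h <= 0) stop("overall harvest is zero; b is undefined", call. = FALSE)
  h_rv <- sum(w * v * h_rates) / sum(w * v)
  h_rv / h
}

#' Growth rate under uniform harvest
#'
#' `lambda(h) = lambda(0) (1 - h)`: the response when every class is
#' harvested at the same rate, i.e. without any compensation.
#'
#' @param lambda0 Unharvested growth rate.
#' @param h Overall harvest proportion in `[0, 1)`.
#' @return Growth rate.
#' @export
lambda_uniform <- function(lambda0, h) {
  if (any(h < 0 | h >= 1)) stop("h must be in [0, 1)", call. = FALSE)
  lambda0 * (1 - h)
}

#' First-order (sensitivity) growth-rate approximation
#'
#' `lambda(h) = lambda(0) (1 - b h)`: the uniform response attenuated by the
#' compensation index.
#'
#' @param lambda0 Unharvested growth rate.
#' @param b Compensation index (> 0).
#' @param h Overall harvest proportion in `[0, 1)`.
#' @return Growth rate.
#' @export
lambda_sensitivity <- function(lambda0, b, h) {
  if (b <= 0) stop("b must be positive", call. = FALSE)
  if (any(h < 0 | h >= 1)) stop("h must be in [0, 1)", call. = FALSE)
  lambda0 * (1 - b * h)
}

#' Apply class-specific harvest to the projection matrix
#'
#' Every transition and fecundity entry sourced from class `j` is multiplied
#' by `1 - h_j`.  With `gosling_first_fall = TRUE` the offspring produced in
#' the fecundity entries are additionally discounted by their own quality
#' class's gosling rate, reflecting a census that a cohort first enters only
#' after its first autumn harvest.
#'
#' @param M A `projection_matrix`.
#' @param h_rates 6-vector of class rates in `[0, 1)`.
#' @param gosling_first_fall Expose offspring to their first-autumn gosling
#'   harvest inside the fecundity terms.
#' @return The harvested matrix.
#' @export
harvest_matrix <- function(M, h_rates, gosling_first_fall = FALSE) {
  if (any(h_rates < 0 | h_rates >= 1)) stop("rates must be in [0, 1)", call. = FALSE)
  A <- .as_plain(M) %*% diag(1 - h_rates)
  if (gosling_first_fall) {
    gos <- c(1L, 4L)
    # fecundity entries are the GOS-row entries not sourced from goslings
    for (i in gos) A[i, -gos] <- A[i, -gos] * (1 - h_rates[i])
  }
  dimnames(A) <- dimnames(M)
  structure(A, rates = attr(M, "rates"),
            class = c("projection_matrix", "matrix", "array"))
}

#' Growth rate of the harvested matrix
#'
#' @inheritParams harvest_matrix
#' @return Dominant eigenvalue of the harvested matrix.
#' @export
lambda_harvested <- function(M, h_rates, gosling_first_fall = FALSE) {
  lambda_dominant(harvest_matrix(M, h_rates, gosling_first_fall))
}

#' Population-level annual survival under harvest
#'
#' Stable-structure-weighted survival with class-specific harvest
#' (`sum w_i s_i (1 - h_i)`) against the homogeneous benchmark in which the
#' same overall proportion is removed uniformly (`(sum w_i s_i) (1 - h)`).
#'
#' @param w Stable structure.
#' @param class_survivals Annual survival of each of the six states.
#' @param h_rates Class-specific harvest rates.
#' @param h_total Overall harvest proportion (defaults to `sum(w * h_rates)`).
#' @return Named vector `c(with_heterogeneity = , homogeneous = )`.
#' @export
population_survival <- function(w, class_survivals, h_rates,
                                h_total = sum(w * h_rates)) {
  c(with_heterogeneity = sum(w * class_survivals * (1 - h_rates)),
    homogeneous = sum(w * class_survivals) * (1 - h_total))
}

.class_survivals <- function(r) {
  sPB <- function(g) if (r$variant == "pb_adult") r$phiA
                     else if (g == "A") r$s2_A else r$s2_B
  c(GOS_A = r$s1_A, PB_A = sPB("A"), BR_A = r$phiA,
    GOS_B = r$s1_B, PB_B = sPB("B"), BR_B = r$phiA)
}

#' Evaluate a harvest scenario over its grid
#'
#' For every overall proportion in the scenario's grid, computes the class
#' rates, the three growth-rate curves (uniform, sensitivity approximation,
#' and the dominant eigenvalue of the harvested matrix) and the two
#' population-survival curves; the compensation index b depends only on the
#' vulnerability ratios and is reported once.
#'
#' @param M A `projection_matrix` built by [build_matrix()].
#' @param scenario A `harvest_scenario`.
#' @param gosling_first_fall Passed to [harvest_matrix()] for the direct
#'   curve (default `TRUE`: offspring face their first-autumn harvest before
#'   entering the census).
#' @return An object of class `scenario_result`: list with `b`, `h_rates_unit`
#'   (rates at the first positive grid point) and a tidy `table`.
#' @export
run_scenario <- function(M, scenario, gosling_first_fall = TRUE) {
  w <- stable_structure(M)
  v <- reproductive_values(M)
  lam0 <- lambda_dominant(M)
  r <- attr(M, "rates")
  surv <- .class_survivals(r)
  hg <- scenario$h_grid
  href <- if (any(hg > 0)) min(hg[hg > 0]) else 0.01
  b <- compensation_index(w, v, class_harvest_rates(scenario, w, href))
  rows <- lapply(hg, function(h) {
    hi <- class_harvest_rates(scenario, w, h)
    s <- population_survival(w, surv, hi, h)
    data.frame(h = h,
               lambda_uniform = lambda_uniform(lam0, h),
               lambda_sensitivity = lambda_sensitivity(lam0, b, h),
               lambda_direct = lambda_harvested(M, hi, gosling_first_fall),
               S_with_het = s[["with_heterogeneity"]],
               S_homogeneous = s[["homogeneous"]])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(h = numeric(0), lambda_uniform = numeric(0),
               lambda_sensitivity = numeric(0), lambda_direct = numeric(0),
               S_with_het = numeric(0), S_homogeneous = numeric(0))
  structure(list(b = b, scenario = scenario, lambda0 = lam0, w = w, v = v,
                 table = tab), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<scenario_result> quality ratio %.2f, stage ratio %.2f, b = %.3f, lambda0 = %.4f\n",
              s$ratio_quality, s$ratio_stage, x$b, x$lambda0))
  print(utils::head(x$table, 12), row.names = FALSE)
  invisible(x)
}

#' Compensation indices of the three reference harvest scenarios
#'
#' Scenario 1: equal clutches, quality ratio 0.5, stage ratio 2.
#' Scenario 2: clutches 5/3, quality ratio 0.5, stage ratio 2.
#' Scenario 3: clutches 5/3, quality ratio 0.3, stage ratio 3.
#' Each b is computed on the d = 0.8 matrix with that scenario's clutches.
#'
#' @param r Baseline `demographic_rates`.
#' @param s0 Calibrated fecundity multiplier (see [quality_scenarios()]).
#' @return `data.frame`, one row per scenario, including b.
#' @export
harvest_reference_scenarios <- function(r = demographic_rates(), s0) {
  defs <- list(list(C = c(4, 4), rq = 0.5, rs = 2),
               list(C = c(5, 3), rq = 0.5, rs = 2),
               list(C = c(5, 3), rq = 0.3, rs = 3))
  out <- lapply(seq_along(defs), function(k) {
    df <- defs[[k]]
    rr <- r; rr$d <- 0.8; rr$C_A <- df$C[1L]; rr$C_B <- df$C[2L]; rr$s0 <- s0
    M <- build_matrix(rr)
    w <- stable_structure(M); v <- reproductive_values(M)
    sc <- harvest_scenario(df$rq, df$rs)
    b <- compensation_index(w, v, class_harvest_rates(sc, w, 0.05))
    data.frame(scenario = k, clutch_high = df$C[1L], clutch_low = df$C[2L],
               ratio_quality = df$rq, ratio_stage = df$rs, b = b,
               lambda0 = lambda_dominant(M))
  })
  do.call(rbind, out)
}

#' Plot the growth-rate curves of a harvest scenario
#'
#' Dotted: uniform harvest (no compensation); thin solid: sensitivity
#' approximation; thick solid: dominant eigenvalue of the harvested matrix.
#'
#' @param x A `scenario_result`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot_scenario <- function(x, ...) {
  tab <- x$table
  graphics::matplot(tab$h, tab[, c("lambda_uniform", "lambda_sensitivity",
                                   "lambda_direct")],
                    type = "l", lty = c(3, 1, 1), lwd = c(1, 1, 2.5),
                    col = "black", xlab = "proportion of population harvested",
                    ylab = expression(lambda), ...)
  graphics::abline(h = 1, col = "grey70")
  invisible(x)
}
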