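# Six-state, two-quality post-breeding-census projection model.
#
# State order: GOS_A, PB_A, BR_A, GOS_B, PB_B, BR_B (gosling, lumped
# prebreeder, breeder, by quality class).  Entry (i, j) is the contribution
# of state j at time t to state i at t + 1.  Fecundity is credited both to
# breeders that survive the year and to prebreeders that survive and recruit
# (a recruit breeds at the census it joins), each mother producing C/2 female
# eggs discounted by the egg-to-census multiplier s0 and split between the
# offspring quality classes by the inheritance probability d.

.MSTATES <- c("GOS_A", "PB_A", "BR_A", "GOS_B", "PB_B", "BR_B")

#' Demographic rates of the two-quality matrix model
#'
#' @param s1_A,s1_B First-year survival per quality class.
#' @param phiA Adult annual survival (shared by the classes).
#' @param a_A,a_B Annual recruitment probabilities.
#' @param C_A,C_B Clutch sizes (eggs).
#' @param d Inheritance: probability an offspring is in its mother's quality
#'   class (applied symmetrically).
#' @param s0 Egg-to-census fecundity multiplier; subsumes hatching, pre-census
#'   gosling survival and the female-only bookkeeping.  Usually obtained from
#'   [calibrate_s0()] rather than set directly.
#' @param s2_A,s2_B Second-year survival; defaults equal to first-year
#'   survival and only used by the `pb_juvenile` variant.
#' @param variant Survival applied to the lumped prebreeder stage:
#'   `"pb_adult"` (adult survival; prebreeders here are mostly age 2+) or
#'   `"pb_juvenile"` (class-specific juvenile survival).
#' @return An object of class `demographic_rates`.
#' @export
demographic_rates <- function(s1_A = 0.73, s1_B = 0.50, phiA = 0.85,
                              a_A = 0.54, a_B = 0.31, C_A = 4, C_B = 4,
                              d = 0.8, s0 = 0.25,
                              s2_A = s1_A, s2_B = s1_B,
                              variant = c("pb_adult", "pb_juvenile")) {
  variant <- match.arg(variant)
  pr <- c(s1_A, s1_B, phiA, a_A, a_B, d, s0, s2_A, s2_B)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (C_A <= 0 || C_B <= 0) stop("clutch sizes must be positive", call. = FALSE)
  structure(list(s1_A = s1_A, s1_B = s1_B, phiA = phiA, a_A = a_A, a_B = a_B,
                 C_A = C_A, C_B = C_B, d = d, s0 = s0, s2_A = s2_A,
                 s2_B = s2_B, variant = variant),
            class = "demographic_rates")
}

#' Build the six-state projection matrix
#'
#' @param r A `demographic_rates` object.
#' @return A `projection_matrix` (6 x 6 matrix with the rates attached).
#' @export
build_matrix <- function(r) {
  stopifnot(inherits(r, "demographic_rates"))
  sPB <- function(g) {
    if (r$variant == "pb_adult") r$phiA
    else if (g == "A") r$s2_A else r$s2_B
  }
  M <- matrix(0, 6L, 6L, dimnames = list(.MSTATES, .MSTATES))
  for (g in c("A", "B")) {
    o <- if (g == "A") 0L else 3L       # block offset
    oo <- if (g == "A") 3L else 0L      # other block
    s1 <- if (g == "A") r$s1_A else r$s1_B
    ag <- if (g == "A") r$a_A else r$a_B
    f <- (if (g == "A") r$C_A else r$C_B) / 2 * r$s0  # female eggs to census
    M[o + 2L, o + 1L] <- s1                        # gosling -> prebreeder
    M[o + 2L, o + 2L] <- sPB(g) * (1 - ag)         # prebreeder stays
    M[o + 3L, o + 2L] <- sPB(g) * ag               # recruits
    M[o + 3L, o + 3L] <- r$phiA                    # breeder survives
    # fecundity: surviving breeders and newly recruiting prebreeders breed
    M[o + 1L, o + 3L] <- M[o + 1L, o + 3L] + r$phiA * f * r$d
    M[oo + 1L, o + 3L] <- M[oo + 1L, o + 3L] + r$phiA * f * (1 - r$d)
    M[o + 1L, o + 2L] <- M[o + 1L, o + 2L] + sPB(g) * ag * f * r$d
    M[oo + 1L, o + 2L] <- M[oo + 1L, o + 2L] + sPB(g) * ag * f * (1 - r$d)
  }
  structure(M, rates = r, class = c("projection_matrix", "matrix", "array"))
}

.as_plain <- function(M) { attr(M, "rates") <- NULL; unclass(M) }

.dominant <- function(M) {
  e <- eigen(.as_plain(M))
  i <- which.max(Re(e$values))
  if (abs(Im(e$values[i])) > 1e-10)
    warning("dominant eigenvalue has a nonzero imaginary part; ",
            "matrix may not be primitive")
  lam <- Re(e$values[i])
  mods <- sort(Mod(e$values), decreasing = TRUE)
  if (length(mods) > 1L && mods[2L] > mods[1L] - 1e-12)
    warning("dominant eigenvalue is not simple; matrix is not primitive")
  lam
}

#' Dominant eigenvalue (asymptotic growth rate)
#'
#' @param M A nonnegative `projection_matrix` (or plain matrix).
#' @param method `"eigen"` (direct decomposition) or `"power"` (power
#'   iteration to 1e-10, kept as an independent numerical cross-check).
#' @return The spectral radius lambda.
#' @export
lambda_dominant <- function(M, method = c("eigen", "power")) {
  method <- match.arg(method)
  if (any(M < 0)) stop("matrix must be nonnegative", call. = FALSE)
  if (method == "eigen") return(.dominant(M))
  A <- .as_plain(M)
  x <- rep(1, ncol(A))
  lam <- 1
  for (i in seq_len(100000L)) {
    y <- A %*% x
    lam_new <- sqrt(sum(y^2))
    if (lam_new == 0) stop("matrix maps the positive cone to zero", call. = FALSE)
    y <- y / lam_new
    if (max(abs(y - x)) < 1e-12 && abs(lam_new - lam) < 1e-10) {
      return(sum(y * (A %*% y)) / sum(y^2))
    }
    x <- y; lam <- lam_new
  }
  warning("power iteration did not converge to 1e-10")
  sum(x * (A %*% x)) / sum(x^2)
}

#' Stable state structure (right eigenvector, summing to one)
#'
#' @param M A `projection_matrix`.
#' @return Nonnegative 6-vector `w` with `sum(w) = 1`.
#' @export
stable_structure <- function(M) {
  A <- .as_plain(M)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  if (any(w < -1e-10)) warning("negative entries in the stable structure; ",
                               "matrix may not be primitive")
  stats::setNames(pmax(w, 0) / sum(pmax(w, 0)), .MSTATES[seq_len(nrow(A))])
}

#' Reproductive values (left eigenvector, summing to one)
#'
#' Normalised so the six entries sum to one, the convention under which each
#' scenario's values are directly comparable across classes.
#'
#' @param M A `projection_matrix`.
#' @return Nonnegative 6-vector `v` with `sum(v) = 1`.
#' @export
reproductive_values <- function(M) {
  A <- .as_plain(M)
  e <- eigen(t(A))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) warning("negative entries in reproductive values; ",
                               "matrix may not be primitive")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), .MSTATES[seq_len(nrow(A))])
}

#' Calibrate the egg-to-census fecundity multiplier
#'
#' The literature components of fecundity (hatching success, gosling survival
#' to the census) are folded into a single multiplier `s0`, chosen so the
#' projection matrix attains a target growth rate; lambda is continuous and
#' strictly increasing in `s0`, so the root is unique.
#'
#' @param r A `demographic_rates` object (its `s0` is ignored).
#' @param target_lambda Growth rate to match.
#' @param interval Search interval for `s0`.
#' @param tol Root tolerance on lambda.
#' @return The calibrated `s0`.
#' @export
calibrate_s0 <- function(r, target_lambda, interval = c(1e-9, 1), tol = 1e-10) {
  f <- function(s0) {
    r$s0 <- s0
    lambda_dominant(build_matrix(r)) - target_lambda
  }
  lo <- f(interval[1L]); hi <- f(interval[2L])
  if (lo > 0 || hi < 0)
    stop(sprintf("target lambda %.4f not attainable for s0 in (%g, %g]",
                 target_lambda, interval[1L], interval[2L]), call. = FALSE)
  stats::uniroot(f, interval, tol = 1e-12)$root
}

#' Choose the prebreeder-survival variant against reference growth rates
#'
#' For each candidate variant the fecundity multiplier is calibrated on the
#' anchor scenario and the remaining reference growth rates are rescored; the
#' variant with the smaller summed absolute error wins, with `pb_adult`
#' preferred on ties.
#'
#' @param r A `demographic_rates` object (variant and `s0` ignored).
#' @param anchor List with `d`, `C` (length 2) and `lambda` for calibration.
#' @param checks List of further lists with `d`, `C`, `lambda` to score.
#' @return List with the winning `variant`, per-variant `scores`, and the
#'   calibrated `s0` of the winner.
#' @export
select_variant <- function(r,
                           anchor = list(d = 0.8, C = c(4, 4), lambda = 1.058),
                           checks = list(list(d = 0.5, C = c(4, 4), lambda = 1.044),
                                         list(d = 0.8, C = c(5, 3), lambda = 1.090))) {
  score_one <- function(variant) {
    rr <- r; rr$variant <- variant
    rr$d <- anchor$d; rr$C_A <- anchor$C[1L]; rr$C_B <- anchor$C[2L]
    s0 <- calibrate_s0(rr, anchor$lambda)
    rr$s0 <- s0
    err <- sum(vapply(checks, function(ck) {
      r2 <- rr; r2$d <- ck$d; r2$C_A <- ck$C[1L]; r2$C_B <- ck$C[2L]
      abs(lambda_dominant(build_matrix(r2)) - ck$lambda)
    }, numeric(1)))
    list(s0 = s0, err = err)
  }
  sc <- lapply(c(pb_adult = "pb_adult", pb_juvenile = "pb_juvenile"), score_one)
  errs <- vapply(sc, `[[`, numeric(1), "err")
  win <- if (errs[["pb_juvenile"]] < errs[["pb_adult"]]) "pb_juvenile" else "pb_adult"
  list(variant = win, scores = errs, s0 = sc[[win]]$s0)
}

#' Growth rates and reproductive values under inheritance scenarios
#'
#' Builds the three reference scenarios (inheritance 0.8 with equal clutches,
#' no inheritance 0.5 with equal clutches, inheritance 0.8 with clutch sizes
#' 5 vs 3), calibrating `s0` on the first when not supplied, and tabulates
#' lambda with the six normalised reproductive values.
#'
#' @param r Baseline `demographic_rates` (clutches/d overridden per row).
#' @param s0 Calibrated fecundity multiplier; when `NULL`, calibrated so the
#'   first scenario gives `anchor_lambda`.
#' @param anchor_lambda Growth rate used for calibration (default 1.058).
#' @return `data.frame` with one row per scenario.
#' @export
quality_scenarios <- function(r = demographic_rates(), s0 = NULL,
                              anchor_lambda = 1.058) {
  rows <- list(list(d = 0.8, C = c(4, 4)),
               list(d = 0.5, C = c(4, 4)),
               list(d = 0.8, C = c(5, 3)))
  if (is.null(s0)) {
    rr <- r; rr$d <- 0.8; rr$C_A <- 4; rr$C_B <- 4
    s0 <- calibrate_s0(rr, anchor_lambda)
  }
  out <- lapply(rows, function(sc) {
    rr <- r; rr$d <- sc$d; rr$C_A <- sc$C[1L]; rr$C_B <- sc$C[2L]; rr$s0 <- s0
    M <- build_matrix(rr)
    v <- reproductive_values(M)
    data.frame(inheritance = sc$d, clutch_high = sc$C[1L], clutch_low = sc$C[2L],
               lambda = lambda_dominant(M), t(v), check.names = FALSE)
  })
  df <- do.call(rbind, out)
  attr(df, "s0") <- s0
  df
}
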