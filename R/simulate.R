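#' Describe a simulation design
#'
#' @param T Number of occasions.
#' @param cohort_sizes_HY Goslings marked per occasion (length `T`; the last
#'   entry must be 0 since a gosling marked at `T` could never be re-observed).
#' @param cohort_sizes_ASY Adult breeders marked per occasion (length `T`).
#' @param params Generating `brant_params`.
#' @param seed Master seed; per-individual RNG streams are derived from it so
#'   output is independent of simulation order.
#' @return An object of class `sim_design`.
#' @export
simulation_design <- function(T, cohort_sizes_HY, cohort_sizes_ASY, params,
                              seed = 1L) {
  T <- as.integer(T)
  pad <- function(v) {
    v <- as.integer(v)
    if (length(v) == 1L) v <- rep.int(v, T)
    if (length(v) > T) stop("cohort size vector longer than T", call. = FALSE)
    c(v, integer(T - length(v)))
  }
  hy <- pad(cohort_sizes_HY)
  asy <- pad(cohort_sizes_ASY)
  if (hy[T] > 0L) stop("no HY cohort may be released at the last occasion",
                       call. = FALSE)
  if (any(hy < 0L) || any(asy < 0L) || sum(hy) + sum(asy) == 0L)
    stop("cohort sizes must be nonnegative with at least one positive",
         call. = FALSE)
  stopifnot(inherits(params, "brant_params"), params$T == T)
  structure(list(T = T, cohort_sizes_HY = hy, cohort_sizes_ASY = asy,
                 params = params, seed = as.integer(seed)),
            class = "sim_design")
}

# per-individual seed, kept under 2^31
.ind_seed <- function(master, i) as.integer((master + i * 48271) %% 2147483629 + 1)

#' Simulate encounter histories from the mixture multievent model
#'
#' Each individual draws its latent quality class from the release occasion's
#' initial-class probability, then walks the hidden chain: goslings survive
#' their first and second year with the year- and class-specific juvenile
#' survival (equal across the two juvenile years), can recruit from age 2 at
#' the class-specific constant rate, and survive as adults thereafter; birds
#' marked as breeders enter the breeder state directly.  Only breeders can be
#' detected, with the occasion- and class-specific detection probability, so
#' one-year-olds are never encountered.  Identical design and seed give
#' identical output.
#'
#' @param design A `sim_design` object.
#' @param keep_latent Attach the simulated truth as attributes:
#'   `latent_group` (1 = A, 2 = B per individual) and `latent_states`
#'   (individuals by occasions matrix of state codes in the order of
#'   [brant_states()]; 0 before release and after the first dead census).
#'   Useful for calibration tests; the
#'   likelihood machinery never sees these.
#' @return An `encounter_histories` object, one row per individual (collapse
#'   with [collapse_histories()] for likelihood work).
#' @export
simulate_histories <- function(design, keep_latent = FALSE) {
  stopifnot(inherits(design, "sim_design"))
  pp <- design$params; Tn <- design$T
  etaB <- function(f) f$intercept + f$year + f$yearB - f$groupB
  phiJ <- cbind(A = stats::plogis(pp$phiJ$intercept + pp$phiJ$year),
                B = stats::plogis(etaB(pp$phiJ)))
  pdet <- cbind(A = stats::plogis(pp$p$intercept + pp$p$year),
                B = stats::plogis(etaB(pp$p)))
  piA <- pp$piA; phiA <- pp$phiA; a <- pp$a
  n <- sum(design$cohort_sizes_HY) + sum(design$cohort_sizes_ASY)
  ev <- matrix(0L, n, Tn)
  entry <- character(n)
  rel <- integer(n)
  grp <- integer(n)
  stmat <- if (keep_latent) matrix(0L, n, Tn)
  scode <- function(state, g) switch(state, GOS = g, PB1 = 2L + g,
                                     PB2 = 4L + g, BR = 6L + g, DEAD = 9L)
  row <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (cls in c("HY", "ASY")) {
    sizes <- if (cls == "HY") design$cohort_sizes_HY else design$cohort_sizes_ASY
    for (r in which(sizes > 0L)) for (k in seq_len(sizes[r])) {
      row <- row + 1L
      set.seed(.ind_seed(design$seed, row))
      entry[row] <- cls; rel[row] <- r
      g <- if (stats::runif(1) < piA[r]) 1L else 2L  # 1 = A, 2 = B
      grp[row] <- g
      ev[row, r] <- if (cls == "HY") 2L else 1L
      state <- if (cls == "HY") "GOS" else "BR"
      if (keep_latent) stmat[row, r] <- scode(state, g)
      if (r < Tn) for (t in r:(Tn - 1L)) {
        state <- switch(state,
          GOS = if (stats::runif(1) < phiJ[t, g]) "PB1" else "DEAD",
          PB1 = if (stats::runif(1) < phiJ[t, g]) {
                  if (stats::runif(1) < a[g]) "BR" else "PB2"
                } else "DEAD",
          PB2 = if (stats::runif(1) < phiA) {
                  if (stats::runif(1) < a[g]) "BR" else "PB2"
                } else "DEAD",
          BR  = if (stats::runif(1) < phiA) "BR" else "DEAD",
          DEAD = "DEAD")
        if (keep_latent) stmat[row, t + 1L] <- scode(state, g)
        if (state == "DEAD") break
        if (state == "BR" && stats::runif(1) < pdet[t + 1L, g])
          ev[row, t + 1L] <- 1L
      }
    }
  }
  out <- encounter_histories(ev, entry_class = entry, validate = FALSE)
  if (keep_latent) {
    attr(out, "latent_group") <- grp
    attr(out, "latent_states") <- stmat
  }
  out
}

.split_cohorts <- function(total, occasions, T) {
  sizes <- integer(T)
  k <- length(occasions)
  base <- total %/% k
  sizes[occasions] <- base
  extra <- total - base * k
  if (extra > 0L) sizes[occasions[seq_len(extra)]] <- base + 1L
  sizes
}

#' Named simulation fixtures
#'
#' Three presets used throughout the test machinery, each returning the data
#' together with its generating truth.
#' \describe{
#'   \item{`paper_like`}{T = 20; 3000 goslings (occasions 1-18) and 2000
#'     adults (1-19); generating values are the best-model point estimates of
#'     the brant analysis: first-year survival 0.73 (A) / 0.50 (B) at the mean
#'     year effect with additive year variation (logit SD 0.3), adult survival
#'     0.85, recruitment 0.54 / 0.31, year-varying detection around 0.79 with
#'     class A 0.35 lower on the logit scale (SD 0.4), and year-varying
#'     initial class-A probabilities (logit SD 0.5 around 0.5).  Year effects
#'     are centred so the mean-year values equal the quoted ones.}
#'   \item{`homogeneous`}{T = 10, one quality class (all offsets zero, equal
#'     recruitment), constant rates: juvenile survival 0.6, adult 0.85,
#'     recruitment 0.4, detection 0.75.}
#'   \item{`tiny`}{T = 5 and about a hundred histories, for brute-force
#'     oracle work.}
#' }
#'
#' @param name One of `"tiny"`, `"paper_like"`, `"homogeneous"`.
#' @param seed Master seed.
#' @param n_HY,n_ASY Optional overrides of the marked totals (paper_like only).
#' @return List with elements `histories`, `params` (the truth), `design` and
#'   `spec` (the generating model structure).
#' @export
make_fixture <- function(name = c("paper_like", "homogeneous", "tiny"),
                         seed = 1L, n_HY = NULL, n_ASY = NULL) {
  name <- match.arg(name)
  centred <- function(n, sd, seed_off) {
    set.seed(.ind_seed(seed, seed_off))
    z <- stats::rnorm(n, 0, sd)
    z - mean(z)
  }
  if (name == "paper_like") {
    T <- 20L
    n_HY <- n_HY %||% 3000L; n_ASY <- n_ASY %||% 2000L
    set.seed(.ind_seed(seed, 101L))
    piA <- stats::plogis(stats::rnorm(T, 0, 0.5))
    params <- parameter_set(T, piA = piA,
      phiJ = list(intercept = stats::qlogis(0.73),
                  year = centred(T - 1L, 0.3, 102L),
                  groupB = stats::qlogis(0.73) - stats::qlogis(0.50)),
      phiA = 0.85, a = c(A = 0.54, B = 0.31),
      p = list(intercept = stats::qlogis(0.79) - 0.35,
               year = centred(T, 0.4, 103L),
               groupB = -0.35))   # class A detected *less* than class B
    design <- simulation_design(T, .split_cohorts(n_HY, 1:18, T),
                                .split_cohorts(n_ASY, 1:19, T), params, seed)
    spec <- model_spec(T)
  } else if (name == "homogeneous") {
    T <- 10L
    params <- parameter_set(T, piA = 0.5,
      phiJ = list(intercept = stats::qlogis(0.6), year = 0, groupB = 0),
      phiA = 0.85, a = c(A = 0.4, B = 0.4),
      p = list(intercept = stats::qlogis(0.75), year = 0, groupB = 0))
    design <- simulation_design(T, .split_cohorts(1200L, 1:8, T),
                                .split_cohorts(1200L, 1:8, T), params, seed)
    spec <- model_spec(T, pi = "constant", phiJ = "constant", a = "constant",
                       p = "constant")
  } else { # tiny
    T <- 5L
    params <- parameter_set(T, piA = 0.5,
      phiJ = list(intercept = stats::qlogis(0.7), year = 0, groupB = 1),
      phiA = 0.85, a = c(A = 0.5, B = 0.3),
      p = list(intercept = stats::qlogis(0.8), year = 0, groupB = 0.5))
    design <- simulation_design(T, c(25L, 25L, 0L, 0L, 0L),
                                c(20L, 20L, 20L, 0L, 0L), params, seed)
    spec <- model_spec(T)
  }
  list(histories = simulate_histories(design), params = params,
       design = design, spec = spec)
}
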