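# Hidden-Markov (multievent) likelihood over the nine-state chain.
#
# The chain is annual: a transition (survival, then breeding-state change)
# followed by an emission at the next occasion's census.  Conditioning is on
# the entry event at first capture, so the initial distribution is the
# occasion's quality split restricted to the states compatible with the entry
# code.  All recursions are scaled row-wise to avoid underflow.

# natural-scale arrays used by the recursions
.nat_arrays <- function(params) {
  Tn <- params$T
  etaB <- function(f) f$intercept + f$year + f$yearB - f$groupB
  phiJ <- cbind(stats::plogis(params$phiJ$intercept + params$phiJ$year),
                stats::plogis(etaB(params$phiJ)))
  p <- cbind(stats::plogis(params$p$intercept + params$p$year),
             stats::plogis(etaB(params$p)))
  if (!is.null(params$pi_full)) {
    pf <- params$pi_full  # rows BR_A, PB_A, BR_B, PB_B
    piA_HY <- pf[2L, ] / (pf[2L, ] + pf[4L, ])
    piA_ASY <- pf[1L, ] / (pf[1L, ] + pf[3L, ])
  } else {
    piA_HY <- piA_ASY <- params$piA
  }
  list(T = Tn, phiJ = phiJ, p = p, phiA = params$phiA, a = params$a,
       piA_HY = piA_HY, piA_ASY = piA_ASY)
}

.trans_mat <- function(phiJ2, phiA, a) {
  M <- matrix(0, 9L, 9L, dimnames = list(.STATES, .STATES))
  for (g in 1:2) {
    GOS <- g; PB1 <- 2L + g; PB2 <- 4L + g; BR <- 6L + g
    sj <- phiJ2[g]; ag <- a[g]
    M[GOS, PB1] <- sj;            M[GOS, 9L] <- 1 - sj
    M[PB1, BR] <- sj * ag;        M[PB1, PB2] <- sj * (1 - ag)
    M[PB1, 9L] <- 1 - sj
    M[PB2, BR] <- phiA * ag;      M[PB2, PB2] <- phiA * (1 - ag)
    M[PB2, 9L] <- 1 - phiA
    M[BR, BR] <- phiA;            M[BR, 9L] <- 1 - phiA
  }
  M[9L, 9L] <- 1
  M
}

#' Annual transition kernel of the hidden chain
#'
#' Rows are source states at occasion `occasion`, columns destination states
#' at `occasion + 1` (order of [brant_states()]).  Goslings survive their
#' first year with the juvenile rate; one-year-old prebreeders survive their
#' second year with the same juvenile rate and recruit with the class rate;
#' older prebreeders and breeders survive with the adult rate; breeding is
#' permanent; quality class is fixed for life; all mortality flows to the
#' absorbing dead state.  The expanded age registers make the kernel
#' independent of entry class and time since marking.
#'
#' @param params A `brant_params` object.
#' @param occasion Survival interval index (1 to `T - 1`).
#' @return A 9 x 9 stochastic matrix.
#' @export
build_transition <- function(params, occasion) {
  stopifnot(inherits(params, "brant_params"))
  if (occasion < 1L || occasion > params$T - 1L)
    stop("occasion must be in 1..T-1", call. = FALSE)
  nat <- .nat_arrays(params)
  bad <- c(nat$phiJ[occasion, ], nat$phiA, nat$a)
  if (any(bad < 0 | bad > 1)) stop("probabilities outside [0, 1]", call. = FALSE)
  .trans_mat(nat$phiJ[occasion, ], nat$phiA, nat$a)
}

#' Emission kernel at one occasion
#'
#' Probability of each event code (0 = not encountered, 1 = encountered as a
#' breeder) for each latent state.  Only breeders are detectable; dead birds
#' and prebreeders (including the unobservable one-year-olds) emit 0 with
#' probability one.
#'
#' @param params A `brant_params` object.
#' @param occasion Occasion index (1 to `T`).
#' @return A 9 x 2 matrix with columns `e0`, `e1`.
#' @export
build_emission <- function(params, occasion) {
  stopifnot(inherits(params, "brant_params"))
  if (occasion < 1L || occasion > params$T)
    stop("occasion must be in 1..T", call. = FALSE)
  nat <- .nat_arrays(params)
  E <- matrix(c(rep(1, 9), rep(0, 9)), 9L, 2L,
              dimnames = list(.STATES, c("e0", "e1")))
  for (g in 1:2) {
    E[6L + g, ] <- c(1 - nat$p[occasion, g], nat$p[occasion, g])
  }
  E
}

# initial state vector (9) for one entry class at occasion r
.init_rows <- function(entryASY, first, nat) {
  n <- length(first)
  u <- matrix(0, n, 9L)
  piA <- ifelse(entryASY, nat$piA_ASY[first], nat$piA_HY[first])
  gA <- ifelse(entryASY, 7L, 1L)  # BR_A or GOS_A
  gB <- ifelse(entryASY, 8L, 2L)
  u[cbind(seq_len(n), gA)] <- piA
  u[cbind(seq_len(n), gB)] <- 1 - piA
  u
}

# Scaled forward pass over all histories at once; optionally the adjoint
# (backward) pass giving exact gradients with respect to the natural-scale
# arrays.  Gradients are count-weighted sums over histories.
.forward_pass <- function(x, nat, grad = FALSE) {
  ev <- x$events; n <- nrow(ev); Tn <- x$T
  first <- x$first_occasion
  entryASY <- x$entry_class == "ASY"
  w <- as.numeric(x$count)
  Ms <- lapply(seq_len(Tn - 1L), function(t) .trans_mat(nat$phiJ[t, ], nat$phiA, nat$a))
  init <- .init_rows(entryASY, first, nat)
  BR <- c(7L, 8L)
  emis <- function(t) {
    # n x 9 emission probabilities of the observed event at occasion t:
    # non-breeder states emit 0 with probability 1, breeders detect with p
    y <- as.numeric(ev[, t] == 1L)
    E <- matrix(1 - y, n, 9L)
    E[, 7L] <- y * nat$p[t, 1L] + (1 - y) * (1 - nat$p[t, 1L])
    E[, 8L] <- y * nat$p[t, 2L] + (1 - y) * (1 - nat$p[t, 2L])
    E
  }
  alpha <- matrix(0, n, 9L)
  ll <- numeric(n)
  Cs <- matrix(1, n, Tn)
  ALPHA <- if (grad) array(0, c(n, 9L, Tn))
  PHI <- if (grad) array(0, c(n, 9L, Tn))
  for (t in seq_len(Tn)) {
    if (t > 1L) {
      phi <- alpha %*% Ms[[t - 1L]]          # zero rows for not-yet-released
      z <- phi * emis(t)
      cs <- rowSums(z)
      cont <- first < t
      cs[!cont] <- 1
      ll[cont] <- ll[cont] + log(cs[cont])  # -Inf for impossible histories
      alpha <- z / ifelse(cs > 0, cs, 1)
      alpha[!cont, ] <- 0
      Cs[, t] <- ifelse(cs > 0, cs, 1)
      if (grad) PHI[, , t] <- phi
    }
    rel <- first == t
    if (any(rel)) alpha[rel, ] <- init[rel, , drop = FALSE]
    if (grad) ALPHA[, , t] <- alpha
  }
  out <- list(loglik = ll)
  if (!grad) return(out)

  dphiJ <- matrix(0, Tn - 1L, 2L); dp <- matrix(0, Tn, 2L)
  dphiA <- 0; da <- c(0, 0)
  dpiA_HY <- numeric(Tn); dpiA_ASY <- numeric(Tn)
  beta <- matrix(1, n, 9L)
  rec_init <- function(t, beta) {
    rel <- which(first == t)
    for (h in rel) {
      g <- if (entryASY[h]) c(7L, 8L) else c(1L, 2L)
      d <- w[h] * (beta[h, g[1L]] - beta[h, g[2L]])
      if (entryASY[h]) dpiA_ASY[t] <<- dpiA_ASY[t] + d
      else dpiA_HY[t] <<- dpiA_HY[t] + d
    }
  }
  for (t in Tn:2L) {
    rec_init(t, beta)
    E <- emis(t)
    R <- E * beta / Cs[, t]
    # emission gradient: d logL / d p(t, g)
    sgn <- ifelse(ev[, t] == 1L, 1, -1)
    D <- PHI[, , t] * beta / Cs[, t]
    dp[t, 1L] <- sum(w * sgn * D[, 7L])
    dp[t, 2L] <- sum(w * sgn * D[, 8L])
    # transition gradient: G[i, j] = sum_h w_h alpha_{t-1}[h,i] R[h,j]
    G <- crossprod(ALPHA[, , t - 1L], R * w)
    M <- Ms[[t - 1L]]
    for (g in 1:2) {
      GOS <- g; PB1 <- 2L + g; PB2 <- 4L + g; BRg <- 6L + g
      sj <- nat$phiJ[t - 1L, g]; ag <- nat$a[g]
      dphiJ[t - 1L, g] <- dphiJ[t - 1L, g] +
        G[GOS, PB1] - G[GOS, 9L] +
        G[PB1, BRg] * ag + G[PB1, PB2] * (1 - ag) - G[PB1, 9L]
      da[g] <- da[g] + G[PB1, BRg] * sj - G[PB1, PB2] * sj +
        G[PB2, BRg] * nat$phiA - G[PB2, PB2] * nat$phiA
      dphiA <- dphiA + G[PB2, BRg] * ag + G[PB2, PB2] * (1 - ag) -
        G[PB2, 9L] + G[BRg, BRg] - G[BRg, 9L]
    }
    beta <- R %*% t(M)
  }
  rec_init(1L, beta)
  out$grad <- list(phiJ = dphiJ, p = dp, phiA = dphiA, a = da,
                   piA_HY = dpiA_HY, piA_ASY = dpiA_ASY)
  out
}

#' Log-likelihood of a single encounter history
#'
#' Forward algorithm over the latent states, conditioned on first capture:
#' the chain starts from the occasion's quality split restricted to the states
#' compatible with the entry event, then alternates transition and emission
#' through the final occasion.  The recursion is scaled, so long histories
#' with high detection do not underflow.
#'
#' @param h An `encounter_histories` object (each row scored separately).
#' @param params A `brant_params` object.
#' @return Numeric vector of per-history log-likelihoods (count-unweighted).
#' @export
history_loglik <- function(h, params) {
  stopifnot(inherits(h, "encounter_histories"), inherits(params, "brant_params"))
  if (h$T != params$T) stop("history and parameter T disagree", call. = FALSE)
  validate_histories(h)
  .forward_pass(h, .nat_arrays(params))$loglik
}

#' Count-weighted dataset log-likelihood and deviance
#'
#' Sums `count`-weighted history log-likelihoods; identical histories are
#' collapsed first, which cannot change the value.
#'
#' @param histories An `encounter_histories` object.
#' @param params A `brant_params` object.
#' @return List with `loglik` and `deviance` (`-2 * loglik`).
#' @export
dataset_loglik <- function(histories, params) {
  stopifnot(inherits(histories, "encounter_histories"))
  if (nrow(histories$events) == 0L) stop("empty collection", call. = FALSE)
  x <- collapse_histories(histories)
  ll <- sum(x$count * .forward_pass(x, .nat_arrays(params))$loglik)
  list(loglik = ll, deviance = -2 * ll)
}
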