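# Independent oracles used across the suite.

# Brute-force likelihood of one history by explicit enumeration of every
# latent state path.  Kernels are assembled here from natural_scale() lookups,
# independently of the package's forward recursion.
oracle_loglik <- function(ev, first, entry, params) {
  Tn <- length(ev)
  S <- brant_states()
  ns <- length(S)
  piA <- natural_scale(params, "pi", first, "A")
  init <- numeric(ns)
  if (entry == "HY") {
    init[match(c("GOS_A", "GOS_B"), S)] <- c(piA, 1 - piA)
  } else {
    init[match(c("BR_A", "BR_B"), S)] <- c(piA, 1 - piA)
  }
  trans <- function(t) {
    M <- matrix(0, ns, ns, dimnames = list(S, S))
    for (g in c("A", "B")) {
      sj <- natural_scale(params, "phiJ", t, g)
      sa <- natural_scale(params, "phiA", t, g)
      ag <- natural_scale(params, "a", t, g)
      M[paste0("GOS_", g), paste0("PB1_", g)] <- sj
      M[paste0("GOS_", g), "DEAD"] <- 1 - sj
      M[paste0("PB1_", g), paste0("BR_", g)] <- sj * ag
      M[paste0("PB1_", g), paste0("PB2_", g)] <- sj * (1 - ag)
      M[paste0("PB1_", g), "DEAD"] <- 1 - sj
      M[paste0("PB2_", g), paste0("BR_", g)] <- sa * ag
      M[paste0("PB2_", g), paste0("PB2_", g)] <- sa * (1 - ag)
      M[paste0("PB2_", g), "DEAD"] <- 1 - sa
      M[paste0("BR_", g), paste0("BR_", g)] <- sa
      M[paste0("BR_", g), "DEAD"] <- 1 - sa
    }
    M["DEAD", "DEAD"] <- 1
    M
  }
  emit <- function(t, s, y) {
    p <- if (S[s] == "BR_A") natural_scale(params, "p", t, "A")
         else if (S[s] == "BR_B") natural_scale(params, "p", t, "B") else 0
    if (y == 1L) p else 1 - p
  }
  if (first == Tn) return(0)
  nsteps <- Tn - first
  Ms <- lapply(first:(Tn - 1L), trans)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), nsteps)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    for (s0 in which(init > 0)) {
      pr <- init[s0]; prev <- s0
      for (k in seq_len(nsteps)) {
        s <- paths[r, k]
        pr <- pr * Ms[[k]][prev, s] * emit(first + k, s, ev[first + k])
        if (pr == 0) break
        prev <- s
      }
      tot <- tot + pr
    }
  }
  log(tot)
}

# a random interior parameter set on T occasions
random_params <- function(T, het = TRUE) {
  parameter_set(T,
    piA = runif(T, 0.2, 0.8),
    phiJ = list(intercept = runif(1, -1, 1.5), year = runif(T - 1, -0.5, 0.5),
                groupB = if (het) runif(1, 0, 2) else 0),
    phiA = runif(1, 0.6, 0.95),
    a = if (het) c(A = runif(1, 0.2, 0.8), B = runif(1, 0.1, 0.6))
        else { v <- runif(1, 0.2, 0.7); c(A = v, B = v) },
    p = list(intercept = runif(1, 0, 2), year = runif(T, -0.5, 0.5),
             groupB = if (het) runif(1, -1, 1) else 0))
}
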