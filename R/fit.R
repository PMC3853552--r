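# Maximum-likelihood fitting of the multievent mixture model.
#
# Free coefficients live on the logit scale and are clamped to [-15, 15];
# a coefficient at the bound corresponds to a probability estimated at 0 or 1
# and is flagged rather than trusted.  The objective uses the exact adjoint
# gradient of the scaled forward recursion (see likelihood.R), which makes
# quasi-Newton optimisation practical for year-rich structures.

.trend_x <- function(idx) {
  x <- numeric(max(idx))
  x[idx] <- (idx - mean(idx)) / stats::sd(idx)
  x
}

# parameter-vector layout for a given structure and data
.par_layout <- function(spec, pi_occasions, covariate = NULL) {
  Tn <- spec$T
  fams <- spec$families
  mix <- spec$heterogeneous
  fam_labels <- function(f, fname, free_idx) {
    lab <- paste0(fname, ".int")
    if (f$year) lab <- c(lab, paste0(fname, ".yr", free_idx))
    if (f$trend) lab <- c(lab, paste0(fname, ".trend"))
    if (f$cov) lab <- c(lab, paste0(fname, ".cov"))
    if (f$group && mix) {
      lab <- c(lab, paste0(fname, ".gB"))
      if (f$relation == "interactive" && f$year)
        lab <- c(lab, paste0(fname, ".yrB", free_idx))
    }
    lab
  }
  yr_phiJ <- if (Tn >= 3L) seq(2L, Tn - 1L) else integer(0)  # ref: interval 1
  yr_p <- if (Tn >= 3L) seq(3L, Tn) else integer(0)          # ref: occasion 2
  labels <- c(
    if (mix) {
      if (spec$pi == "year") paste0("pi.occ", pi_occasions) else "pi"
    },
    fam_labels(fams$phiJ, "phiJ", yr_phiJ),
    "phiA",
    if (fams$a$group && mix) c("a.A", "a.B") else "a",
    fam_labels(fams$p, "p", yr_p))
  if (fams$phiJ$cov && is.null(covariate))
    stop("phiJ covariate requested but no covariate supplied", call. = FALSE)
  list(labels = labels, npar = length(labels), Tn = Tn, mix = mix,
       pi_occasions = pi_occasions, spec = spec, covariate = covariate,
       yr_phiJ = yr_phiJ, yr_p = yr_p,
       x_phiJ = .trend_x(seq_len(Tn - 1L)), x_p = .trend_x(2:Tn))
}

# split a parameter vector into named family pieces
.par_split <- function(layout, par) {
  lab <- layout$labels
  pick <- function(rx) par[grep(rx, lab)]
  fam <- function(fname, nyr_idx, xs, len) {
    f <- layout$spec$families[[fname]]
    yd <- numeric(len)
    if (f$year) yd[nyr_idx] <- pick(paste0("^", fname, "\\.yr[0-9]+$"))
    if (f$trend) yd <- yd + pick(paste0("^", fname, "\\.trend$")) * xs
    if (f$cov) yd <- yd + pick(paste0("^", fname, "\\.cov$")) * layout$covariate
    ydB <- numeric(len)
    gB <- 0
    if (f$group && layout$mix) {
      gB <- pick(paste0("^", fname, "\\.gB$"))
      if (f$relation == "interactive" && f$year)
        ydB[nyr_idx] <- pick(paste0("^", fname, "\\.yrB[0-9]+$"))
    }
    list(intercept = unname(pick(paste0("^", fname, "\\.int$"))),
         year = yd, yearB = ydB, groupB = unname(gB))
  }
  Tn <- layout$Tn
  list(pi = pick("^pi"),
       phiJ = fam("phiJ", layout$yr_phiJ, layout$x_phiJ, Tn - 1L),
       phiA = unname(pick("^phiA$")),
       a = pick("^a\\b"),
       p = fam("p", layout$yr_p, layout$x_p, Tn))
}

# natural-scale arrays (and the params object) from a parameter vector
.par_to_params <- function(layout, par) {
  sp <- .par_split(layout, par)
  Tn <- layout$Tn
  piA <- rep(0.5, Tn)
  if (layout$mix) {
    th <- sp$pi
    if (layout$spec$pi == "year") piA[layout$pi_occasions] <- stats::plogis(th)
    else piA[] <- stats::plogis(th)
  } else piA[] <- 1
  aa <- if (length(sp$a) == 2L) stats::plogis(sp$a) else rep(stats::plogis(sp$a), 2L)
  pp <- parameter_set(Tn, piA = piA,
                      phiJ = list(intercept = sp$phiJ$intercept, year = sp$phiJ$year,
                                  yearB = sp$phiJ$yearB, groupB = sp$phiJ$groupB),
                      phiA = stats::plogis(sp$phiA),
                      a = c(A = unname(aa[1L]), B = unname(aa[2L])),
                      p = list(intercept = sp$p$intercept, year = sp$p$year,
                               yearB = sp$p$yearB, groupB = sp$p$groupB))
  pp
}

# chain-rule the natural-array gradient back to the parameter vector
.grad_to_par <- function(layout, par, nat, g) {
  lab <- layout$labels
  out <- numeric(length(par))
  put <- function(rx, val) out[grep(rx, lab)] <<- val
  Tn <- layout$Tn
  fam_grad <- function(fname, deta, xs, nyr_idx) {
    f <- layout$spec$families[[fname]]
    dint <- sum(deta)
    put(paste0("^", fname, "\\.int$"), dint)
    if (f$year) put(paste0("^", fname, "\\.yr[0-9]+$"), rowSums(deta)[nyr_idx])
    if (f$trend) put(paste0("^", fname, "\\.trend$"), sum(xs * rowSums(deta)))
    if (f$cov) put(paste0("^", fname, "\\.cov$"), sum(layout$covariate * rowSums(deta)))
    if (f$group && layout$mix) {
      put(paste0("^", fname, "\\.gB$"), -sum(deta[, 2L]))
      if (f$relation == "interactive" && f$year)
        put(paste0("^", fname, "\\.yrB[0-9]+$"), deta[nyr_idx, 2L])
    }
  }
  detaJ <- g$phiJ * nat$phiJ * (1 - nat$phiJ)
  fam_grad("phiJ", detaJ, layout$x_phiJ, layout$yr_phiJ)
  detaP <- g$p * nat$p * (1 - nat$p)
  detaP[1L, ] <- 0
  fam_grad("p", detaP, layout$x_p, layout$yr_p)
  put("^phiA$", g$phiA * nat$phiA * (1 - nat$phiA))
  if (sum(grepl("^a\\b", lab)) == 2L) {
    put("^a\\.A$", g$a[1L] * nat$a[1L] * (1 - nat$a[1L]))
    put("^a\\.B$", g$a[2L] * nat$a[2L] * (1 - nat$a[2L]))
  } else {
    put("^a$", sum(g$a * nat$a * (1 - nat$a)))
  }
  if (layout$mix) {
    dpi <- (g$piA_HY + g$piA_ASY) * nat$piA_HY * (1 - nat$piA_HY)
    if (layout$spec$pi == "year") put("^pi\\.occ", dpi[layout$pi_occasions])
    else put("^pi$", sum(dpi))
  }
  out
}

.random_start <- function(layout) {
  par <- stats::runif(layout$npar, -2, 2)
  ipi <- grep("^pi", layout$labels)
  if (length(ipi)) par[ipi] <- stats::qlogis(stats::runif(length(ipi)))
  names(par) <- layout$labels
  par
}

# swap quality-class labels so that class A has the higher juvenile survival
.relabel_params <- function(pp) {
  swap_fam <- function(f) {
    list(intercept = f$intercept - f$groupB,
         year = f$year + f$yearB, yearB = -f$yearB, groupB = -f$groupB)
  }
  pp2 <- parameter_set(pp$T, piA = 1 - pp$piA,
                       phiJ = swap_fam(pp$phiJ), phiA = pp$phiA,
                       a = c(A = unname(pp$a[["B"]]), B = unname(pp$a[["A"]])),
                       p = swap_fam(pp$p),
                       pi_full = if (!is.null(pp$pi_full))
                         pp$pi_full[c(3L, 4L, 1L, 2L), , drop = FALSE])
  pp2
}

.phiJ_means <- function(pp, intervals = NULL) {
  Tn <- pp$T
  intervals <- intervals %||% seq_len(max(1L, Tn - 2L))
  etaA <- pp$phiJ$intercept + mean(pp$phiJ$year[intervals])
  etaB <- etaA + mean(pp$phiJ$yearB[intervals]) - pp$phiJ$groupB
  c(A = stats::plogis(etaA), B = stats::plogis(etaB))
}

#' Fit a multievent mixture model by maximum likelihood
#'
#' Quasi-Newton (L-BFGS-B) maximisation of the count-weighted hidden-Markov
#' log-likelihood on the logit scale, from `n_starts` random initialisations
#' (coefficients uniform on \[-2, 2\]; initial-class probabilities from a flat
#' simplex), with all coefficients clamped to \[-15, 15\].  Multistart follows
#' the usual short-runs-then-polish protocol: every start is screened with a
#' limited iteration budget and the most promising (`polish` of them, by
#' deviance) are run to full convergence, which protects against the local
#' optima that mixture likelihoods are prone to at a fraction of the cost of
#' polishing every start.  The best solution is returned after post-hoc
#' relabelling of the mixture so that class A is the one with the higher mean
#' first-year survival.  Runs are deterministic given `seed`.
#'
#' @param histories An `encounter_histories` object.
#' @param spec A `brant_spec` model structure.
#' @param n_starts Number of random starts (default 10).
#' @param seed Seed for the random starts.
#' @param se Also compute the observed information, standard errors and the
#'   rank-based identifiable-parameter count (slower).
#' @param covariate Optional occasion-level covariate (length `T - 1`) for a
#'   `cov` term in first-year survival.
#' @param control List overriding `maxit` (polish iteration cap, default
#'   2000), `short_maxit` (screening cap, default 150), `polish` (number of
#'   starts polished, default 2), `factr` and `pgtol` (convergence
#'   tolerances), `lmm` (L-BFGS memory).
#' @return An object of class `brant_fit` with the MLE as a `brant_params`
#'   object, the deviance, per-start deviances (screened starts keep their
#'   screening deviance), boundary flags, the parameter count `K` and a
#'   natural-scale `estimates` summary.
#' @export
fit_model <- function(histories, spec, n_starts = 10L, seed = 1L, se = FALSE,
                      covariate = NULL, control = list()) {
  stopifnot(inherits(histories, "encounter_histories"), inherits(spec, "brant_spec"))
  if (histories$T != spec$T) stop("data and spec disagree on T", call. = FALSE)
  x <- collapse_histories(histories)
  pi_occ <- sort(unique(x$first_occasion))
  layout <- .par_layout(spec, pi_occ, covariate)
  fn <- function(par) {
    nat <- .nat_arrays(.par_to_params(layout, par))
    -sum(x$count * .forward_pass(x, nat)$loglik)
  }
  gr <- function(par) {
    pp <- .par_to_params(layout, par)
    nat <- .nat_arrays(pp)
    fp <- .forward_pass(x, nat, grad = TRUE)
    -.grad_to_par(layout, par, nat, fp$grad)
  }
  ctl <- utils::modifyList(list(maxit = 2000L, short_maxit = 150L, polish = 2L,
                                factr = 4.5e7, pgtol = 1e-5, lmm = 20L),
                           control)
  octl <- ctl[c("factr", "pgtol", "lmm")]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  starts <- replicate(n_starts, .random_start(layout), simplify = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  optimise_from <- function(p0, maxit)
    stats::optim(p0, fn, gr, method = "L-BFGS-B",
                 lower = -.LOGIT_BOUND, upper = .LOGIT_BOUND,
                 control = c(octl, list(maxit = maxit)))
  runs <- lapply(starts, optimise_from, maxit = ctl$short_maxit)
  devs <- vapply(runs, function(r) 2 * r$value, numeric(1))
  top <- order(devs)[seq_len(min(ctl$polish, n_starts))]
  for (k in top) {
    runs[[k]] <- optimise_from(runs[[k]]$par, maxit = ctl$maxit)
    devs[k] <- 2 * runs[[k]]$value
  }
  conv <- vapply(runs[top], function(r) r$convergence == 0L, logical(1))
  if (!any(conv))
    warning("no polished start converged within the iteration cap; returning ",
            "the best deviance found (slow boundary convergence is the usual cause)")
  best <- runs[[which.min(devs)]]
  par <- best$par
  pp <- .par_to_params(layout, par)
  relabelled <- FALSE
  if (layout$mix) {
    m <- .phiJ_means(pp)
    if (m[["A"]] < m[["B"]]) { pp <- .relabel_params(pp); relabelled <- TRUE }
  }
  boundary <- abs(par) >= .LOGIT_BOUND - 1e-4
  K <- sum(!boundary)
  out <- list(spec = spec, mle = pp, par = par, layout = layout,
              loglik = -best$value, deviance = 2 * best$value,
              K = K, n_starts = n_starts, start_deviances = devs,
              polished = top,
              converged = any(conv),
              convergence = vapply(runs, `[[`, numeric(1), "convergence"),
              boundary = boundary, relabelled = relabelled, seed = seed,
              n_histories = sum(x$count))
  if (se) {
    H <- stats::optimHess(par, fn, gr)
    ev <- eigen(H, symmetric = TRUE)
    tol <- 1e-8 * max(abs(ev$values))
    free <- !boundary
    Hf <- H[free, free, drop = FALSE]
    evf <- eigen(Hf, symmetric = TRUE)
    out$K <- sum(abs(evf$values) > 1e-8 * max(abs(evf$values)))
    K <- out$K
    vc <- try(solve(Hf), silent = TRUE)
    if (!inherits(vc, "try-error")) {
      se_ <- rep(NA_real_, length(par))
      d <- diag(vc)
      se_[free] <- ifelse(d > 0, sqrt(d), NA_real_)
      names(se_) <- layout$labels
      out$se <- se_
    }
    out$hessian <- H
  }
  out$estimates <- mixture_estimates_params(pp, layout$mix)
  class(out) <- "brant_fit"
  out
}

mixture_estimates_params <- function(pp, mix = TRUE) {
  m <- .phiJ_means(pp)
  list(phiA = pp$phiA,
       a_A = unname(pp$a[["A"]]), a_B = unname(pp$a[["B"]]),
       phiJ_A = unname(m[["A"]]), phiJ_B = unname(m[["B"]]),
       phiJ_gap = unname(m[["A"]] - m[["B"]]),
       p_A = mean(stats::plogis(pp$p$intercept + pp$p$year[-1L])),
       p_B = mean(stats::plogis(pp$p$intercept + pp$p$year[-1L] +
                                  pp$p$yearB[-1L] - pp$p$groupB)),
       piA_mean = mean(pp$piA))
}

#' Natural-scale summary of a fitted mixture model
#'
#' Adult survival, class-specific recruitment, class-specific first-year
#' survival evaluated at the mean year effect (terminal interval excluded,
#' since it is only weakly identified), the survival gap between classes, and
#' mean detection per class.
#'
#' @param fit A `brant_fit` object.
#' @return Named list of point estimates.
#' @export
mixture_estimates <- function(fit) {
  stopifnot(inherits(fit, "brant_fit"))
  fit$estimates
}

#' @export
print.brant_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<brant_fit> deviance %.3f, K = %d, %d starts (best of %s)\n",
              x$deviance, x$K, x$n_starts,
              paste(sprintf("%.1f", sort(x$start_deviances)[seq_len(min(3, x$n_starts))]),
                    collapse = ", ")))
  cat(sprintf("  phiA = %.3f; phiJ(A) = %.3f, phiJ(B) = %.3f (gap %.3f); a = %.3f / %.3f\n",
              e$phiA, e$phiJ_A, e$phiJ_B, e$phiJ_gap, e$a_A, e$a_B))
  if (any(x$boundary))
    cat("  boundary estimates:", paste(names(which(x$boundary)), collapse = ", "), "\n")
  if (!x$converged) cat("  WARNING: no start converged\n")
  invisible(x)
}

#' Quasi-likelihood AIC
#'
#' `deviance / c_hat + 2 K`, the standard overdispersion-adjusted score used
#' for ranking mark-recapture models; with `c_hat = 1` it reduces to AIC.
#'
#' @param fit A `brant_fit` object (or anything with `deviance` and `K`).
#' @param c_hat Overdispersion coefficient (> 0); defaults to the value in the
#'   fit's model structure.
#' @return QAIC value.
#' @export
qaic <- function(fit, c_hat = NULL) {
  c_hat <- c_hat %||% fit$spec$c_hat
  if (c_hat <= 0) stop("c_hat must be positive", call. = FALSE)
  fit$deviance / c_hat + 2 * fit$K
}

#' Rank fitted models by QAIC
#'
#' @param fits List of `brant_fit` objects (optionally named).
#' @param c_hat Common overdispersion coefficient.
#' @return `data.frame` sorted by QAIC with `delta_qaic` relative to the best
#'   model; ties broken in favour of fewer parameters.
#' @export
rank_models <- function(fits, c_hat = 1) {
  if (length(fits) == 0L) stop("need at least one fit", call. = FALSE)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  df <- data.frame(model = nm,
                   K = vapply(fits, function(f) f$K, numeric(1)),
                   deviance = vapply(fits, function(f) f$deviance, numeric(1)))
  df$qaic <- df$deviance / c_hat + 2 * df$K
  df <- df[order(df$qaic, df$K), , drop = FALSE]
  df$delta_qaic <- df$qaic - df$qaic[1L]
  rownames(df) <- NULL
  df
}
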