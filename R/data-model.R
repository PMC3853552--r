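#' brantmix: mixture multievent mark-recapture models and harvest compensation
#'
#' Tools for studying discrete ("frailty") heterogeneity in the demography of
#' long-lived geese marked at a breeding colony: a hidden-Markov multievent
#' likelihood over encounter histories with a two-class quality mixture in
#' juvenile survival, recruitment and detection; maximum-likelihood fitting
#' with QAIC ranking; directional goodness-of-fit components; and a six-state
#' two-quality projection matrix used to evaluate harvest compensation via
#' reproductive values.
#'
#' @keywords internal
"_PACKAGE"

# Latent state order used throughout the likelihood machinery.
# GOS = gosling in its release year, PB1 = prebreeder age 1 (undetectable),
# PB2 = prebreeder age >= 2, BR = breeder; _A/_B = latent quality class
# (A = high quality by the relabelling convention); DEAD absorbs everything.
.STATES <- c("GOS_A", "GOS_B", "PB1_A", "PB1_B", "PB2_A", "PB2_B",
             "BR_A", "BR_B", "DEAD")
.S <- as.list(stats::setNames(seq_along(.STATES), .STATES))

#' Latent state labels of the multievent model
#'
#' Returns the nine latent states of the expanded hidden-Markov chain: gosling
#' at release, one-year-old prebreeder, older prebreeder and breeder, each in
#' quality class A or B, plus a single absorbing dead state.  The two extra
#' prebreeder age registers carry the two-year juvenile survival phase and the
#' age-2 onset of recruitment; breeding is absorbing among live states.
#'
#' @return Character vector of state labels.
#' @export
brant_states <- function() .STATES

#' Build a set of encounter histories
#'
#' An encounter history records, for one marked female, the per-occasion event
#' codes over `T` sampling occasions: `0` = not encountered, `1` = encountered
#' as a breeder, `2` = initial capture as a gosling.  Birds are marked either
#' in their hatch year (`HY`, event 2 at first capture) or as adult breeders
#' (`ASY`, event 1 at first capture), and after marking can only be detected
#' as breeders.  One-year-olds are never encountered, so for an `HY` bird the
#' occasion after first capture is structurally `0`.
#'
#' @param events Integer matrix, one row per history, `T` columns, codes 0/1/2.
#' @param entry_class Optional character vector (`"HY"`/`"ASY"`); inferred from
#'   the first nonzero event code when `NULL`.
#' @param count Positive integer multiplicities (default 1); identical rows may
#'   be collapsed with [collapse_histories()] without changing any likelihood.
#' @param id Optional identifiers; generated when missing.
#' @param validate Check the structural invariants (recommended).
#' @return An object of class `encounter_histories`.
#' @seealso [read_histories()], [simulate_histories()]
#' @export
encounter_histories <- function(events, entry_class = NULL, count = NULL,
                                id = NULL, validate = TRUE) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  n <- nrow(events)
  first <- apply(events != 0L, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  if (anyNA(first)) stop("history with no events at all (row ",
                         which(is.na(first))[1L], ")", call. = FALSE)
  inferred <- ifelse(events[cbind(seq_len(n), first)] == 2L, "HY", "ASY")
  if (is.null(entry_class)) entry_class <- inferred
  entry_class <- as.character(entry_class)
  if (is.null(count)) count <- rep.int(1L, n)
  count <- as.integer(count)
  if (is.null(id)) id <- paste0("h", seq_len(n))
  x <- structure(list(events = events, first_occasion = as.integer(first),
                      entry_class = entry_class, count = count,
                      id = as.character(id), T = ncol(events)),
                 class = "encounter_histories")
  if (validate) validate_histories(x)
  x
}

#' Validate encounter histories
#'
#' Checks the structural invariants of the event coding and fails with a
#' message naming the first offending row.
#'
#' @param x An `encounter_histories` object.
#' @return `x`, invisibly.
#' @export
validate_histories <- function(x) {
  ev <- x$events; n <- nrow(ev); Tn <- x$T
  bad <- function(rows, msg) {
    if (any(rows)) stop("invalid encounter history (row ", which(rows)[1L],
                        "): ", msg, call. = FALSE)
  }
  if (!all(ev %in% 0:2)) stop("event codes must be 0, 1 or 2", call. = FALSE)
  bad(x$count < 1L, "count must be a positive integer")
  bad(!x$entry_class %in% c("HY", "ASY"), "entry_class must be HY or ASY")
  fo <- x$first_occasion
  atfirst <- ev[cbind(seq_len(n), fo)]
  bad(x$entry_class == "HY" & atfirst != 2L, "HY history must open with event 2")
  bad(x$entry_class == "ASY" & atfirst != 1L, "ASY history must open with event 1")
  # code 2 nowhere but the first occasion
  n2 <- rowSums(ev == 2L)
  bad(n2 > 1L | (n2 == 1L & atfirst != 2L), "event 2 only allowed at first capture")
  # one-year-olds are never encountered
  hy <- x$entry_class == "HY" & fo < Tn
  if (any(hy)) {
    nxt <- ev[cbind(which(hy), fo[hy] + 1L)]
    bad2 <- rep(FALSE, n); bad2[which(hy)[nxt != 0L]] <- TRUE
    bad(bad2, "an HY bird cannot be encountered at age 1")
  }
  invisible(x)
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("<encounter_histories> %d unique histories, %d individuals, T = %d occasions\n",
              nrow(x$events), sum(x$count), x$T))
  cat(sprintf("  entry classes: %d HY, %d ASY (weighted: %d / %d)\n",
              sum(x$entry_class == "HY"), sum(x$entry_class == "ASY"),
              sum(x$count[x$entry_class == "HY"]),
              sum(x$count[x$entry_class == "ASY"])))
  invisible(x)
}

#' Collapse duplicated histories into counts
#'
#' Aggregates rows with identical event sequences (and entry class), summing
#' their multiplicities.  Likelihoods and goodness-of-fit statistics are
#' invariant to this operation.
#'
#' @param x An `encounter_histories` object.
#' @return An `encounter_histories` object with unique rows.
#' @export
collapse_histories <- function(x) {
  key <- paste(x$entry_class, apply(x$events, 1L, paste, collapse = ""))
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  cnt <- as.integer(tapply(x$count, grp, sum))
  encounter_histories(x$events[keep, , drop = FALSE],
                      entry_class = x$entry_class[keep],
                      count = cnt, id = x$id[keep], validate = FALSE)
}

#' Subset encounter histories
#' @param x An `encounter_histories` object.
#' @param i Row index.
#' @param ... Ignored.
#' @export
`[.encounter_histories` <- function(x, i, ...) {
  encounter_histories(x$events[i, , drop = FALSE], x$entry_class[i],
                      x$count[i], x$id[i], validate = FALSE)
}

#' Free initial-state parameter count
#'
#' Number of free initial-state probabilities when the distribution over the
#' live mixture states is year specific: one state per occasion is obtained by
#' difference, so `T * (n_states - 1)` parameters remain.  With the four live
#' mixture states (breeder/prebreeder crossed with the two quality classes)
#' and 25 occasions this is the familiar count of 75.
#'
#' @param T Number of occasions (>= 1).
#' @param n_states Number of live states in the initial distribution (>= 2).
#' @return Integer count of free parameters.
#' @examples
#' count_free_initial_params(25, 4)  # 75
#' @export
count_free_initial_params <- function(T, n_states = 4L) {
  if (!is.numeric(T) || length(T) != 1L || T < 1 ||
      !is.numeric(n_states) || length(n_states) != 1L || n_states < 2)
    stop("need T >= 1 and n_states >= 2", call. = FALSE)
  as.integer(T) * (as.integer(n_states) - 1L)
}

.LOGIT_BOUND <- 15

#' Construct a parameter set for the multievent mixture model
#'
#' Holds the generating (or fitted) parameters of the two-class mixture model
#' on the scales they are modelled on.  Linear-predictor families (first-year
#' survival `phiJ` and detection `p`) are stored as logit-scale intercept +
#' per-occasion year deviations + a group-B offset (subtracted for class B, so
#' a positive offset means class B is lower).  Adult survival and the two
#' recruitment probabilities are scalar probabilities.  The initial quality
#' split is the probability `piA` that a newly marked bird belongs to class A,
#' one value per occasion, shared between entry classes (the single series of
#' the fitted model); the unconditional four-state distribution over
#' breeder/prebreeder by class can be supplied as `pi_full` (4 x T, rows
#' BR_A, PB_A, BR_B, PB_B, columns summing to 1), in which case `piA` is
#' derived per entry class by conditioning on the entry event.
#'
#' @param T Number of occasions.
#' @param piA Probability of class A at initial capture, length-`T` vector
#'   (recycled from a scalar).
#' @param phiJ List with `intercept`, `year` (length `T - 1` deviations, one
#'   per survival interval) and `groupB` (logit offset), all logit scale.
#'   Applies to both juvenile years (first- and second-year survival equal).
#' @param phiA Adult (after-second-year) annual apparent survival probability.
#' @param a Named probabilities `c(A = , B = )`: annual recruitment (onset of
#'   breeding, permanent) for each class from age 2 on.
#' @param p List like `phiJ` but with `year` of length `T` (detection is per
#'   occasion); detection applies to breeders only.
#' @param pi_full Optional 4 x T unconditional initial-state matrix.
#' @return An object of class `brant_params`.
#' @examples
#' pp <- parameter_set(5, piA = 0.5,
#'                     phiJ = list(intercept = qlogis(0.73), groupB = qlogis(0.73) - qlogis(0.5)),
#'                     phiA = 0.85, a = c(A = 0.54, B = 0.31),
#'                     p = list(intercept = qlogis(0.79)))
#' natural_scale(pp, "phiJ", 1, "B")  # 0.5
#' @export
parameter_set <- function(T, piA = 0.5,
                          phiJ = list(intercept = 0, year = 0, groupB = 0),
                          phiA = 0.85, a = c(A = 0.5, B = 0.5),
                          p = list(intercept = 0, year = 0, groupB = 0),
                          pi_full = NULL) {
  T <- as.integer(T)
  fill <- function(fam, len) {
    fam$intercept <- fam$intercept %||% 0
    fam$year <- rep_len(fam$year %||% 0, len)
    fam$yearB <- rep_len(fam$yearB %||% 0, len)  # extra class-B deviations
    fam$groupB <- fam$groupB %||% 0
    fam[c("intercept", "year", "yearB", "groupB")]
  }
  phiJ <- fill(phiJ, T - 1L)
  p <- fill(p, T)
  if (!is.null(pi_full)) {
    stopifnot(is.matrix(pi_full), nrow(pi_full) == 4L, ncol(pi_full) == T)
    if (any(pi_full < 0) || any(abs(colSums(pi_full) - 1) > 1e-8))
      stop("pi_full columns must be probability distributions", call. = FALSE)
  }
  piA <- rep_len(piA, T)
  if (any(piA < 0 | piA > 1)) stop("piA must be in [0, 1]", call. = FALSE)
  if (any(phiA < 0 | phiA > 1) || any(a < 0 | a > 1))
    stop("phiA and a must be probabilities", call. = FALSE)
  a <- c(A = unname(a[["A"]]), B = unname(a[["B"]]))
  x <- structure(list(T = T, piA = piA, phiJ = phiJ, phiA = phiA, a = a,
                      p = p, pi_full = pi_full),
                 class = "brant_params")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural-scale parameter lookup
#'
#' Assembles the linear predictor dictated by the family's structure
#' (intercept + year deviation + group offset, logit scale) and returns the
#' inverse-logit value; scalar families return their probability directly.
#' For `family = "pi"` the returned value is the probability of quality class
#' A at initial capture at that occasion.
#'
#' @param params A `brant_params` object.
#' @param family One of `"pi"`, `"phiJ"`, `"phiA"`, `"a"`, `"p"`.
#' @param occasion Occasion (for `p`, `pi`) or survival-interval (for `phiJ`)
#'   index, 1-based.
#' @param group `"A"` or `"B"`.
#' @return A probability in `[0, 1]`.
#' @export
natural_scale <- function(params, family, occasion = 1L, group = "A") {
  stopifnot(inherits(params, "brant_params"))
  if (!group %in% c("A", "B")) stop("unknown group: ", group, call. = FALSE)
  switch(family,
    phiA = params$phiA,
    a = unname(params$a[[group]]),
    phiJ = {
      if (occasion < 1L || occasion > params$T - 1L)
        stop("phiJ interval out of range", call. = FALSE)
      f <- params$phiJ
      stats::plogis(f$intercept + f$year[occasion] +
                      if (group == "B") f$yearB[occasion] - f$groupB else 0)
    },
    p = {
      if (occasion < 1L || occasion > params$T)
        stop("occasion out of range", call. = FALSE)
      f <- params$p
      stats::plogis(f$intercept + f$year[occasion] +
                      if (group == "B") f$yearB[occasion] - f$groupB else 0)
    },
    pi = {
      if (occasion < 1L || occasion > params$T)
        stop("occasion out of range", call. = FALSE)
      if (group == "A") params$piA[occasion] else 1 - params$piA[occasion]
    },
    stop("unknown parameter family: ", family, call. = FALSE))
}

#' Flag logit-scale coefficients at the boundary
#'
#' Coefficients whose absolute logit value reaches the working bound of 15
#' correspond to probabilities estimated at 0 or 1; such estimates are flagged
#' rather than trusted, mirroring common practice in multievent software.
#'
#' @param params A `brant_params` object.
#' @param bound Logit bound (default 15).
#' @return Named logical vector over the linear-predictor coefficients.
#' @export
boundary_flags <- function(params, bound = .LOGIT_BOUND) {
  v <- c(phiJ.intercept = params$phiJ$intercept,
         phiJ.groupB = params$phiJ$groupB,
         stats::setNames(params$phiJ$year, paste0("phiJ.year", seq_along(params$phiJ$year))),
         p.intercept = params$p$intercept, p.groupB = params$p$groupB,
         stats::setNames(params$p$year, paste0("p.year", seq_along(params$p$year))),
         phiA = stats::qlogis(params$phiA),
         a.A = stats::qlogis(params$a[["A"]]), a.B = stats::qlogis(params$a[["B"]]))
  abs(v) >= bound - 1e-6
}

.parse_family <- function(txt, family) {
  txt <- gsub(" ", "", txt)
  relation <- if (grepl("\\*", txt)) "interactive" else "additive"
  toks <- strsplit(txt, "[+*]")[[1]]
  toks <- toks[toks != ""]
  known <- c("constant", "year", "group", "trend", "cov")
  if (!all(toks %in% known))
    stop("unknown term(s) in ", family, ": ",
         paste(setdiff(toks, known), collapse = ", "), call. = FALSE)
  if ("year" %in% toks && "trend" %in% toks)
    stop("'trend' replaces 'year'; they cannot both vary in ", family, call. = FALSE)
  list(year = "year" %in% toks, trend = "trend" %in% toks,
       group = "group" %in% toks, cov = "cov" %in% toks,
       relation = relation)
}

#' Describe the structure of a multievent mixture model
#'
#' A model specification fixes, for each parameter family, which factors enter
#' the logit-linear predictor.  Structures are given as compact formulas over
#' the tokens `constant`, `year`, `group` (the two-class quality mixture),
#' `trend` (a logit-linear year trend replacing free year effects) and `cov`
#' (an occasion-level covariate); `+` denotes additivity and `*` a year-by-group
#' interaction.  The initial-state family `pi` is either `"year"` (one free
#' class-A probability per release occasion) or `"constant"`.  Dropping
#' `group` from every family yields the homogeneous (single-class) model;
#' keeping it only in `p` gives the recapture-heterogeneity-only benchmark.
#'
#' @param T Number of occasions.
#' @param pi `"year"` or `"constant"`.
#' @param phiJ,phiA,a,p Structure strings, e.g. `"year+group"`.
#' @param c_hat Overdispersion coefficient used in QAIC ranking (> 0).
#' @return An object of class `brant_spec`.
#' @examples
#' model_spec(20)                           # the heterogeneous best-model structure
#' model_spec(10, pi = "constant", phiJ = "constant", a = "constant",
#'            p = "constant")               # fully homogeneous
#' @export
model_spec <- function(T, pi = c("year", "constant"),
                       phiJ = "year+group", phiA = "constant",
                       a = "group", p = "year+group", c_hat = 1) {
  pi <- match.arg(pi)
  if (c_hat <= 0) stop("c_hat must be positive", call. = FALSE)
  fams <- list(phiJ = .parse_family(phiJ, "phiJ"),
               phiA = .parse_family(phiA, "phiA"),
               a = .parse_family(a, "a"),
               p = .parse_family(p, "p"))
  if (fams$phiA$year || fams$phiA$trend)
    stop("adult survival is modelled as constant in this package", call. = FALSE)
  het <- vapply(fams, function(f) f$group, logical(1))
  structure(list(T = as.integer(T), pi = pi, families = fams,
                 heterogeneous = any(het), c_hat = c_hat,
                 labels = c(phiJ = phiJ, phiA = phiA, a = a, p = p)),
            class = "brant_spec")
}

#' @export
print.brant_spec <- function(x, ...) {
  cat("<brant_spec> T =", x$T, "occasions;",
      if (x$heterogeneous) "two-class mixture" else "homogeneous", "\n")
  cat("  pi:", x$pi, " phiJ:", x$labels[["phiJ"]], " phiA:", x$labels[["phiA"]],
      " a:", x$labels[["a"]], " p:", x$labels[["p"]], "\n")
  cat("  c_hat:", x$c_hat, "\n")
  invisible(x)
}
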