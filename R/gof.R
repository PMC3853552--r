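# Contingency-table goodness-of-fit components for encounter histories,
# in the style of U-CARE: TEST3.SR / TEST3.SM condition on the occasion of
# an encounter and compare newly against previously encountered animals;
# TEST2.CT / TEST2.CL condition on known-alive animals and compare detected
# against undetected ones.  Detection heterogeneity produces an excess of
# runs of 0s and of 1s, which these components read as simultaneous
# transience (TEST3.SR z > 0) and trap-happiness (TEST2.CT z < 0).
#
# All components operate on detection-collapsed histories (any encounter,
# including the gosling marking event, counts as "seen"), are invariant to
# history order and to splitting counts into duplicate rows, and pool
# occasion tables from latest to earliest until every expected cell count
# reaches 2.

.detection_matrix <- function(x) {
  stopifnot(inherits(x, "encounter_histories"))
  det <- x$events != 0L
  storage.mode(det) <- "integer"
  det
}

# weighted 2x2 table list -> pooled component.  Tables with an empty row or
# column margin carry no contrast at all and are dropped outright (pooling
# them into a neighbour would import a marginal association that is not
# there, a Simpson-type artefact); tables with all margins positive but an
# expected cell below the threshold are pooled into the next earlier
# occasion, latest to earliest.
.pool_tables <- function(tabs, min_expected = 2) {
  degenerate <- function(tb)
    sum(tb) == 0 || any(rowSums(tb) == 0) || any(colSums(tb) == 0)
  sparse <- function(tb)
    any(outer(rowSums(tb), colSums(tb)) / sum(tb) < min_expected)
  tabs <- Filter(function(x) !degenerate(x$table), tabs)
  i <- length(tabs)
  while (i >= 2L) {
    if (sparse(tabs[[i]]$table)) {
      tabs[[i - 1L]]$table <- tabs[[i - 1L]]$table + tabs[[i]]$table
      tabs[[i - 1L]]$occasions <- c(tabs[[i - 1L]]$occasions, tabs[[i]]$occasions)
      tabs[[i]] <- NULL
    }
    i <- i - 1L
  }
  if (length(tabs) && sparse(tabs[[1L]]$table)) tabs[[1L]] <- NULL
  tabs
}

# signed hypergeometric z and Pearson chi-square of one 2x2 table;
# the z is for the (1,1) cell
.table_stats <- function(tb) {
  N <- sum(tb)
  E <- outer(rowSums(tb), colSums(tb)) / N
  V <- prod(rowSums(tb)) * prod(colSums(tb)) / (N^2 * (N - 1))
  list(z = (tb[1L, 1L] - E[1L, 1L]) / sqrt(V),
       chi2 = sum((tb - E)^2 / E))
}

.gof_component <- function(name, tabs, directional = TRUE) {
  if (length(tabs) == 0L)
    return(structure(list(name = name, tables = list(), chi_square = 0,
                          df = 0L, z = NA_real_, p_value = NA_real_,
                          status = "insufficient data"),
                     class = "gof_component"))
  st <- lapply(tabs, function(tb) .table_stats(tb$table))
  chi2 <- sum(vapply(st, `[[`, numeric(1), "chi2"))
  df <- length(tabs)
  z <- if (directional)
    sum(vapply(st, `[[`, numeric(1), "z")) / sqrt(df) else NA_real_
  structure(list(name = name, tables = tabs, chi_square = chi2, df = df,
                 z = z,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 status = "ok"),
            class = "gof_component")
}

#' @export
print.gof_component <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("%-9s %s\n", x$name, x$status))
  } else {
    cat(sprintf("%-9s chi2 = %8.2f  df = %3d  p = %.4f%s\n", x$name,
                x$chi_square, x$df, x$p_value,
                if (!is.na(x$z)) sprintf("  z = %7.2f", x$z) else ""))
  }
  invisible(x)
}

#' Transience / heterogeneity component (TEST3.SR)
#'
#' For each interior occasion, animals encountered at that occasion are
#' cross-classified as newly versus previously encountered against
#' re-encountered later versus never seen again.  The per-table signed
#' statistic standardises the count of newly marked animals never seen again
#' (positive overall z = excess of such animals: transience, or a mixture of
#' detectabilities); the overall z is the table sum divided by the square
#' root of the number of usable tables and is N(0, 1) under homogeneity.
#'
#' @param histories An `encounter_histories` object.
#' @param min_expected Pooling threshold on expected cell counts.
#' @return A `gof_component`.
#' @export
test3_sr <- function(histories, min_expected = 2) {
  det <- .detection_matrix(histories)
  Tn <- ncol(det)
  if (Tn < 3L) stop("need at least 3 occasions", call. = FALSE)
  w <- histories$count
  first <- histories$first_occasion
  seen_after <- function(i) rowSums(det[, (i + 1L):Tn, drop = FALSE]) > 0L
  tabs <- list()
  for (i in 2:(Tn - 1L)) {
    here <- det[, i] == 1L
    new <- here & first == i
    old <- here & first < i
    later <- seen_after(i)
    tb <- rbind(new = c(never = sum(w[new & !later]), again = sum(w[new & later])),
                old = c(never = sum(w[old & !later]), again = sum(w[old & later])))
    tabs[[length(tabs) + 1L]] <- list(table = tb, occasions = i)
  }
  .gof_component("TEST3.SR", .pool_tables(tabs, min_expected))
}

#' Timing-of-reencounter component (TEST3.SM)
#'
#' Among animals encountered at an occasion and re-encountered later,
#' compares newly against previously encountered animals on whether the next
#' re-encounter is immediate (next occasion) or delayed.  Nondirectional.
#'
#' @inheritParams test3_sr
#' @return A `gof_component`.
#' @export
test3_sm <- function(histories, min_expected = 2) {
  det <- .detection_matrix(histories)
  Tn <- ncol(det)
  if (Tn < 4L) stop("need at least 4 occasions", call. = FALSE)
  w <- histories$count
  first <- histories$first_occasion
  tabs <- list()
  for (i in 2:(Tn - 2L)) {
    here <- det[, i] == 1L
    later <- rowSums(det[, (i + 1L):Tn, drop = FALSE]) > 0L
    nxt <- det[, i + 1L] == 1L
    new <- here & later & first == i
    old <- here & later & first < i
    tb <- rbind(new = c(immediate = sum(w[new & nxt]), delayed = sum(w[new & !nxt])),
                old = c(immediate = sum(w[old & nxt]), delayed = sum(w[old & !nxt])))
    tabs[[length(tabs) + 1L]] <- list(table = tb, occasions = i)
  }
  .gof_component("TEST3.SM", .pool_tables(tabs, min_expected), directional = FALSE)
}

#' Trap-dependence component (TEST2.CT)
#'
#' For each occasion pair, compares detection at `t + 1` between animals
#' detected and not detected at `t`, among animals marked by `t` and known
#' alive after `t + 1`.  The sign convention makes the overall z negative
#' under trap-happiness (animals seen at `t` seen again at `t + 1` in
#' excess), the signature detection heterogeneity leaves in these data.
#'
#' @inheritParams test3_sr
#' @return A `gof_component`.
#' @export
test2_ct <- function(histories, min_expected = 2) {
  det <- .detection_matrix(histories)
  Tn <- ncol(det)
  if (Tn < 4L) stop("need at least 4 occasions", call. = FALSE)
  w <- histories$count
  first <- histories$first_occasion
  tabs <- list()
  for (i in 2:(Tn - 2L)) {
    alive_later <- rowSums(det[, (i + 2L):Tn, drop = FALSE]) > 0L
    at_risk <- first <= i & alive_later
    di <- det[, i] == 1L
    dn <- det[, i + 1L] == 1L
    # (1,1) cell = not seen at t but seen at t+1, so excess immediate
    # re-detections of animals seen at t push z negative (trap-happiness)
    tb <- rbind(miss = c(seen = sum(w[at_risk & !di & dn]), missed = sum(w[at_risk & !di & !dn])),
                seen = c(seen = sum(w[at_risk & di & dn]), missed = sum(w[at_risk & di & !dn])))
    tabs[[length(tabs) + 1L]] <- list(table = tb, occasions = i)
  }
  .gof_component("TEST2.CT", .pool_tables(tabs, min_expected))
}

#' Delayed trap-dependence component (TEST2.CL)
#'
#' Among animals marked by `t`, not detected at `t + 1` and seen again
#' afterwards, compares animals detected and not detected at `t` on whether
#' the next encounter comes immediately at `t + 2` or later.  Nondirectional.
#'
#' @inheritParams test3_sr
#' @return A `gof_component`.
#' @export
test2_cl <- function(histories, min_expected = 2) {
  det <- .detection_matrix(histories)
  Tn <- ncol(det)
  if (Tn < 5L) stop("need at least 5 occasions", call. = FALSE)
  w <- histories$count
  first <- histories$first_occasion
  tabs <- list()
  for (i in 2:(Tn - 3L)) {
    again <- rowSums(det[, (i + 2L):Tn, drop = FALSE]) > 0L
    at_risk <- first <= i & det[, i + 1L] == 0L & again
    di <- det[, i] == 1L
    d2 <- det[, i + 2L] == 1L
    tb <- rbind(seen = c(immediate = sum(w[at_risk & di & d2]), delayed = sum(w[at_risk & di & !d2])),
                miss = c(immediate = sum(w[at_risk & !di & d2]), delayed = sum(w[at_risk & !di & !d2])))
    tabs[[length(tabs) + 1L]] <- list(table = tb, occasions = i)
  }
  .gof_component("TEST2.CL", .pool_tables(tabs, min_expected), directional = FALSE)
}

#' Run the full goodness-of-fit suite
#'
#' @param histories An `encounter_histories` object.
#' @param min_expected Pooling threshold on expected cell counts.
#' @return A `gof_suite` list of the four components with a summary print
#'   method; feed it to [estimate_c_hat()].
#' @export
gof_tests <- function(histories, min_expected = 2) {
  comps <- list(test3_sr(histories, min_expected),
                test3_sm(histories, min_expected),
                test2_ct(histories, min_expected),
                test2_cl(histories, min_expected))
  names(comps) <- vapply(comps, `[[`, "", "name")
  structure(comps, class = "gof_suite")
}

#' @export
print.gof_suite <- function(x, ...) {
  cat("Goodness-of-fit components (directional z ~ N(0,1) under homogeneity)\n")
  for (comp in x) print(comp)
  ok <- vapply(x, function(c) c$status == "ok", logical(1))
  if (any(ok))
    cat(sprintf("c-hat (all components)          = %.3f\n", estimate_c_hat(x)),
        sprintf("c-hat (directional parts removed) = %.3f\n",
                estimate_c_hat(x, exclude_directional = TRUE)))
  invisible(x)
}

#' Overdispersion coefficient from goodness-of-fit components
#'
#' The variance inflation factor is the pooled chi-square over its pooled
#' degrees of freedom.  When detection heterogeneity is the known cause of
#' the directional signals, the signed (1-df) parts of TEST3.SR and TEST2.CT
#' can be removed so that only their nondirectional remainders, plus
#' TEST3.SM and TEST2.CL, inflate the variance; that conservative value is
#' the one meant for QAIC ranking of models that already include detection
#' heterogeneity.
#'
#' @param components A `gof_suite` or list of `gof_component`s.
#' @param exclude_directional Remove the signed parts of the directional
#'   components.
#' @return The estimated c-hat (> 0).
#' @export
estimate_c_hat <- function(components, exclude_directional = FALSE) {
  comps <- Filter(function(c) inherits(c, "gof_component") && c$status == "ok",
                  unclass(components))
  if (length(comps) == 0L) stop("no usable components", call. = FALSE)
  chi2 <- vapply(comps, `[[`, numeric(1), "chi_square")
  df <- vapply(comps, function(c) as.numeric(c$df), numeric(1))
  if (exclude_directional) {
    dir_part <- vapply(comps, function(c)
      if (!is.na(c$z) && c$df >= 1L) c$z^2 else 0, numeric(1))
    has_dir <- vapply(comps, function(c) !is.na(c$z) && c$df >= 1L, logical(1))
    chi2 <- pmax(chi2 - dir_part, 0)
    df <- df - as.numeric(has_dir)
  }
  if (sum(df) <= 0) stop("zero pooled degrees of freedom", call. = FALSE)
  sum(chi2) / sum(df)
}

#' Write a goodness-of-fit report as JSON
#'
#' @param suite A `gof_suite`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gof_json <- function(suite, path) {
  rec <- lapply(unclass(suite), function(c)
    list(name = c$name, chi_square = c$chi_square, df = c$df, z = c$z,
         p_value = c$p_value, status = c$status))
  rec$c_hat <- tryCatch(estimate_c_hat(suite), error = function(e) NULL)
  rec$c_hat_nondirectional <- tryCatch(
    estimate_c_hat(suite, exclude_directional = TRUE), error = function(e) NULL)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
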