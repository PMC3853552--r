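#' Read encounter histories from disk
#'
#' Two dialects are supported.  `"csv"` is a headed delimited file (comma or
#' tab, sniffed from the header line) with columns `id`, `entry_class`,
#' `first_occasion`, `h1` ... `hT` and `count`.  `"inp"` is the MARK-style
#' format: one history per record as a digit string over `{0,1,2}` followed by
#' whitespace, a count and a terminating semicolon; `/* ... */` comments are
#' ignored and the entry class is inferred from the first nonzero code
#' (2 = marked as gosling, 1 = marked as breeder).
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"inp"` (default guessed from the extension).
#' @param T Expected number of occasions; checked when given.
#' @return An `encounter_histories` object.
#' @export
read_histories <- function(path, dialect = NULL, T = NULL) {
  dialect <- dialect %||% if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  x <- switch(dialect, csv = .read_csv_histories(path),
              inp = .read_inp_histories(path),
              stop("unknown dialect: ", dialect, call. = FALSE))
  if (!is.null(T) && x$T != T)
    stop("file has T = ", x$T, " occasions, expected ", T, call. = FALSE)
  x
}

.read_csv_histories <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  hcols <- grep("^h[0-9]+$", names(df), value = TRUE)
  if (length(hcols) == 0L) stop("no h1..hT columns found in ", path, call. = FALSE)
  hcols <- hcols[order(as.integer(sub("^h", "", hcols)))]
  need <- c("id", "entry_class", "first_occasion", "count")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  ev <- as.matrix(df[hcols])
  dimnames(ev) <- NULL
  suppressWarnings(storage.mode(ev) <- "integer")
  if (anyNA(ev)) stop("non-numeric or ragged event codes in ", path, call. = FALSE)
  x <- encounter_histories(ev, entry_class = df$entry_class,
                           count = as.integer(df$count), id = df$id)
  if (!all(x$first_occasion == as.integer(df$first_occasion)))
    stop("declared first_occasion disagrees with the event codes", call. = FALSE)
  x
}

.read_inp_histories <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)      # strip comments
  recs <- strsplit(txt, ";")[[1]]
  recs <- trimws(recs)
  recs <- recs[nzchar(recs)]
  if (length(recs) == 0L) stop("no records in ", path, call. = FALSE)
  parts <- regmatches(recs, regexec("^([012]+)\\s+(-?[0-9]+)$", recs))
  ok <- lengths(parts) == 3L
  if (!all(ok)) stop("malformed .inp record: '", recs[!ok][1L], "'", call. = FALSE)
  hist <- vapply(parts, `[`, "", 2L)
  cnt <- as.integer(vapply(parts, `[`, "", 3L))
  if (length(unique(nchar(hist))) != 1L)
    stop("ragged history strings (unequal T) in ", path, call. = FALSE)
  ev <- do.call(rbind, lapply(strsplit(hist, ""), as.integer))
  encounter_histories(ev, count = cnt)
}

#' Write encounter histories to disk
#'
#' @param x An `encounter_histories` object.
#' @param path Output file.
#' @param dialect `"csv"` or `"inp"` (default from the extension).
#' @param sep Field separator for the csv dialect.
#' @param strict For `"inp"`: write a strict two-symbol file in which the
#'   gosling first-capture code 2 is exported as 1 and the entry class is kept
#'   in a trailing `/* HY */` comment (the package's three-symbol dialect is
#'   written when `FALSE`, the default).
#' @return `path`, invisibly.
#' @export
write_histories <- function(x, path, dialect = NULL, sep = ",", strict = FALSE) {
  stopifnot(inherits(x, "encounter_histories"))
  dialect <- dialect %||% if (grepl("\\.inp$", path, ignore.case = TRUE)) "inp" else "csv"
  if (dialect == "csv") {
    df <- data.frame(id = x$id, entry_class = x$entry_class,
                     first_occasion = x$first_occasion,
                     x$events, count = x$count, check.names = FALSE)
    names(df)[3L + seq_len(x$T)] <- paste0("h", seq_len(x$T))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else if (dialect == "inp") {
    ev <- x$events
    if (strict) ev[ev == 2L] <- 1L
    lines <- paste0(apply(ev, 1L, paste, collapse = ""), " ", x$count, ";",
                    if (strict) paste0(" /* ", x$entry_class, " */") else "")
    writeLines(lines, path)
  } else stop("unknown dialect: ", dialect, call. = FALSE)
  invisible(path)
}

#' Write the generating truth of a simulation as JSON
#'
#' @param params A `brant_params` object.
#' @param path Output file.
#' @param extra Optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(params, path, extra = list()) {
  rec <- c(list(T = params$T, piA = params$piA, phiJ = params$phiJ,
                phiA = params$phiA, a = as.list(params$a), p = params$p),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with any of the blocks `seed`, `model`, `rates`,
#'   `scenario`, `c_hat`, `out`.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a run manifest next to a set of outputs
#'
#' Every pipeline run records its configuration, package version and seed so
#' outputs can be reproduced.
#'
#' @param dir Output directory.
#' @param config Named list echoed into the manifest.
#' @param seed Seed used for the run.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, config = list(), seed = NULL) {
  man <- list(package = "brantmix",
              version = as.character(utils::packageVersion("brantmix")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
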