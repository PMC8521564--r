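# Readers for the two public dataset formats, the synthetic cohort
# generator, and result writers.

#' Read a label-prefixed delimited series table
#'
#' Each line holds a class label followed by the series values, the layout of
#' the public eigenworm archive. The delimiter is auto-detected (comma, tab,
#' or whitespace) unless given.
#'
#' @param path file path.
#' @param delimiter `NULL` (auto-detect), `","`, `"\t"` or `" "` (any
#'   whitespace).
#' @param classes optional character vector of allowed labels; lines with
#'   other labels raise an error naming the line.
#' @param fixed_length if `TRUE` (default) all series must share one length.
#' @return Object of class `labeled_series`: list with `values` (list of
#'   numeric vectors), `label` (character vector), `source`.
#' @export
read_labeled_series <- function(path, delimiter = NULL, classes = NULL,
                                fixed_length = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty series table: ", path, call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[1], fixed = TRUE)) "," else
      if (grepl("\t", lines[1], fixed = TRUE)) "\t" else " "
  }
  split_re <- if (delimiter == " ") "[[:space:]]+" else
    paste0("[", delimiter, "]")
  values <- vector("list", length(lines))
  label <- character(length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), split_re)[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 2L)
      stop(sprintf("line %d: expected a label followed by values", lineno[i]),
           call. = FALSE)
    lab <- tok[1]
    if (!is.null(classes) && !(lab %in% classes))
      stop(sprintf("line %d: unknown class label '%s'", lineno[i], lab),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric value '%s'", lineno[i],
                   tok[-1][which(is.na(v))[1] ]), call. = FALSE)
    label[i] <- lab
    values[[i]] <- v
  }
  if (fixed_length) {
    lens <- lengths(values)
    if (length(unique(lens)) > 1L) {
      bad <- which(lens != lens[1])[1]
      stop(sprintf("line %d: ragged row (length %d, expected %d)",
                   lineno[bad], lens[bad], lens[1]), call. = FALSE)
    }
  }
  structure(list(values = values, label = label, source = path),
            class = "labeled_series")
}

#' @export
print.labeled_series <- function(x, ...) {
  cat(sprintf("Labeled series table: %d series from %s\n",
              length(x$values), x$source %||% "memory"))
  print(table(x$label))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a labeled series table
#'
#' Inverse of [read_labeled_series()]: one line per series, label first.
#'
#' @param tab a `labeled_series`.
#' @param path output file.
#' @param delimiter field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_labeled_series <- function(tab, path, delimiter = ",") {
  lines <- vapply(seq_along(tab$values), function(i) {
    paste(c(tab$label[i], format(tab$values[[i]], digits = 17, trim = TRUE,
                                 scientific = FALSE)),
          collapse = delimiter)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read one subject's gait record
#'
#' Parses a whitespace-delimited multi-column per-subject file from the
#' gait-in-neurodegenerative-disease database and extracts the left and right
#' swing-interval columns (seconds). The cohort is taken from an explicit
#' argument, a manifest (data.frame with columns `file`, `cohort`), or the
#' filename prefix (`control` = HC, `park` = PD, `hunt` = HD, `als` = ALS).
#'
#' @param path file path.
#' @param column_map list naming the 1-based `lsi` and `rsi` column indices.
#'   Default `list(lsi = 4, rsi = 5)`, the public database layout.
#' @param cohort explicit cohort label (overrides manifest and filename).
#' @param manifest optional data.frame mapping file basenames to cohorts.
#' @return Object of class `gait_record`: list with `lsi`, `rsi` (raw numeric
#'   series), `cohort`, `subject` (file basename).
#' @export
read_gait_record <- function(path, column_map = list(lsi = 4L, rsi = 5L),
                             cohort = NULL, manifest = NULL) {
  if (!file.exists(path)) stop("gait file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = FALSE)
  idx <- c(column_map$lsi, column_map$rsi)
  if (any(idx < 1L) || any(idx > ncol(d)))
    stop(sprintf("%s: column map (lsi = %d, rsi = %d) outside the %d columns present",
                 path, column_map$lsi, column_map$rsi, ncol(d)), call. = FALSE)
  subject <- basename(path)
  if (is.null(cohort)) {
    if (!is.null(manifest)) {
      hit <- match(subject, manifest$file)
      if (is.na(hit))
        stop(sprintf("%s: not listed in the manifest", subject), call. = FALSE)
      cohort <- manifest$cohort[hit]
    } else {
      cohort <- switch(sub("[0-9].*$", "", tolower(subject)),
                       control = "HC", park = "PD", hunt = "HD", als = "ALS",
                       stop(sprintf("%s: cannot infer cohort from filename; pass cohort= or a manifest",
                                    subject), call. = FALSE))
    }
  }
  structure(list(lsi = d[[column_map$lsi]], rsi = d[[column_map$rsi]],
                 cohort = cohort, subject = subject),
            class = "gait_record")
}

#' Specify one synthetic cohort
#'
#' @param label class label.
#' @param family `"harmonic"` (sinusoid + Gaussian noise), `"ar1"`
#'   (first-order autoregression), or `"logistic"` (logistic map).
#' @param count number of series, `>= 1`.
#' @param length series length.
#' @param noise_sd Gaussian noise SD added to the signal (harmonic) or
#'   innovation SD (ar1).
#' @param freq harmonic frequency in cycles per sample.
#' @param ar AR(1) coefficient, `|ar| < 1`.
#' @param rate logistic-map rate parameter in (0, 4]; 3.9 is chaotic.
#' @return A list describing the class, for [generate_synthetic_cohorts()].
#' @export
cohort_spec <- function(label, family = c("harmonic", "ar1", "logistic"),
                        count = 30L, length = 900L, noise_sd = 0.05,
                        freq = 0.02, ar = 0.8, rate = 3.9) {
  family <- match.arg(family)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  if (length < 2L) stop("length must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (family == "ar1" && abs(ar) >= 1)
    stop("AR(1) coefficient must satisfy |ar| < 1", call. = FALSE)
  if (family == "logistic" && (rate <= 0 || rate > 4))
    stop("logistic rate must be in (0, 4]", call. = FALSE)
  list(label = label, family = family, count = as.integer(count),
       length = as.integer(length), noise_sd = noise_sd, freq = freq,
       ar = ar, rate = rate)
}

#' Generate labeled synthetic cohorts
#'
#' Seeded, reproducible cohorts of scalar series spanning the
#' regular-to-irregular axis the recurrence eigenvalue quantifies: harmonic
#' oscillations with controllable additive noise, AR(1) processes, and the
#' logistic map in its chaotic regime. The default emulates a two-class study
#' (a regular and a noise-corrupted cohort of 30 series of length 900 each).
#' Each series gets a random phase (harmonic) or random initial state, so
#' series within a class differ.
#'
#' @param spec list of [cohort_spec()] entries; default two harmonic classes
#'   with noise SD 0.05 (`"regular"`) and 0.5 (`"irregular"`), 30 series of
#'   length 900 each.
#' @param seed integer seed; the output is a pure function of `spec` + `seed`.
#' @return A `labeled_series` table (see [read_labeled_series()]).
#' @export
generate_synthetic_cohorts <- function(spec = NULL, seed = 1L) {
  if (is.null(spec)) {
    spec <- list(cohort_spec("regular", "harmonic", noise_sd = 0.05),
                 cohort_spec("irregular", "harmonic", noise_sd = 0.5))
  }
  set.seed(seed)
  values <- list()
  label <- character(0)
  for (cl in spec) {
    for (i in seq_len(cl$count)) {
      x <- switch(cl$family,
        harmonic = {
          phase <- stats::runif(1, 0, 2 * pi)
          sin(2 * pi * cl$freq * seq_len(cl$length) + phase) +
            stats::rnorm(cl$length, sd = cl$noise_sd)
        },
        ar1 = {
          as.numeric(stats::arima.sim(list(ar = cl$ar), n = cl$length,
                                      sd = max(cl$noise_sd, 1e-12)))
        },
        logistic = {
          x0 <- stats::runif(1, 0.05, 0.95)
          burn <- 100L
          out <- numeric(cl$length + burn)
          out[1] <- x0
          for (t in seq_len(cl$length + burn - 1L))
            out[t + 1L] <- cl$rate * out[t] * (1 - out[t])
          out[(burn + 1L):(burn + cl$length)]
        })
      values[[length(values) + 1L]] <- x
      label <- c(label, cl$label)
    }
  }
  structure(list(values = values, label = label, source = NULL),
            class = "labeled_series")
}

#' Write pipeline results
#'
#' Writes per-series results as CSV, cohort summaries as CSV in the column
#' order mean, SD, p-value, 95% CI, 99% CI, trees as newick files, and a JSON
#' run manifest echoing the configuration and seed.
#'
#' @param records data.frame of per-series results (may be empty), or `NULL`.
#' @param summaries list of `cohort_summary` objects, or `NULL`.
#' @param trees named list of `upgma_tree` objects, or `NULL`.
#' @param out_dir output directory (created if missing).
#' @param config configuration list echoed into the manifest.
#' @param seed seed echoed into the manifest.
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(records = NULL, summaries = NULL, trees = NULL,
                          out_dir = ".", config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  written <- character(0)
  if (!is.null(records)) {
    f <- file.path(out_dir, "series_results.csv")
    if (nrow(records) == 0L && ncol(records) == 0L)
      records <- data.frame(id = character(0), label = character(0),
                            value = numeric(0))
    rec <- records
    for (col in names(rec)) if (is.numeric(rec[[col]]))
      rec[[col]] <- ifelse(is.infinite(rec[[col]]), "inf",
                           format(rec[[col]], digits = 17, trim = TRUE))
    utils::write.csv(rec, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(summaries)) {
    f <- file.path(out_dir, "cohort_summaries.csv")
    utils::write.csv(summaries_to_df(summaries), f, row.names = FALSE)
    written <- c(written, f)
  }
  for (nm in names(trees)) {
    f <- file.path(out_dir, paste0(nm, ".nwk"))
    writeLines(trees[[nm]]$newick, f)
    written <- c(written, f)
  }
  manifest <- list(written = basename(written), seed = seed, config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(written, mf))
}

#' Published cohort moment tables
#'
#' Returns the bundled table of published per-cohort moments (cohort label,
#' n, mean, SD) for the eigenworm and gait case studies, used by the
#' from-moments summary operations.
#'
#' @param which `"eigenworm_eigenvalue"`, `"eigenworm_sampen"`,
#'   `"gait_eigenvalue"` or `"gait_sampen"`.
#' @return data.frame with columns `group`, `label`, `n`, `mean`, `sd`.
#' @export
cohort_moments <- function(which = c("eigenworm_eigenvalue",
                                     "eigenworm_sampen",
                                     "gait_eigenvalue", "gait_sampen")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_moments.csv"),
                   package = "recureig", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
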