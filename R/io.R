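# Delimited-text readers/writers for the three input formats: signal tables
# (long or wide), population structure, parental dosage priors.  TSV or CSV,
# autodetected from the header; UTF-8; header row required.  Missing codes:
# empty field, "NA", "NaN".

detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t"
  else if (lengths(regmatches(line, gregexpr(",", line))) > 0) ","
  else "\t"
}

na_codes <- c("", "NA", "NaN")

parse_numeric <- function(x, lines, path, column) {
  x[x %in% na_codes] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: unparseable numeric '%s' in column '%s' at line %d",
                 path, x[bad[1]], column, lines[bad[1]]), call. = FALSE)
  }
  out
}

read_delim_raw <- function(path, sep = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  meta <- grepl("^#", lines)
  body <- lines[!meta]
  if (!length(body)) stop(path, ": no header row found", call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(body[1])
  # strsplit drops trailing empty fields; pad to (separator count + 1)
  n_sep <- lengths(gregexpr(sep, body, fixed = TRUE))
  n_sep[!vapply(gregexpr(sep, body, fixed = TRUE),
                function(m) m[1] > 0, logical(1))] <- 0L
  cells <- Map(function(f, n) {
    length(f) <- n + 1L
    f[is.na(f)] <- ""
    f
  }, strsplit(body, sep, fixed = TRUE), n_sep)
  header <- cells[[1]]
  rows <- cells[-1]
  line_no <- which(!meta)[-1]  # original line numbers of data rows
  list(header = header, rows = rows, line_no = line_no,
       meta = lines[meta], sep = sep)
}

#' Read a marker signal table
#'
#' Reads per-marker, per-sample array signals from delimited text (TSV or
#' CSV, autodetected).  Two dialects are accepted:
#' \describe{
#'   \item{long}{columns `marker`, `sample`, then either `signal_a` and
#'     `signal_b` (raw two-channel intensities) or `ratio` (precomputed
#'     s_b/(s_a+s_b)).}
#'   \item{wide}{first column `marker`, remaining columns one per sample,
#'     cells holding the precomputed ratio.}
#' }
#' Empty fields, `NA` and `NaN` are treated as missing.  All markers are
#' returned over the union of samples seen in the file (absent pairs become
#' missing), so the sample set is consistent across markers.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"long"` or `"wide"`.
#' @param sep Field separator; `NULL` autodetects tab/comma.
#' @return Named list of [marker_signals()] objects, one per marker.
#' @export
read_signal_table <- function(path, dialect = c("auto", "long", "wide"),
                              sep = NULL) {
  dialect <- match.arg(dialect)
  tab <- read_delim_raw(path, sep)
  header <- tab$header
  if (dialect == "auto") {
    dialect <- if (all(c("marker", "sample") %in% header)) "long" else "wide"
  }
  nc <- lengths(tab$rows)
  short <- which(nc != length(header))
  if (length(short)) {
    stop(sprintf("%s: line %d has %d fields, expected %d", path,
                 tab$line_no[short[1]], nc[short[1]], length(header)),
         call. = FALSE)
  }
  mat <- do.call(rbind, tab$rows)
  if (dialect == "long") {
    need <- c("marker", "sample")
    if (!all(need %in% header)) {
      stop(path, ": long dialect requires columns 'marker' and 'sample'",
           call. = FALSE)
    }
    has_raw <- all(c("signal_a", "signal_b") %in% header)
    has_ratio <- "ratio" %in% header
    if (!has_raw && !has_ratio) {
      stop(path, ": need 'signal_a'+'signal_b' or 'ratio' columns",
           call. = FALSE)
    }
    marker <- mat[, match("marker", header)]
    sample <- mat[, match("sample", header)]
    key <- paste(marker, sample, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop(sprintf("%s: duplicate (marker, sample) entry '%s'/'%s' at line %d",
                   path, marker[dup[1]], sample[dup[1]], tab$line_no[dup[1]]),
           call. = FALSE)
    }
    samples <- unique(sample)
    out <- list()
    for (m in unique(marker)) {
      sel <- marker == m
      idx <- match(samples, sample[sel])
      if (has_raw) {
        sa <- parse_numeric(mat[sel, match("signal_a", header)],
                            tab$line_no[sel], path, "signal_a")[idx]
        sb <- parse_numeric(mat[sel, match("signal_b", header)],
                            tab$line_no[sel], path, "signal_b")[idx]
        out[[m]] <- marker_signals(m, samples, signal_a = sa, signal_b = sb)
      } else {
        r <- parse_numeric(mat[sel, match("ratio", header)],
                           tab$line_no[sel], path, "ratio")[idx]
        out[[m]] <- marker_signals(m, samples, ratio = r)
      }
    }
    out
  } else {
    samples <- header[-1]
    if (!length(samples)) stop(path, ": wide table has no sample columns",
                               call. = FALSE)
    if (anyDuplicated(samples)) stop(path, ": duplicate sample columns",
                                     call. = FALSE)
    marker <- mat[, 1]
    dup <- which(duplicated(marker))
    if (length(dup)) {
      stop(sprintf("%s: duplicate marker '%s' at line %d", path,
                   marker[dup[1]], tab$line_no[dup[1]]), call. = FALSE)
    }
    out <- list()
    for (i in seq_along(marker)) {
      r <- parse_numeric(mat[i, -1], rep(tab$line_no[i], length(samples)),
                         path, "ratio")
      out[[marker[i]]] <- marker_signals(marker[i], samples, ratio = r)
    }
    out
  }
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a marker signal table
#'
#' Inverse of [read_signal_table()]; numeric fields carry full precision so
#' that a write/read round trip reproduces the input exactly.
#'
#' @param signals Named list of [marker_signals()] objects.
#' @param path Output file.
#' @param dialect `"long"` (two-channel or ratio) or `"wide"` (ratio only).
#' @param what For the long dialect, `"signals"` writes both channels,
#'   `"ratio"` the precomputed ratio.
#' @param sep Field separator (default tab).
#' @export
write_signal_table <- function(signals, path, dialect = c("long", "wide"),
                               what = c("signals", "ratio"), sep = "\t") {
  dialect <- match.arg(dialect)
  what <- match.arg(what)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (dialect == "long") {
    if (what == "signals") {
      writeLines(paste(c("marker", "sample", "signal_a", "signal_b"),
                       collapse = sep), con)
      for (s in signals) {
        writeLines(paste(s$marker_id, s$sample_ids, fmt_num(s$signal_a),
                         fmt_num(s$signal_b), sep = sep), con)
      }
    } else {
      writeLines(paste(c("marker", "sample", "ratio"), collapse = sep), con)
      for (s in signals) {
        writeLines(paste(s$marker_id, s$sample_ids, fmt_num(s$ratio),
                         sep = sep), con)
      }
    }
  } else {
    samples <- signals[[1]]$sample_ids
    writeLines(paste(c("marker", samples), collapse = sep), con)
    for (s in signals) {
      stopifnot(identical(s$sample_ids, samples))
      writeLines(paste(c(s$marker_id, fmt_num(s$ratio)), collapse = sep), con)
    }
  }
  invisible(path)
}

#' Read a population structure file
#'
#' The file holds population definitions in `#pop` metadata lines followed by
#' a two-column `sample`/`population` table:
#' \preformatted{
#' #pop  F1FAM   F1      P1      P2
#' #pop  P1      parent  F1FAM
#' #pop  P2      parent  F1FAM
#' #pop  PANEL   panel_HW
#' sample  population
#' off001  F1FAM
#' ...
#' }
#'
#' @param path File path.
#' @param sep Field separator; `NULL` autodetects.
#' @return A validated [population_structure()].
#' @export
read_population_structure <- function(path, sep = NULL) {
  tab <- read_delim_raw(path, sep)
  if (!all(c("sample", "population") %in% tab$header)) {
    stop(path, ": needs columns 'sample' and 'population'", call. = FALSE)
  }
  popdefs <- tab$meta[startsWith(tab$meta, "#pop")]
  if (!length(popdefs)) stop(path, ": no '#pop' definition lines", call. = FALSE)
  defs <- lapply(strsplit(sub("^#pop[\t ,]+", "", popdefs), tab$sep,
                          fixed = TRUE), function(f) {
    if (length(f) < 2) stop(path, ": malformed #pop line", call. = FALSE)
    c(f, rep(NA_character_, 4 - length(f)))[1:4]
  })
  defs <- as.data.frame(do.call(rbind, defs), stringsAsFactors = FALSE)
  names(defs) <- c("population", "ptype", "link1", "link2")
  mat <- do.call(rbind, tab$rows)
  assignments <- data.frame(sample = mat[, match("sample", tab$header)],
                            population = mat[, match("population", tab$header)],
                            stringsAsFactors = FALSE)
  population_structure(assignments, defs)
}

#' Write a population structure file
#'
#' Inverse of [read_population_structure()].
#' @param structure A [population_structure()].
#' @param path Output file.
#' @param sep Field separator (default tab).
#' @export
write_population_structure <- function(structure, path, sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(structure$populations))) {
    p <- structure$populations[i, ]
    fields <- c(p$population, p$ptype, p$link1, p$link2)
    fields <- fields[!is.na(fields)]
    writeLines(paste(c("#pop", fields), collapse = sep), con)
  }
  writeLines(paste(c("sample", "population"), collapse = sep), con)
  writeLines(paste(structure$assignments$sample,
                   structure$assignments$population, sep = sep), con)
  invisible(path)
}

#' Read parental dosage priors
#'
#' Columns `marker`, `population`, `dosage` (0..4); at most one prior per
#' (marker, parent population).
#'
#' @param path File path.
#' @param sep Field separator; `NULL` autodetects.
#' @return data.frame with columns `marker`, `population`, `dosage`.
#' @export
read_parental_priors <- function(path, sep = NULL) {
  tab <- read_delim_raw(path, sep)
  need <- c("marker", "population", "dosage")
  if (!all(need %in% tab$header)) {
    stop(path, ": needs columns 'marker', 'population', 'dosage'",
         call. = FALSE)
  }
  mat <- do.call(rbind, tab$rows)
  out <- data.frame(marker = mat[, match("marker", tab$header)],
                    population = mat[, match("population", tab$header)],
                    dosage = parse_numeric(mat[, match("dosage", tab$header)],
                                           tab$line_no, path, "dosage"),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$dosage) | out$dosage != round(out$dosage) |
                 out$dosage < 0 | out$dosage > 4)
  if (length(bad)) {
    stop(sprintf("%s: dosage must be an integer 0..4 (line %d)", path,
                 tab$line_no[bad[1]]), call. = FALSE)
  }
  out$dosage <- as.integer(out$dosage)
  key <- paste(out$marker, out$population, sep = "\r")
  if (anyDuplicated(key)) {
    stop(path, ": more than one prior for the same (marker, population)",
         call. = FALSE)
  }
  out
}

#' Write parental dosage priors
#' @param priors data.frame with columns `marker`, `population`, `dosage`.
#' @param path Output file.
#' @param sep Field separator (default tab).
#' @export
write_parental_priors <- function(priors, path, sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("marker", "population", "dosage"), collapse = sep), con)
  writeLines(paste(priors$marker, priors$population, priors$dosage,
                   sep = sep), con)
  invisible(path)
}
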