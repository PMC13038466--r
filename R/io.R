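# Readers and writers: TopSpin variable-counter lists, peak models,
# interferograms, spectra, comparison reports and key-value config files.
# All formats are plain text; writers are deterministic and stamp the
# package version (and seed, where one exists) into a comment header.

provenance_header <- function(extra = character(0)) {
  c(sprintf("# dnsnmr %s", as.character(utils::packageVersion("dnsnmr"))), extra)
}

#' Write a TopSpin variable-counter list
#'
#' Plain ASCII, one positive integer per line, each t1 value's scan count
#' repeated `replication` times (one line per stored FID; 4 for
#' hypercomplex acquisition), newline-terminated. TopSpin reads this file
#' via the `vclist` parameter; no comment lines are written.
#'
#' @param schedule A [build_schedule()] object.
#' @param path Output file path.
#' @param replication Lines per t1 value (default: the schedule's own
#'   replication setting).
#' @return `path`, invisibly.
#' @export
write_vclist <- function(schedule, path, replication = NULL) {
  if (!inherits(schedule, "dns_schedule"))
    stop_param("`schedule` must be a dns_schedule")
  if (is.null(replication)) replication <- schedule$params$replication
  replication <- check_count(replication, "replication")
  counts <- rep(schedule$ns_disc, each = replication)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_runtime(
                    sprintf("cannot open '%s' for writing", path),
                    class = "dnsnmr_io_error"))
  on.exit(close(con))
  writeLines(as.character(counts), con)
  invisible(path)
}

#' Read a variable-counter list
#'
#' @param path File of integer lines; blank trailing lines are ignored.
#' @return Integer vector of scan counts (empty, with a warning, for an
#'   empty file).
#' @export
read_vclist <- function(path) {
  if (!file.exists(path))
    stop_runtime(sprintf("no such file: '%s'", path), class = "dnsnmr_io_error")
  lines <- readLines(path)
  while (length(lines) && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) {
    warning("empty vclist: '", path, "'")
    return(integer(0))
  }
  vals <- suppressWarnings(as.integer(lines))
  bad <- which(is.na(vals) | suppressWarnings(as.numeric(lines)) != vals)
  if (length(bad))
    stop_runtime(sprintf("vclist parse error at line %d of '%s': '%s'",
                         bad[1L], path, lines[bad[1L]]),
                 class = "dnsnmr_parse_error")
  vals
}

#' Write / read a peak model as tab-separated text
#'
#' Columns `offset`, `fwhh`, `amplitude`, `shape`, `j`; the `j` column holds
#' semicolon-separated coupling constants in Hz (empty for none).
#'
#' @param model An [nmr_peaks()] peak list.
#' @param path File path.
#' @return `write_peaks`: `path` invisibly; `read_peaks`: an `nmr_peaks`
#'   object.
#' @export
write_peaks <- function(model, path) {
  df <- as.data.frame(model)
  df$j <- vapply(df$j, function(v) paste(v, collapse = ";"), character(1))
  writeLines(provenance_header(), path)
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(j = "character"))
  j <- lapply(df$j, function(s) {
    if (is.na(s) || s == "") numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
  nmr_peaks(offset = df$offset, fwhh = df$fwhh, amplitude = df$amplitude,
            shape = df$shape, j = j)
}

#' Write / read an interferogram as columnar text
#'
#' Header comments carry `dwell`, `mode`, `sigma0` and `seed`; the body has
#' columns `t`, `re`, `im`, `scans`.
#'
#' @param fid An [acquire()]d `nmr_interferogram`.
#' @param path File path.
#' @return `write_interferogram`: `path` invisibly; `read_interferogram`:
#'   an `nmr_interferogram`.
#' @export
write_interferogram <- function(fid, path) {
  check_fid(fid)
  hdr <- provenance_header(c(
    sprintf("# dwell: %.17g", fid$dwell),
    sprintf("# mode: %s", fid$mode),
    sprintf("# sigma0: %.17g", fid$sigma0),
    sprintf("# seed: %d", fid$seed)))
  writeLines(hdr, path)
  df <- data.frame(t = sprintf("%.17g", fid$t),
                   re = sprintf("%.17g", Re(fid$values)),
                   im = sprintf("%.17g", Im(fid$values)),
                   scans = fid$scans)
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_interferogram
#' @export
read_interferogram <- function(path) {
  meta <- read_header_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(
    list(values = complex(real = df$re, imaginary = df$im),
         t = df$t,
         dwell = as.numeric(meta[["dwell"]]),
         scans = as.integer(df$scans),
         mode = meta[["mode"]],
         sigma0 = as.numeric(meta[["sigma0"]]),
         seed = as.integer(meta[["seed"]])),
    class = "nmr_interferogram")
}

#' Write / read a spectrum as two-column text
#'
#' Columns `freq` (Hz) and `intensity`; processing provenance is stored in
#' the comment header.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path File path.
#' @return `write_spectrum`: `path` invisibly; `read_spectrum`: an
#'   `nmr_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  if (!inherits(spectrum, "nmr_spectrum"))
    stop_param("`spectrum` must be an nmr_spectrum")
  hdr <- provenance_header(c(
    sprintf("# dwell: %.17g", spectrum$dwell),
    sprintf("# provenance: %s", paste(spectrum$provenance, collapse = " -> "))))
  writeLines(hdr, path)
  df <- data.frame(freq = sprintf("%.17g", spectrum$freq),
                   intensity = sprintf("%.17g", spectrum$intensity))
  suppressWarnings(utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  meta <- read_header_meta(path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  prov <- meta[["provenance"]]
  structure(
    list(freq = df$freq, intensity = df$intensity,
         dwell = as.numeric(meta[["dwell"]]),
         provenance = if (is.null(prov) || prov == "") character(0)
                      else strsplit(prov, " -> ", fixed = TRUE)[[1L]]),
    class = "nmr_spectrum")
}

#' Write a strategy-comparison report as tab-separated text
#'
#' @param comparison A [compare_strategies()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  if (!inherits(comparison, "dns_comparison"))
    stop_param("`comparison` must come from compare_strategies()")
  hdr <- provenance_header(c(
    sprintf("# n_seeds: %d", comparison$n_seeds),
    sprintf("# resolution_gain: %.6g", comparison$resolution_gain),
    sprintf("# snr_gain_vs_apodized: %.6g", comparison$snr_gain_vs_apodized),
    sprintf("# snr_gain_vs_conventional: %.6g", comparison$snr_gain_vs_conventional)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    comparison$table, path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  invisible(path)
}

#' Read a layered key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers where possible. Entries in `defaults` are used for keys the
#' file does not set; file entries win over defaults, and callers (e.g. the
#' command line) may override the result again.
#'
#' @param path Config file path (must exist).
#' @param defaults Named list of fallback values.
#' @return Named list of settings.
#' @export
read_config <- function(path, defaults = list()) {
  if (!file.exists(path))
    stop_runtime(sprintf("no such config file: '%s'", path),
                 class = "dnsnmr_io_error")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop_runtime(sprintf("config parse error: '%s'", lines[i]),
                   class = "dnsnmr_parse_error")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

read_header_meta <- function(path) {
  if (!file.exists(path))
    stop_runtime(sprintf("no such file: '%s'", path), class = "dnsnmr_io_error")
  lines <- readLines(path, n = 20L)
  lines <- lines[startsWith(lines, "# ")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# ([a-zA-Z0-9_]+): (.*)$", ln))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}
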