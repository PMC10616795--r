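#' Write a sweep ensemble as an Axon-text-style (ATF) trace file
#'
#' The ATF dialect written here is: a signature line \code{ATF\t1.0}; a
#' line with the number of optional header records and the number of data
#' columns; the header records (quoted \code{"Key=Value"} strings, one per
#' line) carrying units, sample interval, pH condition, temperature and a
#' JSON-encoded protocol; a column-title line; then tab-delimited data with
#' a time column (ms) followed by one column per sweep (pA). Numeric values
#' are written with 9 significant digits.
#'
#' @param ensemble a \code{\link{sweep_ensemble}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_atf <- function(ensemble, path) {
  n_sweeps <- nrow(ensemble$sweeps)
  header <- c(
    "SignalUnits=pA",
    "TimeUnits=ms",
    sprintf("SampleInterval=%.9g", ensemble$protocol$sample_interval),
    sprintf("SweepCount=%d", n_sweeps),
    sprintf("pHin=%.9g", ensemble$condition$pH_in),
    sprintf("pHout=%.9g", ensemble$condition$pH_out),
    sprintf("Temperature=%.9g", ensemble$temperature),
    paste0("Protocol=", protocol_to_json(ensemble$protocol))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ATF\t1.0", con)
  writeLines(sprintf("%d\t%d", length(header), n_sweeps + 1), con)
  writeLines(sprintf("\"%s\"", header), con)
  titles <- c("\"Time (ms)\"",
              sprintf("\"Trace #%d (pA)\"", seq_len(n_sweeps)))
  writeLines(paste(titles, collapse = "\t"), con)
  dat <- cbind(ensemble$time, t(ensemble$sweeps))
  body <- apply(dat, 1, function(r) paste(sprintf("%.9g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an ATF-dialect trace file into a sweep ensemble
#'
#' @param path input file path.
#' @param units declared signal units if the header lacks them; reading
#'   fails when units are neither in the file nor supplied.
#' @return A \code{\link{sweep_ensemble}}.
#' @export
read_atf <- function(path, units = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^ATF", lines[1])) {
    stop(sprintf("%s: not an ATF file (line 1)", path))
  }
  hdr <- strsplit(lines[2], "\t")[[1]]
  n_header <- as.integer(hdr[1])
  n_cols <- as.integer(hdr[2])
  if (is.na(n_header) || is.na(n_cols)) {
    stop(sprintf("%s: malformed ATF count line (line 2)", path))
  }
  recs <- gsub("^\"|\"$", "", lines[2 + seq_len(n_header)])
  meta <- parse_header_records(recs)
  if (is.null(meta$SignalUnits) && is.null(units)) {
    stop(sprintf("%s: missing units (header ends at line %d)", path, 2 + n_header))
  }
  first_data <- 2 + n_header + 2  # skip column-title line
  body <- lines[first_data:length(lines)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  lens <- lengths(fields)
  if (any(lens != n_cols)) {
    bad <- which(lens != n_cols)[1]
    stop(sprintf("%s: ragged columns at line %d (%d fields, expected %d)",
                 path, first_data + bad - 1, lens[bad], n_cols))
  }
  dat <- matrix(as.numeric(unlist(fields)), ncol = n_cols, byrow = TRUE)
  time <- dat[, 1]
  if (any(diff(time) <= 0)) {
    stop(sprintf("%s: non-monotonic time column", path))
  }
  assemble_ensemble(meta, time, t(dat[, -1, drop = FALSE]))
}

#' Write / read a sweep ensemble as CSV
#'
#' Plain comma-separated values (time column plus one column per sweep)
#' preceded by a single \code{#}-prefixed comment line carrying a JSON
#' metadata object (units, sample interval, pH condition, temperature,
#' protocol).
#'
#' @param ensemble a \code{\link{sweep_ensemble}}.
#' @param path file path.
#' @return \code{path} invisibly (write) or a \code{sweep_ensemble} (read).
#' @export
write_sweep_csv <- function(ensemble, path) {
  meta <- list(
    SignalUnits = "pA", TimeUnits = "ms",
    SampleInterval = ensemble$protocol$sample_interval,
    SweepCount = nrow(ensemble$sweeps),
    pHin = ensemble$condition$pH_in, pHout = ensemble$condition$pH_out,
    Temperature = ensemble$temperature,
    Protocol = protocol_to_list(ensemble$protocol)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  dat <- cbind(ensemble$time, t(ensemble$sweeps))
  colnames(dat) <- c("time_ms", sprintf("sweep_%d_pA", seq_len(nrow(ensemble$sweeps))))
  utils::write.table(format(as.data.frame(dat), digits = 9, trim = TRUE,
                            scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#", first)) stop(sprintf("%s: missing JSON metadata comment (line 1)", path))
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", first), simplifyVector = TRUE)
  dat <- utils::read.csv(path, comment.char = "#")
  time <- dat[[1]]
  if (any(diff(time) <= 0)) stop(sprintf("%s: non-monotonic time column", path))
  assemble_ensemble(meta, time, t(as.matrix(dat[, -1, drop = FALSE])))
}

protocol_to_list <- function(protocol) {
  list(kind = protocol$kind, holding_V = protocol$holding_V,
       sample_interval = protocol$sample_interval,
       segments = lapply(protocol$segments, function(s) as.list(s)),
       info = protocol$info)
}

protocol_to_json <- function(protocol) {
  as.character(jsonlite::toJSON(protocol_to_list(protocol),
                                auto_unbox = TRUE, digits = NA))
}

protocol_from_list <- function(pl) {
  segments <- lapply(pl$segments, function(s) {
    data.frame(duration = unlist(s$duration), V_start = unlist(s$V_start),
               V_end = unlist(s$V_end))
  })
  info <- pl$info
  new_protocol(pl$kind, pl$holding_V, pl$sample_interval, segments, info)
}

parse_header_records <- function(recs) {
  kv <- regmatches(recs, regexpr("=", recs), invert = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2) out[[p[1]]] <- p[2]
  out
}

assemble_ensemble <- function(meta, time, sweeps) {
  prot <- NULL
  if (!is.null(meta$Protocol)) {
    pl <- meta$Protocol
    if (is.character(pl)) pl <- jsonlite::fromJSON(pl, simplifyVector = FALSE)
    prot <- tryCatch(protocol_from_list(pl), error = function(e) NULL)
  }
  if (is.null(prot)) {
    dt <- if (!is.null(meta$SampleInterval)) as.numeric(meta$SampleInterval)
          else stats::median(diff(time))
    seg <- data.frame(duration = utils::tail(time, 1) + dt,
                      V_start = 0, V_end = 0)
    prot <- new_protocol("step_family", 0, dt,
                         rep(list(seg), nrow(sweeps)), info = list())
  } else {
    prot <- recycle_protocol(prot, nrow(sweeps))
  }
  cond <- ph_condition(num_or(meta$pHin, 7), num_or(meta$pHout, 7))
  sweep_ensemble(prot, sweeps, time, condition = cond,
                 temperature = num_or(meta$Temperature, hv_constants$T_default))
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
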