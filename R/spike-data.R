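## Spike-table input/output and binning.

#' Construct a SpikeTrainSet
#'
#' @param spikeTimes named list of numeric spike-time vectors (seconds),
#'   one per unit; each sorted strictly increasing.
#' @param duration trial duration in seconds.
#' @param condition condition label (\code{"BL"}, \code{"E"},
#'   \code{"BMI/E"}, or another label).
#' @param sessionId session identifier.
#' @param unitIds unit roster; defaults to \code{names(spikeTimes)}. Units
#'   absent from \code{spikeTimes} are added with empty trains.
#' @return a \linkS4class{SpikeTrainSet}.
#' @examples
#' sts <- SpikeTrainSet(list(u1 = c(0.01, 0.025), u2 = 0.011), duration = 0.1)
#' nUnits(sts)
#' @export
SpikeTrainSet <- function(spikeTimes, duration, condition = "other",
                          sessionId = "s1", unitIds = names(spikeTimes)) {
  if (is.null(unitIds))
    unitIds <- paste0("u", seq_along(spikeTimes))
  spikeTimes <- lapply(spikeTimes, function(t) round(as.numeric(t), 6))
  full <- setNames(vector("list", length(unitIds)), unitIds)
  for (u in unitIds)
    full[[u]] <- if (u %in% names(spikeTimes)) spikeTimes[[u]] else numeric(0)
  new("SpikeTrainSet", unitIds = as.character(unitIds), spikeTimes = full,
      duration = as.numeric(duration), condition = as.character(condition),
      sessionId = as.character(sessionId))
}

#' Read a spike-time table
#'
#' Reads a CSV table with columns \code{unit_id} and \code{spike_time_s}
#' (header optional) into a \linkS4class{SpikeTrainSet}. Rows must carry a
#' parsable non-negative time strictly below \code{duration}; offending
#' rows raise an error naming the line. Units named in \code{unitIds} but
#' absent from the file are kept as empty trains, so silent units survive
#' across the conditions of a session.
#'
#' @param path CSV file path.
#' @param duration trial duration in seconds (defines the valid time range).
#' @param condition,sessionId labels stored on the result.
#' @param unitIds optional declared roster (character); defaults to the
#'   units present in the file, in order of first appearance.
#' @param header does the file carry a header line? Auto-detected by
#'   default from a non-numeric second field in the first line.
#' @return a \linkS4class{SpikeTrainSet}.
#' @seealso \code{\link{writeSpikeTable}}, \code{\link{binSpikes}}
#' @export
readSpikeTable <- function(path, duration, condition = "other",
                           sessionId = "s1", unitIds = NULL, header = NA) {
  if (!file.exists(path)) stop("spike table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (length(lines)) {
    f1 <- strsplit(lines[[1L]], ",")[[1]]
    autoHeader <- length(f1) >= 2L &&
      is.na(suppressWarnings(as.numeric(f1[2]))) &&
      grepl("time", f1[2], ignore.case = TRUE)
    if (isTRUE(header) || (is.na(header) && autoHeader)) {
      lines <- lines[-1L]
      offset <- 1L
    }
  }
  units <- character(length(lines))
  times <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], ",")[[1]])
    lineNo <- i + offset
    if (length(f) < 2L)
      stop(sprintf("line %d: expected 'unit_id,spike_time_s', got '%s'",
                   lineNo, lines[[i]]))
    t <- suppressWarnings(as.numeric(f[2]))
    if (is.na(t))
      stop(sprintf("line %d: unparsable spike time '%s'", lineNo, f[2]))
    if (t < 0)
      stop(sprintf("line %d: negative spike time %g", lineNo, t))
    if (t >= duration)
      stop(sprintf("line %d: spike time %g at or beyond duration %g",
                   lineNo, t, duration))
    units[i] <- f[1]
    times[i] <- t
  }
  roster <- unitIds %||% unique(units)
  unknown <- setdiff(units, roster)
  if (length(unknown))
    stop("units in file but not in declared roster: ",
         paste(unknown, collapse = ", "))
  st <- lapply(setNames(roster, roster), function(u) {
    tt <- sort(times[units == u])
    if (anyDuplicated(round(tt * 1e6)))
      stop(sprintf("unit %s: duplicate spike at identical timestamp", u))
    tt
  })
  SpikeTrainSet(st, duration = duration, condition = condition,
                sessionId = sessionId, unitIds = roster)
}

#' Write a spike-time table
#'
#' Writes the \code{unit_id,spike_time_s} CSV read by
#' \code{\link{readSpikeTable}}. Times are written at microsecond
#' precision, the storage resolution of the package.
#'
#' @param x a \linkS4class{SpikeTrainSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpikeTable <- function(x, path) {
  stopifnot(is(x, "SpikeTrainSet"))
  df <- do.call(rbind, lapply(unitIds(x), function(u) {
    tt <- x@spikeTimes[[u]]
    if (!length(tt)) return(NULL)
    data.frame(unit_id = u, spike_time_s = sprintf("%.6f", tt))
  }))
  if (is.null(df))
    df <- data.frame(unit_id = character(0), spike_time_s = character(0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session manifest
#'
#' A session manifest is a YAML (or JSON) file naming the spike tables of
#' the three conditions of one recording session, the trial duration, and
#' optionally the unit roster:
#' \preformatted{
#' session_id: r1s1
#' duration: 120
#' units: [u1, u2, u3]
#' conditions:
#'   BL: bl.csv
#'   E: e.csv
#'   BMI/E: bmi_e.csv
#' }
#' Relative file paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return named list of \linkS4class{SpikeTrainSet} objects, one per
#'   condition, in manifest order.
#' @export
readSessionManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  for (fld in c("duration", "conditions"))
    if (is.null(man[[fld]])) stop("manifest missing field: ", fld)
  roster <- if (!is.null(man$units)) as.character(man$units) else NULL
  dir <- dirname(path)
  out <- list()
  for (cond in names(man$conditions)) {
    f <- man$conditions[[cond]]
    if (!file.exists(f)) f <- file.path(dir, f)
    out[[cond]] <- readSpikeTable(f, duration = man$duration,
                                  condition = cond,
                                  sessionId = man$session_id %||% "s1",
                                  unitIds = roster)
  }
  out
}

#' Bin spike trains into a count matrix
#'
#' Counts spikes of every unit on a regular half-open grid
#' \code{[t0 + (k-1)*binWidth, t0 + k*binWidth)} with
#' \code{K = ceiling(duration / binWidth)} bins. Total counts are
#' conserved: column sums equal per-unit spike counts. Units with no
#' spikes yield all-zero columns, keeping the roster width stable.
#'
#' @param trains a \linkS4class{SpikeTrainSet}.
#' @param binWidth bin width in seconds (e.g. 0.001 or 0.010).
#' @param t0 start of the first bin, default 0.
#' @return a \linkS4class{BinnedCounts}.
#' @examples
#' sts <- SpikeTrainSet(list(u1 = c(0.0005, 0.0015)), duration = 0.003)
#' counts(binSpikes(sts, 0.001))
#' @export
binSpikes <- function(trains, binWidth, t0 = 0) {
  stopifnot(is(trains, "SpikeTrainSet"))
  if (binWidth <= 0) stop("binWidth must be > 0")
  if (trains@duration < binWidth)
    stop("duration must be at least one bin wide")
  K <- as.integer(ceiling(round(trains@duration / binWidth, 9)))
  J <- nUnits(trains)
  m <- matrix(0L, K, J, dimnames = list(NULL, unitIds(trains)))
  for (u in unitIds(trains)) {
    tt <- trains@spikeTimes[[u]]
    tt <- tt[tt >= t0]
    if (!length(tt)) next
    idx <- binIndex(tt, t0, binWidth, K)
    tb <- tabulate(idx, nbins = K)
    m[, u] <- tb
  }
  new("BinnedCounts", counts = m, binWidth = as.numeric(binWidth),
      t0 = as.numeric(t0), condition = trains@condition)
}

#' Rebin a count matrix to a coarser grid
#'
#' Aggregates a \linkS4class{BinnedCounts} to an integer multiple of its
#' bin width by summing consecutive bins; equivalent to binning the
#' original spike trains directly at the coarser width.
#'
#' @param binned a \linkS4class{BinnedCounts}.
#' @param binWidth target bin width, an integer multiple of the current one.
#' @return a \linkS4class{BinnedCounts} at the coarser width.
#' @export
rebinCounts <- function(binned, binWidth) {
  stopifnot(is(binned, "BinnedCounts"))
  r <- binWidth / binned@binWidth
  if (r < 1 || abs(r - round(r)) > 1e-8)
    stop("target binWidth must be an integer multiple of the current width")
  r <- as.integer(round(r))
  if (r == 1L) return(binned)
  K <- nrow(binned@counts)
  K2 <- as.integer(ceiling(K / r))
  grp <- rep(seq_len(K2), each = r)[seq_len(K)]
  m <- rowsum(binned@counts, grp, reorder = TRUE)
  dimnames(m) <- list(NULL, colnames(binned@counts))
  new("BinnedCounts", counts = m, binWidth = as.numeric(binWidth),
      t0 = binned@t0, condition = binned@condition)
}

#' Write binned counts as CSV
#'
#' @param binned a \linkS4class{BinnedCounts}.
#' @param path output file path; columns are units, rows are bins.
#' @return \code{path}, invisibly.
#' @export
writeBinnedCounts <- function(binned, path) {
  stopifnot(is(binned, "BinnedCounts"))
  write.csv(as.data.frame(binned@counts), path, row.names = FALSE)
  invisible(path)
}
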