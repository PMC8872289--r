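#' Track-table CSV dialect
#'
#' Column mapping for track tables. The default matches the internal
#' dialect written by [writeTracks()]; `trackmateDialect()` matches the
#' spot table exported by TrackMate (upper-case column names,
#' micrometre positions, three extra header rows).
#'
#' @param trackCol,frameCol,xCol,yCol column names for track id, frame
#'   index and x/y position.
#' @param unit coordinate unit, `"um"` or `"nm"` (nm inputs are
#'   converted to um on read).
#' @param skip extra header rows to skip after the column-name row.
#' @return a `TrackTableDialect` (list).
#' @export
trackDialect <- function(trackCol = "track_id", frameCol = "frame",
                         xCol = "x", yCol = "y", unit = c("um", "nm"),
                         skip = 0L) {
  unit <- match.arg(unit)
  structure(list(trackCol = trackCol, frameCol = frameCol, xCol = xCol,
                 yCol = yCol, unit = unit, skip = as.integer(skip)),
            class = "TrackTableDialect")
}

#' @rdname trackDialect
#' @export
trackmateDialect <- function(unit = "um", skip = 3L) {
  trackDialect("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y",
               unit = unit, skip = skip)
}

#' Read a track table
#'
#' Reads a CSV of per-localization records, groups them by track id and
#' sorts by frame. Coordinates in nm are converted to um.
#'
#' @param path CSV file path.
#' @param dialect a [trackDialect()] describing the columns.
#' @param frameInterval frame interval, s.
#' @param condition condition label.
#' @return a [TrackSet-class].
#' @export
readTracks <- function(path, dialect = trackDialect(), frameInterval,
                       condition = "condition") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (dialect$skip > 0L && nrow(raw) >= dialect$skip)
    raw <- raw[-seq_len(dialect$skip), , drop = FALSE]
  need <- c(dialect$trackCol, dialect$frameCol, dialect$xCol, dialect$yCol)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("track table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!nrow(raw)) {
    warning("empty track table: returning an empty TrackSet")
    return(trackSet(data.frame(track_id = integer(), frame = integer(),
                               x = numeric(), y = numeric()),
                    frameInterval, condition))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]]))
    if (any(bad) || anyNA(v))
      stop("track table format error: non-numeric values in column ", col)
    v
  }
  tr <- data.frame(track_id = raw[[dialect$trackCol]],
                   frame = as.integer(num(dialect$frameCol)),
                   x = num(dialect$xCol), y = num(dialect$yCol))
  extra <- setdiff(names(raw), need)
  for (col in extra) tr[[col]] <- raw[[col]]
  if (anyDuplicated(tr[c("track_id", "frame")]))
    stop("track table integrity error: duplicate (track, frame) rows")
  if (dialect$unit == "nm") {
    tr$x <- tr$x / 1000
    tr$y <- tr$y / 1000
  }
  trackSet(tr, frameInterval, condition)
}

#' Write a track table
#'
#' Writes the internal CSV dialect with deterministic row order (track
#' id, then frame) and full double precision, so that
#' `readTracks(writeTracks(ts))` is the identity and two writes of the
#' same TrackSet are byte-identical.
#'
#' @param ts a [TrackSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(ts, path) {
  tr <- ts@tracks
  tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
  for (col in names(tr))
    if (is.double(tr[[col]])) tr[[col]] <- sprintf("%.17g", tr[[col]])
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by length, splitting at large gaps
#'
#' Tracks containing a gap of more than `maxGapFrames` missing frames
#' are split at that gap; afterwards tracks spanning fewer than
#' `minFrames` frames (last - first + 1) are removed. This mirrors the
#' linking settings of the acquisitions modelled here (two-frame gaps
#' allowed, minimum track length five frames). The returned object
#' carries a `filterLog` attribute listing dropped and split track ids.
#'
#' @param ts a [TrackSet-class].
#' @param minFrames minimum frame span (default 5).
#' @param maxGapFrames largest in-track gap retained, in missing frames
#'   (default 2).
#' @return the filtered [TrackSet-class].
#' @export
filterTracks <- function(ts, minFrames = 5L, maxGapFrames = 2L) {
  if (minFrames < 1L) stop("minFrames must be >= 1")
  tr <- ts@tracks
  if (!nrow(tr)) return(ts)

  pieces <- list()
  split_ids <- character()
  for (d in split(tr, tr$track_id)) {
    gap <- c(0L, diff(d$frame) - 1L)
    part <- cumsum(gap > maxGapFrames)
    if (max(part) > 0L) {
      split_ids <- c(split_ids, as.character(d$track_id[1]))
      for (p in unique(part)) {
        dp <- d[part == p, , drop = FALSE]
        dp$track_id <- paste0(dp$track_id, "_", p + 1L)
        pieces[[length(pieces) + 1L]] <- dp
      }
    } else {
      pieces[[length(pieces) + 1L]] <- d
    }
  }
  tr <- do.call(rbind, pieces)

  span <- tapply(tr$frame, tr$track_id,
                 function(f) max(f) - min(f) + 1L)
  keep <- names(span)[span >= minFrames]
  dropped <- setdiff(names(span), keep)
  tr <- tr[as.character(tr$track_id) %in% keep, , drop = FALSE]

  out <- trackSet(tr, ts@frameInterval, ts@condition)
  attr(out, "filterLog") <- list(dropped = dropped, split = split_ids)
  out
}
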