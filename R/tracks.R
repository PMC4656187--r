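# Domain types and tracked-cell table I/O.
#
# A cell track is one contiguous, uniformly sampled segment of a tracked
# cell: apical area, raw medial myosin fluorescence, centroid, optional
# neighbour lists and outline vertices. An embryo dataset bundles tracks with
# an optional per-embryo background-fluorescence series and a stage label.

TRACK_REQUIRED_COLS <- c("embryo_id", "cell_id", "frame", "time_s",
                         "area_um2", "myosin_intensity")
TRACK_OPTIONAL_COLS <- c("centroid_x_um", "centroid_y_um", "neighbours",
                         "vertices", "dev_time_offset_s")

#' Construct a single cell track
#'
#' @param embryo_id,cell_id identifiers (coerced to character).
#' @param time_s sample times in seconds, strictly increasing with a uniform
#'   step (1\% tolerance).
#' @param area_um2 apical area per frame, strictly positive.
#' @param myosin raw medial myosin fluorescence per frame (a.u.).
#' @param centroid optional n x 2 matrix of centroid coordinates (micron).
#' @param neighbours optional list (length n) of neighbour cell-id vectors.
#' @param vertices optional list (length n) of 2-column outline vertex
#'   matrices with frame-to-frame correspondence.
#' @param dev_time_offset_s alignment of this track's t = 0 to the onset of
#'   slow dorsal closure, seconds (input metadata). Analysis time is
#'   `time_s + dev_time_offset_s`.
#' @param segment integer segment index (tracks split at gaps).
#' @return object of class `cell_track`.
#' @export
cell_track <- function(embryo_id, cell_id, time_s, area_um2, myosin,
                       centroid = NULL, neighbours = NULL, vertices = NULL,
                       dev_time_offset_s = 0, segment = 1L) {
  x <- structure(list(
    embryo_id = as.character(embryo_id), cell_id = as.character(cell_id),
    segment = as.integer(segment),
    time_s = as.numeric(time_s), area_um2 = as.numeric(area_um2),
    myosin = as.numeric(myosin), centroid = centroid,
    neighbours = neighbours, vertices = vertices,
    dev_time_offset_s = as.numeric(dev_time_offset_s)
  ), class = "cell_track")
  validate_track(x)
}

validate_track <- function(x) {
  n <- length(x$time_s)
  if (length(x$area_um2) != n || length(x$myosin) != n) {
    stop("cell_track: area and myosin must match the time grid")
  }
  if (n >= 2) {
    if (any(diff(x$time_s) <= 0)) {
      stop("cell_track ", x$embryo_id, "/", x$cell_id,
           ": times must be strictly increasing")
    }
    if (is.na(uniform_step(x$time_s))) {
      stop("cell_track ", x$embryo_id, "/", x$cell_id,
           ": non-uniform sampling beyond 1% tolerance")
    }
  }
  if (any(!is.finite(x$area_um2)) || any(x$area_um2 <= 0)) {
    stop("cell_track ", x$embryo_id, "/", x$cell_id,
         ": area must be positive and finite everywhere")
  }
  if (!is.null(x$centroid) && (!is.matrix(x$centroid) || nrow(x$centroid) != n)) {
    stop("cell_track: centroid must be an n x 2 matrix")
  }
  for (f in c("neighbours", "vertices")) {
    if (!is.null(x[[f]]) && length(x[[f]]) != n) {
      stop("cell_track: ", f, " must have one entry per frame")
    }
  }
  x
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %s/%s segment %d: %d frames, t = [%g, %g] s (offset %g s)\n",
              x$embryo_id, x$cell_id, x$segment, length(x$time_s),
              min(x$time_s), max(x$time_s), x$dev_time_offset_s))
  invisible(x)
}

#' Analysis time of a track (track time plus developmental offset)
#' @param track a `cell_track`.
#' @return numeric vector of analysis times, seconds.
#' @export
analysis_time <- function(track) track$time_s + track$dev_time_offset_s

#' Bundle cell tracks into an embryo dataset
#'
#' @param tracks list of [cell_track()] objects.
#' @param background optional data.frame with columns `embryo_id`, `time_s`,
#'   `background` giving the per-embryo background fluorescence level.
#' @param stage_label free-text label (e.g. "wild type", "ctMLCK").
#' @return object of class `embryo_dataset`.
#' @export
embryo_dataset <- function(tracks, background = NULL, stage_label = "") {
  ds <- structure(list(tracks = tracks, background = background,
                       stage_label = stage_label),
                  class = "embryo_dataset")
  validate_dataset(ds)
}

#' Validate an embryo dataset
#'
#' Checks every track's invariants, uniqueness of
#' (embryo, cell, segment) and that tracks of one embryo agree on the time
#' grid where they overlap (common phase of the sampling comb).
#'
#' @param ds an `embryo_dataset`.
#' @return the dataset, invisibly errors otherwise.
#' @export
validate_dataset <- function(ds) {
  lapply(ds$tracks, validate_track)
  key <- vapply(ds$tracks, function(tr)
    paste(tr$embryo_id, tr$cell_id, tr$segment, sep = "\r"), character(1))
  if (anyDuplicated(key)) stop("embryo_dataset: duplicated (embryo, cell, segment)")
  # shared grid: all tracks of one embryo must sit on one sampling comb
  emb <- vapply(ds$tracks, `[[`, character(1), "embryo_id")
  for (e in unique(emb)) {
    trs <- ds$tracks[emb == e]
    dts <- vapply(trs, function(tr) uniform_step(tr$time_s), numeric(1))
    dts <- dts[!is.na(dts)]
    if (length(dts) > 1 && diff(range(dts)) > 0.01 * stats::median(dts)) {
      stop("embryo_dataset: embryo ", e, " mixes sampling steps")
    }
    if (length(dts)) {
      dt <- stats::median(dts)
      ph <- vapply(trs, function(tr) (tr$time_s[1] / dt) %% 1, numeric(1))
      ph <- sort(ph)
      gap <- pmin(diff(c(ph, ph[1] + 1)), 1)
      if (length(ph) > 1 && max(ph) - min(ph) > 0.01 && min(gap) < 0.99) {
        if (any(ph > 0.01 & ph < 0.99)) {
          stop("embryo_dataset: embryo ", e,
               " tracks are not on a shared time grid")
        }
      }
    }
  }
  if (!is.null(ds$background)) {
    need <- c("embryo_id", "time_s", "background")
    if (!all(need %in% names(ds$background))) {
      stop("embryo_dataset: background needs columns ",
           paste(need, collapse = ", "))
    }
  }
  invisible(ds)
}

#' @export
print.embryo_dataset <- function(x, ...) {
  emb <- unique(vapply(x$tracks, `[[`, character(1), "embryo_id"))
  cat(sprintf("<embryo_dataset> %d track segment(s), %d embryo(s)%s%s\n",
              length(x$tracks), length(emb),
              if (nzchar(x$stage_label)) paste0(", stage: ", x$stage_label) else "",
              if (!is.null(x$background)) ", with background series" else ""))
  invisible(x)
}

# ---- flat-table conversion --------------------------------------------------

fmt_pairs <- function(m) {
  if (is.null(m) || !nrow(m)) return("")
  paste(sprintf("%.17g:%.17g", m[, 1], m[, 2]), collapse = ";")
}

parse_pairs <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
}

#' Flatten an embryo dataset into the documented one-row-per-frame table
#'
#' @param ds an `embryo_dataset`.
#' @return a `data.table` with columns `embryo_id`, `cell_id`, `frame`,
#'   `time_s`, `area_um2`, `myosin_intensity`, `centroid_x_um`,
#'   `centroid_y_um`, `neighbours` (semicolon-separated), `vertices`
#'   (semicolon-separated `x:y` pairs) and `dev_time_offset_s`.
#' @export
tracks_table <- function(ds) {
  rows <- lapply(ds$tracks, function(tr) {
    n <- length(tr$time_s)
    dt <- uniform_step(tr$time_s)
    data.table::data.table(
      embryo_id = tr$embryo_id, cell_id = tr$cell_id,
      frame = as.integer(round(tr$time_s / dt)),
      time_s = tr$time_s, area_um2 = tr$area_um2,
      myosin_intensity = tr$myosin,
      centroid_x_um = if (is.null(tr$centroid)) NA_real_ else tr$centroid[, 1],
      centroid_y_um = if (is.null(tr$centroid)) NA_real_ else tr$centroid[, 2],
      neighbours = if (is.null(tr$neighbours)) "" else
        vapply(tr$neighbours, paste, character(1), collapse = ";"),
      vertices = if (is.null(tr$vertices)) "" else
        vapply(tr$vertices, fmt_pairs, character(1)),
      dev_time_offset_s = tr$dev_time_offset_s
    )
  })
  data.table::rbindlist(rows)
}

#' Write an embryo dataset as CSV
#'
#' Numeric columns are printed at full (round-trip) precision so that
#' [read_tracks()] composed with `write_tracks` is the identity on values.
#'
#' @param ds an `embryo_dataset`.
#' @param path output CSV path.
#' @param background_path optional path for the background series CSV.
#' @return invisibly, the paths written.
#' @export
write_tracks <- function(ds, path, background_path = NULL) {
  validate_dataset(ds)
  tab <- tracks_table(ds)
  if (nrow(tab) == 0) {
    tab <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), length(c(TRACK_REQUIRED_COLS, TRACK_OPTIONAL_COLS))),
                      c(TRACK_REQUIRED_COLS, TRACK_OPTIONAL_COLS)))
  }
  num <- names(tab)[vapply(tab, is.double, logical(1))]
  for (cn in num) data.table::set(tab, j = cn, value = sprintf("%.17g", tab[[cn]]))
  data.table::fwrite(tab, path)
  if (!is.null(ds$background) && !is.null(background_path)) {
    bg <- data.table::as.data.table(ds$background)
    for (cn in names(bg)[vapply(bg, is.double, logical(1))]) {
      data.table::set(bg, j = cn, value = sprintf("%.17g", bg[[cn]]))
    }
    data.table::fwrite(bg, background_path)
  }
  invisible(c(path, background_path))
}

#' Read a tracked-cell table into an embryo dataset
#'
#' Rows are grouped into per-cell tracks sorted by time. Tracks with a
#' missing frame are split into contiguous segments at the gap; segments
#' shorter than the trend window are discarded. All rejections are recorded
#' in the `report` attribute of the result, never dropped silently.
#'
#' @param path CSV with the schema documented in [tracks_table()].
#' @param background_path optional CSV with columns `embryo_id`, `time_s`,
#'   `background`.
#' @param trend_window minimum usable segment duration, seconds.
#' @param stage_label free-text label attached to the dataset.
#' @return an `embryo_dataset`; `attr(, "report")` lists dropped segments
#'   and rejected tracks with reasons.
#' @export
read_tracks <- function(path, background_path = NULL, trend_window = 360,
                        stage_label = "") {
  if (!file.exists(path)) stop("read_tracks: no such file: ", path)
  tab <- data.table::fread(path)
  missing_cols <- setdiff(TRACK_REQUIRED_COLS, names(tab))
  if (length(missing_cols)) {
    stop("read_tracks: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in c("embryo_id", "cell_id")) {
    data.table::set(tab, j = cn, value = as.character(tab[[cn]]))
  }
  if (nrow(tab) && anyDuplicated(tab, by = c("embryo_id", "cell_id", "frame"))) {
    stop("read_tracks: duplicated (embryo_id, cell_id, frame) rows")
  }
  report <- list(dropped_segments = 0L, rejected = character(0))
  tracks <- list()
  if (nrow(tab)) {
    tab <- tab[order(tab$embryo_id, tab$cell_id, tab$time_s)]
    grp <- split(tab, paste(tab$embryo_id, tab$cell_id, sep = "\r"), drop = TRUE)
    for (g in grp) {
      dt <- if (nrow(g) >= 2) stats::median(diff(g$time_s)) else NA_real_
      # split at any step deviating from the nominal by > 1 %
      brk <- if (nrow(g) >= 2) which(abs(diff(g$time_s) - dt) > 0.01 * dt) else integer(0)
      seg_id <- cumsum(c(0L, seq_len(nrow(g) - 1) %in% brk))
      for (sid in unique(seg_id)) {
        s <- g[seg_id == sid, ]
        dur <- diff(range(s$time_s))
        if (nrow(s) < 2 || dur < trend_window) {
          report$dropped_segments <- report$dropped_segments + 1L
          next
        }
        tr <- tryCatch(
          cell_track(
            s$embryo_id[1], s$cell_id[1], s$time_s, s$area_um2,
            s$myosin_intensity,
            centroid = if ("centroid_x_um" %in% names(s) && !all(is.na(s$centroid_x_um)))
              cbind(s$centroid_x_um, s$centroid_y_um) else NULL,
            neighbours = if ("neighbours" %in% names(s) && any(nzchar(s$neighbours)))
              lapply(strsplit(as.character(s$neighbours), ";", fixed = TRUE),
                     function(v) v[nzchar(v)]) else NULL,
            vertices = if ("vertices" %in% names(s) && any(nzchar(s$vertices)))
              lapply(as.character(s$vertices), parse_pairs) else NULL,
            dev_time_offset_s = if ("dev_time_offset_s" %in% names(s))
              s$dev_time_offset_s[1] else 0,
            segment = sid + 1L
          ),
          error = function(e) conditionMessage(e)
        )
        if (is.character(tr)) {
          report$rejected <- c(report$rejected, tr)
        } else {
          tracks[[length(tracks) + 1]] <- tr
        }
      }
    }
  }
  background <- if (!is.null(background_path)) {
    as.data.frame(data.table::fread(background_path))
  } else NULL
  ds <- embryo_dataset(tracks, background = background, stage_label = stage_label)
  attr(ds, "report") <- report
  ds
}
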