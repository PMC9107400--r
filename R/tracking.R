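#' Link localizations into tracks by greedy nearest-neighbour assignment
#'
#' Builds trajectories from a table of sub-pixel localizations using a simple
#' proximity-based algorithm: for each frame, candidate pairings between open
#' track ends and current localizations within `max_jump` are accepted in
#' ascending distance order, each end and each localization used at most
#' once. Track ends may bridge up to `max_gap` empty frames. Localizations
#' left unmatched start new tracks; tracks with a single localization are
#' discarded.
#'
#' Input rows are first put into a canonical (frame, x, y) order so the
#' result does not depend on row order; exact distance ties are then broken
#' by the lower localization index in that order.
#'
#' @param locs data.frame with columns `frame` (0-based integer), `x`, `y`
#'   (um) and optionally `quality`.
#' @param max_jump maximum frame-to-frame displacement (um) for a link.
#' @param max_gap maximum number of empty frames a track may bridge
#'   (default 0, no gap closing).
#' @return data.frame with columns `track_id`, `frame`, `x`, `y` (and
#'   `quality` when present), ordered by track and frame.
#' @export
link_localizations <- function(locs, max_jump, max_gap = 0L) {
  stopifnot(is.data.frame(locs), max_jump > 0, max_gap >= 0)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(locs)))
    stop("locs must have columns frame, x, y")
  empty <- locs[0, intersect(c("frame", "x", "y", "quality"), names(locs))]
  empty$track_id <- integer(0)
  if (nrow(locs) == 0) return(empty)
  if (any(!is.finite(locs$x)) || any(!is.finite(locs$y)) || any(locs$frame < 0))
    stop("coordinates must be finite and frames non-negative")
  dup <- duplicated(locs[, c("frame", "x", "y")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (frame, x, y) rows removed")
    locs <- locs[!dup, ]
  }
  locs <- locs[order(locs$frame, locs$x, locs$y), , drop = FALSE]
  rownames(locs) <- NULL
  has_q <- "quality" %in% names(locs)

  n <- nrow(locs)
  track_of <- integer(n)          # track id per localization row
  # open track ends: row index of last localization per track
  end_row <- integer(0)
  end_track <- integer(0)
  next_id <- 1L
  rows_by_frame <- split(seq_len(n), locs$frame)
  frames <- as.integer(names(rows_by_frame))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- rows_by_frame[[fi]]
    # keep only ends recent enough to bridge to this frame
    ok <- locs$frame[end_row] >= f - 1L - max_gap & locs$frame[end_row] < f
    end_row <- end_row[ok]; end_track <- end_track[ok]
    if (length(end_row) > 0) {
      dx <- outer(locs$x[end_row], locs$x[cur], "-")
      dy <- outer(locs$y[end_row], locs$y[cur], "-")
      d <- sqrt(dx * dx + dy * dy)
      cand <- which(d <= max_jump, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        dist <- d[cand]
        ord <- order(dist, cur[cand[, 2]], end_row[cand[, 1]])
        cand <- cand[ord, , drop = FALSE]
        used_end <- logical(length(end_row))
        used_cur <- logical(length(cur))
        for (ci in seq_len(nrow(cand))) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (!used_end[i] && !used_cur[j]) {
            used_end[i] <- TRUE; used_cur[j] <- TRUE
            track_of[cur[j]] <- end_track[i]
            end_row[i] <- cur[j]
          }
        }
      }
    }
    new <- cur[track_of[cur] == 0L]
    if (length(new) > 0) {
      ids <- seq.int(next_id, length.out = length(new))
      track_of[new] <- ids
      next_id <- next_id + length(new)
      end_row <- c(end_row, new)
      end_track <- c(end_track, ids)
    }
  }

  keep <- track_of %in% which(tabulate(track_of) >= 2L)
  if (!any(keep)) return(empty)
  out <- locs[keep, c("frame", "x", "y", if (has_q) "quality")]
  out$track_id <- match(track_of[keep], unique(track_of[keep]))
  out <- out[order(out$track_id, out$frame),
             c("track_id", "frame", "x", "y", if (has_q) "quality")]
  rownames(out) <- NULL
  out
}

#' Create a nucleus mask from polygon vertices
#'
#' @param nucleus_id identifier for the nucleus.
#' @param vertices two-column matrix or data.frame of polygon vertices (um);
#'   the polygon is treated as closed (last vertex joins the first).
#' @return list of class `nucleus_mask`.
#' @export
nucleus_mask <- function(nucleus_id, vertices) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3, all(is.finite(v)))
  # shoelace area; zero-area polygons are degenerate
  xs <- v[, 1]; ys <- v[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area <= 0) stop("mask polygon has zero area")
  structure(list(nucleus_id = nucleus_id, vertices = v, area = area),
            class = "nucleus_mask")
}

# even-odd point-in-polygon test; points on an edge or vertex count as inside
point_in_polygon <- function(px, py, vertices, tol = 1e-12) {
  xs <- vertices[, 1]; ys <- vertices[, 2]
  nv <- length(xs)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment test via cross product and bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= tol * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    boundary <- boundary | on
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | boundary
}

#' Restrict tracks to nucleus masks
#'
#' Keeps a track only if every one of its localizations lies inside one and
#' the same nucleus polygon (even-odd rule, boundary points inside) and
#' annotates kept tracks with that nucleus id. When masks overlap, a track is
#' assigned to the first listed mask containing its first localization, with
#' a warning.
#'
#' @param tracks track table as produced by [link_localizations()].
#' @param masks non-empty list of [nucleus_mask()] objects.
#' @return The kept rows of `tracks` with an added `nucleus_id` column.
#' @export
filter_tracks_by_mask <- function(tracks, masks) {
  stopifnot(is.data.frame(tracks))
  if (length(masks) == 0) stop("masks must be a non-empty list of nucleus_mask")
  if (!all(vapply(masks, inherits, logical(1), "nucleus_mask")))
    stop("every mask must be a nucleus_mask object")
  if (nrow(tracks) == 0) { tracks$nucleus_id <- character(0); return(tracks) }
  inside <- vapply(masks,
                   function(m) point_in_polygon(tracks$x, tracks$y, m$vertices),
                   logical(nrow(tracks)))
  inside <- matrix(inside, nrow = nrow(tracks))
  ids <- vapply(masks, function(m) as.character(m$nucleus_id), character(1))
  if (any(rowSums(inside) > 1))
    warning("overlapping masks: tracks assigned to the first mask ",
            "containing their first localization")
  split_idx <- split(seq_len(nrow(tracks)), tracks$track_id)
  keep_rows <- integer(0)
  nuc <- character(0)
  for (rows in split_idx) {
    rows <- rows[order(tracks$frame[rows])]
    cand <- which(inside[rows[1], ])
    if (length(cand) == 0) next
    m <- cand[1]
    if (all(inside[rows, m])) {
      keep_rows <- c(keep_rows, rows)
      nuc <- c(nuc, rep(ids[m], length(rows)))
    }
  }
  out <- tracks[keep_rows, , drop = FALSE]
  out$nucleus_id <- nuc
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove defocused or mislinked tracks
#'
#' A track is removed if its median localization quality falls below
#' `min_quality` (when a quality column is present) or if any single-frame
#' displacement exceeds `max_frame_jump`, a physically implausible jump that
#' flags defocusing or a linking error. The underlying imaging software's
#' defocus criterion is not published, so this quality/jump heuristic is a
#' documented stand-in.
#'
#' @param tracks track table.
#' @param min_quality minimum acceptable median quality (default 0, i.e. no
#'   quality filtering).
#' @param max_frame_jump maximum plausible displacement (um) between
#'   consecutive frames (default 5).
#' @return The filtered track table.
#' @export
filter_defocused <- function(tracks, min_quality = 0, max_frame_jump = 5) {
  stopifnot(is.data.frame(tracks), max_frame_jump > 0, min_quality >= 0)
  if (nrow(tracks) == 0) return(tracks)
  has_q <- "quality" %in% names(tracks)
  if (!has_q && min_quality > 0)
    warning("no quality column; quality criterion skipped")
  bad <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(rows) {
    rows <- rows[order(tracks$frame[rows])]
    if (has_q && stats::median(tracks$quality[rows]) < min_quality) return(TRUE)
    df <- diff(tracks$frame[rows])
    step <- sqrt(diff(tracks$x[rows])^2 + diff(tracks$y[rows])^2)
    any(df == 1 & step > max_frame_jump)
  }, logical(1))
  bad_ids <- names(bad)[bad]
  out <- tracks[!(as.character(tracks$track_id) %in% bad_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track duration distribution
#'
#' Duration of a track spanning frames `f_first..f_last` is
#' `(f_last - f_first + 1) * frame_interval`: a molecule observed in one
#' frame has one frame interval of exposure. This is the quantitative
#' endpoint of the kymograph analysis.
#'
#' @param tracks track table.
#' @param frame_interval frame interval (s).
#' @return list of class `track_durations` with `durations` (data.frame:
#'   `track_id`, `n_frames`, `duration`) and `quantiles`.
#' @export
track_durations <- function(tracks, frame_interval) {
  stopifnot(is.data.frame(tracks), frame_interval > 0)
  agg <- stats::aggregate(frame ~ track_id, data = tracks,
                          FUN = function(f) c(min(f), max(f)))
  first <- agg$frame[, 1]; last <- agg$frame[, 2]
  d <- data.frame(track_id = agg$track_id,
                  n_frames = last - first + 1,
                  duration = (last - first + 1) * frame_interval)
  qs <- if (nrow(d) > 0)
    stats::quantile(d$duration, c(0.25, 0.5, 0.75, 0.9, 0.95)) else
      stats::setNames(rep(NA_real_, 5), c("25%", "50%", "75%", "90%", "95%"))
  structure(list(durations = d, quantiles = qs,
                 frame_interval = frame_interval),
            class = "track_durations")
}

#' @export
print.track_durations <- function(x, ...) {
  cat(sprintf("Track durations: %d tracks, median %.3g s\n",
              nrow(x$durations), stats::median(x$durations$duration)))
  print(x$quantiles)
  invisible(x)
}
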