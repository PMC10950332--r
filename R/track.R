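# Maximum-weight bipartite matching between track heads and new spots.
# Returns an integer vector: for each left node, the matched right index or NA.
match_pairs <- function(cost, allowed) {
  nl <- nrow(cost); nr <- ncol(cost)
  if (!nl || !nr || !any(allowed)) return(rep(NA_integer_, nl))
  edges <- which(allowed, arr.ind = TRUE)
  # large constant makes cardinality dominate, then total squared
  # displacement is minimized among maximum matchings
  C <- 1e6 * (max(cost[allowed]) + 1)
  w <- C - cost[allowed]
  el <- rbind(edges[, 1], nl + edges[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nl), rep(TRUE, nr)),
                                    as.vector(el))
  m <- igraph::max_bipartite_match(g, weights = w)$matching
  out <- rep(NA_integer_, nl)
  matched <- m[seq_len(nl)]
  ok <- !is.na(matched)
  out[ok] <- matched[ok] - nl
  out
}

#' Link per-frame spots into cisterna tracks
#'
#' Frame-to-frame assignment by optimal bipartite matching: among all
#' assignments of maximal size, the one minimizing total squared displacement
#' is chosen; links longer than the gating distance are forbidden. Tracks
#' whose spot was missed stay open for up to `max_gap` frames, with the
#' gating distance growing proportionally to the bridged interval, so short
#' detection dropouts are bridged by the same criterion. Unmatched spots
#' seed new tracks. No splitting or merging is attempted. Given identical
#' input the output is reproducible (ids are assigned in order of track
#' birth, then spot order).
#'
#' @param spots Data frame with columns `frame`, `z_um`, `y_um`, `x_um`
#'   (e.g. rows of [detect_spots()] outputs bound together).
#' @param max_displacement Gating distance per frame interval, um.
#' @param max_gap Maximum number of missed frames bridged within one track.
#' @return The input data frame with a `track` column, ordered by
#'   (track, frame); class `track_table`.
#' @export
link_tracks <- function(spots, max_displacement = 0.5, max_gap = 2L) {
  need <- c("frame", "z_um", "y_um", "x_um")
  if (!all(need %in% names(spots))) {
    stop("'spots' needs columns frame, z_um, y_um, x_um", call. = FALSE)
  }
  stopifnot_scalar(max_displacement, "max_displacement")
  if (!nrow(spots)) {
    out <- cbind(spots, track = integer())
    class(out) <- c("track_table", "data.frame")
    return(out)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  spots$track <- NA_integer_
  frames <- sort(unique(spots$frame))
  # open track state: id, last row index, last frame
  open <- data.frame(id = integer(), row = integer(), frame = integer())
  next_id <- 1L
  for (f in frames) {
    rows_f <- which(spots$frame == f)
    open <- open[open$frame >= f - 1L - max_gap, , drop = FALSE]
    assigned <- rep(NA_integer_, length(rows_f))
    if (nrow(open)) {
      P_open <- as.matrix(spots[open$row, c("z_um", "y_um", "x_um")])
      P_new <- as.matrix(spots[rows_f, c("z_um", "y_um", "x_um")])
      gap_n <- f - open$frame  # 1 = consecutive
      d2 <- outer(P_open[, 1], P_new[, 1], "-")^2 +
        outer(P_open[, 2], P_new[, 2], "-")^2 +
        outer(P_open[, 3], P_new[, 3], "-")^2
      lim <- (max_displacement * gap_n)^2
      allowed <- d2 <= matrix(lim, nrow(open), length(rows_f))
      match <- match_pairs(d2, allowed)
      for (i in seq_along(match)) {
        if (!is.na(match[i])) {
          r <- rows_f[match[i]]
          spots$track[r] <- open$id[i]
          open$row[i] <- r
          open$frame[i] <- f
          assigned[match[i]] <- i
        }
      }
    }
    for (j in seq_along(rows_f)) {
      if (is.na(assigned[j])) {
        spots$track[rows_f[j]] <- next_id
        open <- rbind(open, data.frame(id = next_id, row = rows_f[j],
                                       frame = f))
        next_id <- next_id + 1L
      }
    }
  }
  out <- spots[order(spots$track, spots$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Summarize a track table
#'
#' @param tracks A `track_table` from [link_tracks()].
#' @return Data frame with one row per track: `track`, `birth_frame`,
#'   `death_frame`, `n_spots`.
#' @export
track_summary <- function(tracks) {
  if (!nrow(tracks)) {
    return(data.frame(track = integer(), birth_frame = integer(),
                      death_frame = integer(), n_spots = integer()))
  }
  sp <- split(tracks$frame, tracks$track)
  data.frame(track = as.integer(names(sp)),
             birth_frame = vapply(sp, min, 0),
             death_frame = vapply(sp, max, 0),
             n_spots = lengths(sp), row.names = NULL)
}

# Per-frame centers of one track over its full span, linearly interpolating
# across bridged gaps. Returns data frame frame, z_um, y_um, x_um.
track_centers <- function(track_spots) {
  fr <- min(track_spots$frame):max(track_spots$frame)
  out <- data.frame(frame = fr)
  for (col in c("z_um", "y_um", "x_um")) {
    out[[col]] <- approx(track_spots$frame, track_spots[[col]], xout = fr,
                         rule = 2)$y
  }
  out
}

#' Detect transient cisterna-ERES contact events
#'
#' A contact event is a maximal run of at least `min_frames` consecutive
#' frames during which a track center stays within `contact_distance` of a
#' static ERES punctum. The event duration is (last - first) x frame
#' interval, so a single-frame approach counts 0 s; this convention (one of
#' several defensible ones) is applied consistently to ground truth
#' comparisons.
#'
#' @param tracks A `track_table` from [link_tracks()].
#' @param eres Data frame of static reference puncta with columns `eres`,
#'   `z_um`, `y_um`, `x_um` (e.g. from a detection on the ERES channel or
#'   the simulator's ground truth).
#' @param frame_interval Seconds between frames (required).
#' @param contact_distance Center-to-center contact threshold, um. The
#'   default 0.35 um is roughly the sum of typical spot radii for ~0.5 um
#'   puncta.
#' @param min_frames Minimum run length in frames.
#' @return Data frame with one row per event: `track`, `eres`,
#'   `start_frame`, `end_frame`, `duration_s`, `min_distance_um`.
#' @export
detect_contacts <- function(tracks, eres, frame_interval,
                            contact_distance = 0.35, min_frames = 2L) {
  if (missing(frame_interval)) {
    stop("'frame_interval' is required to convert frames to seconds",
         call. = FALSE)
  }
  stopifnot_scalar(frame_interval, "frame_interval")
  empty <- data.frame(track = integer(), eres = integer(),
                      start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), min_distance_um = numeric())
  if (!nrow(tracks) || !nrow(eres)) return(empty)
  events <- list()
  for (tid in unique(tracks$track)) {
    ctr <- track_centers(tracks[tracks$track == tid, , drop = FALSE])
    for (j in seq_len(nrow(eres))) {
      d <- sqrt((ctr$z_um - eres$z_um[j])^2 + (ctr$y_um - eres$y_um[j])^2 +
                  (ctr$x_um - eres$x_um[j])^2)
      inside <- d <= contact_distance
      r <- rle(inside)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_frames)) {
        seg <- starts[k]:ends[k]
        events[[length(events) + 1L]] <- data.frame(
          track = tid, eres = eres$eres[j],
          start_frame = ctr$frame[starts[k]], end_frame = ctr$frame[ends[k]],
          duration_s = (ctr$frame[ends[k]] - ctr$frame[starts[k]]) *
            frame_interval,
          min_distance_um = min(d[seg]))
      }
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
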