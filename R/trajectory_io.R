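#' Trajectory sets
#'
#' A `trajectory_set` holds tracked 2D positions of mitochondria over time, as
#' produced by particle tracking of time-lapse confocal video. Positions are in
#' micrometres and times in seconds. Tracking videos of *Arabidopsis*
#' hypocotyl cells are typically acquired at a frame interval of 1.94 s and
#' rescaled to a universal length scale of 5.0 pixels per micrometre; those
#' values are the defaults here and can be overridden.
#'
#' @param points data frame with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`. One row per tracked spot.
#' @param frame_interval seconds between consecutive frames.
#' @param pixel_scale pixels per micrometre used when converting files stored
#'   in pixel units.
#' @param window_length length of the observation window in seconds; defaults
#'   to the time span covered by the points.
#'
#' @return An object of class `trajectory_set`: a list with elements `points`
#'   (data frame sorted by track and frame), `frame_interval`, `pixel_scale`
#'   and `window_length`.
#' @export
trajectory_set <- function(points,
                           frame_interval = 1.94,
                           pixel_scale = 5.0,
                           window_length = NULL) {
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  if (!is.data.frame(points)) {
    stop("`points` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- points[required]
  points$track_id <- as.character(points$track_id)
  for (col in c("frame", "t_s", "x_um", "y_um")) {
    if (!is.numeric(points[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
  }
  if (nrow(points) > 0) {
    if (any(!is.finite(points$x_um)) || any(!is.finite(points$y_um))) {
      stop("positions must be finite", call. = FALSE)
    }
    if (any(points$frame < 0)) {
      stop("frames must be non-negative", call. = FALSE)
    }
    points <- points[order(points$track_id, points$frame), , drop = FALSE]
    rownames(points) <- NULL
    dup <- stats::ave(points$frame, points$track_id,
                      FUN = function(f) c(0, diff(f)))
    # after sorting, a non-positive step within a track means repeated frames
    first_of_track <- !duplicated(points$track_id)
    if (any(dup[!first_of_track] <= 0)) {
      bad <- unique(points$track_id[!first_of_track & dup <= 0])
      stop("track(s) with non-increasing frames: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  assert_scalar_number(frame_interval, "frame_interval", lower = 0)
  assert_scalar_number(pixel_scale, "pixel_scale", lower = .Machine$double.eps)
  if (is.null(window_length)) {
    window_length <- if (nrow(points) > 0) max(points$t_s) - min(0, min(points$t_s)) else 0
  }
  structure(
    list(points = points,
         frame_interval = frame_interval,
         pixel_scale = pixel_scale,
         window_length = window_length),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_tracks <- length(unique(x$points$track_id))
  cat(sprintf("<trajectory_set: %d tracks, %d points, window %.4g s>\n",
              n_tracks, nrow(x$points), x$window_length))
  invisible(x)
}

#' Number of tracks in a trajectory set
#' @param trajectories a [trajectory_set()].
#' @return integer count of distinct tracks.
#' @export
n_tracks <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  length(unique(trajectories$points$track_id))
}

#' Read TrackMate XML tracking output
#'
#' Parses the `Model/AllSpots` + `Model/AllTracks/Track` dialect written by
#' TrackMate (the Fiji particle tracker). Each `Track` element becomes one
#' trajectory; spots are resolved through the `Edge` elements'
#' `SPOT_SOURCE_ID`/`SPOT_TARGET_ID` attributes. Tracking output may be stored
#' either in pixels (the raw TrackMate convention, converted here using
#' `pixel_scale`) or already in micrometres.
#'
#' @param path path to a TrackMate XML file.
#' @param pixel_scale pixels per micrometre (used when `units = "pixels"`).
#' @param frame_interval seconds per frame, used to compute spot times as
#'   `frame * frame_interval`.
#' @param units `"pixels"` if spot coordinates are stored in pixels,
#'   `"micrometres"` if they already carry physical units.
#' @return A [trajectory_set()].
#' @export
read_trackmate_xml <- function(path,
                               pixel_scale = 5.0,
                               frame_interval = 1.94,
                               units = c("pixels", "micrometres")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  spots <- xml2::xml_find_all(doc, ".//Model/AllSpots//Spot")
  if (length(spots) == 0) {
    stop("no <Spot> elements found under Model/AllSpots in ", path,
         call. = FALSE)
  }
  spot_id <- xml2::xml_attr(spots, "ID")
  spot_x <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  spot_y <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  spot_frame <- as.numeric(xml2::xml_attr(spots, "FRAME"))
  if (any(is.na(spot_id)) || any(is.na(spot_x)) || any(is.na(spot_y)) ||
      any(is.na(spot_frame))) {
    stop("offending element <Spot>: each spot needs ID, POSITION_X, ",
         "POSITION_Y and FRAME attributes", call. = FALSE)
  }
  spot_tab <- data.frame(id = spot_id, x = spot_x, y = spot_y,
                         frame = spot_frame, stringsAsFactors = FALSE)

  tracks <- xml2::xml_find_all(doc, ".//Model/AllTracks/Track")
  if (length(tracks) == 0) {
    stop("no <Track> elements found under Model/AllTracks in ", path,
         call. = FALSE)
  }
  pieces <- lapply(tracks, function(trk) {
    tid <- xml2::xml_attr(trk, "TRACK_ID")
    if (is.na(tid)) {
      stop("offending element <Track>: missing TRACK_ID attribute",
           call. = FALSE)
    }
    edges <- xml2::xml_find_all(trk, "./Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) {
      # single-spot track: TrackMate can record it with a SPOT_IDS attribute
      ids <- strsplit(xml2::xml_attr(trk, "SPOT_IDS") %||% "", " ")[[1]]
      ids <- ids[nzchar(ids)]
    }
    if (length(ids) == 0) {
      stop(sprintf("offending element <Track TRACK_ID=\"%s\">: no spots", tid),
           call. = FALSE)
    }
    idx <- match(ids, spot_tab$id)
    if (any(is.na(idx))) {
      stop(sprintf(
        "offending element <Track TRACK_ID=\"%s\">: unknown spot id(s) %s",
        tid, paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    sp <- spot_tab[idx, , drop = FALSE]
    data.frame(track_id = tid,
               frame = sp$frame,
               x = sp$x,
               y = sp$y,
               stringsAsFactors = FALSE)
  })
  all_pts <- do.call(rbind, pieces)
  scale <- if (units == "pixels") pixel_scale else 1.0
  pts <- data.frame(
    track_id = all_pts$track_id,
    frame = as.integer(all_pts$frame),
    t_s = all_pts$frame * frame_interval,
    x_um = all_pts$x / scale,
    y_um = all_pts$y / scale,
    stringsAsFactors = FALSE
  )
  trajectory_set(pts, frame_interval = frame_interval,
                 pixel_scale = pixel_scale)
}

#' Write a minimal TrackMate-dialect XML file
#'
#' Emits the `Model/AllSpots` + `Model/AllTracks/Track` layout that
#' [read_trackmate_xml()] consumes; useful for interchange and round-trip
#' testing. Coordinates are written in the requested unit system.
#'
#' @param trajectories a [trajectory_set()].
#' @param path output file path.
#' @param units write coordinates in `"pixels"` (multiplying by the set's
#'   `pixel_scale`) or `"micrometres"`.
#' @return `path`, invisibly.
#' @export
write_trackmate_xml <- function(trajectories, path,
                                units = c("pixels", "micrometres")) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  units <- match.arg(units)
  pts <- trajectories$points
  scale <- if (units == "pixels") trajectories$pixel_scale else 1.0
  pts$spot_id <- sprintf("s%d", seq_len(nrow(pts)))

  doc <- xml2::xml_new_root("TrackMate")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel",
                               timeunits = "frame")
  allspots <- xml2::xml_add_child(model, "AllSpots")
  for (fr in sort(unique(pts$frame))) {
    sif <- xml2::xml_add_child(allspots, "SpotsInFrame",
                               frame = as.character(fr))
    rows <- pts[pts$frame == fr, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      xml2::xml_add_child(
        sif, "Spot",
        ID = rows$spot_id[i],
        FRAME = as.character(rows$frame[i]),
        POSITION_X = format(rows$x_um[i] * scale, digits = 17),
        POSITION_Y = format(rows$y_um[i] * scale, digits = 17)
      )
    }
  }
  alltracks <- xml2::xml_add_child(model, "AllTracks")
  for (tid in unique(pts$track_id)) {
    rows <- pts[pts$track_id == tid, , drop = FALSE]
    trk <- xml2::xml_add_child(alltracks, "Track", TRACK_ID = tid,
                               SPOT_IDS = paste(rows$spot_id, collapse = " "))
    if (nrow(rows) >= 2) {
      for (i in seq_len(nrow(rows) - 1)) {
        xml2::xml_add_child(trk, "Edge",
                            SPOT_SOURCE_ID = rows$spot_id[i],
                            SPOT_TARGET_ID = rows$spot_id[i + 1])
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a plain trajectory table
#'
#' Generic interchange format: a comma-separated table with header
#' `track_id,frame,t_s,x_um,y_um`, positions already in micrometres.
#'
#' @param path path to the CSV file.
#' @param frame_interval,pixel_scale metadata attached to the returned set.
#' @return A [trajectory_set()].
#' @export
read_trajectory_table <- function(path, frame_interval = 1.94,
                                  pixel_scale = 5.0) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(track_id = "character"))
  required <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("frame", "t_s", "x_um", "y_um")) {
    if (!is.numeric(tab[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
  }
  trajectory_set(tab, frame_interval = frame_interval,
                 pixel_scale = pixel_scale)
}

#' Write a plain trajectory table
#'
#' Inverse of [read_trajectory_table()]; lossless for the five columns.
#'
#' @param trajectories a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  utils::write.csv(trajectories$points, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
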