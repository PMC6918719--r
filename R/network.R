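# Habitual route network construction. Daily travel paths are overlaid within
# a sampling week (deduplicating repeats), weekly paths are overlaid across
# weeks, and every stretch of geometry carries the number of distinct weeks in
# which it was travelled. Two path stretches are "the same segment" when one
# runs within `buffer_m` of the other for at least `min_overlap_m` without the
# local travel bearings deviating by more than `max_dev_deg` (bearings are
# direction-agnostic: a route is the same whichever way it is walked).

.check_resampled <- function(xy, max_step = 1) {
  st <- attr(xy, "step_m")
  if (is.null(st)) {
    d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    if (length(d) && max(d) > max_step + 1e-6)
      stop("path must be resampled at <= ", max_step, " m; see resample_path()")
  } else if (st > max_step + 1e-6) {
    stop("path must be resampled at <= ", max_step, " m; see resample_path()")
  }
  invisible(xy)
}

# nearest vertex of B for each vertex of A (chunked exact search)
.nearest_vertex <- function(A, B, chunk = 1024L) {
  nA <- nrow(A)
  idx <- integer(nA); d2 <- numeric(nA)
  for (st in seq(1L, nA, by = chunk)) {
    en <- min(nA, st + chunk - 1L)
    dx <- outer(A[st:en, 1], B[, 1], "-")
    dy <- outer(A[st:en, 2], B[, 2], "-")
    D <- dx * dx + dy * dy
    w <- max.col(-D, ties.method = "first")
    idx[st:en] <- w
    d2[st:en] <- D[cbind(seq_len(en - st + 1L), w)]
  }
  list(idx = idx, dist = sqrt(d2))
}

# per-vertex match flags of path A against a list of paths (OR over the list)
.match_mask <- function(A, bearA, B_list, bearB_list,
                        buffer_m, max_dev_deg) {
  mask <- rep(FALSE, nrow(A))
  for (k in seq_along(B_list)) {
    B <- B_list[[k]]
    nv <- .nearest_vertex(A, B)
    ok <- nv$dist <= buffer_m &
      bearing_diff(bearA, bearB_list[[k]][nv$idx]) <= max_dev_deg
    mask <- mask | ok
  }
  mask
}

# restrict TRUE-runs of `mask` to those spanning >= min_overlap_m of arc length
.qualified_runs <- function(mask, s, min_overlap_m) {
  out <- rep(FALSE, length(mask))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- NULL
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (s[ends[i]] - s[starts[i]] >= min_overlap_m - 1e-9) {
      out[starts[i]:ends[i]] <- TRUE
      runs <- rbind(runs, c(starts[i], ends[i]))
    }
  }
  list(mask = out, runs = runs)
}

#' Shared sub-segments between two travel paths
#'
#' A vertex of `pathA` is matched when its nearest vertex on `pathB` lies
#' within `buffer_m` and the local travel bearings (computed over a centered
#' 10 m window, modulo 180 degrees) differ by at most `max_dev_deg`. Maximal
#' runs of matched vertices spanning at least `min_overlap_m` of arc length
#' are returned as shared segments (sub-polylines of `pathA`).
#'
#' @param pathA,pathB polylines resampled at <= 1 m ([resample_path()]).
#' @param buffer_m lateral tolerance (default 10 m).
#' @param min_overlap_m minimum shared arc length (default 15 m).
#' @param max_dev_deg maximum local bearing deviation (default 45 degrees).
#' @return List of shared segments, each a list with `xy` (vertex matrix),
#'   `from`, `to` (vertex indices into `pathA`) and `length_m`. The
#'   per-vertex match flags are attached as attribute `"mask"`.
#' @export
shared_segments <- function(pathA, pathB, buffer_m = 10, min_overlap_m = 15,
                            max_dev_deg = 45) {
  A <- .check_resampled(as_xy(pathA)); B <- .check_resampled(as_xy(pathB))
  attributes(A) <- attributes(pathA); attributes(B) <- attributes(pathB)
  sA <- attr(pathA, "s")
  if (is.null(sA)) sA <- c(0, cumsum(sqrt(diff(A[, 1])^2 + diff(A[, 2])^2)))
  bearA <- path_bearings(pathA)
  bearB <- path_bearings(pathB)
  mask <- .match_mask(A, bearA, list(B), list(bearB), buffer_m, max_dev_deg)
  qr <- .qualified_runs(mask, sA, min_overlap_m)
  segs <- list()
  if (!is.null(qr$runs)) {
    for (i in seq_len(nrow(qr$runs))) {
      a <- qr$runs[i, 1]; b <- qr$runs[i, 2]
      segs[[length(segs) + 1]] <-
        list(xy = A[a:b, , drop = FALSE], from = a, to = b,
             length_m = sA[b] - sA[a])
    }
  }
  attr(segs, "mask") <- qr$mask
  segs
}

# prepare a raw polyline for matching: 1 m resample + cached bearings
.prep_line <- function(xy) {
  r <- resample_path(xy, 1)
  list(xy = r, s = attr(r, "s"), bear = path_bearings(r))
}

#' Deduplicate daily paths within one sampling week
#'
#' Processes the week's daily paths in day order. Stretches of a later path
#' that match already-retained geometry (same buffer / overlap / bearing rules)
#' are collapsed onto the earlier day's geometry; unmatched stretches are kept
#' as new weekly-path lines. The result is the week's unique travel geometry.
#'
#' @param daily_lines list of polylines (one or more per day).
#' @param day_ids integer/character vector parallel to `daily_lines`.
#' @param week_ids optional parallel vector; supplying fixes from more than
#'   one week is an error.
#' @param buffer_m,min_overlap_m,max_dev_deg matching parameters.
#' @return List of weekly-path polylines (1 m resampled, bearings cached),
#'   each a list `xy`, `s`, `bear`.
#' @export
build_weekly_paths <- function(daily_lines, day_ids,
                               week_ids = NULL,
                               buffer_m = 10, min_overlap_m = 15,
                               max_dev_deg = 45) {
  if (!is.null(week_ids) && length(unique(week_ids)) > 1)
    stop("daily paths from multiple weeks supplied; deduplicate one week at a time")
  if (length(daily_lines) != length(day_ids))
    stop("day_ids must parallel daily_lines")
  ord <- order(day_ids)
  retained <- list()
  for (i in ord) {
    p <- .prep_line(daily_lines[[i]])
    if (!length(retained)) { retained[[1]] <- p; next }
    mask <- .match_mask(p$xy, p$bear, lapply(retained, `[[`, "xy"),
                        lapply(retained, `[[`, "bear"),
                        buffer_m, max_dev_deg)
    qmask <- .qualified_runs(mask, p$s, min_overlap_m)$mask
    # unmatched stretches become new weekly geometry
    r <- rle(!qmask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || ends[j] - starts[j] < 1) next
      seg <- p$xy[starts[j]:ends[j], , drop = FALSE]
      attr(seg, "s") <- p$s[starts[j]:ends[j]] - p$s[starts[j]]
      attr(seg, "step_m") <- 1
      retained[[length(retained) + 1]] <-
        list(xy = seg, s = attr(seg, "s"), bear = p$bear[starts[j]:ends[j]])
    }
  }
  retained
}

# running-average update of a segment's representative geometry: matched
# vertices move toward their nearest point on this week's geometry with
# weight 1/(k+1), k = weeks matched so far
.blend_geometry <- function(seg, qmask, wk_xy) {
  sel <- which(qmask)
  A <- seg$xy[sel, , drop = FALSE]
  bestd <- rep(Inf, length(sel))
  bestp <- A
  for (B in wk_xy) {
    nv <- .nearest_vertex(A, B)
    upd <- nv$dist < bestd
    bestd[upd] <- nv$dist[upd]
    bestp[upd, ] <- B[nv$idx[upd], , drop = FALSE]
  }
  k <- seg$weeks_used
  seg$xy[sel, ] <- (k * A + bestp) / (k + 1)
  seg$s <- c(0, cumsum(sqrt(diff(seg$xy[, 1])^2 + diff(seg$xy[, 2])^2)))
  attr(seg$xy, "s") <- seg$s
  seg$bear <- path_bearings(seg$xy)
  seg
}

# split segment vertex range into pieces alternating matched/unmatched;
# adjacent pieces share the boundary vertex so lengths are conserved
.split_pieces <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pieces <- list()
  for (i in seq_along(r$values)) {
    a <- if (i == 1) starts[i] else starts[i] - 1L
    b <- ends[i]
    if (b > a) pieces[[length(pieces) + 1]] <-
      list(from = a, to = b, matched = r$values[i])
  }
  pieces
}

#' Build a habitual route network from weekly paths
#'
#' Weeks are processed chronologically. Each week's paths are matched against
#' the accumulating network's representative geometry: matched stretches of
#' existing segments gain one week of use (once per week, however many of the
#' week's lines touch them), splitting segments where the matched region
#' starts or ends; unmatched stretches of the week's paths join the network
#' as new segments with one week of use.
#'
#' The representative geometry of a segment is, by default, the running
#' average of the weekly geometries matched onto it (`update_geometry =
#' "average"`): with GPS noise on every fix, the average of k matched weeks
#' estimates the true route with SD shrinking as `1/sqrt(k)`, so later weeks
#' are matched against progressively cleaner geometry. Set
#' `update_geometry = "keep"` to freeze the earliest week's geometry instead.
#'
#' @param weekly_paths named list (one element per week, chronological order);
#'   each element is the output of [build_weekly_paths()] or a plain list of
#'   polylines.
#' @param group_id label stored on the network.
#' @param buffer_m,min_overlap_m,max_dev_deg matching parameters.
#' @param habitual_threshold weeks of use for a segment to count as habitual
#'   (default 2).
#' @param update_geometry `"average"` (default) or `"keep"` (see above).
#' @return Object of class `"route_network"`: `segments` (list of `xy`,
#'   `bear`, `weeks_used`), `group_id`, `n_weeks`, `habitual_threshold`.
#' @export
build_route_network <- function(weekly_paths, group_id = "G1",
                                buffer_m = 10, min_overlap_m = 15,
                                max_dev_deg = 45, habitual_threshold = 2,
                                update_geometry = c("average", "keep")) {
  update_geometry <- match.arg(update_geometry)
  if (!length(weekly_paths)) stop("need at least one week of paths")
  segments <- list()
  for (w in seq_along(weekly_paths)) {
    wk <- weekly_paths[[w]]
    wk <- lapply(wk, function(l) if (is.list(l) && !is.null(l$xy)) l else .prep_line(l))
    wk <- Filter(function(l) nrow(l$xy) >= 2, wk)
    if (!length(wk)) next
    wk_xy <- lapply(wk, `[[`, "xy"); wk_bear <- lapply(wk, `[[`, "bear")
    if (!length(segments)) {
      for (l in wk) segments[[length(segments) + 1]] <-
        list(xy = l$xy, s = l$s, bear = l$bear, weeks_used = 1L)
      next
    }
    net_xy <- lapply(segments, `[[`, "xy")
    net_bear <- lapply(segments, `[[`, "bear")
    # 1) count this week on matched stretches of existing segments
    new_segments <- list()
    for (seg in segments) {
      mask <- .match_mask(seg$xy, seg$bear, wk_xy, wk_bear,
                          buffer_m, max_dev_deg)
      # the overlap rule concerns path overlap, not partition bookkeeping:
      # a short segment wholly covered by a matched stretch still counts
      ovl <- min(min_overlap_m, max(seg$s) - min(seg$s))
      qmask <- .qualified_runs(mask, seg$s, ovl)$mask
      if (any(qmask) && update_geometry == "average")
        seg <- .blend_geometry(seg, qmask, wk_xy)
      if (!any(qmask)) {
        new_segments[[length(new_segments) + 1]] <- seg
      } else if (all(qmask)) {
        seg$weeks_used <- seg$weeks_used + 1L
        new_segments[[length(new_segments) + 1]] <- seg
      } else {
        for (pc in .split_pieces(qmask)) {
          piece <- list(
            xy = seg$xy[pc$from:pc$to, , drop = FALSE],
            s = seg$s[pc$from:pc$to] - seg$s[pc$from],
            bear = seg$bear[pc$from:pc$to],
            weeks_used = seg$weeks_used + as.integer(pc$matched))
          new_segments[[length(new_segments) + 1]] <- piece
        }
      }
    }
    segments <- new_segments
    # 2) add this week's unmatched geometry as new segments
    for (l in wk) {
      mask <- .match_mask(l$xy, l$bear, net_xy, net_bear,
                          buffer_m, max_dev_deg)
      qmask <- .qualified_runs(mask, l$s, min_overlap_m)$mask
      r <- rle(!qmask)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in seq_along(r$values)) {
        if (!r$values[j] || ends[j] - starts[j] < 1) next
        segments[[length(segments) + 1]] <- list(
          xy = l$xy[starts[j]:ends[j], , drop = FALSE],
          s = l$s[starts[j]:ends[j]] - l$s[starts[j]],
          bear = l$bear[starts[j]:ends[j]],
          weeks_used = 1L)
      }
    }
  }
  net <- list(group_id = group_id, segments = segments,
              n_weeks = length(weekly_paths),
              habitual_threshold = habitual_threshold,
              buffer_m = buffer_m, min_overlap_m = min_overlap_m,
              max_dev_deg = max_dev_deg)
  class(net) <- "route_network"
  net
}

#' @export
print.route_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<route_network> group %s: %d segments, %.0f m total, %.0f m habitual (>= %d weeks)\n",
              x$group_id, length(x$segments), s$total_m, s$habitual_m,
              x$habitual_threshold))
  invisible(x)
}

#' Segment lengths and usage table of a network
#'
#' @param network a `"route_network"`.
#' @return data.frame `segment_id`, `weeks_used`, `length_m`.
#' @export
network_segments <- function(network) {
  if (!length(network$segments))
    return(data.frame(segment_id = integer(0), weeks_used = integer(0),
                      length_m = numeric(0)))
  data.frame(
    segment_id = seq_along(network$segments),
    weeks_used = vapply(network$segments, `[[`, 0L, "weeks_used"),
    length_m = vapply(network$segments, function(s) max(s$s) - min(s$s), 0))
}

#' Total and habitual length of a network
#'
#' @param network a `"route_network"`.
#' @param min_weeks habitual threshold (defaults to the network's).
#' @return One-row data.frame `group_id`, `total_m`, `habitual_m`, `n_segments`.
#' @export
network_summary <- function(network, min_weeks = network$habitual_threshold) {
  tab <- network_segments(network)
  data.frame(group_id = network$group_id,
             total_m = sum(tab$length_m),
             habitual_m = sum(tab$length_m[tab$weeks_used >= min_weeks]),
             n_segments = nrow(tab))
}

#' Habitual subset of a network's segments
#'
#' @param network a `"route_network"`.
#' @param min_weeks usage threshold (defaults to the network's).
#' @return List of segments (same structure as `network$segments`).
#' @export
habitual_segments <- function(network, min_weeks = network$habitual_threshold) {
  Filter(function(s) s$weeks_used >= min_weeks, network$segments)
}

#' Fraction of travel bouts that fall within the habitual network
#'
#' A bout counts as "within" the network when at least `frac_threshold` of
#' its vertices (1 m resampled) match a habitual segment under the same
#' buffer-and-bearing rule used for network construction.
#'
#' @param bout_lines list of bout polylines.
#' @param network a `"route_network"`.
#' @param min_weeks habitual threshold.
#' @param frac_threshold fraction of bout length required (default 0.5).
#' @return Fraction of bouts within the network; per-bout fractions are
#'   attached as attribute `"bout_fraction"`.
#' @export
network_coverage <- function(bout_lines, network,
                             min_weeks = network$habitual_threshold,
                             frac_threshold = 0.5) {
  hab <- habitual_segments(network, min_weeks)
  if (!length(hab) || !length(bout_lines)) {
    res <- 0
    attr(res, "bout_fraction") <- rep(0, length(bout_lines))
    return(res)
  }
  hxy <- lapply(hab, `[[`, "xy"); hbear <- lapply(hab, `[[`, "bear")
  fr <- vapply(bout_lines, function(b) {
    p <- .prep_line(b)
    m <- .match_mask(p$xy, p$bear, hxy, hbear,
                     network$buffer_m, network$max_dev_deg)
    mean(m)
  }, 0)
  res <- mean(fr >= frac_threshold)
  attr(res, "bout_fraction") <- fr
  res
}

#' Split a track table into bout polylines and weekly day groups
#'
#' @param tracks data.frame with columns `group_id, week_id, day_id, bout_id,
#'   fix_idx, x, y` and optionally `rec_type` (only `"travel"` rows are used).
#' @return List with `lines` (list of bout vertex matrices) and `info`
#'   (data.frame `group_id`, `week_id`, `day_id`, `bout_id`).
#' @export
tracks_to_bouts <- function(tracks) {
  if ("rec_type" %in% names(tracks)) tracks <- tracks[tracks$rec_type == "travel", ]
  need <- c("group_id", "week_id", "day_id", "bout_id", "fix_idx", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stop("tracks missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(tracks$group_id, tracks$bout_id, drop = TRUE)
  lines <- list(); info <- list()
  for (lev in levels(key)) {
    sub <- tracks[key == lev, ]
    sub <- sub[order(sub$fix_idx), ]
    if (nrow(sub) < 2) next
    lines[[length(lines) + 1]] <- cbind(x = sub$x, y = sub$y)
    info[[length(info) + 1]] <- sub[1, c("group_id", "week_id", "day_id", "bout_id")]
  }
  list(lines = lines, info = do.call(rbind, info))
}

#' Build one group's route network from a track table
#'
#' Convenience wrapper: splits travel fixes into bouts, deduplicates within
#' weeks, and overlays weeks chronologically.
#'
#' @param tracks track table for a single group (see [tracks_to_bouts()]).
#' @param buffer_m,min_overlap_m,max_dev_deg,habitual_threshold matching
#'   parameters (defaults 10 m / 15 m / 45 degrees / 2 weeks).
#' @return A `"route_network"`.
#' @export
build_group_network <- function(tracks, buffer_m = 10, min_overlap_m = 15,
                                max_dev_deg = 45, habitual_threshold = 2) {
  bb <- tracks_to_bouts(tracks)
  if (!length(bb$lines)) stop("no travel bouts in tracks")
  gid <- as.character(bb$info$group_id[1])
  if (length(unique(bb$info$group_id)) > 1)
    stop("build_group_network expects a single group")
  weeks <- sort(unique(bb$info$week_id))
  weekly <- lapply(weeks, function(w) {
    sel <- bb$info$week_id == w
    build_weekly_paths(bb$lines[sel], bb$info$day_id[sel],
                       buffer_m = buffer_m, min_overlap_m = min_overlap_m,
                       max_dev_deg = max_dev_deg)
  })
  names(weekly) <- weeks
  build_route_network(weekly, group_id = gid, buffer_m = buffer_m,
                      min_overlap_m = min_overlap_m, max_dev_deg = max_dev_deg,
                      habitual_threshold = habitual_threshold)
}

#' Write a network as GeoJSON LineStrings
#'
#' @param network a `"route_network"`.
#' @param path output file.
#' @export
write_network_geojson <- function(network, path) {
  tab <- network_segments(network)
  tab$group_id <- network$group_id
  write_lines_geojson(lapply(network$segments, `[[`, "xy"), path,
                      properties = tab[, c("group_id", "weeks_used", "length_m")])
  invisible(path)
}
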