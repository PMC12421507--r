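# Per-cell EV uptake quantification: select a fixed subset of tracked cells,
# split EVs into internal/external per cell mask, and tabulate the
# nuclei-normalized EV count and the EV area coverage per time point.

#' Select a fixed subset of cells to track through a time-lapse
#'
#' The `n` largest cells of the first frame are kept when a counterpart
#' (nearest cell centroid within `match_radius`) exists in every frame;
#' tracks that cannot be matched in some frame are dropped with a warning.
#'
#' @param results list of `segmentation_result`, one per frame.
#' @param n number of cells to track.
#' @param match_radius maximum centroid displacement in pixels between
#'   frames.
#' @return An object of class `tracked_cells`: `track_ids` and an
#'   `n_frames x n_tracks` integer matrix `labels` mapping each track to its
#'   cell label per frame.
#' @export
select_tracked_cells <- function(results, n, match_radius = 15) {
  stopifnot(length(results) >= 1L, n >= 0L)
  first <- results[[1]]$cells
  ids <- sort(unique(first[first > 0]))
  if (n == 0L || length(ids) == 0L) {
    return(structure(list(track_ids = integer(0),
                          labels = matrix(integer(0), length(results), 0)),
                     class = "tracked_cells"))
  }
  areas <- vapply(ids, function(k) sum(first == k), integer(1))
  cand <- ids[order(-areas, ids)]
  if (n > length(cand)) {
    warning(sprintf(
      "requested %d tracks but only %d cells in the first frame", n,
      length(cand)
    ))
  }
  cand <- head(cand, n)
  cents0 <- label_centroids(first)
  labels <- matrix(0L, length(results), length(cand))
  labels[1, ] <- cand
  keep <- rep(TRUE, length(cand))
  for (f in seq_along(results)[-1]) {
    cf <- label_centroids(results[[f]]$cells)
    for (q in seq_along(cand)) {
      if (!keep[q]) next
      c0 <- cents0[as.character(cand[q]), ]
      if (nrow(cf) == 0L) {
        keep[q] <- FALSE
        next
      }
      dd <- sqrt((cf[, 1] - c0[1])^2 + (cf[, 2] - c0[2])^2)
      j <- which.min(dd)
      if (dd[j] <= match_radius) {
        labels[f, q] <- as.integer(rownames(cf)[j])
      } else {
        keep[q] <- FALSE
      }
    }
  }
  if (any(!keep)) {
    warning(sprintf("dropped %d track(s) that could not be matched in every frame",
                    sum(!keep)))
  }
  structure(
    list(track_ids = seq_len(sum(keep)),
         labels = labels[, keep, drop = FALSE]),
    class = "tracked_cells"
  )
}

#' Split EV instances into internal and external sets for one cell mask
#'
#' An EV is internal when at least 50% of its pixels lie inside the cell
#' mask; the partition is exhaustive and disjoint.
#'
#' @param evs integer EV instance label matrix.
#' @param cell_mask logical matrix of the same shape.
#' @return List with integer vectors `internal` and `external` of EV ids.
#' @export
split_internal_external <- function(evs, cell_mask) {
  stopifnot(identical(dim(evs), dim(cell_mask)))
  ids <- sort(unique(evs[evs > 0]))
  internal <- logical(length(ids))
  for (q in seq_along(ids)) {
    m <- evs == ids[q]
    internal[q] <- sum(m & cell_mask) >= 0.5 * sum(m)
  }
  list(internal = ids[internal], external = ids[!internal])
}

#' Count nuclei whose centroid lies inside a cell mask
#'
#' @param nuclei integer nucleus instance label matrix.
#' @param cell_mask logical matrix of the same shape.
#' @return Integer count.
#' @export
count_nuclei_in_cell <- function(nuclei, cell_mask) {
  stopifnot(identical(dim(nuclei), dim(cell_mask)))
  cents <- label_centroids(nuclei)
  if (nrow(cents) == 0L) return(0L)
  ri <- round(cents[, "row"]); ci <- round(cents[, "col"])
  sum(vapply(seq_len(nrow(cents)), function(q)
    cell_mask[ri[q], ci[q]], logical(1)))
}

# Assign each internal-capable EV to one tracked cell: largest pixel
# overlap, requiring >= 50% of the EV inside that cell; ties to the lower
# track id. Returns per-track lists of EV ids and clipped areas.
assign_evs_to_tracks <- function(evs, cell_masks) {
  ids <- sort(unique(evs[evs > 0]))
  n_tracks <- length(cell_masks)
  out <- replicate(n_tracks, list(ids = integer(0), area = 0L),
                   simplify = FALSE)
  for (k in ids) {
    m <- evs == k
    ov <- vapply(cell_masks, function(cm) sum(m & cm), integer(1))
    if (n_tracks == 0L || max(ov) < 0.5 * sum(m)) next
    best <- which.max(ov)  # first maximum = lowest track id
    out[[best]]$ids <- c(out[[best]]$ids, k)
    out[[best]]$area <- out[[best]]$area + ov[best]
  }
  out
}

#' Quantify EV uptake for one segmented frame
#'
#' Per tracked cell: the internal EV count (majority-overlap rule, each EV
#' credited to at most one cell), the count normalized by the number of
#' nuclei in the cell mask (`max(n_nuclei, 1)` guards anucleate
#' segmentations), and the internal EV area clipped to the cell mask as a
#' percentage of the cell area.
#'
#' @param result a `segmentation_result` (or any list with `cells`,
#'   `nuclei`, `evs` label images).
#' @param tracks a `tracked_cells` object.
#' @param time acquisition time in minutes.
#' @param frame_index row of `tracks$labels` to use (default 1).
#' @return Data frame with one row per resolvable track: `time_min`,
#'   `track_id`, `internal_ev_count`, `n_nuclei`, `evs_per_cell`,
#'   `cell_area_px`, `internal_ev_area_px`, `coverage_percent`.
#' @export
quantify_frame <- function(result, tracks, time, frame_index = 1L) {
  stopifnot(inherits(tracks, "tracked_cells"))
  n_tracks <- length(tracks$track_ids)
  empty <- data.frame(
    time_min = numeric(0), track_id = integer(0),
    internal_ev_count = integer(0), n_nuclei = integer(0),
    evs_per_cell = numeric(0), cell_area_px = integer(0),
    internal_ev_area_px = integer(0), coverage_percent = numeric(0)
  )
  if (n_tracks == 0L) return(empty)
  labs <- tracks$labels[frame_index, ]
  resolvable <- labs > 0 &
    vapply(labs, function(l) l > 0 && any(result$cells == l), logical(1))
  if (any(!resolvable)) {
    warning(sprintf("omitting %d unresolvable track(s) at t = %g",
                    sum(!resolvable), time))
  }
  sel <- which(resolvable)
  if (length(sel) == 0L) return(empty)
  cell_masks <- lapply(labs[sel], function(l) result$cells == l)
  assign <- assign_evs_to_tracks(result$evs, cell_masks)
  rows <- lapply(seq_along(sel), function(q) {
    cm <- cell_masks[[q]]
    n_nuc <- count_nuclei_in_cell(result$nuclei, cm)
    n_ev <- length(assign[[q]]$ids)
    area <- sum(cm)
    ev_area <- assign[[q]]$area
    data.frame(
      time_min = time, track_id = tracks$track_ids[sel[q]],
      internal_ev_count = n_ev, n_nuclei = n_nuc,
      evs_per_cell = n_ev / max(n_nuc, 1L),
      cell_area_px = area, internal_ev_area_px = as.integer(ev_area),
      coverage_percent = 100 * ev_area / area
    )
  })
  do.call(rbind, rows)
}

#' Quantify EV uptake over a whole time-lapse
#'
#' @param results list of `segmentation_result`, one per schedule entry.
#' @param tracks a `tracked_cells` object.
#' @param schedule acquisition times in minutes (one per result).
#' @return An uptake table: the row-bound [quantify_frame()] outputs sorted
#'   by `(time_min, track_id)`.
#' @export
quantify_timelapse <- function(results, tracks, schedule) {
  if (length(results) != length(schedule)) {
    stop("one segmentation result is required per schedule entry")
  }
  rows <- lapply(seq_along(results), function(f) {
    quantify_frame(results[[f]], tracks, schedule[f], frame_index = f)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(out)
  out <- out[order(out$time_min, out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
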