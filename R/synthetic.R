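# Synthetic fluorescence-microscopy generator with exact instance ground
# truth. Scenes emulate adherent cells stained on three channels: nuclei
# (Hoechst-like, plane 1), EV puncta (DiD-like, plane 2) and a membrane/merge
# channel (WGA-like, plane 3) in which cell bodies appear with dim interiors
# and partially broken ("sparse") borders. All randomness flows from a single
# integer seed.

#' Parameters of a synthetic fluorescence scene
#'
#' @param image_size integer `(H, W)` in pixels.
#' @param n_cells number of cells.
#' @param n_nuclei_per_cell integer `(min, max)`; each cell draws its nucleus
#'   count uniformly from this range (cells with >1 nucleus emulate cell
#'   clusters segmented as one body).
#' @param n_evs_internal number of EV puncta placed inside cells.
#' @param n_evs_external number of EV puncta placed wholly outside all cells.
#' @param cell_radius `(mean, sd)` of the cell radius in pixels.
#' @param ev_radius `(mean, sd)` of the EV punctum radius in pixels.
#' @param border_gap_fraction fraction in `[0, 1]` of each cell perimeter
#'   rendered without the bright membrane rim (sparse cell borders).
#' @param blur_sigma Gaussian blur sigma in pixels applied to every plane.
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   a.u. on the `[0, 1]` scale).
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   scenes.
#'
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(image_size = c(128L, 128L),
                         n_cells = 5L,
                         n_nuclei_per_cell = c(1L, 2L),
                         n_evs_internal = 8L,
                         n_evs_external = 5L,
                         cell_radius = c(14, 2),
                         ev_radius = c(2, 0.3),
                         border_gap_fraction = 0.3,
                         blur_sigma = 1,
                         noise_sd = 0.02,
                         seed = 1L) {
  p <- list(
    image_size = as.integer(image_size),
    n_cells = as.integer(n_cells),
    n_nuclei_per_cell = as.integer(n_nuclei_per_cell),
    n_evs_internal = as.integer(n_evs_internal),
    n_evs_external = as.integer(n_evs_external),
    cell_radius = as.numeric(cell_radius),
    ev_radius = as.numeric(ev_radius),
    border_gap_fraction = as.numeric(border_gap_fraction),
    blur_sigma = as.numeric(blur_sigma),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  stopifnot(
    length(p$image_size) == 2L, all(p$image_size >= 8L),
    p$n_cells >= 0L, p$n_evs_internal >= 0L, p$n_evs_external >= 0L,
    length(p$n_nuclei_per_cell) == 2L, all(p$n_nuclei_per_cell >= 0L),
    p$n_nuclei_per_cell[1] <= p$n_nuclei_per_cell[2],
    p$cell_radius[1] > 0, p$ev_radius[1] > 0,
    p$border_gap_fraction >= 0, p$border_gap_fraction <= 1,
    p$blur_sigma >= 0, p$noise_sd >= 0
  )
  class(p) <- "scene_params"
  p
}

#' Parameter presets for the four simulated imaging conditions
#'
#' Four scene families mirroring the spread of the real experiments: they
#' vary cell count, EV load (about 5-10 puncta per scene), noise level and
#' membrane-border sparsity. Six scenes per condition form the standard
#' training fixture; further seeds give held-out scenes.
#'
#' @param condition integer 1-4.
#' @param seed integer scene seed.
#' @param image_size integer `(H, W)`; the study fixtures use 96 x 96.
#' @return A [scene_params()] object.
#' @export
condition_params <- function(condition, seed, image_size = c(96L, 96L)) {
  stopifnot(condition %in% 1:4)
  base <- list(
    list(n_cells = 3L, n_evs_internal = 5L, n_evs_external = 3L,
         noise_sd = 0.01, border_gap_fraction = 0.3),
    list(n_cells = 3L, n_evs_internal = 10L, n_evs_external = 5L,
         noise_sd = 0.02, border_gap_fraction = 0.3),
    list(n_cells = 2L, n_evs_internal = 5L, n_evs_external = 5L,
         noise_sd = 0.03, border_gap_fraction = 0.4),
    list(n_cells = 3L, n_evs_internal = 8L, n_evs_external = 4L,
         noise_sd = 0.02, border_gap_fraction = 0.2)
  )[[condition]]
  do.call(scene_params, c(base, list(
    image_size = image_size, cell_radius = c(12, 1.5),
    n_nuclei_per_cell = c(1L, 2L), seed = seed
  )))
}

#' Construct a multi-channel acquisition frame
#'
#' @param nuclei_plane,ev_plane,merge_plane non-negative intensity matrices of
#'   identical shape.
#' @param time acquisition time in minutes since EV administration.
#' @return An object of class `multichannel_frame`.
#' @export
multichannel_frame <- function(nuclei_plane, ev_plane, merge_plane, time = 0) {
  stopifnot(
    is.matrix(nuclei_plane), is.matrix(ev_plane), is.matrix(merge_plane),
    identical(dim(nuclei_plane), dim(ev_plane)),
    identical(dim(nuclei_plane), dim(merge_plane)),
    all(is.finite(nuclei_plane)), all(is.finite(ev_plane)),
    all(is.finite(merge_plane)),
    all(nuclei_plane >= 0), all(ev_plane >= 0), all(merge_plane >= 0),
    is.numeric(time), length(time) == 1L
  )
  structure(
    list(
      nuclei_plane = nuclei_plane, ev_plane = ev_plane,
      merge_plane = merge_plane, time = as.numeric(time)
    ),
    class = "multichannel_frame"
  )
}

#' @export
print.multichannel_frame <- function(x, ...) {
  cat(sprintf(
    "<multichannel_frame %dx%d, t = %g min>\n",
    nrow(x$nuclei_plane), ncol(x$nuclei_plane), x$time
  ))
  invisible(x)
}

#' Default time-lapse acquisition schedule
#'
#' Acquisitions start 30 min after EV administration, every 5 min up to
#' 1 h, then every 10 min up to 4 h.
#'
#' @return Numeric vector of acquisition times in minutes.
#' @export
default_schedule <- function() c(seq(30, 60, by = 5), seq(70, 240, by = 10))

# ---------------------------------------------------------------------------
# Geometry helpers (all consume the active RNG stream).

# Rasterize a smoothed star-convex blob: radius(theta) = R * (1 + sum_k a_k
# cos(k theta + phi_k)), k = 2..4, with mild amplitudes so that erosions of
# the shape stay connected. Returns a logical matrix over the full image.
raster_blob <- function(H, W, cy, cx, R, wobble = 0.08) {
  a <- runif(3, 0, wobble)
  ph <- runif(3, 0, 2 * pi)
  r0 <- ceiling(R * (1 + sum(a)) + 1)
  rmin <- max(1L, floor(cy - r0)); rmax <- min(H, ceiling(cy + r0))
  cmin <- max(1L, floor(cx - r0)); cmax <- min(W, ceiling(cx + r0))
  if (rmin > rmax || cmin > cmax) {
    return(matrix(FALSE, H, W))
  }
  ii <- rmin:rmax; jj <- cmin:cmax
  dy <- outer(ii - cy, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - cx)
  th <- atan2(dy, dx)
  rad <- R * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                a[3] * cos(4 * th + ph[3]))
  sub <- sqrt(dy^2 + dx^2) <= rad
  out <- matrix(FALSE, H, W)
  out[ii, jj] <- sub
  out
}

place_error <- function(what, k, n) {
  stop(sprintf(
    "could not place %s %d of %d without violating placement constraints; the scene is too crowded for the requested counts",
    what, k, n
  ), call. = FALSE)
}

# Place n cells as non-touching star-convex blobs. Cells keep a clearance of
# several pixels from each other and from the image border so that instances
# are unambiguous and fusion's closing cannot bridge neighbours.
place_cells <- function(H, W, n, rmean, rsd, max_attempts = 400L) {
  lab <- matrix(0L, H, W)
  info <- vector("list", n)
  if (n == 0L) return(list(labels = lab, info = info))
  clearance <- disc_brush(3L)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      R <- max(4, rnorm(1, rmean, rsd))
      margin <- R * 1.12 + 3
      if (2 * margin >= min(H, W)) next
      cy <- runif(1, margin, H - margin)
      cx <- runif(1, margin, W - margin)
      m <- raster_blob(H, W, cy, cx, R)
      if (sum(m) < 12) next
      grown <- EBImage::dilate(m + 0, clearance) > 0
      if (any(grown & (lab > 0))) next
      lab[m] <- k
      info[[k]] <- list(cy = cy, cx = cx, R = R)
      placed <- TRUE
      break
    }
    if (!placed) place_error("cell", k, n)
  }
  list(labels = lab, info = info)
}

# Place nuclei fully inside their parent cells, non-touching.
place_nuclei <- function(cells, cell_info, nrange, max_attempts = 400L) {
  H <- nrow(cells); W <- ncol(cells)
  lab <- matrix(0L, H, W)
  n_cells <- length(cell_info)
  counts <- integer(n_cells)
  if (n_cells == 0L) return(list(labels = lab, counts = counts))
  next_id <- 0L
  gap <- disc_brush(1L)
  for (k in seq_len(n_cells)) {
    nk <- if (nrange[1] == nrange[2]) nrange[1] else
      sample(seq(nrange[1], nrange[2]), 1L)
    counts[k] <- nk
    ci <- cell_info[[k]]
    cell_mask <- cells == k
    for (q in seq_len(nk)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        nr <- ci$R * runif(1, 0.22, 0.30) / sqrt(nk)
        off <- ci$R * runif(1, 0, 0.55)
        ang <- runif(1, 0, 2 * pi)
        m <- raster_blob(H, W, ci$cy + off * sin(ang), ci$cx + off * cos(ang),
                         nr, wobble = 0.05)
        if (sum(m) < 4) next
        if (any(m & !cell_mask)) next            # must sit wholly in the cell
        grown <- EBImage::dilate(m + 0, gap) > 0
        if (any(grown & (lab > 0))) next         # keep nuclei separated
        next_id <- next_id + 1L
        lab[m] <- next_id
        placed <- TRUE
        break
      }
      if (!placed) place_error("nucleus", q, nk)
    }
  }
  list(labels = lab, counts = counts)
}

disc_mask_at <- function(H, W, cy, cx, r) {
  r0 <- ceiling(r + 1)
  rmin <- max(1L, floor(cy - r0)); rmax <- min(H, ceiling(cy + r0))
  cmin <- max(1L, floor(cx - r0)); cmax <- min(W, ceiling(cx + r0))
  if (rmin > rmax || cmin > cmax) return(matrix(FALSE, H, W))
  ii <- rmin:rmax; jj <- cmin:cmax
  dy <- outer(ii - cy, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - cx)
  out <- matrix(FALSE, H, W)
  out[ii, jj] <- (dy^2 + dx^2) <= r^2
  out
}

# Draw one EV punctum mask honouring separation from other EVs and nuclei.
# `region = "internal"` requires the punctum wholly inside some cell (and off
# nuclei); `"external"` requires zero contact with any cell.
place_one_ev <- function(cells, nuclei, ev_lab, evr, region,
                         max_attempts = 600L) {
  H <- nrow(cells); W <- ncol(cells)
  gap <- disc_brush(1L)
  cell_ids <- sort(unique(cells[cells > 0]))
  for (a in seq_len(max_attempts)) {
    r <- max(1.2, rnorm(1, evr[1], evr[2]))
    if (region == "internal") {
      if (length(cell_ids) == 0L) break
      k <- if (length(cell_ids) == 1L) cell_ids else sample(cell_ids, 1L)
      w <- which(cells == k, arr.ind = TRUE)
      p <- w[sample.int(nrow(w), 1L), ]
      m <- disc_mask_at(H, W, p[1], p[2], r)
      if (!any(m)) next
      if (any(m & (cells != k))) next
      if (any(m & !(cells == k))) next
      if (any(m & (nuclei > 0))) next
    } else {
      cy <- runif(1, r + 2, H - r - 1)
      cx <- runif(1, r + 2, W - r - 1)
      m <- disc_mask_at(H, W, cy, cx, r)
      if (!any(m)) next
      if (any((EBImage::dilate(m + 0, gap) > 0) & (cells > 0))) next
    }
    grown <- EBImage::dilate(m + 0, gap) > 0
    if (any(grown & (ev_lab > 0))) next
    return(m)
  }
  NULL
}

# ---------------------------------------------------------------------------
# Rendering.

# Perimeter angles that fall into randomly drawn arcs totalling
# `gap_fraction` of the circle are suppressed (dim membrane).
draw_gap_arcs <- function(gap_fraction) {
  if (gap_fraction <= 0) return(matrix(numeric(0), 0, 2))
  n_arcs <- sample(1:3, 1L)
  widths <- runif(n_arcs)
  widths <- widths / sum(widths) * gap_fraction * 2 * pi
  starts <- runif(n_arcs, 0, 2 * pi)
  cbind(starts, starts + widths)
}

angle_in_arcs <- function(theta, arcs) {
  if (nrow(arcs) == 0L) return(rep(FALSE, length(theta)))
  th <- theta %% (2 * pi)
  hit <- rep(FALSE, length(th))
  for (i in seq_len(nrow(arcs))) {
    a <- arcs[i, 1] %% (2 * pi)
    b <- a + (arcs[i, 2] - arcs[i, 1])
    hit <- hit | (th >= a & th <= b) | (th + 2 * pi >= a & th + 2 * pi <= b)
  }
  hit
}

# Per-structure intensities are drawn once (with the geometry) so that a
# time-lapse keeps constant brightness per object; per-frame noise is drawn
# at render time.
draw_intensities <- function(n_cells, n_nuclei, n_evs) {
  list(
    cell_interior = runif(max(n_cells, 0), 0.20, 0.30),
    cell_border = runif(max(n_cells, 0), 0.70, 0.85),
    nucleus = runif(max(n_nuclei, 0), 0.70, 0.95),
    ev = runif(max(n_evs, 0), 0.80, 1.00)
  )
}

# Render the three planes from label images; deterministic given the drawn
# intensities and gap arcs. Noise is consumed from the active RNG stream.
render_planes <- function(cells, nuclei, evs, cell_info, inten, gap_arcs,
                          params) {
  H <- nrow(cells); W <- ncol(cells)
  nuc_plane <- matrix(0, H, W)
  ids <- sort(unique(nuclei[nuclei > 0]))
  for (k in ids) nuc_plane[nuclei == k] <- inten$nucleus[k]
  ev_plane <- matrix(0, H, W)
  ids <- sort(unique(evs[evs > 0]))
  for (k in ids) ev_plane[evs == k] <- inten$ev[k]
  cell_plane <- matrix(0, H, W)
  ids <- sort(unique(cells[cells > 0]))
  rim_brush <- disc_brush(2L)
  for (k in ids) {
    m <- cells == k
    cell_plane[m] <- inten$cell_interior[k]
    rim <- m & !(EBImage::erode(m + 0, rim_brush) > 0)
    if (any(rim)) {
      w <- which(rim, arr.ind = TRUE)
      th <- atan2(w[, 1] - cell_info[[k]]$cy, w[, 2] - cell_info[[k]]$cx)
      keep <- !angle_in_arcs(th, gap_arcs[[k]])
      cell_plane[rim][keep] <- inten$cell_border[k]
    }
  }
  merge_plane <- pmax(cell_plane, 0.40 * nuc_plane, 0.60 * ev_plane)
  finish <- function(pl) {
    if (params$blur_sigma > 0) {
      pl <- as.matrix(EBImage::gblur(pl, sigma = params$blur_sigma))
    }
    if (params$noise_sd > 0) pl <- pl + rnorm(length(pl), 0, params$noise_sd)
    # clamp and quantize to the 16-bit camera grid so TIFF round-trips are
    # bit-exact
    round(clamp(pl, 0, 1) * 65535) / 65535
  }
  list(
    nuclei = finish(nuc_plane), ev = finish(ev_plane),
    merge = finish(merge_plane)
  )
}

# ---------------------------------------------------------------------------
# Truth bookkeeping.

# Internal/external flag per EV: >= 50% of the punctum's pixels inside the
# union of cell bodies.
ev_internal_flags <- function(evs, cells) {
  ids <- sort(unique(evs[evs > 0]))
  union_mask <- cells > 0
  vapply(ids, function(k) {
    m <- evs == k
    sum(m & union_mask) >= 0.5 * sum(m)
  }, logical(1))
}

# Per-cell truth table using the same conventions as the quantifier: a
# nucleus belongs to the cell containing its centroid; an EV is credited to
# the cell with the largest pixel overlap provided that overlap is >= 50% of
# the EV area (ties to the lower cell id); its area contribution is clipped
# to the cell mask.
compute_per_cell_truth <- function(cells, nuclei, evs) {
  cell_ids <- sort(unique(cells[cells > 0]))
  n_nuc <- integer(length(cell_ids))
  cent <- label_centroids(nuclei)
  if (nrow(cent) > 0) {
    ri <- round(cent[, "row"]); ci <- round(cent[, "col"])
    for (q in seq_len(nrow(cent))) {
      lab <- cells[ri[q], ci[q]]
      if (lab > 0) {
        idx <- match(lab, cell_ids)
        n_nuc[idx] <- n_nuc[idx] + 1L
      }
    }
  }
  n_int <- integer(length(cell_ids))
  area_int <- integer(length(cell_ids))
  ev_ids <- sort(unique(evs[evs > 0]))
  for (k in ev_ids) {
    m <- evs == k
    ov <- vapply(cell_ids, function(cc) sum(m & (cells == cc)), integer(1))
    if (length(ov) == 0L || max(ov) < 0.5 * sum(m)) next
    best <- cell_ids[which.max(ov)]   # which.max takes the first (lowest id)
    idx <- match(best, cell_ids)
    n_int[idx] <- n_int[idx] + 1L
    area_int[idx] <- area_int[idx] + max(ov)
  }
  data.frame(
    cell = cell_ids, n_nuclei = n_nuc, n_internal_evs = n_int,
    internal_ev_area = area_int
  )
}

make_scene_truth <- function(cells, nuclei, evs) {
  structure(
    list(
      cells = cells, nuclei = nuclei, evs = evs,
      ev_internal_flags = ev_internal_flags(evs, cells),
      per_cell_truth = compute_per_cell_truth(cells, nuclei, evs)
    ),
    class = "scene_truth"
  )
}

# ---------------------------------------------------------------------------

#' Generate one synthetic fluorescence scene with exact ground truth
#'
#' Cells are smoothed star-convex blobs with nuclei wholly inside them;
#' internal EV puncta are placed inside cell bodies (off nuclei), external
#' ones wholly outside all cells. Planes are blurred, corrupted with additive
#' Gaussian noise, clipped at zero and quantized to a 16-bit grid.
#'
#' @param params a [scene_params()] object.
#' @return A list with elements `frame` (a [multichannel_frame()]) and
#'   `truth` (a `scene_truth`: instance label images `cells`, `nuclei`,
#'   `evs`, per-EV `ev_internal_flags`, and a `per_cell_truth` data frame).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_local_seed(params$seed, {
    geo <- draw_scene_geometry(params)
    inten <- draw_intensities(
      params$n_cells, max(geo$nuclei), max(geo$evs)
    )
    gap_arcs <- lapply(seq_len(params$n_cells), function(k)
      draw_gap_arcs(params$border_gap_fraction))
    planes <- render_planes(geo$cells, geo$nuclei, geo$evs, geo$cell_info,
                            inten, gap_arcs, params)
    list(
      frame = multichannel_frame(planes$nuclei, planes$ev, planes$merge, 0),
      truth = make_scene_truth(geo$cells, geo$nuclei, geo$evs)
    )
  })
}

# Draw the full static geometry of a scene (cells, nuclei, then internal and
# external EVs) from the active RNG stream.
draw_scene_geometry <- function(params) {
  H <- params$image_size[1]; W <- params$image_size[2]
  pc <- place_cells(H, W, params$n_cells, params$cell_radius[1],
                    params$cell_radius[2])
  pn <- place_nuclei(pc$labels, pc$info, params$n_nuclei_per_cell)
  evs <- matrix(0L, H, W)
  n_int <- params$n_evs_internal
  if (n_int > 0 && params$n_cells == 0L) {
    place_error("internal EV", 1L, n_int)
  }
  for (k in seq_len(n_int)) {
    m <- place_one_ev(pc$labels, pn$labels, evs, params$ev_radius, "internal")
    if (is.null(m)) place_error("internal EV", k, n_int)
    evs[m] <- k
  }
  for (k in seq_len(params$n_evs_external)) {
    m <- place_one_ev(pc$labels, pn$labels, evs, params$ev_radius, "external")
    if (is.null(m)) place_error("external EV", k, params$n_evs_external)
    evs[m] <- n_int + k
  }
  list(cells = pc$labels, cell_info = pc$info, nuclei = pn$labels, evs = evs)
}

#' Generate a synthetic uptake time-lapse
#'
#' Cell and nucleus geometry (and external EVs) are fixed across frames; at
#' acquisition time `t` the scene contains `round(uptake_curve(t))` internal
#' EVs, drawn as a nested prefix of one deterministic placement stream so
#' that counts grow by accretion, mimicking progressive internalization.
#'
#' @param params a [scene_params()] object; `n_evs_internal` is ignored (the
#'   curve drives internal counts), `n_evs_external` is the constant number
#'   of external puncta.
#' @param uptake_curve function mapping time (minutes) to the expected
#'   internal EV count per scene; must be non-negative on the schedule.
#' @param schedule acquisition times in minutes, strictly increasing;
#'   defaults to [default_schedule()].
#' @return A list of class `timelapse` with `frames`, `truths` and
#'   `schedule`.
#' @export
generate_timelapse <- function(params, uptake_curve,
                               schedule = default_schedule()) {
  stopifnot(inherits(params, "scene_params"), is.function(uptake_curve),
            length(schedule) >= 1L, all(diff(schedule) > 0))
  targets <- vapply(schedule, uptake_curve, numeric(1))
  if (any(!is.finite(targets)) || any(targets < 0)) {
    stop("uptake_curve must be finite and non-negative on the schedule")
  }
  counts <- as.integer(round(targets))
  with_local_seed(params$seed, {
    H <- params$image_size[1]; W <- params$image_size[2]
    pc <- place_cells(H, W, params$n_cells, params$cell_radius[1],
                      params$cell_radius[2])
    pn <- place_nuclei(pc$labels, pc$info, params$n_nuclei_per_cell)
    max_int <- max(counts, 0L)
    if (max_int > 0 && params$n_cells == 0L) {
      place_error("internal EV", 1L, max_int)
    }
    # master streams of EV masks; frame t uses the first counts[t] internal
    all_ev <- matrix(0L, H, W)
    int_masks <- vector("list", max_int)
    for (k in seq_len(max_int)) {
      m <- place_one_ev(pc$labels, pn$labels, all_ev, params$ev_radius,
                        "internal")
      if (is.null(m)) place_error("internal EV", k, max_int)
      all_ev[m] <- k
      int_masks[[k]] <- m
    }
    ext_masks <- vector("list", params$n_evs_external)
    for (k in seq_len(params$n_evs_external)) {
      m <- place_one_ev(pc$labels, pn$labels, all_ev, params$ev_radius,
                        "external")
      if (is.null(m)) place_error("external EV", k, params$n_evs_external)
      all_ev[m] <- max_int + k
      ext_masks[[k]] <- m
    }
    inten <- draw_intensities(params$n_cells, max(pn$labels),
                              max_int + params$n_evs_external)
    gap_arcs <- lapply(seq_len(params$n_cells), function(k)
      draw_gap_arcs(params$border_gap_fraction))
    frames <- vector("list", length(schedule))
    truths <- vector("list", length(schedule))
    for (f in seq_along(schedule)) {
      evs <- matrix(0L, H, W)
      k_int <- counts[f]
      lab <- 0L
      ev_int_sel <- integer(0)
      for (k in seq_len(k_int)) {
        lab <- lab + 1L
        evs[int_masks[[k]]] <- lab
        ev_int_sel <- c(ev_int_sel, k)
      }
      for (k in seq_along(ext_masks)) {
        lab <- lab + 1L
        evs[ext_masks[[k]]] <- lab
      }
      # intensities indexed by per-frame EV label: internals keep their
      # master intensity, externals theirs
      ev_inten <- c(inten$ev[ev_int_sel],
                    inten$ev[max_int + seq_along(ext_masks)])
      planes <- render_planes(
        pc$labels, pn$labels, evs, pc$info,
        list(cell_interior = inten$cell_interior,
             cell_border = inten$cell_border,
             nucleus = inten$nucleus, ev = ev_inten),
        gap_arcs, params
      )
      frames[[f]] <- multichannel_frame(planes$nuclei, planes$ev,
                                        planes$merge, schedule[f])
      truths[[f]] <- make_scene_truth(pc$labels, pn$labels, evs)
    }
    structure(list(frames = frames, truths = truths, schedule = schedule),
              class = "timelapse")
  })
}
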