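test_that("internal/external split follows the majority-overlap rule", {
  evs <- matrix(0L, 10, 10)
  evs[2:3, 2:3] <- 1L            # 4 px
  evs[7:8, 7:8] <- 2L
  empty <- matrix(FALSE, 10, 10)
  sp <- split_internal_external(evs, empty)
  expect_equal(sp$external, c(1L, 2L))
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE
  sp2 <- split_internal_external(evs, mask)
  expect_equal(sp2$internal, 1L)
  expect_equal(sp2$external, 2L)
  # exactly half inside counts as internal (>= rule)
  mask3 <- matrix(FALSE, 10, 10); mask3[2:3, 2] <- TRUE  # 2 of 4 px of EV 1
  sp3 <- split_internal_external(evs, mask3)
  expect_true(1L %in% sp3$internal)
  # conservation: partition is exhaustive and disjoint
  expect_setequal(c(sp3$internal, sp3$external), c(1L, 2L))
  expect_length(intersect(sp3$internal, sp3$external), 0)
})

test_that("nuclei are counted by the centroid rule", {
  nuclei <- matrix(0L, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  expect_equal(count_nuclei_in_cell(nuclei, mask), 0L)
  nuclei[2:4, 2:4] <- 1L
  nuclei[7:9, 7:9] <- 2L
  mask[1:10, 1:5] <- TRUE
  expect_equal(count_nuclei_in_cell(nuclei, mask), 1L)
  # nucleus straddling the boundary with centroid outside is not counted
  nuclei2 <- matrix(0L, 10, 10)
  nuclei2[4:8, 4:6] <- 3L        # centroid at row 6
  mask2 <- matrix(FALSE, 10, 10); mask2[1:5, ] <- TRUE
  expect_equal(count_nuclei_in_cell(nuclei2, mask2), 0L)
})

# Build a degenerate segmentation-like list from masks.
seg_from <- function(cells, nuclei, evs, tau = 0.5) {
  list(cells = cells, nuclei = nuclei, evs = evs, fusion_tau = tau)
}

tracks_all_cells <- function(result_list) {
  n <- max(result_list[[1]]$cells)
  select_tracked_cells(result_list, n)
}

test_that("per-frame quantification reproduces the defining arithmetic", {
  cells <- matrix(0L, 20, 20)
  cells[1:10, 1:10] <- 1L              # area 100
  nuclei <- matrix(0L, 20, 20)
  nuclei[4:6, 4:6] <- 1L
  evs <- matrix(0L, 20, 20)
  evs[2:3, 7:9] <- 1L                  # 6 px, wholly inside
  evs[8:9, 2:3] <- 2L                  # 4 px, wholly inside
  res <- seg_from(cells, nuclei, evs)
  tr <- select_tracked_cells(list(res), 1)
  tab <- quantify_frame(res, tr, time = 30)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$internal_ev_count, 2)
  expect_equal(tab$n_nuclei, 1)
  expect_equal(tab$evs_per_cell, 2)
  expect_equal(tab$cell_area_px, 100)
  expect_equal(tab$internal_ev_area_px, 10)
  expect_equal(tab$coverage_percent, 10)
  # zero internal EVs
  res0 <- seg_from(cells, nuclei, matrix(0L, 20, 20))
  tab0 <- quantify_frame(res0, tr, time = 30)
  expect_equal(tab0$internal_ev_count, 0)
  expect_equal(tab0$coverage_percent, 0)
  # multiple nuclei divide the count
  nuclei2 <- nuclei; nuclei2[8:9, 8:9] <- 2L
  res2 <- seg_from(cells, nuclei2, evs)
  tab2 <- quantify_frame(res2, tr, time = 30)
  expect_equal(tab2$evs_per_cell, 1)
})

test_that("quantification of ground-truth masks reproduces per-cell truth exactly", {
  for (s in c(4, 19, 41)) {
    sc <- generate_scene(scene_params(seed = s))
    res <- seg_from(sc$truth$cells, sc$truth$nuclei, sc$truth$evs)
    tr <- tracks_all_cells(list(res))
    tab <- quantify_frame(res, tr, time = 0)
    truth <- sc$truth$per_cell_truth
    # tracks are ordered by decreasing area; map back to cell labels
    for (q in seq_along(tr$track_ids)) {
      lab <- tr$labels[1, q]
      trow <- truth[truth$cell == lab, ]
      row <- tab[tab$track_id == tr$track_ids[q], ]
      expect_equal(row$internal_ev_count, trow$n_internal_evs)
      expect_equal(row$n_nuclei, trow$n_nuclei)
      expect_equal(row$internal_ev_area_px, trow$internal_ev_area)
      expect_equal(row$cell_area_px, sum(sc$truth$cells == lab))
      expect_equal(row$coverage_percent,
                   100 * trow$internal_ev_area / sum(sc$truth$cells == lab))
    }
  }
})

test_that("coverage is stable under 2x nearest-neighbour upsampling", {
  sc <- generate_scene(scene_params(seed = 12))
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  res1 <- seg_from(sc$truth$cells, sc$truth$nuclei, sc$truth$evs)
  res2 <- seg_from(up(sc$truth$cells), up(sc$truth$nuclei),
                   up(sc$truth$evs))
  t1 <- quantify_frame(res1, tracks_all_cells(list(res1)), 0)
  t2 <- quantify_frame(res2, tracks_all_cells(list(res2)), 0)
  expect_equal(t2$coverage_percent, t1$coverage_percent, tolerance = 0.5)
  expect_equal(t2$internal_ev_count, t1$internal_ev_count)
})

test_that("tracked-cell selection picks the largest matchable cells", {
  cells <- matrix(0L, 30, 30)
  cells[1:10, 1:10] <- 1L    # 100 px
  cells[15:29, 15:29] <- 2L  # 225 px
  cells[1:5, 20:24] <- 3L    # 25 px
  res <- seg_from(cells, matrix(0L, 30, 30), matrix(0L, 30, 30))
  tr <- select_tracked_cells(list(res), 2)
  expect_equal(sort(tr$labels[1, ]), c(1L, 2L))
  tr0 <- select_tracked_cells(list(res), 0)
  expect_length(tr0$track_ids, 0)
  expect_warning(select_tracked_cells(list(res), 5), "only")
  # static time-lapse: every track maps to the same label in all frames
  tr3 <- select_tracked_cells(list(res, res, res), 2)
  expect_equal(tr3$labels[1, ], tr3$labels[3, ])
})

test_that("time-lapse quantification preserves truth monotonicity and cardinality", {
  p <- scene_params(image_size = c(96, 96), n_cells = 3,
                    cell_radius = c(12, 1), n_evs_external = 3, seed = 31)
  sch <- default_schedule()
  tl <- generate_timelapse(p, function(t) 8 * (t - 30) / 210, sch)
  results <- lapply(tl$truths, function(tr)
    seg_from(tr$cells, tr$nuclei, tr$evs))
  tracks <- select_tracked_cells(results, 3)
  tab <- quantify_timelapse(results, tracks, sch)
  expect_equal(nrow(tab), length(sch) * 3)
  for (id in tracks$track_ids) {
    v <- tab$evs_per_cell[tab$track_id == id]
    expect_true(all(diff(v) >= 0))
  }
  expect_error(quantify_timelapse(results[-1], tracks, sch), "schedule")
  # all-empty EV masks give all-zero counts
  results0 <- lapply(results, function(r) {
    r$evs <- matrix(0L, nrow(r$evs), ncol(r$evs)); r
  })
  tab0 <- quantify_timelapse(results0, tracks, sch)
  expect_true(all(tab0$internal_ev_count == 0))
})
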