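test_that("scene generation honours requested counts and containment", {
  p <- scene_params(n_cells = 3, n_nuclei_per_cell = c(1, 1),
                    n_evs_internal = 4, n_evs_external = 3,
                    noise_sd = 0, blur_sigma = 0, seed = 11)
  sc <- generate_scene(p)
  expect_equal(max(sc$truth$cells), 3)
  expect_equal(max(sc$truth$nuclei), 3)
  expect_equal(max(sc$truth$evs), 7)
  # every nucleus lies entirely within exactly one cell
  for (k in 1:3) {
    m <- sc$truth$nuclei == k
    owners <- unique(sc$truth$cells[m])
    expect_length(owners, 1)
    expect_gt(owners, 0)
  }
  # planes finite, non-negative, same shape
  expect_true(all(sc$frame$nuclei_plane >= 0))
  expect_identical(dim(sc$frame$ev_plane), dim(sc$frame$merge_plane))
})

test_that("a scene without cells has only external EVs", {
  p <- scene_params(n_cells = 0, n_nuclei_per_cell = c(0, 0),
                    n_evs_internal = 0, n_evs_external = 5, seed = 2)
  sc <- generate_scene(p)
  expect_equal(max(sc$truth$cells), 0)
  expect_equal(max(sc$truth$evs), 5)
  expect_false(any(sc$truth$ev_internal_flags))
})

test_that("identical parameters and seed give bit-identical scenes", {
  p <- scene_params(seed = 33)
  expect_identical(generate_scene(p), generate_scene(p))
})

test_that("internal/external truth flags agree with the brute-force overlap rule", {
  for (s in c(5, 21, 48)) {
    sc <- generate_scene(scene_params(seed = s))
    cells_union <- sc$truth$cells > 0
    ids <- sort(unique(sc$truth$evs[sc$truth$evs > 0]))
    oracle <- vapply(ids, function(k) {
      px <- which(sc$truth$evs == k)
      sum(cells_union[px]) >= 0.5 * length(px)
    }, logical(1))
    expect_identical(sc$truth$ev_internal_flags, oracle)
  }
})

test_that("truth depends only on geometry, not on rendering noise", {
  p1 <- scene_params(noise_sd = 0.01, seed = 9)
  p2 <- scene_params(noise_sd = 0.2, seed = 9)
  expect_identical(generate_scene(p1)$truth, generate_scene(p2)$truth)
})

test_that("per-cell internal counts sum to the number of internal flags", {
  for (s in c(3, 17)) {
    sc <- generate_scene(scene_params(seed = s))
    expect_equal(sum(sc$truth$per_cell_truth$n_internal_evs),
                 sum(sc$truth$ev_internal_flags))
  }
})

test_that("impossible placements raise errors naming the offending count", {
  p <- scene_params(n_cells = 0, n_evs_internal = 3, n_evs_external = 0,
                    seed = 1)
  expect_error(generate_scene(p), "internal EV")
  crowded <- scene_params(image_size = c(32, 32), n_cells = 10,
                          cell_radius = c(12, 1), seed = 1)
  expect_error(generate_scene(crowded), "cell")
})

test_that("the default schedule runs every 5 min to 1 h then every 10 min to 4 h", {
  sch <- default_schedule()
  expect_equal(sch[1], 30)
  expect_equal(max(sch), 240)
  expect_true(all(diff(sch[sch <= 60]) == 5))
  expect_true(all(diff(sch[sch >= 60]) == 10))
  expect_true(all(diff(sch) > 0))
})

test_that("time-lapse geometry is static and internal counts follow the curve", {
  p <- scene_params(image_size = c(96, 96), n_cells = 2,
                    cell_radius = c(12, 1), n_evs_external = 3, seed = 5)
  sch <- seq(30, 120, by = 15)
  curve <- function(t) 6 * (t - 30) / 90
  tl <- generate_timelapse(p, curve, sch)
  expect_length(tl$frames, length(sch))
  for (f in seq_along(sch)) {
    expect_identical(tl$truths[[f]]$cells, tl$truths[[1]]$cells)
    expect_identical(tl$truths[[f]]$nuclei, tl$truths[[1]]$nuclei)
    expect_equal(sum(tl$truths[[f]]$ev_internal_flags), round(curve(sch[f])))
    expect_equal(sum(!tl$truths[[f]]$ev_internal_flags), 3)
  }
  # monotone curve => non-decreasing internal counts
  counts <- vapply(tl$truths, function(tr) sum(tr$ev_internal_flags),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a zero uptake curve yields zero internal EVs in every frame", {
  p <- scene_params(image_size = c(64, 64), n_cells = 1,
                    cell_radius = c(11, 1), n_evs_external = 2, seed = 8)
  tl <- generate_timelapse(p, function(t) 0, c(30, 60, 90))
  for (tr in tl$truths) expect_equal(sum(tr$ev_internal_flags), 0)
})
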