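test_that("predict_maps keeps shape, simplex and determinism contracts", {
  model <- init_model(model_config(depth = 2, base_features = 8), seed = 1)
  img <- matrix(runif(13 * 17), 13, 17)  # not divisible by the stride
  mp1 <- predict_maps(model, img)
  mp2 <- predict_maps(model, img)
  expect_identical(mp1, mp2)
  expect_equal(dim(mp1$dmap), c(13, 17))
  expect_equal(dim(mp1$cmap), c(13, 17, 3))
  expect_true(all(is.finite(mp1$dmap)) && all(mp1$dmap >= 0 & mp1$dmap <= 1))
  sums <- apply(mp1$cmap, c(1, 2), sum)
  expect_equal(sums, matrix(1, 13, 17), tolerance = 1e-5)
  zero <- predict_maps(model, matrix(0, 12, 12))
  expect_true(all(is.finite(zero$dmap)))
})

test_that("an all-zero distance map yields an empty labeling", {
  cmap <- one_hot3(matrix(1L, 8, 8))
  lab <- instances_from_maps(matrix(0, 8, 8), cmap, 0.5)
  expect_equal(max(lab), 0)
})

test_that("ideal maps of separated blobs are recovered exactly", {
  lab <- matrix(0L, 20, 20)
  lab[3:8, 3:8] <- 1L
  lab[12:18, 11:17] <- 2L
  rec <- instances_from_maps(distance_target(lab),
                             one_hot3(border_target(lab, 2)), 0.5)
  expect_true(labels_match_exact(lab, rec))
})

test_that("a border-class ridge splits touching blobs", {
  lab <- matrix(0L, 10, 16)
  lab[3:8, 3:8] <- 1L
  lab[3:8, 9:14] <- 2L   # shares an edge with instance 1
  rec <- instances_from_maps(distance_target(lab),
                             one_hot3(border_target(lab, 1)), 0.5)
  expect_equal(max(rec), 2)
  expect_true(labels_match_exact(lab, rec))
})

test_that("perfect maps recover generator scenes exactly for every entity", {
  for (s in c(2, 9, 23)) {
    sc <- generate_scene(scene_params(seed = s))
    for (ent in c("cells", "nuclei", "evs")) {
      L <- sc$truth[[ent]]
      thr <- if (ent == "evs") 0.3 else 0.5
      bw <- if (ent == "evs") 1L else 2L
      rec <- instances_from_maps(distance_target(L),
                                 one_hot3(border_target(L, bw)), thr)
      expect_true(labels_match_exact(L, rec))
    }
  }
})

# hand-built fusion fixture: cells, nuclei and EVs as simple discs
fusion_fixture <- function() {
  H <- 48; W <- 48
  disc <- function(ci, cj, r) {
    m <- matrix(FALSE, H, W)
    for (i in max(1, ci - r):min(H, ci + r))
      for (j in max(1, cj - r):min(W, cj + r))
        if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
    m
  }
  cells <- matrix(0L, H, W)
  cells[disc(16, 16, 12)] <- 1L
  cells[disc(34, 34, 10)] <- 2L
  nuclei <- matrix(0L, H, W)
  nuclei[disc(16, 16, 4)] <- 1L
  nuclei[disc(34, 34, 4)] <- 2L
  evs <- matrix(0L, H, W)
  evs[disc(16, 16, 2)] <- 1L   # fully on nucleus 1
  evs[disc(34, 34, 2)] <- 2L   # fully on nucleus 2
  evs[disc(16, 26, 2)] <- 3L   # inside cell 1, off nuclei
  evs[disc(40, 28, 2)] <- 4L
  evs[disc(6, 40, 2)] <- 5L    # outside all cells
  list(cells = cells, nuclei = nuclei, evs = evs)
}

test_that("fusion deletes nucleus-overlapping EVs according to tau", {
  fx <- fusion_fixture()
  # tau = 1: overlap can never exceed the EV's own area
  r1 <- fuse(fx$cells, fx$nuclei, fx$evs, tau = 1)
  expect_equal(max(r1$evs), 5)
  # tau = 0.5: the two EVs sitting on nuclei (overlap 100%) are removed
  r05 <- fuse(fx$cells, fx$nuclei, fx$evs, tau = 0.5)
  expect_equal(max(r05$evs), 3)
  # tau = 0: one shared pixel suffices for deletion
  evs <- fx$evs
  evs[20, 16] <- 6L  # single pixel touching nucleus 1's disc boundary region
  nuclei <- fx$nuclei
  nuclei[20, 16] <- 1L
  r0 <- fuse(fx$cells, nuclei, evs, tau = 0)
  surviving <- max(r0$evs)
  expect_equal(surviving, 3)  # EVs 1, 2 and the new 6 all touch nuclei
  expect_error(fuse(fx$cells, fx$nuclei, fx$evs, tau = 1.5), "tau")
})

test_that("orphan nuclei are removed and cells repaired by closing", {
  fx <- fusion_fixture()
  nuclei <- fx$nuclei
  nuclei[2:5, 2:5] <- 3L  # nucleus with no cell overlap
  r <- fuse(fx$cells, nuclei, fx$evs, tau = 1)
  expect_equal(max(r$nuclei), 2)
  expect_equal(r$report$nuclei_deleted_no_cell, 1)
  # a cell with a small hole is repaired
  cells <- fx$cells
  cells[15:17, 15:17] <- 0L
  r2 <- fuse(cells, fx$nuclei, fx$evs, tau = 1)
  expect_true(all(r2$cells[15:17, 15:17] > 0))
})

test_that("fusion is idempotent and EV deletion is monotone in tau", {
  set.seed(21)
  for (rep in 1:10) {
    sc <- generate_scene(scene_params(seed = 300 + rep))
    # move some EVs onto nuclei to create overlaps
    evs <- sc$truth$evs
    nuc <- sc$truth$nuclei
    ids <- sort(unique(evs[evs > 0]))
    if (length(ids) >= 2 && max(nuc) > 0) {
      w <- which(nuc == 1, arr.ind = TRUE)
      ctr <- round(colMeans(w))
      m <- evs == ids[1]
      sh <- which(m, arr.ind = TRUE)
      off <- ctr - round(colMeans(sh))
      sh2 <- sweep(sh, 2, off, `+`)
      ok <- sh2[, 1] >= 1 & sh2[, 1] <= nrow(evs) &
        sh2[, 2] >= 1 & sh2[, 2] <= ncol(evs)
      evs[m] <- 0L
      evs[sh2[ok, , drop = FALSE]] <- ids[1]
    }
    r <- fuse(sc$truth$cells, nuc, evs, tau = 0.4)
    r2 <- fuse(r$cells, r$nuclei, r$evs, tau = 0.4)
    expect_identical(r2$cells, r$cells)
    expect_identical(r2$nuclei, r$nuclei)
    expect_identical(r2$evs, r$evs)
    # tau-monotonicity: higher tau never deletes more
    del <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(tau)
      fuse(sc$truth$cells, nuc, evs, tau)$report$evs_deleted_overlap,
      numeric(1))
    expect_true(all(diff(del) <= 0))
  }
})

test_that("triple prediction output shapes match the frame and permutation is stateless", {
  model <- init_model(model_config(depth = 2, base_features = 8), seed = 2)
  sc1 <- generate_scene(scene_params(image_size = c(64, 64), n_cells = 2,
                                     cell_radius = c(11, 1), seed = 1))
  sc2 <- generate_scene(scene_params(image_size = c(64, 64), n_cells = 2,
                                     cell_radius = c(11, 1), seed = 2))
  a1 <- triple_predict(model, sc1$frame)
  b1 <- triple_predict(model, sc2$frame)
  a2 <- triple_predict(model, sc1$frame)  # after another frame: stateless
  expect_identical(a1, a2)
  for (ent in names(a1)) expect_equal(dim(a1[[ent]]), c(64, 64))
})
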