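rigidTransform <- function(cells, angle, dx, dy) {
  out <- cells
  out$x <- cos(angle) * cells$x - sin(angle) * cells$y + dx
  out$y <- sin(angle) * cells$x + cos(angle) * cells$y + dy
  out$orientation <- (cells$orientation + angle) %% pi
  out
}

test_that("pair nematic order is exact and pi-periodic", {
  expect_equal(pairNematicOrder(0), 1)
  expect_equal(pairNematicOrder(pi / 2), -0.5)
  expect_equal(pairNematicOrder(pi / 4), 0.25)
  th <- seq(-3, 3, by = 0.37)
  expect_equal(pairNematicOrder(th + pi), pairNematicOrder(th))
  expect_true(all(pairNematicOrder(th) >= -0.5 &
                    pairNematicOrder(th) <= 1))
})

test_that("local nematic order averages neighbours within 10 um", {
  # all-parallel cells: order 1 wherever a neighbour exists
  cells <- data.frame(x = c(0, 5, 8, 100), y = 0, orientation = 0.7,
                      speed = 10)
  s <- localNematicOrder(cells)
  expect_equal(s[1:3], rep(1, 3))
  expect_true(is.na(s[4]))   # isolated cell excluded
  # isotropic dense field: population mean ~ 0.25 (E[cos^2] = 1/2)
  set.seed(14)
  iso <- simCellTable("isotropic", nCells = 500L, fieldSize = 100,
                      seed = 14)
  vals <- localNematicOrder(iso)
  m <- mean(vals, na.rm = TRUE)
  se <- sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals)))
  expect_lt(abs(m - 0.25), 3 * se + 0.02)
})

test_that("non-motile cluster detection honours all three thresholds", {
  chain <- function(n, speed) {
    data.frame(x = (seq_len(n) - 1) * 1.5, y = 0, orientation = 0,
               speed = speed)
  }
  # 10 slow linked cells: one cluster
  expect_equal(nrow(nonMotileClusters(chain(10, 2))), 1L)
  # 9 linked cells: below minimum size
  expect_equal(nrow(nonMotileClusters(chain(9, 2))), 0L)
  # speed exactly at the cut-off is motile (strict < 8)
  expect_equal(nrow(nonMotileClusters(chain(10, 8))), 0L)
  expect_equal(nrow(nonMotileClusters(chain(10, 7.99))), 1L)
  # a gap wider than the linkage cut-off splits the chain
  split <- chain(20, 2)
  split$x[11:20] <- split$x[11:20] + 10
  res <- nonMotileClusters(split)
  expect_equal(nrow(res), 2L)
  expect_equal(res$n_cells, c(10L, 10L))
  # constructed scenario: exactly one cluster
  cl <- simCellTable("non_motile_cluster", nCells = 60L, seed = 3)
  expect_equal(nrow(nonMotileClusters(cl)), 1L)
})

test_that("local rafting ratio counts aligned motile neighbours", {
  # 4 aligned motile neighbours within 30 um: ratio 1
  cells <- data.frame(x = c(0, 5, 10, -5, -10), y = 0,
                      orientation = 0.3, speed = 15)
  expect_equal(localRaftingRatio(cells)[1], 1)
  # 2 aligned motile + 2 slow neighbours: ratio 0.5
  mixed <- data.frame(x = c(0, 5, 10, -5, -10), y = 0,
                      orientation = 0.3, speed = c(15, 15, 15, 2, 2))
  expect_equal(localRaftingRatio(mixed)[1], 0.5)
  # speed exactly 10 counts as motile (inclusive)
  edge <- data.frame(x = c(0, 5), y = 0, orientation = 0.3,
                     speed = c(15, 10))
  expect_equal(localRaftingRatio(edge)[1], 1)
  # misaligned beyond 15 degrees does not count
  mis <- data.frame(x = c(0, 5), y = 0,
                    orientation = c(0, 20 * pi / 180), speed = 15)
  expect_equal(localRaftingRatio(mis)[1], 0)
  # empty neighbourhood is undefined
  far <- data.frame(x = c(0, 100), y = 0, orientation = 0, speed = 15)
  expect_true(all(is.na(localRaftingRatio(far))))
  # constructed raft: members' ratios exceed 0.9
  raft <- simCellTable("raft", nCells = 60L, seed = 4)
  rr <- localRaftingRatio(raft)
  expect_true(all(rr[attr(raft, "raft")] > 0.9))
})

test_that("density fluctuations follow the population-SD convention", {
  # uniform coverage: zero fluctuation
  expect_equal(densityFluctuations(list(matrix(0.4, 4, 4))), 0)
  # half the tiles full, half empty: SD 0.5
  expect_equal(densityFluctuations(list(cbind(c(1, 1), c(0, 0)))), 0.5)
  # empty frame: zero
  expect_equal(densityFluctuations(list(matrix(0, 2, 2))), 0)
  # cell-table route: one saturated tile out of four
  cells <- data.frame(frame = 1L, x = 24, y = 24, orientation = 0,
                      speed = 1, area = 48^2)
  v <- densityFluctuations(cells, fieldSize = 96, tile = 48)
  expect_equal(v, sqrt(3) / 4)   # tiles (1,0,0,0): population SD
  expect_error(densityFluctuations(cells, fieldSize = 20), "smaller")
})

test_that("per-video properties use median-then-mean aggregation", {
  one <- data.frame(frame = 1L, x = 1:3, y = 0, orientation = 0,
                    speed = c(1, 2, 100), area = 3)
  p <- simpleProperties(one)
  expect_equal(unname(p["mean_speed"]), 2)
  expect_equal(unname(p["non_motile_fraction"]), 2 / 3)
  # all cells slow: non-motile fraction 1
  slow <- transform(one, speed = 3)
  expect_equal(unname(simpleProperties(slow)["non_motile_fraction"]), 1)
  # identical frames: video value equals the frame value
  many <- do.call(rbind, lapply(1:48, function(f) transform(one, frame = f)))
  expect_equal(simpleProperties(many), p)
})

test_that("metrics are invariant under rigid motions and relabeling", {
  cells <- simCellTable("mixed", nCells = 90L, seed = 6)
  moved <- rigidTransform(cells, angle = 0.8, dx = 37, dy = -12)
  expect_equal(localNematicOrder(moved), localNematicOrder(cells),
               tolerance = 1e-9)
  expect_equal(localRaftingRatio(moved), localRaftingRatio(cells),
               tolerance = 1e-9)
  expect_equal(nrow(nonMotileClusters(moved)),
               nrow(nonMotileClusters(cells)))
  # row shuffling permutes per-cell outputs identically
  set.seed(7)
  perm <- sample(nrow(cells))
  shuffled <- cells[perm, ]
  expect_equal(localRaftingRatio(shuffled),
               localRaftingRatio(cells)[perm], tolerance = 1e-12)
  expect_equal(localNematicOrder(shuffled),
               localNematicOrder(cells)[perm], tolerance = 1e-12)
})

test_that("phenotype kymographs share the gene tiling contract", {
  ann <- data.frame(sample_id = c("v1", "v2"), time = c(1, 2),
                    position = c(1.5, 1.5))
  ky <- phenotypeKymograph(c(v1 = 0.2, v2 = 0.9), ann, "rafting")
  expect_equal(nrow(ky), 2L)
  expect_identical(attr(ky, "property"), "rafting")
  expect_error(phenotypeKymograph(c(1, 2), rbind(ann[1, ], ann[1, ])),
               "duplicate")
})

test_that("cell-table scenarios satisfy their constructions", {
  expect_equal(nrow(simCellTable("isotropic", nCells = 0L)), 0L)
  iso <- simCellTable("isotropic", nCells = 400L, seed = 9)
  # orientations uniform on [0, pi): Kolmogorov-Smirnov against uniform
  ks <- suppressWarnings(
    stats::ks.test(iso$orientation / pi, "punif")$p.value)
  expect_gt(ks, 0.01)
  raft <- simCellTable("raft", nCells = 40L, seed = 10)
  rIdx <- attr(raft, "raft")
  expect_true(diff(range(raft$orientation[rIdx])) < 5 * pi / 180)
  expect_true(all(raft$speed[rIdx] >= 10))
  expect_error(simCellTable("warp"), "arg")
  # bit-reproducible given the seed
  expect_identical(simCellTable("mixed", nCells = 50L, seed = 2),
                   simCellTable("mixed", nCells = 50L, seed = 2))
})
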