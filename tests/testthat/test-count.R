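# 3D segmentation, statistical filtering, cluster splitting and
# concentration bookkeeping.

test_that("segmentation finds isolated particles and rejects speckle", {
  zs <- seq(-20, 20, by = 1)
  empty <- phase_volume(array(0, c(64, 64, 41)), zs, 0.234)
  expect_identical(nrow(segment_volume(empty, 0.5)), 0L)
  expect_error(segment_volume(empty, -1), "tau")

  # one supra-threshold voxel: removed by the opening
  spik <- array(0, c(64, 64, 41)); spik[30, 30, 20] <- 5
  expect_identical(nrow(segment_volume(phase_volume(spik, zs, 0.234), 0.5)), 0L)

  # two synthetic 1 um particles 10 um apart
  vol <- synthetic_volume(rbind(c(-5, 0, -6), c(5, 0, 6)))
  comps <- segment_volume(vol, 0.5, "sphere", 0.5)
  expect_identical(nrow(comps), 2L)
  comps <- comps[order(comps$x), ]
  expect_lt(max(abs(comps$x - c(-5, 5))), 1)
  expect_lt(max(abs(comps$y)), 1)
  expect_lt(max(abs(comps$z - c(-6, 6))), 1)
  expect_true(all(comps$volume_um3 > 0))
  expect_error(segment_volume(vol, 0.5, "sphere", 1000), "larger than the volume")
})

test_that("cube and sphere elements both preserve compact structures", {
  vol <- synthetic_volume(rbind(c(0, 0, 0)))
  for (el in c("sphere", "cube"))
    expect_identical(nrow(segment_volume(vol, 0.5, el, 0.5)), 1L)
})

test_that("volume gates drop debris and flag clusters", {
  mk <- function(v) {
    n <- length(v)
    structure(data.frame(label = seq_len(n), voxels = round(v / 0.01),
                         volume_um3 = v, x = numeric(n), y = numeric(n),
                         z = numeric(n), peak_phase = rep(1, n)),
              class = c("holo_components", "data.frame"), pitch = 0.1, step = 1)
  }
  same <- filter_components(mk(rep(1, 20)))
  expect_identical(nrow(same), 20L)
  expect_false(any(same$cluster))
  expect_equal(attr(same, "V_avg"), 1)

  out <- filter_components(mk(c(rep(1, 20), 0.1)))
  expect_identical(nrow(out), 20L)  # the 0.1 V component is debris

  emptyc <- filter_components(mk(numeric(0)))
  expect_identical(nrow(emptyc), 0L)
  expect_true(is.na(attr(emptyc, "V_avg")))

  clus <- filter_components(mk(c(rep(1, 10), 5)), f_high = 3)
  expect_true(clus$cluster[11])
  expect_equal(attr(clus, "V_avg"), 1)

  pk <- mk(rep(1, 5)); pk$peak_phase <- c(1, 1, 0.2, 1, 0.3)
  expect_identical(nrow(filter_components(pk, min_peak = 0.5)), 3L)
})

test_that("clip_components culls by physical region", {
  df <- structure(data.frame(label = 1:3, voxels = 10, volume_um3 = 0.5,
                             x = c(0, 20, 0), y = 0, z = c(0, 0, 150),
                             peak_phase = 1),
                  class = c("holo_components", "data.frame"), pitch = 0.1, step = 1)
  out <- clip_components(df, xlim = c(-10, 10), ylim = c(-10, 10),
                         zlim = c(-100, 100))
  expect_identical(out$label, 1L)
})

test_that("counts split clusters and concentrations carry units", {
  mk <- function(v) {
    structure(data.frame(label = seq_along(v), voxels = 1, volume_um3 = v,
                         x = 0, y = 0, z = 0, peak_phase = 1, cluster = FALSE),
              class = c("holo_components", "data.frame"), pitch = 0.1, step = 1)
  }
  # measurement volume: 120 x 120 um field over 200 um -> 2.88 nL
  res <- count_and_concentration(mk(rep(1, 3)), V_avg = 1,
                                 fov = c(120, 120), z_extent = 200)
  expect_equal(res$measurement_volume_nl, 2.88)
  # one structure of volume 2 V_avg contributes 2
  res2 <- count_and_concentration(mk(c(1, 2)), V_avg = 1, fov = c(120, 120),
                                  z_extent = 200)
  expect_identical(res2$adjusted_count, 3L)
  # 288 particles in 2.88 nL -> 1e8 per mL
  res3 <- count_and_concentration(mk(rep(1, 288)), V_avg = 1,
                                  fov = c(120, 120), z_extent = 200)
  expect_equal(res3$concentration_per_ml, 1e8)
  expect_error(count_and_concentration(mk(1), V_avg = -1, fov = c(10, 10),
                                       z_extent = 10), "positive")
})

test_that("counting is monotone when a well-separated particle is added", {
  base <- rbind(c(-6, -6, -8), c(6, 6, 8))
  v1 <- synthetic_volume(base)
  v2 <- synthetic_volume(rbind(base, c(-6, 6, 0)))
  n1 <- nrow(filter_components(segment_volume(v1, 0.5, "sphere", 0.5)))
  n2 <- nrow(filter_components(segment_volume(v2, 0.5, "sphere", 0.5)))
  expect_gte(n2, n1 + 1L)
})
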