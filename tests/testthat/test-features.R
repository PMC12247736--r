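test_that("total volume counts voxels times physical voxel volume", {
  g <- grid_spec(c(6, 6, 6), spacing = c(0.5, 0.5, 0.5))
  empty <- vessel_mask(array(0, dim = g$shape), g)
  expect_identical(total_volume(empty), 0)
  m10 <- mask_from_ijk(cbind(1:6, 1L, 1L), g)
  m10$values[1, 2, 1:4] <- 1 # 10 voxels total
  expect_equal(total_volume(vessel_mask(m10$values, g)), 10 * 0.125)
})

test_that("total volume is additive and scales as spacing cubed", {
  a <- blob_mask(1, n = 16, n_balls = 1)
  b <- mask_from_ijk(cbind(14:16, 16L, 16L), a$grid)
  expect_equal(sum(a$values * b$values), 0) # disjoint by construction
  u <- vessel_mask(pmin(a$values + b$values, 1), a$grid)
  expect_equal(total_volume(u), total_volume(a) + total_volume(b))
  gk <- grid_spec(a$grid$shape, spacing = a$grid$spacing * 3)
  expect_equal(total_volume(vessel_mask(a$values, gk)),
               27 * total_volume(a))
})

test_that("rasterized cylinder volume is within 5% of pi r^2 L", {
  ph <- make_phantom("straight_tube", radius_mm = 2, length_mm = 20,
                     grid = default_phantom_grid(96, 0.5))
  analytic <- pi * 4 * 20
  expect_lt(abs(total_volume(ph$mask) - analytic) / analytic, 0.05)
})

test_that("dice: identity, disjoint, 2-2-1 overlap, empty, symmetry", {
  g <- iso_grid(10)
  a <- mask_from_ijk(cbind(2:3, 2L, 2L), g)
  b <- mask_from_ijk(cbind(3:4, 2L, 2L), g)
  expect_identical(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5) # |A|=2, |B|=2, overlap 1
  d <- mask_from_ijk(cbind(8L, 8L, 8L), g)
  expect_equal(dice(a, d), 0)
  e <- vessel_mask(array(0, dim = g$shape), g)
  expect_equal(dice(e, e), 1) # both empty
  g2 <- iso_grid(10, s = 2)
  expect_error(dice(a, mask_from_ijk(cbind(2L, 2L, 2L), g2)),
               "different grids")
  # symmetry on random pairs
  set.seed(11)
  for (r in 1:25) {
    m1 <- blob_mask(100 + r, n = 12, n_balls = 2)
    m2 <- blob_mask(200 + r, n = 12, n_balls = 2)
    expect_identical(dice(m1, m2), dice(m2, m1))
  }
})

test_that("extract_features recovers phantom construction", {
  f1 <- extract_features(make_phantom("straight_tube", radius_mm = 1.5,
                                      length_mm = 30)$mask)
  expect_equal(f1$n_bifurcations, 0)
  expect_equal(f1$n_endpoints, 2)
  expect_equal(f1$n_segments, 1)
  expect_lt(abs(f1$mean_tortuosity - 1), 0.01)

  fy <- extract_features(make_phantom("y_tree", radius_mm = 1.5)$mask)
  expect_equal(fy$n_bifurcations, 1)
  expect_equal(fy$n_endpoints, 3)
  expect_equal(fy$n_segments, 3)
})

test_that("the feature vector has the 11 documented features", {
  expect_length(vessel_feature_names(), 11)
  fv <- extract_features(line_mask(8))
  expect_named(fv, vessel_feature_names())
  sub <- extract_features(line_mask(8),
                          features = c("total_volume_mm3", "n_segments"),
                          subject_id = "s1")
  expect_named(sub, c("subject_id", "total_volume_mm3", "n_segments"))
})

test_that("feature counts are additive over a disjoint union of phantoms", {
  g <- iso_grid(48, s = 0.5)
  a <- array(0, dim = g$shape)
  a[10, 10, 5:40] <- 1                     # line 1
  b <- array(0, dim = g$shape)
  b[35:45, 30, 30] <- 1                    # line 2
  fa <- extract_features(vessel_mask(a, g))
  fb <- extract_features(vessel_mask(b, g))
  fu <- extract_features(vessel_mask(pmin(a + b, 1), g))
  for (col in c("n_segments", "n_bifurcations", "n_endpoints"))
    expect_equal(fu[[col]], fa[[col]] + fb[[col]])
  expect_equal(fu$total_volume_mm3, fa$total_volume_mm3 + fb$total_volume_mm3)
})

test_that("feature extraction is deterministic and safe on empty masks", {
  m <- blob_mask(9, n = 20, n_balls = 2)
  expect_identical(extract_features(m), extract_features(m))
  g <- iso_grid(6)
  fe <- extract_features(vessel_mask(array(0, dim = g$shape), g))
  expect_equal(fe$total_volume_mm3, 0)
  expect_equal(fe$n_segments, 0)
  expect_true(is.na(fe$mean_radius_mm))
  expect_true(is.na(fe$mean_tortuosity))
})

test_that("feature tables are written with a configuration sidecar", {
  fv <- extract_features(line_mask(8), subject_id = "sub-0001")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fv, f)
  back <- utils::read.csv(f)
  expect_equal(back$subject_id, "sub-0001")
  expect_equal(back$n_segments, 1)
  sidecar <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(unlist(sidecar$feature_set), vessel_feature_names())
})
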