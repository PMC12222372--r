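geom_of <- function(d, vs = c(1, 1, 1)) image_geometry(d, vs)

test_that("largest connected component keeps the bigger of two blobs", {
  d <- c(10L, 10L, 6L)
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:3] <- TRUE        # 18 voxels
  m[8:9, 8:9, 5] <- TRUE          # 4 voxels, disjoint
  out <- largest_connected_component(voi_mask(m, geom_of(d), "liver"))
  expect_equal(sum(out$mask), 18)
  expect_true(all(out$mask[2:4, 2:4, 2:3]))
  expect_equal(out$label, "liver")

  single <- array(FALSE, d); single[5, 5, 3] <- TRUE
  out1 <- largest_connected_component(voi_mask(single, geom_of(d)))
  expect_equal(which(out1$mask), which(single))

  expect_error(largest_connected_component(
    voi_mask(array(FALSE, d), geom_of(d))), "empty")
})

test_that("corner-touching voxels join through the 26-neighbourhood", {
  d <- c(4L, 4L, 4L)
  m <- array(FALSE, d)
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # shares only a corner
  out <- largest_connected_component(voi_mask(m, geom_of(d)))
  expect_equal(sum(out$mask), 2)
})

test_that("largest component matches a BFS flood-fill oracle", {
  set.seed(33)
  for (rep in 1:3) {
    d <- c(12L, 12L, 8L)
    m <- array(runif(prod(d)) < 0.2, d)
    m[1, 1, 1] <- TRUE  # never empty
    got <- largest_connected_component(voi_mask(m, geom_of(d)))
    lab <- bfs_components_oracle(m)
    sizes <- tabulate(lab[lab > 0])
    big <- which(sizes == max(sizes))
    if (length(big) > 1) {
      first <- vapply(big, function(cc) min(which(lab == cc)), numeric(1))
      big <- big[which.min(first)]
    }
    expect_equal(which(got$mask), which(lab == big))
  }
})

test_that("mask resampling is exact on matching and nested grids", {
  d <- c(10L, 10L, 10L)
  m <- array(FALSE, d); m[3:6, 4:7, 2:5] <- TRUE
  src <- voi_mask(m, geom_of(d), "liver")

  same <- resample_mask(src, geom_of(d))
  expect_identical(same$mask, src$mask)

  # halving the voxel size: every source voxel splits into 8
  fine <- resample_mask(src, image_geometry(c(20L, 20L, 20L),
                                            c(0.5, 0.5, 0.5)))
  expect_equal(sum(fine$mask), 8 * sum(m))

  # world-coordinate oracle: a target voxel is inside iff its centre maps
  # into an inside source voxel
  tgeom <- image_geometry(c(7L, 7L, 7L), c(1.5, 1.5, 1.5))
  got <- resample_mask(src, tgeom)
  want <- array(FALSE, tgeom$dim)
  for (i in 0:6) for (j in 0:6) for (k in 0:6) {
    w <- tgeom$affine %*% c(i, j, k, 1)
    s <- round(solve(src$geometry$affine) %*% w)[1:3]
    if (all(s >= 0) && all(s < d))
      want[i + 1, j + 1, k + 1] <- m[s[1] + 1, s[2] + 1, s[3] + 1]
  }
  expect_identical(got$mask, want)

  expect_warning(resample_mask(src, image_geometry(c(4L, 4L, 4L), c(1, 1, 1),
                 affine = rbind(cbind(diag(3), c(500, 500, 500)),
                                c(0, 0, 0, 1)))),
                 "empty")
})

test_that("coarse-and-back resampling keeps most of a convex mask", {
  # the motivating geometry: a segmentation drawn on a CT-resolution grid
  # (0.977 x 0.977 x 2.8 mm) carried to the PET grid (1.65 x 1.65 x 2.8 mm)
  # and back
  d <- c(48L, 48L, 16L)
  vs <- c(0.977, 0.977, 2.8)
  idx <- as.matrix(expand.grid(x = 1:48, y = 1:48, z = 1:16))
  w <- sweep(idx, 2, vs, `*`)
  ctr <- (c(49, 49, 17) / 2) * vs
  sphere <- array(sqrt(rowSums(sweep(w, 2, ctr)^2)) <= 12, d)
  src <- voi_mask(sphere, image_geometry(d, vs))
  pet_grid <- image_geometry(c(29L, 29L, 16L), c(1.65, 1.65, 2.8))
  back <- resample_mask(resample_mask(src, pet_grid), image_geometry(d, vs))
  overlap <- sum(back$mask & src$mask) / sum(src$mask)
  expect_gte(overlap, 0.95)
})

test_that("mean TAC is the per-frame in-mask average", {
  s <- default_frame_schedule()
  d <- c(6L, 6L, 4L)
  m <- array(FALSE, d); m[2:4, 2:4, 2:3] <- TRUE
  voi <- voi_mask(m, geom_of(d), "liver")

  # constant image: the mean is that constant in every frame
  pet <- array(7.5, c(d, 24L))
  expect_equal(mean_tac(pet, voi, s)$values, rep(7.5, 24))

  # random image: explicit loop oracle
  set.seed(34)
  pet2 <- array(rnorm(prod(d) * 24, 1000, 100), c(d, 24L))
  got <- mean_tac(pet2, voi, s)
  want <- vapply(1:24, function(fr) {
    fr3 <- pet2[, , , fr]
    mean(fr3[m])
  }, numeric(1))
  expect_equal(got$values, want, tolerance = 1e-12)
  expect_equal(got$label, "liver")

  expect_error(mean_tac(pet2[, , , 1], voi, s), "4D")
  expect_error(mean_tac(array(0, c(5, 5, 5, 24)), voi, s), "PET grid")
})

test_that("percentile TAC follows the threshold-and-average definition", {
  s <- default_frame_schedule()
  d <- c(10L, 10L, 1L)
  m <- array(TRUE, d)  # 100 voxels
  voi <- voi_mask(m, geom_of(d), "portal_vein")

  # values 1..100 in each frame: the linear-interpolation 90th percentile
  # is 90.1, so voxels 91..100 are at or above it and their mean is 95.5
  pet <- array(rep(1:100, 24), c(d, 24L))
  got <- percentile_tac(pet, voi, s, q = 90)
  thr <- unname(stats::quantile(1:100, 0.9, type = 7))
  expect_equal(thr, 90.1)
  expect_equal(got$values, rep(mean((1:100)[1:100 >= thr]), 24))
  expect_equal(got$values, rep(95.5, 24))

  # uniform in-mask values: any percentile rule returns that value
  flat <- array(42, c(d, 24L))
  expect_equal(percentile_tac(flat, voi, s, q = 90)$values, rep(42, 24))

  # q = 0 reduces exactly to the mean
  set.seed(35)
  pet2 <- array(runif(prod(d) * 24, 0, 1e4), c(d, 24L))
  expect_equal(percentile_tac(pet2, voi, s, q = 0)$values,
               mean_tac(pet2, voi, s)$values, tolerance = 1e-12)

  # the upper-percentile mean never falls below the plain mean
  p90 <- percentile_tac(pet2, voi, s, q = 90)$values
  expect_true(all(p90 >= mean_tac(pet2, voi, s)$values))

  # tiny masks fall back to the per-frame maximum
  small <- array(FALSE, d); small[1:3, 1, 1] <- TRUE
  sv <- voi_mask(small, geom_of(d), "portal_vein")
  expect_warning(pm <- percentile_tac(pet2, sv, s), "maximum")
  expect_equal(pm$values,
               vapply(1:24, function(fr) max(pet2[1:3, 1, 1, fr]),
                      numeric(1)))
})

test_that("NIfTI images and label masks round-trip through files", {
  d <- c(8L, 8L, 5L)
  nf <- 4L
  set.seed(36)
  arr <- array(runif(prod(d) * nf, 0, 1e4), c(d, nf))
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  img4 <- RNifti::asNifti(arr)
  RNifti::pixdim(img4) <- c(2, 2, 3, 1)
  RNifti::writeNifti(img4, f4)
  img <- read_pet_image(f4)
  expect_equal(dim(img$data), c(d, nf))
  expect_equal(img$data, arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(img$geometry$voxel_size, c(2, 2, 3), tolerance = 1e-6)

  # a 3D volume reads as a single-frame 4D array
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr[, , , 1]), f3)
  expect_equal(dim(read_pet_image(f3)$data), c(d, 1L))

  labels <- array(0L, d)
  labels[1:3, 1:3, 1:2] <- 5L
  labels[6:8, 6:8, 4:5] <- 9L
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(labels), fl)
  masks <- read_label_masks(fl, list(liver = 5, spleen = 9))
  expect_setequal(names(masks), c("liver", "spleen"))
  expect_equal(which(masks$liver$mask), which(labels == 5L))
  expect_equal(sum(masks$spleen$mask), 18)
  expect_error(read_label_masks(f4, list(liver = 5)), "3D")
})

test_that("study extraction applies the component filter and portal rule", {
  s <- default_frame_schedule()
  d <- c(12L, 12L, 6L)
  set.seed(37)

  pv_true <- seq(100, 2400, length.out = 24)
  pet <- array(0, c(d, 24L))
  core <- array(FALSE, d); core[4:7, 4:7, 2:4] <- TRUE
  spur <- array(FALSE, d); spur[11:12, 11:12, 6] <- TRUE
  for (fr in 1:24) {
    fr3 <- array(0, d)
    fr3[core] <- pv_true[fr]
    fr3[spur] <- 0.1 * pv_true[fr]   # spurious low blob
    pet[, , , fr] <- fr3
  }
  masks <- list(portal_vein = voi_mask(core | spur, geom_of(d),
                                       "portal_vein"))
  tacs <- extract_study_tacs(pet, masks, s, pv_percentile = 90)
  # the spurious blob is removed by the component filter, and the uniform
  # core makes the percentile mean equal the true value
  expect_equal(tacs$portal_vein$values, pv_true, tolerance = 1e-12)
  expect_equal(tacs$portal_vein$label, "portal_vein")

  # non-portal VOIs use the plain mean
  liver_mask <- voi_mask(core, geom_of(d), "liver")
  t2 <- extract_study_tacs(pet, list(liver = liver_mask), s)
  expect_equal(t2$liver$values, pv_true, tolerance = 1e-12)
})
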