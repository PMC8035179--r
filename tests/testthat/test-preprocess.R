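test_that("soft-tissue mask is the [-160, 240] HU band", {
  expect_true(all(soft_tissue_mask(flat_volume(40))))
  expect_false(any(soft_tissue_mask(flat_volume(-1000))))
  expect_error(soft_tissue_mask(flat_volume(5, modality = "SPECT")), "CT")
  # boundary values are inside the window
  v <- flat_volume(0)
  v$voxels[1] <- -160; v$voxels[2] <- 240; v$voxels[3] <- -161; v$voxels[4] <- 241
  m <- soft_tissue_mask(v)
  expect_true(m[1] && m[2])
  expect_false(m[3] || m[4])
})

test_that("the mask covers the phantom body but not bone or air", {
  st <- generate_study(exact_spec(seed = 13), 1)
  m <- soft_tissue_mask(st$ct20)
  expect_true(all(m[st$truth_labels$labels > 0]))          # glands inside
  expect_false(any(m[st$ct20$voxels <= -900]))             # air outside
  expect_false(any(m[st$ct20$voxels >= 600]))              # bone outside
})

test_that("the z-window equals exhaustive search over contiguous windows", {
  set.seed(14)
  for (i in 1:5) {
    st <- suppressWarnings(generate_study(tiny_spec(seed = 14 + i), 1))
    target <- c(48L, 32L, 16L)
    plan <- plan_crop(st$ct20, target)
    prof <- apply(soft_tissue_mask(st$ct20), 3, sum)
    nz <- length(prof)
    best <- -Inf; best_s <- NA
    for (s in 1:(nz - target[3] + 1)) {                    # brute force
      w <- sum(prof[s:(s + target[3] - 1)])
      if (w > best) { best <- w; best_s <- s }
    }
    expect_equal(plan$start[3], best_s)
  }
})

test_that("soft tissue confined to a slice band is contained in the window", {
  vox <- array(-1000, dim = c(20, 20, 64))
  vox[5:15, 5:15, 10:40] <- 40
  ct <- sq_volume(vox, spacing = c(2, 2, 2), modality = "CT")
  plan <- plan_crop(ct, c(20L, 20L, 32L))
  expect_true(plan$start[3] <= 10 && plan$stop[3] >= 40)
})

test_that("an already-target-shaped volume with tissue everywhere gets an identity plan", {
  ct <- flat_volume(40, dim = c(16L, 12L, 8L))
  plan <- plan_crop(ct, c(16L, 12L, 8L))
  expect_equal(plan$start, c(1L, 1L, 1L))
  expect_equal(plan$stop, c(16L, 12L, 8L))
  expect_equal(plan$pad_before + plan$pad_after, c(0L, 0L, 0L))
  out <- apply_crop(ct, plan)
  expect_equal(out$voxels, ct$voxels)
})

test_that("a body narrower than the target is padded symmetrically", {
  vox <- array(-1000, dim = c(10, 10, 10))
  vox[3:8, , ] <- 40
  ct <- sq_volume(vox, spacing = c(2, 2, 2), modality = "CT")
  plan <- plan_crop(ct, c(16L, 10L, 10L))
  expect_equal(plan$stop - plan$start + 1L + plan$pad_before + plan$pad_after,
               plan$target)
  expect_lte(abs(plan$pad_before[1] - plan$pad_after[1]), 1L)
  out <- apply_crop(ct, plan)
  expect_equal(dim(out$voxels), c(16L, 10L, 10L))
  expect_true(all(out$voxels[1:plan$pad_before[1], , ] == -1000))
})

test_that("plan_crop is translation-equivariant in z", {
  vox <- array(-1000, dim = c(12, 12, 40))
  vox[3:10, 3:10, 8:20] <- 40
  ct <- sq_volume(vox, spacing = c(2, 2, 2), modality = "CT")
  p1 <- plan_crop(ct, c(12L, 12L, 10L))
  vox2 <- array(-1000, dim = c(12, 12, 40))
  vox2[3:10, 3:10, 13:25] <- 40                      # shifted by 5 slices
  ct2 <- sq_volume(vox2, spacing = c(2, 2, 2), modality = "CT")
  p2 <- plan_crop(ct2, c(12L, 12L, 10L))
  expect_equal(p2$start[3] - p1$start[3], 5L)
})

test_that("crop and uncrop round-trip labels and conserve in-window glands", {
  st <- generate_study(tiny_spec(seed = 16), 1)
  target <- c(48L, 32L, 24L)
  plan <- plan_crop(st$ct20, target)
  labc <- apply_crop(st$truth_labels, plan)
  back <- uncrop(labc, plan)
  win <- list(plan$start[1]:plan$stop[1], plan$start[2]:plan$stop[2],
              plan$start[3]:plan$stop[3])
  expect_identical(back$labels[win[[1]], win[[2]], win[[3]]],
                   st$truth_labels$labels[win[[1]], win[[2]], win[[3]]])
  # CT pad voxels take -1000
  ctp <- apply_crop(st$ct20, plan)
  expect_equal(dim(ctp$voxels), target)
  # gland fully inside the window keeps its voxel count
  counts_full <- tabulate(st$truth_labels$labels, 4)
  counts_crop <- tabulate(labc$labels, 4)
  expect_equal(counts_crop, counts_full)
})

test_that("network normalisation maps the window to [0, 1]", {
  v <- flat_volume(40)
  v$voxels[1] <- -1000; v$voxels[2] <- 240; v$voxels[3] <- -160
  n <- normalize_for_network(v)
  expect_equal(n[4], 0.5)
  expect_equal(n[1], 0.0)
  expect_equal(n[2], 1.0)
  expect_equal(n[3], 0.0)
  expect_true(all(n >= 0 & n <= 1))
})

test_that("crop plans serialise to JSON and back", {
  st <- generate_study(tiny_spec(seed = 17), 1)
  plan <- plan_crop(st$ct20, c(48L, 32L, 16L))
  path <- tempfile(fileext = ".json")
  write_crop_plan(plan, path)
  r <- read_crop_plan(path)
  expect_equal(unclass(r), unclass(plan))
})

test_that("default phantoms keep all gland voxels inside the default crop", {
  # sweep: every gland voxel of each phantom falls inside the planned window
  n_ok <- 0L; n <- 12L
  for (i in seq_len(n)) {
    st <- suppressWarnings(generate_study(tiny_spec(seed = 18), i))
    plan <- plan_crop(st$ct20, c(48L, 32L, 24L))
    labc <- apply_crop(st$truth_labels, plan)
    ok <- identical(tabulate(labc$labels, 4),
                    tabulate(st$truth_labels$labels, 4))
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok, n - 1L)
})
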