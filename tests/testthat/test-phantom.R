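test_that("the generator is bit-identical for the same spec, seed and index", {
  sp <- tiny_spec(seed = 30)
  a <- generate_study(sp, 3)
  b <- generate_study(sp, 3)
  expect_identical(a$ct20$voxels, b$ct20$voxels)
  expect_identical(a$spect20$voxels, b$spect20$voxels)
  expect_identical(a$spect40$voxels, b$spect40$voxels)
  expect_identical(a$truth_labels$labels, b$truth_labels$labels)
  expect_identical(a$applied_misalignment, b$applied_misalignment)
  c <- generate_study(sp, 4)
  expect_false(identical(a$spect20$voxels, c$spect20$voxels))
})

test_that("zero misalignment range yields the identity transform", {
  st <- generate_study(tiny_spec(seed = 31, misalign_trans_mm = 0,
                                 misalign_rot_deg = 0), 1)
  expect_equal(st$applied_misalignment$translation, c(0, 0, 0))
  expect_equal(st$applied_misalignment$rotation, c(0, 0, 0))
})

test_that("noiseless zero-variance phantoms recover the programmed activity budget", {
  st <- generate_study(exact_spec(seed = 32), 1)
  expect_equal(st$programmed$pid20, c(0.36, 0.36, 0.17, 0.17))
  pid <- percent_injected_dose(st$spect20, st$truth_labels, st$injected_MBq)
  # per gland within 2% relative; both parotids together 0.72%
  expect_true(all(abs(pid - st$programmed$pid20) / st$programmed$pid20 < 0.02))
  expect_equal(sum(pid[1:2]), 0.72, tolerance = 0.02 * 0.72)
})

test_that("without PSF compensation the gland total is conserved and the VOI reads low", {
  st <- generate_study(exact_spec(seed = 32, psf_compensate = FALSE), 1)
  d20 <- 2^(-20 / (6.0058 * 60))
  vox_mL <- prod(st$spect20$spacing) / 1000
  total <- sum(st$spect20$voxels) * vox_mL                 # Bq, whole field
  programmed <- sum(st$programmed$pid20) / 100 +
    (5.0 + 2.0 + 0.3) / 100                                # background/thyroid/oral
  expect_equal(total, programmed * 555e6 * d20,
               tolerance = 0.01 * programmed * 555e6 * d20)
  pid <- percent_injected_dose(st$spect20, st$truth_labels, st$injected_MBq)
  # partial-volume loss at 10 mm FWHM is substantial for ~10-25 mL glands
  expect_true(all(pid < st$programmed$pid20))
})

test_that("programmed 40-min uptake obeys the %EF relation exactly", {
  sp <- tiny_spec(seed = 33)
  st <- generate_study(sp, 2)
  expect_equal(st$programmed$pid40,
               st$programmed$pid20 * (1 - st$programmed$ef / 100),
               tolerance = 1e-12)
})

test_that("cohorts are reproducible, distinct, and follow the volume distribution", {
  sp <- tiny_spec(seed = 34)
  co <- generate_cohort(sp, 5)
  expect_equal(length(unique(vapply(co, `[[`, "", "study_id"))), 5L)
  co2 <- generate_cohort(sp, 5)
  expect_identical(co[[3]]$spect20$voxels, co2[[3]]$spect20$voxels)
  expect_error(generate_cohort(sp, 0), "n")
  # law of large numbers on the drawn parotid volumes (50 studies = 100 glands)
  sp2 <- tiny_spec(seed = 35)
  vols <- unlist(lapply(generate_cohort(sp2, 50), function(s)
    s$programmed$volume_mL[1:2]))
  se <- 10.42 / sqrt(length(vols))
  # truncation of the normal at low volumes shifts the mean up slightly
  expect_lt(abs(mean(vols) - 23.43), 3 * se + 0.7)
})

test_that("the cohort manifest carries programmed values and misalignments", {
  co <- suppressWarnings(generate_cohort(tiny_spec(seed = 36), 3))
  man <- cohort_manifest(co)
  expect_equal(nrow(man), 12L)
  expect_true(all(c("study_id", "pid20", "ef", "mis_tx", "mis_rz") %in%
                    names(man)))
})

test_that("slice-wise rater simulation is exact for constant contours without jitter", {
  lab <- array(0L, dim = c(24, 24, 20))
  co <- (0:23) * 2
  disk <- outer((co - 24)^2, (co - 24)^2, "+") <= 100
  for (z in 5:15) lab[, , z][disk] <- 1L
  truth <- sq_labels(lab, spacing = c(2, 2, 2))
  out <- simulate_manual_labels(truth, every_k = 2L, jitter_prob = 0,
                                seed = 1)
  expect_identical(out$labels, truth$labels)
  expect_error(simulate_manual_labels(truth, every_k = 4L), "2 or 3")
})

test_that("empty gland classes stay empty in the simulated rater output", {
  st <- generate_study(tiny_spec(seed = 37), 1)
  lab <- st$truth_labels$labels
  lab[lab == 3L] <- 0L                       # resect a submandibular gland
  truth <- sq_labels(lab, spacing = st$truth_labels$spacing)
  out <- simulate_manual_labels(truth, 2L, 0.5, seed = 2)
  expect_equal(sum(out$labels == 3L), 0L)
  expect_gt(sum(out$labels == 1L), 0L)
})

test_that("two simulated raters agree at the expert Dice range", {
  sp <- tiny_spec(seed = 38)
  ds <- c()
  for (i in 1:5) {
    st <- generate_study(sp, i)
    r1 <- simulate_manual_labels(st$truth_labels, 2L,
                                 sp$rater_jitter_prob, seed = 100 + i)
    r2 <- simulate_manual_labels(st$truth_labels, 2L,
                                 sp$rater_jitter_prob, seed = 200 + i)
    for (g in 1:4) ds <- c(ds, dice(r1$labels == g, r2$labels == g))
  }
  expect_gt(mean(ds, na.rm = TRUE), 0.70)
  expect_lt(mean(ds, na.rm = TRUE), 0.95)
})
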