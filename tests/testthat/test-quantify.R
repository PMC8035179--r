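test_that("%ID follows the VOI-sum arithmetic exactly", {
  # 2000 voxels of 8 mm^3 at 5000 Bq/mL = 16 mL x 5000 Bq/mL = 0.08 MBq
  dim3 <- c(20L, 10L, 10L)
  vox <- array(0, dim = dim3)
  lab <- array(0L, dim = dim3)
  vox[1:20, 1:10, 1:10] <- 5000
  lab[1:20, 1:10, 1:10] <- 1L
  spect <- sq_volume(vox, spacing = c(2, 2, 2), modality = "SPECT",
                     time_min = 20)
  labels <- sq_labels(lab, spacing = c(2, 2, 2))
  pid <- percent_injected_dose(spect, labels, 555, decay_correct = FALSE)
  expect_equal(unname(pid["parotid_r"]), 100 * 0.08 / 555, tolerance = 1e-12)
  expect_equal(unname(pid["parotid_r"]), 0.014414, tolerance = 1e-4)
  # decay correction divides the reference by 2^(-t/T), T = 6.0058 h
  pid_dc <- percent_injected_dose(spect, labels, 555, decay_correct = TRUE)
  f <- 2^(-20 / (6.0058 * 60))                        # independent oracle
  expect_equal(unname(pid_dc["parotid_r"]), 100 * 0.08 / (555 * f),
               tolerance = 1e-12)
  expect_equal(unname(pid_dc["parotid_r"]), 0.01498, tolerance = 1e-3)
  # empty gland classes report zero uptake
  expect_equal(unname(pid["submandibular_l"]), 0)
})

test_that("%ID input contracts are enforced", {
  spect <- flat_volume(10, modality = "SPECT", time_min = 20)
  labels <- sq_labels(array(0L, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
  expect_error(percent_injected_dose(spect, labels, 555), "grid")
  labels8 <- sq_labels(array(0L, dim = c(8, 8, 8)), spacing = c(2, 2, 2))
  expect_error(percent_injected_dose(spect, labels8, 0), "positive")
})

test_that("excretion fraction implements 100 x (pid20 - pid40)/pid20", {
  expect_equal(excretion_fraction(0.30, 0.12), 60.0)
  expect_equal(excretion_fraction(0.30, 0.30), 0.0)
  expect_equal(excretion_fraction(0.25, 0.0), 100.0)
  expect_warning(ef0 <- excretion_fraction(0, 0.1), "undefined")
  expect_true(is.na(ef0))
  expect_error(excretion_fraction(0.3, -0.1), "non-negative")
})

test_that("the %EF identity holds exactly across the whole range", {
  e <- seq(0, 100, by = 0.5)
  pid20 <- 0.37
  expect_equal(excretion_fraction(rep(pid20, length(e)),
                                  pid20 * (1 - e / 100)),
               e, tolerance = 1e-12)
})

test_that("VOI volume is voxel count x voxel volume", {
  lab <- array(0L, dim = c(10L, 10L, 10L))
  lab[1:10, 1:10, 1:10] <- 0L
  lab[seq_len(1000)] <- 2L
  lm <- sq_labels(lab, spacing = c(2, 2, 2))
  v <- voi_volume(lm)
  expect_equal(unname(v["parotid_l"]), 8.0)
  expect_equal(unname(v["submandibular_r"]), 0.0)
})

test_that("phantom truth VOI volumes match the drawn gland volumes", {
  st <- generate_study(exact_spec(seed = 10), 1)
  v <- voi_volume(st$truth_labels)
  # within one voxel shell of the continuous ellipsoid volume
  sp <- st$truth_labels$spacing
  for (g in 1:4) {
    drawn <- st$programmed$volume_mL[g]
    r_eq <- (3 * drawn * 1000 / (4 * pi))^(1 / 3)
    shell <- 4 * pi * r_eq^2 * max(sp) / 1000   # mL
    expect_lt(abs(unname(v[g]) - drawn), shell)
  }
})

test_that("dose accounting reproduces the protocol arithmetic", {
  expect_equal(ct_effective_dose(60.31, 0.0031), 0.186961, tolerance = 1e-9)
  expect_equal(ct_effective_dose(0, 0.0031), 0)
  expect_equal(ct_effective_dose(100, 0.0031), 0.31)
  expect_equal(tracer_effective_dose(555, 0.013), 7.215)
  expect_equal(protocol_effective_dose(7.22, 0.19), 7.41)
  expect_equal(protocol_effective_dose(7.22, 0.37), 7.59)
  expect_equal(protocol_effective_dose(5.5, numeric(0)), 5.5)
  expect_error(ct_effective_dose(-1), ">= 0")
  expect_error(protocol_effective_dose(-1, 0.1), ">= 0")
})

test_that("%ID is linear in voxel values and inversely proportional to activity", {
  st <- generate_study(tiny_spec(seed = 11), 1)
  pid <- percent_injected_dose(st$spect20, st$truth_labels, st$injected_MBq)
  spect2 <- st$spect20
  spect2$voxels <- spect2$voxels * 3
  pid3 <- percent_injected_dose(spect2, st$truth_labels, st$injected_MBq)
  expect_equal(pid3, 3 * pid, tolerance = 1e-12)
  pid_half <- percent_injected_dose(st$spect20, st$truth_labels,
                                    2 * st$injected_MBq)
  expect_equal(pid_half, pid / 2, tolerance = 1e-12)
})
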