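#' Phantom specification
#'
#' Parameters of the synthetic head-and-neck CT/SPECT phantom. Defaults
#' reproduce the reference study conditions: gland volumes of 23.43 +/- 10.42
#' mL (parotid) and 11.57 +/- 4.48 mL (submandibular), 20-min uptake of
#' 0.36 +/- 0.11 %ID and 0.17 +/- 0.09 %ID, excretion fractions of
#' 61.41 +/- 9.04 % and 45.22 +/- 16.14 %, 555 MBq injected Tc-99m
#' pertechnetate, and a 10 mm FWHM SPECT point-spread function. Glands are
#' ellipsoids with jittered axis ratios placed laterally symmetric inside a
#' body ellipsoid; a spine cylinder supplies bone and a thyroid plus oral
#' cavity supply confounding activity. The seed fully determines all output.
#'
#' Programmed %ID is defined as the uptake an ideal noiseless truth-VOI
#' measurement reads: pre-blur gland activities are solved from a small
#' linear system accounting for PSF self-recovery, gland cross-talk and
#' spill-in from background/thyroid/oral sources (`psf_compensate = TRUE`).
#' With `psf_compensate = FALSE` the gland's total activity equals the
#' programmed value instead and the VOI reading falls short by the
#' partial-volume loss.
#'
#' @param shape,spacing grid dimensions and voxel size (mm).
#' @param body_semiaxes body ellipsoid semi-axes (mm), x lateral / y
#'   anterior-posterior / z axial.
#' @param gland_volume_mean,gland_volume_sd mL, `c(parotid, submandibular)`.
#' @param gland_hu mean HU, `c(parotid, submandibular)`.
#' @param soft_hu,bone_hu,air_hu tissue HU means.
#' @param hu_noise_sd CT noise SD in HU.
#' @param pid20_mean,pid20_sd programmed 20-min %ID per gland,
#'   `c(parotid, submandibular)`.
#' @param ef_mean,ef_sd programmed excretion fraction (%),
#'   `c(parotid, submandibular)`.
#' @param thyroid_pid,oral_pid,oral_pid40,background_pid %ID of the thyroid,
#'   oral cavity (20 and 40 min) and total soft-tissue background.
#' @param injected_MBq injected activity (MBq).
#' @param psf_fwhm_mm SPECT point-spread FWHM (mm).
#' @param count_scale detected counts per Bq; the default gives ~3% relative
#'   Poisson noise on a mean parotid VOI sum (~1000 counts).
#' @param misalign_trans_mm,misalign_rot_deg half-ranges of the uniform
#'   random rigid misalignment applied to the 40-min SPECT.
#' @param rater_jitter_prob per-slice probability of a one-voxel boundary
#'   dilation/erosion in the simulated manual rater; the default is
#'   calibrated so two simulated raters agree at a Dice of roughly 0.8.
#' @param seed base RNG seed.
#' @param decay apply physical Tc-99m decay to simulated activity.
#' @param psf_compensate see Details.
#' @param noiseless infinite-count limit: skip Poisson sampling.
#' @param half_life_h physical half-life (h).
#' @return An object of class `sq_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(112L, 80L, 48L),
                         spacing = c(2.2, 2.2, 4.0),
                         body_semiaxes = c(85, 62, 110),
                         gland_volume_mean = c(23.43, 11.57),
                         gland_volume_sd = c(10.42, 4.48),
                         gland_hu = c(15, 55),
                         soft_hu = 40, bone_hu = 700, air_hu = -1000,
                         hu_noise_sd = 15,
                         pid20_mean = c(0.36, 0.17),
                         pid20_sd = c(0.11, 0.09),
                         ef_mean = c(61.41, 45.22),
                         ef_sd = c(9.04, 16.14),
                         thyroid_pid = 2.0, oral_pid = 0.3, oral_pid40 = 0.9,
                         background_pid = 5.0,
                         injected_MBq = 555,
                         psf_fwhm_mm = 10,
                         count_scale = 5.5e-4,
                         misalign_trans_mm = 6, misalign_rot_deg = 5,
                         rater_jitter_prob = 0.8,
                         seed = 1L,
                         decay = TRUE, psf_compensate = TRUE,
                         noiseless = FALSE,
                         half_life_h = 6.0058) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_semiaxes = body_semiaxes,
               gland_volume_mean = gland_volume_mean,
               gland_volume_sd = gland_volume_sd,
               gland_hu = gland_hu, soft_hu = soft_hu, bone_hu = bone_hu,
               air_hu = air_hu, hu_noise_sd = hu_noise_sd,
               pid20_mean = pid20_mean, pid20_sd = pid20_sd,
               ef_mean = ef_mean, ef_sd = ef_sd,
               thyroid_pid = thyroid_pid, oral_pid = oral_pid,
               oral_pid40 = oral_pid40, background_pid = background_pid,
               injected_MBq = injected_MBq, psf_fwhm_mm = psf_fwhm_mm,
               count_scale = count_scale,
               misalign_trans_mm = misalign_trans_mm,
               misalign_rot_deg = misalign_rot_deg,
               rater_jitter_prob = rater_jitter_prob,
               seed = as.integer(seed), decay = decay,
               psf_compensate = psf_compensate, noiseless = noiseless,
               half_life_h = half_life_h)
  with(spec, {
    stopifnot(all(shape > 0), all(spacing > 0), all(body_semiaxes > 0),
              all(gland_volume_mean > 0), all(gland_volume_sd >= 0),
              all(pid20_mean > 0), all(ef_mean > 0), all(ef_mean < 100),
              injected_MBq > 0, psf_fwhm_mm > 0, count_scale > 0,
              misalign_trans_mm >= 0, misalign_rot_deg >= 0,
              rater_jitter_prob >= 0, rater_jitter_prob <= 1,
              half_life_h > 0)
  })
  structure(spec, class = "sq_phantom_spec")
}

# voxel-centre coordinate vectors (mm) of a grid with origin 0
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# logical mask of an ellipsoid given centre and semi-axes in mm
ellipsoid_mask <- function(shape, spacing, center, semi) {
  co <- grid_coords(shape, spacing)
  ax <- ((co[[1]] - center[1]) / semi[1])^2
  ay <- ((co[[2]] - center[2]) / semi[2])^2
  az <- ((co[[3]] - center[3]) / semi[3])^2
  outer(outer(ax, ay, "+"), az, "+") <= 1
}

decay_factor <- function(t_min, half_life_h) 2^(-t_min / (half_life_h * 60))

# Truncated-normal draw: redraws below `lo` (keeps sizes physical).
rnorm_trunc <- function(n, mean, sd, lo) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lo <- rep_len(lo, n)
  x <- rnorm(n, mean, sd)
  for (i in which(x < lo)) {
    while (x[i] < lo[i]) x[i] <- rnorm(1, mean[i], sd[i])
  }
  x
}

#' Generate one synthetic study
#'
#' Builds a full study record: a CT with body, spine and four gland
#' ellipsoids; truth labels; a 20-min SPECT whose expected truth-VOI activity
#' per gland equals programmed %ID x injected activity; and a 40-min SPECT
#' built from 40-min %ID = 20-min %ID x (1 - %EF/100), rigidly displaced by a
#' random transform recorded in `applied_misalignment`. Same spec, seed and
#' index give bit-identical output.
#'
#' @param spec an [phantom_spec()] object.
#' @param study_index positive integer distinguishing studies of a cohort.
#' @return An object of class `sq_study` with elements `ct20`, `spect20`,
#'   `spect40`, `truth_labels`, `applied_misalignment`, `injected_MBq`,
#'   `programmed` (data frame of drawn per-gland values) and `study_id`.
#' @export
generate_study <- function(spec, study_index = 1L) {
  stopifnot(inherits(spec, "sq_phantom_spec"), study_index >= 1)
  with_seed(derive_seed(spec$seed, study_index), {
    shape <- spec$shape; spacing <- spec$spacing
    vox_mL <- prod(spacing) / 1000
    ctr <- (shape - 1) / 2 * spacing

    # --- per-study draws ---------------------------------------------------
    gtype <- c(1L, 1L, 2L, 2L)          # parotid x2, submandibular x2
    vols <- rnorm_trunc(4, spec$gland_volume_mean[gtype],
                        spec$gland_volume_sd[gtype],
                        lo = 0.25 * spec$gland_volume_mean[gtype])
    pid20 <- rnorm_trunc(4, spec$pid20_mean[gtype], spec$pid20_sd[gtype],
                         lo = 0.1 * spec$pid20_mean[gtype])
    ef <- pmin(95, rnorm_trunc(4, spec$ef_mean[gtype], spec$ef_sd[gtype],
                               lo = 5))
    pid40 <- pid20 * (1 - ef / 100)

    # gland centres (mm, relative to body centre); right = smaller x
    side <- c(-1, 1, -1, 1)
    base_xyz <- rbind(c(52, 10, 24), c(52, 10, 24),
                      c(22, -26, -28), c(22, -26, -28))
    centers <- t(vapply(1:4, function(g) {
      ctr + c(side[g] * base_xyz[g, 1], base_xyz[g, 2], base_xyz[g, 3]) +
        runif(3, -3, 3)
    }, numeric(3)))
    ratios <- rbind(c(0.75, 0.95, 1.45), c(0.75, 0.95, 1.45),
                    c(1, 1, 1.1), c(1, 1, 1.1))
    ratios <- ratios * matrix(exp(rnorm(12, 0, 0.08)), 4, 3)

    gland_masks <- vector("list", 4)
    for (g in 1:4) {
      s <- (3 * vols[g] * 1000 / (4 * pi * prod(ratios[g, ])))^(1/3)
      gland_masks[[g]] <- ellipsoid_mask(shape, spacing, centers[g, ],
                                         ratios[g, ] * s)
    }

    body <- ellipsoid_mask(shape, spacing, ctr, spec$body_semiaxes)
    if (any(vols * 1000 > prod(spec$body_semiaxes) * 4 / 3 * pi))
      stop("gland volume exceeds body volume")
    spine <- {
      co <- grid_coords(shape, spacing)
      r2 <- outer((co[[1]] - ctr[1])^2, (co[[2]] - (ctr[2] + 34))^2, "+")
      array(rep(r2 <= 14^2, shape[3]), dim = shape) & body
    }
    thyroid <- ellipsoid_mask(shape, spacing, ctr + c(0, -34, -62),
                              c(22, 10, 18)) & body
    oral <- ellipsoid_mask(shape, spacing, ctr + c(0, -30, 48),
                           c(18, 14, 12)) & body

    labels <- array(0L, dim = shape)
    for (g in 1:4) labels[gland_masks[[g]] & labels == 0L] <- g

    # --- CT ----------------------------------------------------------------
    ct <- array(spec$air_hu, dim = shape)
    ct[body] <- spec$soft_hu
    ct[spine] <- spec$bone_hu
    for (g in 1:4) ct[labels == g] <- spec$gland_hu[gtype[g]]
    if (spec$hu_noise_sd > 0)
      ct <- ct + array(rnorm(length(ct), 0, spec$hu_noise_sd), dim = shape)
    ct <- pmax(ct, -1024)

    # --- SPECT source maps (unit total activity, blurred) --------------------
    sigma_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
    unit_map <- function(mask) {
      v <- sum(mask) * vox_mL
      conc <- array(0, dim = shape)
      conc[mask] <- 1 / v
      b <- gauss_blur_cpp(as.numeric(conc), shape, sigma_vox)
      dim(b) <- shape
      b
    }
    bg_mask <- body & labels == 0L & !thyroid & !oral & !spine
    B <- lapply(gland_masks, unit_map)
    B_bg <- unit_map(bg_mask); B_thy <- unit_map(thyroid); B_oral <- unit_map(oral)

    A_Bq <- spec$injected_MBq * 1e6
    d20 <- if (spec$decay) decay_factor(20, spec$half_life_h) else 1
    d40 <- if (spec$decay) decay_factor(40, spec$half_life_h) else 1

    voi_sum <- function(map, g) sum(map[labels == g]) * vox_mL
    M <- matrix(0, 4, 4)
    for (g in 1:4) for (h in 1:4) M[g, h] <- voi_sum(B[[h]], g)

    expected_spect <- function(pid_glands, d, oral_pid) {
      a_bg <- spec$background_pid / 100 * A_Bq * d
      a_thy <- spec$thyroid_pid / 100 * A_Bq * d
      a_oral <- oral_pid / 100 * A_Bq * d
      other <- a_bg * B_bg + a_thy * B_thy + a_oral * B_oral
      targets <- pid_glands / 100 * A_Bq * d
      if (spec$psf_compensate) {
        cvec <- vapply(1:4, function(g) sum(other[labels == g]) * vox_mL,
                       numeric(1))
        a <- solve(M, targets - cvec)
        if (any(a < 0)) {
          # spill-in from other sources already exceeds the programmed
          # target; the realisable floor replaces it and the programmed
          # table is updated by the caller via the "realized" attribute
          warning("PSF compensation clipped a negative gland activity")
          a <- pmax(a, 0)
        }
        realized <- as.numeric(M %*% a + cvec)
      } else {
        a <- targets
        realized <- targets
      }
      acc <- other
      for (g in 1:4) acc <- acc + a[g] * B[[g]]
      attr(acc, "realized_pid") <- 100 * realized / (A_Bq * d)
      acc
    }
    add_noise <- function(conc) {
      if (spec$noiseless) return(conc)
      lam <- conc * vox_mL * spec$count_scale
      cnt <- rpois(length(lam), as.vector(lam))
      array(cnt / (vox_mL * spec$count_scale), dim = shape)
    }

    exp20 <- expected_spect(pid20, d20, spec$oral_pid)
    pid20 <- attr(exp20, "realized_pid")
    spect20 <- sq_volume(add_noise(exp20), spacing, modality = "SPECT",
                         time_min = 20)

    exp40 <- expected_spect(pid40, d40, spec$oral_pid40)
    pid40 <- attr(exp40, "realized_pid")
    ef <- 100 * (pid20 - pid40) / pid20
    if (spec$misalign_trans_mm > 0 || spec$misalign_rot_deg > 0) {
      mis <- rigid_transform(runif(3, -spec$misalign_trans_mm,
                                   spec$misalign_trans_mm),
                             runif(3, -spec$misalign_rot_deg,
                                   spec$misalign_rot_deg))
    } else mis <- rigid_transform()
    exp40_vol <- sq_volume(exp40, spacing, modality = "SPECT", time_min = 40)
    exp40_moved <- apply_alignment(exp40_vol, mis)
    spect40 <- sq_volume(add_noise(exp40_moved$voxels), spacing,
                         modality = "SPECT", time_min = 40)

    programmed <- data.frame(gland = names(GLAND_CODES),
                             code = as.integer(GLAND_CODES),
                             volume_mL = vols, pid20 = pid20,
                             pid40 = pid40, ef = ef)
    structure(list(ct20 = sq_volume(ct, spacing, modality = "CT"),
                   spect20 = spect20, spect40 = spect40, ct40 = NULL,
                   injected_MBq = spec$injected_MBq,
                   truth_labels = sq_labels(labels, spacing = spacing),
                   applied_misalignment = mis,
                   programmed = programmed,
                   study_id = sprintf("phantom-%04d", as.integer(study_index))),
              class = "sq_study")
  })
}

#' @export
print.sq_study <- function(x, ...) {
  cat(sprintf("<sq_study> %s: injected %.0f MBq\n", x$study_id, x$injected_MBq))
  if (!is.null(x$programmed)) print(x$programmed, digits = 3)
  invisible(x)
}

#' Generate a cohort of synthetic studies
#'
#' @param spec an [phantom_spec()] object.
#' @param n number of studies (>= 1).
#' @return List of `sq_study`, reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec, n) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) generate_study(spec, i))
}

#' Cohort manifest table
#'
#' One row per study and gland with programmed %ID/%EF/volume and the
#' applied misalignment parameters (phantom assumptions, not measured data).
#'
#' @param cohort list of `sq_study`.
#' @return A data frame.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    p <- s$programmed
    p$study_id <- s$study_id
    m <- s$applied_misalignment
    p$mis_tx <- m$translation[1]; p$mis_ty <- m$translation[2]
    p$mis_tz <- m$translation[3]
    p$mis_rx <- m$rotation[1]; p$mis_ry <- m$rotation[2]
    p$mis_rz <- m$rotation[3]
    p[, c("study_id", setdiff(names(p), "study_id"))]
  }))
}

# --- simulated manual rater --------------------------------------------------

dilate2d <- function(m) {
  out <- m
  out[-1, ] <- out[-1, ] | m[-nrow(m), ]
  out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -ncol(m)]
  out[, -ncol(m)] <- out[, -ncol(m)] | m[, -1]
  out
}

erode2d <- function(m) !dilate2d(!m)

signed_dist2d <- function(m) {
  if (!any(m)) return(matrix(Inf, nrow(m), ncol(m)))
  edt2d_cpp(m) - edt2d_cpp(!m)
}

#' Simulate manual slice-wise gland segmentation
#'
#' Emulates the clinical drawing procedure: contours are drawn on every
#' k-th axial slice with occasional one-voxel boundary errors, and the
#' skipped slices are reconstructed by shape-based interpolation (linear
#' interpolation of per-slice signed distance maps) between adjacent drawn
#' slices. With `jitter_prob = 0` and a gland whose contour is constant
#' across slices the output reproduces the truth.
#'
#' @param truth an `sq_labels` truth map.
#' @param every_k draw on every 2nd or 3rd slice (2 or 3).
#' @param jitter_prob per drawn slice, probability of a random one-voxel
#'   dilation or erosion of the contour.
#' @param seed RNG seed for the rater.
#' @return An `sq_labels` with the simulated manual segmentation.
#' @export
simulate_manual_labels <- function(truth, every_k = 2L, jitter_prob = 0.5,
                                   seed = 1L) {
  stopifnot(inherits(truth, "sq_labels"))
  if (!every_k %in% c(2L, 3L)) stop("every_k must be 2 or 3")
  with_seed(seed, {
    d <- dim(truth$labels)
    out <- array(0L, dim = d)
    for (g in 1:4) {
      mask <- truth$labels == g
      zs <- which(apply(mask, 3, any))
      if (length(zs) == 0) next
      kept <- unique(c(seq(zs[1], zs[length(zs)], by = every_k),
                       zs[length(zs)]))
      drawn <- list()
      for (z in kept) {
        m <- mask[, , z]
        if (runif(1) < jitter_prob) {
          m2 <- if (runif(1) < 0.5) dilate2d(m) else erode2d(m)
          if (any(m2)) m <- m2
        }
        drawn[[as.character(z)]] <- m
      }
      newmask <- array(FALSE, dim = d)
      for (z in kept) newmask[, , z] <- drawn[[as.character(z)]]
      if (length(kept) > 1) {
        for (i in seq_len(length(kept) - 1)) {
          z0 <- kept[i]; z1 <- kept[i + 1]
          if (z1 - z0 < 2) next
          sd0 <- signed_dist2d(drawn[[as.character(z0)]])
          sd1 <- signed_dist2d(drawn[[as.character(z1)]])
          for (z in (z0 + 1):(z1 - 1)) {
            w <- (z - z0) / (z1 - z0)
            newmask[, , z] <- ((1 - w) * sd0 + w * sd1) < 0
          }
        }
      }
      out[newmask & out == 0L] <- g
    }
    sq_labels(out, spacing = truth$spacing, origin = truth$origin)
  })
}
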