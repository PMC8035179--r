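#' Per-gland percent injected dose
#'
#' Sums activity concentration x voxel volume over each gland's VOI and
#' divides by the reference activity: the injected activity, physically
#' decayed to acquisition time (Tc-99m half-life 6.0058 h) when
#' `decay_correct` is on, so that %ID reflects biology rather than decay.
#'
#' @param spect SPECT `sq_volume` (Bq/mL) with `time_min` set when decay
#'   correction is requested.
#' @param labels `sq_labels` on the same grid (resample first otherwise).
#' @param injected_MBq injected activity (MBq), > 0.
#' @param decay_correct logical, default `TRUE`.
#' @param half_life_h physical half-life in hours.
#' @return Named numeric vector of %ID for the four gland codes; glands with
#'   no voxels get 0.
#' @export
percent_injected_dose <- function(spect, labels, injected_MBq,
                                  decay_correct = TRUE,
                                  half_life_h = 6.0058) {
  stopifnot(inherits(spect, "sq_volume"), spect$modality == "SPECT",
            inherits(labels, "sq_labels"))
  if (!same_grid(spect, labels))
    stop("labels are not on the SPECT grid; resample_to_grid() first")
  if (!is.numeric(injected_MBq) || injected_MBq <= 0)
    stop("injected activity must be positive")
  ref_Bq <- injected_MBq * 1e6
  if (decay_correct) {
    if (is.na(spect$time_min))
      stop("decay correction requires the acquisition time")
    ref_Bq <- ref_Bq * decay_factor(spect$time_min, half_life_h)
  }
  vox_mL <- vox_mm3(spect) / 1000
  lab <- labels$labels
  vapply(GLAND_CODES, function(g) {
    100 * sum(spect$voxels[lab == g]) * vox_mL / ref_Bq
  }, numeric(1))
}

#' Percent excretion fraction
#'
#' `%EF = 100 x (pid20 - pid40) / pid20`. Undefined (returned as `NA` with a
#' warning) when the 20-min %ID is not positive, so that missing excretion is
#' reported as missing rather than as zero.
#'
#' @param pid20,pid40 20-min and 40-min %ID (vectors recycle).
#' @return %EF, same length as the inputs.
#' @export
excretion_fraction <- function(pid20, pid40) {
  stopifnot(is.numeric(pid20), is.numeric(pid40))
  if (any(pid40 < 0)) stop("pid40 must be non-negative")
  bad <- pid20 <= 0
  if (any(bad))
    warning("undefined %EF for non-positive 20-min %ID; reported as NA")
  ef <- 100 * (pid20 - pid40) / pid20
  ef[bad] <- NA_real_
  ef
}

#' Per-gland VOI volume
#'
#' @param labels an `sq_labels`.
#' @return Named numeric vector of gland volumes in mL
#'   (voxel count x voxel volume / 1000).
#' @export
voi_volume <- function(labels) {
  stopifnot(inherits(labels, "sq_labels"))
  vox_mL <- vox_mm3(labels) / 1000
  counts <- tabulate(labels$labels, nbins = 4L)
  setNames(counts * vox_mL, names(GLAND_CODES))
}

#' CT effective dose from dose-length product
#'
#' @param dlp_mGy_cm dose-length product (mGy cm).
#' @param k region-specific conversion coefficient (mSv per mGy cm), default
#'   0.0031 for the head.
#' @return Effective dose in mSv.
#' @export
ct_effective_dose <- function(dlp_mGy_cm, k = 0.0031) {
  if (any(dlp_mGy_cm < 0) || any(k < 0)) stop("dose inputs must be >= 0")
  dlp_mGy_cm * k
}

#' Tracer effective dose
#'
#' @param injected_MBq injected activity (MBq).
#' @param coeff effective-dose coefficient (mSv/MBq), default 0.013 for
#'   Tc-99m pertechnetate.
#' @return Effective dose in mSv.
#' @export
tracer_effective_dose <- function(injected_MBq, coeff = 0.013) {
  if (injected_MBq < 0 || coeff < 0) stop("dose inputs must be >= 0")
  injected_MBq * coeff
}

#' Total protocol effective dose
#'
#' @param tracer_mSv tracer effective dose (mSv).
#' @param ct_session_mSv numeric vector of per-CT-session effective doses.
#' @return tracer dose + sum of CT session doses (mSv).
#' @export
protocol_effective_dose <- function(tracer_mSv, ct_session_mSv = numeric(0)) {
  if (tracer_mSv < 0 || any(ct_session_mSv < 0))
    stop("dose components must be >= 0")
  tracer_mSv + sum(ct_session_mSv)
}

#' Quantify one study
#'
#' Computes the per-gland VOI volume, 20-min %ID, 40-min %ID and %EF for one
#' study using a given label source. The 40-min SPECT can be brought into the
#' 20-min CT frame first: `correct = "estimate"` registers it to the 20-min
#' SPECT by [estimate_alignment()], `correct = "none"` quantifies it as
#' stored, and an `sq_transform` supplies a known correction directly.
#'
#' @param study an `sq_study`.
#' @param labels label source; default the study's truth labels.
#' @param correct `"estimate"`, `"none"`, or an `sq_transform` applied to the
#'   40-min SPECT.
#' @param decay_correct passed to [percent_injected_dose()].
#' @param sum_lr also report left+right sums per gland type.
#' @return Data frame with one row per gland: `gland`, `voi_mL`, `pid20`,
#'   `pid40`, `ef`.
#' @export
quantify_study <- function(study, labels = study$truth_labels,
                           correct = "estimate", decay_correct = TRUE,
                           sum_lr = FALSE) {
  stopifnot(inherits(study, "sq_study"), inherits(labels, "sq_labels"))
  spect40 <- study$spect40
  if (inherits(correct, "sq_transform")) {
    spect40 <- apply_alignment(spect40, correct)
  } else if (identical(correct, "estimate")) {
    tr <- estimate_alignment(spect40, study$spect20)
    spect40 <- apply_alignment(spect40, tr)
  } else if (!identical(correct, "none")) {
    stop("correct must be 'estimate', 'none', or an sq_transform")
  }
  pid20 <- percent_injected_dose(study$spect20, labels, study$injected_MBq,
                                 decay_correct = decay_correct)
  pid40 <- percent_injected_dose(spect40, labels, study$injected_MBq,
                                 decay_correct = decay_correct)
  out <- data.frame(study_id = study$study_id, gland = names(GLAND_CODES),
                    voi_mL = as.numeric(voi_volume(labels)),
                    pid20 = as.numeric(pid20), pid40 = as.numeric(pid40))
  out$ef <- suppressWarnings(excretion_fraction(out$pid20, out$pid40))
  if (sum_lr) {
    type <- c("parotid", "parotid", "submandibular", "submandibular")
    agg <- aggregate(cbind(voi_mL, pid20, pid40) ~ type,
                     data = cbind(out, type = type), FUN = sum)
    agg$ef <- suppressWarnings(excretion_fraction(agg$pid20, agg$pid40))
    agg <- data.frame(study_id = study$study_id, gland = agg$type,
                      voi_mL = agg$voi_mL, pid20 = agg$pid20,
                      pid40 = agg$pid40, ef = agg$ef)
    out <- rbind(out, agg)
  }
  out
}
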