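#' Pipeline configuration
#'
#' Bundles all stage settings of the end-to-end protocol into one
#' serialisable object: phantom spec, crop target, network config,
#' registration search ranges, quantification flags, dose constants and the
#' global seed. Reloading a saved config reproduces the run.
#'
#' @param phantom an [phantom_spec()].
#' @param n_studies number of phantom studies to generate.
#' @param crop_target crop / network input shape.
#' @param unet an [unet_config()]; its `input_shape` must equal
#'   `crop_target`.
#' @param n_train number of studies used for training (the rest are
#'   evaluated); `NULL` trains on all and evaluates in-sample.
#' @param register_search search half-ranges for [estimate_alignment()].
#' @param decay_correct,sum_lr quantification flags.
#' @param tracer_coeff_mSv_MBq,dlp_mGy_cm,ct_dose_k dose constants.
#' @param seed global seed.
#' @return Object of class `sq_pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(), n_studies = 12L,
                            crop_target = c(96L, 64L, 32L),
                            unet = unet_config(input_shape = crop_target),
                            n_train = NULL,
                            register_search = list(trans = 8, rot = 8),
                            decay_correct = TRUE, sum_lr = FALSE,
                            tracer_coeff_mSv_MBq = 0.013,
                            dlp_mGy_cm = 60.31, ct_dose_k = 0.0031,
                            seed = 1L) {
  if (!identical(as.integer(crop_target), unet$input_shape))
    stop("unet input_shape must equal crop_target")
  structure(list(phantom = phantom, n_studies = as.integer(n_studies),
                 crop_target = as.integer(crop_target), unet = unet,
                 n_train = n_train, register_search = register_search,
                 decay_correct = decay_correct, sum_lr = sum_lr,
                 tracer_coeff_mSv_MBq = tracer_coeff_mSv_MBq,
                 dlp_mGy_cm = dlp_mGy_cm, ct_dose_k = ct_dose_k,
                 seed = as.integer(seed)),
            class = "sq_pipeline_config")
}

#' Run the end-to-end protocol
#'
#' Generates (or accepts) a cohort, preprocesses and trains the segmentation
#' network, segments each evaluation study, registers the 40-min SPECT to
#' the 20-min frame, quantifies per-gland %ID/%EF with the automatic labels
#' and compares them against the truth labels. When `out_dir` is given, the
#' quantification table (CSV, numbers at fixed 6-significant-digit
#' formatting), agreement report, config snapshot and a run log are written
#' there.
#'
#' @param config an [pipeline_config()].
#' @param cohort optional pre-generated list of `sq_study`; generated from
#'   `config$phantom` otherwise.
#' @param model optional pre-trained `sq_unet`; trained otherwise.
#' @param out_dir optional output directory.
#' @return List with `quant` (per-study gland table), `agreement`
#'   (`sq_agreement` of automatic vs truth), `model`, `dose` (protocol dose
#'   summary), and `eval_idx`.
#' @export
run_protocol <- function(config, cohort = NULL, model = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sq_pipeline_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("run started %s", format(t0)),
                 sprintf("seed %d", config$seed))
  if (is.null(cohort))
    cohort <- generate_cohort(config$phantom, config$n_studies)
  n <- length(cohort)
  n_train <- config$n_train
  if (is.null(n_train)) { train_idx <- seq_len(n); eval_idx <- seq_len(n) }
  else { train_idx <- seq_len(n_train); eval_idx <- setdiff(seq_len(n), train_idx) }

  prep <- prepare_training_data(cohort, config$crop_target,
                                coord_channels = config$unet$coord_channels)
  if (is.null(model)) {
    model <- unet_train(prep$samples[train_idx], config$unet)
    log_lines <- c(log_lines, sprintf("trained %d epochs on %d studies",
                                      config$unet$epochs, length(train_idx)))
  }

  auto_labels <- list()
  quant <- list()
  for (i in eval_idx) {
    st <- cohort[[i]]
    probs <- predict(model, prep$samples[[i]]$x)
    lab_c <- postprocess_labels(probs, st$ct20$spacing,
                                origin = crop_origin(prep$plans[[i]],
                                                     st$ct20))
    auto_labels[[as.character(i)]] <- uncrop(lab_c, prep$plans[[i]])
    tr <- estimate_alignment(st$spect40, st$spect20,
                             search = config$register_search)
    quant[[as.character(i)]] <-
      quantify_study(st, labels = auto_labels[[as.character(i)]],
                     correct = tr, decay_correct = config$decay_correct,
                     sum_lr = config$sum_lr)
  }
  quant_tab <- do.call(rbind, quant)
  rownames(quant_tab) <- NULL

  agreement <- compare_segmentations(cohort[eval_idx], labels_a = "truth",
                                     labels_b = unname(auto_labels),
                                     decay_correct = config$decay_correct)

  tracer <- tracer_effective_dose(config$phantom$injected_MBq,
                                  config$tracer_coeff_mSv_MBq)
  ct1 <- ct_effective_dose(config$dlp_mGy_cm, config$ct_dose_k)
  dose <- list(tracer_mSv = tracer, ct_session_mSv = ct1,
               protocol_mSv = protocol_effective_dose(round(tracer, 2),
                                                      round(ct1, 2)))
  log_lines <- c(log_lines,
                 sprintf("evaluated %d studies; mean DSC %.3f; %%ID MAPE %.2f%%",
                         length(eval_idx), agreement$dsc["mean"],
                         agreement$mape["mean"]),
                 sprintf("run finished %s (%.1f s)", format(Sys.time()),
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    qt <- quant_tab
    for (cc in c("voi_mL", "pid20", "pid40", "ef"))
      qt[[cc]] <- sprintf("%.6g", qt[[cc]])
    write.csv(qt, file.path(out_dir, "quant.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(agreement$per_gland, file.path(out_dir, "agreement.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(serialize_config(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(quant = quant_tab, agreement = agreement, model = model,
       dose = dose, eval_idx = eval_idx, log = log_lines)
}

serialize_config <- function(config) {
  list(phantom = unclass(config$phantom),
       n_studies = config$n_studies,
       crop_target = config$crop_target,
       unet = unclass(config$unet),
       n_train = config$n_train,
       register_search = config$register_search,
       decay_correct = config$decay_correct, sum_lr = config$sum_lr,
       tracer_coeff_mSv_MBq = config$tracer_coeff_mSv_MBq,
       dlp_mGy_cm = config$dlp_mGy_cm, ct_dose_k = config$ct_dose_k,
       seed = config$seed)
}

#' Read a pipeline config from JSON
#'
#' @param path file written by [run_protocol()]'s config snapshot (or by
#'   hand in the same layout).
#' @return An `sq_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- do.call(phantom_spec, x$phantom[names(x$phantom) %in%
                                          names(formals(phantom_spec))])
  uc <- do.call(unet_config, x$unet[names(x$unet) %in%
                                      names(formals(unet_config))])
  pipeline_config(phantom = ph, n_studies = x$n_studies,
                  crop_target = x$crop_target, unet = uc,
                  n_train = x$n_train,
                  register_search = as.list(x$register_search),
                  decay_correct = x$decay_correct, sum_lr = x$sum_lr,
                  tracer_coeff_mSv_MBq = x$tracer_coeff_mSv_MBq,
                  dlp_mGy_cm = x$dlp_mGy_cm, ct_dose_k = x$ct_dose_k,
                  seed = x$seed)
}
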