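#' Experiment configuration
#'
#' Describes a full synthetic-cohort experiment: how many subjects, how organ
#' volumes and kinetics are drawn, how images are acquired, which VOI
#' propagation strategies and recovery-coefficient modes are compared, and
#' where reports go. Defaults mirror the clinical study design: 18 subjects,
#' two kidneys plus a spleen control each, kidney parenchymal volumes in
#' 27.7-248.8 mL (mean 130.6, SD 46.1), spleen volumes around 183.5 mL,
#' kidney volume multipliers `{D0 1.0877, D1 1.1007, D2 1.0110, D7 1.0110}`,
#' imaging near 4/24/48/168 h, 4.42 mm SPECT voxels, and a 12 mm FWHM PSF.
#'
#' @param n_subjects Number of subjects (>= 1; default 18).
#' @param seed Integer seed governing all randomness of the experiment.
#' @param strategies Subset of
#'   `c("reference","single_D0","single_D1","single_D2","single_D7")`; the
#'   reference strategy (tag-matched VOIs) must be present.
#' @param rc_modes Subset of `c("fixed", "specific")`; `"fixed"` uses RC =
#'   0.85, `"specific"` computes a shape-specific Gaussian-PSF RC per VOI.
#' @param acquisition An [acquisition_spec()].
#' @param constants A [dosimetry_constants()].
#' @param align Logical: apply integer-voxel VOI alignment before
#'   quantification (default `FALSE`).
#' @param max_shift_voxels Alignment search radius when `align = TRUE`.
#' @param kidney_volume_mean,kidney_volume_sd,kidney_volume_range Sampling of
#'   per-kidney baseline volumes (truncated normal, mL).
#' @param spleen_volume_mean,spleen_volume_sd,spleen_volume_range Same for
#'   the spleen control.
#' @param kidney_multipliers,spleen_multipliers Named per-tag volume
#'   multipliers for the generated organs (defaults:
#'   [default_volume_multipliers()]).
#' @param kinetics List of generating-kinetics settings: rates `b`, `c`, `d`
#'   (1/h), `peak_conc_Bq_mL` (target peak concentration at baseline volume),
#'   `subject_cv` (lognormal coefficient of variation applied per subject),
#'   `mode` (`"activity_primary"` or `"concentration_primary"`).
#' @param pooling `"kidneys"` (left+right pooled, 2 n pairs) or `"subjects"`
#'   (per-subject kidney mean, n pairs) for the agreement statistics.
#' @param include_spleen Include the spleen control organ.
#' @param output_dir Optional directory; when set, [run_experiment()] writes
#'   the CSV/JSON report there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 18L,
                              seed = 1L,
                              strategies = c("reference", "single_D0",
                                             "single_D1", "single_D2",
                                             "single_D7"),
                              rc_modes = c("fixed", "specific"),
                              acquisition = acquisition_spec(seed = seed),
                              constants = dosimetry_constants(),
                              align = FALSE,
                              max_shift_voxels = 2L,
                              kidney_volume_mean = 130.6,
                              kidney_volume_sd = 46.1,
                              kidney_volume_range = c(27.7, 248.8),
                              spleen_volume_mean = 183.5,
                              spleen_volume_sd = 115.1,
                              spleen_volume_range = c(60, 380),
                              kidney_multipliers = default_volume_multipliers("kidney"),
                              spleen_multipliers = default_volume_multipliers("spleen"),
                              kinetics = list(b = 0.01, c = 0.05, d = 0.7,
                                              peak_conc_Bq_mL = 3e5,
                                              subject_cv = 0.15,
                                              mode = "activity_primary"),
                              pooling = c("kidneys", "subjects"),
                              include_spleen = TRUE,
                              output_dir = NULL) {
  pooling <- match.arg(pooling)
  known <- c("reference", "single_D0", "single_D1", "single_D2", "single_D7")
  if (!all(strategies %in% known))
    stop("unknown strategy; allowed: ", paste(known, collapse = ", "))
  if (!"reference" %in% strategies)
    stop("the reference strategy must be present")
  if (!all(rc_modes %in% c("fixed", "specific")) || length(rc_modes) == 0)
    stop("rc_modes must be a subset of fixed/specific")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 strategies = strategies, rc_modes = rc_modes,
                 acquisition = acquisition, constants = constants,
                 align = isTRUE(align),
                 max_shift_voxels = as.integer(max_shift_voxels),
                 kidney_volume_mean = kidney_volume_mean,
                 kidney_volume_sd = kidney_volume_sd,
                 kidney_volume_range = kidney_volume_range,
                 spleen_volume_mean = spleen_volume_mean,
                 spleen_volume_sd = spleen_volume_sd,
                 spleen_volume_range = spleen_volume_range,
                 kidney_multipliers = kidney_multipliers,
                 spleen_multipliers = spleen_multipliers,
                 kinetics = kinetics, pooling = pooling,
                 include_spleen = isTRUE(include_spleen),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Top-level keys are [experiment_config()] arguments; `acquisition` and
#' `constants` may be given as nested maps.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$acquisition))
    raw$acquisition <- do.call(acquisition_spec, raw$acquisition)
  if (!is.null(raw$constants))
    raw$constants <- do.call(dosimetry_constants, raw$constants)
  if (!is.null(raw$kidney_volume_range))
    raw$kidney_volume_range <- as.numeric(raw$kidney_volume_range)
  if (!is.null(raw$spleen_volume_range))
    raw$spleen_volume_range <- as.numeric(raw$spleen_volume_range)
  do.call(experiment_config, raw)
}

ALL_TAGS <- c("B_L", "D0", "D1", "D2", "D7")
POST_TAGS <- c("D0", "D1", "D2", "D7")

rtruncnorm1 <- function(mean, sd, range) {
  for (i in 1:1000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  mean(range)
}

# Draw one subject's anatomy and generating kinetics. Organ layout keeps the
# three organs well separated so PSF cross-talk is negligible.
sample_subject <- function(config, subject_id) {
  kr <- config$kidney_volume_range
  vL <- rtruncnorm1(config$kidney_volume_mean, config$kidney_volume_sd, kr)
  vR <- rtruncnorm1(config$kidney_volume_mean, config$kidney_volume_sd, kr)
  organs <- list(
    organ_spec("kidney_L", vL, shape = "bean",
               shape_params = list(axis_ratios = c(1.6, 1.0, 0.85),
                                   concavity_depth = 0.45),
               center_mm = c(0, -10, -95) + stats::runif(3, -2, 2),
               volume_multipliers = config$kidney_multipliers),
    organ_spec("kidney_R", vR, shape = "bean",
               shape_params = list(axis_ratios = c(1.6, 1.0, 0.85),
                                   concavity_depth = 0.45),
               center_mm = c(0, -10, 95) + stats::runif(3, -2, 2),
               volume_multipliers = config$kidney_multipliers))
  if (config$include_spleen) {
    vS <- rtruncnorm1(config$spleen_volume_mean, config$spleen_volume_sd,
                      config$spleen_volume_range)
    organs <- c(organs, list(
      organ_spec("spleen", vS, shape = "ellipsoid",
                 shape_params = list(axis_ratios = c(1.3, 1.0, 0.8)),
                 center_mm = c(0, 52, 0) + stats::runif(3, -2, 2),
                 volume_multipliers = config$spleen_multipliers)))
  }
  kin <- config$kinetics
  cv <- if (is.null(kin$subject_cv)) 0 else kin$subject_cv
  truths <- lapply(organs, function(org) {
    b <- kin$b * exp(stats::rnorm(1, 0, cv))
    c_ <- kin$c * exp(stats::rnorm(1, 0, cv))
    d <- kin$d * exp(stats::rnorm(1, 0, cv))
    # relative amplitudes 2:1, scaled so the baseline-volume peak
    # concentration hits the configured target
    rel <- triexp_params(2, 1, b, c_, d)
    peak_rel <- max(triexp_value(rel, seq(0, 200, by = 0.25)))
    target_peak <- kin$peak_conc_Bq_mL * exp(stats::rnorm(1, 0, cv))
    scale <- if (identical(kin$mode, "concentration_primary"))
      target_peak / peak_rel
    else target_peak * org$base_volume_mL / peak_rel
    kinetics_truth(2 * scale, 1 * scale, b, c_, d,
                   mode = if (is.null(kin$mode)) "activity_primary" else kin$mode)
  })
  names(truths) <- vapply(organs, `[[`, "", "name")
  list(id = subject_id, organs = organs, truths = truths)
}

subject_ct_geometry <- function() {
  default_ct_geometry(extent_mm = c(150, 170, 290), center_mm = c(0, 20, 0))
}

log_stage <- function(logfile, subject, organ, tag, stage, t0,
                      verbose = FALSE) {
  if (is.null(logfile) && !verbose) return(invisible(NULL))
  line <- sprintf("subject=%s organ=%s tag=%s stage=%s elapsed=%.2fs",
                  subject, organ, tag, stage,
                  as.numeric(proc.time()[3]) - t0)
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

#' Run the full synthetic-cohort experiment
#'
#' For every subject: builds CT-resolution phantoms at `B_L, D0, D1, D2, D7`
#' (kidney volumes follow the per-tag multipliers; the spleen is the no-change
#' control), renders SPECT-like images at the four post-administration time
#' points, quantifies mean kidney concentrations under each VOI propagation
#' strategy (tag-matched reference vs a single delineation propagated without
#' geometric change), applies the recovery-coefficient correction per mode,
#' fits the tri-exponential model, integrates to TIAC, and converts to
#' absorbed dose. Cohort-level Bland-Altman and paired Wilcoxon comparisons
#' are then computed for volumes (each tag vs baseline), concentrations
#' (delineation-tag vs reference at each measurement tag), and doses (each
#' single-VOI strategy vs reference, per RC mode).
#'
#' @param config An [experiment_config()].
#' @param logfile Optional path for the structured stage log.
#' @param verbose Echo log lines via `message()` (default `FALSE`).
#' @return An object of class `experiment_result` with data.frames `volumes`,
#'   `concentrations`, `doses`, `volume_agreement`, `conc_agreement`,
#'   `dose_agreement`, `rc_cross` (fixed-vs-specific reference doses), and
#'   the `config`. If `config$output_dir` is set the report is also written
#'   there (see [write_report()]).
#' @export
run_experiment <- function(config, logfile = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- as.numeric(proc.time()[3])
  set.seed(config$seed)
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) sample_subject(config, i))
  ct_geom <- subject_ct_geometry()
  spect_geom <- default_spect_geometry(ct_geom)
  acq <- config$acquisition
  vol_rows <- list(); conc_rows <- list(); dose_rows <- list()
  for (sub in subjects) {
    res <- tryCatch(
      process_subject(sub, config, ct_geom, spect_geom, acq, logfile, t0, verbose),
      error = function(e)
        stop(sprintf("subject %d failed: %s", sub$id, conditionMessage(e)),
             call. = FALSE))
    vol_rows[[sub$id]] <- res$volumes
    conc_rows[[sub$id]] <- res$concentrations
    dose_rows[[sub$id]] <- res$doses
  }
  volumes <- do.call(rbind, vol_rows)
  concentrations <- do.call(rbind, conc_rows)
  doses <- do.call(rbind, dose_rows)
  vol_agree <- volume_change_analysis(volumes, pooling = config$pooling)
  conc_agree <- concentration_agreement(concentrations, config)
  dose_out <- dose_agreement(doses, config)
  out <- structure(list(volumes = volumes, concentrations = concentrations,
                        doses = doses, volume_agreement = vol_agree,
                        conc_agreement = conc_agree,
                        dose_agreement = dose_out$vs_reference,
                        rc_cross = dose_out$rc_cross,
                        config = config),
                   class = "experiment_result")
  if (!is.null(config$output_dir)) write_report(out, config$output_dir)
  out
}

# all per-subject imaging, quantification, fitting and dose work
process_subject <- function(sub, config, ct_geom, spect_geom, acq, logfile, t0, verbose = FALSE) {
  organs <- sub$organs
  organ_names <- vapply(organs, `[[`, "", "name")
  times_h <- acq$times_h[POST_TAGS]
  if (acq$jitter) {
    win <- acquisition_windows()
    times_h <- vapply(POST_TAGS, function(tg)
      stats::runif(1, win[[tg]][1], win[[tg]][2]), 0)
    names(times_h) <- POST_TAGS
  }
  phantoms <- list(); svois <- list()
  vol_rows <- list()
  for (tag in ALL_TAGS) {
    ph <- make_phantom(organs, tag, ct_geom)
    phantoms[[tag]] <- ph
    # CT delineations transferred to the SPECT grid (fractional coverage)
    svois[[tag]] <- lapply(ph$vois, resample_voi, target = spect_geom,
                           binarize_threshold = "fractional")
    vol_rows[[tag]] <- data.frame(subject = sub$id, organ = organ_names,
                                  tag = tag,
                                  volume_mL = unname(ph$volumes_mL[organ_names]))
    log_stage(logfile, sub$id, "all", tag, "phantom", t0, verbose)
  }
  images <- list()
  for (ti in seq_along(POST_TAGS)) {
    tag <- POST_TAGS[ti]
    conc_true <- vapply(seq_along(organs), function(i)
      true_concentration(sub$truths[[i]], organs[[i]], times_h[[tag]], tag), 0)
    noise_seed <- config$seed + 7919L * sub$id + ti
    images[[tag]] <- render_spect(phantoms[[tag]]$labels, conc_true, acq,
                                  spect_geometry = spect_geom,
                                  rng = noise_seed)
    log_stage(logfile, sub$id, "all", tag, "render", t0, verbose)
  }
  kidney_names <- organ_names[grepl("^kidney", organ_names)]
  conc_rows <- list(); dose_rows <- list()
  for (organ in kidney_names) {
    # per-delineation-tag specific RCs (shape- and volume-dependent)
    rcs <- lapply(ALL_TAGS, function(tag)
      compute_rc(svois[[tag]][[organ]], acq$psf_fwhm_mm))
    names(rcs) <- ALL_TAGS
    for (strategy in config$strategies) {
      delin <- function(tag) if (strategy == "reference") tag
        else sub("single_", "", strategy)
      for (rc_mode in config$rc_modes) {
        series_conc <- numeric(length(POST_TAGS))
        meas <- numeric(length(POST_TAGS))
        rc_vals <- numeric(length(POST_TAGS))
        for (ti in seq_along(POST_TAGS)) {
          tag <- POST_TAGS[ti]
          v <- svois[[delin(tag)]][[organ]]
          if (config$align)
            v <- align_voi(images[[tag]], v, config$max_shift_voxels)
          m <- mean_concentration(images[[tag]], v)
          rc <- if (rc_mode == "fixed") fixed_rc() else rcs[[delin(tag)]]
          meas[ti] <- m
          rc_vals[ti] <- rc$value
          series_conc[ti] <- apply_rc(m, rc)
        }
        conc_rows[[length(conc_rows) + 1L]] <-
          data.frame(subject = sub$id, organ = organ, strategy = strategy,
                     rc_mode = rc_mode, tag = POST_TAGS,
                     time_h = unname(times_h[POST_TAGS]),
                     conc_measured_Bq_mL = meas, rc = rc_vals,
                     conc_corrected_Bq_mL = series_conc)
        fit <- fit_triexp(ta_series(unname(times_h[POST_TAGS]), series_conc))
        dose <- absorbed_dose(tiac_to_decays_per_mL(fit$tiac),
                              config$constants)
        dose_rows[[length(dose_rows) + 1L]] <-
          data.frame(subject = sub$id, organ = organ, strategy = strategy,
                     rc_mode = rc_mode, tiac_Bq_h_per_mL = fit$tiac,
                     sse = fit$sse, dose_Gy = dose)
      }
    }
    log_stage(logfile, sub$id, organ, "-", "fit+dose", t0, verbose)
  }
  list(volumes = do.call(rbind, vol_rows),
       concentrations = do.call(rbind, conc_rows),
       doses = do.call(rbind, dose_rows))
}

#' Baseline-relative volume-change analysis
#'
#' Bland-Altman (reference-denominator, i.e. baseline-relative percentage
#' differences) of each post-administration tag's organ volumes against
#' baseline, plus a paired Wilcoxon test per tag, computed separately for
#' kidneys (pooled or per-subject) and the spleen control.
#'
#' @param volumes Data.frame with columns `subject`, `organ`, `tag`,
#'   `volume_mL` (as produced by [run_experiment()], or any equivalent
#'   measurement table).
#' @param denominator_mode Passed to [bland_altman()]; default `"reference"`
#'   so a configured multiplier `m` is recovered as bias `100 (m - 1)`.
#' @param pooling `"kidneys"` or `"subjects"`.
#' @return Data.frame: `organ_class`, `tag`, `n_pairs`, `bias_pct`, `sd_pct`,
#'   `loa_low_pct`, `loa_high_pct`, `wilcoxon_p` (NA when degenerate).
#' @export
volume_change_analysis <- function(volumes,
                                   denominator_mode = "reference",
                                   pooling = c("kidneys", "subjects")) {
  pooling <- match.arg(pooling)
  need <- c("subject", "organ", "tag", "volume_mL")
  if (!all(need %in% names(volumes))) stop("volumes table lacks required columns")
  if (!all(POST_TAGS %in% volumes$tag) || !"B_L" %in% volumes$tag)
    stop("missing tags: need B_L and D0/D1/D2/D7")
  if (length(unique(volumes$subject)) < 2) stop("need >= 2 subjects")
  volumes$organ_class <- ifelse(grepl("^kidney", volumes$organ), "kidney",
                                volumes$organ)
  if (pooling == "subjects") {
    volumes <- stats::aggregate(volume_mL ~ subject + organ_class + tag,
                                volumes, mean)
    volumes$unit <- volumes$subject
  } else {
    volumes$unit <- paste(volumes$subject, volumes$organ)
  }
  rows <- list()
  for (oc in unique(volumes$organ_class)) {
    voc <- volumes[volumes$organ_class == oc, ]
    base <- voc[voc$tag == "B_L", ]
    base_v <- stats::setNames(base$volume_mL, base$unit)
    for (tag in POST_TAGS) {
      cur <- voc[voc$tag == tag, ]
      test <- cur$volume_mL
      ref <- base_v[cur$unit]
      ba <- bland_altman(test, ref, denominator_mode = denominator_mode)
      wp <- tryCatch(wilcoxon_paired(test, ref)$p_value,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(organ_class = oc, tag = tag, n_pairs = ba$n_pairs,
                   bias_pct = ba$bias_pct, sd_pct = ba$sd_pct,
                   loa_low_pct = ba$loa_low_pct,
                   loa_high_pct = ba$loa_high_pct, wilcoxon_p = wp)
    }
  }
  do.call(rbind, rows)
}

# Bland-Altman matrix of concentrations: delineation tag j vs the reference
# (tag-matched) delineation, at each measurement tag i
concentration_agreement <- function(concentrations, config) {
  cc <- concentrations[concentrations$rc_mode == config$rc_modes[1] &
                         concentrations$organ != "spleen", ]
  ref <- cc[cc$strategy == "reference", ]
  key <- function(df) paste(df$subject, df$organ, df$tag)
  ref_map <- stats::setNames(ref$conc_corrected_Bq_mL, key(ref))
  rows <- list()
  for (strategy in setdiff(config$strategies, "reference")) {
    j <- sub("single_", "", strategy)
    sc <- cc[cc$strategy == strategy, ]
    for (tag in POST_TAGS) {
      cur <- sc[sc$tag == tag, ]
      test <- cur$conc_corrected_Bq_mL
      refv <- ref_map[key(cur)]
      ba <- bland_altman(test, refv, denominator_mode = "pair_mean")
      wp <- tryCatch(wilcoxon_paired(test, refv)$p_value,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(delineation_tag = j, measurement_tag = tag,
                   n_pairs = ba$n_pairs, bias_pct = ba$bias_pct,
                   sd_pct = ba$sd_pct, wilcoxon_p = wp)
    }
  }
  # the tag-matched cell of each row is identically zero by construction
  do.call(rbind, rows)
}

# per-strategy, per-RC-mode dose agreement vs the reference strategy, plus
# the fixed-vs-specific cross-comparison on the reference strategy
dose_agreement <- function(doses, config) {
  key <- function(df) paste(df$subject, df$organ)
  rows <- list()
  for (rc_mode in config$rc_modes) {
    dd <- doses[doses$rc_mode == rc_mode, ]
    ref <- dd[dd$strategy == "reference", ]
    ref_map <- stats::setNames(ref$dose_Gy, key(ref))
    for (strategy in config$strategies) {
      cur <- dd[dd$strategy == strategy, ]
      test <- cur$dose_Gy
      refv <- ref_map[key(cur)]
      if (strategy == "reference") {
        ba <- list(n_pairs = length(test), bias_pct = 0, sd_pct = 0,
                   loa_low_pct = 0, loa_high_pct = 0)
        wp <- NA_real_
      } else {
        ba <- bland_altman(test, refv, denominator_mode = "pair_mean")
        wp <- tryCatch(wilcoxon_paired(test, refv)$p_value,
                       error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = strategy, rc_mode = rc_mode,
                   n_pairs = ba$n_pairs, mean_dose_Gy = mean(test),
                   sd_dose_Gy = stats::sd(test), bias_pct = ba$bias_pct,
                   sd_pct = ba$sd_pct, loa_low_pct = ba$loa_low_pct,
                   loa_high_pct = ba$loa_high_pct, wilcoxon_p = wp)
    }
  }
  vs_reference <- do.call(rbind, rows)
  rc_cross <- NULL
  if (all(c("fixed", "specific") %in% config$rc_modes)) {
    rf <- doses[doses$strategy == "reference" & doses$rc_mode == "fixed", ]
    rs <- doses[doses$strategy == "reference" & doses$rc_mode == "specific", ]
    rs_map <- stats::setNames(rs$dose_Gy, key(rs))
    ba <- bland_altman(rf$dose_Gy, rs_map[key(rf)],
                       denominator_mode = "pair_mean")
    rc_cross <- data.frame(comparison = "reference fixed vs specific RC",
                           n_pairs = ba$n_pairs, bias_pct = ba$bias_pct,
                           sd_pct = ba$sd_pct)
  }
  list(vs_reference = vs_reference, rc_cross = rc_cross)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects, %d strategies, RC modes: %s\n",
              x$config$n_subjects, length(x$config$strategies),
              paste(x$config$rc_modes, collapse = "/")))
  cat("\nVolume change vs baseline:\n")
  print(x$volume_agreement, row.names = FALSE, digits = 4)
  cat("\nDose agreement vs reference:\n")
  print(x$dose_agreement[, c("strategy", "rc_mode", "mean_dose_Gy",
                             "bias_pct", "sd_pct")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write the experiment report
#'
#' CSV tables (`volumes`, `concentrations`, `doses`, `volume_agreement`,
#' `conc_agreement`, `dose_agreement`) plus a `summary.json`. Output depends
#' only on the experiment's seed and configuration, so identically-seeded
#' runs write byte-identical reports.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("volumes", "concentrations", "doses", "volume_agreement",
            "conc_agreement", "dose_agreement")
  for (tb in tabs)
    utils::write.csv(result[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  summary <- list(
    n_subjects = result$config$n_subjects,
    seed = result$config$seed,
    strategies = result$config$strategies,
    rc_modes = result$config$rc_modes,
    kidney_volume_bias_pct = stats::setNames(
      as.list(result$volume_agreement$bias_pct[
        result$volume_agreement$organ_class == "kidney"]),
      result$volume_agreement$tag[
        result$volume_agreement$organ_class == "kidney"]),
    mean_reference_dose_Gy = result$dose_agreement$mean_dose_Gy[
      result$dose_agreement$strategy == "reference"][1],
    rc_cross = result$rc_cross)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
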