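#' Measure one segmented scan
#'
#' Computes every quantity the reliability study tracks for a single
#' fat-water volume and mask: whole-muscle percent fat (both estimators)
#' and volume, plus regional values over the superior-inferior quartile
#' and lateral-medial tertile partitions.
#'
#' @param volume a [fat_water_volume()].
#' @param mask a [label_mask()].
#' @param schemes any of `"quartile"`, `"tertile"`.
#' @return Long data frame: `muscle`, `scheme` (`whole`, `quartile_SI`,
#'   `tertile_ML`), `region`, `measure` (`fat_pct_slice`, `fat_pct_voxel`,
#'   `volume_cm3`), `value`.
#' @export
measure_scan <- function(volume, mask, schemes = c("quartile", "tertile")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  map <- compute_fat_fraction(volume)
  labs <- setdiff(sort(unique(as.vector(mask$labels))), 0L)
  rows <- list()
  for (lab in labs) {
    nm <- label_display_name(mask, lab)
    ws <- suppressWarnings(muscle_mean_fat(map, mask, lab, "slice_mean"))
    wv <- suppressWarnings(muscle_mean_fat(map, mask, lab, "voxel"))
    rows[[length(rows) + 1L]] <- data.frame(
      muscle = nm, scheme = "whole", region = "whole",
      measure = c("fat_pct_slice", "fat_pct_voxel", "volume_cm3"),
      value = c(as.numeric(ws), as.numeric(wv), muscle_volume(mask, lab)),
      stringsAsFactors = FALSE)
    for (sch in schemes) {
      part <- if (sch == "quartile") partition_quartiles(mask, lab)
              else partition_tertiles(mask, lab)
      rs <- suppressWarnings(regional_stats(map, mask, part))
      rows[[length(rows) + 1L]] <- data.frame(
        muscle = nm, scheme = rs$scheme[1],
        region = rep(rs$region, each = 3),
        measure = rep(c("fat_pct_slice", "fat_pct_voxel", "volume_cm3"),
                      nrow(rs)),
        value = as.vector(rbind(rs$mean_fat_pct_slice,
                                rs$mean_fat_pct_voxel, rs$volume_cm3)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reliability tables from repeated study measurements
#'
#' Given measurements of the same subjects by several raters (or
#' sessions), computes ICC, confidence interval, qualitative band, mean,
#' SEM and MDC for every muscle x region x measure cell, in the layout of
#' published reliability tables.
#'
#' @param measurements data frame with columns `subject_id`, `rater_id`,
#'   `muscle`, `scheme`, `region`, `measure`, `value` (rows from
#'   [measure_scan()] plus identifiers).
#' @param model,sem_method,z,conf_level see [icc()], [sem()], [mdc()].
#' @return Data frame: `muscle`, `scheme`, `region`, `measure`, `icc`,
#'   `ci_low`, `ci_high`, `band`, `mean`, `sem`, `mdc`.
#' @export
study_reliability <- function(measurements,
                              model = "two_way_random_absolute_single",
                              sem_method = "sd_sqrt",
                              z = 1, conf_level = 0.95) {
  keys <- unique(measurements[, c("muscle", "scheme", "region", "measure")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    kk <- keys[i, ]
    sub <- merge(measurements, kk)
    fit <- icc(data.frame(subject_id = sub$subject_id,
                          rater_id = sub$rater_id, value = sub$value),
               model = model, conf_level = conf_level)
    s <- sem(data.frame(subject_id = sub$subject_id,
                        rater_id = sub$rater_id, value = sub$value),
             fit$icc, method = sem_method)
    cbind(kk,
          data.frame(icc = fit$icc, ci_low = fit$ci_low,
                     ci_high = fit$ci_high, band = fit$band,
                     mean = fit$grand_mean, sem = s, mdc = mdc(s, z = z),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$muscle, out$scheme, out$region, out$measure), ]
}

#' Simulate a complete reliability study on synthetic phantoms
#'
#' Generates `n_subjects` phantom scans with between-subject variation in
#' fat level and muscle size, derives each additional rater's mask by
#' [perturb_mask()] (rater 1 keeps the reference segmentation), measures
#' every scan with [measure_scan()], and summarises inter-rater
#' reliability with [study_reliability()].  A concurrent-comparison table
#' (slice-mean vs voxel-weighted percent-fat estimator, treated as two
#' methods on rater 1's measurements) is also produced.
#'
#' @param n_subjects number of simulated patients (default 13, a typical
#'   reliability-cohort size).
#' @param k_raters raters per subject (>= 2 for reliability output).
#' @param seed RNG seed governing the whole simulation.
#' @param noise_sd intensity noise SD passed to the phantom.
#' @param boundary_op_prob,max_shift rater segmentation variability; set
#'   both to 0 for identical raters.
#' @param subject_ff_sd between-subject SD of the base fat fraction
#'   (percent fat).
#' @param subject_size_sd between-subject SD of the muscle size scale
#'   factor.
#' @param base_spec template [phantom_spec()].
#' @param model,sem_method,z passed to [study_reliability()].
#' @return List with `measurements`, `reliability`, `concurrent`.
#' @export
simulate_study <- function(n_subjects = 13, k_raters = 2, seed = 1,
                           noise_sd = 5, boundary_op_prob = 0.1,
                           max_shift = 1, subject_ff_sd = 2.5,
                           subject_size_sd = 0.06,
                           base_spec = phantom_spec(),
                           model = "two_way_random_absolute_single",
                           sem_method = "sd_sqrt", z = 1) {
  stopifnot(n_subjects >= 1, k_raters >= 1)
  meas <- with_seed(seed, {
    out <- list()
    for (i in seq_len(n_subjects)) {
      ff_shift <- rnorm(1, 0, subject_ff_sd)
      size_scale <- exp(rnorm(1, 0, subject_size_sd))
      spec_i <- base_spec
      spec_i$noise_sd <- noise_sd
      spec_i$muscles <- lapply(base_spec$muscles, function(m) {
        m$base_ff <- max(1, m$base_ff + ff_shift)
        m$semi_start <- pmax(2, m$semi_start * size_scale)
        m$semi_end <- pmax(2, m$semi_end * size_scale)
        m
      })
      ph <- make_phantom(spec_i)
      for (r in seq_len(k_raters)) {
        msk <- if (r == 1L) ph$mask else
          perturb_mask(ph$mask, boundary_op_prob, max_shift)
        m <- measure_scan(ph$volume, msk)
        m$subject_id <- sprintf("S%03d", i)
        m$rater_id <- sprintf("R%d", r)
        out[[length(out) + 1L]] <- m
      }
    }
    do.call(rbind, out)
  })

  rel <- NULL
  concurrent <- NULL
  if (k_raters >= 2) {
    rel <- study_reliability(meas, model = model, sem_method = sem_method,
                             z = z)
    concurrent <- concurrent_table(meas)
  } else {
    message("single rater: reliability stage skipped")
  }
  list(measurements = meas, reliability = rel, concurrent = concurrent)
}

# slice-mean vs voxel-weighted percent fat on rater 1's measurements,
# treated as two methods (stand-in for an external-software comparison arm)
concurrent_table <- function(measurements) {
  m1 <- measurements[measurements$rater_id == measurements$rater_id[1], ]
  keys <- unique(m1[m1$measure == "fat_pct_slice",
                    c("muscle", "scheme", "region")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    kk <- keys[i, ]
    sub <- merge(m1, kk)
    a <- sub[sub$measure == "fat_pct_slice", ]
    b <- sub[sub$measure == "fat_pct_voxel", ]
    fit <- concurrent_validity(
      stats::setNames(a$value, a$subject_id),
      stats::setNames(b$value, b$subject_id))
    cbind(kk, data.frame(icc = fit$icc, ci_low = fit$ci_low,
                         ci_high = fit$ci_high, band = fit$band,
                         stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a segmentation reliability study from a configuration
#'
#' The end-to-end command: reads each subject's fat/water/mask triplet per
#' rater, writes per-scan quantification CSVs, and (when at least two
#' raters are present) reliability CSVs in the published table layout —
#' quartile rows Q1-Q4 and tertile rows whole/lateral/intermediate/medial
#' per muscle — plus a concurrent-comparison CSV and a JSON run manifest.
#'
#' @param config list or YAML path with `subjects:` (each with `id` and
#'   `raters:`, each rater with `id`, `fat`, `water`, `mask`), and
#'   optional `labels`, `axes`, `model`, `sem_method`, `z`.
#' @param out_dir output directory (created if missing).
#' @param round_like_paper round ICCs to 3 decimals and means/SEM/MDC to 2
#'   in the written CSVs.
#' @return Invisibly, a list with `measurements`, `reliability`,
#'   `concurrent`, and `files` written.
#' @export
run_study <- function(config, out_dir, round_like_paper = FALSE) {
  config <- load_config(config)
  if (is.null(config$subjects) || !length(config$subjects)) {
    stop("config must list at least one subject", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  out <- list()
  for (subj in config$subjects) {
    if (is.null(subj$id)) stop("every subject needs an id", call. = FALSE)
    for (rater in subj$raters) {
      pair <- read_volume_pair(rater$fat, rater$water, rater$mask, config)
      m <- measure_scan(pair$volume, pair$mask)
      m$subject_id <- as.character(subj$id)
      m$rater_id <- as.character(rater$id)
      f <- file.path(out_dir,
                     sprintf("quant_%s_%s.csv", subj$id, rater$id))
      write.csv(m, f, row.names = FALSE)
      files <- c(files, f)
      out[[length(out) + 1L]] <- m
    }
  }
  meas <- do.call(rbind, out)

  rel <- NULL; concurrent <- NULL
  n_raters <- length(unique(meas$rater_id))
  if (n_raters >= 2 && length(unique(meas$subject_id)) >= 2) {
    rel <- study_reliability(
      meas,
      model = config$model %||% "two_way_random_absolute_single",
      sem_method = config$sem_method %||% "sd_sqrt",
      z = config$z %||% 1)
    for (sch in unique(rel$scheme)) {
      tab <- reliability_layout(rel, sch)
      if (round_like_paper) tab <- round_like_paper_tab(tab)
      f <- file.path(out_dir, sprintf("reliability_%s.csv",
                                      sub("_.*$", "", sch)))
      write.csv(tab, f, row.names = FALSE)
      files <- c(files, f)
    }
    concurrent <- concurrent_table(meas)
    f <- file.path(out_dir, "concurrent_validity.csv")
    ct <- concurrent
    if (round_like_paper) {
      ct$icc <- round(ct$icc, 3); ct$ci_low <- round(ct$ci_low, 3)
      ct$ci_high <- round(ct$ci_high, 3)
    }
    write.csv(ct, f, row.names = FALSE)
    files <- c(files, f)
  } else {
    message("fewer than 2 raters or subjects: reliability stage skipped")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rcfat")),
    r_version = as.character(getRversion()),
    n_subjects = length(unique(meas$subject_id)),
    n_raters = n_raters,
    timestamped = FALSE)
  mf <- file.path(out_dir, "run_manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), mf)
  files <- c(files, mf)

  invisible(list(measurements = meas, reliability = rel,
                 concurrent = concurrent, files = files))
}

# published layout, one row per muscle x region: quartile tables carry %fat
# over Q1-Q4; tertile tables carry %fat and volume side by side over
# whole/lateral/intermediate/medial
reliability_layout <- function(rel, scheme) {
  stat_cols <- c("icc", "ci_low", "ci_high", "band", "mean", "sem", "mdc")
  if (startsWith(scheme, "quartile")) {
    tab <- rel[rel$scheme == scheme & rel$measure == "fat_pct_slice", ]
    region_order <- c("Q1", "Q2", "Q3", "Q4")
    names(tab)[match(stat_cols, names(tab))] <- paste0("fat_", stat_cols)
    tab$measure <- NULL
  } else {
    sel <- rel[(rel$scheme == scheme | rel$scheme == "whole") &
                 rel$measure %in% c("fat_pct_slice", "volume_cm3"), ]
    region_order <- c("whole", "lateral", "intermediate", "medial")
    fat <- sel[sel$measure == "fat_pct_slice",
               c("muscle", "region", stat_cols)]
    names(fat)[-(1:2)] <- paste0("fat_", stat_cols)
    vol <- sel[sel$measure == "volume_cm3", c("muscle", "region", stat_cols)]
    names(vol)[-(1:2)] <- paste0("vol_", stat_cols)
    tab <- merge(fat, vol, by = c("muscle", "region"))
  }
  tab$region <- factor(tab$region, levels = region_order)
  tab <- tab[order(tab$muscle, tab$region), ]
  tab$region <- as.character(tab$region)
  tab$scheme <- NULL
  rownames(tab) <- NULL
  tab
}

round_like_paper_tab <- function(tab) {
  for (cl in grep("_(icc|ci_low|ci_high)$", names(tab), value = TRUE)) {
    tab[[cl]] <- round(tab[[cl]], 3)
  }
  for (cl in grep("_(mean|sem|mdc)$", names(tab), value = TRUE)) {
    tab[[cl]] <- round(tab[[cl]], 2)
  }
  tab
}
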