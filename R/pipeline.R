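# Pipeline orchestration: configuration (JSON round-trippable, strictly
# validated), the simulate -> reconstruct -> quantify -> classify -> stats
# run, and table/metrics reporting.

#' Default run configuration
#'
#' All defaults are the calibrated study conditions: cohort sizes 82 PD /
#' 107 HC, 0.5 x 0.5 x 1 mm voxels, TE 13.77/26.39/39 ms at 3 T, truncation
#' threshold 0.1 with 30 refinement iterations, SMV radius 2 mm, paramagnetic
#' mask threshold 150 ppb with power 4.
#'
#' @return nested list of class \code{run_config}.
#' @export
default_config <- function() {
  structure(list(
    cohort = list(n_pd = 82L, n_hc = 107L, effect_scale = 1,
                  left_offset = 0.125, side_noise = 0.15),
    grid = list(dims = c(96L, 96L, 32L), voxel_size = c(0.5, 0.5, 1.0),
                slice_axis = 3L),
    acquisition = list(te_list = c(13.77, 26.39, 39), b0 = 3,
                       n_channels = 2L, noise_sd = 0.01),
    recon = list(delta = 0.1, n_iter = 30L, smv_radius_mm = 2),
    smwi = list(chi_threshold = 150, power = 4L),
    quant = list(rn_fraction = 0.1, rel_threshold = 0.15, n_thresholds = 25L),
    stats = list(alpha = 0.05, m_override = NULL),
    output_dir = NULL, seed = 1L, skip_recon = FALSE
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop(sprintf("schema error: unknown key `%s`", here))
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop(sprintf("schema error: `%s` must be an object", here))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

#' Validate a JSON run configuration
#'
#' Parses a JSON document (text or file path), fills defaults, rejects
#' unknown keys, and checks every invariant, reporting the offending key
#' path.
#'
#' @param document JSON text (or a file path to one).
#' @return a validated \code{run_config}.
#' @examples
#' cfg <- validate_config("{}")          # fully defaulted
#' cfg$acquisition$te_list
#' @export
validate_config <- function(document = "{}") {
  user <- jsonlite::fromJSON(document, simplifyVector = TRUE)
  cfg <- merge_config(unclass(default_config()), user)
  chk <- function(ok, path, msg) if (!ok) stop(sprintf("schema error: `%s` %s", path, msg))
  chk(cfg$cohort$n_pd >= 0, "cohort.n_pd", "must be >= 0")
  chk(cfg$cohort$n_hc >= 0, "cohort.n_hc", "must be >= 0")
  chk(cfg$cohort$n_pd + cfg$cohort$n_hc > 0, "cohort", "is empty")
  chk(length(cfg$grid$dims) == 3 && all(cfg$grid$dims >= 1), "grid.dims",
      "must be 3 positive integers")
  chk(all(cfg$grid$voxel_size > 0), "grid.voxel_size", "must be positive")
  chk(length(cfg$acquisition$te_list) >= 1 &&
        all(diff(cfg$acquisition$te_list) > 0), "acquisition.te_list",
      "must be strictly increasing and nonempty")
  chk(cfg$acquisition$b0 > 0, "acquisition.b0", "must be positive")
  chk(cfg$acquisition$n_channels >= 1, "acquisition.n_channels", "must be >= 1")
  chk(cfg$recon$delta > 0 && cfg$recon$delta < 1 / 3, "recon.delta",
      "must be in (0, 1/3)")
  chk(cfg$recon$n_iter >= 0, "recon.n_iter", "must be >= 0")
  chk(cfg$recon$smv_radius_mm > 0, "recon.smv_radius_mm", "must be positive")
  chk(cfg$smwi$chi_threshold > 0, "smwi.chi_threshold", "must be positive")
  chk(cfg$smwi$power >= 1, "smwi.power", "must be >= 1")
  chk(cfg$quant$rn_fraction > 0 && cfg$quant$rn_fraction < 1,
      "quant.rn_fraction", "must be in (0, 1)")
  chk(cfg$quant$rel_threshold > 0, "quant.rel_threshold", "must be positive")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1, "stats.alpha",
      "must be in (0, 1)")
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

# FNV-1a-style hash of a string, as provenance fingerprint (32-bit, kept in
# doubles; only the low byte participates in the xor).
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

measure_names <- function() c("composite", "qsm_based_volume",
                              "nms_based_volume", "nms_contrast_range",
                              "n1_volume")

# Image-route quantification of one simulated subject. Returns the per-side
# QSM/NMS region values on the analysis slices plus the SMWI N1 volume.
quantify_subject_images <- function(latent_row, subject_seed, grid, acq, recon,
                                    smwi_par, quant_par) {
  phantom <- render_phantom(latent_row, grid, seed = subject_seed)
  series <- simulate_multiecho_gre(
    phantom$chi, grid, te_list = acq$te_list, b0 = acq$b0,
    n_channels = acq$n_channels, noise_sd = acq$noise_sd,
    seed = derive_seed(subject_seed, 1L, stage = 2L),
    magnitude_support = phantom$head
  )
  rec <- reconstruct_smwi(series, mask = NULL,
                          chi_threshold = smwi_par$chi_threshold,
                          power = smwi_par$power, delta = recon$delta,
                          n_iter = recon$n_iter,
                          smv_radius_mm = recon$smv_radius_mm)
  slices <- select_analysis_slices(phantom$masks$RN_L | phantom$masks$RN_R,
                                   grid, fraction = quant_par$rn_fraction)
  out <- list(slices = slices)
  for (s in c("L", "R")) {
    sn <- phantom$masks[[paste0("SN_", s)]]
    out[[paste0("qsm_vals_", s)]] <- slice_values(rec$qsm$values, sn, slices, grid)
    out[[paste0("nms_vals_", s)]] <- slice_values(phantom$nms, sn, slices, grid)
    out[[paste0("contrast_", s)]] <- nms_contrast_range(phantom$nms, sn, slices, grid)
    out[[paste0("n1_", s)]] <- n1_volume_smwi(rec$smwi, sn, slices, grid,
                                              rel_threshold = quant_par$rel_threshold,
                                              background_mask = rec$mask)
  }
  out$phantom <- phantom
  out$rec <- rec
  out
}

image_route_measures <- function(cohort, cfg, keep_volumes = FALSE) {
  grid <- voxel_grid(cfg$grid$dims, cfg$grid$voxel_size, cfg$grid$slice_axis)
  n <- nrow(cohort$subjects)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    q <- quantify_subject_images(cohort$latent[i, ], cohort$subjects$seed[i],
                                 grid, cfg$acquisition, cfg$recon, cfg$smwi,
                                 cfg$quant)
    if (!is.null(cfg$output_dir)) {
      id <- cohort$subjects$id[i]
      write_volume(q$phantom$chi, file.path(cfg$output_dir,
                                            sprintf("%s_chi.nii.gz", id)), grid)
      write_volume(q$phantom$nms, file.path(cfg$output_dir,
                                            sprintf("%s_nms.nii.gz", id)), grid)
      write_volume(q$rec$qsm$values, file.path(cfg$output_dir,
                                               sprintf("%s_qsm.nii.gz", id)), grid)
      write_volume(q$rec$smwi$values, file.path(cfg$output_dir,
                                                sprintf("%s_smwi.nii.gz", id)), grid)
      for (mn in names(q$phantom$masks))
        write_volume(q$phantom$masks[[mn]],
                     file.path(cfg$output_dir, sprintf("%s_mask_%s.nii.gz", id, mn)),
                     grid)
    }
    q$phantom <- NULL; q$rec <- NULL
    per[[i]] <- q
  }
  labels <- cohort$subjects$group
  pooled_qsm <- lapply(per, function(q) c(q$qsm_vals_L, q$qsm_vals_R))
  pooled_nms <- lapply(per, function(q) c(q$nms_vals_L, q$nms_vals_R))
  qgrid <- stats::quantile(unlist(pooled_qsm), probs = seq(0.05, 0.95,
                                                           length.out = cfg$quant$n_thresholds))
  ngrid <- stats::quantile(unlist(pooled_nms), probs = seq(0.05, 0.95,
                                                           length.out = cfg$quant$n_thresholds))
  qsm_search <- optimize_threshold(pooled_qsm, labels, qgrid, "below")
  nms_search <- optimize_threshold(pooled_nms, labels, ngrid, "above")
  vv <- voxel_volume(grid)
  rows <- list()
  for (s in c("L", "R")) {
    qsm_vol <- vapply(per, function(q) sum(q[[paste0("qsm_vals_", s)]] <
                                             qsm_search$threshold) * vv, 0)
    nms_vol <- vapply(per, function(q) sum(q[[paste0("nms_vals_", s)]] >
                                             nms_search$threshold) * vv, 0)
    contrast <- vapply(per, function(q) q[[paste0("contrast_", s)]], 0)
    n1 <- vapply(per, function(q) q[[paste0("n1_", s)]], 0)
    rows[[s]] <- data.frame(
      id = cohort$subjects$id, group = labels, side = s,
      n1_volume = n1, qsm_based_volume = qsm_vol, nms_based_volume = nms_vol,
      nms_contrast_range = contrast,
      composite = composite_score(qsm_vol, nms_vol, contrast),
      stringsAsFactors = FALSE
    )
  }
  list(measures = rbind(rows$L, rows$R),
       thresholds = list(qsm = qsm_search, nms = nms_search))
}

iqr_label <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
}

build_table1 <- function(subjects, agg, alpha) {
  pd <- subjects$group == "PD"
  rows <- list()
  tt <- t_test_pooled(subjects$age[pd], subjects$age[!pd])
  rows[[1]] <- data.frame(variable = "age",
                          pd = sprintf("%.2f (%.2f)", mean(subjects$age[pd]),
                                       stats::sd(subjects$age[pd])),
                          hc = sprintf("%.2f (%.2f)", mean(subjects$age[!pd]),
                                       stats::sd(subjects$age[!pd])),
                          test = "t", p = tt$p)
  cs <- suppressWarnings(
    chi_square_2x2(sum(pd & subjects$sex == "M"), sum(pd & subjects$sex == "F"),
                   sum(!pd & subjects$sex == "M"), sum(!pd & subjects$sex == "F")))
  rows[[2]] <- data.frame(variable = "sex_male", pd = sprintf("%d", sum(pd & subjects$sex == "M")),
                          hc = sprintf("%d", sum(!pd & subjects$sex == "M")),
                          test = "chi2", p = cs$p)
  mw <- mann_whitney(subjects$updrs3[pd], subjects$updrs3[!pd])
  rows[[3]] <- data.frame(variable = "updrs3", pd = iqr_label(subjects$updrs3[pd]),
                          hc = iqr_label(subjects$updrs3[!pd]), test = "mann_whitney",
                          p = mw$p)
  apd <- agg[agg$group == "PD", ]; ahc <- agg[agg$group == "HC", ]
  for (m in c("n1_volume", "qsm_based_volume", "nms_based_volume",
              "nms_contrast_range", "composite")) {
    mwm <- mann_whitney(apd[[m]], ahc[[m]])
    rows[[length(rows) + 1]] <- data.frame(variable = m, pd = iqr_label(apd[[m]]),
                                           hc = iqr_label(ahc[[m]]),
                                           test = "mann_whitney", p = mwm$p)
  }
  do.call(rbind, rows)
}

build_table2 <- function(measures) {
  rows <- list()
  for (m in c("n1_volume", "qsm_based_volume", "nms_based_volume",
              "nms_contrast_range", "composite")) {
    for (s in c("L", "R")) {
      sub <- measures[measures$side == s, ]
      mw <- mann_whitney(sub[[m]][sub$group == "PD"], sub[[m]][sub$group == "HC"])
      rows[[length(rows) + 1]] <- data.frame(
        variable = m, side = s,
        pd = iqr_label(sub[[m]][sub$group == "PD"]),
        hc = iqr_label(sub[[m]][sub$group == "HC"]),
        p = mw$p)
    }
  }
  do.call(rbind, rows)
}

build_table3 <- function(measures_all) {
  rows <- list()
  for (m in measure_names()) {
    for (s in c("aggregate", "L", "R")) {
      sub <- measures_all[measures_all$side == s, ]
      cm <- classify_measure(sub[[m]], sub$group, orientation = "lower_is_positive")
      rows[[length(rows) + 1]] <- data.frame(
        model = m, side = s, auc = round(cm$auc, 3),
        accuracy = round(cm$accuracy, 2), sensitivity = round(cm$sensitivity, 2),
        specificity = round(cm$specificity, 2), youden = round(cm$youden, 2),
        cutoff = cm$cutoff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

build_table4 <- function(measures_all, subjects, alpha, m_override = NULL) {
  pd_ids <- subjects$id[subjects$group == "PD"]
  clin <- subjects[match(pd_ids, subjects$id), ]
  combos <- expand.grid(measure = measure_names(),
                        clinical = c("updrs3", "hy_stage", "ledd", "duration"),
                        side = c("L", "R", "aggregate"),
                        stringsAsFactors = FALSE)
  m_tests <- if (is.null(m_override)) nrow(combos) else m_override
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    sub <- measures_all[measures_all$side == cb$side, ]
    sub <- sub[match(pd_ids, sub$id), ]
    res <- tryCatch({
      if (cb$clinical == "hy_stage")
        kendall_tau_b(sub[[cb$measure]], clin[[cb$clinical]],
                      alpha = alpha, m = m_tests)
      else
        spearman_corr(sub[[cb$measure]], clin[[cb$clinical]],
                      alpha = alpha, m = m_tests)
    }, error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- data.frame(
      measure = cb$measure, clinical = cb$clinical, side = cb$side,
      method = res$method, coefficient = res$coefficient, p = res$p_value,
      n = res$n, significant = res$significant_after_bonferroni,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' simulate -> (reconstruct -> quantify | draw measures from the calibrated
#' latent model when \code{skip_recon}) -> classify -> group/correlation
#' statistics. Deterministic given config + seed; per-subject seeds are
#' derived from the master seed by counters, not execution order. Tables and
#' a flat metrics JSON are written under \code{output_dir} when set.
#'
#' @param config a \code{run_config} (see \code{\link{validate_config}}).
#' @return object of class \code{nigra_run}: list with \code{tables} (table1
#'   ... table4 analogs), \code{measures}, \code{metrics} (flat list),
#'   \code{thresholds}, \code{cohort}, \code{provenance}.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!is.null(cfg$output_dir) && !dir.exists(cfg$output_dir))
    dir.create(cfg$output_dir, recursive = TRUE)

  cohort <- with_stage("simulate", {
    generate_cohort(cohort_spec(
      n_pd = cfg$cohort$n_pd, n_hc = cfg$cohort$n_hc, seed = cfg$seed,
      effect_scale = cfg$cohort$effect_scale,
      left_offset = cfg$cohort$left_offset,
      side_noise = cfg$cohort$side_noise))
  })
  if (!is.null(cfg$output_dir))
    write_cohort_csv(cohort, file.path(cfg$output_dir, "cohort.csv"))

  thresholds <- NULL
  measures <- if (isTRUE(cfg$skip_recon)) {
    with_stage("quantify", measures_from_latent(cohort))
  } else {
    res <- with_stage("reconstruct", image_route_measures(cohort, cfg))
    thresholds <- res$thresholds
    res$measures
  }
  agg <- with_stage("quantify", aggregate_measures(measures))
  measures_all <- rbind(measures, agg)
  if (!is.null(cfg$output_dir))
    utils::write.csv(measures_all, file.path(cfg$output_dir, "measures.csv"),
                     row.names = FALSE)

  table3 <- with_stage("classify", build_table3(measures_all))
  tables <- with_stage("stats", {
    list(
      table1 = build_table1(cohort$subjects, agg, cfg$stats$alpha),
      table2 = build_table2(measures),
      table3 = table3,
      table4 = build_table4(measures_all, cohort$subjects, cfg$stats$alpha,
                            cfg$stats$m_override)
    )
  })

  metrics <- list()
  for (i in seq_len(nrow(table3))) {
    key <- sprintf("auc_%s_%s", table3$model[i], table3$side[i])
    metrics[[key]] <- table3$auc[i]
    metrics[[sprintf("accuracy_%s_%s", table3$model[i], table3$side[i])]] <-
      table3$accuracy[i]
    metrics[[sprintf("cutoff_%s_%s", table3$model[i], table3$side[i])]] <-
      table3$cutoff[i]
  }
  metrics$n_subjects <- nrow(cohort$subjects)
  metrics$n_pd <- sum(cohort$subjects$group == "PD")

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                               digits = NA)
  provenance <- list(config_hash = fnv1a(as.character(cfg_json)),
                     seed = cfg$seed,
                     version = as.character(utils::packageVersion("nigra")))
  if (!is.null(cfg$output_dir)) {
    for (tn in names(tables))
      utils::write.csv(tables[[tn]], file.path(cfg$output_dir,
                                               paste0(tn, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(metrics, file.path(cfg$output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(tables = tables, measures = measures_all, metrics = metrics,
                 thresholds = thresholds, cohort = cohort,
                 provenance = provenance, config = cfg),
            class = "nigra_run")
}

#' @export
print.nigra_run <- function(x, ...) {
  cat(sprintf("nigra_run: %d subjects (%d PD), seed %d, config %s\n",
              x$metrics$n_subjects, x$metrics$n_pd, x$provenance$seed,
              x$provenance$config_hash))
  cat("classification (aggregate measures):\n")
  t3 <- x$tables$table3
  print(t3[t3$side == "aggregate", c("model", "auc", "accuracy", "sensitivity",
                                     "specificity", "youden", "cutoff")],
        row.names = FALSE)
  invisible(x)
}
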