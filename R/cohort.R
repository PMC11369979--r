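#' Fit a log-normal distribution to reported quartiles
#'
#' Calibrates a log-normal marginal to a published median and inter-quartile
#' range by quartile matching: \code{mu = log(median)},
#' \code{sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))}. The fitted
#' distribution always reproduces the median, and reproduces both quartiles
#' exactly when \code{q1 * q3 == median^2}.
#'
#' @param median,q1,q3 positive reals with \code{q1 <= median <= q3}.
#' @return named numeric vector \code{c(mu, sigma)} (log-scale location and
#'   spread). A degenerate zero-spread fit (\code{q1 == q3}) is returned with
#'   a warning.
#' @examples
#' fit_lognormal_from_quartiles(3.00, 1.35, 5.44)
#' @export
fit_lognormal_from_quartiles <- function(median, q1, q3) {
  median <- as.numeric(median); q1 <- as.numeric(q1); q3 <- as.numeric(q3)
  if (any(c(median, q1, q3) <= 0)) stop("quartile inputs must be positive")
  if (q1 > q3) stop("q1 must not exceed q3")
  if (q1 > median || median > q3) stop("must have q1 <= median <= q3")
  sigma <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  if (sigma == 0) warning("degenerate fit: q1 == q3 gives a point mass")
  c(mu = log(median), sigma = sigma)
}

table1_marginals <- function() {
  list(
    n1_volume = list(pd = c(3.00, 1.35, 5.44), hc = c(14.00, 8.94, 20.00)),
    qsm_based_volume = list(pd = c(27.50, 15.50, 45.00), hc = c(98.00, 56.00, 142.00)),
    nms_based_volume = list(pd = c(16.00, 6.00, 27.00), hc = c(51.00, 25.00, 108.00)),
    nms_contrast_range = list(pd = c(1.139, 1.126, 1.156), hc = c(1.173, 1.163, 1.188))
  )
}

default_clinical_params <- function() {
  list(
    age_pd = c(mean = 65.00, sd = 9.29),
    age_hc = c(mean = 65.51, sd = 6.57),
    male_frac_pd = 56 / 82,
    male_frac_hc = 51 / 107,
    updrs3_pd = c(median = 31, q1 = 20, q3 = 38),
    updrs3_hc = c(median = 2, sigma = 0.85),
    updrs3_floor = 5,
    hy_probs = c(`1` = 0.06, `2` = 0.83, `3` = 0.11),
    ledd = c(median = 375, q1 = 250, q3 = 564),
    duration = c(median = 4.83, q1 = 1.44, q3 = 8.70)
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles the cohort sizes, the per-measure group marginals (median and IQR)
#' that calibrate the generator, clinical covariate parameters, and the latent
#' degeneration model's knobs. Defaults reproduce the study-population summary
#' statistics of the reference cohort (82 PD / 107 HC).
#'
#' The latent model: each subject carries one severity factor \code{x ~ N(0,1)}
#' shifted by a group offset; degeneration is its probit transform. All four
#' imaging measures and the clinical scores load on that single factor, which
#' induces the positive cross-measure and clinical correlation structure.
#' \code{effect_scale} scales the PD-vs-HC group offset (0 disables the group
#' effect entirely, yielding exchangeable groups for null calibration).
#'
#' @param n_pd,n_hc group sizes (nonnegative integers).
#' @param marginals per-measure list of \code{list(pd = c(median, q1, q3),
#'   hc = ...)}; defaults to the reference values.
#' @param clinical_params list of clinical calibration constants.
#' @param seed integer seed controlling the whole cohort.
#' @param effect_scale multiplier on the PD group shift; 1 = calibrated
#'   defaults, 0 = no group difference.
#' @param group_shift_pd,group_shift_hc latent-severity offsets of the two
#'   groups (probit scale).
#' @param left_offset left-hemisphere degeneration offset on the probit scale
#'   (default 0.125, about +5 percentage points of degeneration mid-scale).
#' @param side_noise SD of independent per-hemisphere latent noise.
#' @param measure_coupling not used directly; reserved.
#' @param n1_loss_threshold degeneration fraction above which the nigrosome-1
#'   is considered lost (\code{n1_intact = degeneration < threshold}).
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_pd = 82L, n_hc = 107L,
                        marginals = table1_marginals(),
                        clinical_params = default_clinical_params(),
                        seed = 1L,
                        effect_scale = 1,
                        group_shift_pd = 1.5, group_shift_hc = -1.0,
                        left_offset = 0.125, side_noise = 0.15,
                        measure_coupling = NULL,
                        n1_loss_threshold = 0.5) {
  n_pd <- as.integer(n_pd); n_hc <- as.integer(n_hc)
  stopifnot(n_pd >= 0L, n_hc >= 0L)
  for (m in names(marginals)) {
    for (g in c("pd", "hc")) {
      v <- marginals[[m]][[g]]
      if (!(v[2] <= v[1] && v[1] <= v[3]))
        stop(sprintf("marginal %s/%s violates q1 <= median <= q3", m, g))
    }
  }
  structure(list(n_pd = n_pd, n_hc = n_hc, marginals = marginals,
                 clinical_params = clinical_params, seed = as.integer(seed),
                 effect_scale = effect_scale,
                 group_shift_pd = group_shift_pd,
                 group_shift_hc = group_shift_hc,
                 left_offset = left_offset, side_noise = side_noise,
                 n1_loss_threshold = n1_loss_threshold),
            class = "cohort_spec")
}

# Per-measure loadings (a, b, s): log-median a - b * eta with eta the shifted
# latent severity; residual SD s tops the within-group log-variance up to the
# average of the two fitted sigmas.
measure_loadings <- function(spec) {
  dshift <- spec$group_shift_pd - spec$group_shift_hc
  out <- lapply(names(spec$marginals), function(m) {
    fp <- fit_lognormal_from_quartiles(spec$marginals[[m]]$pd[1],
                                       spec$marginals[[m]]$pd[2],
                                       spec$marginals[[m]]$pd[3])
    fh <- fit_lognormal_from_quartiles(spec$marginals[[m]]$hc[1],
                                       spec$marginals[[m]]$hc[2],
                                       spec$marginals[[m]]$hc[3])
    b <- (fh[["mu"]] - fp[["mu"]]) / dshift
    a <- fh[["mu"]] + b * spec$group_shift_hc
    sig2 <- (fp[["sigma"]]^2 + fh[["sigma"]]^2) / 2
    s <- sqrt(max(sig2 - b^2, 0.01 * sig2))
    c(a = a, b = b, s = s)
  })
  names(out) <- names(spec$marginals)
  out
}

clamp01 <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

#' Generate a synthetic cohort with latent nigral degeneration
#'
#' Draws \code{n_pd + n_hc} subjects. Each subject receives a latent severity
#' factor; degeneration per hemisphere is its probit transform with a
#' left-dominant offset plus independent hemispheric noise. Clinical
#' covariates (age, sex, MDS-UPDRS-III, H&Y stage, LEDD, disease duration) are
#' generated coupled to the same factor. Deterministic given the spec seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return object of class \code{nigra_cohort}: list with \code{subjects}
#'   (one row per subject: id, group, age, sex, updrs3, hy_stage, ledd,
#'   duration, seed) and \code{latent} (per-hemisphere degeneration, latent
#'   scores, iron elevation, neuromelanin level, n1_intact flags).
#' @examples
#' co <- generate_cohort(cohort_spec(n_pd = 5, n_hc = 5, seed = 42))
#' co$subjects
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_pd + spec$n_hc
  if (n == 0L) stop("empty cohort: n_pd + n_hc must be positive")
  set.seed(spec$seed)
  group <- c(rep("PD", spec$n_pd), rep("HC", spec$n_hc))
  id <- c(sprintf("PD%03d", seq_len(spec$n_pd)),
          sprintf("HC%03d", seq_len(spec$n_hc)))
  cp <- spec$clinical_params

  x <- stats::rnorm(n)                       # shared severity factor
  xi_l <- stats::rnorm(n); xi_r <- stats::rnorm(n)
  shift <- ifelse(group == "PD",
                  spec$group_shift_hc +
                    spec$effect_scale * (spec$group_shift_pd - spec$group_shift_hc),
                  spec$group_shift_hc)
  eta <- x + shift
  deg <- clamp01(stats::pnorm(eta))
  # left-dominant asymmetry, split symmetrically so the bilateral mean stays
  # on the calibrated marginal
  deg_l <- clamp01(stats::pnorm(eta + spec$left_offset / 2))
  deg_r <- clamp01(stats::pnorm(eta - spec$left_offset / 2))

  is_pd <- group == "PD"
  age <- ifelse(is_pd,
                stats::rnorm(n, cp$age_pd["mean"], cp$age_pd["sd"]),
                stats::rnorm(n, cp$age_hc["mean"], cp$age_hc["sd"]))
  sex <- ifelse(stats::runif(n) < ifelse(is_pd, cp$male_frac_pd, cp$male_frac_hc),
                "M", "F")

  # MDS-UPDRS-III: PD floor + log-normal component rising with severity;
  # HC small scores around the configured median.
  fu <- fit_lognormal_from_quartiles(cp$updrs3_pd["median"] - cp$updrs3_floor,
                                     cp$updrs3_pd["q1"] - cp$updrs3_floor,
                                     cp$updrs3_pd["q3"] - cp$updrs3_floor)
  eps_u <- stats::rnorm(n)
  rho_u <- 0.5
  updrs_pd <- cp$updrs3_floor +
    exp(fu[["mu"]] + fu[["sigma"]] * (rho_u * x + sqrt(1 - rho_u^2) * eps_u))
  updrs_pd[deg <= 1e-9] <- cp$updrs3_floor
  updrs_hc <- exp(log(cp$updrs3_hc["median"] + 0.5) +
                    cp$updrs3_hc["sigma"] * (0.3 * x + sqrt(1 - 0.09) * eps_u)) - 0.5
  updrs3 <- pmax(0, round(ifelse(is_pd, updrs_pd, updrs_hc)))

  # H&Y by severity bands matching the reference stage frequencies.
  p_hy <- cp$hy_probs
  cut_lo <- stats::qnorm(p_hy[["1"]]); cut_hi <- stats::qnorm(1 - p_hy[["3"]])
  hy <- ifelse(is_pd, ifelse(x < cut_lo, 1L, ifelse(x > cut_hi, 3L, 2L)), 0L)

  fl <- fit_lognormal_from_quartiles(cp$ledd["median"], cp$ledd["q1"], cp$ledd["q3"])
  fd <- fit_lognormal_from_quartiles(cp$duration["median"], cp$duration["q1"],
                                     cp$duration["q3"])
  eps_l <- stats::rnorm(n); eps_d <- stats::rnorm(n)
  ledd <- ifelse(is_pd,
                 round(exp(fl[["mu"]] + fl[["sigma"]] *
                             (0.4 * x + sqrt(1 - 0.16) * eps_l))),
                 NA_real_)
  duration <- ifelse(is_pd,
                     round(exp(fd[["mu"]] + fd[["sigma"]] *
                                 (0.3 * x + sqrt(1 - 0.09) * eps_d)), 2),
                     NA_real_)

  subjects <- data.frame(
    id = id, group = group, age = round(age, 1), sex = sex,
    updrs3 = updrs3, hy_stage = hy, ledd = ledd, duration = duration,
    seed = vapply(seq_len(n), function(i) derive_seed(spec$seed, i), 1L),
    stringsAsFactors = FALSE
  )
  latent <- data.frame(
    id = id, group = group,
    severity = x, eta = eta,
    degeneration_L = deg_l, degeneration_R = deg_r,
    xi_L = xi_l, xi_R = xi_r,
    iron_elevation_L = 60 * deg_l, iron_elevation_R = 60 * deg_r,
    neuromelanin_L = 1 - 0.75 * deg_l, neuromelanin_R = 1 - 0.75 * deg_r,
    n1_intact_L = deg_l < spec$n1_loss_threshold,
    n1_intact_R = deg_r < spec$n1_loss_threshold,
    sn_scale = exp(stats::rnorm(n, 0, 0.05)),
    stringsAsFactors = FALSE
  )
  structure(list(subjects = subjects, latent = latent, spec = spec),
            class = "nigra_cohort")
}

#' @export
print.nigra_cohort <- function(x, ...) {
  cat(sprintf("nigra_cohort: %d subjects (%d PD, %d HC), seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == "PD"),
              sum(x$subjects$group == "HC"), x$spec$seed))
  invisible(x)
}

#' Draw per-hemisphere measures directly from the calibrated latent model
#'
#' Fast route bypassing image simulation and reconstruction: each of the four
#' quantitative SN measures is generated from its calibrated log-normal
#' loading on the subject's latent severity, per hemisphere, with measure
#' noise held on fixed per-subject random streams (common random numbers, so
#' increasing a subject's degeneration never increases a measure). The
#' composite is the product of the QSM-based volume, NMS-based volume and NMS
#' contrast range.
#'
#' @param cohort a \code{nigra_cohort}.
#' @return data.frame with one row per subject per side: \code{id}, \code{group},
#'   \code{side}, the four measures, and \code{composite}.
#' @export
measures_from_latent <- function(cohort) {
  stopifnot(inherits(cohort, "nigra_cohort"))
  spec <- cohort$spec
  lat <- cohort$latent
  n <- nrow(lat)
  loads <- measure_loadings(spec)
  # measure noise on a dedicated stream so it is invariant to latent edits
  set.seed(derive_seed(spec$seed, 0L, stage = 17L))
  eps <- lapply(seq_along(loads), function(i) stats::rnorm(n))
  names(eps) <- names(loads)

  side_vals <- function(side) {
    dcol <- paste0("degeneration_", side)
    xicol <- paste0("xi_", side)
    eta_s <- stats::qnorm(clamp01(lat[[dcol]])) + spec$side_noise * lat[[xicol]]
    out <- data.frame(id = lat$id, group = lat$group, side = side,
                      stringsAsFactors = FALSE)
    for (m in names(loads)) {
      l <- loads[[m]]
      out[[m]] <- exp(l[["a"]] - l[["b"]] * eta_s + l[["s"]] * eps[[m]])
    }
    out$composite <- out$qsm_based_volume * out$nms_based_volume *
      out$nms_contrast_range
    out
  }
  rbind(side_vals("L"), side_vals("R"))
}

#' Average per-hemisphere measures into aggregate (bilateral) values
#'
#' Left and right values of each continuous measure (including the composite)
#' are averaged per subject, mirroring the bilateral aggregation used for the
#' primary analysis.
#'
#' @param measures long data.frame as returned by \code{\link{measures_from_latent}}
#'   or the image-based quantification.
#' @return data.frame with one row per subject, \code{side = "aggregate"}.
#' @export
aggregate_measures <- function(measures) {
  cols <- setdiff(names(measures), c("id", "group", "side"))
  ids <- unique(measures$id)
  lt <- measures[measures$side == "L", ][match(ids, measures$id[measures$side == "L"]), ]
  rt <- measures[measures$side == "R", ][match(ids, measures$id[measures$side == "R"]), ]
  if (any(is.na(lt$id)) || any(is.na(rt$id)))
    stop("missing side: every subject needs both L and R rows")
  out <- data.frame(id = ids, group = lt$group, side = "aggregate",
                    stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- (lt[[cl]] + rt[[cl]]) / 2
  out
}
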