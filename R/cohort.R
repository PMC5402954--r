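# Synthetic study cohorts.
#
# The cohort generator reproduces the study structure of the reference
# population: 26 control eyes (one per control subject), 20 BRVO and 14 CRVO
# affected eyes, each occluded subject contributing an unaffected fellow eye,
# with stated per-group age and gender distributions. Between-eye correlation
# is driven by a per-subject latent severity scalar shared by both eyes.
#
# Two modes:
#  * "metrics" draws FD/VD/SD/VDI per eye and layer directly from the
#    latent-severity model, calibrated to the group means and SDs observed
#    in the source population; this is the fast path for Monte Carlo studies
#    of the statistics.
#  * "images" grows, perturbs and renders full synthetic angiograms per eye
#    and computes the metrics by actually quantifying the images (the
#    closed-loop path).

#' Calibration table for the metrics-mode cohort generator
#'
#' Group means and SDs per layer x group x metric (FD, VD, SD, VDI for
#' control, BRVO and CRVO affected eyes in the NS-RL, SRL and DRL slabs)
#' that the latent-severity draw is calibrated to. Edit a copy and pass it
#' to [cohort_spec()] to simulate other effect sizes.
#'
#' @return data.frame with columns `layer`, `group`, `metric`, `mean`, `sd`.
#' @export
metric_calibration <- function() {
  g <- function(layer, group, fd, fd_sd, vd, vd_sd, sd, sd_sd, vdi, vdi_sd)
    data.frame(layer = layer, group = group,
               metric = c("fd", "vd", "sd", "vdi"),
               mean = c(fd, vd, sd, vdi),
               sd = c(fd_sd, vd_sd, sd_sd, vdi_sd))
  rbind(
    g("NS-RL", "control", 1.72, 0.01, 0.43, 0.01, 0.099, 0.004, 4.37, 0.18),
    g("NS-RL", "BRVO",    1.68, 0.04, 0.36, 0.06, 0.080, 0.020, 4.39, 0.26),
    g("NS-RL", "CRVO",    1.59, 0.10, 0.26, 0.09, 0.060, 0.020, 4.51, 0.27),
    g("SRL",   "control", 1.71, 0.01, 0.43, 0.01, 0.094, 0.004, 4.56, 0.22),
    g("SRL",   "BRVO",    1.68, 0.04, 0.36, 0.05, 0.080, 0.010, 4.49, 0.23),
    g("SRL",   "CRVO",    1.62, 0.06, 0.29, 0.07, 0.060, 0.020, 4.63, 0.21),
    g("DRL",   "control", 1.72, 0.01, 0.42, 0.01, 0.098, 0.004, 4.31, 0.14),
    g("DRL",   "BRVO",    1.71, 0.03, 0.40, 0.05, 0.090, 0.010, 4.30, 0.16),
    g("DRL",   "CRVO",    1.69, 0.03, 0.37, 0.06, 0.090, 0.010, 4.35, 0.19))
}

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the reference study composition: 26 control subjects
#' (one eye each), 20 BRVO and 14 CRVO subjects (affected + fellow eye),
#' group age distributions 60.9 +/- 9.6, 63.3 +/- 9.2 and 67.0 +/- 8.1 years
#' (truncated to [40, 95]), and the stated female proportions.
#'
#' @param n_control,n_brvo,n_crvo subjects per group.
#' @param include_fellow include the unaffected fellow eye of each occluded
#'   subject.
#' @param rho between-eye correlation of the latent severity scalar, in
#'   [0, 1).
#' @param fellow_shift fraction of the affected-group mean shift applied to
#'   fellow eyes (0 = fellow eyes distributed like controls; small positive
#'   values emulate the sub-clinical fellow-eye changes seen in occlusion
#'   patients).
#' @param age_mean,age_sd named vectors (control, BRVO, CRVO).
#' @param female_prop named vector of female proportions per group.
#' @param edema_prob named vector (BRVO, CRVO) of macular edema probability
#'   for affected eyes.
#' @param logmar_mean,logmar_sd named vectors (control, BRVO, CRVO) for the
#'   affected-eye acuity draw (control value also used for fellow eyes).
#' @param pathology named list of [pathology_spec()] for affected eyes in
#'   images mode.
#' @param calibration layer x group x metric table of means and SDs for the
#'   metrics mode; defaults to the reference-population values.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 26, n_brvo = 20, n_crvo = 14,
                        include_fellow = TRUE, rho = 0.5, fellow_shift = 0.1,
                        age_mean = c(control = 60.9, BRVO = 63.3, CRVO = 67.0),
                        age_sd = c(control = 9.6, BRVO = 9.2, CRVO = 8.1),
                        female_prop = c(control = 0.577, BRVO = 0.60, CRVO = 0.571),
                        edema_prob = c(BRVO = 0.65, CRVO = 0.643),
                        logmar_mean = c(control = 0.05, BRVO = 0.31, CRVO = 1.09),
                        logmar_sd = c(control = 0.08, BRVO = 0.40, CRVO = 0.86),
                        pathology = list(
                          BRVO = pathology_spec("BRVO", wedge_center_deg = 90,
                                                wedge_extent_deg = 180,
                                                dropout_fraction = 0.45,
                                                survivor_dilation_factor = 1.15),
                          CRVO = pathology_spec("CRVO", dropout_fraction = 0.65,
                                                survivor_dilation_factor = 1.3)),
                        calibration = metric_calibration()) {
  if (n_control < 0 || n_brvo < 0 || n_crvo < 0)
    stop("group sizes must be non-negative", call. = FALSE)
  if (n_control + n_brvo + n_crvo == 0)
    stop("empty cohort", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  structure(list(n_control = n_control, n_brvo = n_brvo, n_crvo = n_crvo,
                 include_fellow = include_fellow, rho = rho,
                 fellow_shift = fellow_shift,
                 age_mean = age_mean, age_sd = age_sd,
                 female_prop = female_prop, edema_prob = edema_prob,
                 logmar_mean = logmar_mean, logmar_sd = logmar_sd,
                 pathology = pathology, calibration = calibration),
            class = "cohort_spec")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Generate a synthetic cohort
#'
#' Builds the long-format eye-level table consumed by the cohort statistics:
#' one row per eye and layer with covariates and the four microvascular
#' parameters. All randomness flows from `seed` through per-subject
#' substreams, so identical seeds give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed.
#' @param mode `"metrics"` (latent-severity draw calibrated to the reference
#'   population) or `"images"` (grow, perturb, render and quantify synthetic
#'   angiograms per eye).
#' @param layers layers to generate.
#' @param image_size_px canvas side for images mode.
#' @param keep_images in images mode, attach the per-eye rendered angiograms
#'   and ground-truth masks as attribute `"eyes"`.
#' @param base_coverage healthy capillary coverage target for images mode.
#' @return A `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `eye`, `rvo_status` (`control`/`fellow`/`RVO`), `rvo_type` (the eye's
#'   own: `none`/`BRVO`/`CRVO`), `subject_type`, `edema`, `age`, `gender`,
#'   `logmar`, `layer`, `fd`, `vd`, `sd`, `vdi`.
#' @export
generate_cohort <- function(spec, seed = 1L, mode = c("metrics", "images"),
                            layers = c("NS-RL", "SRL", "DRL"),
                            image_size_px = 1024, keep_images = FALSE,
                            base_coverage = 0.40) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  groups <- c(rep("control", spec$n_control), rep("BRVO", spec$n_brvo),
              rep("CRVO", spec$n_crvo))
  n_sub <- length(groups)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)

  rows <- vector("list", n_sub)
  eyes_out <- list()
  for (i in seq_len(n_sub)) {
    set.seed(sub_seeds[i])
    grp <- groups[i]
    sid <- sprintf("S%03d", i)
    age <- rtruncnorm1(spec$age_mean[[grp]], spec$age_sd[[grp]], 40, 95)
    gender <- if (stats::runif(1) < spec$female_prop[[grp]]) "F" else "M"
    u <- stats::rnorm(1)  # subject latent severity, shared between eyes

    if (grp == "control") {
      eye_tab <- data.frame(eye = sample(c("OD", "OS"), 1),
                            rvo_status = "control", rvo_type = "none",
                            edema = FALSE)
    } else {
      affected <- sample(c("OD", "OS"), 1)
      eye_tab <- data.frame(eye = affected, rvo_status = "RVO", rvo_type = grp,
                            edema = stats::runif(1) < spec$edema_prob[[grp]])
      if (spec$include_fellow)
        eye_tab <- rbind(eye_tab,
                         data.frame(eye = setdiff(c("OD", "OS"), affected),
                                    rvo_status = "fellow", rvo_type = "none",
                                    edema = FALSE))
    }

    sub_rows <- list()
    for (j in seq_len(nrow(eye_tab))) {
      st <- eye_tab$rvo_status[j]
      lg_grp <- if (st == "RVO") grp else "control"
      logmar <- rtruncnorm1(spec$logmar_mean[[lg_grp]], spec$logmar_sd[[lg_grp]],
                            -0.3, 3)
      e_eye <- sqrt(spec$rho) * u + sqrt(1 - spec$rho) * stats::rnorm(1)
      if (mode == "metrics") {
        met <- draw_metrics(spec, st, grp, layers, e_eye)
      } else {
        img_eye <- simulate_eye_images(spec, st, grp, e_eye, layers,
                                       image_size_px, base_coverage,
                                       eye_tab$edema[j],
                                       seed = sub_seeds[i] %% 100000L + j)
        met <- img_eye$metrics
        if (keep_images) {
          img_eye$images$subject_id <- sid
          img_eye$images$eye <- eye_tab$eye[j]
          eyes_out[[paste0(sid, "_", eye_tab$eye[j])]] <- img_eye$images
        }
      }
      sub_rows[[j]] <- data.frame(subject_id = sid, eye = eye_tab$eye[j],
                                  rvo_status = st, rvo_type = eye_tab$rvo_type[j],
                                  subject_type = grp, edema = eye_tab$edema[j],
                                  age = age, gender = gender, logmar = logmar,
                                  met, row.names = NULL)
    }
    rows[[i]] <- do.call(rbind, sub_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "seed") <- seed
  if (keep_images) attr(out, "eyes") <- eyes_out
  out
}

# metrics mode: value = group mean + group SD * per-eye latent, with VDI
# recomputed as VD/SD is NOT imposed here -- the four parameters are drawn
# on their observed marginal scales
draw_metrics <- function(spec, status, subject_grp, layers, e_eye) {
  cal <- spec$calibration
  out <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    lay <- layers[k]
    grp_eff <- if (status == "RVO") subject_grp else "control"
    base <- cal[cal$layer == lay & cal$group == grp_eff, ]
    vals <- numeric(4); names(vals) <- base$metric
    for (m in base$metric) {
      b <- base[base$metric == m, ]
      mu <- b$mean
      if (status == "fellow" && spec$fellow_shift != 0) {
        aff <- cal[cal$layer == lay & cal$group == subject_grp & cal$metric == m, ]
        mu <- mu + spec$fellow_shift * (aff$mean - mu)
      }
      # severity lowers FD/VD/SD and raises VDI
      sgn <- if (m == "vdi") 1 else -1
      vals[m] <- mu + sgn * b$sd * e_eye
    }
    vals["vd"] <- min(max(vals["vd"], 0.01), 1)
    vals["sd"] <- min(max(vals["sd"], 0.005), vals["vd"])
    vals["fd"] <- min(max(vals["fd"], 0.5), 2)
    vals["vdi"] <- max(vals["vdi"], 1)
    out[[k]] <- data.frame(layer = lay, fd = vals[["fd"]], vd = vals[["vd"]],
                           sd = vals[["sd"]], vdi = vals[["vdi"]])
  }
  do.call(rbind, out)
}

# images mode: two plexus networks (superficial, deep); the nonsegmented
# layer is the pixelwise maximum of the two rendered images
simulate_eye_images <- function(spec, status, subject_grp, e_eye, layers,
                                image_size_px, base_coverage, edema, seed) {
  cov_eye <- min(max(base_coverage * (1 - 0.04 * e_eye), 0.05), 0.85)
  blur <- 0
  path <- NULL
  if (status == "RVO") {
    path <- spec$pathology[[subject_grp]]
    if (edema && path$edema_blur_sigma_px > 0) blur <- path$edema_blur_sigma_px
  }
  mk_net <- function(n_trunks, sd_off) {
    ns <- vascular_network_spec(n_trunks = n_trunks, coverage = cov_eye,
                                coverage_check_px = image_size_px)
    net <- grow_network(ns, seed = seed + sd_off)
    if (!is.null(path)) net <- apply_pathology(net, path, seed = seed + sd_off + 1L)
    net
  }
  need_srl <- any(layers %in% c("SRL", "NS-RL"))
  need_drl <- any(layers %in% c("DRL", "NS-RL"))
  srl <- if (need_srl) mk_net(5L, 0L)
  drl <- if (need_drl) mk_net(3L, 1000L)
  rendered <- list()
  if (need_srl)
    rendered$SRL <- render_angiogram(srl, image_size_px, blur_sigma_px = blur,
                                     layer = "SRL", seed = seed + 7L)
  if (need_drl)
    rendered$DRL <- render_angiogram(drl, image_size_px, blur_sigma_px = blur,
                                     layer = "DRL", seed = seed + 8L)
  if ("NS-RL" %in% layers) {
    px <- pmax(rendered$SRL$angiogram$pixels, rendered$DRL$angiogram$pixels)
    rendered$`NS-RL` <- list(
      angiogram = enface_angiogram(px, fov_mm = 3, layer = "NS-RL"),
      truth = binary_vessel_map(rendered$SRL$truth$mask | rendered$DRL$truth$mask))
  }
  met <- lapply(layers, function(lay) {
    ms <- quantify(rendered[[lay]]$angiogram)
    data.frame(layer = lay, fd = ms$fd, vd = ms$vd, sd = ms$sd, vdi = ms$vdi)
  })
  list(metrics = do.call(rbind, met), images = rendered[layers])
}

#' Table-1-style cohort summary
#'
#' @param cohort a `cohort_table` (or compatible data.frame, one row per
#'   eye x layer).
#' @return A data.frame with per-group eye counts, gender and edema counts,
#'   age mean +/- SD, logMAR mean +/- SE and its Snellen equivalent.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  one <- cohort[!duplicated(paste(cohort$subject_id, cohort$eye)), ]
  split_by <- ifelse(one$rvo_status == "RVO", one$subject_type, one$rvo_status)
  do.call(rbind, lapply(split(one, split_by), function(d) {
    data.frame(group = ifelse(d$rvo_status[1] == "RVO", d$subject_type[1],
                              d$rvo_status[1]),
               n_eyes = nrow(d),
               n_subjects = length(unique(d$subject_id)),
               n_female = sum(d$gender == "F"),
               n_edema = sum(d$edema),
               age_mean = mean(d$age), age_sd = stats::sd(d$age),
               logmar_mean = mean(d$logmar),
               logmar_se = stats::sd(d$logmar) / sqrt(nrow(d)),
               snellen = logmar_to_snellen(mean(d$logmar)),
               row.names = NULL)
  }))
}
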