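# Synthetic cohort generator: complete subjects for the two asthma groups
# (A: reversible obstruction, B: fixed airway obstruction) with the
# statistical structure the downstream analysis assumes — demographics and
# lung function, CT-resolved airway trees at TLC and FRC, lobar volumes,
# lobe seeds for volume filling, PRM density pairs, and structural tables.

# Group-level distribution defaults. Means/SDs follow the published group
# summaries for asthma with and without fixed airway obstruction; heights
# and lung air volumes are plausible adult values consistent with the
# pressure magnitudes those summaries imply.
.cohort_defaults <- function() {
  list(
    n = c(A = 24L, B = 12L),
    n_male = c(A = 4L, B = 8L),
    age = list(A = c(mean = 62.583, sd = 11.100),
               B = c(mean = 63.667, sd = 13.089)),
    bmi = list(A = c(mean = 25.219, sd = 4.888),
               B = c(mean = 24.382, sd = 3.819)),
    height_male = c(mean = 1.70, sd = 0.06),
    height_female = c(mean = 1.57, sd = 0.055),
    pft = list( # %predicted FEV1/FVC and the FEV1/FVC ratio, pre/post
      fev1_pre = list(A = c(101.125, 18.755), B = c(76.917, 20.025)),
      fvc_pre = list(A = c(95.792, 13.584), B = c(87.417, 16.638)),
      fev1_fvc_pre = list(A = c(75.833, 5.113), B = c(61.250, 8.476)),
      fev1_post = list(A = c(102.913, 17.962), B = c(81.083, 21.284)),
      fvc_post = list(A = c(96.087, 12.986), B = c(91.500, 18.158)),
      fev1_fvc_post = list(A = c(77.130, 4.404), B = c(61.750, 7.461))),
    # per-lobe Dave* at FRC: mean, sd per group
    dave_star_frc = list(
      A = list(LUL = c(0.918, 0.107), LLL = c(0.927, 0.110),
               RUL = c(0.864, 0.147), RML = c(0.873, 0.139),
               RLL = c(0.876, 0.140)),
      B = list(LUL = c(0.969, 0.101), LLL = c(0.836, 0.123),
               RUL = c(0.809, 0.143), RML = c(0.864, 0.137),
               RLL = c(0.881, 0.158))),
    # per-branch inflation increment Dave*_TLC - Dave*_FRC: group A airways
    # dilate more on inflation than the stiffer, remodelled group B airways
    tlc_increment = list(A = c(mean = 0.10, sd = 0.02),
                         B = c(mean = 0.05, sd = 0.02)),
    # central-airway caliber relative to the predicted trachea (Dh*-like)
    central_dh_star = list(
      A = list(Trachea = c(1.035, 0.117), RMB = c(0.833, 0.094),
               BronInt = c(0.624, 0.066), LMB = c(0.662, 0.073)),
      B = list(Trachea = c(1.191, 0.160), RMB = c(0.926, 0.079),
               BronInt = c(0.691, 0.056), LMB = c(0.755, 0.108))),
    central_frc_ratio = 0.92, # central caliber at FRC relative to TLC
    # normalized wall thickness per structural region
    wt_star = list(
      A = list(Trachea = c(0.996, 0.120), RMB = c(0.891, 0.188),
               BronInt = c(0.676, 0.064), TriRLL = c(0.611, 0.041),
               LMB = c(0.710, 0.115), TriLLB = c(0.640, 0.051),
               sRUL = c(0.595, 0.033), sRML = c(0.570, 0.069),
               sRLL = c(0.573, 0.038), sLUL = c(0.535, 0.037),
               sLLL = c(0.589, 0.041)),
      B = list(Trachea = c(1.061, 0.097), RMB = c(1.042, 0.095),
               BronInt = c(0.712, 0.077), TriRLL = c(0.671, 0.075),
               LMB = c(0.845, 0.193), TriLLB = c(0.704, 0.060),
               sRUL = c(0.645, 0.075), sRML = c(0.632, 0.059),
               sRLL = c(0.606, 0.057), sLUL = c(0.578, 0.054),
               sLLL = c(0.642, 0.069))),
    wt_reference_mm = 1.5,
    # PRM class targets per lobe (percent)
    emph_pct = list(
      A = c(LUL = 0.192, LLL = 0.222, RUL = 0.084, RML = 0.397, RLL = 0.176),
      B = c(LUL = 0.631, LLL = 1.951, RUL = 0.792, RML = 1.266, RLL = 1.126)),
    fsad_pct = list(
      A = c(LUL = 5.613, LLL = 3.228, RUL = 4.708, RML = 12.356, RLL = 3.316),
      B = c(LUL = 17.236, LLL = 16.373, RUL = 14.129, RML = 26.318, RLL = 9.097)),
    voxels_per_lobe = 2000L,
    insp_threshold = -950, exp_threshold = -856,
    # lung air volumes (L): FRC air trapping separates the groups and sets
    # the transpulmonary pressure magnitude through V / C
    frc_air = list(A = c(mean = 1.28, sd = 0.36), B = c(mean = 1.82, sd = 0.59)),
    insp_capacity = c(mean = 2.6, sd = 0.4), # TLC air = FRC air + this
    lobe_fraction = c(LUL = 0.22, LLL = 0.20, RUL = 0.20, RML = 0.08, RLL = 0.30),
    points_per_segment = 24L,
    seed = 20240107L)
}

#' Cohort generation parameters
#'
#' Returns the default parameter list for [generate_cohort()], optionally
#' overridden. Defaults encode the two study groups: sizes 24 (A, without
#' fixed obstruction) and 12 (B, with), the published sex splits, age,
#' BMI and lung-function distributions, per-lobe Dave* means/SDs at FRC,
#' lobar Emph%/fSAD% targets, and group-separated FRC air volumes.
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   replaced wholesale).
#' @return Parameter list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- utils::modifyList(.cohort_defaults(), list(...))
  stopifnot(all(p$n >= 2), all(p$n_male <= p$n), all(p$n_male >= 0))
  for (g in c("A", "B")) {
    infeasible <- p$emph_pct[[g]] + p$fsad_pct[[g]] > 100
    if (any(infeasible)) {
      stop("infeasible PRM targets (Emph% + fSAD% > 100) in group ", g,
           call. = FALSE)
    }
  }
  class(p) <- c("cohort_params", "list")
  p
}

# segment labels per lobe (19 segments; RB7 is absent by convention)
.lobe_segments <- list(
  RUL = c("RB1", "RB2", "RB3"), RML = c("RB4", "RB5"),
  RLL = c("RB6", "RB8", "RB9", "RB10"), LUL = c("LB1", "LB2", "LB3", "LB4", "LB5"),
  LLL = c("LB6", "LB7", "LB8", "LB9", "LB10"))

.lobe_centers <- rbind(LUL = c(-60, 12, -95), LLL = c(-62, -10, -185),
                       RUL = c(58, 10, -80), RML = c(52, 22, -160),
                       RLL = c(62, -14, -195))
.lobe_axes <- rbind(LUL = c(32, 30, 42), LLL = c(30, 30, 40),
                    RUL = c(32, 30, 38), RML = c(26, 24, 30),
                    RLL = c(32, 30, 42))

.trunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower | out > upper
  guard <- 0L
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower | out > upper
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated sampling failed to converge", call. = FALSE)
  }
  out
}

# Build the canonical resolved tree template for one subject at one state.
# `dave_draws` holds the per-branch Dave* multipliers for lobe-labelled
# branches (named by segment/lobar key); `central` the central Dh*-like
# scales. Geometry is a fixed anatomical layout scaled by `coord_scale`.
.template_tree <- function(demo, dave_draws, central, state, coord_scale = 1,
                           table = daver_table()) {
  dtr <- predict_trachea_diameter(demo)
  nodes <- list(c(1, 0, 0, 0), c(2, 0, 0, -100), c(3, 28, 0, -118),
                c(4, -32, 0, -122), c(5, 52, 8, -92), c(6, 40, -4, -150),
                c(7, -55, 10, -100), c(8, -52, -8, -165), c(9, 48, 18, -160),
                c(10, 55, -12, -185))
  # id, parent, prox, dist, lobe, generation
  core <- list(
    list(1L, NA_integer_, 1L, 2L, "central", 1L, "Trachea"),
    list(2L, 1L, 2L, 3L, "central", 2L, "RMB"),
    list(3L, 1L, 2L, 4L, "central", 2L, "LMB"),
    list(4L, 2L, 3L, 5L, "RUL", 3L, "RUL_lobar"),
    list(5L, 2L, 3L, 6L, "central", 3L, "BronInt"),
    list(6L, 3L, 4L, 7L, "LUL", 3L, "LUL_lobar"),
    list(7L, 3L, 4L, 8L, "LLL", 3L, "TriLLB"),
    list(8L, 5L, 6L, 9L, "RML", 4L, "RML_lobar"),
    list(9L, 5L, 6L, 10L, "RLL", 4L, "TriRLL"))
  br <- do.call(rbind, lapply(core, function(b) {
    data.frame(id = b[[1]], parent = b[[2]], prox_node = b[[3]],
               dist_node = b[[4]], lobe = b[[5]], generation = b[[6]],
               key = b[[7]], stringsAsFactors = FALSE)
  }))
  # segmental branches fan out from the lobar bronchus toward the lobe
  lobar_of <- c(RUL = 4L, RML = 8L, RLL = 9L, LUL = 6L, LLL = 7L)
  nid <- 10L; bid <- 9L
  for (lb in names(.lobe_segments)) {
    segs <- .lobe_segments[[lb]]
    k <- length(segs)
    parent <- lobar_of[[lb]]
    prow <- br[br$id == parent, ]
    ctr <- .lobe_centers[lb, ]
    for (j in seq_len(k)) {
      ang <- 2 * pi * (j - 0.5) / k
      tip <- ctr + c(14 * cos(ang), 14 * sin(ang), 10 * (j %% 2) - 5)
      nid <- nid + 1L; bid <- bid + 1L
      nodes[[nid]] <- c(nid, tip)
      br <- rbind(br, data.frame(id = bid, parent = parent,
                                 prox_node = prow$dist_node, dist_node = nid,
                                 lobe = lb, generation = prow$generation + 1L,
                                 key = segs[j], stringsAsFactors = FALSE))
    }
  }
  nodes <- as.data.frame(do.call(rbind, nodes))
  names(nodes) <- c("id", "x", "y", "z")
  nodes[, c("x", "y", "z")] <- nodes[, c("x", "y", "z")] * coord_scale
  # diameters: central from Dh*-like scales of the predicted trachea;
  # lobe-labelled from Eq.-style predicted generation diameter x Dave*
  diam <- numeric(nrow(br))
  for (i in seq_len(nrow(br))) {
    if (br$lobe[i] == "central") {
      key <- br$key[i]
      diam[i] <- dtr * central[[key]]
    } else {
      diam[i] <- dtr * lookup_daver(br$lobe[i], br$generation[i], table) *
        dave_draws[[br$key[i]]]
    }
  }
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  len <- sqrt(rowSums((xyz[br$dist_node, ] - xyz[br$prox_node, ])^2))
  br$order <- NA_integer_
  br$diameter_mm <- diam
  br$length_mm <- len
  br$resolved <- TRUE
  key <- br$key
  br$key <- NULL
  tree <- airway_tree(nodes, br, state = state)
  attr(tree, "region_key") <- stats::setNames(key, br$id)
  tree
}

# Solve PRM mixture weights so expected class percentages hit the targets.
.prm_mixture_weights <- function(emph_pct, fsad_pct, insp_threshold = -950,
                                 exp_threshold = -856) {
  comps <- list(E = list(insp = c(-980, 15), exp = c(-980, 15)),
                F = list(insp = c(-880, 25), exp = c(-880, 20)),
                N = list(insp = c(-850, 40), exp = c(-750, 60)))
  M <- sapply(comps, function(cp) {
    pI <- stats::pnorm(insp_threshold, cp$insp[1], cp$insp[2])
    pX <- stats::pnorm(exp_threshold, cp$exp[1], cp$exp[2])
    c(emph = pI, fsad = (1 - pI) * pX, normal = (1 - pI) * (1 - pX))
  })
  t <- c(emph_pct, fsad_pct, 100 - emph_pct - fsad_pct) / 100
  w <- solve(M, t)
  w <- pmax(w, 0)
  list(weights = w / sum(w), components = comps)
}

# Draw density pairs for one lobe (clamped to the valid HU window).
.draw_density_pairs <- function(n, emph_pct, fsad_pct, insp_threshold,
                                exp_threshold) {
  mix <- .prm_mixture_weights(emph_pct, fsad_pct, insp_threshold, exp_threshold)
  comp <- sample(names(mix$components), n, replace = TRUE, prob = mix$weights)
  insp <- exp_ <- numeric(n)
  for (k in names(mix$components)) {
    at <- comp == k
    cp <- mix$components[[k]]
    insp[at] <- stats::rnorm(sum(at), cp$insp[1], cp$insp[2])
    exp_[at] <- stats::rnorm(sum(at), cp$exp[1], cp$exp[2])
  }
  data.frame(insp_hu = pmin(pmax(insp, -1024), 200),
             exp_hu = pmin(pmax(exp_, -1024), 200))
}

#' Generate one synthetic subject
#'
#' Draws demographics and lung function from the group's distributions,
#' builds the canonical resolved airway-tree template (trachea through the
#' 19 labelled segmental bronchi) at TLC and FRC with per-branch Dave*
#' draws (TLC caliber exceeds FRC caliber branchwise by construction),
#' samples lobar PRM density pairs from a three-component HU mixture whose
#' weights are solved to hit the group's lobe targets, and attaches lobe
#' seeds and air volumes.
#'
#' @param group `"A"` (without fixed obstruction) or `"B"` (with).
#' @param params A [cohort_params()] list.
#' @param id Subject identifier.
#' @param sex Optional fixed sex code (0/1); by default drawn from the
#'   group's sex ratio.
#' @param seed Optional integer seed for subject-level reproducibility.
#' @return An object of class `subject_record`.
#' @export
generate_subject <- function(group = c("A", "B"), params = cohort_params(),
                             id = "S1", sex = NULL, seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sex)) {
    sex <- stats::rbinom(1, 1, 1 - params$n_male[[group]] / params$n[[group]])
  }
  hgt <- if (sex == 0) params$height_male else params$height_female
  demo <- demographics(sex = sex,
                       height = .trunc_norm(1, hgt["mean"], hgt["sd"], 1.3, 2.1),
                       age = .trunc_norm(1, params$age[[group]]["mean"],
                                         params$age[[group]]["sd"], 18, 100))
  pft <- lapply(params$pft, function(v) stats::rnorm(1, v[[group]][1], v[[group]][2]))
  # the fixed-obstruction label is defined by post-bronchodilator FEV1/FVC < 70
  lim <- params$pft$fev1_fvc_post[[group]]
  pft$fev1_fvc_post <- if (group == "B") .trunc_norm(1, lim[1], lim[2], -Inf, 69.99)
                       else .trunc_norm(1, lim[1], lim[2], 70.01, Inf)
  pft$bmi <- stats::rnorm(1, params$bmi[[group]]["mean"], params$bmi[[group]]["sd"])

  # per-branch constriction draws: FRC from the group's lobar Dave*
  # distributions, TLC = FRC + positive inflation increment
  keys <- c(paste0(names(.lobe_segments), "_lobar"), unlist(.lobe_segments))
  keys[1:5] <- c("RUL_lobar", "RML_lobar", "TriRLL", "LUL_lobar", "TriLLB")
  lobe_of_key <- c(stats::setNames(names(.lobe_segments),
                                   c("RUL_lobar", "RML_lobar", "TriRLL",
                                     "LUL_lobar", "TriLLB")),
                   stats::setNames(rep(names(.lobe_segments),
                                       lengths(.lobe_segments)),
                                   unlist(.lobe_segments)))
  inc <- params$tlc_increment[[group]]
  frc_draw <- tlc_draw <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    ds <- params$dave_star_frc[[group]][[lobe_of_key[[k]]]]
    frc_draw[k] <- .trunc_norm(1, ds[1], ds[2], 0.051, Inf)
    tlc_draw[k] <- frc_draw[k] + .trunc_norm(1, inc["mean"], inc["sd"], 0.01, Inf)
  }
  central_tlc <- lapply(params$central_dh_star[[group]],
                        function(v) .trunc_norm(1, v[1], v[2], 0.1, Inf))
  central_frc <- lapply(central_tlc, function(v) v * params$central_frc_ratio)

  # air volumes; lobar split by fixed anatomical fractions
  fa <- params$frc_air[[group]]
  frc_air <- .trunc_norm(1, fa["mean"], fa["sd"], 0.6, Inf)
  tlc_air <- frc_air + .trunc_norm(1, params$insp_capacity["mean"],
                                   params$insp_capacity["sd"], 1.2, Inf)
  coord_scale_tlc <- 1
  coord_scale_frc <- (frc_air / tlc_air)^(1 / 3)

  tree_tlc <- .template_tree(demo, as.list(tlc_draw), central_tlc, "TLC",
                             coord_scale_tlc)
  tree_frc <- .template_tree(demo, as.list(frc_draw), central_frc, "FRC",
                             coord_scale_frc)

  lobe_tlc <- params$lobe_fraction * tlc_air
  lobe_frc <- params$lobe_fraction * frc_air
  seeds <- lapply(LOBES, function(lb) {
    npts <- params$points_per_segment * length(.lobe_segments[[lb]])
    u <- matrix(stats::rnorm(3 * npts), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * stats::runif(npts)^(1 / 3)
    pts <- u %*% diag(.lobe_axes[lb, ]) +
      matrix(.lobe_centers[lb, ], npts, 3, byrow = TRUE)
    lobe_seed(lb, pts, tlc_volume_L = lobe_tlc[[lb]], frc_volume_L = lobe_frc[[lb]])
  })
  names(seeds) <- LOBES

  dens <- do.call(rbind, lapply(LOBES, function(lb) {
    d <- .draw_density_pairs(params$voxels_per_lobe,
                             params$emph_pct[[group]][[lb]],
                             params$fsad_pct[[group]][[lb]],
                             params$insp_threshold, params$exp_threshold)
    d$lobe <- lb
    d
  }))

  # structural table: hydraulic geometry read off the TLC tree (circular
  # lumen), wall thickness drawn around the group's normalized profile
  rk <- attr(tree_tlc, "region_key")
  region_d <- function(region) {
    ids <- switch(region,
                  Trachea = "Trachea", RMB = "RMB", LMB = "LMB",
                  BronInt = "BronInt", TriRLL = "TriRLL", TriLLB = "TriLLB",
                  sRUL = .lobe_segments$RUL, sRML = .lobe_segments$RML,
                  sRLL = .lobe_segments$RLL, sLUL = paste0("LB", 1:5),
                  sLLL = c("LB6", "LB8", "LB9", "LB10"))
    bid <- as.integer(names(rk)[rk %in% ids])
    mean(tree_tlc$branches$diameter_mm[match(bid, tree_tlc$branches$id)])
  }
  structure_df <- do.call(rbind, lapply(STRUCTURE_REGIONS, function(rg) {
    d <- region_d(rg)
    wt <- params$wt_reference_mm *
      .trunc_norm(1, params$wt_star[[group]][[rg]][1],
                  params$wt_star[[group]][[rg]][2], 0.05, Inf)
    data.frame(region = rg, lumen_area_mm2 = pi * d^2 / 4,
               lumen_perimeter_mm = pi * d, wt_mm = wt,
               stringsAsFactors = FALSE)
  }))

  structure(list(id = id, group = group, demographics = demo, pft = pft,
                 tree_tlc = tree_tlc, tree_frc = tree_frc, seeds = seeds,
                 densities = dens, structure = structure_df,
                 frc_air_L = frc_air, tlc_air_L = tlc_air,
                 lobar_volumes = data.frame(lobe = LOBES,
                                            tlc_L = as.numeric(lobe_tlc[LOBES]),
                                            frc_L = as.numeric(lobe_frc[LOBES]))),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("subject_record %s (group %s): %s, age %.0f, FRC %.2f L / TLC %.2f L\n",
              x$id, x$group, if (x$demographics$sex == 0) "male" else "female",
              x$demographics$age, x$frc_air_L, x$tlc_air_L))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_A + n_B` subjects under the master seed, with sex assigned to
#' match the configured group sex counts exactly. Deterministic given the
#' seed.
#'
#' @param params A [cohort_params()] list (its `seed` element is the
#'   master seed).
#' @return List of [generate_subject()] records with group labels.
#' @export
generate_cohort <- function(params = cohort_params()) {
  set.seed(params$seed)
  out <- list()
  for (g in c("A", "B")) {
    n <- params$n[[g]]
    sexes <- sample(rep(c(0L, 1L), c(params$n_male[[g]], n - params$n_male[[g]])))
    for (i in seq_len(n)) {
      id <- sprintf("%s%02d", g, i)
      out[[id]] <- generate_subject(g, params, id = id, sex = sexes[i])
    }
  }
  out
}

#' Quality-control filter on expiratory effort
#'
#' Subjects whose expiratory-to-inspiratory lung volume ratio exceeds 90%
#' show inadequate expiration and are excluded (strict inequality: a
#' ratio of exactly 0.9 is kept).
#'
#' @param subject A `subject_record`.
#' @return List with `included` (logical) and `reason` (string or `NA`).
#' @export
qc_filter <- function(subject) {
  if (is.null(subject$frc_air_L) || is.null(subject$tlc_air_L) ||
      !is.finite(subject$frc_air_L) || !is.finite(subject$tlc_air_L)) {
    stop("subject lacks inspiratory/expiratory volumes", call. = FALSE)
  }
  ratio <- subject$frc_air_L / subject$tlc_air_L
  if (ratio > 0.9) list(included = FALSE, reason = "inadequate expiration")
  else list(included = TRUE, reason = NA_character_)
}

#' Write a cohort to a directory
#'
#' `cohort.csv` holds per-subject metadata; each subject's trees are
#' written under `trees/<id>/<state>/`; `densities.csv` pools the PRM
#' pairs; `manifest.json` records the seed and group sizes.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @param params The [cohort_params()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(id = s$id, group = s$group, sex = s$demographics$sex,
               height_m = s$demographics$height, age_y = s$demographics$age,
               frc_air_L = s$frc_air_L, tlc_air_L = s$tlc_air_L,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  dens <- do.call(rbind, lapply(cohort, function(s) {
    d <- s$densities; d$id <- s$id; d
  }))
  utils::write.csv(dens, file.path(dir, "densities.csv"), row.names = FALSE)
  for (s in cohort) {
    write_airway_tree(s$tree_tlc, file.path(dir, "trees", s$id, "TLC"))
    write_airway_tree(s$tree_frc, file.path(dir, "trees", s$id, "FRC"))
  }
  manifest <- list(seed = if (!is.null(params)) params$seed else NA,
                   n = vapply(split(meta$id, meta$group), length, integer(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
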