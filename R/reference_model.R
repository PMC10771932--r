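# Healthy-reference airway geometry: predicted tracheal diameter from
# demographics, generational healthy diameter ratios (Daver) per lobe,
# predicted generation diameters, and the constriction index Dave*.

LOBES <- c("LUL", "LLL", "RUL", "RML", "RLL")

.pkg_env <- new.env(parent = emptyenv())

#' Subject demographics
#'
#' Constructs and validates the demographic triplet that drives the
#' healthy-reference tracheal diameter model: sex (coded 0 = male,
#' 1 = female), standing height in meters, and age in years.
#'
#' @param sex Integer code, 0 (male) or 1 (female).
#' @param height Height in meters; must lie in (0.5, 2.5).
#' @param age Age in years; must be at least 18.
#' @return An object of class `demographics` (a named list).
#' @examples
#' demographics(sex = 0, height = 1.70, age = 60)
#' @export
demographics <- function(sex, height, age) {
  if (length(sex) != 1 || !sex %in% c(0, 1)) {
    stop("`sex` must be 0 (male) or 1 (female)", call. = FALSE)
  }
  if (!is.numeric(height) || length(height) != 1 || !is.finite(height) ||
      height <= 0.5 || height >= 2.5) {
    stop("`height` must be a single value in meters, strictly between 0.5 and 2.5",
         call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1 || !is.finite(age) || age < 18) {
    stop("`age` must be a single value of at least 18 years", call. = FALSE)
  }
  structure(list(sex = as.integer(sex), height = height, age = age),
            class = "demographics")
}

#' @export
print.demographics <- function(x, ...) {
  cat(sprintf("demographics: sex=%s, height=%.2f m, age=%.0f y\n",
              if (x$sex == 0) "male" else "female", x$height, x$age))
  invisible(x)
}

#' Predicted tracheal diameter from sex, height and age
#'
#' Regression model of tracheal diameter fitted to 222 healthy Korean
#' adults:
#' \deqn{D = 12.79 - 0.13\,\ln(age) - 5.82\,\ln(height)\,sex
#'       + 3.01\,\ln(age)\,\ln(height)}
#' with height in meters, age in years, sex coded 0 (male) / 1 (female),
#' and natural logarithms throughout.
#'
#' @param demo A [demographics()] object.
#' @return Predicted tracheal diameter in mm (strictly positive).
#' @examples
#' predict_trachea_diameter(demographics(0, 1.70, 60)) # 18.797 mm
#' @export
predict_trachea_diameter <- function(demo) {
  if (!inherits(demo, "demographics")) demo <- do.call(demographics, as.list(demo))
  d <- 12.79 - 0.13 * log(demo$age) - 5.82 * log(demo$height) * demo$sex +
    3.01 * log(demo$age) * log(demo$height)
  if (!is.finite(d) || d <= 0) {
    stop("predicted tracheal diameter is nonpositive for these demographics",
         call. = FALSE)
  }
  d
}

#' Healthy generational diameter-ratio table (Daver)
#'
#' Loads the reference table of generational mean diameter ratios
#' Daver = Dave / Dtrachea,pred measured in five lung lobes of 222 healthy
#' Korean adults (mean and standard error per lobe and generation;
#' generation 1 is the trachea). The packaged table covers LUL/LLL/RUL
#' generations 2-7, RML 3-7 and RLL 3-10. A user-supplied CSV with
#' columns `lobe, generation, mean, se` may override the packaged one.
#'
#' @param path Optional path to a replacement CSV file.
#' @return A data.frame of class `daver_table` with columns
#'   `lobe`, `generation`, `mean`, `se`.
#' @export
daver_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkg_env$daver)) return(.pkg_env$daver)
    path <- system.file("extdata", "daver_table.csv", package = "airwaycfd",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("lobe", "generation", "mean", "se")
  if (!all(req %in% names(tab))) {
    stop("Daver table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(tab$lobe %in% LOBES), all(tab$generation >= 2),
            all(tab$mean > 0 & tab$mean < 1), all(tab$se >= 0))
  # ratios must fall off with depth within every lobe
  for (lb in unique(tab$lobe)) {
    m <- tab$mean[tab$lobe == lb][order(tab$generation[tab$lobe == lb])]
    if (any(diff(m) >= 0)) {
      stop("Daver ratios must strictly decrease with generation in lobe ", lb,
           call. = FALSE)
    }
  }
  class(tab) <- c("daver_table", "data.frame")
  if (cache) .pkg_env$daver <- tab
  tab
}

#' Look up the healthy diameter ratio for a lobe and generation
#'
#' Returns the tabulated mean Daver for `(lobe, generation)`. Generations
#' deeper than the deepest tabulated one reuse the deepest tabulated value
#' (the ratios flatten with depth); generations shallower than the lobe's
#' first tabulated entry are an error.
#'
#' @param lobe One of `"LUL", "LLL", "RUL", "RML", "RLL"`.
#' @param generation Integer generation (trachea = 1, so lobar entries
#'   start at 2 or 3).
#' @param table A [daver_table()]; defaults to the packaged one.
#' @return Dimensionless mean diameter ratio in (0, 1).
#' @examples
#' lookup_daver("LUL", 2)  # 0.567
#' lookup_daver("LUL", 9)  # clamped to the generation-7 value, 0.167
#' @export
lookup_daver <- function(lobe, generation, table = daver_table()) {
  stopifnot(length(lobe) == length(generation) || length(lobe) == 1 ||
              length(generation) == 1)
  n <- max(length(lobe), length(generation))
  lobe <- rep_len(as.character(lobe), n)
  generation <- rep_len(generation, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (!lobe[i] %in% LOBES) stop("unknown lobe: ", lobe[i], call. = FALSE)
    g <- generation[i]
    if (!is.finite(g) || g != round(g) || g < 2) {
      stop("generation must be an integer >= 2", call. = FALSE)
    }
    sub <- table[table$lobe == lobe[i], ]
    if (g < min(sub$generation)) {
      stop(sprintf("Daver is undefined for lobe %s at generation %d (first tabulated: %d)",
                   lobe[i], as.integer(g), min(sub$generation)), call. = FALSE)
    }
    g <- min(g, max(sub$generation))
    out[i] <- sub$mean[sub$generation == g]
  }
  out
}

#' Predicted healthy average diameter for a lobe and generation
#'
#' Dave,pred = Dtrachea,pred x Daver: the predicted tracheal diameter for
#' the subject scaled by the healthy generational ratio.
#'
#' @inheritParams lookup_daver
#' @param demo A [demographics()] object.
#' @return Predicted diameter in mm.
#' @export
predict_generation_diameter <- function(demo, lobe, generation,
                                        table = daver_table()) {
  predict_trachea_diameter(demo) * lookup_daver(lobe, generation, table)
}

#' Constriction/dilation index Dave*
#'
#' Dave* = Dave / Dave,pred: the measured average diameter divided by its
#' healthy predicted value. Values near 1 indicate normal caliber; below 1,
#' constriction; above 1, dilation.
#'
#' @param measured Measured diameter(s), mm. Must be positive.
#' @param predicted Predicted healthy diameter(s), mm. Must be positive.
#' @return Dimensionless ratio(s).
#' @export
constriction_index <- function(measured, predicted) {
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured diameter must be positive", call. = FALSE)
  }
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("predicted diameter must be positive", call. = FALSE)
  }
  measured / predicted
}

#' Per-lobe constriction statistics from CT-resolved airways
#'
#' Computes Dave* for every CT-resolved, lobe-labelled branch of a tree
#' and summarizes it per lobe as the sample mean and standard deviation
#' (denominator n - 1; a single-branch lobe reports SD = 0). Only
#' resolved branches enter; generated (unresolved) branches never do.
#'
#' @param tree An [airway_tree()].
#' @param demo A [demographics()] object.
#' @param table A [daver_table()].
#' @param lobes Lobes to summarize (default: every lobe present).
#' @return A data.frame of class `constriction_stats` with columns
#'   `lobe`, `mean`, `sd`, `n`, `state`.
#' @export
lobar_constriction_stats <- function(tree, demo, table = daver_table(),
                                     lobes = NULL) {
  br <- tree$branches
  res <- br[br$resolved & br$lobe %in% LOBES, ]
  if (is.null(lobes)) lobes <- intersect(LOBES, unique(res$lobe))
  missing <- setdiff(lobes, unique(res$lobe))
  if (length(missing)) {
    stop("no CT-resolved branches in lobe(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dtr <- predict_trachea_diameter(demo)
  out <- lapply(lobes, function(lb) {
    sub <- res[res$lobe == lb, ]
    pred <- dtr * lookup_daver(sub$lobe, sub$generation, table)
    ds <- constriction_index(sub$diameter_mm, pred)
    data.frame(lobe = lb, mean = mean(ds),
               sd = if (nrow(sub) > 1) stats::sd(ds) else 0,
               n = nrow(sub), state = tree$state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("constriction_stats", "data.frame")
  out
}

#' Sample stochastic constriction multipliers for a lobe
#'
#' Draws from Normal(mean, SD) of the lobe's Dave* statistics, redrawing
#' any value at or below 0.05 (a nonpositive or near-zero diameter
#' multiplier is unphysical). With SD = 0 the mean is returned exactly.
#' Reproducible given the caller's RNG seed.
#'
#' @param stats A `constriction_stats` data.frame (see
#'   [lobar_constriction_stats()]).
#' @param lobe Lobe label to sample for.
#' @param n Number of draws.
#' @return Numeric vector of `n` multipliers, all > 0.05.
#' @export
sample_constriction_multiplier <- function(stats, lobe, n = 1) {
  row <- stats[stats$lobe == lobe, ]
  if (nrow(row) != 1) stop("no constriction statistics for lobe ", lobe, call. = FALSE)
  m <- row$mean; s <- row$sd
  if (s == 0) {
    if (m <= 0.05) stop("degenerate multiplier distribution at or below the positivity guard",
                        call. = FALSE)
    return(rep(m, n))
  }
  out <- stats::rnorm(n, m, s)
  bad <- out <= 0.05
  guard <- 0L
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), m, s)
    bad <- out <= 0.05
    guard <- guard + 1L
    if (guard > 10000L) stop("positivity guard failed to converge", call. = FALSE)
  }
  out
}
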