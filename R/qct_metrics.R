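# Parametric-response-map functional metrics (Emph%, fSAD%) from paired
# registered voxel densities, and normalized structural metrics (hydraulic
# diameter, wall thickness) over the standard 11 airway regions.

#' The 11 structural regions
#'
#' Six central branches (trachea, right/left main bronchi, bronchus
#' intermedius, and the lower-lobe trifurcations) plus five subgrouped
#' segmental regions averaging their constituent segments.
#' @export
STRUCTURE_REGIONS <- c("Trachea", "RMB", "BronInt", "TriRLL", "LMB",
                       "TriLLB", "sRUL", "sRML", "sRLL", "sLUL", "sLLL")

#' PRM voxel classification
#'
#' Classifies registered inspiratory/expiratory voxel density pairs:
#' emphysema when the inspiratory density falls below the inspiratory
#' threshold; else functional small airway disease (air trapping) when
#' the expiratory density falls below the expiratory threshold; else
#' normal. Defaults are the standard parametric-response-map thresholds,
#' -950 HU (inspiratory) and -856 HU (expiratory); both are adjustable.
#'
#' @param insp_hu,exp_hu Paired voxel densities, HU (vectorized).
#' @param insp_threshold,exp_threshold Classification thresholds, HU; the
#'   inspiratory threshold must lie below the expiratory one.
#' @return Character vector in `{"Emph", "fSAD", "Normal"}`.
#' @export
classify_voxel <- function(insp_hu, exp_hu, insp_threshold = -950,
                           exp_threshold = -856) {
  if (insp_threshold >= exp_threshold) {
    stop("inspiratory threshold must lie below the expiratory threshold",
         call. = FALSE)
  }
  ifelse(insp_hu < insp_threshold, "Emph",
         ifelse(exp_hu < exp_threshold, "fSAD", "Normal"))
}

#' Lobar and total PRM percentages
#'
#' Percent of voxels per class for each lobe and for the pooled total
#' lung (the total pools voxels; it is not a mean of lobe percentages).
#'
#' @param pairs data.frame with columns `insp_hu`, `exp_hu`, `lobe`.
#' @param lobes Lobes required in the output (default: the five lobes).
#' @inheritParams classify_voxel
#' @return data.frame with columns `region` (lobes then `"Total"`),
#'   `emph_pct`, `fsad_pct`, `normal_pct`, `n_voxels`.
#' @export
lobe_percentages <- function(pairs, lobes = LOBES, insp_threshold = -950,
                             exp_threshold = -856) {
  stopifnot(all(c("insp_hu", "exp_hu", "lobe") %in% names(pairs)))
  missing <- setdiff(lobes, unique(pairs$lobe))
  if (length(missing)) {
    stop("no density pairs for lobe(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cls <- classify_voxel(pairs$insp_hu, pairs$exp_hu, insp_threshold, exp_threshold)
  one <- function(region, mask) {
    n <- sum(mask)
    data.frame(region = region,
               emph_pct = 100 * sum(cls[mask] == "Emph") / n,
               fsad_pct = 100 * sum(cls[mask] == "fSAD") / n,
               normal_pct = 100 * sum(cls[mask] == "Normal") / n,
               n_voxels = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(lobes, function(lb) one(lb, pairs$lobe == lb)))
  rbind(out, one("Total", pairs$lobe %in% lobes))
}

#' Hydraulic diameter
#'
#' Dh = 4 A / P for a lumen of cross-sectional area A and perimeter P;
#' equals the geometric diameter for a circular lumen.
#'
#' @param lumen_area_mm2 Lumen area, mm^2 (> 0).
#' @param lumen_perimeter_mm Lumen perimeter, mm (> 0).
#' @return Hydraulic diameter, mm.
#' @export
hydraulic_diameter <- function(lumen_area_mm2, lumen_perimeter_mm) {
  if (any(lumen_area_mm2 <= 0) || any(lumen_perimeter_mm <= 0)) {
    stop("lumen area and perimeter must be positive", call. = FALSE)
  }
  4 * lumen_area_mm2 / lumen_perimeter_mm
}

#' Normalize structural metrics by demographic predictions
#'
#' Dh* = Dh / predicted tracheal diameter; WT* = WT / predicted tracheal
#' wall thickness. The wall-thickness reference is pluggable (a constant
#' in mm or a function of the demographics); it rescales WT* uniformly
#' without affecting group contrasts.
#'
#' @param dh_mm Hydraulic diameter(s), mm.
#' @param wt_mm Wall thickness(es), mm.
#' @param demo A [demographics()] object.
#' @param wt_reference Predicted tracheal wall thickness: a positive
#'   number (mm) or a function of `demo` returning one. Default 1.5 mm.
#' @return data.frame with columns `dh_star`, `wt_star`.
#' @export
normalize_structure <- function(dh_mm, wt_mm, demo, wt_reference = 1.5) {
  if (any(dh_mm <= 0) || any(wt_mm <= 0)) {
    stop("structural measurements must be positive", call. = FALSE)
  }
  wt_ref <- if (is.function(wt_reference)) wt_reference(demo) else wt_reference
  if (!is.numeric(wt_ref) || length(wt_ref) != 1 || wt_ref <= 0) {
    stop("wall-thickness reference must resolve to a positive scalar", call. = FALSE)
  }
  data.frame(dh_star = dh_mm / predict_trachea_diameter(demo),
             wt_star = wt_mm / wt_ref)
}
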