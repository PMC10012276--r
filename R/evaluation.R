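#' Voxel-based mean error and mean absolute error
#'
#' Mean (signed or absolute) difference between predicted and ground-truth
#' dose over a region, expressed as a percentage of the prescription dose:
#' `mean(pred - gt) / prescription * 100` over the masked voxels. Per-case
#' values aggregate across a test set by an unweighted mean over cases
#' (per-case mean first, then mean over cases — not pooled voxels).
#'
#' The prescription denominator is a choice with two prescription levels in
#' play; see [metric_prescription()] for the package's policy.
#'
#' @param pred,gt dose maps ([volume_grid()] or arrays, Gy) on one grid.
#' @param mask logical array selecting the ROI; must be non-empty.
#' @param prescription denominator in Gy (> 0).
#' @return Percent value (scalar).
#' @export
mean_error <- function(pred, gt, mask, prescription) {
  p <- vol_values(pred)
  g <- vol_values(gt)
  stop_if_misaligned(p, g, "pred and gt")
  m <- as.logical(mask)
  if (!any(m)) stop("empty evaluation mask")
  if (prescription <= 0) stop("prescription must be positive")
  mean(p[m] - g[m]) / prescription * 100
}

#' @rdname mean_error
#' @export
mean_absolute_error <- function(pred, gt, mask, prescription) {
  p <- vol_values(pred)
  g <- vol_values(gt)
  stop_if_misaligned(p, g, "pred and gt")
  m <- as.logical(mask)
  if (!any(m)) stop("empty evaluation mask")
  if (prescription <= 0) stop("prescription must be positive")
  mean(abs(p[m] - g[m])) / prescription * 100
}

#' Prescription denominator policy for percent metrics
#'
#' With two prescription levels (60.06 Gy PTV, 69.96 Gy boost) the percent
#' denominator of the voxel metrics is ambiguous. Policy: body,
#' normal-tissue and OAR metrics are normalized by the boost prescription
#' (the plan's highest level); each target is normalized by its own
#' prescription. This choice rescales every percentage and is therefore
#' surfaced as an explicit, overridable function.
#'
#' @param case a `phantom_case`.
#' @param roi_name ROI the metric is computed on.
#' @return Prescription in Gy.
#' @export
metric_prescription <- function(case, roi_name) {
  role <- case$rois$roles[roi_name]
  if (!is.na(role) && role == "target" && roi_name %in%
      names(case$prescriptions)) {
    case$prescriptions[[roi_name]]
  } else {
    case$prescriptions$boost
  }
}

#' Dice similarity of isodose volumes
#'
#' Thresholds both dose maps at `>= level` Gy and returns
#' `2 |A intersect B| / (|A| + |B|)`. When both isodose volumes are empty
#' the coefficient is defined as 1 (perfect agreement on absence) and the
#' result carries attribute `degenerate = TRUE`.
#'
#' @param pred,gt dose maps on one grid.
#' @param level isodose level in Gy (> 0).
#' @return DSC in `[0, 1]`.
#' @export
isodose_dsc <- function(pred, gt, level) {
  p <- vol_values(pred)
  g <- vol_values(gt)
  stop_if_misaligned(p, g, "pred and gt")
  if (level <= 0) stop("isodose level must be positive")
  a <- p >= level
  b <- g >= level
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(structure(1, degenerate = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Isodose DSC curve over 1-60 Gy
#'
#' One DSC per integer dose level across the prescription range, plus the
#' 5-55 Gy / 5-Gy-bin extraction used for statistical comparison.
#'
#' @param pred,gt dose maps on one grid.
#' @param levels dose levels in Gy (default `1:60`).
#' @return A data.frame with columns `level` and `dsc`; attribute
#'   `stat_levels` holds `seq(5, 55, by = 5)`.
#' @export
dsc_curve <- function(pred, gt, levels = 1:60) {
  dsc <- vapply(levels, function(l) as.numeric(isodose_dsc(pred, gt, l)),
                numeric(1))
  structure(data.frame(level = levels, dsc = dsc),
            stat_levels = seq(5, 55, by = 5))
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the ROI volume receiving at least each dose bin edge,
#' starting at 100 percent at 0 Gy and falling to 0 above the maximum
#' dose.
#'
#' @param dose dose map (Gy).
#' @param mask logical ROI mask, non-empty.
#' @param bin_width histogram resolution in Gy.
#' @return An object of class `dvh_curve`: data.frame with `dose` (bin
#'   edges, Gy) and `volume_pct`.
#' @export
dvh <- function(dose, mask, bin_width = 0.1) {
  d <- vol_values(dose)
  m <- as.logical(mask)
  if (!any(m)) stop("empty ROI mask")
  v <- d[m]
  edges <- seq(0, max(v) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(v >= e) * 100, numeric(1))
  structure(data.frame(dose = edges, volume_pct = frac),
            class = c("dvh_curve", "data.frame"))
}

#' Dose to the hottest x percent of a structure (Dx%)
#'
#' The largest dose d such that at least x percent of the ROI volume
#' receives >= d, linearly interpolated between DVH bins. `dose_at_volume`
#' with `x = 5` is the D5% metric.
#'
#' @param dvh a [dvh()] curve.
#' @param x volume percentage in (0, 100).
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (!is.data.frame(dvh) || !all(c("dose", "volume_pct") %in% names(dvh)))
    stop("malformed DVH curve")
  if (x <= 0 || x >= 100) stop("x must be in (0, 100)")
  v <- dvh$volume_pct
  d <- dvh$dose
  if (any(diff(v) > 1e-9)) stop("malformed DVH curve: not non-increasing")
  # last index with coverage >= x
  i <- max(which(v >= x))
  if (i == length(v)) return(d[i])
  # interpolate within the falling segment [i, i+1], but never past the
  # largest dose actually received (a cliff bin interpolates to its edge)
  v1 <- v[i]
  v2 <- v[i + 1L]
  if (v1 == v2) return(d[i])
  min(d[i] + (d[i + 1L] - d[i]) * (v1 - x) / (v1 - v2), max(d[v > 0]))
}

#' Mean dose over a structure
#'
#' @param dose dose map (Gy).
#' @param mask logical ROI mask, non-empty.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  d <- vol_values(dose)
  m <- as.logical(mask)
  if (!any(m)) stop("empty ROI mask")
  mean(d[m])
}

#' Paired two-sided comparison of per-case metrics
#'
#' Two-sided paired t-test on the per-case differences between two models'
#' metric values. Zero-variance differences (including identical inputs)
#' are flagged as degenerate rather than producing a spurious p-value.
#'
#' @param values_a,values_b equal-length (>= 2) per-case metric vectors,
#'   paired by case.
#' @return List with `mean_diff`, `p_value`, `n`, and `degenerate`.
#' @export
paired_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired metric vectors differ in length")
  if (length(values_a) < 2L) stop("need at least 2 pairs")
  d <- values_a - values_b
  degenerate <- list(mean_diff = mean(d), p_value = NA_real_,
                     n = length(d), degenerate = TRUE)
  if (sd(d) == 0) return(degenerate)
  tt <- tryCatch(
    t.test(values_a, values_b, paired = TRUE, alternative = "two.sided"),
    error = function(e) {
      if (grepl("essentially constant", conditionMessage(e))) NULL
      else stop(e)
    })
  if (is.null(tt)) return(degenerate)
  list(mean_diff = unname(tt$estimate), p_value = tt$p.value,
       n = length(d), degenerate = FALSE)
}
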