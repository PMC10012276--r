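#' 3D scalar volume on a spaced voxel grid
#'
#' The common carrier for CT images, dose maps and distance maps: a 3D
#' numeric array plus the physical voxel spacing in millimetres and a grid
#' origin. Voxel centers sit at `origin + (index - 1) * spacing` per axis.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm coordinate of the first voxel center.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-d array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ (%s) mm, range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

# Accept either a volume_grid or a bare array; return the array.
vol_values <- function(x) {
  if (inherits(x, "volume_grid")) x$values else as.array(x)
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "volume_grid")) x$spacing else default
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!identical(dim(vol_values(a)), dim(vol_values(b))))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(vol_values(a)), collapse = "x"),
                 paste(dim(vol_values(b)), collapse = "x")))
  invisible(TRUE)
}

#' Named set of regions of interest
#'
#' Binary masks over a common grid, each tagged with a role: `target`
#' (PTV, boost), `oar`, `body`, or `field` (the in-field region). Carries
#' the per-target prescription levels in Gy and the fraction count.
#'
#' @param masks named list of logical 3D arrays, all the same shape.
#' @param roles named character vector, one of `"target"`, `"oar"`,
#'   `"body"`, `"field"` per mask.
#' @param spacing voxel spacing in mm.
#' @param prescriptions list with elements `ptv`, `boost` (Gy) and
#'   `fractions`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, roles, spacing,
                    prescriptions = list(ptv = 60.06, boost = 69.96,
                                         fractions = 33L)) {
  stopifnot(is.list(masks), length(masks) >= 1L,
            !is.null(names(masks)), all(nzchar(names(masks))))
  d <- dim(masks[[1L]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m)) storage.mode(masks[[nm]]) <- "logical"
    if (!identical(dim(masks[[nm]]), d))
      stop("mask '", nm, "' has a different grid shape")
  }
  roles <- roles[names(masks)]
  if (anyNA(roles) || !all(roles %in% c("target", "oar", "body", "field")))
    stop("every mask needs a role in target/oar/body/field")
  if (!any(roles == "body")) stop("roi_set requires a body mask")
  structure(list(masks = masks, roles = roles,
                 spacing = as.numeric(spacing),
                 prescriptions = prescriptions),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  tab <- table(x$roles)
  cat(sprintf("<roi_set> %d ROIs (%s) on %s grid\n", length(x$masks),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              paste(dim(x$masks[[1L]]), collapse = "x")))
  invisible(x)
}

roi_names_by_role <- function(rois, role) {
  names(rois$roles)[rois$roles == role]
}

roi_mask <- function(rois, name) {
  m <- rois$masks[[name]]
  if (is.null(m)) stop("no ROI named '", name, "'")
  m
}

body_mask <- function(rois) {
  roi_mask(rois, roi_names_by_role(rois, "body")[1L])
}

field_mask <- function(rois) {
  fn <- roi_names_by_role(rois, "field")
  if (!length(fn)) stop("roi_set has no in-field region mask")
  roi_mask(rois, fn[1L])
}

target_union <- function(rois) {
  tn <- roi_names_by_role(rois, "target")
  if (!length(tn)) stop("roi_set has no target mask")
  m <- rois$masks[[tn[1L]]]
  for (nm in tn[-1L]) m <- m | rois$masks[[nm]]
  m
}
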