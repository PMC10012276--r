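#' Write a phantom case to a directory of NIfTI volumes
#'
#' Writes `ct.nii.gz`, `dose.nii.gz` (when present), `dptv.nii.gz` (when
#' cached), one `mask_<roi>.nii.gz` per ROI, and a `case.json` sidecar with
#' spacing, prescriptions, ROI roles, the structure-map label table and the
#' case seed.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$rois$spacing
  wv <- function(values, file) {
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, file.path(dir, file))
  }
  wv(vol_values(case$ct), "ct.nii.gz")
  if (!is.null(case$dose_gt)) wv(vol_values(case$dose_gt), "dose.nii.gz")
  if (!is.null(case$dptv)) wv(vol_values(case$dptv), "dptv.nii.gz")
  for (nm in names(case$rois$masks))
    wv(array(as.integer(case$rois$masks[[nm]]), dim = dim(case$rois$masks[[nm]])),
       sprintf("mask_%s.nii.gz", nm))
  lt <- make_label_table(case$rois)
  sidecar <- list(spacing_mm = sp,
                  prescriptions = case$prescriptions,
                  rois = as.list(case$rois$roles),
                  label_table = as.list(lt),
                  max_label_code = attr(lt, "max_code"),
                  seed = case$seed)
  jsonlite::write_json(sidecar, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom case from a directory written by [write_case()]
#'
#' @param dir case directory.
#' @return A `phantom_case` (without the generating `spec`).
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"),
                              simplifyVector = TRUE)
  sp <- as.numeric(meta$spacing_mm)
  rv <- function(file) {
    img <- RNifti::readNifti(file.path(dir, file))
    array(as.numeric(img), dim = dim(img))
  }
  roles <- unlist(meta$rois)
  masks <- list()
  for (nm in names(roles))
    masks[[nm]] <- rv(sprintf("mask_%s.nii.gz", nm)) > 0.5
  prescriptions <- meta$prescriptions
  prescriptions$fractions <- as.integer(prescriptions$fractions)
  case <- list(ct = volume_grid(rv("ct.nii.gz"), sp),
               rois = roi_set(masks, roles, sp, prescriptions),
               dose_gt = NULL,
               prescriptions = prescriptions,
               seed = as.integer(meta$seed))
  if (file.exists(file.path(dir, "dose.nii.gz")))
    case$dose_gt <- volume_grid(rv("dose.nii.gz"), sp)
  if (file.exists(file.path(dir, "dptv.nii.gz")))
    case$dptv <- volume_grid(rv("dptv.nii.gz"), sp)
  structure(case, class = "phantom_case")
}

#' Write feature volumes (DPTV and structure map) for a case
#'
#' @param case a `phantom_case`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_features <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$rois$spacing
  d <- compute_dptv_case(case)
  smap <- encode_structures(case$rois)
  wv <- function(values, file) {
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, file.path(dir, file))
  }
  wv(vol_values(d), "dptv.nii.gz")
  wv(smap$labels, "structmap.nii.gz")
  jsonlite::write_json(c(as.list(smap$label_table),
                         list(max_code = attr(smap$label_table, "max_code"))),
                       file.path(dir, "label_table.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
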