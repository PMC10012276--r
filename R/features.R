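#' Minimum distance to the PTV for every normal-tissue voxel
#'
#' For each voxel inside the body but outside the PTV, computes the minimum
#' 3D Euclidean distance in millimetres from the voxel center to the
#' nearest PTV voxel center, honouring anisotropic voxel spacing (so a 3 mm
#' slice step counts 3 mm). PTV voxels and voxels outside the body are
#' assigned 0 — the same (deliberately ambiguous) zero coding used for the
#' network input, where the structure-map channel disambiguates the two.
#'
#' The transform is exact: a separable lower-envelope squared-distance
#' transform, not a chamfer approximation.
#'
#' @param ptv_mask logical 3D array (or [volume_grid()]), non-empty, a
#'   subset of `body_mask`.
#' @param body_mask logical 3D array on the same grid.
#' @param spacing mm per voxel, length 3, all positive.
#' @return A [volume_grid()] of distances in mm.
#' @export
compute_dptv <- function(ptv_mask, body_mask, spacing) {
  ptv <- vol_values(ptv_mask)
  body <- vol_values(body_mask)
  storage.mode(ptv) <- "logical"
  storage.mode(body) <- "logical"
  if (!identical(dim(ptv), dim(body)))
    stop("PTV and body masks have different grid shapes")
  if (!any(ptv)) stop("PTV mask is empty")
  if (any(ptv & !body)) stop("PTV mask must lie inside the body mask")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  d <- .cpp_edt3d(ptv, spacing)
  d[ptv] <- 0
  d[!body] <- 0
  volume_grid(d, spacing)
}

# DPTV for a phantom case, using its cached map when present
compute_dptv_case <- function(case) {
  if (!is.null(case$dptv)) return(case$dptv)
  compute_dptv(roi_mask(case$rois, "ptv"), body_mask(case$rois),
               case$rois$spacing)
}

#' Build the integer label table for structure-map encoding
#'
#' Targets get large, well-separated codes (multiples of 100) and OARs
#' small consecutive codes, so that the summed code of an OAR-target
#' overlap can never collide with a plain code or with another sum. Body
#' and out-of-field regions carry their own codes, and 0 denotes outside
#' the body.
#'
#' @param rois a [roi_set()].
#' @return Named integer vector with attribute `max_code` (the largest
#'   code that can occur in a map, overlap sums included).
#' @export
make_label_table <- function(rois) {
  oars <- roi_names_by_role(rois, "oar")
  targets <- roi_names_by_role(rois, "target")
  codes <- c(outside = 0L, body = 1L, out_of_field = 2L)
  if (length(oars)) codes[oars] <- seq_along(oars) + 2L
  codes[targets] <- 100L * seq_along(targets)
  sums <- if (length(oars)) as.vector(outer(codes[oars], codes[targets], `+`))
          else integer(0)
  all_codes <- c(codes, sums)
  if (anyDuplicated(all_codes))
    stop("label table collision: an overlap sum equals another code")
  attr(codes, "max_code") <- max(all_codes)
  codes
}

#' Encode a structure map from a set of ROIs
#'
#' Paints every ROI with its integer code into a single labeled volume.
#' Painting order: body code everywhere inside the body, then the
#' out-of-field code on body voxels outside the in-field region, then
#' OARs, then targets — so ROI codes always survive and every
#' non-overlapping ROI is exactly recoverable from the map. A voxel inside
#' both an OAR and a target gets the sum of the two codes. Where two OARs
#' overlap (a PRV and its core organ), the later-painted ROI wins, so list
#' cores after their PRV expansions. The boost target is painted after the
#' PTV and overwrites it, keeping target codes plain rather than
#' target+target sums.
#'
#' @param rois a [roi_set()] containing a body mask and at least one target.
#' @param label_table optional table from [make_label_table()]; validated
#'   for sum collisions at construction.
#' @return A list of class `structure_map`: `labels` (integer 3D array) and
#'   `label_table`.
#' @export
encode_structures <- function(rois, label_table = make_label_table(rois)) {
  if (!length(roi_names_by_role(rois, "target")))
    stop("roi_set has at least one target mask required for encoding")
  body <- body_mask(rois)
  oar_codes <- label_table[roi_names_by_role(rois, "oar")]
  target_codes <- label_table[roi_names_by_role(rois, "target")]
  sums <- if (length(oar_codes) && length(target_codes))
    as.vector(outer(oar_codes, target_codes, `+`))
  else integer(0)
  if (anyDuplicated(c(as.vector(label_table), sums)))
    stop("label table collision: an overlap sum equals another code")
  labels <- array(0L, dim = dim(body))
  labels[body] <- label_table[["body"]]
  fn <- roi_names_by_role(rois, "field")
  if (length(fn)) {
    off <- body & !rois$masks[[fn[1L]]]
    labels[off] <- label_table[["out_of_field"]]
  }
  for (nm in roi_names_by_role(rois, "oar"))
    labels[rois$masks[[nm]]] <- label_table[[nm]]
  for (nm in roi_names_by_role(rois, "target")) {
    m <- rois$masks[[nm]]
    prev <- labels[m]
    is_oar <- prev %in% oar_codes
    labels[m] <- ifelse(is_oar, prev + label_table[[nm]], label_table[[nm]])
  }
  structure(list(labels = labels, label_table = label_table),
            class = "structure_map")
}

#' @export
print.structure_map <- function(x, ...) {
  cat(sprintf("<structure_map> %s grid, %d table codes, max code %d\n",
              paste(dim(x$labels), collapse = "x"),
              length(x$label_table), attr(x$label_table, "max_code")))
  invisible(x)
}

#' Assemble normalized per-slice network inputs
#'
#' Builds the channel stack the dose predictor consumes, one axial slice at
#' a time. Channel order is fixed: CT, structure map, and (COM mode only)
#' DPTV. CT is windowed linearly from `ct_window` to `[0, 1]` and clipped;
#' structure codes are divided by the largest possible table code; DPTV is
#' divided by `dptv_cap_mm` and clipped to `[0, 1]`.
#'
#' @param case a `phantom_case` (or any object with `ct`, `rois` and
#'   optionally a cached `dptv`).
#' @param mode `"ANAT"` (2 channels: CT, structure) or `"COM"` (3 channels:
#'   CT, structure, DPTV).
#' @param ct_window HU window mapped to `[0, 1]`.
#' @param dptv_cap_mm distance normalization cap in mm.
#' @return An object of class `input_stack`: `x` is an `(H, W, C, S)` array
#'   over the S axial slices, plus normalization metadata.
#' @export
assemble_inputs <- function(case, mode = c("COM", "ANAT"),
                            ct_window = c(-1000, 1000), dptv_cap_mm = 150) {
  mode <- match.arg(mode)
  ct <- vol_values(case$ct)
  dims <- dim(ct)
  smap <- encode_structures(case$rois)
  ct_n <- (ct - ct_window[1L]) / diff(ct_window)
  ct_n[ct_n < 0] <- 0
  ct_n[ct_n > 1] <- 1
  st_n <- smap$labels / attr(smap$label_table, "max_code")
  nchan <- if (mode == "COM") 3L else 2L
  x <- array(0, dim = c(dims[1L], dims[2L], nchan, dims[3L]))
  x[, , 1L, ] <- ct_n
  x[, , 2L, ] <- st_n
  if (mode == "COM") {
    d_n <- vol_values(compute_dptv_case(case)) / dptv_cap_mm
    d_n[d_n > 1] <- 1
    x[, , 3L, ] <- d_n
  }
  structure(list(x = x, mode = mode, ct_window = ct_window,
                 dptv_cap_mm = dptv_cap_mm,
                 label_scale = attr(smap$label_table, "max_code")),
            class = "input_stack")
}
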