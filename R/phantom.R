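#' Specification of a synthetic head-and-neck phantom
#'
#' Describes one schematic case: an ellipsoidal body section containing a
#' PTV with an interior boost volume, and a set of organ-at-risk primitives
#' placed at varying distances from the target. The defaults emulate a
#' nasopharyngeal treatment site at desk scale: a 64x64x16 grid at
#' (4, 4, 3) mm spacing (3 mm slices as in clinical CT, coarsened in-plane),
#' 21 OARs including paired structures and PRV expansions, and the two-level
#' prescription geometry (PTV + boost).
#'
#' All geometry is in millimetres in a coordinate frame centered on the
#' grid. OAR descriptors are triples `(shape, center, size)` where shape is
#' `"sphere"` (size = radius), `"ellipsoid"` (size = 3 semiaxes) or `"zcyl"`
#' (size = radius, half-length along z).
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 8).
#' @param spacing mm per voxel, length-3.
#' @param body_semiaxes mm, length-3.
#' @param ptv_center,ptv_semiaxes mm.
#' @param boost_center,boost_semiaxes mm; the boost must lie strictly
#'   inside the PTV.
#' @param oar_descriptors named list of OAR primitives (see Details).
#' @param field_margin_mm superior/inferior extent of the in-field region
#'   beyond the axial bounds of the target union.
#' @param seed integer seed controlling CT noise.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [make_cohort()]
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         spacing = c(4, 4, 3),
                         body_semiaxes = c(105, 88, 23),
                         ptv_center = c(0, 10, 0),
                         ptv_semiaxes = c(34, 28, 11),
                         boost_center = c(0, 10, 0),
                         boost_semiaxes = c(15, 12, 5),
                         oar_descriptors = default_oar_descriptors(),
                         field_margin_mm = 6,
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing = as.numeric(spacing),
                         body_semiaxes = as.numeric(body_semiaxes),
                         ptv_center = as.numeric(ptv_center),
                         ptv_semiaxes = as.numeric(ptv_semiaxes),
                         boost_center = as.numeric(boost_center),
                         boost_semiaxes = as.numeric(boost_semiaxes),
                         oar_descriptors = oar_descriptors,
                         field_margin_mm = as.numeric(field_margin_mm),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default organ-at-risk layout for the head-and-neck phantom
#'
#' Twenty-one schematic structures mirroring a nasopharyngeal OAR list:
#' larynx, paired lenses, paired mandible halves, optic chiasm, paired optic
#' nerves, paired parotids, pituitary, paired temporomandibular joints,
#' paired temporal lobes, thyroid, trachea, brain stem and spinal cord with
#' their PRV expansions. Positions are schematic, chosen to span near-target
#' through distant locations; they are not an anatomical atlas.
#'
#' @return Named list of OAR descriptors.
#' @export
default_oar_descriptors <- function() {
  oar <- function(shape, center, size) list(shape = shape, center = center,
                                            size = size)
  list(
    brainstem_prv   = oar("zcyl", c(0, -45, 5), c(11, 23)),
    brainstem       = oar("zcyl", c(0, -45, 5), c(8, 20)),
    spinal_cord_prv = oar("zcyl", c(0, -62, 0), c(10, 24)),
    spinal_cord     = oar("zcyl", c(0, -62, 0), c(5, 24)),
    larynx          = oar("ellipsoid", c(0, 26, -10), c(14, 14, 12)),
    lens_l          = oar("sphere", c(-28, 78, 6), 4),
    lens_r          = oar("sphere", c(28, 78, 6), 4),
    mandible_l      = oar("ellipsoid", c(-34, 48, -10), c(10, 22, 12)),
    mandible_r      = oar("ellipsoid", c(34, 48, -10), c(10, 22, 12)),
    optic_chiasm    = oar("ellipsoid", c(0, 48, 8), c(10, 6, 4)),
    optic_nerve_l   = oar("ellipsoid", c(-18, 62, 6), c(10, 4, 4)),
    optic_nerve_r   = oar("ellipsoid", c(18, 62, 6), c(10, 4, 4)),
    parotid_l       = oar("ellipsoid", c(-62, -10, 0), c(14, 18, 14)),
    parotid_r       = oar("ellipsoid", c(62, -10, 0), c(14, 18, 14)),
    pituitary       = oar("sphere", c(0, 40, 10), 4),
    temporal_lobe_l = oar("ellipsoid", c(-48, 20, 14), c(22, 18, 12)),
    temporal_lobe_r = oar("ellipsoid", c(48, 20, 14), c(22, 18, 12)),
    thyroid         = oar("ellipsoid", c(0, 46, -14), c(16, 10, 8)),
    tmj_l           = oar("sphere", c(-58, 22, 8), 6),
    tmj_r           = oar("sphere", c(58, 22, 8), 6),
    trachea         = oar("zcyl", c(0, 58, -12), c(7, 10))
  )
}

# quadratic form of an ellipsoid; < 1 means strictly inside
ellipsoid_q <- function(p, center, semiaxes) {
  sum(((p - center) / semiaxes)^2)
}

# containment check by sampling the inner surface over a direction grid
ellipsoid_inside <- function(ci, si, co, so, n_theta = 24L, n_phi = 12L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-1L]
  ph <- seq(0, pi, length.out = n_phi)
  for (p1 in ph) for (t1 in th) {
    u <- c(sin(p1) * cos(t1), sin(p1) * sin(t1), cos(p1))
    if (ellipsoid_q(ci + si * u, co, so) >= 1) return(FALSE)
  }
  TRUE
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 8L))
    stop("grid_shape must be at least 8 voxels per axis")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (any(spec$body_semiaxes <= 0) || any(spec$ptv_semiaxes <= 0) ||
      any(spec$boost_semiaxes <= 0))
    stop("all semiaxes must be positive")
  half_extent <- spec$grid_shape * spec$spacing / 2
  if (any(abs(spec$body_semiaxes) > half_extent))
    stop("grid too small to contain the body ellipsoid")
  if (!ellipsoid_inside(spec$ptv_center, spec$ptv_semiaxes,
                        c(0, 0, 0), spec$body_semiaxes))
    stop("PTV is not strictly inside the body")
  if (!ellipsoid_inside(spec$boost_center, spec$boost_semiaxes,
                        spec$ptv_center, spec$ptv_semiaxes))
    stop("boost is not strictly inside the PTV")
  invisible(spec)
}

# voxel-center coordinates per axis, grid-centered frame
grid_axes <- function(grid_shape, spacing) {
  lapply(1:3, function(a) {
    n <- grid_shape[a]
    (seq_len(n) - (n + 1) / 2) * spacing[a]
  })
}

rasterize_ellipsoid <- function(axes, center, semiaxes) {
  qx <- ((axes[[1L]] - center[1L]) / semiaxes[1L])^2
  qy <- ((axes[[2L]] - center[2L]) / semiaxes[2L])^2
  qz <- ((axes[[3L]] - center[3L]) / semiaxes[3L])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

rasterize_zcyl <- function(axes, center, radius, half_len) {
  qx <- ((axes[[1L]] - center[1L]) / radius)^2
  qy <- ((axes[[2L]] - center[2L]) / radius)^2
  inplane <- outer(qx, qy, `+`) <= 1
  inz <- abs(axes[[3L]] - center[3L]) <= half_len
  outer(inplane, inz, `&`)
}

rasterize_primitive <- function(axes, desc) {
  switch(desc$shape,
         sphere = rasterize_ellipsoid(axes, desc$center, rep(desc$size[1L], 3)),
         ellipsoid = rasterize_ellipsoid(axes, desc$center, desc$size),
         zcyl = rasterize_zcyl(axes, desc$center, desc$size[1L], desc$size[2L]),
         stop("unknown OAR shape '", desc$shape, "'"))
}

#' Generate one synthetic phantom case (without dose)
#'
#' Rasterizes the body, PTV, boost and OAR primitives of a [phantom_spec()]
#' onto its voxel grid, builds a schematic CT (air outside the body, soft
#' tissue inside, a bone-like shell near the body surface, plus seeded
#' Gaussian texture) and derives the in-field region: all axial slices
#' within `field_margin_mm` of the target union, mirroring a coplanar-arc
#' field extent.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case` with elements `ct`
#'   (a [volume_grid()]), `rois` (a [roi_set()]), `prescriptions`, `seed`
#'   and `spec`. Dose is attached by [simulate_dose()] or [make_cohort()].
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  axes <- grid_axes(spec$grid_shape, spec$spacing)

  body <- rasterize_ellipsoid(axes, c(0, 0, 0), spec$body_semiaxes)
  ptv <- rasterize_ellipsoid(axes, spec$ptv_center, spec$ptv_semiaxes)
  boost <- rasterize_ellipsoid(axes, spec$boost_center, spec$boost_semiaxes)
  ptv <- ptv & body
  boost <- boost & ptv
  if (!any(boost) || !any(ptv & !boost) || !any(body & !ptv))
    stop("grid too coarse: body/PTV/boost nesting degenerates")

  masks <- list(body = body)
  roles <- c(body = "body")
  for (nm in names(spec$oar_descriptors)) {
    masks[[nm]] <- rasterize_primitive(axes, spec$oar_descriptors[[nm]]) & body
    roles[nm] <- "oar"
  }
  masks$ptv <- ptv
  masks$boost <- boost
  roles[c("ptv", "boost")] <- "target"

  # in-field region: slices within field_margin_mm of the target extent
  tz <- axes[[3L]][apply(ptv | boost, 3L, any)]
  in_field_slice <- axes[[3L]] >= min(tz) - spec$field_margin_mm &
    axes[[3L]] <= max(tz) + spec$field_margin_mm
  field <- array(FALSE, dim = spec$grid_shape)
  field[, , in_field_slice] <- TRUE
  masks$field <- field
  roles["field"] <- "field"

  # schematic CT in HU tiers: air, soft tissue, bone-like shell
  qx <- (axes[[1L]] / spec$body_semiaxes[1L])^2
  qy <- (axes[[2L]] / spec$body_semiaxes[2L])^2
  qz <- (axes[[3L]] / spec$body_semiaxes[3L])^2
  rq <- outer(outer(qx, qy, `+`), qz, `+`)
  ct <- array(-1000, dim = spec$grid_shape)
  ct[body] <- 40
  ct[body & rq >= 0.85] <- 700
  set.seed(spec$seed)
  ct[body] <- ct[body] + rnorm(sum(body), sd = 20)

  prescriptions <- list(ptv = 60.06, boost = 69.96, fractions = 33L)
  structure(list(ct = volume_grid(ct, spec$spacing),
                 rois = roi_set(masks, roles, spec$spacing, prescriptions),
                 dose_gt = NULL,
                 prescriptions = prescriptions,
                 seed = spec$seed,
                 spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> grid %s @ (%s) mm, %d ROIs, dose %s, seed %d\n",
              paste(dim(x$ct$values), collapse = "x"),
              paste(format(x$ct$spacing), collapse = ", "),
              length(x$rois$masks),
              if (is.null(x$dose_gt)) "absent" else "present",
              x$seed))
  invisible(x)
}

#' Parameters of the phantom dose engine
#'
#' The engine stands in for a treatment planning system: it produces a
#' ground-truth dose that plateaus at the prescription inside the targets
#' and decays exponentially with the distance-to-PTV outside them, with
#' per-OAR multiplicative sparing, a low out-of-field plateau, and optional
#' additive Gaussian noise. Dose is a deterministic function of DPTV by
#' construction, which makes the distance channel informative for the
#' prediction network.
#'
#' @param prescription_ptv PTV prescription in Gy (60.06 Gy / 33 fractions).
#' @param prescription_boost boost prescription in Gy (69.96 Gy).
#' @param falloff_tau exponential decay scale of dose versus DPTV, mm.
#' @param oar_sparing named multipliers in (0, 1] applied to normal-tissue
#'   dose inside each named OAR; the minimum applies where OARs overlap.
#' @param out_of_field_level out-of-field dose cap as a fraction of the PTV
#'   prescription.
#' @param noise_sd additive Gaussian noise on body voxels, Gy.
#' @return An object of class `dose_engine_params`.
#' @export
dose_engine_params <- function(prescription_ptv = 60.06,
                               prescription_boost = 69.96,
                               falloff_tau = 25,
                               oar_sparing = default_oar_sparing(),
                               out_of_field_level = 0.02,
                               noise_sd = 0.5) {
  if (!(prescription_boost >= prescription_ptv && prescription_ptv > 0))
    stop("need prescription_boost >= prescription_ptv > 0")
  if (falloff_tau <= 0) stop("falloff_tau must be positive")
  if (length(oar_sparing) &&
      (any(oar_sparing <= 0) || any(oar_sparing > 1)))
    stop("sparing multipliers must lie in (0, 1]")
  structure(list(prescription_ptv = prescription_ptv,
                 prescription_boost = prescription_boost,
                 falloff_tau = falloff_tau,
                 oar_sparing = oar_sparing,
                 out_of_field_level = out_of_field_level,
                 noise_sd = noise_sd),
            class = "dose_engine_params")
}

#' Default OAR sparing multipliers for the dose engine
#'
#' Stronger sparing for serial structures (cord, optics, lenses) and
#' moderate sparing for parallel ones, loosely echoing clinical priorities.
#'
#' @return Named numeric vector of multipliers in (0, 1].
#' @export
default_oar_sparing <- function() {
  c(brainstem_prv = 0.60, brainstem = 0.50,
    spinal_cord_prv = 0.45, spinal_cord = 0.35,
    larynx = 0.60, lens_l = 0.25, lens_r = 0.25,
    mandible_l = 0.80, mandible_r = 0.80,
    optic_chiasm = 0.55, optic_nerve_l = 0.60, optic_nerve_r = 0.60,
    parotid_l = 0.55, parotid_r = 0.55, pituitary = 0.65,
    temporal_lobe_l = 0.75, temporal_lobe_r = 0.75,
    thyroid = 0.70, tmj_l = 0.75, tmj_r = 0.75, trachea = 0.65)
}

#' Simulate ground-truth dose for a phantom case
#'
#' Before noise: boost voxels receive the boost prescription, remaining PTV
#' voxels the PTV prescription, in-field normal tissue
#' `prescription_ptv * exp(-DPTV / falloff_tau)` times the sparing
#' multiplier of any covering OAR, out-of-field body voxels are capped at
#' `out_of_field_level * prescription_ptv`, and voxels outside the body get
#' zero. Gaussian noise (if any) is added to body voxels and the result is
#' clipped at zero.
#'
#' @param case a `phantom_case`.
#' @param params a [dose_engine_params()].
#' @param dptv DPTV map from [compute_dptv()] on the same grid.
#' @param seed noise seed; defaults to a value derived from the case seed.
#' @return The case with `dose_gt` set (a [volume_grid()] in Gy).
#' @export
simulate_dose <- function(case, params = dose_engine_params(),
                          dptv = NULL, seed = NULL) {
  rois <- case$rois
  if (is.null(dptv)) dptv <- compute_dptv_case(case)
  stop_if_misaligned(case$ct, dptv, "case and DPTV map")
  d <- vol_values(dptv)
  body <- body_mask(rois)
  targets <- target_union(rois)
  ptv <- roi_mask(rois, "ptv")
  boost <- roi_mask(rois, "boost")

  dose <- params$prescription_ptv * exp(-d / params$falloff_tau)
  spar <- array(1, dim = dim(d))
  for (nm in intersect(names(params$oar_sparing), names(rois$masks))) {
    m <- rois$masks[[nm]] & !targets
    spar[m] <- pmin(spar[m], params$oar_sparing[[nm]])
  }
  dose <- dose * spar
  dose[ptv] <- params$prescription_ptv
  dose[boost] <- params$prescription_boost
  off <- body & !field_mask(rois)
  dose[off] <- pmin(dose[off], params$out_of_field_level *
                      params$prescription_ptv)
  dose[!body] <- 0
  if (params$noise_sd > 0) {
    if (is.null(seed)) seed <- (case$seed + 104729L) %% .Machine$integer.max
    set.seed(seed)
    dose[body] <- dose[body] + rnorm(sum(body), sd = params$noise_sd)
    dose[dose < 0] <- 0
  }
  case$dose_gt <- volume_grid(dose, rois$spacing)
  case$dose_params <- params
  case
}

#' Generate a cohort of distinct phantom cases with simulated dose
#'
#' Draws per-case geometric variation (target position and scale, OAR
#' positions, body scale) within `spec_ranges`, generates each phantom,
#' computes its DPTV map and attaches engine dose. Per-case seeds are
#' derived deterministically from the master seed, so a cohort is fully
#' reproducible.
#'
#' @param n number of cases (>= 1).
#' @param spec_ranges list of variation ranges: `ptv_jitter_mm`,
#'   `oar_jitter_mm` (uniform half-widths), `ptv_scale`, `body_scale`
#'   (min/max multipliers).
#' @param seed master seed.
#' @param base_spec template [phantom_spec()].
#' @param params [dose_engine_params()] for the dose engine.
#' @return List of `phantom_case`, each with `dose_gt` and a cached `dptv`.
#' @export
make_cohort <- function(n, spec_ranges = default_spec_ranges(), seed = 1L,
                        base_spec = phantom_spec(),
                        params = dose_engine_params()) {
  if (n < 1L) stop("cohort size must be at least 1")
  for (r in c("ptv_scale", "body_scale")) {
    rg <- spec_ranges[[r]]
    if (is.null(rg) || length(rg) != 2L || rg[2L] < rg[1L])
      stop("spec_ranges$", r, " must be a non-empty (min, max) range")
  }
  lapply(seq_len(n), function(i) {
    case_seed <- (seed + 7919L * i) %% .Machine$integer.max
    set.seed(case_seed)
    jit <- function(w) stats::runif(3, -w, w)
    sc <- function(rg) stats::runif(1, rg[1L], rg[2L])
    spec <- base_spec
    spec$seed <- as.integer(case_seed)
    spec$body_semiaxes <- spec$body_semiaxes * sc(spec_ranges$body_scale)
    shift <- jit(spec_ranges$ptv_jitter_mm)
    scale <- sc(spec_ranges$ptv_scale)
    spec$ptv_center <- spec$ptv_center + shift
    spec$boost_center <- spec$boost_center + shift
    spec$ptv_semiaxes <- spec$ptv_semiaxes * scale
    spec$boost_semiaxes <- spec$boost_semiaxes * scale
    spec$oar_descriptors <- lapply(spec$oar_descriptors, function(d) {
      d$center <- d$center + jit(spec_ranges$oar_jitter_mm)
      d
    })
    validate_phantom_spec(spec)
    case <- generate_phantom(spec)
    case$dptv <- compute_dptv_case(case)
    simulate_dose(case, params, dptv = case$dptv)
  })
}

#' Default cohort variation ranges
#'
#' Target centers jitter by up to 6 mm in-plane and 2 mm axially (so every
#' case keeps out-of-field slices on the default grid), OARs by up to 4 mm;
#' target scale varies by +/-15 percent and body scale by -8/+4 percent —
#' enough that no two cases share geometry while all stay valid.
#'
#' @return List of ranges for [make_cohort()].
#' @export
default_spec_ranges <- function() {
  list(ptv_jitter_mm = c(6, 6, 2), oar_jitter_mm = 4,
       ptv_scale = c(0.85, 1.15), body_scale = c(0.92, 1.04))
}
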