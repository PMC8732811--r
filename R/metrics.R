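#' Maximum SUV within a VOI
#'
#' SUV_max is the hottest voxel among those whose centers lie inside the VOI.
#'
#' @param grid a [voxel_grid()].
#' @param voi a [sphere_voi()].
#' @return Numeric scalar.
#' @export
suv_max_in_voi <- function(grid, voi) {
  idx <- voi_voxels(grid, voi)
  if (!length(idx))
    stop(sprintf("VOI %s contains no voxel centers",
                 if (is.null(voi$label)) "" else sQuote(voi$label)))
  max(grid$values[idx])
}

#' Peak SUV within a VOI (1.2-cm sphere mean)
#'
#' SUV_peak is the mean SUV over a fixed-size sphere (default 1.2 cm
#' diameter) placed at the hottest site of the lesion. The site is found by
#' exhaustive search: every voxel center inside the lesion VOI is tried as
#' the sphere center and the largest sphere mean is returned. With
#' `placement = "max"` the sphere is instead centered on the hottest voxel
#' (single evaluation), a cheaper convention some workstations use.
#'
#' @param grid a [voxel_grid()].
#' @param voi lesion [sphere_voi()].
#' @param peak_diameter_mm diameter of the averaging sphere in mm (12 mm).
#' @param placement `"search"` (exhaustive, default) or `"max"`.
#' @return Numeric scalar, the sphere-mean SUV at the hottest placement.
#' @export
suv_peak_in_voi <- function(grid, voi, peak_diameter_mm = 12,
                            placement = c("search", "max")) {
  placement <- match.arg(placement)
  idx <- voi_voxels(grid, voi)
  if (!length(idx))
    stop(sprintf("VOI %s contains no voxel centers",
                 if (is.null(voi$label)) "" else sQuote(voi$label)))
  d <- dim(grid$values)
  # integer offset stencil: voxels whose centers fall inside the peak sphere
  # when it is centered on a voxel center
  r <- peak_diameter_mm / 2
  nmax <- pmax(0L, floor(r / grid$voxel_size_mm))
  off <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2],
                     k = -nmax[3]:nmax[3])
  keep <- (off$i * grid$voxel_size_mm[1])^2 +
    (off$j * grid$voxel_size_mm[2])^2 +
    (off$k * grid$voxel_size_mm[3])^2 <= r^2
  off <- off[keep, , drop = FALSE]
  if (!nrow(off))
    stop("peak sphere holds no voxel centers; use a finer grid or a larger peak_diameter_mm")
  centers <- linear_to_sub(idx, d)
  if (placement == "max") {
    centers <- centers[which.max(grid$values[idx]), , drop = FALSE]
  }
  best <- -Inf
  for (c in seq_len(nrow(centers))) {
    ii <- centers[c, 1] + off$i
    jj <- centers[c, 2] + off$j
    kk <- centers[c, 3] + off$k
    ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    if (!any(ok)) next
    v <- grid$values[cbind(ii[ok], jj[ok], kk[ok])]
    m <- mean(v)
    if (m > best) best <- m
  }
  best
}

#' Lean body mass (James formula)
#'
#' The sex-specific James estimate used in the original SUL definition:
#' males `1.10 W - 128 (W/H)^2`, females `1.07 W - 148 (W/H)^2`, with weight
#' `W` in kg and height `H` in cm. The result is clamped to `(0, W]`: for
#' extreme habitus the quadratic term can exceed physiologic bounds.
#'
#' @param weight_kg body weight in kg.
#' @param height_cm height in cm.
#' @param sex `"male"` or `"female"`.
#' @return Lean body mass in kg.
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.numeric(weight_kg) || weight_kg <= 0) stop("`weight_kg` must be > 0")
  if (!is.numeric(height_cm) || height_cm <= 0) stop("`height_cm` must be > 0")
  lbm <- if (sex == "male") {
    1.10 * weight_kg - 128 * (weight_kg / height_cm)^2
  } else {
    1.07 * weight_kg - 148 * (weight_kg / height_cm)^2
  }
  if (lbm <= 0)
    stop(sprintf("non-physiologic habitus (LBM = %.2f kg <= 0)", lbm))
  min(lbm, weight_kg)
}

#' Convert SUV to SUL
#'
#' SUL rescales SUV by lean body mass over total body mass:
#' `SUL = SUV * LBM / W`. Because LBM is clamped to at most `W`,
#' `SUL <= SUV` always.
#'
#' @param suv non-negative SUV value(s).
#' @inheritParams lean_body_mass
#' @return SUL value(s), same length as `suv`.
#' @export
suv_to_sul <- function(suv, weight_kg, height_cm, sex = c("male", "female")) {
  if (any(suv < 0)) stop("`suv` must be >= 0")
  suv * lean_body_mass(weight_kg, height_cm, sex) / weight_kg
}

# 26-connected component of `mask` (logical over dims) containing seed_idx.
# Small flood fill; mask regions are lesion-sized so this stays cheap.
connected_component_26 <- function(mask_idx, seed_idx, dims) {
  if (!seed_idx %in% mask_idx) return(integer(0))
  in_mask <- logical(prod(dims))
  in_mask[mask_idx] <- TRUE
  seen <- logical(prod(dims))
  off <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  off <- off[!(off$i == 0 & off$j == 0 & off$k == 0), ]
  queue <- seed_idx
  seen[seed_idx] <- TRUE
  comp <- integer(0)
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    comp <- c(comp, cur)
    sub <- linear_to_sub(cur, dims)
    for (o in seq_len(nrow(off))) {
      ii <- sub[, 1] + off$i[o]
      jj <- sub[, 2] + off$j[o]
      kk <- sub[, 3] + off$k[o]
      ok <- ii >= 1L & ii <= dims[1] & jj >= 1L & jj <= dims[2] &
        kk >= 1L & kk <= dims[3]
      if (!any(ok)) next
      lin <- ii[ok] + (jj[ok] - 1L) * dims[1] + (kk[ok] - 1L) * dims[1] * dims[2]
      new <- lin[in_mask[lin] & !seen[lin]]
      if (length(new)) {
        seen[new] <- TRUE
        queue <- c(queue, unique(new))
      }
    }
  }
  sort(unique(comp))
}

#' Metabolic tumor volume and total lesion glycolysis
#'
#' MTV is the volume of the VOI voxels at or above 40% of the lesion
#' SUV_max, restricted to the 26-connected component containing the hottest
#' voxel (background speckle inside the VOI is thereby excluded). SUV_mean
#' is the mean over those voxels and TLG = SUV_mean x MTV.
#'
#' @param grid a [voxel_grid()].
#' @param voi lesion [sphere_voi()].
#' @param threshold_fraction isocontour threshold as a fraction of SUV_max
#'   (default 0.4).
#' @return List with `mtv_ml`, `suv_mean`, `tlg`.
#' @export
mtv_and_tlg <- function(grid, voi, threshold_fraction = 0.4) {
  idx <- voi_voxels(grid, voi)
  if (!length(idx))
    stop(sprintf("VOI %s contains no voxel centers",
                 if (is.null(voi$label)) "" else sQuote(voi$label)))
  vals <- grid$values[idx]
  smax <- max(vals)
  if (smax <= 0) {
    warning("lesion SUV_max is 0; MTV and TLG set to 0")
    return(list(mtv_ml = 0, suv_mean = 0, tlg = 0))
  }
  above <- idx[vals >= threshold_fraction * smax]
  seed <- idx[which.max(vals)]
  comp <- connected_component_26(above, seed, dim(grid$values))
  vol_ml <- length(comp) * prod(grid$voxel_size_mm) / 1000
  smean <- mean(grid$values[comp])
  list(mtv_ml = vol_ml, suv_mean = smean, tlg = smean * vol_ml)
}

#' Liver SUL reference from a 3-cm spherical ROI
#'
#' Computes per-voxel liver SUL mean and SD over a 3-cm sphere on the normal
#' right lobe, and the two derived thresholds the response criteria use:
#' the CMR comparator `sul_mean + 2 SD` and the PERCIST measurability floor
#' `1.5 * sul_mean + 2 SD`.
#'
#' @param grid a [voxel_grid()] (already in SUL units, or in SUV with
#'   `weight_kg`/`height_cm`/`sex` supplied to convert).
#' @param liver_voi a [sphere_voi()], conventionally 30 mm diameter.
#' @param weight_kg,height_cm,sex optional habitus; when given, voxel values
#'   are converted SUV -> SUL before the statistics.
#' @return Object of class `liver_reference`: list with `sul_mean`, `sul_sd`,
#'   `sul_mean_plus_2sd`, `measurability_floor`, `n_voxels`.
#' @export
liver_reference <- function(grid, liver_voi, weight_kg = NULL,
                            height_cm = NULL, sex = NULL) {
  idx <- voi_voxels(grid, liver_voi)
  if (length(idx) < 10L)
    stop(sprintf("liver sphere contains %d voxels (>= 10 required)", length(idx)))
  v <- grid$values[idx]
  if (!is.null(weight_kg))
    v <- suv_to_sul(v, weight_kg, height_cm, sex)
  m <- mean(v)
  s <- stats::sd(v)
  liver_reference_values(m, s, n_voxels = length(idx))
}

#' Build a liver reference from summary values
#'
#' For the lesion-table workflow where only the liver SUL mean and SD are
#' available (not the voxel data).
#'
#' @param sul_mean,sul_sd liver SUL mean and SD (SD defaults to 0).
#' @param n_voxels optional voxel count for provenance.
#' @return Object of class `liver_reference`.
#' @export
liver_reference_values <- function(sul_mean, sul_sd = 0, n_voxels = NA_integer_) {
  if (sul_mean < 0 || sul_sd < 0) stop("liver SUL mean/SD must be >= 0")
  structure(list(
    sul_mean = sul_mean,
    sul_sd = sul_sd,
    sul_mean_plus_2sd = sul_mean + 2 * sul_sd,
    measurability_floor = 1.5 * sul_mean + 2 * sul_sd,
    n_voxels = n_voxels
  ), class = "liver_reference")
}

#' Measure all lesions and the liver reference on one scan
#'
#' Composes the per-lesion metrics into a lesion table: one row per lesion
#' VOI with SUV_max, SUV_mean (over the 40% isocontour), SUV_peak, SUL_peak,
#' MTV (mL) and TLG, plus the liver SUL reference. Whole-body MTV/TLG are
#' the sums over lesions.
#'
#' @param grid a [voxel_grid()] in SUV units.
#' @param lesion_vois list of [sphere_voi()]; names (or `label`s) become
#'   lesion ids.
#' @param liver_voi a [sphere_voi()] for the liver reference.
#' @param weight_kg,height_cm,sex body habitus used for the SUL conversions.
#' @param organ_labels optional character vector of organ labels, one per
#'   lesion VOI (defaults to the VOI labels).
#' @return List with `lesions` (data.frame) and `liver` (`liver_reference`).
#' @export
measure_scan <- function(grid, lesion_vois, liver_voi,
                         weight_kg = 70, height_cm = 170, sex = "male",
                         organ_labels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- length(lesion_vois)
  liver <- liver_reference(grid, liver_voi, weight_kg, height_cm, sex)
  if (n == 0L) {
    return(list(lesions = empty_lesion_frame(), liver = liver))
  }
  ids <- names(lesion_vois)
  if (is.null(ids))
    ids <- vapply(seq_len(n), function(i) {
      lab <- lesion_vois[[i]]$label
      if (is.null(lab)) sprintf("lesion_%02d", i) else lab
    }, character(1))
  if (is.null(organ_labels)) organ_labels <- ids
  sul_factor <- lean_body_mass(weight_kg, height_cm, sex) / weight_kg
  rows <- lapply(seq_len(n), function(i) {
    voi <- lesion_vois[[i]]
    smax <- suv_max_in_voi(grid, voi)
    speak <- suv_peak_in_voi(grid, voi)
    mt <- mtv_and_tlg(grid, voi)
    data.frame(
      lesion_id = ids[i], organ = organ_labels[i],
      suv_max = smax, suv_mean = mt$suv_mean, suv_peak = speak,
      sul_peak = speak * sul_factor,
      mtv_ml = mt$mtv_ml, tlg = mt$tlg,
      stringsAsFactors = FALSE
    )
  })
  list(lesions = do.call(rbind, rows), liver = liver)
}

empty_lesion_frame <- function() {
  data.frame(lesion_id = character(0), organ = character(0),
             suv_max = numeric(0), suv_mean = numeric(0),
             suv_peak = numeric(0), sul_peak = numeric(0),
             mtv_ml = numeric(0), tlg = numeric(0),
             stringsAsFactors = FALSE)
}
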