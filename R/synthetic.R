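## Class-conditional synthetic lesion phantoms.
##
## The stated world: three adenocarcinoma-like classes of increasing
## invasiveness whose lesions grow in size (mean radii 4 / 7 / 11 mm),
## density (ground-glass to solid: intensity 0.35 / 0.55 / 0.80 on the
## [-1000, 400] HU window) and margin irregularity (spiculation amplitude
## 0 / 0.15 / 0.35). A lesion is a radially perturbed sphere in millimetre
## space, r(theta, phi) = r0 * (1 + amp * P(theta, phi)) with P a fixed
## low-order harmonic, embedded in a -900 HU lung field; anisotropic voxel
## spacing makes it an ellipsoid in voxel space. Clinical records shift
## with class, and nodule diameter is genuinely correlated with the sampled
## lesion radius.
##
## Geometry convention: voxel i is the cell [i*s, (i+1)*s) mm with center at
## (i + 0.5) * s; lesion centers sit on cell boundaries (k * s), so a
## noise-free sphere of radius r0 has a tight box of ceiling(2*r0/s) voxels
## per axis.

#' Fixed low-order harmonic perturbation used for spiculation
#'
#' Bounded by 1 in absolute value; zero amplitude recovers a perfect sphere.
#' @param theta Polar angle from the z axis.
#' @param phi Azimuth in the x-y plane.
#' @return Perturbation values in `[-1, 1]`.
#' @keywords internal
harmonic_perturbation <- function(theta, phi) {
  sin(2 * theta) * cos(3 * phi)
}

#' Specification of the synthetic lesion world
#'
#' Defaults encode the three-class adenocarcinoma narrative above, with the
#' class mix of a merged four-subtype cohort (22.4% / 24.1% / 53.5% for
#' AIS / MIA / IA). The per-case lesion radius is drawn uniformly within
#' +/-15% of the class mean, so the three class radius ranges are disjoint
#' and a noise-free dataset is separable by lesion size alone.
#'
#' @param n_classes Number of classes (fixed at 3).
#' @param class_probs Class mixture; must sum to 1.
#' @param lesion_radius_mean_mm Per-class mean lesion radius, mm.
#' @param lesion_intensity_mean Per-class lesion intensity in `[0, 1]` on the
#'   `[-1000, 400]` HU window (HU = intensity * 1400 - 1000).
#' @param spiculation_amp Per-class radial perturbation amplitude, >= 0.
#' @param noise_sd Gaussian intensity noise sd (in window units; added to HU
#'   as `1400 * noise_sd`).
#' @param ehr_schema Clinical field list; each entry has `name`, `kind`
#'   (`"numeric"` or `"categorical"`) and either per-class `means` (numeric),
#'   per-class `probs` rows over `levels` (categorical), or `link =
#'   "diameter"` for a numeric field tied to the sampled lesion diameter.
#' @param volume_shape_vox Integer volume shape.
#' @param spacing_mm Voxel spacing (anisotropic by default so resampling is
#'   exercised).
#' @param center_jitter_vox Max integer jitter of the lesion center, voxels.
#' @param seed Default seed used by [build_dataset()].
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_classes = 3L,
                         class_probs = c(0.224, 0.241, 0.535),
                         lesion_radius_mean_mm = c(4, 7, 11),
                         lesion_intensity_mean = c(0.35, 0.55, 0.80),
                         spiculation_amp = c(0.0, 0.15, 0.35),
                         noise_sd = 0.05,
                         ehr_schema = default_ehr_schema(),
                         volume_shape_vox = c(96L, 96L, 64L),
                         spacing_mm = c(0.8, 0.8, 1.25),
                         center_jitter_vox = 2L,
                         seed = 20260918L) {
  n_classes <- as.integer(n_classes)
  if (n_classes != 3L) stop("phantom_spec(): n_classes is fixed at 3")
  if (abs(sum(class_probs) - 1) > 1e-9) {
    stop("phantom_spec(): class_probs must sum to 1")
  }
  if (any(class_probs < 0)) stop("phantom_spec(): negative class probability")
  for (v in list(lesion_radius_mean_mm, lesion_intensity_mean,
                 spiculation_amp)) {
    if (length(v) != n_classes) {
      stop("phantom_spec(): per-class parameters must have length n_classes")
    }
  }
  if (any(lesion_radius_mean_mm <= 0)) {
    stop("phantom_spec(): radii must be strictly positive")
  }
  if (any(lesion_intensity_mean < 0 | lesion_intensity_mean > 1)) {
    stop("phantom_spec(): intensities must lie in [0, 1]")
  }
  if (any(spiculation_amp < 0) || noise_sd < 0) {
    stop("phantom_spec(): amplitudes and noise_sd must be >= 0")
  }
  if (length(ehr_schema) == 0L) stop("phantom_spec(): empty ehr_schema")
  spec <- structure(list(
    n_classes = n_classes, class_probs = as.double(class_probs),
    lesion_radius_mean_mm = as.double(lesion_radius_mean_mm),
    lesion_intensity_mean = as.double(lesion_intensity_mean),
    spiculation_amp = as.double(spiculation_amp),
    noise_sd = as.double(noise_sd), ehr_schema = ehr_schema,
    volume_shape_vox = as.integer(volume_shape_vox),
    spacing_mm = as.double(spacing_mm),
    center_jitter_vox = as.integer(center_jitter_vox),
    seed = as.integer(seed)), class = "phantom_spec")
  # margin check: the largest possible lesion must fit inside the volume
  # even at maximal center jitter
  max_r <- max(spec$lesion_radius_mean_mm * 1.15 * (1 + spec$spiculation_amp))
  half_extent <- spec$volume_shape_vox * spec$spacing_mm / 2
  margin <- (spec$center_jitter_vox + 1) * spec$spacing_mm
  if (any(max_r > half_extent - margin)) {
    stop("phantom_spec(): largest lesion cannot fit inside the volume")
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$n_classes, " classes, volume ",
      paste(x$volume_shape_vox, collapse = "x"), " @ ",
      paste(x$spacing_mm, collapse = "x"), " mm, radii ",
      paste(x$lesion_radius_mean_mm, collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

#' Default clinical schema of the synthetic world
#'
#' Five fields chosen to exercise both encodings: age (numeric, class-shifted),
#' sex (binary categorical), smoking (three-level categorical),
#' nodule_diameter_mm (numeric, tied to the sampled lesion diameter) and
#' marker_level (numeric, class-shifted).
#' @return A schema list accepted by [phantom_spec()].
#' @export
default_ehr_schema <- function() {
  list(
    list(name = "age", kind = "numeric", means = c(55, 61, 67)),
    list(name = "sex", kind = "categorical", levels = c("F", "M"),
         probs = rbind(c(0.65, 0.35), c(0.60, 0.40), c(0.50, 0.50))),
    list(name = "smoking", kind = "categorical",
         levels = c("never", "former", "current"),
         probs = rbind(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2),
                       c(0.35, 0.35, 0.30))),
    list(name = "nodule_diameter_mm", kind = "numeric", link = "diameter"),
    list(name = "marker_level", kind = "numeric", means = c(0, 1, 2))
  )
}

#' Convert the generator schema to encoder field descriptors
#' @param spec A [phantom_spec()].
#' @return A list of [ehr_field()] entries.
#' @export
phantom_ehr_fields <- function(spec) {
  lapply(spec$ehr_schema, function(f) ehr_field(f$name, f$kind))
}

#' Draw class labels from the phantom class mixture
#'
#' @param spec A [phantom_spec()].
#' @param n Number of labels.
#' @return Integer vector of 0-based labels.
#' @export
draw_labels <- function(spec, n) {
  sample(seq_len(spec$n_classes) - 1L, n, replace = TRUE,
         prob = spec$class_probs)
}

#' Nearest-integer apportionment of class counts
#'
#' Largest-remainder (Hamilton) apportionment of `n` among the class
#' probabilities: floors plus the largest fractional remainders, so counts
#' sum to `n` exactly and each differs from `n * p` by less than 1.
#'
#' @param probs Probability vector.
#' @param n Total count.
#' @return Integer vector of per-class counts summing to `n`.
#' @export
apportion_counts <- function(probs, n) {
  quota <- probs * n
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

sample_ehr_record <- function(spec, label, r0_mm) {
  rec <- list()
  for (f in spec$ehr_schema) {
    if (f$kind == "numeric") {
      if (identical(f$link, "diameter")) {
        rec[[f$name]] <- 2 * r0_mm + rnorm(1)
      } else {
        rec[[f$name]] <- rnorm(1, mean = f$means[label + 1L], sd = 1)
      }
    } else {
      rec[[f$name]] <- sample(f$levels, 1L, prob = f$probs[label + 1L, ])
    }
  }
  rec
}

#' Generate one synthetic lesion case
#'
#' Draws a lesion radius within +/-15% of the class mean, renders the
#' perturbed sphere into a -900 HU lung field (lesion HU = intensity * 1400
#' - 1000, plus Gaussian noise), computes the tight voxel bounding box of
#' the lesion support, and samples a class-conditional clinical record.
#'
#' @param spec A [phantom_spec()].
#' @param label 0-based class index.
#' @param seed Optional seed; when given, the case is a pure function of
#'   `(spec, label, seed)`.
#' @return A list with `volume` ([ct_volume()] in HU), `bbox` (voxel-frame
#'   [bbox3d()]), `ehr` (named list), `label`, and `radius_mm`.
#' @export
sample_case <- function(spec, label, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- as.integer(label)
  if (label < 0L || label >= spec$n_classes) {
    stop("sample_case(): label must be in 0..", spec$n_classes - 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  shape <- spec$volume_shape_vox
  s <- spec$spacing_mm
  cls <- label + 1L

  r0 <- runif(1, 0.85, 1.15) * spec$lesion_radius_mean_mm[cls]
  amp <- spec$spiculation_amp[cls]
  intensity <- spec$lesion_intensity_mean[cls]
  jit <- spec$center_jitter_vox
  # lesion center on a cell boundary near the volume center
  k <- round(shape / 2) + sample(seq(-jit, jit), 3L, replace = TRUE)
  center_mm <- k * s

  hu_noise <- 1400 * spec$noise_sd
  vol <- array(-900, shape)
  if (hu_noise > 0) {
    vol <- vol + rnorm(length(vol), sd = hu_noise)
  }

  # render only inside a conservative sub-box around the center
  r_max <- r0 * (1 + amp)
  half <- ceiling(r_max / s) + 1L
  lo <- k - half
  hi <- k + half - 1L
  if (any(lo < 0L) || any(hi > shape - 1L)) {
    stop("sample_case(): lesion extends outside the volume bounds")
  }
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx <- (ix + 0.5) * s[1] - center_mm[1]
  dy <- (iy + 0.5) * s[2] - center_mm[2]
  dz <- (iz + 0.5) * s[3] - center_mm[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  DX <- array(dx, c(nx, ny, nz))
  DY <- array(rep(dy, each = nx), c(nx, ny, nz))
  DZ <- array(rep(dz, each = nx * ny), c(nx, ny, nz))
  dist <- sqrt(DX^2 + DY^2 + DZ^2)
  if (amp > 0) {
    theta <- acos(ifelse(dist > 0, DZ / dist, 1))
    phi <- atan2(DY, DX)
    rad <- r0 * (1 + amp * harmonic_perturbation(theta, phi))
  } else {
    rad <- r0
  }
  mask <- dist <= rad
  if (!any(mask)) stop("sample_case(): degenerate lesion (empty support)")
  lesion_hu <- -1000 + 1400 * intensity
  sub <- vol[ix + 1L, iy + 1L, iz + 1L]
  noise_in <- if (hu_noise > 0) rnorm(sum(mask), sd = hu_noise) else 0
  sub[mask] <- lesion_hu + noise_in
  vol[ix + 1L, iy + 1L, iz + 1L] <- sub

  # tight axis-aligned box of the lesion support (0-based voxel indices)
  w <- which(mask, arr.ind = TRUE)
  supp_lo <- c(ix[min(w[, 1])], iy[min(w[, 2])], iz[min(w[, 3])])
  supp_hi <- c(ix[max(w[, 1])], iy[max(w[, 2])], iz[max(w[, 3])])
  bbox <- bbox3d(center = (supp_lo + supp_hi) / 2,
                 size = supp_hi - supp_lo + 1, frame = "voxel")

  ehr <- sample_ehr_record(spec, label, r0)
  list(volume = ct_volume(vol, spacing_mm = s), bbox = bbox, ehr = ehr,
       label = label, radius_mm = r0)
}

#' Generate a dataset of phantoms on disk
#'
#' Writes one NIfTI volume per case plus a CSV manifest (case id, label,
#' voxel-frame box columns, clinical fields, file path) and a JSON copy of
#' the generating specification. Labels are assigned by stratified
#' nearest-integer apportionment of `class_probs`, so the class counts match
#' the mixture as closely as integers allow.
#'
#' @param spec A [phantom_spec()].
#' @param n_cases Number of cases (>= `n_classes`).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed (default `spec$seed`).
#' @return The manifest data frame, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
build_dataset <- function(spec, n_cases, out_dir, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_cases <- as.integer(n_cases)
  if (n_cases < spec$n_classes) {
    stop("build_dataset(): need at least one case per class")
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("build_dataset(): cannot create output directory '", out_dir, "'")
  }
  counts <- apportion_counts(spec$class_probs, n_cases)
  labels <- rep(seq_len(spec$n_classes) - 1L, counts)
  set.seed(seed)
  labels <- sample(labels)  # shuffle case order, counts unchanged

  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case <- sample_case(spec, labels[i])
    case_id <- sprintf("case_%04d", i)
    path <- file.path(out_dir, paste0(case_id, ".nii.gz"))
    write_nifti(case$volume, path)
    rows[[i]] <- data.frame(
      case_id = case_id, label = case$label,
      cx = case$bbox$center[1], cy = case$bbox$center[2],
      cz = case$bbox$center[3],
      w = case$bbox$size[1], h = case$bbox$size[2], d = case$bbox$size[3],
      frame = "voxel",
      as.data.frame(case$ehr, stringsAsFactors = FALSE),
      path = path, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  spec_out <- spec
  class(spec_out) <- NULL
  jsonlite::write_json(spec_out, file.path(out_dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Generate a dataset in memory
#'
#' Like [build_dataset()] but returns the cases as a list without touching
#' disk; used for training experiments and tests.
#'
#' @inheritParams build_dataset
#' @return A list of [sample_case()] results in shuffled stratified order.
#' @export
build_dataset_memory <- function(spec, n_cases, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  counts <- apportion_counts(spec$class_probs, as.integer(n_cases))
  labels <- rep(seq_len(spec$n_classes) - 1L, counts)
  set.seed(seed)
  labels <- sample(labels)
  lapply(labels, function(lab) sample_case(spec, lab))
}
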