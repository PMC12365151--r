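## Dataset I/O: manifest reading and a preprocessed-sample cache
## (NIfTI crops + one JSON sidecar per case).

manifest_meta_cols <- c("case_id", "label", "cx", "cy", "cz", "w", "h", "d",
                        "frame", "path")

#' Load cases listed in a dataset manifest
#'
#' Reads the CSV manifest written by [build_dataset()] (columns `case_id`,
#' `label`, box center/size, `frame`, clinical fields, `path`) and loads
#' each referenced NIfTI volume.
#'
#' @param manifest Manifest data frame or path to `manifest.csv`.
#' @return List of cases (`volume`, `bbox`, `ehr`, `label`, `case_id`)
#'   ready for [preprocess_cases()].
#' @export
load_manifest_cases <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  ehr_cols <- setdiff(names(manifest), manifest_meta_cols)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, , drop = FALSE]
    if (!identical(row$frame, "voxel")) {
      stop("load_manifest_cases(): expected voxel-frame boxes")
    }
    list(volume = read_nifti(row$path),
         bbox = bbox3d(c(row$cx, row$cy, row$cz), c(row$w, row$h, row$d),
                       frame = "voxel"),
         ehr = as.list(row[ehr_cols]),
         label = as.integer(row$label),
         case_id = row$case_id)
  })
}

#' Cache preprocessed samples to disk
#'
#' Writes, per case, the two normalized crops as NIfTI files and a JSON
#' sidecar holding the crop-relative boxes, the raw clinical record and the
#' label.
#'
#' @param samples Preprocessed samples ([preprocess_cases()]).
#' @param out_dir Cache directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
cache_preprocessed <- function(samples, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cache_preprocessed(): cannot create '", out_dir, "'")
  }
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stem <- file.path(out_dir, sprintf("sample_%04d", i))
    write_nifti(s$roi_small, paste0(stem, "_small.nii.gz"))
    write_nifti(s$roi_large, paste0(stem, "_large.nii.gz"))
    jsonlite::write_json(list(
      bbox_small = list(center = s$bbox_small$center, size = s$bbox_small$size),
      bbox_large = list(center = s$bbox_large$center, size = s$bbox_large$size),
      ehr = s$ehr, label = s$label),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Load a preprocessed-sample cache
#'
#' @param cache_dir Directory written by [cache_preprocessed()].
#' @return List of preprocessed samples.
#' @export
load_preprocessed <- function(cache_dir) {
  sidecars <- sort(list.files(cache_dir, pattern = "^sample_\\d+\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0) stop("load_preprocessed(): empty cache")
  lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    stem <- sub("\\.json$", "", sc)
    list(roi_small = read_nifti(paste0(stem, "_small.nii.gz"))$voxels,
         roi_large = read_nifti(paste0(stem, "_large.nii.gz"))$voxels,
         bbox_small = bbox3d(meta$bbox_small$center, meta$bbox_small$size,
                             frame = "relative"),
         bbox_large = bbox3d(meta$bbox_large$center, meta$bbox_large$size,
                             frame = "relative"),
         ehr = as.list(meta$ehr), label = as.integer(meta$label))
  })
}
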