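#' Write a synthetic cohort as NIfTI volumes
#'
#' Emits one grey-matter value map per subject plus a single shared
#' integer atlas volume. Regions are laid out as consecutive runs of
#' voxels in array order — deliberately geometry-free — such that
#' re-extraction with [extract_regional_values()] recovers each
#' subject's regional value bags exactly. Value maps are written as
#' float64 so the round trip is bit-exact.
#'
#' @param cohort a `morph_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param atlas_shape integer triple; must hold `90 * voxels_per_region`
#'   voxels.
#' @return invisibly, a list with `atlas` (path) and `maps` (named
#'   vector of per-subject paths).
#' @export
write_cohort_nifti <- function(cohort, dir, atlas_shape = c(30L, 30L, 30L)) {
  stopifnot(inherits(cohort, "morph_cohort"))
  vpr <- lengths(cohort$subjects[[1]]$region_values)
  need <- sum(vpr)
  if (prod(atlas_shape) < need)
    stop(sprintf("atlas_shape holds %d voxels but %d are needed: parcels too small for the requested voxels per region",
                 prod(atlas_shape), need))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  atlas <- array(0L, dim = atlas_shape)
  atlas[seq_len(need)] <- rep(seq_len(90), times = vpr)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(atlas, atlas_path, datatype = "int16")

  maps <- character(length(cohort$subjects))
  names(maps) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  for (i in seq_along(cohort$subjects)) {
    vol <- array(0, dim = atlas_shape)
    vol[seq_len(need)] <- unlist(cohort$subjects[[i]]$region_values)
    maps[i] <- file.path(dir, paste0(names(maps)[i], "_gm.nii.gz"))
    RNifti::writeNifti(vol, maps[i], datatype = "double")
  }
  invisible(list(atlas = atlas_path, maps = maps))
}

#' Extract per-region voxel values from a grey-matter map
#'
#' Collects, for each atlas label 1..90, the map values at the voxels
#' carrying that label.
#'
#' @param gm_map path to a NIfTI value map, or a numeric array.
#' @param atlas path to a NIfTI label volume (integers 1..90; 0 =
#'   background), or an integer array of the same shape.
#' @param region_labels optional character vector of 90 region names.
#' @return a list with `subject_id` (NA unless set by the caller),
#'   `region_values` (90 numeric vectors) and `region_labels`.
#' @export
extract_regional_values <- function(gm_map, atlas,
                                    region_labels = aal90_labels()) {
  if (is.character(gm_map)) gm_map <- as.array(RNifti::readNifti(gm_map))
  if (is.character(atlas))  atlas  <- as.array(RNifti::readNifti(atlas))
  if (!identical(dim(gm_map), dim(atlas)))
    stop("gm_map and atlas are not on the same voxel grid")
  lab <- as.integer(round(atlas))
  present <- sort(unique(lab[lab > 0L]))
  missing <- setdiff(seq_len(90), present)
  if (length(missing))
    stop("atlas is missing label(s): ", paste(missing, collapse = ", "))
  vals <- as.numeric(gm_map)
  bags <- split(vals[lab > 0L], lab[lab > 0L])
  region_values <- unname(bags[as.character(seq_len(90))])
  list(subject_id = NA_character_,
       region_values = region_values,
       region_labels = region_labels)
}
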