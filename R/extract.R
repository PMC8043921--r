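#' Feature extraction configuration
#'
#' @param method discretization method, `"fixed_bin_size"` (default,
#'   0.5 SUV bins — common PET practice) or `"fixed_bin_number"`.
#' @param param bin width (SUV) or bin count.
#' @param aggregation directional aggregation for GLCM/GLRLM: `"average"`
#'   (feature values averaged over the 13 directions, default) or `"merge"`
#'   (matrices pooled before feature computation).
#' @param max_autocorr_voxels exact-computation cap for Moran's I / Geary's C.
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(method = "fixed_bin_size", param = 0.5,
                              aggregation = "average",
                              max_autocorr_voxels = 20000L) {
  structure(list(method = method, param = param, aggregation = aggregation,
                 max_autocorr_voxels = as.integer(max_autocorr_voxels)),
            class = "extraction_config")
}

#' Canonical dictionary of the 101 extracted features
#'
#' Family cardinalities: 19 morphology, 2 local intensity, 18 intensity
#' statistics, 25 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM. Family membership
#' follows the standard IBSI feature lists, filled to each family's count.
#'
#' @return data.frame with columns `name` (family-prefixed) and `family`.
#' @export
feature_dictionary <- function() {
  fam <- c(rep("morphology", 19), rep("local_intensity", 2),
           rep("statistics", 18), rep("glcm", 25), rep("glrlm", 16),
           rep("glszm", 16), rep("ngtdm", 5))
  nm <- c(paste0("morph.", morph_feature_names),
          c("local.peak_global", "local.peak_local"),
          paste0("stat.", stat_feature_names),
          paste0("glcm.", glcm_feature_names),
          paste0("glrlm.", rl_feature_names(zone = FALSE)),
          paste0("glszm.", rl_feature_names(zone = TRUE)),
          paste0("ngtdm.", c("coarseness", "contrast", "busyness",
                             "complexity", "strength")))
  data.frame(name = nm, family = fam, stringsAsFactors = FALSE)
}

#' Extract all 101 radiomic features from a PET volume and tumor mask
#'
#' Runs every feature family and returns a single named vector of exactly
#' 101 values. Features that are undefined for the input (e.g. correlation
#' on a single gray level, mesh metrics on a single voxel) are returned as
#' `NA` and listed in the `flags` attribute rather than silently dropped, so
#' downstream screening can exclude them.
#'
#' @param vol a [pet_volume()].
#' @param mask a [roi_mask()] on the same grid.
#' @param config an [extraction_config()].
#' @return named numeric vector of class `feature_vector` (length 101) with
#'   attributes `flags` (character) and `config_hash`.
#' @export
extract_all <- function(vol, mask, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  droi <- discretize(vol, mask, method = config$method, param = config$param)
  parts <- list(
    morph = morphology_features(mask, vol),
    local = local_intensity_features(vol, mask),
    stat = intensity_statistics(vol, mask,
                                max_autocorr_voxels =
                                  config$max_autocorr_voxels),
    glcm = glcm_features(droi, aggregation = config$aggregation),
    glrlm = glrlm_features(droi, aggregation = config$aggregation),
    glszm = glszm_features(droi),
    ngtdm = ngtdm_features(droi)
  )
  flags <- unlist(lapply(names(parts), function(nm) {
    fl <- attr(parts[[nm]], "flags")
    if (length(fl)) paste0(nm, ":", fl) else character(0)
  }))
  flags <- c(flags, if (length(droi$flags)) paste0("discretize:", droi$flags))
  vals <- unlist(lapply(parts, function(p) {
    attributes(p) <- list(names = names(p))
    p
  }))
  names(vals) <- feature_dictionary()$name
  structure(vals, flags = unname(flags),
            config_hash = config_hash(unclass(config)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features (%d flagged undefined)\n",
              length(x), sum(is.na(x))))
  invisible(x)
}

#' Extract features for a list of image/mask pairs into a table
#'
#' @param pairs list of `list(volume =, mask =)` pairs (as returned by
#'   [generate_phantom()] or [read_pet_pair()]).
#' @param config an [extraction_config()].
#' @return data.frame, one row per pair, 101 canonical feature columns.
#' @export
extract_feature_table <- function(pairs, config = extraction_config()) {
  rows <- lapply(pairs, function(p) {
    fv <- extract_all(p$volume, p$mask, config)
    as.data.frame(as.list(unclass(fv)), check.names = FALSE)
  })
  do.call(rbind, rows)
}
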