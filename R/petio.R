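#' Write a PET volume and tumor mask as a NIfTI pair
#'
#' The image is written with double precision so SUV values round-trip
#' bit-exactly; the mask is written as unsigned 8-bit.
#'
#' @param volume a [pet_volume()].
#' @param mask a [roi_mask()] on the same grid.
#' @param image_path,mask_path output NIfTI paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_pet_pair <- function(volume, mask, image_path, mask_path) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  img <- volume$values
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, image_path, datatype = "double")
  msk <- array(as.integer(mask$values), dim(mask$values))
  RNifti::pixdim(msk) <- mask$spacing
  RNifti::writeNifti(msk, mask_path, datatype = "uint8")
  invisible(c(image = image_path, mask = mask_path))
}

#' Read a PET image / tumor mask NIfTI pair
#'
#' Verifies that both files share the same voxel grid (shape exactly; spacing
#' within 1e-3 mm) and binarizes the mask at > 0.
#'
#' @param image_path,mask_path NIfTI file paths.
#' @param spacing_tol spacing agreement tolerance in mm.
#' @return list with `volume` ([pet_volume()]) and `mask` ([roi_mask()]).
#' @export
read_pet_pair <- function(image_path, mask_path, spacing_tol = 1e-3) {
  abort_if(!file.exists(image_path), "image file not found: ", image_path)
  abort_if(!file.exists(mask_path), "mask file not found: ", mask_path)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  isp <- RNifti::pixdim(img)[1:3]
  msp <- RNifti::pixdim(msk)[1:3]
  ia <- array(as.numeric(img), dim = dim(img)[1:3])
  ma <- array(as.numeric(msk) > 0, dim = dim(msk)[1:3])
  abort_if(!identical(dim(ia), dim(ma)),
           "grid mismatch: image ", paste(dim(ia), collapse = "x"),
           " voxels vs mask ", paste(dim(ma), collapse = "x"), " voxels")
  abort_if(any(abs(isp - msp) > spacing_tol),
           "grid mismatch: image spacing (",
           paste(signif(isp, 6), collapse = ", "), ") mm vs mask spacing (",
           paste(signif(msp, 6), collapse = ", "), ") mm")
  abort_if(!any(ma), "mask is empty: no foreground voxel in ", mask_path)
  list(volume = pet_volume(ia, isp),
       mask = roi_mask(ma, msp, provenance = mask_path))
}

clinical_levels <- list(
  histology = c("adenocarcinoma", "squamous"),
  ct_stage = c("T1-2", "T3-4a"),
  cn_stage = c("N0-1", "N2-3"),
  sex = c("male", "female")
)
marker_cols <- c("her2", "cd44", "hif1a_nucleus", "hif1a_cytosol",
                 "ptch1", "shh")

#' Read and validate a per-patient clinical table
#'
#' Validates categorical levels, preserves missing marker entries as `NA`
#' (never imputed; analyses that use a marker exclude its missing cases), and
#' derives the binary response: pathologic complete response (pCR) if and
#' only if Mandard tumor regression grade equals 1.
#'
#' @param path CSV file path, or a data.frame with the same columns.
#' @return data.frame with validated factors, marker columns as
#'   `"negative"`/`"positive"`/`NA`, and an added `response` factor with
#'   levels `c("non-pCR", "pCR")`.
#' @export
read_clinical <- function(path) {
  df <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "histology", "ct_stage", "cn_stage", "mandard")
  miss <- setdiff(required, names(df))
  abort_if(length(miss) > 0, "missing required columns: ",
           paste(miss, collapse = ", "))
  df$mandard <- as.integer(df$mandard)
  bad <- which(!df$mandard %in% 1:5)
  abort_if(length(bad) > 0, "invalid Mandard grade in row(s): ",
           paste(df$id[bad], collapse = ", "))
  for (col in intersect(names(clinical_levels), names(df))) {
    lv <- clinical_levels[[col]]
    bad <- which(!(df[[col]] %in% lv) & !is.na(df[[col]]) & df[[col]] != "")
    abort_if(length(bad) > 0, "unknown ", col, " level in row(s): ",
             paste(df$id[bad], collapse = ", "))
    df[[col]] <- factor(df[[col]], levels = lv)
  }
  if ("chemo_cycles" %in% names(df)) {
    df$chemo_cycles <- as.integer(df$chemo_cycles)
    bad <- which(!df$chemo_cycles %in% c(4L, 5L))
    abort_if(length(bad) > 0, "chemo_cycles must be 4 or 5; offending row(s): ",
             paste(df$id[bad], collapse = ", "))
  }
  for (col in intersect(marker_cols, names(df))) {
    v <- df[[col]]
    v[v %in% c("", "missing", "NA")] <- NA
    bad <- which(!v %in% c("negative", "positive") & !is.na(v))
    abort_if(length(bad) > 0, "unknown ", col, " level in row(s): ",
             paste(df$id[bad], collapse = ", "))
    df[[col]] <- v
  }
  df$response <- factor(ifelse(df$mandard == 1L, "pCR", "non-pCR"),
                        levels = c("non-pCR", "pCR"))
  df
}
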