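#' PET volume container
#'
#' A 3D array of standardized uptake values (SUV, body-weight normalized,
#' dimensionless) with its voxel spacing in millimetres. All geometric and
#' autocorrelation features are computed in world units from `spacing`; the
#' in-memory axis order is fixed (x, y, z) regardless of on-disk layout.
#'
#' @param values 3D numeric array of SUV.
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param origin numeric length-3, mm offset of the first voxel corner.
#' @return object of class `pet_volume` (list with `values`, `spacing`,
#'   `origin`).
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  abort_if(length(dim(values)) != 3L, "`values` must be a 3D array")
  abort_if(!all(is.finite(values)), "PET volume contains non-finite values")
  spacing <- as.numeric(spacing)
  abort_if(length(spacing) != 3L || any(spacing <= 0),
           "`spacing` must be 3 positive numbers (mm)")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "pet_volume")
}

#' Region-of-interest mask container
#'
#' Binary tumor mask on the same voxel grid as its paired [pet_volume()].
#'
#' @param values 3D logical (or 0/1) array; at least one foreground voxel.
#' @param spacing numeric length-3, mm per axis.
#' @param provenance free-text description of how the mask was obtained.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing, provenance = "") {
  abort_if(length(dim(values)) != 3L, "`values` must be a 3D array")
  m <- array(as.logical(values != 0), dim = dim(values))
  abort_if(!any(m), "mask is empty: no foreground voxel")
  spacing <- as.numeric(spacing)
  abort_if(length(spacing) != 3L || any(spacing <= 0),
           "`spacing` must be 3 positive numbers (mm)")
  structure(list(values = m, spacing = spacing,
                 provenance = as.character(provenance)),
            class = "roi_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

check_same_grid <- function(vol, mask, tol = 1e-3) {
  abort_if(!identical(dim(vol$values), dim(mask$values)),
           "image/mask grid mismatch: image ",
           paste(dim(vol$values), collapse = "x"), " vs mask ",
           paste(dim(mask$values), collapse = "x"))
  abort_if(any(abs(vol$spacing - mask$spacing) > tol),
           "image/mask spacing mismatch: image (",
           paste(signif(vol$spacing, 6), collapse = ", "), ") mm vs mask (",
           paste(signif(mask$spacing, 6), collapse = ", "), ") mm")
  invisible(TRUE)
}

# voxel-centre world coordinates along one axis (mm)
axis_coords <- function(n, sp) (seq_len(n) - 0.5) * sp
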