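#' Discretize in-mask SUV into gray levels
#'
#' Fixed-bin-size (default, bin width in SUV): level = floor((SUV - min)/w) + 1
#' with the top value clamped so the maximum maps to Ng = floor((max - min)/w)
#' + 1. Fixed-bin-number: Nb equal-width bins over the in-mask range.
#'
#' @param vol a [pet_volume()].
#' @param mask a [roi_mask()] on the same grid.
#' @param method `"fixed_bin_size"` or `"fixed_bin_number"`.
#' @param param bin width w (SUV) or bin count Nb; must be > 0.
#' @return list of class `discretized_roi`: `levels` (integer array, `NA`
#'   outside the mask), `ng` (number of gray levels), `method`, `param`,
#'   `flags` (character vector of degeneracy flags).
#' @export
discretize <- function(vol, mask, method = c("fixed_bin_size",
                                             "fixed_bin_number"),
                       param = 0.5) {
  stopifnot(inherits(vol, "pet_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  method <- match.arg(method)
  abort_if(param <= 0, "`param` must be > 0")
  m <- mask$values
  x <- vol$values[m]
  abort_if(length(x) < 1, "no in-mask voxel")
  flags <- character(0)
  rng <- range(x)
  if (method == "fixed_bin_size") {
    w <- param
    if (rng[2] > rng[1]) {
      ng <- as.integer(floor((rng[2] - rng[1]) / w + 1e-9)) + 1L
      lev <- pmin(as.integer(floor((x - rng[1]) / w + 1e-9)) + 1L, ng)
    } else {
      ng <- 1L
      lev <- rep(1L, length(x))
    }
  } else {
    nb <- as.integer(param)
    if (rng[2] > rng[1]) {
      ng <- nb
      lev <- pmin(as.integer(floor(nb * (x - rng[1]) / (rng[2] - rng[1]))) +
                    1L, nb)
    } else {
      ng <- 1L
      lev <- rep(1L, length(x))
      flags <- c(flags, "constant_intensity_single_level")
    }
  }
  if (ng == 1L && !("constant_intensity_single_level" %in% flags) &&
      rng[2] == rng[1]) {
    flags <- c(flags, "constant_intensity_single_level")
  }
  levels <- array(NA_integer_, dim = dim(m))
  levels[m] <- lev
  structure(list(levels = levels, ng = ng, method = method, param = param,
                 spacing = mask$spacing, flags = flags),
            class = "discretized_roi")
}

# shift a 3D array by integer offset d, padding with NA: result[x] = a[x + d]
shift_array <- function(a, d) {
  dims <- dim(a)
  out <- array(NA, dim = dims)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dims[ax]
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n - d[ax])
      src[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      dst[[ax]] <- seq_len(n + d[ax]) - d[ax]
      src[[ax]] <- seq_len(n + d[ax])
    }
    if (length(dst[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# the 13 unique 3D direction vectors (26-connectivity modulo sign)
unique_directions3 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- apply(dirs, 1, function(d) {
    nz <- which(d != 0)[1]
    d[nz] > 0
  })
  as.matrix(dirs[keep, ])
}
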