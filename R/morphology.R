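# Morphological features: mesh-based volume/area from an iso-surface of the
# binary mask at level 0.5, voxel-count volume, shape ratios, principal-axis
# metrics from the voxel-coordinate covariance spectrum, and total lesion
# glycolysis.

# Iso-surface of the mask at level 0.5 by marching tetrahedra: the binary
# occupancy is first smoothed with a small Gaussian (sigma in voxels) so the
# 0.5 level set tracks the true boundary with sub-voxel accuracy, then each
# grid cube (8 neighboring voxel centres) is split into 6 tetrahedra sharing
# the main diagonal and intersected edges are cut by linear interpolation.
# Triangles carry outward normals, so the divergence theorem gives the
# enclosed volume directly. Very small ROIs whose smoothed field never
# exceeds the level fall back to the unsmoothed binary field.
mask_isosurface <- function(mask, spacing, sigma_vox = 0.7, level = 0.5) {
  field <- array(as.numeric(mask), dim(mask))
  if (sigma_vox > 0) {
    sm <- gaussian_smooth3(field, rep(sigma_vox, 3))
    if (max(sm) > level) field <- sm
  }
  dims <- dim(field)
  pad <- array(0, dim = dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- field
  pd <- dim(pad)
  # cube corner offsets, vertex bit order (i, j, k)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  # candidate cubes: corner in/out states disagree
  base <- pad[1:(pd[1] - 1), 1:(pd[2] - 1), 1:(pd[3] - 1)] > level
  mixed <- array(FALSE, dim = pd - 1L)
  for (ci in 2:8) {
    o <- corner[ci, ]
    shifted <- pad[(1:(pd[1] - 1)) + o[1], (1:(pd[2] - 1)) + o[2],
                   (1:(pd[3] - 1)) + o[3]] > level
    mixed <- mixed | (shifted != base)
  }
  cubes <- which(mixed, arr.ind = TRUE)
  area <- 0
  vol6 <- 0
  if (nrow(cubes) > 0) {
    for (r in seq_len(nrow(cubes))) {
      cb <- cubes[r, ]
      vals <- numeric(8)
      pts <- matrix(0, 8, 3)
      for (ci in 1:8) {
        ijk <- cb + corner[ci, ]
        vals[ci] <- pad[ijk[1], ijk[2], ijk[3]]
        # padded index ijk corresponds to original voxel ijk - 1,
        # centre at (ijk - 1 - 0.5) * spacing
        pts[ci, ] <- (ijk - 1.5) * spacing
      }
      for (t in 1:6) {
        vv <- vals[tets[t, ]]
        pp <- pts[tets[t, ], , drop = FALSE]
        tris <- tet_triangles(vv, pp, level)
        for (tri in tris) {
          e1 <- tri[2, ] - tri[1, ]
          e2 <- tri[3, ] - tri[1, ]
          n <- c(e1[2] * e2[3] - e1[3] * e2[2],
                 e1[3] * e2[1] - e1[1] * e2[3],
                 e1[1] * e2[2] - e1[2] * e2[1])
          area <- area + sqrt(sum(n^2)) / 2
          # signed volume of tetra (origin, p1, p2, p3) with outward normal
          vol6 <- vol6 + sum(tri[1, ] * c(
            tri[2, 2] * tri[3, 3] - tri[2, 3] * tri[3, 2],
            tri[2, 3] * tri[3, 1] - tri[2, 1] * tri[3, 3],
            tri[2, 1] * tri[3, 2] - tri[2, 2] * tri[3, 1]))
        }
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6)
}

# triangles (each a 3x3 matrix of vertex coordinates, outward-oriented) for
# one tetrahedron; edges crossing the level are cut by linear interpolation
tet_triangles <- function(vals, pts, level = 0.5) {
  inside <- which(vals > level)
  n_in <- length(inside)
  if (n_in == 0 || n_in == 4) return(list())
  cut <- function(a, b) {
    t <- (level - vals[a]) / (vals[b] - vals[a])
    pts[a, ] + t * (pts[b, ] - pts[a, ])
  }
  orient <- function(tri, in_centroid) {
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    ctr <- colMeans(tri)
    if (sum(n * (ctr - in_centroid)) < 0) tri[c(1, 3, 2), ] else tri
  }
  in_centroid <- colMeans(pts[inside, , drop = FALSE])
  outside <- setdiff(1:4, inside)
  if (n_in == 1) {
    a <- inside
    tri <- rbind(cut(a, outside[1]), cut(a, outside[2]), cut(a, outside[3]))
    return(list(orient(tri, in_centroid)))
  }
  if (n_in == 3) {
    a <- outside
    tri <- rbind(cut(inside[1], a), cut(inside[2], a), cut(inside[3], a))
    return(list(orient(tri, in_centroid)))
  }
  # two in, two out: quad split into two triangles
  a <- inside[1]; b <- inside[2]
  cc <- outside[1]; dd <- outside[2]
  q1 <- cut(a, cc); q2 <- cut(a, dd); q3 <- cut(b, dd); q4 <- cut(b, cc)
  list(orient(rbind(q1, q2, q3), in_centroid),
       orient(rbind(q1, q3, q4), in_centroid))
}

morph_feature_names <- c(
  "volume_mesh", "volume_voxel", "surface_area", "surface_to_volume_ratio",
  "compactness_1", "compactness_2", "spherical_disproportion", "sphericity",
  "asphericity", "centre_of_mass_shift", "max_3d_diameter",
  "major_axis_length", "minor_axis_length", "least_axis_length",
  "elongation", "flatness", "volume_density_aabb", "area_density_aabb",
  "tlg")

#' Morphological features (19)
#'
#' Mesh volume and surface area come from a marching-tetrahedra iso-surface
#' of the binary mask at level 0.5; principal axis lengths, elongation
#' (sqrt(lambda2/lambda1)) and flatness (sqrt(lambda3/lambda1)) from the
#' eigen-spectrum of the voxel-centre coordinate covariance; total lesion
#' glycolysis (TLG) is SUVmean times voxel-count volume. For a single-voxel
#' ROI the mesh and covariance metrics are undefined and returned as `NA`
#' (flagged); voxel-count metrics are always returned. A disconnected mask is
#' reduced to its largest 26-connected component with a warning.
#'
#' @param mask a [roi_mask()].
#' @param vol the paired [pet_volume()] (for TLG and centre-of-mass shift).
#' @return named numeric vector of 19 features with attribute `flags`.
#' @export
morphology_features <- function(mask, vol) {
  stopifnot(inherits(mask, "roi_mask"), inherits(vol, "pet_volume"))
  check_same_grid(vol, mask)
  sp <- mask$spacing
  m <- mask$values
  comp <- mask_components(m)
  flags <- character(0)
  if (comp$n > 1) {
    warning("mask has ", comp$n,
            " connected components; using the largest", call. = FALSE)
    m <- comp$largest
    flags <- c(flags, "disconnected_mask_largest_component_used")
  }
  idx <- which(m, arr.ind = TRUE)
  nvox <- nrow(idx)
  coords <- sweep(idx - 0.5, 2, sp, `*`)
  suv <- vol$values[m]
  v_vox <- nvox * prod(sp)
  suv_mean <- mean(suv)
  tlg <- suv_mean * v_vox
  com_geom <- colMeans(coords)
  com_int <- if (sum(suv) > 0) colSums(coords * suv) / sum(suv) else com_geom
  com_shift <- sqrt(sum((com_geom - com_int)^2))
  ext_lo <- (apply(idx, 2, min) - 1) * sp
  ext_hi <- apply(idx, 2, max) * sp
  aabb_vol <- prod(ext_hi - ext_lo)
  aabb_area <- {
    e <- ext_hi - ext_lo
    2 * (e[1] * e[2] + e[1] * e[3] + e[2] * e[3])
  }
  if (nvox < 2) {
    flags <- c(flags, "single_voxel_mesh_metrics_undefined")
    vals <- c(volume_mesh = NA, volume_voxel = v_vox, surface_area = NA,
              surface_to_volume_ratio = NA, compactness_1 = NA,
              compactness_2 = NA, spherical_disproportion = NA,
              sphericity = NA, asphericity = NA,
              centre_of_mass_shift = com_shift, max_3d_diameter = 0,
              major_axis_length = NA, minor_axis_length = NA,
              least_axis_length = NA, elongation = NA, flatness = NA,
              volume_density_aabb = NA, area_density_aabb = NA, tlg = tlg)
    attr(vals, "flags") <- flags
    return(vals)
  }
  mesh <- mask_isosurface(m, sp)
  a <- mesh$area
  v <- mesh$volume
  ev <- eigen(cov(coords), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  boundary <- boundary_voxels(m)
  bidx <- which(boundary, arr.ind = TRUE)
  bc <- sweep(bidx - 0.5, 2, sp, `*`)
  maxd <- if (nrow(bc) > 1) max(dist(bc)) else 0
  vals <- c(
    volume_mesh = v,
    volume_voxel = v_vox,
    surface_area = a,
    surface_to_volume_ratio = a / v,
    compactness_1 = v / (sqrt(pi) * a^1.5),
    compactness_2 = 36 * pi * v^2 / a^3,
    spherical_disproportion = a / (36 * pi * v^2)^(1 / 3),
    sphericity = (36 * pi * v^2)^(1 / 3) / a,
    asphericity = (a^3 / (36 * pi * v^2))^(1 / 3) - 1,
    centre_of_mass_shift = com_shift,
    max_3d_diameter = maxd,
    major_axis_length = 4 * sqrt(ev[1]),
    minor_axis_length = 4 * sqrt(ev[2]),
    least_axis_length = 4 * sqrt(ev[3]),
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_,
    volume_density_aabb = v / aabb_vol,
    area_density_aabb = a / aabb_area,
    tlg = tlg
  )
  if (anyNA(vals)) flags <- c(flags, "degenerate_axis_metrics")
  attr(vals, "flags") <- flags
  vals
}

# 26-connected components of a logical mask (via igraph)
mask_components <- function(m) {
  dims <- dim(m)
  ids <- which(m)
  if (length(ids) == 0) return(list(n = 0, largest = m))
  pos <- match(seq_len(prod(dims)), ids)
  lv <- array(NA_integer_, dims)
  lv[m] <- 1L
  dirs <- unique_directions3()
  e_from <- integer(0); e_to <- integer(0)
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    b <- shift_array(lv, d)
    sel <- which(!is.na(lv) & !is.na(b))
    if (length(sel)) {
      step <- d[1] + d[2] * dims[1] + d[3] * dims[1] * dims[2]
      e_from <- c(e_from, pos[sel])
      e_to <- c(e_to, pos[sel + step])
    }
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (length(e_from)) g <- igraph::add_edges(g, rbind(e_from, e_to))
  comp <- igraph::components(g)
  largest <- array(FALSE, dims)
  largest[ids[comp$membership == which.max(comp$csize)]] <- TRUE
  list(n = comp$no, largest = largest)
}

# voxels with at least one 6-neighbor outside the mask (or on the border)
boundary_voxels <- function(m) {
  inner <- m
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- shift_array(m, d)
    nb[is.na(nb)] <- FALSE
    inner <- inner & nb
  }
  m & !inner
}
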