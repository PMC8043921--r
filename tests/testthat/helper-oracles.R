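# Independent naive-enumeration oracles used to verify the vectorized
# feature implementations. Everything here is written as plain scalar loops
# straight from the definitions, deliberately sharing no code with R/.

make_vol <- function(a, spacing = c(1, 1, 1)) {
  pet_volume(array(a, dim = dim(a) %||% c(length(a), 1, 1)), spacing)
}
make_mask <- function(a, spacing = c(1, 1, 1)) {
  roi_mask(array(a, dim = dim(a) %||% c(length(a), 1, 1)), spacing)
}

# random discretized grid: dims up to 5^3, levels 1..ng, random mask
random_level_grid <- function(seed, max_dim = 5, ng = 4, p_mask = 0.85) {
  set.seed(seed)
  dims <- sample(2:max_dim, 3, replace = TRUE)
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1, 1, 1] <- TRUE
  lev <- array(NA_integer_, dims)
  lev[m] <- sample.int(ng, sum(m), replace = TRUE)
  list(levels = lev, ng = ng, dims = dims, mask = m)
}

o_moran_geary <- function(x, coords) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- 0; num_m <- 0; num_g <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    w <- 1 / d
    s0 <- s0 + w
    num_m <- num_m + w * z[i] * z[j]
    num_g <- num_g + w * (x[i] - x[j])^2
  }
  c(morans_i = (n / s0) * num_m / sum(z^2),
    gearys_c = ((n - 1) / (2 * s0)) * num_g / sum(z^2))
}

o_glcm_counts <- function(lev, ng, d) {
  dims <- dim(lev)
  C <- matrix(0, ng, ng)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
        kk < 1 || kk > dims[3]) next
    b <- lev[ii, jj, kk]
    if (is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  C
}

o_glcm_features <- function(C) {
  ng <- nrow(C)
  P <- C / sum(C)
  px <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) px[i] <- px[i] + P[i, j]
  mu_x <- 0; for (i in 1:ng) mu_x <- mu_x + i * px[i]
  var_x <- 0; for (i in 1:ng) var_x <- var_x + (i - mu_x)^2 * px[i]
  jmax <- 0; javg <- 0; jvar <- 0; jent <- 0; asm <- 0; con <- 0; dis <- 0
  id <- 0; idn <- 0; idm <- 0; idmn <- 0; iv <- 0; ac <- 0
  ct <- 0; cs <- 0; cp <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    if (p > jmax) jmax <- p
    javg <- javg + i * p
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    id <- id + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    if (i != j) iv <- iv + p / (i - j)^2
    ac <- ac + i * j * p
    ct <- ct + (i + j - 2 * mu_x)^2 * p
    cs <- cs + (i + j - 2 * mu_x)^3 * p
    cp <- cp + (i + j - 2 * mu_x)^4 * p
    if (p > 0) {
      jent <- jent - p * log2(p)
      hxy1 <- hxy1 - p * log2(px[i] * px[j])
    }
    if (px[i] * px[j] > 0) hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
  }
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    jvar <- jvar + (i - javg)^2 * p
  }
  pdm <- numeric(ng); psp <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pdm[abs(i - j) + 1] <- pdm[abs(i - j) + 1] + P[i, j]
    psp[i + j - 1] <- psp[i + j - 1] + P[i, j]
  }
  da <- 0; for (k in 0:(ng - 1)) da <- da + k * pdm[k + 1]
  dv <- 0; dent <- 0
  for (k in 0:(ng - 1)) {
    dv <- dv + (k - da)^2 * pdm[k + 1]
    if (pdm[k + 1] > 0) dent <- dent - pdm[k + 1] * log2(pdm[k + 1])
  }
  sa <- 0; for (k in 2:(2 * ng)) sa <- sa + k * psp[k - 1]
  sv <- 0; sent <- 0
  for (k in 2:(2 * ng)) {
    sv <- sv + (k - sa)^2 * psp[k - 1]
    if (psp[k - 1] > 0) sent <- sent - psp[k - 1] * log2(psp[k - 1])
  }
  hx <- 0; for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  c(joint_max = jmax, joint_average = javg, joint_variance = jvar,
    joint_entropy = jent, difference_average = da, difference_variance = dv,
    difference_entropy = dent, sum_average = sa, sum_variance = sv,
    sum_entropy = sent, angular_second_moment = asm, contrast = con,
    dissimilarity = dis, inverse_difference = id,
    inverse_difference_norm = idn, inverse_difference_moment = idm,
    inverse_difference_moment_norm = idmn, inverse_variance = iv,
    correlation = if (var_x > 0) (ac - mu_x^2) / var_x else NA_real_,
    autocorrelation = ac, cluster_tendency = ct, cluster_shade = cs,
    cluster_prominence = cp,
    information_correlation_1 = if (hx > 0) (jent - hxy1) / hx else NA_real_,
    information_correlation_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - jent)))))
}

o_glrlm <- function(lev, ng, d) {
  dims <- dim(lev)
  maxlen <- max(dims)
  R <- matrix(0, ng, maxlen)
  inb <- function(i, j, k) i >= 1 && i <= dims[1] && j >= 1 &&
    j <= dims[2] && k >= 1 && k <= dims[3]
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    # run start: predecessor out of grid, out of mask, or different level
    pi <- i - d[1]; pj <- j - d[2]; pk <- k - d[3]
    if (inb(pi, pj, pk) && !is.na(lev[pi, pj, pk]) &&
        lev[pi, pj, pk] == a) next
    len <- 1
    ci <- i + d[1]; cj <- j + d[2]; ck <- k + d[3]
    while (inb(ci, cj, ck) && !is.na(lev[ci, cj, ck]) &&
           lev[ci, cj, ck] == a) {
      len <- len + 1
      ci <- ci + d[1]; cj <- cj + d[2]; ck <- ck + d[3]
    }
    R[a, len] <- R[a, len] + 1
  }
  R
}

o_glszm <- function(lev, ng) {
  dims <- dim(lev)
  visited <- array(FALSE, dims)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    if (is.na(lev[i, j, k]) || visited[i, j, k]) next
    val <- lev[i, j, k]
    stack <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (visited[nb[1], nb[2], nb[3]]) next
        v <- lev[nb[1], nb[2], nb[3]]
        if (!is.na(v) && v == val) {
          visited[nb[1], nb[2], nb[3]] <- TRUE
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  maxs <- max(vapply(zones, `[`, 0, 2))
  S <- matrix(0, ng, maxs)
  for (z in zones) S[z[1], z[2]] <- S[z[1], z[2]] + 1
  S
}

o_rl_features <- function(R, nv, zone = FALSE) {
  ns <- sum(R)
  ng <- nrow(R); nl <- ncol(R)
  f <- numeric(16)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- R[i, j] / ns
    mu_i <- mu_i + i * p
    mu_j <- mu_j + j * p
  }
  glv <- 0; rlv <- 0; re <- 0
  for (i in 1:ng) for (j in 1:nl) {
    r <- R[i, j]; p <- r / ns
    f[1] <- f[1] + r / j^2
    f[2] <- f[2] + r * j^2
    f[3] <- f[3] + r / i^2
    f[4] <- f[4] + r * i^2
    f[5] <- f[5] + r / (i^2 * j^2)
    f[6] <- f[6] + r * i^2 / j^2
    f[7] <- f[7] + r * j^2 / i^2
    f[8] <- f[8] + r * i^2 * j^2
    glv <- glv + p * (i - mu_i)^2
    rlv <- rlv + p * (j - mu_j)^2
    if (p > 0) re <- re - p * log2(p)
  }
  f[1:8] <- f[1:8] / ns
  ri <- numeric(ng); rj <- numeric(nl)
  for (i in 1:ng) for (j in 1:nl) {
    ri[i] <- ri[i] + R[i, j]
    rj[j] <- rj[j] + R[i, j]
  }
  f[9] <- sum(ri^2) / ns
  f[10] <- sum(ri^2) / ns^2
  f[11] <- sum(rj^2) / ns
  f[12] <- sum(rj^2) / ns^2
  f[13] <- ns / nv
  f[14] <- glv
  f[15] <- rlv
  f[16] <- re
  names(f) <- rl_feature_names(zone)
  f
}

o_ngtdm <- function(lev, ng) {
  dims <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng); nvv <- 0
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    tot <- 0; cnt <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
          kk < 1 || kk > dims[3]) next
      b <- lev[ii, jj, kk]
      if (!is.na(b)) { tot <- tot + b; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    nvv <- nvv + 1
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - tot / cnt)
  }
  list(n_i = n_i, s_i = s_i, nvv = nvv)
}

o_ngtdm_features <- function(nn, ng, eps = 1e-12) {
  p_i <- nn$n_i / nn$nvv
  s_i <- nn$s_i
  pres <- which(p_i > 0)
  ngp <- length(pres)
  coar <- 1 / (eps + sum(p_i * s_i))
  if (ngp > 1) {
    contr <- 0; busy_d <- 0; cplx <- 0; stren <- 0
    for (i in pres) for (j in pres) {
      contr <- contr + p_i[i] * p_i[j] * (i - j)^2
      busy_d <- busy_d + abs(i * p_i[i] - j * p_i[j])
      cplx <- cplx + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      stren <- stren + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contr <- contr / (ngp * (ngp - 1)) * sum(s_i) / nn$nvv
    busy <- if (busy_d > 0) sum(p_i * s_i) / busy_d else NA_real_
    cplx <- cplx / nn$nvv
    stren <- if (sum(s_i) > 0) stren / sum(s_i) else 0
  } else {
    contr <- 0; busy <- NA_real_; cplx <- 0; stren <- 0
  }
  c(coarseness = coar, contrast = contr, busyness = busy,
    complexity = cplx, strength = stren)
}

o_suv_peak <- function(vol, mask, spacing, r = (3 / (4 * pi))^(1 / 3) * 10) {
  dims <- dim(vol)
  sphere_mean <- function(ci, cj, ck) {
    tot <- 0; cnt <- 0
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
      d <- sqrt(((i - ci) * spacing[1])^2 + ((j - cj) * spacing[2])^2 +
                  ((k - ck) * spacing[3])^2)
      if (d <= r) { tot <- tot + vol[i, j, k]; cnt <- cnt + 1 }
    }
    tot / cnt
  }
  best <- -Inf
  maxv <- -Inf; at_max <- -Inf
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    if (!mask[i, j, k]) next
    sm <- sphere_mean(i, j, k)
    if (sm > best) best <- sm
    if (vol[i, j, k] > maxv) { maxv <- vol[i, j, k]; at_max <- sm }
    else if (vol[i, j, k] == maxv && sm > at_max) at_max <- sm
  }
  c(peak_global = best, peak_local = at_max)
}

o_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# full-enumeration two-sided Fisher p for a 2x2 table (point-prob method)
o_fisher <- function(t) {
  rs <- rowSums(t); cs <- colSums(t); n <- sum(t)
  p_of <- function(a) {
    b <- rs[1] - a; cc <- cs[1] - a; d <- rs[2] - cc
    if (b < 0 || cc < 0 || d < 0) return(NA_real_)
    exp(lgamma(rs[1] + 1) + lgamma(rs[2] + 1) + lgamma(cs[1] + 1) +
          lgamma(cs[2] + 1) - lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) -
          lgamma(cc + 1) - lgamma(d + 1))
  }
  ps <- vapply(0:min(rs[1], cs[1]), p_of, 0)
  ps <- ps[!is.na(ps)]
  pobs <- p_of(t[1, 1])
  sum(ps[ps <= pobs * (1 + 1e-7)])
}
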