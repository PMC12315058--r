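# Independent brute-force oracles.  These deliberately take different code
# paths than the package: SVD instead of covariance eigenvectors, ordered
# quadruple loops instead of edge-centered path enumeration, acos-of-normals
# torsions instead of the signed atan2 formula, plain loops for sums.

# best-fit-plane z-spread via SVD of centered coordinates
oracle_delta_z <- function(coords) {
  X <- sweep(coords, 2, colMeans(coords))
  sv <- svd(X)
  normal <- sv$v[, 3]
  z <- as.numeric(X %*% normal)
  max(z) - min(z)
}

# distance-based bond matrix, independent of perceive_bonds
oracle_cc_bonds <- function(structure, cutoff = 1.75) {
  idx <- which(structure$elements == "C")
  n <- length(idx)
  B <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((structure$coords[idx[i], ] - structure$coords[idx[j], ])^2))
    if (d > 0.9 && d <= cutoff) B[i, j] <- TRUE
  }
  list(idx = idx, B = B)
}

# torsion deviation from the nearest planar configuration (degrees in
# [0, 90]): |sin(phi)| = sin(min(|phi|, 180 - |phi|)), and the sine is
# well-conditioned at the planar limit (unlike acos of the normal angle)
oracle_torsion_dev <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  sinphi <- sqrt(sum(cr^2)) / sqrt(sum(n1^2) * sum(n2^2))
  asin(min(1, sinphi)) * 180 / pi
}

# brute-force total dihedral deviation over all ordered quadruples
oracle_sum_dihedral <- function(structure, cutoff = 1.75) {
  bb <- oracle_cc_bonds(structure, cutoff)
  idx <- bb$idx; B <- bb$B
  n <- length(idx)
  total <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) for (c0 in seq_len(n))
    for (d in seq_len(n)) {
      if (length(unique(c(a, b, c0, d))) != 4L) next
      if (a > d) next                       # each path once
      if (!(B[a, b] && B[b, c0] && B[c0, d])) next
      total <- total + oracle_torsion_dev(structure$coords[idx[a], ],
                                          structure$coords[idx[b], ],
                                          structure$coords[idx[c0], ],
                                          structure$coords[idx[d], ])
    }
  total
}

# brute-force C-C-C angle enumeration; returns vector of angles (degrees)
oracle_ccc_angles <- function(structure, cutoff = 1.75) {
  bb <- oracle_cc_bonds(structure, cutoff)
  idx <- bb$idx; B <- bb$B
  n <- length(idx)
  out <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i >= k || j == i || j == k) next
    if (!(B[i, j] && B[j, k])) next
    v1 <- structure$coords[idx[i], ] - structure$coords[idx[j], ]
    v2 <- structure$coords[idx[k], ] - structure$coords[idx[j], ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    out <- c(out, acos(min(1, max(-1, cs))) * 180 / pi)
  }
  out
}

# plain-loop HOMA over one bond-length pool
oracle_homa_pool <- function(lengths, r_opt = 1.388, alpha = 257.7) {
  s <- 0
  for (L in lengths) s <- s + (L - r_opt)^2
  1 - alpha * s / length(lengths)
}

# per-atom pyramidalization via explicit plane distance
oracle_pyr_angle <- function(center, nb1, nb2, nb3) {
  n <- c((nb2 - nb1)[2] * (nb3 - nb1)[3] - (nb2 - nb1)[3] * (nb3 - nb1)[2],
         (nb2 - nb1)[3] * (nb3 - nb1)[1] - (nb2 - nb1)[1] * (nb3 - nb1)[3],
         (nb2 - nb1)[1] * (nb3 - nb1)[2] - (nb2 - nb1)[2] * (nb3 - nb1)[1])
  h <- abs(sum((center - nb1) * n)) / sqrt(sum(n^2))
  lm <- mean(c(sqrt(sum((center - nb1)^2)), sqrt(sum((center - nb2)^2)),
               sqrt(sum((center - nb3)^2))))
  asin(min(1, h / lm)) * 180 / pi
}

# exhaustive grid search LAD (one descriptor)
oracle_lad_grid1 <- function(x, y, a0_grid, a1_grid) {
  best <- Inf; b0 <- NA; b1 <- NA
  for (a0 in a0_grid) for (a1 in a1_grid) {
    m <- mean(abs(y - a0 - a1 * x))
    if (m < best) { best <- m; b0 <- a0; b1 <- a1 }
  }
  list(a0 = b0, a1 = b1, mad = best)
}

# exhaustive grid search LAD (two descriptors)
oracle_lad_grid2 <- function(X, y, a0_grid, a1_grid, a2_grid) {
  best <- Inf; arg <- c(NA, NA, NA)
  for (a0 in a0_grid) for (a1 in a1_grid) for (a2 in a2_grid) {
    m <- mean(abs(y - a0 - a1 * X[, 1] - a2 * X[, 2]))
    if (m < best) { best <- m; arg <- c(a0, a1, a2) }
  }
  list(coef = arg, mad = best)
}

# random proper rotation + translation
random_rigid_motion <- function(structure) {
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- stats::runif(3, -20, 20)
  pah_structure(structure$elements,
                sweep(structure$coords %*% Q, 2, shift, "+"),
                structure$comment)
}

# random atom reordering
random_permutation <- function(structure) {
  p <- sample(length(structure$elements))
  pah_structure(structure$elements[p],
                structure$coords[p, , drop = FALSE], structure$comment)
}

# random connected benzenoid cell set grown from the origin
random_benzenoid_cells <- function(n_cells) {
  cells <- matrix(c(0L, 0L), 1)
  nbrs <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1, 1, -1, -1, 1), ncol = 2,
                 byrow = TRUE)
  while (nrow(cells) < n_cells) {
    base <- cells[sample(nrow(cells), 1), ]
    cand <- base + nbrs[sample(6, 1), ]
    if (!any(cells[, 1] == cand[1] & cells[, 2] == cand[2]))
      cells <- rbind(cells, cand)
  }
  cells
}
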