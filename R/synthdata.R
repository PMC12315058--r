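# Synthetic benzenoid structures, controlled distortions, and synthetic
# descriptor/energy tables.  Everything here is generated, seeded and
# geometric -- fixtures emulate the planar-to-helical spectrum of fused
# hexagon PAHs, not equilibrated (xTB-quality) thermochemistry.

# run expr with a private RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# hexagon-lattice axial neighbor offsets
.hex_nbrs <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1, 1, -1, -1, 1),
                    ncol = 2, byrow = TRUE)

#' Build an idealized planar benzenoid
#'
#' Fuses regular hexagons on a lattice: every C-C bond has length
#' `bond_length`, every angle is 120 degrees and the skeleton is exactly
#' planar, so a perfect lattice has sum_dihedral = 0, delta_z = 0 and
#' per-ring HOMA = 1 - alpha * (bond_length - r_opt)^2.  Hydrogens are
#' placed in-plane on every two-coordinate carbon.
#'
#' @param cells either a single integer n (a linear n-ring acene) or a
#'   two-column matrix/data.frame of axial hexagon coordinates (q, r);
#'   adjacent cells (offsets (1,0), (0,1), (1,-1) and negatives) fuse.
#' @param bond_length C-C bond length, Angstrom (default 1.40).
#' @param ch_length C-H bond length, Angstrom (default 1.09).
#' @param hydrogens place hydrogens (default TRUE).
#' @return a [pah_structure] (carbons first, then hydrogens).
#' @export
make_benzenoid <- function(cells, bond_length = 1.40, ch_length = 1.09,
                           hydrogens = TRUE) {
  if (is.numeric(cells) && length(cells) == 1L) {
    stopifnot(cells >= 1)
    cells <- cbind(seq_len(cells) - 1L, 0L)
  }
  cells <- matrix(as.integer(round(as.matrix(cells))), ncol = 2)
  if (anyDuplicated(paste(cells[, 1], cells[, 2])))
    stop("duplicate cells")
  n_cells <- nrow(cells)
  # cell connectivity check
  if (n_cells > 1L) {
    key <- paste(cells[, 1], cells[, 2])
    adj <- lapply(seq_len(n_cells), function(i) {
      nb <- sweep(.hex_nbrs, 2, cells[i, ], "+")
      which(key %in% paste(nb[, 1], nb[, 2]))
    })
    comp <- .components(adj, seq_len(n_cells))
    if (comp$n > 1L) stop("disconnected cell set (", comp$n, " fragments)")
  }
  L <- bond_length
  centers <- cbind(sqrt(3) * L * (cells[, 1] + cells[, 2] / 2),
                   1.5 * L * cells[, 2])
  ang <- (90 + 60 * (0:5)) * pi / 180
  vx <- L * cos(ang); vy <- L * sin(ang)
  pts <- do.call(rbind, lapply(seq_len(n_cells), function(i)
    cbind(centers[i, 1] + vx, centers[i, 2] + vy)))
  key <- paste(round(pts[, 1], 6), round(pts[, 2], 6))
  pts <- pts[!duplicated(key), , drop = FALSE]
  nC <- nrow(pts)
  coords <- cbind(pts, 0)
  # rim hydrogens: carbons with exactly 2 carbon neighbors at distance ~L
  d <- as.matrix(stats::dist(pts))
  h_coords <- NULL
  if (hydrogens) {
    for (i in seq_len(nC)) {
      nb <- which(abs(d[i, ] - L) < 1e-6)
      if (length(nb) == 2L) {
        u1 <- (pts[nb[1], ] - pts[i, ]) / L
        u2 <- (pts[nb[2], ] - pts[i, ]) / L
        dir <- -(u1 + u2)
        dir <- dir / sqrt(sum(dir^2))
        h_coords <- rbind(h_coords, c(pts[i, ] + ch_length * dir, 0))
      }
    }
  }
  pah_structure(c(rep("C", nC), rep("H", NROW(h_coords))),
                rbind(coords, h_coords),
                sprintf("benzenoid %d cells, L = %.4f A", n_cells, L))
}

# rotation matrix about unit axis u by angle theta (radians)
.rot_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st,
           ux * uz * (1 - ct) + uy * st,
           uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),
           uy * uz * (1 - ct) - ux * st,
           uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st,
           ct + uz^2 * (1 - ct)), 3, 3, byrow = TRUE)
}

# greedy + augmenting-path perfect matching on the (bipartite) carbon
# skeleton; returns 2-column matrix of matched atom pairs
.kekule_matching <- function(cadj, carbons) {
  mate <- integer(max(carbons))
  # two-color by BFS (benzenoid skeletons are bipartite)
  color <- integer(max(carbons))
  color[carbons[1]] <- 1L
  queue <- carbons[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in cadj[[v]]) if (!color[w]) {
      color[w] <- 3L - color[v]; queue <- c(queue, w)
    }
  }
  left <- carbons[color[carbons] == 1L]
  try_augment <- function(v, visited) {
    for (w in cadj[[v]]) {
      if (visited[w]) next
      visited[w] <- TRUE
      if (mate[w] == 0L) { mate[w] <<- v; mate[v] <<- w; return(TRUE) }
      prev <- mate[w]
      mate[w] <<- v; mate[v] <<- w; mate[prev] <<- 0L
      if (try_augment(prev, visited)) return(TRUE)
      mate[prev] <<- w; mate[w] <<- prev; mate[v] <<- 0L
    }
    FALSE
  }
  for (v in left)
    if (mate[v] == 0L) try_augment(v, logical(length(mate)))
  pairs <- t(vapply(carbons[mate[carbons] > carbons], function(v)
    c(v, mate[v]), integer(2)))
  if (!is.matrix(pairs)) pairs <- matrix(pairs, ncol = 2)
  pairs
}

#' Apply a controlled distortion to a structure
#'
#' Modes:
#' \describe{
#'   \item{twist}{progressive rotation about the long (x) axis, linear in
#'     the atom's x position; total twist across the molecule equals
#'     `magnitude` degrees.  Produces helical nonplanarity.}
#'   \item{bend}{rigid rotation of one fragment about a fused C-C bond by
#'     `magnitude` degrees (`locus` selects the fused bond by index,
#'     default 1).  If cutting the bond's two atoms splits the skeleton,
#'     the smaller fragment (plus its hydrogens) rotates; otherwise the
#'     atoms beyond the bond midpoint along x do.}
#'   \item{noise}{i.i.d. Gaussian displacement of every atom with
#'     standard deviation `magnitude` Angstrom, seeded.}
#'   \item{kekule}{in-plane bond alternation of amplitude `magnitude`
#'     Angstrom.  A single hexagon is rebuilt exactly (alternating side
#'     lengths L + a / L - a, all angles 120 degrees); fused systems are
#'     approximated by contracting the bonds of a perfect (Kekule)
#'     matching, each matched atom moving a/2 along the bond.}
#' }
#' Magnitude 0 is the identity for every mode; for a fixed seed the result
#' is fully reproducible.
#'
#' @param structure a [pah_structure].
#' @param mode one of `"twist"`, `"bend"`, `"noise"`, `"kekule"`.
#' @param magnitude degrees (twist/bend) or Angstrom (noise/kekule), >= 0.
#' @param locus fused-bond index for `bend`.
#' @param seed integer RNG seed for `noise`.
#' @return the distorted [pah_structure].
#' @export
apply_distortion <- function(structure, mode, magnitude, locus = 1L,
                             seed = 1L) {
  stopifnot(inherits(structure, "pah_structure"), magnitude >= 0)
  if (magnitude == 0) return(structure)
  P <- structure$coords
  el <- structure$elements
  if (mode == "twist") {
    x <- P[, 1]
    rng <- diff(range(x))
    if (rng < 1e-12) return(structure)
    phi <- (x - min(x)) / rng * magnitude * pi / 180
    y <- P[, 2] * cos(phi) - P[, 3] * sin(phi)
    z <- P[, 2] * sin(phi) + P[, 3] * cos(phi)
    P <- cbind(x, y, z)
  } else if (mode == "bend") {
    graph <- perceive_bonds(structure)
    rings <- perceive_rings(graph)
    if (!nrow(rings$fused_bonds)) stop("bend needs a fused bond")
    if (locus < 1L || locus > nrow(rings$fused_bonds))
      stop("locus out of range: ", locus)
    bond <- rings$fused_bonds[locus, ]
    cadj <- carbon_adjacency(graph)
    # cut the two bridgehead atoms out; rotate the smaller carbon fragment
    cadj_cut <- lapply(cadj, function(nb) setdiff(nb, bond))
    rest <- setdiff(graph$carbon_indices, bond)
    comp <- .components(cadj_cut, rest)
    move <- if (comp$n >= 2L) {
      sizes <- tabulate(comp$membership[rest], comp$n)
      which(comp$membership == which.min(sizes))
    } else {
      mid_x <- mean(P[bond, 1])
      setdiff(which(el == "C" & P[, 1] > mid_x), bond)
    }
    # hydrogens ride with their carbon
    hyd <- which(el == "H")
    h_follow <- hyd[vapply(hyd, function(h)
      any(graph$adjacency[[h]] %in% move), TRUE)]
    move <- c(move, h_follow)
    R <- .rot_about(P[bond[2], ] - P[bond[1], ], magnitude * pi / 180)
    P[move, ] <- sweep(sweep(P[move, , drop = FALSE], 2, P[bond[1], ]) %*%
                         t(R), 2, P[bond[1], ], "+")
  } else if (mode == "noise") {
    disp <- .with_seed(seed,
      matrix(stats::rnorm(length(P), 0, magnitude), ncol = 3))
    P <- P + disp
  } else if (mode == "kekule") {
    graph <- perceive_bonds(structure)
    rings <- perceive_rings(graph)
    carbons <- graph$carbon_indices
    if (rings$n_rings == 1L && length(carbons) == 6L) {
      ring <- rings$rings[[1]]
      L0 <- mean(vapply(seq_len(6), function(t)
        .bond_len(P, ring[t], ring[(t %% 6) + 1L]), 0))
      lens <- rep(c(L0 + magnitude, L0 - magnitude), 3)
      dirs <- (60 * (0:5)) * pi / 180
      pos <- matrix(0, 6, 2)
      for (t in 1:5)
        pos[t + 1, ] <- pos[t, ] + lens[t] * c(cos(dirs[t]), sin(dirs[t]))
      pos <- sweep(pos, 2, colMeans(pos))
      new_ring <- cbind(pos, 0)
      shift <- new_ring - P[ring, ]
      P[ring, ] <- new_ring
      # hydrogens follow their carbon
      for (h in which(el == "H")) {
        c0 <- graph$adjacency[[h]][1]
        t <- match(c0, ring)
        if (!is.na(t)) P[h, ] <- P[h, ] + shift[t, ]
      }
    } else {
      cadj <- carbon_adjacency(graph)
      pairs <- .kekule_matching(cadj, carbons)
      shift <- matrix(0, nrow(P), 3)
      for (t in seq_len(nrow(pairs))) {
        i <- pairs[t, 1]; j <- pairs[t, 2]
        u <- (P[j, ] - P[i, ])
        u <- u / sqrt(sum(u^2))
        shift[i, ] <- shift[i, ] + u * magnitude / 2
        shift[j, ] <- shift[j, ] - u * magnitude / 2
      }
      for (h in which(el == "H"))
        shift[h, ] <- shift[graph$adjacency[[h]][1], ]
      P <- P + shift
    }
  } else stop("unknown distortion mode: ", mode)
  pah_structure(el, P, structure$comment)
}

# Laplace(0, b) deviates
.rlaplace <- function(n, b) {
  u <- stats::runif(n) - 0.5
  -b * sign(u) * log(1 - 2 * abs(u))
}

#' Generate a synthetic isomer descriptor/energy table
#'
#' Emulates the statistical shape of a large PAH isomer dataset: per
#' formula group, descriptors are drawn from seeded distributions spanning
#' the observed ranges (sum_dihedral 0-1912 degrees with a planar fraction
#' near zero, delta_z 0-8.78 Angstrom correlated with sum_dihedral so both
#' planarity classes occur, homa 0.55-0.95, theta_rmsd 0.5-6 degrees), and
#' the reference energy is exactly linear in the descriptors plus Laplace
#' noise:  e_ref = a0 + sum a_i d_i + Laplace(noise_scale).  Laplace noise
#' matches the MAD objective of the fitting module.  Optionally an
#' XTB-like energy column is added as an affine distortion of e_ref with
#' its own small Laplace noise (systematic compression + offset).
#'
#' @param n_per_formula isomers per formula group (>= 2).
#' @param formulas character vector of formula labels.
#' @param true_coefficients named vector with `intercept` and one entry
#'   per descriptor used in the linear law; defaults to the published
#'   three-descriptor equation.
#' @param noise_scale Laplace scale of the energy noise, kcal/mol.
#' @param seed integer; fixes the whole table exactly.
#' @param xtb add an `e_xtb` column (default TRUE).
#' @param planar_fraction fraction of isomers drawn in the planar regime.
#' @return data.frame with columns `id`, `formula`, `sum_dihedral`,
#'   `homa`, `theta_rmsd`, `delta_z`, `e_ref` and optionally `e_xtb`.
#' @export
synth_isomer_table <- function(n_per_formula = 50L,
                               formulas = c("C36H20", "C38H20",
                                            "C40H22", "C44H24"),
                               true_coefficients = c(intercept = 236.09,
                                                     sum_dihedral = 0.0207,
                                                     homa = -339.00,
                                                     theta_rmsd = 16.44),
                               noise_scale = 3, seed = 1L, xtb = TRUE,
                               planar_fraction = 0.08) {
  stopifnot(n_per_formula >= 2L, noise_scale >= 0,
            "intercept" %in% names(true_coefficients))
  dnames <- setdiff(names(true_coefficients), "intercept")
  .with_seed(seed, {
    rows <- lapply(formulas, function(f) {
      n <- n_per_formula
      planar <- stats::runif(n) < planar_fraction
      sum_dihedral <- ifelse(planar, stats::runif(n, 0, 30),
                             stats::runif(n, 100, 1912))
      delta_z <- ifelse(planar, stats::runif(n, 0, 0.2),
                        pmin(8.78, (sum_dihedral / 1912)^0.7 *
                               stats::runif(n, 2, 8.78)))
      df <- data.frame(
        id = paste0(f, "_", seq_len(n)),
        formula = f,
        sum_dihedral = sum_dihedral,
        homa = stats::runif(n, 0.55, 0.95),
        theta_rmsd = stats::runif(n, 0.5, 6),
        delta_z = delta_z,
        stringsAsFactors = FALSE)
      lin <- true_coefficients[["intercept"]]
      for (nm in dnames) lin <- lin + true_coefficients[[nm]] * df[[nm]]
      df$e_ref <- lin + .rlaplace(n, noise_scale)
      if (xtb)
        df$e_xtb <- -4 + 0.7 * df$e_ref + .rlaplace(n, 0.5)
      df
    })
    do.call(rbind, rows)
  })
}
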