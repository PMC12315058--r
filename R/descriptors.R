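# Geometric descriptors of PAH stability: aromaticity (HOMA family),
# bond-length/angle metrics, and nonplanarity metrics.  All descriptors are
# computed on the carbon skeleton; hydrogens only enter the pyramidalization
# neighbor planes (an sp2 carbon's three bonded atoms include its H).

.bond_len <- function(coords, i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

.ring_bond_lengths <- function(structure, ring) {
  k <- length(ring)
  vapply(seq_len(k), function(t)
    .bond_len(structure$coords, ring[t], ring[(t %% k) + 1L]), 0)
}

#' HOMA aromaticity parameters
#'
#' The harmonic-oscillator model of aromaticity scores a set of n C-C bond
#' lengths R_k against an optimal aromatic length:
#' HOMA = 1 - (alpha/n) * sum (R_k - r_opt)^2.  Values near 1 indicate
#' aromatic bond-length uniformity at r_opt; large deviations drive the
#' score down (it is unbounded below).
#'
#' @param r_opt optimal aromatic C-C bond length, Angstrom (default 1.388).
#' @param alpha normalization constant for C-C bonds, Angstrom^-2 scale
#'   (default 257.7).
#' @param variant `"all"` (mean of per-ring HOMA), `"fused"` (one evaluation
#'   over all bonds shared between rings) or `"edge"` (over perimeter bonds).
#' @return list of class `homa_params`.
#' @export
homa_params <- function(r_opt = 1.388, alpha = 257.7,
                        variant = c("all", "fused", "edge")) {
  stopifnot(r_opt > 0, alpha > 0)
  structure(list(r_opt = r_opt, alpha = alpha,
                 variant = match.arg(variant)),
            class = "homa_params")
}

# Eq. for one bond pool
.homa_pool <- function(lengths, r_opt, alpha)
  1 - alpha / length(lengths) * sum((lengths - r_opt)^2)

#' HOMA aromaticity index
#'
#' The `all` variant computes HOMA ring by ring and averages over rings
#' (equal ring weights).  The `fused`/`edge` variants evaluate the formula
#' once over the pooled set of fused (shared between >= 2 rings) or
#' perimeter (in exactly 1 ring) C-C bonds, since those bond classes do not
#' partition into rings.
#'
#' @param structure a [pah_structure].
#' @param rings a `pah_rings` from [perceive_rings()].
#' @param params a [homa_params()].
#' @return dimensionless HOMA value (<= 1).
#' @export
homa <- function(structure, rings, params = homa_params()) {
  stopifnot(inherits(rings, "pah_rings"), inherits(params, "homa_params"))
  if (params$variant == "all") {
    if (!length(rings$rings)) stop("HOMA undefined: structure has no rings")
    per_ring <- vapply(rings$rings, function(r)
      .homa_pool(.ring_bond_lengths(structure, r), params$r_opt,
                 params$alpha), 0)
    return(mean(per_ring))
  }
  pool <- if (params$variant == "fused") rings$fused_bonds
          else rings$perimeter_bonds
  if (!nrow(pool))
    stop("HOMA_", params$variant, " undefined: no ",
         if (params$variant == "fused") "fused" else "perimeter", " bonds")
  lens <- vapply(seq_len(nrow(pool)), function(b)
    .bond_len(structure$coords, pool[b, 1], pool[b, 2]), 0)
  .homa_pool(lens, params$r_opt, params$alpha)
}

#' Bond length alternation
#'
#' Per ring, the mean absolute difference of consecutive bond lengths around
#' the cycle (cyclically closed); the result is the mean over rings.  Zero
#' for perfectly uniform rings.
#'
#' @inheritParams homa
#' @return BLA in Angstrom (>= 0).
#' @export
bla <- function(structure, rings) {
  stopifnot(inherits(rings, "pah_rings"))
  if (!length(rings$rings)) stop("BLA undefined: structure has no rings")
  per_ring <- vapply(rings$rings, function(r) {
    L <- .ring_bond_lengths(structure, r)
    mean(abs(L - L[c(2:length(L), 1)]))
  }, 0)
  mean(per_ring)
}

# All C-C-C angles (degrees), one per unordered neighbor pair at each carbon
# center.  Returns list(center=, angles=).
.ccc_angles <- function(structure, graph) {
  cadj <- carbon_adjacency(graph)
  centers <- integer(0)
  angles <- numeric(0)
  pairs1 <- integer(0); pairs2 <- integer(0)
  for (c0 in graph$carbon_indices) {
    nb <- cadj[[c0]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(nb, 2)
    for (t in seq_len(ncol(cmb))) {
      v1 <- structure$coords[cmb[1, t], ] - structure$coords[c0, ]
      v2 <- structure$coords[cmb[2, t], ] - structure$coords[c0, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      angles <- c(angles, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
      centers <- c(centers, c0)
      pairs1 <- c(pairs1, cmb[1, t]); pairs2 <- c(pairs2, cmb[2, t])
    }
  }
  list(center = centers, a = pairs1, b = pairs2, angles = angles)
}

#' Bond-angle and bond-length metrics
#'
#' Enumerates every unordered C-C-C angle centered on a carbon and reports:
#' `sum_theta`, the summed absolute deviation from the ideal sp2 angle of
#' 120 degrees; `theta_rmsd`, the RMSD of the same deviations; `baa`, bond
#' angle alternation (per ring, the mean cyclic absolute difference of
#' consecutive in-ring vertex angles, averaged over rings); and `l_avg`,
#' the mean C-C bond length.
#'
#' @param structure a [pah_structure].
#' @param graph a `pah_graph` from [perceive_bonds()].
#' @param rings a `pah_rings`; needed for `baa` (NA if omitted).
#' @return named list with `sum_theta`, `theta_rmsd`, `baa` (degrees) and
#'   `l_avg` (Angstrom).
#' @export
bond_angle_metrics <- function(structure, graph, rings = NULL) {
  stopifnot(inherits(graph, "pah_graph"))
  ang <- .ccc_angles(structure, graph)
  if (!length(ang$angles)) stop("no C-C-C angles in structure")
  dev <- ang$angles - 120
  cc <- graph$elements[graph$bonds[, 1]] == "C" &
        graph$elements[graph$bonds[, 2]] == "C"
  l_avg <- mean(graph$bond_lengths[cc])
  baa_val <- NA_real_
  if (!is.null(rings) && length(rings$rings)) {
    per_ring <- vapply(rings$rings, function(r) {
      k <- length(r)
      th <- vapply(seq_len(k), function(t) {
        c0 <- r[t]
        p <- r[((t - 2L) %% k) + 1L]   # previous ring neighbor
        q <- r[(t %% k) + 1L]          # next ring neighbor
        v1 <- structure$coords[p, ] - structure$coords[c0, ]
        v2 <- structure$coords[q, ] - structure$coords[c0, ]
        acos(pmin(1, pmax(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }, 0)
      mean(abs(th - th[c(2:k, 1)]))
    }, 0)
    baa_val <- mean(per_ring)
  }
  list(sum_theta = sum(abs(dev)),
       theta_rmsd = sqrt(mean(dev^2)),
       baa = baa_val,
       l_avg = l_avg)
}

# Signed torsion angle (degrees, in (-180, 180]) of the bonded path
# a-b-c-d ("Praxeolitic" formula: robust near 0/180).
.torsion <- function(coords, a, b, c0, d) {
  b0 <- coords[a, ] - coords[b, ]
  b1 <- coords[c0, ] - coords[b, ]
  b2 <- coords[d, ] - coords[c0, ]
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

# Enumerate each distinct simple bonded 4-carbon path a-b-c-d once
# (a-b-c-d identified with d-c-b-a).  Returns 4-column matrix.
.cccc_paths <- function(graph) {
  cadj <- carbon_adjacency(graph)
  cc <- graph$bonds[graph$elements[graph$bonds[, 1]] == "C" &
                    graph$elements[graph$bonds[, 2]] == "C", , drop = FALSE]
  out <- matrix(integer(0), 0, 4)
  for (e in seq_len(nrow(cc))) {
    b <- cc[e, 1]; c0 <- cc[e, 2]     # central bond, b < c0 so each path once
    for (a in setdiff(cadj[[b]], c0))
      for (d in setdiff(cadj[[c0]], b)) {
        if (a == d) next               # 3-cycles give no proper torsion
        out <- rbind(out, c(a, b, c0, d))
      }
  }
  out
}

#' Total dihedral deviation from planarity
#'
#' Enumerates every distinct simple bonded 4-carbon path a-b-c-d and sums,
#' over paths, each torsion's angular distance to the nearest planar
#' configuration (0 degrees, cis, or 180 degrees, trans):
#' deviation = min(|phi|, 180 - |phi|).  Exactly zero for planar
#' structures; a cost-free global nonplanarity metric and the strongest
#' single predictor of PAH isomerization energy.
#'
#' @inheritParams bond_angle_metrics
#' @return sum of deviations, degrees (>= 0).
#' @export
sum_dihedral <- function(structure, graph) {
  stopifnot(inherits(graph, "pah_graph"))
  if (length(graph$carbon_indices) < 4L)
    stop("sum_dihedral undefined: fewer than 4 carbons")
  paths <- .cccc_paths(graph)
  if (!nrow(paths)) stop("sum_dihedral undefined: no bonded C-C-C-C path")
  devs <- vapply(seq_len(nrow(paths)), function(t) {
    phi <- abs(.torsion(structure$coords, paths[t, 1], paths[t, 2],
                        paths[t, 3], paths[t, 4]))
    min(phi, 180 - phi)
  }, 0)
  sum(devs)
}

#' RMSD of the pyramidalization angle
#'
#' For every carbon with exactly three bonded neighbors (C or H), the
#' pyramidalization angle is theta_pyr = asin(h / l_mean), where h is the
#' distance of the carbon from the plane of its three neighbors and l_mean
#' the mean length of its three bonds.  Planar sp2 centers give 0.  The
#' returned value is the RMSD over all qualifying carbons.
#'
#' @inheritParams bond_angle_metrics
#' @return RMSD of pyramidalization angles, degrees (>= 0).
#' @export
pyramidalization_rmsd <- function(structure, graph) {
  stopifnot(inherits(graph, "pah_graph"))
  q <- graph$carbon_indices[
    lengths(graph$adjacency[graph$carbon_indices]) == 3L]
  if (!length(q))
    stop("pyramidalization undefined: no carbon with exactly 3 bonds")
  th <- vapply(q, function(c0) {
    nb <- graph$adjacency[[c0]]
    P <- structure$coords[nb, , drop = FALSE]
    v1 <- P[2, ] - P[1, ]
    v2 <- P[3, ] - P[1, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    nlen <- sqrt(sum(nrm^2))
    if (nlen < 1e-12) return(0)        # collinear neighbors: no plane
    h <- abs(sum((structure$coords[c0, ] - P[1, ]) * nrm)) / nlen
    lm <- mean(vapply(nb, function(j) .bond_len(structure$coords, c0, j), 0))
    asin(pmin(1, h / lm)) * 180 / pi
  }, 0)
  sqrt(mean(th^2))
}

#' Maximal z-displacement from the best-fit plane
#'
#' Aligns the structure to its best-fit plane (carbons only by default) and
#' returns the spread max(z) - min(z) over the selected atoms.  Zero for
#' exactly planar molecules regardless of input orientation.
#'
#' @param structure a [pah_structure].
#' @param atom_selection passed to [align_to_plane()].
#' @return delta-z in Angstrom (>= 0).
#' @export
delta_z <- function(structure, atom_selection = c("carbons", "all")) {
  atom_selection <- match.arg(atom_selection)
  al <- align_to_plane(structure, atom_selection)
  sel <- if (atom_selection == "carbons") which(al$elements == "C")
         else seq_along(al$elements)
  z <- al$coords[sel, 3]
  max(z) - min(z)
}

#' Compute the full descriptor panel for one structure
#'
#' Chains bond perception, ring perception and every descriptor into a
#' single deterministic call.  A descriptor whose preconditions fail on the
#' given structure (e.g. HOMA_fused on a single ring with no fused bond) is
#' reported as NA rather than raising.
#'
#' @param structure a [pah_structure].
#' @param r_opt,alpha HOMA constants, see [homa_params()].
#' @param cc_cutoff,ch_cutoff bond-perception windows, see
#'   [perceive_bonds()].
#' @return A one-row `data.frame` of class `pah_descriptors` with columns
#'   `homa`, `homa_fused`, `homa_edge`, `bla`, `l_avg`, `baa`, `sum_theta`,
#'   `theta_rmsd`, `sum_dihedral`, `theta_pyr_rmsd`, `delta_z`,
#'   `n_highly_connected_rings`.
#' @export
compute_all <- function(structure, r_opt = 1.388, alpha = 257.7,
                        cc_cutoff = 1.75, ch_cutoff = 1.30) {
  graph <- perceive_bonds(structure, cc_cutoff, ch_cutoff)
  rings <- perceive_rings(graph)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  bm <- safe(bond_angle_metrics(structure, graph, rings))
  if (length(bm) == 1L && is.na(bm))
    bm <- list(sum_theta = NA_real_, theta_rmsd = NA_real_,
               baa = NA_real_, l_avg = NA_real_)
  out <- data.frame(
    homa = safe(homa(structure, rings, homa_params(r_opt, alpha, "all"))),
    homa_fused = safe(homa(structure, rings,
                           homa_params(r_opt, alpha, "fused"))),
    homa_edge = safe(homa(structure, rings,
                          homa_params(r_opt, alpha, "edge"))),
    bla = safe(bla(structure, rings)),
    l_avg = bm$l_avg,
    baa = bm$baa,
    sum_theta = bm$sum_theta,
    theta_rmsd = bm$theta_rmsd,
    sum_dihedral = safe(sum_dihedral(structure, graph)),
    theta_pyr_rmsd = safe(pyramidalization_rmsd(structure, graph)),
    delta_z = safe(delta_z(structure)),
    n_highly_connected_rings = count_highly_connected_rings(rings))
  class(out) <- c("pah_descriptors", "data.frame")
  out
}

#' Canonical descriptor column order
#'
#' Column order used by [compute_all()] and the CLI `descriptors`
#' subcommand.
#' @return character vector of column names.
#' @export
descriptor_columns <- function() {
  c("homa", "homa_fused", "homa_edge", "bla", "l_avg", "baa", "sum_theta",
    "theta_rmsd", "sum_dihedral", "theta_pyr_rmsd", "delta_z",
    "n_highly_connected_rings")
}
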