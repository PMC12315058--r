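# Structure I/O, bond/ring perception and plane alignment for PAH skeletons.

#' Create a molecular structure
#'
#' A `pah_structure` holds element symbols and Cartesian coordinates (in
#' Angstrom) for one molecule, plus the free-text comment line of its XYZ
#' source.  Atom order is preserved everywhere; all atom indices used by the
#' perception and descriptor functions refer to rows of `coords`.
#'
#' @param elements character vector of IUPAC element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param comment single string stored as the XYZ title line.
#' @return An object of class `pah_structure` with fields `elements`,
#'   `coords` and `comment`.
#' @examples
#' s <- pah_structure("C", matrix(0, 1, 3))
#' @export
pah_structure <- function(elements, coords, comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  elements <- as.character(elements)
  if (length(elements) != nrow(coords))
    stop("elements and coords disagree on atom count")
  if (length(elements) < 1L) stop("structure needs at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  bad <- setdiff(unique(elements), .iupac_symbols)
  if (length(bad))
    stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  structure(list(elements = elements, coords = coords,
                 comment = as.character(comment)[1]),
            class = "pah_structure")
}

# All current IUPAC element symbols (1..118).
.iupac_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' @export
print.pah_structure <- function(x, ...) {
  tab <- table(x$elements)
  cat("<pah_structure> ", nrow(x$coords), " atoms (",
      paste0(names(tab), tab, collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' Read structures from an XYZ file
#'
#' Parses the standard XYZ dialect: an atom-count line, a free-text comment
#' line, then one `symbol x y z` row per atom, whitespace-delimited.
#' Multi-frame files (concatenated blocks) yield one structure per frame.
#'
#' @param source path to an XYZ file, or a character vector of lines.
#' @return list of [pah_structure] objects, one per frame.
#' @seealso [write_xyz()]
#' @export
read_xyz <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) &&
               file.exists(source)) readLines(source, warn = FALSE)
           else unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  out <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }  # skip blank padding
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("XYZ parse error at line ", i, ": malformed atom count line: ",
           sQuote(lines[i]))
    if (i + 1L + n > n_lines)
      stop("XYZ parse error at line ", i, ": frame declares ", n,
           " atoms but file is truncated")
    comment <- lines[i + 1L]
    elements <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'")
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
      elements[k] <- tok[1]
      coords[k, ] <- xyz
    }
    out[[length(out) + 1L]] <- pah_structure(elements, coords, comment)
    i <- i + 2L + n
  }
  out
}

#' Write structures to an XYZ file
#'
#' Frames are concatenated; coordinates are printed with 6 decimals, so
#' `read_xyz(write_xyz(s))` reproduces `s` to 1e-6 Angstrom.
#'
#' @param structures a [pah_structure] or list of them.
#' @param target output file path or connection.
#' @return `target`, invisibly.
#' @export
write_xyz <- function(structures, target) {
  if (inherits(structures, "pah_structure")) structures <- list(structures)
  lines <- unlist(lapply(structures, function(s) {
    c(as.character(nrow(s$coords)), s$comment,
      sprintf("%-2s %14.6f %14.6f %14.6f",
              s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3]))
  }))
  writeLines(if (is.null(lines)) character(0) else lines, target)
  invisible(target)
}

#' Perceive covalent bonds by distance windows
#'
#' Bonds are assigned from interatomic distances: C-C pairs in
#' (0.9, `cc_cutoff`] Angstrom and C-H pairs in (0.7, `ch_cutoff`] Angstrom.
#' Hydrogens are never bonded to each other.  The windows suit sp2 PAH
#' skeletons; both cutoffs are configurable.  Elements other than C and H
#' are rejected.
#'
#' @param structure a [pah_structure].
#' @param cc_cutoff upper C-C bond distance, Angstrom (default 1.75).
#' @param ch_cutoff upper C-H bond distance, Angstrom (default 1.30).
#' @param sanity_check error when a carbon has fewer than 1 or more than 4
#'   bonds (default TRUE); disable to inspect pathological geometries.
#' @return A `pah_graph`: list with `n_atoms`, `bonds` (two-column matrix of
#'   atom index pairs, first < second), `bond_lengths` (Angstrom),
#'   `carbon_indices`, `elements`, and `adjacency` (per-atom neighbor lists).
#' @export
perceive_bonds <- function(structure, cc_cutoff = 1.75, ch_cutoff = 1.30,
                           sanity_check = TRUE) {
  stopifnot(inherits(structure, "pah_structure"),
            cc_cutoff > 0, ch_cutoff > 0)
  el <- structure$elements
  bad <- setdiff(unique(el), c("C", "H"))
  if (length(bad))
    stop("only C/H structures are supported; found: ",
         paste(bad, collapse = ", "))
  n <- length(el)
  d <- as.matrix(stats::dist(structure$coords))
  bonds <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  if (n >= 2L) {
    pr <- which(upper.tri(d), arr.ind = TRUE)
    dd <- d[pr]
    e1 <- el[pr[, 1]]; e2 <- el[pr[, 2]]
    is_cc <- e1 == "C" & e2 == "C" & dd > 0.9 & dd <= cc_cutoff
    is_ch <- ((e1 == "C" & e2 == "H") | (e1 == "H" & e2 == "C")) &
             dd > 0.7 & dd <= ch_cutoff
    keep <- is_cc | is_ch
    bonds <- cbind(pmin(pr[keep, 1], pr[keep, 2]),
                   pmax(pr[keep, 1], pr[keep, 2]))
    lens <- dd[keep]
    o <- order(bonds[, 1], bonds[, 2])
    bonds <- bonds[o, , drop = FALSE]
    lens <- lens[o]
  }
  adjacency <- rep(list(integer(0)), n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adjacency[[i]] <- c(adjacency[[i]], j)
    adjacency[[j]] <- c(adjacency[[j]], i)
  }
  adjacency <- lapply(adjacency, sort)
  carbons <- which(el == "C")
  deg <- lengths(adjacency)
  bad_c <- if (sanity_check)
    carbons[deg[carbons] < 1L | deg[carbons] > 4L] else integer(0)
  if (length(bad_c))
    stop("geometry sanity check failed: carbon atom(s) ",
         paste(bad_c, collapse = ", "), " have ",
         paste(deg[bad_c], collapse = ", "), " bonds (expected 1-4)")
  structure(list(n_atoms = n, bonds = bonds, bond_lengths = lens,
                 carbon_indices = carbons, elements = el,
                 adjacency = adjacency),
            class = "pah_graph")
}

# Neighbor lists restricted to the carbon skeleton.
carbon_adjacency <- function(graph) {
  is_c <- graph$elements == "C"
  lapply(seq_len(graph$n_atoms), function(i)
    if (is_c[i]) graph$adjacency[[i]][is_c[graph$adjacency[[i]]]]
    else integer(0))
}

# BFS shortest path between from and to in an adjacency list, optionally
# with one edge removed.  Returns vector of vertices or NULL.
.bfs_path <- function(adj, from, to, drop_edge = NULL) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) {
      if (!is.null(drop_edge) &&
          ((v == drop_edge[1] && w == drop_edge[2]) ||
           (v == drop_edge[2] && w == drop_edge[1]))) next
      if (!seen[w]) { seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w) }
    }
  }
  if (!seen[to]) return(NULL)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# Connected components (over vertices with at least one listed neighbor or
# in `vertices`).
.components <- function(adj, vertices) {
  comp <- integer(0)
  unvisited <- vertices
  n_comp <- 0L
  membership <- integer(max(vertices))
  while (length(unvisited)) {
    n_comp <- n_comp + 1L
    queue <- unvisited[1]
    membership[queue] <- n_comp
    unvisited <- unvisited[-1]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- intersect(adj[[v]], unvisited)
      membership[nb] <- n_comp
      unvisited <- setdiff(unvisited, nb)
      queue <- c(queue, nb)
    }
  }
  list(n = n_comp, membership = membership)
}

#' Perceive the smallest-ring basis of the carbon skeleton
#'
#' Returns a smallest-set-of-smallest-rings (SSSR) basis: for every carbon
#' skeleton edge the shortest cycle through it is found by breadth-first
#' search, candidates are sorted by size and then lexicographically by
#' sorted member indices, and a greedy GF(2)-independent subset of size
#' equal to the cycle rank (bonds - atoms + components) is kept.  For
#' benzenoid PAHs every ring is a hexagon and the basis is unambiguous.
#'
#' @param graph a `pah_graph` from [perceive_bonds()].
#' @return A `pah_rings`: list with `rings` (list of ordered atom-index
#'   cycles), `fused_bonds` and `perimeter_bonds` (two-column matrices),
#'   `ring_adjacency` (list: fused neighbors of each ring) and `n_rings`.
#' @export
perceive_rings <- function(graph) {
  stopifnot(inherits(graph, "pah_graph"))
  cadj <- carbon_adjacency(graph)
  carbons <- graph$carbon_indices
  if (!length(carbons)) stop("no carbon atoms in structure")
  comp <- .components(cadj, carbons)
  if (comp$n > 1L)
    stop("carbon skeleton is disconnected (", comp$n,
         " components); not a single PAH")
  cc <- graph$bonds[graph$elements[graph$bonds[, 1]] == "C" &
                    graph$elements[graph$bonds[, 2]] == "C", , drop = FALSE]
  rank <- nrow(cc) - length(carbons) + 1L
  rings <- list()
  if (rank > 0L) {
    cand <- list()
    for (b in seq_len(nrow(cc))) {
      p <- .bfs_path(cadj, cc[b, 1], cc[b, 2], drop_edge = cc[b, ])
      if (!is.null(p)) cand[[length(cand) + 1L]] <- p
    }
    # canonical cycle form: start at min index, step toward smaller neighbor
    canon <- lapply(cand, function(cyc) {
      k <- length(cyc)
      s <- which.min(cyc)
      fwd <- cyc[((s - 1L + seq_len(k) - 1L) %% k) + 1L]
      rev_ <- cyc[((s - 1L - (seq_len(k) - 1L)) %% k) + 1L]
      if (fwd[2] <= rev_[2]) fwd else rev_
    })
    key <- vapply(canon, function(x) paste(x, collapse = ","), "")
    canon <- canon[!duplicated(key)]
    sizes <- lengths(canon)
    sortkey <- vapply(canon, function(x)
      paste(sprintf("%06d", sort(x)), collapse = ","), "")
    canon <- canon[order(sizes, sortkey)]
    # greedy GF(2)-independent basis over edge incidence vectors
    edge_id <- function(i, j) paste(min(i, j), max(i, j))
    all_ids <- apply(cc, 1, function(r) edge_id(r[1], r[2]))
    basis <- matrix(FALSE, 0, nrow(cc))
    for (cyc in canon) {
      if (length(rings) == rank) break
      v <- rep(FALSE, nrow(cc))
      k <- length(cyc)
      for (t in seq_len(k)) {
        id <- edge_id(cyc[t], cyc[(t %% k) + 1L])
        v[match(id, all_ids)] <- TRUE
      }
      # reduce against current basis
      w <- v
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ])[1]
        if (w[piv]) w <- xor(w, basis[r, ])
      }
      if (any(w)) {
        basis <- rbind(basis, w)
        rings[[length(rings) + 1L]] <- cyc
      }
    }
    if (length(rings) != rank)
      stop("ring perception failed: found ", length(rings),
           " independent rings, cycle rank is ", rank)
  }
  # classify in-ring C-C bonds
  ring_edges <- lapply(rings, function(cyc) {
    k <- length(cyc)
    cbind(pmin(cyc, cyc[c(2:k, 1)]), pmax(cyc, cyc[c(2:k, 1)]))
  })
  counts <- new.env()
  for (re in ring_edges)
    for (t in seq_len(nrow(re))) {
      id <- paste(re[t, 1], re[t, 2])
      counts[[id]] <- (if (is.null(counts[[id]])) 0L else counts[[id]]) + 1L
    }
  fused <- matrix(integer(0), 0, 2)
  perim <- matrix(integer(0), 0, 2)
  seen <- character(0)
  for (re in ring_edges)
    for (t in seq_len(nrow(re))) {
      id <- paste(re[t, 1], re[t, 2])
      if (id %in% seen) next
      seen <- c(seen, id)
      if (counts[[id]] >= 2L) fused <- rbind(fused, re[t, ])
      else perim <- rbind(perim, re[t, ])
    }
  ring_adj <- lapply(seq_along(rings), function(i) {
    if (!length(rings)) return(integer(0))
    nb <- integer(0)
    for (j in seq_along(rings)) {
      if (j == i) next
      shared <- merge(as.data.frame(ring_edges[[i]]),
                      as.data.frame(ring_edges[[j]]))
      if (nrow(shared)) nb <- c(nb, j)
    }
    nb
  })
  structure(list(rings = rings, fused_bonds = fused, perimeter_bonds = perim,
                 ring_adjacency = ring_adj, n_rings = length(rings)),
            class = "pah_rings")
}

#' Count highly connected rings
#'
#' A ring is highly connected when three or more fused-ring connections
#' intersect at it, i.e. its fused-neighbor degree in the ring adjacency is
#' at least 3.  Such nodes mark branching / peri-condensed congestion that
#' correlates with high isomerization energy.
#'
#' @param rings a `pah_rings` from [perceive_rings()].
#' @return integer count.
#' @export
count_highly_connected_rings <- function(rings) {
  stopifnot(inherits(rings, "pah_rings"))
  sum(lengths(rings$ring_adjacency) >= 3L)
}

#' Align a structure to its best-fit plane
#'
#' Translates the structure to the centroid of the selected atoms and
#' rotates it so that the least-squares best-fit plane of the selection is
#' z = 0 (the smallest-variance principal direction becomes +z, with the
#' sign chosen so the first selected atom has z >= 0).  By default only
#' carbons define the plane, so C-H tilt does not bias it.
#'
#' @param structure a [pah_structure].
#' @param atom_selection `"carbons"` (default) or `"all"`.
#' @return the aligned [pah_structure].
#' @export
align_to_plane <- function(structure, atom_selection = c("carbons", "all")) {
  atom_selection <- match.arg(atom_selection)
  sel <- if (atom_selection == "carbons") which(structure$elements == "C")
         else seq_along(structure$elements)
  if (length(sel) < 3L) stop("need at least 3 selected atoms to fit a plane")
  P <- structure$coords[sel, , drop = FALSE]
  ctr <- colMeans(P)
  X <- sweep(structure$coords, 2, ctr)
  C <- crossprod(sweep(P, 2, ctr)) / length(sel)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1))
    stop("degenerate selection: atoms are collinear, plane undefined")
  # columns: largest-variance axis -> x, middle -> y, smallest (normal) -> z
  R <- ev$vectors[, c(1, 2, 3)]
  if (det(R) < 0) R[, 2] <- -R[, 2]
  Y <- X %*% R
  if (Y[sel[1], 3] < 0) { Y[, 2] <- -Y[, 2]; Y[, 3] <- -Y[, 3] }
  pah_structure(structure$elements, Y, structure$comment)
}

#' Export a bond graph or ring set as JSON
#'
#' Debug-friendly JSON with atom-index lists (1-based, matching R row
#' indices of the source structure).
#'
#' @param x a `pah_graph` or `pah_rings`.
#' @return a JSON string (class `json`).
#' @export
as_json <- function(x) UseMethod("as_json")

#' @export
as_json.pah_graph <- function(x) {
  jsonlite::toJSON(list(
    n_atoms = x$n_atoms,
    bonds = lapply(seq_len(nrow(x$bonds)), function(b)
      as.integer(x$bonds[b, ])),
    bond_lengths = x$bond_lengths,
    carbon_indices = as.integer(x$carbon_indices)),
    auto_unbox = TRUE, digits = NA)
}

#' @export
as_json.pah_rings <- function(x) {
  pairlist_of <- function(m) lapply(seq_len(nrow(m)), function(b)
    as.integer(m[b, ]))
  jsonlite::toJSON(list(
    rings = lapply(x$rings, as.integer),
    fused_bonds = pairlist_of(x$fused_bonds),
    perimeter_bonds = pairlist_of(x$perimeter_bonds),
    ring_adjacency = lapply(x$ring_adjacency, as.integer)),
    auto_unbox = TRUE, digits = NA)
}
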