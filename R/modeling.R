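# MAD-minimizing linear models of isomerization energy, error statistics,
# XTB correction, R_opt sensitivity scan and per-formula transferability.

#' Isomerization energies within one formula group
#'
#' Energies relative to the minimum-energy isomer of the group:
#' dE_iso = E - min(E).  At least one value is exactly zero; ties at the
#' minimum give several zeros.
#'
#' @param energies numeric vector, kcal/mol (one formula group).
#' @return numeric vector of dE_iso, kcal/mol, all >= 0.
#' @export
isomerization_energies <- function(energies) {
  if (!length(energies)) stop("empty energy group")
  if (!all(is.finite(energies))) stop("non-finite energy in group")
  energies - min(energies)
}

#' Deviation statistics of predictions against a reference
#'
#' Deviations are d = predicted - reference.  Reports the mean absolute
#' deviation (MAD), root-mean-square deviation (RMSD), mean signed
#' deviation (MSD) and maximum absolute deviation (MaxD); these always obey
#' maxd >= rmsd >= mad >= |msd|.
#'
#' @param predicted,reference numeric vectors of equal length.
#' @return list of class `pah_stats`: `mad`, `rmsd`, `msd`, `maxd`
#'   (kcal/mol) and `n`.
#' @export
error_stats <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference lengths differ (",
         length(predicted), " vs ", length(reference), ")")
  if (!length(predicted)) stop("empty vectors")
  d <- predicted - reference
  structure(list(mad = mean(abs(d)), rmsd = sqrt(mean(d^2)),
                 msd = mean(d), maxd = max(abs(d)), n = length(d)),
            class = "pah_stats")
}

#' @export
print.pah_stats <- function(x, ...) {
  cat(sprintf("MAD %.4f  RMSD %.4f  MSD %+.4f  MaxD %.4f  (n = %d)\n",
              x$mad, x$rmsd, x$msd, x$maxd, x$n))
  invisible(x)
}

# Weighted least squares start for the LAD iteration.
.wls <- function(A, y, w) {
  Aw <- A * sqrt(w)
  qr.coef(qr(Aw), y * sqrt(w))
}

# Lower weighted median: smallest x with cumulative weight >= half.
.weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

#' Least-absolute-deviation linear fit
#'
#' Fits y ~ a0 + X a by minimizing the weighted mean absolute residual
#' (the MAD), the objective used throughout for isomerization-energy
#' models.  The solver runs iteratively reweighted least squares to near
#' the optimum and then polishes to an exact vertex: an LAD optimum
#' interpolates p = ncol(X) + 1 observations, so small subsets of the
#' smallest-residual points are enumerated and the exact interpolant with
#' the lowest objective is kept, iterated to a fixed point.  Deterministic
#' for fixed input.
#'
#' @param X numeric descriptor matrix (n rows, k >= 0 columns); column
#'   names become coefficient names.
#' @param y numeric response (dE_iso, kcal/mol).
#' @param weights optional non-negative per-row weights (default uniform).
#' @return A `pah_fit`: `descriptor_names`, `coefficients` (named, one per
#'   column of X), `intercept`, `training_stats` ([error_stats()] on the
#'   fit data) and `weights_spec`.
#' @export
fit_lad <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  k <- ncol(X)
  p <- k + 1L
  if (nrow(X) != n) stop("X and y disagree on row count")
  if (n <= k) stop("need more observations than descriptors")
  if (is.null(weights)) {
    weights <- rep(1, n)
    wspec <- "uniform"
  } else {
    if (length(weights) != n || any(weights < 0) || all(weights == 0))
      stop("weights must be non-negative, not all zero, length n")
    wspec <- "user-supplied"
  }
  A <- cbind(`(intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < p) {
    drop_cols <- setdiff(seq_len(p), qrA$pivot[seq_len(qrA$rank)])
    stop("rank-deficient design: collinear column(s) ",
         paste(colnames(A)[drop_cols], collapse = ", "))
  }
  obj <- function(beta) sum(weights * abs(y - A %*% beta)) / sum(weights)

  if (k == 0L) {
    beta <- .weighted_median(y, weights)
  } else {
    beta <- .wls(A, y, weights)
    eps <- 1e-9
    for (it in seq_len(100L)) {
      r <- as.numeric(y - A %*% beta)
      w_it <- weights / pmax(abs(r), eps)
      beta_new <- tryCatch(.wls(A, y, w_it), error = function(e) beta)
      if (any(!is.finite(beta_new))) break
      if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
      beta <- beta_new
    }
    # vertex polish: enumerate exact interpolants through p of the
    # smallest-residual points
    for (round in seq_len(12L)) {
      r <- as.numeric(y - A %*% beta)
      m <- min(n, p + 9L)
      cand <- order(abs(r))[seq_len(m)]
      if (choose(m, p) > 20000) cand <- order(abs(r))[seq_len(p + 4L)]
      subsets <- utils::combn(sort(cand), p)
      best <- obj(beta)
      improved <- FALSE
      for (s in seq_len(ncol(subsets))) {
        idx <- subsets[, s]
        As <- A[idx, , drop = FALSE]
        b_try <- tryCatch(solve(As, y[idx]), error = function(e) NULL)
        if (is.null(b_try) || any(!is.finite(b_try))) next
        o_try <- obj(b_try)
        if (o_try < best - 1e-13) {
          best <- o_try; beta <- b_try; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  beta <- as.numeric(beta)
  fitted <- as.numeric(A %*% beta)
  structure(list(descriptor_names = colnames(X),
                 coefficients = stats::setNames(beta[-1], colnames(X)),
                 intercept = beta[1],
                 training_stats = error_stats(fitted, y),
                 weights_spec = wspec),
            class = "pah_fit")
}

#' @export
print.pah_fit <- function(x, ...) {
  cat("<pah_fit> dE_iso =", format(x$intercept, digits = 6))
  if (length(x$coefficients))
    cat("", paste(sprintf("%+g*%s", x$coefficients, x$descriptor_names),
                  collapse = " "))
  cat("\n  training: ")
  print(x$training_stats)
  invisible(x)
}

#' Fit a linear correction for semiempirical (XTB) energies
#'
#' Fits e_ref ~ a0 + a1 * e_xtb (both as per-formula dE_iso) so that
#' corrected energies C.XTB = a0 + a1 * e_xtb can be used directly or as a
#' descriptor column in combined models.  The default objective is LAD for
#' consistency with the energy models; ordinary least squares is available.
#'
#' @param e_xtb,e_ref paired finite energies, kcal/mol.
#' @param objective `"lad"` (default) or `"ls"`.
#' @param weights optional per-row weights (LAD only).
#' @return A `pah_fit` with descriptor `"e_xtb"` and an extra `corrected`
#'   field holding C.XTB for the training rows.
#' @export
correct_xtb <- function(e_xtb, e_ref, objective = c("lad", "ls"),
                        weights = NULL) {
  objective <- match.arg(objective)
  if (length(e_xtb) != length(e_ref)) stop("paired energies required")
  if (!all(is.finite(e_xtb)) || !all(is.finite(e_ref)))
    stop("energies must be finite")
  X <- matrix(e_xtb, ncol = 1, dimnames = list(NULL, "e_xtb"))
  if (objective == "lad") {
    fit <- fit_lad(X, e_ref, weights)
  } else {
    co <- stats::lm.fit(cbind(1, X), e_ref)$coefficients
    fitted <- co[1] + co[2] * e_xtb
    fit <- structure(list(descriptor_names = "e_xtb",
                          coefficients = c(e_xtb = unname(co[2])),
                          intercept = unname(co[1]),
                          training_stats = error_stats(fitted, e_ref),
                          weights_spec = "uniform (least squares)"),
                     class = "pah_fit")
  }
  fit$corrected <- fit$intercept + unname(fit$coefficients[1]) * e_xtb
  fit
}

#' Partition isomers into planar and nonplanar sets
#'
#' Isomers with maximal z-displacement at or below the threshold are
#' planar or nearly planar; the default 1.0 Angstrom is the boundary at
#' which PAHs are already visibly nonplanar.  The boundary value itself is
#' classified planar.
#'
#' @param table a data.frame with a `delta_z` column (Angstrom).
#' @param threshold planarity cutoff, Angstrom (default 1.0).
#' @return list with data.frames `planar` and `nonplanar` (exhaustive,
#'   disjoint).
#' @export
planarity_partition <- function(table, threshold = 1.0) {
  if (!"delta_z" %in% names(table)) stop("table has no delta_z column")
  if (any(is.na(table$delta_z))) stop("missing delta_z values")
  list(planar = table[table$delta_z <= threshold, , drop = FALSE],
       nonplanar = table[table$delta_z > threshold, , drop = FALSE])
}

#' Per-ring C-C bond lengths of a structure
#'
#' Convenience extractor used to cache the inputs of the HOMA formula so
#' an R_opt scan can recompute HOMA without re-reading structures.
#'
#' @param structure a [pah_structure].
#' @return list of numeric vectors, one per perceived ring.
#' @export
ring_bond_length_sets <- function(structure) {
  rings <- perceive_rings(perceive_bonds(structure))
  lapply(rings$rings, function(r) .ring_bond_lengths(structure, r))
}

#' HOMA from cached ring bond lengths
#'
#' @param ring_lengths list of per-ring bond-length vectors (Angstrom),
#'   as produced by [ring_bond_length_sets()].
#' @param r_opt,alpha HOMA constants.
#' @return mean per-ring HOMA.
#' @export
homa_from_lengths <- function(ring_lengths, r_opt = 1.388, alpha = 257.7) {
  if (!length(ring_lengths)) stop("no rings")
  mean(vapply(ring_lengths, .homa_pool, 0, r_opt = r_opt, alpha = alpha))
}

#' Sensitivity scan of the HOMA optimal bond length
#'
#' Recomputes the HOMA descriptor over a grid of R_opt values from cached
#' per-ring bond lengths, refits the energy model at each grid point
#' (optionally together with fixed extra descriptor columns) and records
#' the error statistics.  The grid point with the lowest MAD is reported.
#'
#' @param y response vector (dE_iso, kcal/mol).
#' @param ring_lengths list (one element per row of y) of per-ring
#'   bond-length vectors.
#' @param grid R_opt values to scan, Angstrom, each in (0, 5].
#' @param extra optional data.frame/matrix of additional descriptor
#'   columns held fixed during the scan.
#' @param alpha HOMA normalization constant.
#' @param weights optional fit weights.
#' @return data.frame with columns `r_opt`, `mad`, `rmsd`, `msd`, `maxd`;
#'   attribute `best_r_opt` holds the argmin-MAD grid point.
#' @export
ropt_scan <- function(y, ring_lengths, grid, extra = NULL, alpha = 257.7,
                      weights = NULL) {
  if (!length(grid)) stop("empty R_opt grid")
  if (any(grid <= 0 | grid > 5)) stop("R_opt grid must lie in (0, 5]")
  if (length(ring_lengths) != length(y))
    stop("ring_lengths and y disagree on row count")
  if (!is.null(extra)) extra <- as.matrix(extra)
  rows <- lapply(grid, function(r_opt) {
    h <- vapply(ring_lengths, homa_from_lengths, 0,
                r_opt = r_opt, alpha = alpha)
    X <- cbind(homa = h, extra)
    st <- fit_lad(X, y, weights)$training_stats
    data.frame(r_opt = r_opt, mad = st$mad, rmsd = st$rmsd,
               msd = st$msd, maxd = st$maxd)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_r_opt") <- out$r_opt[which.min(out$mad)]
  out
}

#' Parse a Hill-style hydrocarbon formula
#'
#' @param formula string such as `"C44H24"`.
#' @return named integer vector `c(C = ..., H = ...)`.
#' @export
parse_formula <- function(formula) {
  m <- regmatches(formula,
                  regexec("^C([0-9]+)H([0-9]+)$", as.character(formula)))[[1]]
  if (length(m) != 3L) stop("cannot parse formula: ", formula)
  c(C = as.integer(m[2]), H = as.integer(m[3]))
}

#' Is a formula in the C(16+4n)H(10+2n) series?
#'
#' The polybenzenoid series C(16+4n)H(10+2n) (pyrene and its
#' ring-extensions, e.g. C36H20, C40H22, C44H24) shows distinctly
#' transferable fitted slopes and intercepts across system sizes.
#'
#' @param formula string such as `"C40H22"`.
#' @return logical.
#' @export
in_series <- function(formula) {
  vapply(formula, function(f) {
    cn <- parse_formula(f)
    d <- cn["C"] - 16L
    d >= 0 && d %% 4L == 0L && cn["H"] == 10L + d %/% 2L
  }, TRUE, USE.NAMES = FALSE)
}

#' Pooled fit of an isomer table
#'
#' Computes dE_iso independently within each formula group (each isomer
#' relative to its own group minimum) and fits one LAD model on the chosen
#' descriptor combination.  With `train_formula` set, only that group is
#' fitted (the transferability protocol: train on a small formula, apply
#' to a larger one with [predict()]).
#'
#' @param table data.frame with columns `formula`, `e_ref` and the
#'   descriptors in `combo`.
#' @param combo character vector of descriptor column names.
#' @param train_formula optional single formula to restrict the fit to.
#' @param weights optional per-row weights (aligned with `table`).
#' @return a `pah_fit`.
#' @export
fit_isomer_table <- function(table, combo, train_formula = NULL,
                             weights = NULL) {
  missing_cols <- setdiff(c("formula", "e_ref", combo), names(table))
  if (length(missing_cols))
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "))
  de <- stats::ave(table$e_ref, table$formula,
                   FUN = isomerization_energies)
  keep <- if (is.null(train_formula)) rep(TRUE, nrow(table))
          else table$formula == train_formula
  if (!any(keep)) stop("no rows for formula ", train_formula)
  X <- as.matrix(table[keep, combo, drop = FALSE])
  fit_lad(X, de[keep], if (is.null(weights)) NULL else weights[keep])
}

#' Independent fits per chemical formula, with a series summary
#'
#' Fits the descriptor combination separately within every formula group
#' (each referenced to its own minimum-energy isomer), labels groups
#' belonging to the C(16+4n)H(10+2n) series, and summarizes how much each
#' slope and the intercept vary across the in-series fits (maximum percent
#' deviation from the series mean).
#'
#' @inheritParams fit_isomer_table
#' @param min_rows smallest group size fitted (default: descriptors + 2);
#'   smaller groups are skipped with a warning.
#' @return list with `fits` (named list of `pah_fit`), `in_series` (named
#'   logical) and `series_summary` (data.frame: term, max percent deviation
#'   across in-series formulas).
#' @export
per_formula_fit <- function(table, combo, min_rows = NULL, weights = NULL) {
  missing_cols <- setdiff(c("formula", "e_ref", combo), names(table))
  if (length(missing_cols))
    stop("table is missing column(s): ", paste(missing_cols, collapse = ", "))
  groups <- split(seq_len(nrow(table)), table$formula)
  if (length(groups) < 2L) stop("need at least 2 formula groups")
  if (is.null(min_rows)) min_rows <- length(combo) + 2L
  fits <- list()
  for (f in names(groups)) {
    idx <- groups[[f]]
    if (length(idx) < min_rows) {
      warning("formula ", f, " has only ", length(idx),
              " rows; skipped (need ", min_rows, ")")
      next
    }
    de <- isomerization_energies(table$e_ref[idx])
    X <- as.matrix(table[idx, combo, drop = FALSE])
    fits[[f]] <- fit_lad(X, de,
                         if (is.null(weights)) NULL else weights[idx])
  }
  series <- stats::setNames(in_series(names(fits)), names(fits))
  summary <- NULL
  if (sum(series) >= 2L) {
    terms <- c(combo, "(intercept)")
    vals <- sapply(fits[series], function(ft)
      c(ft$coefficients, `(intercept)` = ft$intercept))
    vals <- matrix(vals, nrow = length(terms),
                   dimnames = list(terms, names(fits)[series]))
    spread <- apply(vals, 1, function(v) {
      m <- mean(v)
      if (abs(m) < 1e-12) return(NA_real_)
      100 * max(abs(v - m)) / abs(m)
    })
    summary <- data.frame(term = terms, max_pct_deviation = unname(spread))
  }
  list(fits = fits, in_series = series, series_summary = summary)
}

#' Read an isomer table from CSV
#'
#' The native dialect uses columns `id`, `formula`, descriptor columns as
#' in [descriptor_columns()], `e_ref` and optionally `e_xtb`.  A column
#' mapping renames columns of foreign exports (such as a supplementary
#' descriptor/energy table) onto the native names.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector: names are native column
#'   names, values the column names found in the file.
#' @return data.frame.
#' @export
read_isomer_table <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    absent <- setdiff(unname(mapping), names(df))
    if (length(absent))
      stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
    for (native in names(mapping)) names(df)[names(df) == mapping[[native]]] <- native
  }
  df
}

#' Write an isomer table as CSV
#' @param table data.frame.
#' @param path output path.
#' @export
write_isomer_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit as JSON
#' @param fit a `pah_fit`.
#' @param path optional file; if NULL the JSON string is returned.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "pah_fit"))
  obj <- list(descriptor_names = as.list(fit$descriptor_names),
              coefficients = as.list(fit$coefficients),
              intercept = fit$intercept,
              training_stats = unclass(fit$training_stats),
              weights_spec = fit$weights_spec)
  if (!is.null(fit$provenance)) obj$provenance <- fit$provenance
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a fit back from JSON
#' @param path file written by [write_fit_json()].
#' @return a `pah_fit`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  fit <- structure(list(
    descriptor_names = as.character(obj$descriptor_names),
    coefficients = stats::setNames(as.numeric(obj$coefficients),
                                   names(obj$coefficients)),
    intercept = obj$intercept,
    training_stats = structure(obj$training_stats, class = "pah_stats"),
    weights_spec = obj$weights_spec), class = "pah_fit")
  if (!is.null(obj$provenance)) fit$provenance <- obj$provenance
  fit
}
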