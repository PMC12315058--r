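# Fixed published three-descriptor predictor and generic model application.

#' The published three-descriptor model
#'
#' The fixed-coefficient model
#' dE_iso = 0.0207 * sum_dihedral - 339.00 * homa + 16.44 * theta_rmsd
#'          + 236.09  (kcal/mol)
#' obtained by MAD-minimizing fitting on the C36H20 isomer subset.  Its
#' coefficients are immutable; the provenance string travels with every
#' serialized copy.
#'
#' @param bound symmetric error bound reported with predictions, kcal/mol.
#'   Default 2.48, the all-isomer training MAD of this descriptor
#'   combination.
#' @return a `pah_fit` with a `provenance` field.
#' @export
published_model <- function(bound = 2.48) {
  fitted_stats <- structure(list(mad = bound, rmsd = NA_real_,
                                 msd = NA_real_, maxd = NA_real_,
                                 n = NA_integer_),
                            class = "pah_stats")
  structure(list(
    descriptor_names = c("sum_dihedral", "homa", "theta_rmsd"),
    coefficients = c(sum_dihedral = 0.0207, homa = -339.00,
                     theta_rmsd = 16.44),
    intercept = 236.09,
    training_stats = fitted_stats,
    weights_spec = "uniform",
    provenance = "trained on the C36H20 subset"),
    class = "pah_fit")
}

#' Predict isomerization energy with the published model
#'
#' Applies the fixed published equation to one descriptor set and returns
#' the estimate together with a symmetric error bound (the model's training
#' MAD).  Negative estimates are possible for inputs outside the training
#' manifold (e.g. a perfectly aromatic planar ring); they are reported
#' as-is with a warning rather than clamped.
#'
#' @param d a `pah_descriptors` row, data.frame row, or named list/vector
#'   providing `sum_dihedral`, `homa` and `theta_rmsd`.
#' @param bound error bound to report, kcal/mol (default 2.48).
#' @return list with `estimate` and `bound` (kcal/mol) and `provenance`.
#' @export
predict_published <- function(d, bound = 2.48) {
  model <- published_model(bound)
  d <- as.list(d)
  for (nm in model$descriptor_names) {
    v <- d[[nm]]
    if (is.null(v) || is.na(v))
      stop("descriptor ", sQuote(nm), " is undefined for this input")
  }
  est <- model$intercept +
    sum(model$coefficients *
          vapply(model$descriptor_names, function(nm) as.numeric(d[[nm]]), 0))
  if (est < 0)
    warning("negative predicted dE_iso (", format(est, digits = 6),
            " kcal/mol): input lies below the training manifold")
  list(estimate = est, bound = bound, provenance = model$provenance)
}

#' Apply a fitted model to new descriptor rows
#'
#' @param object a `pah_fit`.
#' @param newdata data.frame (or named list for a single row) containing
#'   every descriptor the fit uses.
#' @param ... unused.
#' @return numeric vector of estimates, with attribute `bound` set to the
#'   fit's training MAD.
#' @export
predict.pah_fit <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing_cols <- setdiff(object$descriptor_names, names(newdata))
  if (length(missing_cols))
    stop("newdata is missing descriptor(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[, object$descriptor_names, drop = FALSE])
  if (anyNA(X)) stop("undefined (NA) descriptor value in newdata")
  est <- as.numeric(object$intercept + X %*% object$coefficients)
  if (any(est < 0))
    warning(sum(est < 0), " negative predicted dE_iso value(s); ",
            "inputs may lie below the training manifold")
  attr(est, "bound") <- object$training_stats$mad
  est
}
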