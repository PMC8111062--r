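#' Preprocessing configuration
#'
#' Parameters of the fixed chemometric pipeline
#' region -> baseline -> smooth -> normalise. Defaults are conventional for
#' serum transmission/ATR spectra: restrict to the fingerprint region
#' (1800--900 cm\eqn{^{-1}}), remove the broad background with a rubberband
#' (lower convex hull) baseline, no smoothing, and vector (unit Euclidean
#' norm) normalisation so that features are invariant to the multiplicative
#' droplet-thickness variation the simulator injects.
#'
#' @param region_lo,region_hi Wavenumber window in cm\eqn{^{-1}}
#'   (`region_lo < region_hi`).
#' @param baseline_method One of `"none"`, `"polynomial"`, `"rubberband"`.
#' @param baseline_degree Polynomial degree (polynomial method only).
#' @param smooth_window Odd Savitzky-Golay window length, or `NULL` for no
#'   smoothing.
#' @param smooth_polyorder Savitzky-Golay polynomial order,
#'   `< smooth_window`.
#' @param normalise One of `"none"`, `"vector_unit"`, `"minmax"`.
#' @return A validated list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(region_lo = 900, region_hi = 1800,
                              baseline_method = c("rubberband", "polynomial", "none"),
                              baseline_degree = 2L,
                              smooth_window = NULL,
                              smooth_polyorder = 3L,
                              normalise = c("vector_unit", "minmax", "none")) {
  baseline_method <- match.arg(baseline_method)
  normalise <- match.arg(normalise)
  if (!is.numeric(region_lo) || !is.numeric(region_hi) || region_lo >= region_hi) {
    abort("`region_lo` must be smaller than `region_hi`.",
          class = "spectriage_config_error")
  }
  if (!is.null(smooth_window)) {
    if (!is.numeric(smooth_window) || smooth_window < 3 ||
        smooth_window %% 2 != 1) {
      abort("`smooth_window` must be an odd integer >= 3.",
            class = "spectriage_config_error")
    }
    if (smooth_polyorder >= smooth_window) {
      abort("`smooth_polyorder` must be smaller than `smooth_window`.",
            class = "spectriage_config_error")
    }
  }
  structure(
    list(region_lo = region_lo, region_hi = region_hi,
         baseline_method = baseline_method,
         baseline_degree = as.integer(baseline_degree),
         smooth_window = if (is.null(smooth_window)) NULL else as.integer(smooth_window),
         smooth_polyorder = as.integer(smooth_polyorder),
         normalise = normalise),
    class = "preprocess_config"
  )
}

# ---- long <-> matrix plumbing -----------------------------------------------

# long spectra tibble -> (key, wavenumbers, matrix); errors if spectra do not
# share one common grid
.spectra_matrix <- function(spectra) {
  need <- c("patient_id", "well", "scan", "wavenumber", "absorbance")
  miss <- setdiff(need, names(spectra))
  if (length(miss) > 0) {
    abort(paste0("Spectra table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spectriage_format_error")
  }
  df <- dplyr::arrange(spectra, .data$patient_id, .data$well, .data$scan)
  key <- dplyr::distinct(df, .data$patient_id, .data$well, .data$scan)
  n <- nrow(key)
  if (nrow(df) %% n != 0) {
    abort("Spectra have differing grid lengths; one common grid is required.",
          class = "spectriage_grid_error")
  }
  m <- nrow(df) / n
  wn <- df$wavenumber[seq_len(m)]
  W <- matrix(df$wavenumber, nrow = n, ncol = m, byrow = TRUE)
  if (!all(W == matrix(wn, n, m, byrow = TRUE))) {
    abort("Spectra are on incompatible wavenumber grids.",
          class = "spectriage_grid_error")
  }
  list(key = key, wavenumbers = wn,
       A = matrix(df$absorbance, nrow = n, ncol = m, byrow = TRUE))
}

.spectra_long <- function(key, wavenumbers, A) {
  m <- length(wavenumbers)
  tibble::tibble(
    patient_id = rep(key$patient_id, each = m),
    well = rep(key$well, each = m),
    scan = rep(key$scan, each = m),
    wavenumber = rep(wavenumbers, times = nrow(key)),
    absorbance = as.vector(t(A))
  )
}

# ---- matrix workers ---------------------------------------------------------

.baseline_poly_matrix <- function(A, x, degree) {
  if (ncol(A) < degree + 2) {
    abort("Too few points for polynomial baseline of this degree.",
          class = "spectriage_input_error")
  }
  B <- cbind(1, poly(x, degree = degree))
  H <- B %*% solve(crossprod(B), t(B))
  A - A %*% H
}

# lower convex hull indices for strictly increasing x (monotone chain)
.lower_hull <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      j <- stack[top]; k <- stack[top - 1L]
      if ((x[j] - x[k]) * (y[i] - y[k]) - (y[j] - y[k]) * (x[i] - x[k]) <= 0) {
        top <- top - 1L
      } else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  stack[seq_len(top)]
}

.baseline_rubber_matrix <- function(A, x) {
  if (ncol(A) < 3) {
    abort("Rubberband baseline needs at least 3 points.",
          class = "spectriage_input_error")
  }
  ord <- order(x)
  xs <- x[ord]
  out <- A
  for (i in seq_len(nrow(A))) {
    y <- A[i, ord]
    h <- .lower_hull(xs, y)
    base <- approx(xs[h], y[h], xout = xs)$y
    out[i, ord] <- y - base
  }
  out
}

.smooth_matrix <- function(A, window, polyorder) {
  if (window %% 2 != 1 || window > ncol(A)) {
    abort("Smoothing window must be odd and no longer than the spectrum.",
          class = "spectriage_input_error")
  }
  if (polyorder >= window) {
    abort("Smoothing polynomial order must be smaller than the window.",
          class = "spectriage_input_error")
  }
  t(apply(A, 1, function(r) signal::sgolayfilt(r, p = polyorder, n = window)))
}

.normalise_matrix <- function(A, method) {
  switch(method,
    none = A,
    vector_unit = {
      nrm <- sqrt(rowSums(A^2))
      if (any(nrm == 0)) {
        abort("Cannot vector-normalise an all-zero spectrum.",
              class = "spectriage_degenerate_error")
      }
      A / nrm
    },
    minmax = {
      lo <- apply(A, 1, min)
      hi <- apply(A, 1, max)
      if (any(hi == lo)) {
        abort("Cannot min-max normalise a constant spectrum.",
              class = "spectriage_degenerate_error")
      }
      (A - lo) / (hi - lo)
    }
  )
}

# ---- tidy per-spectrum operations ------------------------------------------

#' Restrict spectra to a wavenumber window
#'
#' Keeps the grid points inside `[lo, hi]`, preserving order. Idempotent.
#'
#' @param spectra Long spectra tibble (`patient_id`, `well`, `scan`,
#'   `wavenumber`, `absorbance`).
#' @param lo,hi Window bounds in cm\eqn{^{-1}} (either order).
#' @return Long spectra tibble on the restricted grid.
#' @export
select_region <- function(spectra, lo, hi) {
  bounds <- range(c(lo, hi))
  out <- dplyr::filter(spectra, .data$wavenumber >= bounds[1],
                       .data$wavenumber <= bounds[2])
  if (nrow(out) == 0) {
    abort(sprintf("No grid points fall inside [%g, %g] cm^-1.",
                  bounds[1], bounds[2]),
          class = "spectriage_input_error")
  }
  out
}

#' Baseline-correct spectra
#'
#' `"polynomial"` subtracts the least-squares polynomial of the stated degree
#' from each spectrum; `"rubberband"` subtracts the linear interpolation of
#' each spectrum's lower convex hull, so the corrected trace is non-negative
#' up to numerical tolerance.
#'
#' @inheritParams select_region
#' @param method `"polynomial"` or `"rubberband"`.
#' @param degree Polynomial degree (polynomial method).
#' @return Long spectra tibble.
#' @export
baseline_correct <- function(spectra, method = c("rubberband", "polynomial"),
                             degree = 2L) {
  method <- match.arg(method)
  sm <- .spectra_matrix(spectra)
  A <- switch(method,
    polynomial = .baseline_poly_matrix(sm$A, sm$wavenumbers, degree),
    rubberband = .baseline_rubber_matrix(sm$A, sm$wavenumbers)
  )
  .spectra_long(sm$key, sm$wavenumbers, A)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of each spectrum. Signals that are
#' globally polynomial of degree `<= polyorder` are reproduced exactly,
#' including at the edges.
#'
#' @inheritParams select_region
#' @param window Odd window length.
#' @param polyorder Polynomial order, `< window`.
#' @return Long spectra tibble.
#' @export
smooth_spectra <- function(spectra, window, polyorder = 3L) {
  sm <- .spectra_matrix(spectra)
  .spectra_long(sm$key, sm$wavenumbers,
                .smooth_matrix(sm$A, window, polyorder))
}

#' Normalise spectra
#'
#' `"vector_unit"` scales each spectrum to unit Euclidean norm (scale-free
#' features); `"minmax"` maps each spectrum onto \[0, 1\].
#'
#' @inheritParams select_region
#' @param method `"vector_unit"` or `"minmax"`.
#' @return Long spectra tibble.
#' @export
normalise_spectra <- function(spectra, method = c("vector_unit", "minmax")) {
  method <- match.arg(method)
  sm <- .spectra_matrix(spectra)
  .spectra_long(sm$key, sm$wavenumbers, .normalise_matrix(sm$A, method))
}

#' Run the full preprocessing pipeline
#'
#' Applies, in this fixed order: region selection, baseline correction,
#' Savitzky-Golay smoothing, normalisation (each stage only if enabled in the
#' configuration), and returns one feature row per spectrum aligned to the
#' common restricted grid. The order is fixed so that normalisation is last
#' and classifier features are scale-free.
#'
#' @param spectra Long spectra tibble; all spectra must share one grid.
#' @param config A [preprocess_config()].
#' @return An `"slb_features"` tibble: key columns `patient_id`, `well`,
#'   `scan`, then one numeric column per wavenumber (column name = wavenumber
#'   value).
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 3, n_points = 40, seed = 1))
#' ft <- preprocess_pipeline(coh$spectra, preprocess_config())
#' dim(features_matrix(ft))
preprocess_pipeline <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  spectra <- select_region(spectra, config$region_lo, config$region_hi)
  sm <- .spectra_matrix(spectra)
  A <- sm$A
  if (config$baseline_method == "polynomial") {
    A <- .baseline_poly_matrix(A, sm$wavenumbers, config$baseline_degree)
  } else if (config$baseline_method == "rubberband") {
    A <- .baseline_rubber_matrix(A, sm$wavenumbers)
  }
  if (!is.null(config$smooth_window)) {
    A <- .smooth_matrix(A, config$smooth_window, config$smooth_polyorder)
  }
  if (config$normalise != "none") {
    A <- .normalise_matrix(A, config$normalise)
  }
  if (!all(is.finite(A))) {
    abort("Preprocessing produced non-finite values.",
          class = "spectriage_input_error")
  }
  out <- sm$key
  feat <- tibble::as_tibble(A, .name_repair = "minimal")
  names(feat) <- as.character(sm$wavenumbers)
  out <- dplyr::bind_cols(out, feat)
  class(out) <- c("slb_features", class(out))
  attr(out, "wavenumbers") <- sm$wavenumbers
  out
}

#' Extract the numeric feature matrix / grid from a feature table
#'
#' @param features An `"slb_features"` tibble from [preprocess_pipeline()].
#' @return `features_matrix()`: numeric matrix (spectra x wavenumbers);
#'   `features_wavenumbers()`: the numeric grid parsed from column names.
#' @export
features_matrix <- function(features) {
  key <- c("patient_id", "well", "scan")
  as.matrix(features[, setdiff(names(features), key), drop = FALSE])
}

#' @rdname features_matrix
#' @export
features_wavenumbers <- function(features) {
  key <- c("patient_id", "well", "scan")
  as.numeric(setdiff(names(features), key))
}
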