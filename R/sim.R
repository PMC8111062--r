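#' Default infrared band library for synthetic serum spectra
#'
#' Serum absorbance in the fingerprint region (1800--900 cm\eqn{^{-1}}) is
#' dominated by a handful of broad biomolecular bands. The synthetic generator
#' models a spectrum as a sum of Gaussian bands; this library supplies default
#' centres, widths and arbitrary-unit amplitudes loosely matching the amide I
#' (~1650), amide II (~1540), CH bending (~1450), carboxylate (~1400),
#' amide III / phosphate (~1240) and carbohydrate / phosphate (~1080) bands.
#'
#' The `cancer_shift` column marks the bands whose amplitude differs between
#' classes and the direction of the difference: the cancer-class amplitude is
#' `amplitude * (1 + cancer_shift * effect_size)`. The defaults perturb three
#' bands in opposite directions so that the class difference is a change of
#' spectral *shape*, which survives vector normalisation; a uniform scaling
#' would not.
#'
#' @return A tibble with columns `centre` (cm\eqn{^{-1}}), `width` (Gaussian
#'   standard deviation, cm\eqn{^{-1}}), `amplitude` (arbitrary absorbance
#'   units) and `cancer_shift` (-1, 0 or +1).
#' @export
#' @examples
#' default_band_library()
default_band_library <- function() {
  tibble::tibble(
    centre       = c(1650, 1540, 1450, 1400, 1240, 1080),
    width        = c(25, 22, 18, 18, 24, 28),
    amplitude    = c(1.00, 0.65, 0.30, 0.28, 0.22, 0.30),
    cancer_shift = c(1, -1, 0, 0, 0, 1)
  )
}

#' Configuration of the synthetic spectral cohort generator
#'
#' Bundles and validates every parameter of the generative model. Defaults
#' emulate the design of a symptomatic-referral brain-tumour cohort: 385
#' patients at prevalence 67/385, a glioblastoma-dominant tumour subtype mix,
#' three sample wells per patient with three spectrometer scans per well
#' (nine spectra per patient), and a fingerprint-region grid of 1800--900
#' cm\eqn{^{-1}} at 2 cm\eqn{^{-1}} spacing.
#'
#' The per-spectrum generative model is
#' `scale_w * bandsum(class) + offset_w + baseline_w(x) + noise`,
#' where `bandsum` is the Gaussian band mixture from `band_library` (cancer
#' amplitudes shifted by `effect_size`, see [default_band_library()]),
#' `scale_w = exp(N(0, mult_scale_sd^2))` models droplet-thickness variation,
#' `offset_w ~ N(0, well_effect_sd^2)` is a well-level offset, `baseline_w` is
#' a random polynomial of degree `baseline_order` with i.i.d.
#' `N(0, baseline_amp^2)` coefficients on the grid rescaled to \[-1, 1\], and
#' `noise` is i.i.d. `N(0, noise_additive_sd^2)` per point. Draws subscripted
#' `w` are shared by all scans of a well, so replicate spectra within a well
#' are more alike than spectra across wells.
#'
#' @param n_patients Number of patients (positive integer).
#' @param prevalence Fraction of patients with cancer, in \[0, 1\]. The cancer
#'   count is `round_half_away(n_patients * prevalence)` so configured
#'   prevalence targets are hit exactly.
#' @param subtype_mix Named numeric vector of tumour-subtype fractions among
#'   cancer patients; must sum to 1. Default mirrors a glioblastoma-dominant
#'   clinical mix (34/67 glioblastoma).
#' @param grid_start,grid_stop Wavenumber endpoints in cm\eqn{^{-1}}.
#' @param n_points Number of grid points (>= 2).
#' @param band_library Tibble of Gaussian bands; see [default_band_library()].
#' @param effect_size Dimensionless fractional amplitude shift applied to the
#'   cancer-designated bands for cancer patients. Default 0.03: small enough
#'   that class mean spectra look identical to the eye.
#' @param noise_additive_sd Scan-level white-noise SD (absorbance units).
#' @param baseline_order Degree of the random polynomial baseline.
#' @param baseline_amp SD of each baseline coefficient (absorbance units).
#' @param mult_scale_sd SD of the log multiplicative well scale.
#' @param well_effect_sd SD of the additive well offset (absorbance units).
#' @param wells_per_patient,scans_per_well Replicate structure; defaults 3 and
#'   3, i.e. nine spectra per patient.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 1)
#' cfg$n_points
sim_config <- function(n_patients = 385L,
                       prevalence = 67 / 385,
                       subtype_mix = c(
                         glioblastoma = 34, metastatic = 16, meningioma = 5,
                         `anaplastic astrocytoma` = 3,
                         `anaplastic oligodendroglioma` = 2, other = 7
                       ) / 67,
                       grid_start = 1800,
                       grid_stop = 900,
                       n_points = 451L,
                       band_library = default_band_library(),
                       effect_size = 0.03,
                       noise_additive_sd = 0.005,
                       baseline_order = 2L,
                       baseline_amp = 0.05,
                       mult_scale_sd = 0.05,
                       well_effect_sd = 0.01,
                       wells_per_patient = 3L,
                       scans_per_well = 3L,
                       seed = 1L) {
  check_config <- function(ok, msg) {
    if (!isTRUE(ok)) abort(msg, class = "spectriage_config_error")
  }
  check_config(is.numeric(n_patients) && length(n_patients) == 1 &&
                 n_patients >= 1 && n_patients == trunc(n_patients),
               "`n_patients` must be a positive integer.")
  check_config(is.numeric(prevalence) && length(prevalence) == 1 &&
                 prevalence >= 0 && prevalence <= 1,
               "`prevalence` must be a fraction in [0, 1].")
  check_config(is.numeric(subtype_mix) && length(subtype_mix) >= 1 &&
                 !is.null(names(subtype_mix)) && all(nzchar(names(subtype_mix))),
               "`subtype_mix` must be a named numeric vector.")
  check_config(all(subtype_mix >= 0 & subtype_mix <= 1),
               "`subtype_mix` fractions must lie in [0, 1].")
  check_config(abs(sum(subtype_mix) - 1) <= 1e-9,
               "`subtype_mix` fractions must sum to 1.")
  check_config(is.numeric(n_points) && length(n_points) == 1 && n_points >= 2 &&
                 n_points == trunc(n_points),
               "`n_points` must be an integer >= 2.")
  check_config(grid_start != grid_stop,
               "`grid_start` and `grid_stop` must differ.")
  check_config(is.data.frame(band_library) &&
                 all(c("centre", "width", "amplitude", "cancer_shift") %in%
                       names(band_library)) && nrow(band_library) >= 1,
               "`band_library` needs columns centre, width, amplitude, cancer_shift.")
  check_config(all(band_library$width > 0),
               "`band_library` widths must be positive.")
  for (nm in c("effect_size", "noise_additive_sd", "baseline_amp",
               "mult_scale_sd", "well_effect_sd")) {
    v <- get(nm)
    check_config(is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0,
                 paste0("`", nm, "` must be a single non-negative number."))
  }
  check_config(is.numeric(baseline_order) && length(baseline_order) == 1 &&
                 baseline_order >= 0 && baseline_order == trunc(baseline_order),
               "`baseline_order` must be a non-negative integer.")
  check_config(is.numeric(wells_per_patient) && wells_per_patient >= 1 &&
                 wells_per_patient == trunc(wells_per_patient),
               "`wells_per_patient` must be a positive integer.")
  check_config(is.numeric(scans_per_well) && scans_per_well >= 1 &&
                 scans_per_well == trunc(scans_per_well),
               "`scans_per_well` must be a positive integer.")
  check_config(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
               "`seed` must be a single integer.")

  structure(
    list(
      n_patients = as.integer(n_patients), prevalence = prevalence,
      subtype_mix = subtype_mix, grid_start = grid_start,
      grid_stop = grid_stop, n_points = as.integer(n_points),
      band_library = tibble::as_tibble(band_library),
      effect_size = effect_size, noise_additive_sd = noise_additive_sd,
      baseline_order = as.integer(baseline_order), baseline_amp = baseline_amp,
      mult_scale_sd = mult_scale_sd, well_effect_sd = well_effect_sd,
      wells_per_patient = as.integer(wells_per_patient),
      scans_per_well = as.integer(scans_per_well), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, prevalence %.4f, %d x %d spectra/patient\n",
              x$n_patients, x$prevalence, x$wells_per_patient, x$scans_per_well))
  cat(sprintf("  grid %g..%g cm^-1 (%d points), effect size %g, seed %d\n",
              x$grid_start, x$grid_stop, x$n_points, x$effect_size, x$seed))
  invisible(x)
}

#' Build a wavenumber grid
#'
#' Evenly spaced, strictly monotone grid between two wavenumbers. A decreasing
#' grid (e.g. 1800 to 900 cm\eqn{^{-1}}, the conventional FTIR display order)
#' is produced when `start > stop`.
#'
#' @param start,stop Endpoint wavenumbers in cm\eqn{^{-1}}; must differ.
#' @param n_points Number of points, >= 2.
#' @return Numeric vector of length `n_points`.
#' @export
#' @examples
#' make_grid(1800, 900, 451)[1:3]
make_grid <- function(start, stop, n_points) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 2 ||
      n_points != trunc(n_points)) {
    abort("`n_points` must be an integer >= 2.", class = "spectriage_config_error")
  }
  if (start == stop) {
    abort("`start` and `stop` must differ.", class = "spectriage_config_error")
  }
  seq(start, stop, length.out = n_points)
}

#' Noise-free class mean spectrum
#'
#' Evaluates the Gaussian band mixture on a grid: the deterministic component
#' of every simulated spectrum before well effects, baseline and noise are
#' added.
#'
#' @param wavenumbers Numeric grid (cm\eqn{^{-1}}).
#' @param band_library Band tibble as in [default_band_library()].
#' @param effect_size Fractional amplitude shift for cancer-designated bands.
#' @param cancer Logical: evaluate the cancer-class profile?
#' @return Numeric vector of absorbances, same length as `wavenumbers`.
#' @export
band_profile <- function(wavenumbers, band_library = default_band_library(),
                         effect_size = 0, cancer = FALSE) {
  amp <- band_library$amplitude
  if (cancer) amp <- amp * (1 + band_library$cancer_shift * effect_size)
  prof <- numeric(length(wavenumbers))
  for (k in seq_len(nrow(band_library))) {
    prof <- prof + amp[k] *
      exp(-((wavenumbers - band_library$centre[k])^2) /
            (2 * band_library$width[k]^2))
  }
  prof
}

# round half away from zero, so prevalence targets are hit exactly
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# one patient's spectra as a (wells*scans) x n_points matrix; consumes the
# current RNG stream in a fixed order (offsets, log-scales, baseline
# coefficients per well, then the noise matrix)
.simulate_patient_matrix <- function(cancer, config, wavenumbers) {
  m <- length(wavenumbers)
  w <- config$wells_per_patient
  s <- config$scans_per_well
  prof <- band_profile(wavenumbers, config$band_library,
                       effect_size = config$effect_size, cancer = cancer)
  x <- 2 * (wavenumbers - min(wavenumbers)) / diff(range(wavenumbers)) - 1
  basis <- outer(x, 0:config$baseline_order, `^`)

  offsets <- rnorm(w, 0, config$well_effect_sd)
  scales <- exp(rnorm(w, 0, config$mult_scale_sd))
  coefs <- matrix(rnorm(w * (config$baseline_order + 1), 0, config$baseline_amp),
                  nrow = config$baseline_order + 1)
  noise <- matrix(rnorm(w * s * m, 0, config$noise_additive_sd), nrow = w * s)

  out <- matrix(0, nrow = w * s, ncol = m)
  for (j in seq_len(w)) {
    well_trace <- scales[j] * prof + offsets[j] + drop(basis %*% coefs[, j])
    rows <- (j - 1) * s + seq_len(s)
    out[rows, ] <- matrix(well_trace, nrow = s, ncol = m, byrow = TRUE)
  }
  out + noise
}

#' Simulate the nine replicate spectra of one patient
#'
#' Draws the well-level effects (offset, multiplicative scale, polynomial
#' baseline) and scan-level noise for a single patient and returns the
#' resulting `wells_per_patient * scans_per_well` spectra in long format.
#' Randomness is taken from the current RNG state; wrap in
#' [withr::with_seed()] (or use [simulate_cohort()], which seeds itself) for
#' reproducibility.
#'
#' @param record One-row data frame with columns `patient_id` and `true_class`
#'   (`"cancer"` or `"non-cancer"`).
#' @param config A [sim_config()].
#' @return Long tibble with columns `patient_id`, `well`, `scan`,
#'   `wavenumber`, `absorbance`.
#' @export
#' @examples
#' rec <- tibble::tibble(patient_id = "P1", true_class = "non-cancer")
#' withr::with_seed(1, simulate_patient(rec, sim_config(n_points = 5)))
simulate_patient <- function(record, config) {
  stopifnot(is.data.frame(record), nrow(record) == 1,
            all(c("patient_id", "true_class") %in% names(record)))
  wn <- make_grid(config$grid_start, config$grid_stop, config$n_points)
  A <- .simulate_patient_matrix(record$true_class == "cancer", config, wn)
  key <- tidyr::expand_grid(
    patient_id = record$patient_id,
    well = seq_len(config$wells_per_patient),
    scan = seq_len(config$scans_per_well)
  )
  tibble::tibble(
    patient_id = rep(key$patient_id, each = length(wn)),
    well = rep(key$well, each = length(wn)),
    scan = rep(key$scan, each = length(wn)),
    wavenumber = rep(wn, times = nrow(key)),
    absorbance = as.vector(t(A))
  )
}

#' Simulate a full spectral cohort
#'
#' Generates the patient truth table (classes, tumour subtypes, cohort of
#' origin) and all replicate spectra under one seed. The number of cancer
#' patients is `round_half_away(n_patients * prevalence)`; subtypes are
#' apportioned among cancers by largest remainder from `subtype_mix` and then
#' shuffled. Identical configurations (including seed) give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `"slb_cohort"` with elements
#'   \describe{
#'     \item{truth}{tibble: `patient_id`, `true_class`, `subtype` (NA for
#'       non-cancer), `cohort` (1 = symptomatic referral, 2 = new diagnosis).}
#'     \item{spectra}{long tibble: `patient_id`, `well`, `scan`, `wavenumber`,
#'       `absorbance`.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 4, n_points = 20, seed = 7))
#' coh$truth
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  n_cancer <- as.integer(round_half_away(n * config$prevalence))
  wn <- make_grid(config$grid_start, config$grid_stop, config$n_points)

  withr::with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(n))
    cancer_ids <- if (n_cancer > 0) sort(sample(ids, n_cancer)) else character()
    is_cancer <- ids %in% cancer_ids

    subtype <- rep(NA_character_, n)
    if (n_cancer > 0) {
      counts <- .apportion(config$subtype_mix, n_cancer)
      subtype[is_cancer] <- sample(rep(names(counts), counts))
    }
    truth <- tibble::tibble(
      patient_id = ids,
      true_class = ifelse(is_cancer, "cancer", "non-cancer"),
      subtype = subtype,
      cohort = ifelse(is_cancer, 2L, 1L)
    )

    per_spec <- config$wells_per_patient * config$scans_per_well
    A <- matrix(0, nrow = n * per_spec, ncol = length(wn))
    for (i in seq_len(n)) {
      A[(i - 1) * per_spec + seq_len(per_spec), ] <-
        .simulate_patient_matrix(is_cancer[i], config, wn)
    }
    key <- tidyr::expand_grid(
      patient_id = ids,
      well = seq_len(config$wells_per_patient),
      scan = seq_len(config$scans_per_well)
    )
    spectra <- tibble::tibble(
      patient_id = rep(key$patient_id, each = length(wn)),
      well = rep(key$well, each = length(wn)),
      scan = rep(key$scan, each = length(wn)),
      wavenumber = rep(wn, times = nrow(key)),
      absorbance = as.vector(t(A))
    )
    structure(list(truth = truth, spectra = spectra, config = config),
              class = "slb_cohort")
  })
}

# largest-remainder apportionment of n among named fractions
.apportion <- function(fracs, n) {
  quota <- fracs * n
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- names(fracs)
  counts
}

#' @export
print.slb_cohort <- function(x, ...) {
  n_spec <- nrow(dplyr::distinct(x$spectra, .data$patient_id, .data$well, .data$scan))
  cat(sprintf("<slb_cohort> %d patients (%d cancer), %d spectra x %d points\n",
              nrow(x$truth), sum(x$truth$true_class == "cancer"),
              n_spec, dplyr::n_distinct(x$spectra$wavenumber)))
  invisible(x)
}

#' Write / read a cohort as plain CSV
#'
#' `write_cohort()` writes the long-format spectra table and the patient truth
#' table as two CSV files. `read_cohort()` reads them back, validating the
#' schema: required columns present, class tokens in
#' \{`cancer`, `non-cancer`\}, and no orphan spectra (every `patient_id` in
#' the spectra file must appear in the truth table). Violations raise a
#' `spectriage_format_error` naming the offending column or patient id.
#'
#' @param cohort An `"slb_cohort"` (or a list with `truth` and `spectra`
#'   tibbles).
#' @param spectra_path,truth_path CSV file paths.
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()`
#'   returns an `"slb_cohort"` list (without a `config` element).
#' @export
write_cohort <- function(cohort, spectra_path, truth_path) {
  stopifnot(is.list(cohort), !is.null(cohort$truth), !is.null(cohort$spectra))
  readr::write_csv(cohort$spectra, spectra_path)
  readr::write_csv(cohort$truth, truth_path)
  invisible(c(spectra = spectra_path, truth = truth_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(spectra_path, truth_path) {
  spectra <- readr::read_csv(spectra_path, show_col_types = FALSE,
                             progress = FALSE)
  truth <- readr::read_csv(truth_path, show_col_types = FALSE,
                           progress = FALSE)
  need_s <- c("patient_id", "well", "scan", "wavenumber", "absorbance")
  miss <- setdiff(need_s, names(spectra))
  if (length(miss) > 0) {
    abort(paste0("Spectra file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spectriage_format_error")
  }
  need_t <- c("patient_id", "true_class")
  miss <- setdiff(need_t, names(truth))
  if (length(miss) > 0) {
    abort(paste0("Truth table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spectriage_format_error")
  }
  bad_class <- setdiff(unique(truth$true_class), c("cancer", "non-cancer"))
  if (length(bad_class) > 0) {
    abort(paste0("Unknown class token(s) in truth table: ",
                 paste(bad_class, collapse = ", ")),
          class = "spectriage_format_error")
  }
  orphans <- setdiff(unique(spectra$patient_id), truth$patient_id)
  if (length(orphans) > 0) {
    abort(paste0("Spectra without a truth-table entry: ",
                 paste(head(orphans, 5), collapse = ", ")),
          class = "spectriage_format_error")
  }
  if (!"subtype" %in% names(truth)) truth$subtype <- NA_character_
  truth$subtype <- as.character(truth$subtype)
  structure(list(truth = tibble::as_tibble(truth),
                 spectra = tibble::as_tibble(spectra)),
            class = "slb_cohort")
}

#' Class-mean spectra plot
#'
#' Overlays the mean spectrum of each class, the standard first look at a
#' two-class spectral cohort (for realistic effect sizes the two traces are
#' nearly indistinguishable).
#'
#' @param spectra Long spectra tibble.
#' @param truth Truth tibble with `patient_id` and `true_class`.
#' @return A ggplot object.
#' @export
plot_class_means <- function(spectra, truth) {
  df <- spectra |>
    dplyr::left_join(dplyr::select(truth, "patient_id", "true_class"),
                     by = "patient_id") |>
    dplyr::group_by(.data$true_class, .data$wavenumber) |>
    dplyr::summarise(absorbance = mean(.data$absorbance), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                   colour = .data$true_class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Absorbance (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}
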