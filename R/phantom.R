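#' Configuration for the synthetic multi-modality phantom generator
#'
#' The generator emulates the data regime the weak-supervision protocol is
#' designed for: co-registered multi-modality 2-D brain slices, one irregular
#' tumor blob per patient whose contrast differs by modality (bright on some
#' channels, dark on others, as T1ce vs T1), a smooth brain-like background
#' shading field shared by all modalities, and independent Gaussian noise per
#' channel. The ground-truth mask marks exactly the tumor pixels before noise.
#'
#' @param n_patients Number of synthetic patients.
#' @param image_size Pixels per side (square slices).
#' @param n_modalities Number of channels, 2..4.
#' @param tumor_area_frac_range Min/max tumor area as a fraction of the image
#'   area; must lie within (0, 0.5).
#' @param tumor_irregularity Non-negative scalar controlling radial boundary
#'   perturbation of the tumor; 0 gives an exact ellipse.
#' @param contrast_per_modality Signed tumor-minus-background intensity offset
#'   per modality; length must equal `n_modalities`.
#' @param noise_sigma Standard deviation of the per-channel Gaussian noise.
#' @param n_slices Slices per patient; the tumor keeps its shape across a
#'   patient's slices with a small (+/-2 px) center jitter.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   phantoms.
#' @return A `phantom_config` list.
#' @examples
#' cfg <- phantom_config(n_patients = 2, seed = 7)
#' generate_phantoms(cfg)
#' @export
phantom_config <- function(n_patients = 10,
                           image_size = 64,
                           n_modalities = 2,
                           tumor_area_frac_range = c(0.02, 0.08),
                           tumor_irregularity = 1.0,
                           contrast_per_modality = NULL,
                           noise_sigma = 0.06,
                           n_slices = 3,
                           seed = 1L) {
  check_number(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_number(image_size, "image_size", lower = 16, integer = TRUE)
  if (image_size %% 16 != 0)
    abort_config("`image_size` must be divisible by 16 (four pooling levels)",
                 field = "image_size")
  check_number(n_modalities, "n_modalities", lower = 2, upper = 4,
               integer = TRUE)
  if (length(tumor_area_frac_range) != 2L ||
      any(!is.finite(tumor_area_frac_range)) ||
      tumor_area_frac_range[1] > tumor_area_frac_range[2] ||
      tumor_area_frac_range[1] <= 0 || tumor_area_frac_range[2] >= 0.5)
    abort_config("`tumor_area_frac_range` must be increasing and within (0, 0.5)",
                 field = "tumor_area_frac_range")
  check_number(tumor_irregularity, "tumor_irregularity", lower = 0)
  if (is.null(contrast_per_modality))
    contrast_per_modality <- c(0.4, -0.35, 0.35, -0.3)[seq_len(n_modalities)]
  if (length(contrast_per_modality) != n_modalities)
    abort_config("`contrast_per_modality` length must equal `n_modalities`",
                 field = "contrast_per_modality")
  if (any(contrast_per_modality == 0))
    abort_config("`contrast_per_modality` entries must be nonzero",
                 field = "contrast_per_modality")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(n_slices, "n_slices", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_patients = as.integer(n_patients),
         image_size = as.integer(image_size),
         n_modalities = as.integer(n_modalities),
         tumor_area_frac_range = as.numeric(tumor_area_frac_range),
         tumor_irregularity = as.numeric(tumor_irregularity),
         contrast_per_modality = as.numeric(contrast_per_modality),
         noise_sigma = as.numeric(noise_sigma),
         n_slices = as.integer(n_slices),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# smooth periodic radial perturbation with unit RMS, from harmonics 2..5
shape_perturbation <- function(coef) {
  force(coef)
  norm <- sqrt(sum(coef^2) / 2)
  function(theta) {
    k <- 2:5
    s <- outer(theta, k, function(t, k) cos(k * t)) %*% coef[1:4] +
      outer(theta, k, function(t, k) sin(k * t)) %*% coef[5:8]
    as.numeric(s) / norm
  }
}

# rasterize one star-convex tumor: pixel is tumor iff its elliptical radius u
# is below 1 + amp * s(theta), with theta the angle in the ellipse frame
rasterize_tumor <- function(center, a, b, phi, amp, s_fun, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- cc - center[2]
  dy <- -(rr - center[1])
  u1 <- dx * cos(phi) + dy * sin(phi)
  v1 <- -dx * sin(phi) + dy * cos(phi)
  un <- u1 / a; vn <- v1 / b
  u <- sqrt(un^2 + vn^2)
  theta <- atan2(vn, un)
  g <- pmax(1 + amp * s_fun(as.numeric(theta)), 0.3)
  (u <= matrix(g, H, W)) * 1
}

smooth_background <- function(size, coarse = 6) {
  grid <- matrix(rnorm(coarse^2, mean = 0.5, sd = 0.08), coarse, coarse)
  field <- EBImage::resize(grid, w = size, h = size, filter = "bilinear")
  pmin(pmax(field, 0.4), 0.6)
}

#' Generate synthetic multi-modality phantom patients
#'
#' @param config A [phantom_config()].
#' @return A tibble with one row per slice and columns `patient_id`, `view`
#'   (`"axial"`), `slice_index`, `image` (list of `H x W x C` arrays), `mask`
#'   (list of binary `H x W` ground-truth matrices) and `annotated` (all
#'   `FALSE`; annotation status is assigned by the training protocol).
#' @export
generate_phantoms <- function(config) {
  if (!inherits(config, "phantom_config"))
    abort_config("`config` must be a phantom_config")
  cfg <- config
  size <- cfg$image_size
  amp <- 0.15 * cfg$tumor_irregularity
  rows <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("phantom%03d", p)
    pars <- with_seed(derive_seed(cfg$seed, "tumor", p), {
      list(center = c(runif(1, 0.35, 0.65) * size, runif(1, 0.35, 0.65) * size),
           area_frac = runif(1, cfg$tumor_area_frac_range[1],
                             cfg$tumor_area_frac_range[2]),
           aspect = runif(1, 1, 2),
           phi = runif(1, -pi / 2, pi / 2),
           coef = rnorm(8),
           jitter = matrix(sample(-2:2, 2 * cfg$n_slices, replace = TRUE),
                           ncol = 2))
    })
    s_fun <- shape_perturbation(pars$coef)
    ab <- pars$area_frac * size * size / pi
    b <- sqrt(ab / pars$aspect)
    a <- pars$aspect * b
    slices <- vector("list", cfg$n_slices)
    masks <- vector("list", cfg$n_slices)
    for (s in seq_len(cfg$n_slices)) {
      ctr <- pars$center + pars$jitter[s, ]
      mask <- rasterize_tumor(ctr, a, b, pars$phi, amp, s_fun, c(size, size))
      img <- array(0, dim = c(size, size, cfg$n_modalities))
      bg <- with_seed(derive_seed(cfg$seed, "bg", p, s),
                      smooth_background(size))
      for (m in seq_len(cfg$n_modalities)) {
        ch <- bg + cfg$contrast_per_modality[m] * mask
        if (cfg$noise_sigma > 0)
          ch <- ch + with_seed(derive_seed(cfg$seed, "noise", p, s, m),
                               matrix(rnorm(size * size, 0, cfg$noise_sigma),
                                      size, size))
        img[, , m] <- ch
      }
      slices[[s]] <- img
      masks[[s]] <- mask
    }
    rows[[p]] <- tibble::tibble(
      patient_id = pid, view = "axial", slice_index = seq_len(cfg$n_slices),
      image = slices, mask = masks, annotated = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  bad <- out |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(ok = any(purrr::map_dbl(.data$mask, sum) > 0)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0)
    abort_config(sprintf("patient %s has no slice with tumor pixels",
                         bad$patient_id[1]))
  out
}

#' Write phantom patients to NIfTI volumes with a manifest
#'
#' Writes, per patient, one single-precision NIfTI volume per modality
#' (`<id>_mod<m>.nii.gz`, slices stacked along the third axis) plus the
#' ground-truth mask volume (`<id>_mask.nii.gz`), and a `manifest.csv` with
#' columns `patient_id`, `path`, `n_slices`, `n_modalities`.
#'
#' @param slices Tibble from [generate_phantoms()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
save_phantoms <- function(slices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- slices |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(function(d, key) {
      pid <- key$patient_id
      n_mod <- dim(d$image[[1]])[3]
      for (m in seq_len(n_mod)) {
        vol <- simplify2array(purrr::map(d$image, ~ .x[, , m]))
        RNifti::writeNifti(vol, file.path(dir, sprintf("%s_mod%d.nii.gz", pid, m)))
      }
      vol <- simplify2array(d$mask)
      RNifti::writeNifti(vol, file.path(dir, sprintf("%s_mask.nii.gz", pid)))
      tibble::tibble(patient_id = pid, path = sprintf("%s_mod1.nii.gz", pid),
                     n_slices = nrow(d), n_modalities = n_mod)
    }) |>
    dplyr::bind_rows()
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read phantom patients written by [save_phantoms()]
#'
#' @param dir Directory containing a phantom manifest.
#' @return A slice tibble in the [generate_phantoms()] format.
#' @export
load_phantoms <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) abort_io(sprintf("no manifest at %s", mpath))
  man <- read.csv(mpath, stringsAsFactors = FALSE)
  rows <- purrr::pmap(man, function(patient_id, path, n_slices, n_modalities) {
    mods <- purrr::map(seq_len(n_modalities), function(m) {
      f <- file.path(dir, sprintf("%s_mod%d.nii.gz", patient_id, m))
      if (!file.exists(f)) abort_io(sprintf("missing modality volume: %s", f))
      as.array(RNifti::readNifti(f))
    })
    mask <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("%s_mask.nii.gz", patient_id))))
    if (length(unique(purrr::map(mods, dim))) != 1)
      abort_io(sprintf("modalities of %s have mismatched shapes", patient_id))
    tibble::tibble(
      patient_id = patient_id, view = "axial", slice_index = seq_len(n_slices),
      image = purrr::map(seq_len(n_slices), function(s)
        array(unlist(purrr::map(mods, ~ .x[, , s])),
              dim = c(dim(mods[[1]])[1:2], n_modalities))),
      mask = purrr::map(seq_len(n_slices), ~ round(mask[, , .x])),
      annotated = FALSE)
  })
  dplyr::bind_rows(rows)
}
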