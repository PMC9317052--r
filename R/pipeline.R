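#' Load a 3-D volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return List with `data` (3-D array) and `meta` (axis order and pixel
#'   dimensions). The axis order is recorded as (sagittal, coronal, axial).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such volume: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    abort_io(sprintf("failed to read %s: %s", path,
                                     conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    abort_io(sprintf("%s is not a 3-D volume (dims: %s)", path,
                     paste(dim(arr), collapse = "x")))
  list(data = arr,
       meta = list(path = path, axes = c("sagittal", "coronal", "axial"),
                   pixdim = attr(img, "pixdim") %||% rep(1, 3)))
}

#' Merge multi-class tumor sub-region labels into a binary tumor mask
#'
#' Glioma reference annotations label sub-regions separately (necrotic and
#' non-enhancing core, peritumoral edema, enhancing tumor). For two-class
#' tumor/non-tumor segmentation every nonzero sub-region label is merged into
#' the single tumor class.
#'
#' @param multiclass_mask Integer matrix (or array) with 0 = background.
#' @return Binary mask of the same shape.
#' @examples
#' binarize_label(matrix(c(0, 1, 2, 4), 2, 2))
#' @export
binarize_label <- function(multiclass_mask) {
  if (!is.numeric(multiclass_mask))
    abort_input("`multiclass_mask` must be numeric")
  if (any(multiclass_mask < 0))
    abort_input("`multiclass_mask` must not contain negative labels")
  out <- (multiclass_mask != 0) * 1
  dim(out) <- dim(multiclass_mask)
  out
}

view_slice <- function(vol, view, i) {
  switch(view,
         sagittal = vol[i, , ],
         coronal = vol[, i, ],
         axial = vol[, , i],
         abort_input(sprintf("unknown view '%s'", view)))
}

# center slice + alternating +step/-step/+2step/... offsets, skipping
# out-of-range positions, until `count` slices are collected
slice_offsets <- function(center, n_total, count, step) {
  taken <- integer(0)
  k <- 0
  repeat {
    cand <- if (k == 0) 0 else if (k %% 2 == 1) ((k + 1) %/% 2) * step
            else -(k %/% 2) * step
    k <- k + 1
    pos <- center + cand
    if (pos >= 1 && pos <= n_total) taken <- c(taken, pos)
    if (length(taken) >= count || k > 2 * (n_total %/% max(step, 1)) + 2) break
  }
  sort(taken)
}

#' Extract 2-D training slices from a 3-D scan
#'
#' For each of the three orthogonal views the slice with the largest tumor
#' area is taken as the center slice; neighbours are added at multiples of
#' `step` alternating above/below the center until `slices_per_view` slices
#' are collected (out-of-range offsets are skipped). With the defaults
#' (`slices_per_view = 3`, `step = 5`) nine slices per scan are produced.
#'
#' @param volume 3-D array (one modality) or `H x W x D x C` 4-D array.
#' @param tumor_mask 3-D binary mask aligned with `volume`.
#' @param patient_id Identifier stored with each record.
#' @param slices_per_view Number of slices per view.
#' @param step Slice spacing between extracted neighbours.
#' @return Slice tibble (`patient_id`, `view`, `slice_index`, `image`,
#'   `mask`, `annotated`).
#' @export
extract_slices <- function(volume, tumor_mask, patient_id = "patient",
                           slices_per_view = 3, step = 5) {
  check_number(slices_per_view, "slices_per_view", lower = 1, integer = TRUE,
               config = FALSE)
  check_number(step, "step", lower = 1, integer = TRUE, config = FALSE)
  if (length(dim(volume)) == 3L) volume <- array(volume, c(dim(volume), 1L))
  if (length(dim(tumor_mask)) != 3L ||
      !all(dim(tumor_mask) == dim(volume)[1:3]))
    abort_input("`tumor_mask` must be a 3-D mask aligned with `volume`")
  if (sum(tumor_mask) == 0)
    abort_input("tumor mask is empty: no center slice definable")
  n_mod <- dim(volume)[4]
  views <- c("sagittal", "coronal", "axial")
  rows <- purrr::map(seq_along(views), function(v) {
    counts <- apply(tumor_mask, v, sum)
    center <- which.max(counts)
    idx <- slice_offsets(center, dim(tumor_mask)[v], slices_per_view, step)
    purrr::map(idx, function(i) {
      sl <- purrr::map(seq_len(n_mod),
                       ~ view_slice(volume[, , , .x], views[v], i))
      tibble::tibble(
        patient_id = patient_id, view = views[v], slice_index = as.integer(i),
        image = list(array(unlist(sl), c(dim(sl[[1]]), n_mod))),
        mask = list(view_slice(tumor_mask, views[v], i)),
        annotated = FALSE)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

eb_resize <- function(m, size, nearest = FALSE) {
  if (all(dim(m)[1:2] == size)) return(m)
  EBImage::resize(m, w = size, h = size,
                  filter = if (nearest) "none" else "bilinear")
}

#' Standardize one multi-channel slice
#'
#' Resamples the slice to a `size x size` square (bilinear) and standardizes
#' each channel to zero mean and unit variance.
#'
#' @param image `H x W x C` array (a matrix is treated as one channel).
#' @param size Target side length (default 176).
#' @return `size x size x C` array.
#' @export
normalize_slice <- function(image, size = 176) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot(length(dim(image)) == 3L)
  out <- array(0, c(size, size, dim(image)[3]))
  for (m in seq_len(dim(image)[3])) {
    ch <- eb_resize(image[, , m], size)
    s <- sd(ch)
    if (!is.finite(s) || s == 0)
      abort_input(sprintf("channel %d is constant; cannot standardize", m))
    out[, , m] <- (ch - mean(ch)) / (s * sqrt((length(ch) - 1) / length(ch)))
  }
  out
}

#' Standardize every slice of a slice tibble
#'
#' Images are resampled bilinearly and standardized per channel with
#' [normalize_slice()]; masks and trimaps are resampled with nearest-neighbour
#' interpolation so label values are preserved.
#'
#' @param slices Slice tibble.
#' @param size Target side length.
#' @return Slice tibble with transformed `image` (and `mask`/`trimap`) columns.
#' @export
normalize_slices <- function(slices, size = 176) {
  slices$image <- purrr::map(slices$image, normalize_slice, size = size)
  if ("mask" %in% names(slices))
    slices$mask <- purrr::map(slices$mask, function(m)
      if (is.null(m)) NULL else round(eb_resize(m, size, nearest = TRUE)))
  if ("trimap" %in% names(slices))
    slices$trimap <- purrr::map(slices$trimap, function(tm) {
      if (is.null(tm)) return(NULL)
      tm$labels <- round(eb_resize(tm$labels, size, nearest = TRUE))
      tm
    })
  slices
}

#' Derive ellipse-box weak labels for every slice
#'
#' Emulates the cheap annotation: an initial ellipse is fitted around each
#' slice's rough tumor localization (the mask of its largest connected tumor
#' region, dilated by `dilation`), then shrunk by `p1` and enlarged by `p2`
#' to produce the foreground/background/ignore trimap.
#'
#' @param slices Slice tibble with a `mask` column of rough localizations.
#' @param p1,p2 Trimap scale factors (defaults 0.9 and 1.2).
#' @param dilation Axis dilation of the initial ellipse (default 1.05).
#' @return The tibble with a `trimap` list-column added.
#' @export
derive_weak_labels <- function(slices, p1 = 0.9, p2 = 1.2, dilation = 1.05) {
  slices$trimap <- purrr::map(slices$mask, function(m) {
    if (is.null(m) || sum(m) < 5) return(NULL)
    lab <- EBImage::bwlabel(m)
    if (max(lab) > 1) {
      main <- which.max(tabulate(lab[lab > 0]))
      m <- (lab == main) * 1
    }
    make_trimap(initial_ellipse(m, dilation), dim(m), p1 = p1, p2 = p2)
  })
  slices
}

#' Strict patient-separated data split
#'
#' Patients (never slices) are shuffled deterministically and assigned to
#' train/validation/test so that no patient contributes to more than one
#' subset. Counts are `round(fraction * n)` for train and validation, with
#' the remainder as test.
#'
#' @param patients Character vector of patient ids (or a slice tibble with a
#'   `patient_id` column).
#' @param fractions `(train, validation, test)` fractions summing to 1, e.g.
#'   `c(0.6, 0.2, 0.2)`, or the small-dataset setting `c(0.2, 0, 0.8)`.
#' @param seed Integer seed.
#' @return A `split_spec` list with `train_patients`, `val_patients`,
#'   `test_patients` and `fractions`.
#' @examples
#' split_patients(sprintf("p%03d", 1:285), c(0.6, 0.2, 0.2), seed = 1)
#' @export
split_patients <- function(patients, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (is.data.frame(patients)) patients <- unique(patients$patient_id)
  patients <- as.character(unique(patients))
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    abort_input("`fractions` must be 3 non-negative numbers summing to 1")
  n <- length(patients)
  n_sub <- sum(fractions > 0)
  if (n < n_sub)
    abort_input(sprintf("%d patients cannot fill %d subsets", n, n_sub))
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  shuffled <- with_seed(derive_seed(seed, "split"), sample(patients))
  spec <- structure(
    list(train_patients = sort(shuffled[seq_len(n_train)]),
         val_patients = sort(shuffled[seq_len(n_val) + n_train]),
         test_patients = sort(shuffled[seq(n_train + n_val + 1,
                                           length.out = n - n_train - n_val)]),
         fractions = fractions, seed = as.integer(seed)),
    class = "split_spec")
  assert_no_leakage(spec)
  spec
}

assert_no_leakage <- function(spec) {
  sets <- list(spec$train_patients, spec$val_patients, spec$test_patients)
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov) > 0)
      abort_input(sprintf("patient leakage across subsets: %s",
                          paste(ov, collapse = ", ")))
  }
  invisible(spec)
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> train=%d  val=%d  test=%d patients\n",
              length(x$train_patients), length(x$val_patients),
              length(x$test_patients)))
  invisible(x)
}

#' @rdname split_patients
#' @param x A `split_spec`.
#' @param ... Unused.
#' @method tidy split_spec
#' @export
tidy.split_spec <- function(x, ...) {
  tibble::tibble(
    patient_id = c(x$train_patients, x$val_patients, x$test_patients),
    subset = rep(c("train", "val", "test"),
                 c(length(x$train_patients), length(x$val_patients),
                   length(x$test_patients))))
}

#' Attach subset membership to a slice tibble
#'
#' @param slices Slice tibble.
#' @param spec A [split_patients()] result.
#' @return The tibble with a `subset` column (`train`/`val`/`test`).
#' @export
apply_split <- function(slices, spec) {
  stopifnot(inherits(spec, "split_spec"))
  dplyr::left_join(slices, tidy(spec), by = "patient_id")
}

#' Mark the annotated patient subset for refinement training
#'
#' Deterministically selects `n_annotated` patients (first-k after a seeded
#' shuffle) whose slices carry full masks during round-2 training; all other
#' patients keep only their weak trimap labels.
#'
#' @param slices Slice tibble.
#' @param n_annotated Number of annotated patients.
#' @param seed Integer seed.
#' @return The tibble with `annotated` set.
#' @export
mark_annotated <- function(slices, n_annotated, seed = 1L) {
  ids <- unique(slices$patient_id)
  check_number(n_annotated, "n_annotated", lower = 0, upper = length(ids),
               integer = TRUE, config = FALSE)
  chosen <- with_seed(derive_seed(seed, "annotated"),
                      head(sample(ids), n_annotated))
  slices$annotated <- slices$patient_id %in% chosen
  slices
}

#' Randomly augment one labelled slice
#'
#' Draws a transform from the augmentation family used during training:
#' horizontal/vertical flips, rotation/shear up to 0.2 degrees, and isotropic
#' scaling in `[0.9, 1.1]`. Image channels are resampled bilinearly; masks and
#' trimap labels use nearest-neighbour resampling so their value sets are
#' preserved. Image and labels receive the identical transform.
#'
#' @param record One-row slice tibble (or a list with `image` and optionally
#'   `mask`/`trimap`).
#' @param seed Integer seed for the transform draw.
#' @return The transformed record.
#' @export
augment <- function(record, seed = 1L) {
  draw <- with_seed(seed, list(
    hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
    angle = runif(1, -0.2, 0.2) * pi / 180,
    scale = runif(1, 0.9, 1.1)))
  apply_transform(record, draw)
}

# EBImage::affine maps a point p (dim1, dim2) to p %*% M + t
affine_warp <- function(m, M, t, nearest = FALSE) {
  EBImage::affine(m, rbind(M, t), filter = if (nearest) "none" else "bilinear",
                  bg.col = 0, antialias = FALSE)
}

apply_transform <- function(record, draw) {
  warp_plane <- function(m, nearest) {
    if (draw$hflip) m <- m[, rev(seq_len(ncol(m)))]
    if (draw$vflip) m <- m[rev(seq_len(nrow(m))), ]
    if (abs(draw$angle) < 1e-12 && abs(draw$scale - 1) < 1e-12) return(m)
    ctr <- (dim(m) + 1) / 2
    M <- draw$scale * matrix(c(cos(draw$angle), sin(draw$angle),
                               -sin(draw$angle), cos(draw$angle)), 2, 2)
    t <- ctr - as.numeric(ctr %*% M)
    affine_warp(m, M, t, nearest = nearest)
  }
  tx <- function(row) {
    img <- row$image
    for (m in seq_len(dim(img)[3])) img[, , m] <- warp_plane(img[, , m], FALSE)
    row$image <- img
    if (!is.null(row$mask)) row$mask <- round(warp_plane(row$mask, TRUE))
    if (!is.null(row$trimap)) {
      tm <- row$trimap
      # out-of-frame pixels introduced by the warp are ignore, not background
      lab <- warp_plane(tm$labels + 1, TRUE)
      lab[lab == 0] <- TRIMAP_IGNORE + 1
      tm$labels <- round(lab) - 1
      row$trimap <- tm
    }
    row
  }
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    row <- as.list(record)
    row$image <- record$image[[1]]
    row$mask <- if ("mask" %in% names(record)) record$mask[[1]] else NULL
    row$trimap <- if ("trimap" %in% names(record)) record$trimap[[1]] else NULL
    out <- tx(row)
    record$image[[1]] <- out$image
    if ("mask" %in% names(record)) record$mask[[1]] <- out$mask
    if ("trimap" %in% names(record)) record$trimap[[1]] <- out$trimap
    record
  } else {
    tx(record)
  }
}
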