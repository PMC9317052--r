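#' Parametric ellipse in pixel coordinates
#'
#' Constructs the ellipse object used for weak tumor annotations. Coordinates
#' are 1-based `(row, col)` pixel centers; `orientation` is the angle of the
#' major axis measured from the column (x) axis, counter-clockwise with the
#' image displayed row 1 at top, normalised to `[-pi/2, pi/2)`.
#'
#' @param center Numeric length-2, `(row, col)` of the ellipse center.
#' @param semi_major,semi_minor Semi-axes in pixels; `semi_major >= semi_minor > 0`.
#' @param orientation Major-axis angle in radians.
#' @return An object of class `tumor_ellipse`.
#' @examples
#' e <- tumor_ellipse(c(32, 32), 20, 10, pi / 6)
#' tidy(e)
#' @export
tumor_ellipse <- function(center, semi_major, semi_minor, orientation = 0) {
  if (length(center) != 2L || !is.numeric(center) || any(!is.finite(center)))
    abort_input("`center` must be numeric (row, col)")
  check_number(semi_major, "semi_major", lower = 1e-9, config = FALSE)
  check_number(semi_minor, "semi_minor", lower = 1e-9, config = FALSE)
  if (semi_minor > semi_major + 1e-12)
    abort_input("`semi_major` must be >= `semi_minor`")
  orientation <- ((orientation + pi / 2) %% pi) - pi / 2
  structure(
    list(center = as.numeric(center), semi_major = as.numeric(semi_major),
         semi_minor = as.numeric(semi_minor), orientation = orientation),
    class = "tumor_ellipse"
  )
}

#' @export
print.tumor_ellipse <- function(x, ...) {
  cat(sprintf(
    "<tumor_ellipse> center=(%.2f, %.2f) axes=(%.2f, %.2f) theta=%.3f rad\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor, x$orientation))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tumor_ellipse
#' @param x A `tumor_ellipse`.
#' @param ... Unused.
#' @method tidy tumor_ellipse
#' @export
tidy.tumor_ellipse <- function(x, ...) {
  tibble::tibble(center_row = x$center[1], center_col = x$center[2],
                 semi_major = x$semi_major, semi_minor = x$semi_minor,
                 orientation = x$orientation)
}

#' Fit a moment-matching ellipse to a binary region
#'
#' Returns the ellipse with the same centroid and the same normalised second
#' central moments as the foreground region (the `regionprops` ellipse): the
#' semi-axes are `2 * sqrt(eigenvalues)` of the pixel covariance matrix and the
#' orientation is the principal eigenvector's angle.
#'
#' @param region_mask Binary matrix with a single connected foreground region
#'   of at least 5 pixels.
#' @return A [tumor_ellipse()].
#' @examples
#' m <- ellipse_mask(tumor_ellipse(c(40, 40), 20, 10, 0), c(80, 80))
#' fit_ellipse(m)
#' @export
fit_ellipse <- function(region_mask) {
  m <- check_mask(region_mask, "region_mask")
  n <- sum(m)
  if (n < 5) abort_input("region must contain at least 5 foreground pixels")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1)
    abort_input(sprintf("region must be a single connected component, found %d",
                        max(lab)))
  idx <- which(m == 1, arr.ind = TRUE)
  r <- idx[, 1]; cc <- idx[, 2]
  mu_r <- mean(r); mu_c <- mean(cc)
  # covariance in (x = col, y = -row) so positive angles are counter-clockwise
  x <- cc - mu_c; y <- -(r - mu_r)
  cov <- matrix(c(mean(x^2), mean(x * y), mean(x * y), mean(y^2)), 2, 2)
  eg <- eigen(cov, symmetric = TRUE)
  a <- 2 * sqrt(max(eg$values[1], 0))
  b <- 2 * sqrt(max(eg$values[2], 0))
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1])
  tumor_ellipse(c(mu_r, mu_c), max(a, 1e-6), max(b, 1e-6), theta)
}

#' Scale an ellipse about its center
#'
#' Multiplies both semi-axes by `factor`, keeping center and orientation. The
#' foreground ellipse of a trimap uses `factor = 0.9` and the background
#' ellipse `factor = 1.2`.
#'
#' @param e A [tumor_ellipse()].
#' @param factor Positive scale factor.
#' @return A [tumor_ellipse()].
#' @export
scale_ellipse <- function(e, factor) {
  stopifnot(inherits(e, "tumor_ellipse"))
  check_number(factor, "factor", config = FALSE)
  if (factor <= 0) abort_input("`factor` must be > 0")
  tumor_ellipse(e$center, e$semi_major * factor, e$semi_minor * factor,
                e$orientation)
}

# signed elliptical radius of every pixel center: <= 1 is inside
ellipse_radius_map <- function(e, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dx <- cc - e$center[2]
  dy <- -(rr - e$center[1])
  u <- dx * cos(e$orientation) + dy * sin(e$orientation)
  v <- -dx * sin(e$orientation) + dy * cos(e$orientation)
  sqrt((u / e$semi_major)^2 + (v / e$semi_minor)^2)
}

#' Rasterize an ellipse interior
#'
#' A pixel belongs to the interior iff its center satisfies the ellipse
#' inequality (closed interior), which makes rasterization deterministic and
#' resolution independent.
#'
#' @param e A [tumor_ellipse()].
#' @param image_shape Integer `(H, W)`.
#' @return Binary `H x W` matrix.
#' @export
ellipse_mask <- function(e, image_shape) {
  stopifnot(inherits(e, "tumor_ellipse"))
  (ellipse_radius_map(e, image_shape) <= 1) * 1
}

#' Trimap label codes
#'
#' Pixel label values used in trimaps: background 0, foreground 1, ignore 2.
#' @export
TRIMAP_BG <- 0
#' @rdname TRIMAP_BG
#' @export
TRIMAP_FG <- 1
#' @rdname TRIMAP_BG
#' @export
TRIMAP_IGNORE <- 2

#' Build a foreground/background/ignore trimap from an initial ellipse
#'
#' Shrinks the initial ellipse by `p1` to obtain the foreground region (high
#' probability of tumor) and enlarges it by `p2` to obtain the background
#' boundary (its exterior has high probability of normal tissue). Pixels in
#' the annulus between the two ellipses are labelled ignore and excluded from
#' the coarse-training loss, since their class is genuinely uncertain.
#'
#' @param initial A [tumor_ellipse()] drawn around the tumor; its center must
#'   lie inside the image.
#' @param image_shape Integer `(H, W)`.
#' @param p1 Shrink factor for the foreground ellipse (default 0.9).
#' @param p2 Enlargement factor for the background ellipse (default 1.2);
#'   must exceed `p1`.
#' @return An object of class `trimap` with fields `labels` (H x W matrix of
#'   0/1/2), `small_ellipse`, `large_ellipse`, `p1`, `p2`.
#' @examples
#' tm <- make_trimap(tumor_ellipse(c(32, 32), 12, 8), c(64, 64))
#' table(tm$labels)
#' @export
make_trimap <- function(initial, image_shape, p1 = 0.9, p2 = 1.2) {
  stopifnot(inherits(initial, "tumor_ellipse"))
  check_number(p1, "p1", lower = 1e-9, config = FALSE)
  check_number(p2, "p2", lower = 1e-9, config = FALSE)
  if (p1 >= p2)
    abort_input("`p1` must be < `p2` (the ignore annulus would be empty or inverted)")
  H <- image_shape[1]; W <- image_shape[2]
  if (initial$center[1] < 1 || initial$center[1] > H ||
      initial$center[2] < 1 || initial$center[2] > W)
    abort_input("initial ellipse center must lie inside the image")
  small <- scale_ellipse(initial, p1)
  large <- scale_ellipse(initial, p2)
  u <- ellipse_radius_map(initial, image_shape)
  labels <- matrix(TRIMAP_IGNORE, H, W)
  labels[u <= p1] <- TRIMAP_FG
  labels[u > p2] <- TRIMAP_BG
  structure(list(labels = labels, small_ellipse = small, large_ellipse = large,
                 p1 = p1, p2 = p2),
            class = "trimap")
}

#' @export
print.trimap <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(TRIMAP_BG, TRIMAP_FG, TRIMAP_IGNORE),
                      labels = c("BG", "FG", "IGNORE")))
  cat(sprintf("<trimap> %dx%d  FG=%d  BG=%d  IGNORE=%d  (p1=%.2f, p2=%.2f)\n",
              nrow(x$labels), ncol(x$labels), tab[["FG"]], tab[["BG"]],
              tab[["IGNORE"]], x$p1, x$p2))
  invisible(x)
}

#' Initial ellipse surrounding a rough tumor localization
#'
#' Emulates the manual draw of an ellipse around (not through) a tumor: fits
#' the moment-matching ellipse to the region and dilates its axes slightly so
#' the ellipse surrounds the region before the `p1`/`p2` scaling is applied.
#'
#' @param region_mask Binary localization mask.
#' @param dilation Axis dilation applied to the fitted ellipse (default 1.05).
#' @return A [tumor_ellipse()].
#' @export
initial_ellipse <- function(region_mask, dilation = 1.05) {
  scale_ellipse(fit_ellipse(region_mask), dilation)
}

#' Quantify how well a trimap's weak labels agree with the true mask
#'
#' @param trimap A [make_trimap()] result.
#' @param truth_mask Binary ground-truth tumor mask of the same shape.
#' @return One-row tibble with `fg_purity` (fraction of foreground-labelled
#'   pixels that are true tumor), `bg_purity` (fraction of background-labelled
#'   pixels that are true non-tumor) and `tumor_coverage` (fraction of tumor
#'   pixels labelled foreground).
#' @export
trimap_quality <- function(trimap, truth_mask) {
  stopifnot(inherits(trimap, "trimap"))
  truth <- check_mask(truth_mask, "truth_mask")
  if (!all(dim(truth) == dim(trimap$labels)))
    abort_input("trimap and truth mask shapes differ")
  fg <- trimap$labels == TRIMAP_FG
  bg <- trimap$labels == TRIMAP_BG
  if (!any(fg) || !any(bg))
    abort_metric("trimap has an empty FG or BG region; purity is undefined")
  n_tumor <- sum(truth)
  tibble::tibble(
    fg_purity = sum(truth[fg]) / sum(fg),
    bg_purity = sum(1 - truth[bg]) / sum(bg),
    tumor_coverage = if (n_tumor > 0) sum(truth[fg]) / n_tumor else NA_real_
  )
}

#' Write / read a trimap as a PNG with a JSON parameter sidecar
#'
#' Labels are stored as 8-bit gray values 0/1/2; ellipse parameters, `p1` and
#' `p2` go to `<path>.json`.
#'
#' @param trimap A trimap object.
#' @param path Output PNG path.
#' @return `path`, invisibly (`read_trimap` returns the trimap).
#' @export
write_trimap <- function(trimap, path) {
  stopifnot(inherits(trimap, "trimap"))
  png::writePNG(t(trimap$labels) / 255, path)
  side <- list(
    small_ellipse = unclass(tidy(trimap$small_ellipse)),
    large_ellipse = unclass(tidy(trimap$large_ellipse)),
    p1 = trimap$p1, p2 = trimap$p2
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trimap
#' @export
read_trimap <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such trimap: %s", path))
  labels <- t(round(png::readPNG(path) * 255))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ell <- function(s) tumor_ellipse(c(s$center_row, s$center_col),
                                   s$semi_major, s$semi_minor, s$orientation)
  structure(list(labels = labels, small_ellipse = ell(side$small_ellipse),
                 large_ellipse = ell(side$large_ellipse),
                 p1 = side$p1, p2 = side$p2),
            class = "trimap")
}
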