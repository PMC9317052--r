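#' Specification of the multi-stream U-Net
#'
#' One independent encoder-decoder (U-Net) stream per imaging modality; the
#' streams' final 32-channel feature maps are concatenated (feature-level
#' fusion) and a 1x1 convolution with per-pixel softmax classifies each pixel
#' as tumor or non-tumor. Each stream has five downstream blocks of double
#' 3x3 convolutions (ReLU) with batch norm, 2x2 max-pooling after blocks 1-4,
#' and dropout at the end of the downstream path; the upstream path mirrors it
#' with 2x2 stride-2 transposed convolutions and skip concatenations (batch
#' norm in all upstream blocks but the first).
#'
#' @param n_streams Number of U-Net streams (= modalities), >= 1.
#' @param input_size Input side length; must be divisible by 16 (default 176).
#' @param channels Downstream channel widths per block (default
#'   `c(32, 64, 128, 256, 512)`); the upstream path mirrors them.
#' @param n_classes Number of output classes (2: tumor / non-tumor).
#' @param dropout_rate Dropout rate at the end of the downstream path
#'   (default 0.10).
#' @param l2_penalty L2 regularization weight on convolution kernels
#'   (default 1e-3).
#' @param fusion Fusion strategy; `"concat_1x1"` (channel concatenation
#'   followed by a 1x1 convolution) is the only implemented strategy.
#' @param literal_transpose_128 If `TRUE`, every transposed convolution
#'   produces 128 channels (the literal reading of the architecture table)
#'   instead of matching its skip partner; the symmetric reading is the
#'   default.
#' @return A `network_spec` object.
#' @examples
#' network_spec(n_streams = 4)
#' reduced_spec(n_streams = 2)
#' @export
network_spec <- function(n_streams, input_size = 176,
                         channels = c(32, 64, 128, 256, 512),
                         n_classes = 2, dropout_rate = 0.1,
                         l2_penalty = 1e-3, fusion = "concat_1x1",
                         literal_transpose_128 = FALSE) {
  check_number(n_streams, "n_streams", lower = 1, integer = TRUE)
  check_number(input_size, "input_size", lower = 16, integer = TRUE)
  if (input_size %% 16 != 0)
    abort_config("`input_size` must be divisible by 16 so four 2x2 poolings and four 2x2 upsamplings restore the input shape",
                 field = "input_size")
  if (length(channels) != 5L || any(channels < 1))
    abort_config("`channels` must give 5 positive block widths",
                 field = "channels")
  check_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  check_number(dropout_rate, "dropout_rate", lower = 0, upper = 0.99)
  check_number(l2_penalty, "l2_penalty", lower = 0)
  if (!identical(fusion, "concat_1x1"))
    abort_config("`fusion` must be 'concat_1x1'", field = "fusion")
  structure(
    list(n_streams = as.integer(n_streams),
         input_size = as.integer(input_size),
         channels = as.integer(channels), n_classes = as.integer(n_classes),
         dropout_rate = dropout_rate, l2_penalty = l2_penalty,
         fusion = fusion, literal_transpose_128 = isTRUE(literal_transpose_128)),
    class = "network_spec")
}

#' @rdname network_spec
#' @export
reduced_spec <- function(n_streams, input_size = 64,
                         channels = c(8, 16, 32, 64, 128), ...) {
  network_spec(n_streams, input_size = input_size, channels = channels, ...)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d-stream U-Net, input %dx%d, channels (%s), %d classes\n",
              x$n_streams, x$input_size, x$input_size,
              paste(x$channels, collapse = ","), x$n_classes))
  invisible(x)
}

tconv_out_channels <- function(spec, j) {
  if (spec$literal_transpose_128) 128L else spec$channels[j]
}

#' Per-block shape walk of the architecture
#'
#' @param spec A [network_spec()].
#' @return Tibble with one row per block and stage: `stream` stages walk a
#'   single stream (identical across streams); the final rows describe the
#'   fusion and classifier.
#' @export
describe_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  s <- spec$input_size
  rows <- list()
  sz <- s
  for (b in 1:5) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      stage = "down", block = b, out_channels = spec$channels[b],
      height = sz, width = sz)
    if (b < 5) sz <- sz / 2
  }
  for (b in 6:9) {
    j <- 10L - b
    sz <- sz * 2
    rows[[length(rows) + 1]] <- tibble::tibble(
      stage = "up", block = b, out_channels = spec$channels[j],
      height = sz, width = sz)
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    stage = "fusion", block = 10L,
    out_channels = spec$n_streams * spec$channels[1], height = s, width = s)
  rows[[length(rows) + 1]] <- tibble::tibble(
    stage = "classifier", block = 11L, out_channels = spec$n_classes,
    height = s, width = s)
  dplyr::bind_rows(rows)
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

init_stream_params <- function(spec, prefix) {
  ch <- spec$channels
  p <- list()
  st <- list()
  cin <- 1L
  for (b in 1:5) {
    co <- ch[b]
    p[[paste0(prefix, ".down", b, ".W1")]] <- he_init(c(3, 3, cin, co), 9 * cin)
    p[[paste0(prefix, ".down", b, ".b1")]] <- numeric(co)
    p[[paste0(prefix, ".down", b, ".W2")]] <- he_init(c(3, 3, co, co), 9 * co)
    p[[paste0(prefix, ".down", b, ".b2")]] <- numeric(co)
    p[[paste0(prefix, ".down", b, ".gamma")]] <- rep(1, co)
    p[[paste0(prefix, ".down", b, ".beta")]] <- numeric(co)
    st[[paste0(prefix, ".down", b)]] <- list(mean = numeric(co), var = rep(1, co))
    cin <- co
  }
  prev <- ch[5]
  for (b in 6:9) {
    j <- 10L - b
    ct <- tconv_out_channels(spec, j)
    p[[paste0(prefix, ".up", b, ".Wt")]] <- he_init(c(2, 2, prev, ct), prev)
    p[[paste0(prefix, ".up", b, ".bt")]] <- numeric(ct)
    cc <- ct + ch[j]
    if (b > 6) {
      p[[paste0(prefix, ".up", b, ".gamma")]] <- rep(1, cc)
      p[[paste0(prefix, ".up", b, ".beta")]] <- numeric(cc)
      st[[paste0(prefix, ".up", b)]] <- list(mean = numeric(cc),
                                             var = rep(1, cc))
    }
    co <- ch[j]
    p[[paste0(prefix, ".up", b, ".W1")]] <- he_init(c(3, 3, cc, co), 9 * cc)
    p[[paste0(prefix, ".up", b, ".b1")]] <- numeric(co)
    p[[paste0(prefix, ".up", b, ".W2")]] <- he_init(c(3, 3, co, co), 9 * co)
    p[[paste0(prefix, ".up", b, ".b2")]] <- numeric(co)
    prev <- co
  }
  list(params = p, bn_state = st)
}

#' Build one U-Net stream
#'
#' Returns the initialized parameter set of a single encoder-decoder stream;
#' mostly useful for inspection and shape audits. [build_multistream()] builds
#' the full model.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization.
#' @return List with `params` (named arrays) and `bn_state`.
#' @export
build_stream <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(derive_seed(seed, "stream"), init_stream_params(spec, "s1"))
}

#' Build the multi-stream U-Net
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization (He-normal kernels).
#' @return An object of class `msunet`.
#' @export
build_multistream <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  params <- list(); bn_state <- list()
  with_seed(derive_seed(seed, "init"), {
    for (i in seq_len(spec$n_streams)) {
      sp <- init_stream_params(spec, paste0("s", i))
      params <- c(params, sp$params)
      bn_state <- c(bn_state, sp$bn_state)
    }
    fan <- spec$n_streams * spec$channels[1]
    params[["fuse.W"]] <- he_init(c(1, 1, fan, spec$n_classes), fan)
    params[["fuse.b"]] <- numeric(spec$n_classes)
  })
  structure(list(spec = spec, params = params, bn_state = bn_state,
                 history = NULL, provenance = list(init_seed = seed)),
            class = "msunet")
}

#' @export
print.msunet <- function(x, ...) {
  cat(sprintf("<msunet> %d-stream U-Net, input %d, %s parameters%s\n",
              x$spec$n_streams, x$spec$input_size,
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Total trainable parameter count
#' @param net An `msunet`.
#' @return Integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

stream_forward <- function(net, x, i, training) {
  p <- net$params
  spec <- net$spec
  pre <- paste0("s", i)
  cache <- list(down = vector("list", 5), up = vector("list", 4))
  skips <- vector("list", 5)
  h <- x
  for (b in 1:5) {
    nm <- paste0(pre, ".down", b)
    z1 <- .conv2d_forward(h, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]])
    a1 <- relu_fw(z1)
    z2 <- .conv2d_forward(a1, p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]])
    a2 <- relu_fw(z2)
    bn <- bn_fw(a2, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                net$bn_state[[nm]], training)
    net$bn_state[[nm]] <- bn$state
    blk <- list(x = h, z1 = z1, a1 = a1, z2 = z2, bn = bn$cache,
                in_dim = dim(a2))
    h <- bn$y
    skips[[b]] <- h
    if (b < 5) {
      pl <- .maxpool2x2_forward(h)
      blk$pool_idx <- pl$idx
      blk$pool_in_dim <- dim(h)
      h <- pl$out
    } else if (training && spec$dropout_rate > 0) {
      dp <- dropout_fw(h, spec$dropout_rate, training)
      blk$drop_mask <- dp$mask
      h <- dp$y
    }
    cache$down[[b]] <- blk
  }
  for (b in 6:9) {
    j <- 10L - b
    nm <- paste0(pre, ".up", b)
    tc <- .tconv2x2_forward(h, p[[paste0(nm, ".Wt")]], p[[paste0(nm, ".bt")]])
    cc <- ch_concat(tc, skips[[j]])
    blk <- list(x = h, tc_dim = dim(tc), cc = NULL)
    if (b > 6) {
      bn <- bn_fw(cc, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                  net$bn_state[[nm]], training)
      net$bn_state[[nm]] <- bn$state
      blk$bn <- bn$cache
      cc_in <- bn$y
    } else {
      cc_in <- cc
    }
    z1 <- .conv2d_forward(cc_in, p[[paste0(nm, ".W1")]], p[[paste0(nm, ".b1")]])
    a1 <- relu_fw(z1)
    z2 <- .conv2d_forward(a1, p[[paste0(nm, ".W2")]], p[[paste0(nm, ".b2")]])
    a2 <- relu_fw(z2)
    blk <- modifyList(blk, list(cc_in = cc_in, z1 = z1, a1 = a1, z2 = z2))
    cache$up[[b - 5]] <- blk
    h <- a2
  }
  list(out = h, cache = cache, bn_state = net$bn_state)
}

stream_backward <- function(net, x_in, cache, dout, i) {
  p <- net$params
  pre <- paste0("s", i)
  g <- list()
  dskips <- vector("list", 5)
  dh <- dout
  for (b in 9:6) {
    j <- 10L - b
    nm <- paste0(pre, ".up", b)
    blk <- cache$up[[b - 5]]
    da2 <- dh
    dz2 <- relu_bw(da2, blk$z2)
    cb2 <- .conv2d_backward(blk$a1, p[[paste0(nm, ".W2")]], dz2)
    g[[paste0(nm, ".W2")]] <- cb2$dW; g[[paste0(nm, ".b2")]] <- cb2$db
    dz1 <- relu_bw(cb2$dx, blk$z1)
    cb1 <- .conv2d_backward(blk$cc_in, p[[paste0(nm, ".W1")]], dz1)
    g[[paste0(nm, ".W1")]] <- cb1$dW; g[[paste0(nm, ".b1")]] <- cb1$db
    dcc <- cb1$dx
    if (b > 6) {
      bb <- bn_bw(dcc, blk$bn, p[[paste0(nm, ".gamma")]])
      g[[paste0(nm, ".gamma")]] <- bb$dgamma
      g[[paste0(nm, ".beta")]] <- bb$dbeta
      dcc <- bb$dx
    }
    ct <- blk$tc_dim[3]
    dtc <- dcc[, , seq_len(ct), , drop = FALSE]
    dskips[[j]] <- dcc[, , ct + seq_len(dim(dcc)[3] - ct), , drop = FALSE]
    tb <- .tconv2x2_backward(blk$x, p[[paste0(nm, ".Wt")]], dtc)
    g[[paste0(nm, ".Wt")]] <- tb$dW; g[[paste0(nm, ".bt")]] <- tb$db
    dh <- tb$dx
  }
  for (b in 5:1) {
    nm <- paste0(pre, ".down", b)
    blk <- cache$down[[b]]
    if (b < 5) {
      dh <- .maxpool2x2_backward(dh, blk$pool_idx, blk$pool_in_dim)
    } else if (!is.null(blk$drop_mask)) {
      dh <- dh * blk$drop_mask
    }
    if (!is.null(dskips[[b]])) dh <- dh + dskips[[b]]
    bb <- bn_bw(dh, blk$bn, p[[paste0(nm, ".gamma")]])
    g[[paste0(nm, ".gamma")]] <- bb$dgamma
    g[[paste0(nm, ".beta")]] <- bb$dbeta
    dz2 <- relu_bw(bb$dx, blk$z2)
    cb2 <- .conv2d_backward(blk$a1, p[[paste0(nm, ".W2")]], dz2)
    g[[paste0(nm, ".W2")]] <- cb2$dW; g[[paste0(nm, ".b2")]] <- cb2$db
    dz1 <- relu_bw(cb2$dx, blk$z1)
    cb1 <- .conv2d_backward(blk$x, p[[paste0(nm, ".W1")]], dz1)
    g[[paste0(nm, ".W1")]] <- cb1$dW; g[[paste0(nm, ".b1")]] <- cb1$db
    dh <- cb1$dx
  }
  g
}

msunet_forward <- function(net, x, training = FALSE) {
  x <- as_tensor(x)
  spec <- net$spec
  if (dim(x)[3] != spec$n_streams)
    abort_input(sprintf("input has %d channels but the network has %d streams",
                        dim(x)[3], spec$n_streams))
  if (dim(x)[1] != spec$input_size || dim(x)[2] != spec$input_size)
    abort_input(sprintf("input is %dx%d but the network expects %dx%d",
                        dim(x)[1], dim(x)[2], spec$input_size, spec$input_size))
  stream_out <- vector("list", spec$n_streams)
  caches <- vector("list", spec$n_streams)
  xs <- vector("list", spec$n_streams)
  for (i in seq_len(spec$n_streams)) {
    xi <- x[, , i, , drop = FALSE]
    sf <- stream_forward(net, xi, i, training)
    net$bn_state <- sf$bn_state
    stream_out[[i]] <- sf$out
    caches[[i]] <- sf$cache
    xs[[i]] <- xi
  }
  fused <- Reduce(ch_concat, stream_out)
  logits <- .conv2d_forward(fused, net$params[["fuse.W"]],
                            net$params[["fuse.b"]])
  probs <- softmax_channels(logits)
  list(probs = probs, logits = logits, fused = fused,
       stream_out = stream_out,
       cache = list(streams = caches, xs = xs), bn_state = net$bn_state)
}

msunet_backward <- function(net, fw, dlogits) {
  spec <- net$spec
  fb <- .conv2d_backward(fw$fused, net$params[["fuse.W"]], dlogits)
  g <- list(fuse.W = fb$dW, fuse.b = fb$db)
  dfused <- fb$dx
  ch1 <- dim(fw$stream_out[[1]])[3]
  for (i in seq_len(spec$n_streams)) {
    dout <- dfused[, , (i - 1) * ch1 + seq_len(ch1), , drop = FALSE]
    g <- c(g, stream_backward(net, fw$cache$xs[[i]], fw$cache$streams[[i]],
                              dout, i))
  }
  g
}

#' Segment an image with a (trained) multi-stream U-Net
#'
#' @param object An `msunet`.
#' @param image `H x W x C` array with `C` equal to the number of streams, or
#'   a `[H, W, C, N]` batch.
#' @param ... Unused.
#' @return For a single image, a `segmentation_output` list with
#'   `probabilities` (`H x W x 2`, summing to 1 at every pixel) and
#'   `predicted_mask` (binary `H x W`, the per-pixel argmax). For a batch, a
#'   list of such objects.
#' @export
predict.msunet <- function(object, image, ...) {
  x <- as_tensor(image)
  fw <- msunet_forward(object, x, training = FALSE)
  outs <- purrr::map(seq_len(dim(x)[4]), function(n) {
    pr <- fw$probs[, , , n]
    structure(list(probabilities = pr,
                   predicted_mask = (pr[, , 2] > pr[, , 1]) * 1),
              class = "segmentation_output")
  })
  if (length(outs) == 1L) outs[[1]] else outs
}

#' Segment every slice of a slice tibble
#'
#' @param net A trained `msunet`.
#' @param slices Slice tibble.
#' @param batch_size Slices per forward pass.
#' @return The tibble with `pred_mask` and `prob_fg` list-columns added.
#' @export
predict_slices <- function(net, slices, batch_size = 16) {
  n <- nrow(slices)
  pred <- vector("list", n); prob <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- simplify2array(slices$image[idx])
    fw <- msunet_forward(net, x, training = FALSE)
    for (k in seq_along(idx)) {
      p <- fw$probs[, , , k]
      prob[[idx[k]]] <- p[, , 2]
      pred[[idx[k]]] <- (p[, , 2] > p[, , 1]) * 1
    }
  }
  slices$pred_mask <- pred
  slices$prob_fg <- prob
  slices
}
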