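test_that("compiled convolution primitives match naive R evaluation", {
  set.seed(20)
  naive_conv <- function(x, W, b) {
    d <- dim(x); k <- dim(W)[1]; pad <- (k - 1) / 2; Cout <- dim(W)[4]
    out <- array(0, c(d[1], d[2], Cout, d[4]))
    for (n in 1:d[4]) for (co in 1:Cout) for (h in 1:d[1]) for (w in 1:d[2]) {
      s <- b[co]
      for (ci in 1:d[3]) for (i in 1:k) for (j in 1:k) {
        hh <- h + i - 1 - pad; ww <- w + j - 1 - pad
        if (hh >= 1 && hh <= d[1] && ww >= 1 && ww <= d[2])
          s <- s + x[hh, ww, ci, n] * W[i, j, ci, co]
      }
      out[h, w, co, n] <- s
    }
    out
  }
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  W <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)); b <- rnorm(4)
  expect_equal(ellipseg:::.conv2d_forward(x, W, b), naive_conv(x, W, b),
               tolerance = 1e-12)
  W1 <- array(rnorm(1 * 1 * 3 * 2), c(1, 1, 3, 2)); b1 <- rnorm(2)
  expect_equal(ellipseg:::.conv2d_forward(x, W1, b1), naive_conv(x, W1, b1),
               tolerance = 1e-12)

  # transposed 2x2 stride-2: every input pixel paints a 2x2 output patch
  xt <- array(rnorm(3 * 3 * 2 * 1), c(3, 3, 2, 1))
  Wt <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)); bt <- rnorm(3)
  yt <- ellipseg:::.tconv2x2_forward(xt, Wt, bt)
  expect_equal(dim(yt), c(6, 6, 3, 1))
  ref <- array(0, c(6, 6, 3, 1))
  for (o in 1:3) ref[, , o, 1] <- bt[o]
  for (h in 1:3) for (w in 1:3) for (ci in 1:2) for (i in 1:2) for (j in 1:2)
    for (o in 1:3)
      ref[2 * (h - 1) + i, 2 * (w - 1) + j, o, 1] <-
        ref[2 * (h - 1) + i, 2 * (w - 1) + j, o, 1] + Wt[i, j, ci, o] * xt[h, w, ci, 1]
  expect_equal(yt, ref, tolerance = 1e-12)

  xp <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  pl <- ellipseg:::.maxpool2x2_forward(xp)
  for (n in 1:2) for (c in 1:3) for (h in 1:2) for (w in 1:2)
    expect_equal(pl$out[h, w, c, n],
                 max(xp[(2 * h - 1):(2 * h), (2 * w - 1):(2 * w), c, n]))
})

test_that("analytic gradients match finite differences through the whole net", {
  spec <- network_spec(n_streams = 2, input_size = 16,
                       channels = c(2, 3, 4, 5, 6), dropout_rate = 0,
                       l2_penalty = 0)
  net <- build_multistream(spec, seed = 3)
  set.seed(8)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  tgt <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
  wts <- c(1.7, 1)
  lossfn <- function(n) {
    fw <- ellipseg:::msunet_forward(n, x, training = TRUE)
    ellipseg:::seg_loss_grad(fw$probs, tgt, wts, grad = FALSE)$loss
  }
  fw <- ellipseg:::msunet_forward(net, x, training = TRUE)
  lg <- ellipseg:::seg_loss_grad(fw$probs, tgt, wts)
  g <- ellipseg:::msunet_backward(net, fw, lg$dlogits)
  for (nm in c("s1.down1.W1", "s2.down3.gamma", "s1.up7.Wt", "s2.up9.W2",
               "fuse.W", "s1.down5.beta")) {
    i <- sample(length(g[[nm]]), 1)
    n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + 1e-5
    n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - 1e-5
    fd <- (lossfn(n1) - lossfn(n2)) / 2e-5
    expect_lt(abs(fd - g[[nm]][i]) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("the shape walk reproduces the architecture pyramid", {
  spec <- network_spec(n_streams = 4)
  tab <- describe_network(spec)
  down <- dplyr::filter(tab, stage == "down")
  expect_equal(down$out_channels, c(32, 64, 128, 256, 512))
  expect_equal(down$height, c(176, 88, 44, 22, 11))
  up <- dplyr::filter(tab, stage == "up")
  expect_equal(up$out_channels, c(256, 128, 64, 32))
  expect_equal(up$height, c(22, 44, 88, 176))
  expect_equal(tab$out_channels[tab$stage == "fusion"], 128)
  expect_equal(tab$out_channels[tab$stage == "classifier"], 2)
  # two-stream variant fuses at depth 64
  expect_equal(describe_network(network_spec(2)) |>
                 dplyr::filter(stage == "fusion") |> dplyr::pull(out_channels),
               64)
  red <- describe_network(reduced_spec(2))
  expect_equal(dplyr::filter(red, stage == "down")$height,
               c(64, 32, 16, 8, 4))
})

test_that("forward activations follow the spatial pyramid block by block", {
  spec <- micro_spec(n_streams = 1)
  net <- build_multistream(spec, seed = 2)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  fw <- ellipseg:::msunet_forward(net, x, training = FALSE)
  cache <- fw$cache$streams[[1]]
  got <- purrr::map(cache$down, ~ dim(.x$z1)[c(3, 1)])
  expect_equal(purrr::map(got, ~ .x[2]), list(32, 16, 8, 4, 2))
  expect_equal(purrr::map_int(cache$down, ~ dim(.x$z2)[3]),
               c(4L, 8L, 16L, 32L, 64L))
  expect_equal(dim(cache$up[[4]]$z2)[1:3], c(32, 32, 4))
  expect_equal(dim(fw$probs), c(32, 32, 2, 1))
})

test_that("parameter tensors mirror the table layout", {
  net <- build_multistream(network_spec(4), seed = 1)
  p <- net$params
  expect_equal(dim(p[["s1.down1.W1"]]), c(3, 3, 1, 32))
  expect_equal(dim(p[["s1.down5.W2"]]), c(3, 3, 512, 512))
  expect_equal(dim(p[["s1.up6.Wt"]]), c(2, 2, 512, 256))
  expect_equal(dim(p[["s1.up9.W2"]]), c(3, 3, 32, 32))
  expect_equal(dim(p[["fuse.W"]]), c(1, 1, 128, 2))
  expect_false("s1.up6.gamma" %in% names(p)) # no batch norm in block 6
  expect_true(all(paste0("s", 1:4, ".down1.W1") %in% names(p)))
  # literal variant: every transposed conv outputs 128 channels
  lit <- build_multistream(network_spec(1, literal_transpose_128 = TRUE),
                           seed = 1)
  expect_equal(dim(lit$params[["s1.up9.Wt"]]), c(2, 2, 64, 128))
})

test_that("softmax output is a probability field and inference is deterministic", {
  spec <- micro_spec(n_streams = 2)
  net <- build_multistream(spec, seed = 4)
  img <- array(rnorm(32 * 32 * 2), c(32, 32, 2))
  out <- predict(net, img)
  expect_s3_class(out, "segmentation_output")
  expect_lt(max(abs(out$probabilities[, , 1] + out$probabilities[, , 2] - 1)),
            1e-5)
  expect_identical(out$predicted_mask,
                   (out$probabilities[, , 2] > out$probabilities[, , 1]) * 1)
  out2 <- predict(net, img)
  expect_identical(out$probabilities, out2$probabilities)
})

test_that("a zeroed classifier yields uniform class probabilities", {
  net <- build_multistream(micro_spec(n_streams = 1), seed = 4)
  net$params[["fuse.W"]][] <- 0
  net$params[["fuse.b"]][] <- 0
  out <- predict(net, array(rnorm(32 * 32), c(32, 32, 1)))
  expect_equal(max(abs(out$probabilities - 0.5)), 0, tolerance = 1e-12)
  expect_true(all(out$predicted_mask == 0)) # ties resolve to background
})

test_that("streams are independent before fusion", {
  net <- build_multistream(micro_spec(n_streams = 2), seed = 6)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 2, 1))
  x2 <- x; x2[, , 2, ] <- 0
  f1 <- ellipseg:::msunet_forward(net, x, training = FALSE)
  f2 <- ellipseg:::msunet_forward(net, x2, training = FALSE)
  expect_identical(f1$stream_out[[1]], f2$stream_out[[1]])
  expect_false(identical(f1$stream_out[[2]], f2$stream_out[[2]]))
})

test_that("parameter count scales roughly quadratically with width", {
  n1 <- n_parameters(build_multistream(
    network_spec(1, input_size = 32, channels = c(8, 16, 32, 64, 128)),
    seed = 1))
  n2 <- n_parameters(build_multistream(
    network_spec(1, input_size = 32, channels = c(16, 32, 64, 128, 256)),
    seed = 1))
  expect_lt(abs(n2 / n1 - 4), 0.25)
})

test_that("spec and input validation reject inconsistent shapes", {
  expect_config_error(network_spec(2, input_size = 100))
  expect_config_error(network_spec(0))
  expect_config_error(network_spec(2, channels = c(8, 16)))
  net <- build_multistream(micro_spec(n_streams = 2), seed = 1)
  expect_input_error(predict(net, array(0, c(32, 32, 3))))
  expect_input_error(predict(net, array(0, c(16, 16, 2))))
})

test_that("checkpoints round-trip through disk", {
  net <- build_multistream(micro_spec(n_streams = 1), seed = 9)
  p <- file.path(withr::local_tempdir(), "m.rds")
  save_msunet(net, p)
  back <- load_msunet(p)
  img <- array(rnorm(32 * 32), c(32, 32, 1))
  expect_identical(predict(net, img)$probabilities,
                   predict(back, img)$probabilities)
  expect_error(load_msunet(file.path(tempdir(), "missing.rds")),
               class = "ellipseg_io_error")
})
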