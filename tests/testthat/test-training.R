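trimap_stub <- function(fg, bg, ignore, n = 40) {
  lab <- matrix(TRIMAP_IGNORE, n, n)
  stopifnot(fg + bg + ignore == n * n)
  v <- c(rep(TRIMAP_FG, fg), rep(TRIMAP_BG, bg), rep(TRIMAP_IGNORE, ignore))
  lab[] <- v
  structure(list(labels = lab, p1 = 0.9, p2 = 1.2), class = "trimap")
}

stub_records <- function(trimaps) {
  tibble::tibble(patient_id = sprintf("p%d", seq_along(trimaps)),
                 trimap = trimaps)
}

test_that("class weights follow inverse pixel frequency with ignore excluded", {
  # FG : BG = 1 : 9 across records
  recs <- stub_records(list(trimap_stub(160, 1440, 0),
                            trimap_stub(160, 1440, 0)))
  expect_equal(compute_class_weights(recs), c(w_fg = 9, w_bg = 1))
  expect_equal(compute_class_weights(stub_records(list(trimap_stub(800, 800, 0)))),
               c(w_fg = 1, w_bg = 1))
  one <- stub_records(list(trimap_stub(100, 400, 1100)))
  expect_equal(compute_class_weights(one), c(w_fg = 4, w_bg = 1))
  expect_input_error(compute_class_weights(
    stub_records(list(trimap_stub(0, 1600, 0)))))
})

test_that("trimap loss has the closed-form values on degenerate predictions", {
  lab <- trimap_stub(400, 800, 400)
  probs <- array(0, c(40, 40, 2))
  probs[, , 1] <- (lab$labels != TRIMAP_FG) * 1
  probs[, , 2] <- (lab$labels == TRIMAP_FG) * 1
  expect_equal(trimap_loss(probs, lab, c(1, 1)), 0, tolerance = 1e-9)
  uni <- array(0.5, c(40, 40, 2))
  expect_equal(trimap_loss(uni, lab, c(1, 1)), log(2), tolerance = 1e-12)
  # weighted: mean over counted pixels of w[class] * ln 2
  w <- c(3, 1)
  expect_equal(trimap_loss(uni, lab, w),
               (400 * 3 + 800 * 1) * log(2) / 1200, tolerance = 1e-12)
})

test_that("ignore pixels contribute no loss and no gradient", {
  set.seed(31)
  lab <- trimap_stub(300, 900, 400)
  probs <- array(runif(40 * 40 * 2), c(40, 40, 2))
  s <- probs[, , 1] + probs[, , 2]
  probs[, , 1] <- probs[, , 1] / s; probs[, , 2] <- probs[, , 2] / s
  base <- trimap_loss(probs, lab, c(2, 1))
  flip <- probs
  ig <- lab$labels == TRIMAP_IGNORE
  flip[, , 1][ig] <- 1 - flip[, , 1][ig]
  flip[, , 2][ig] <- 1 - flip[, , 2][ig]
  expect_identical(trimap_loss(flip, lab, c(2, 1)), base)
  lg <- ellipseg:::seg_loss_grad(ellipseg:::as_tensor(probs), lab$labels,
                                 c(2, 1))
  expect_true(all(lg$dlogits[, , 1, 1][ig] == 0))
  expect_true(all(lg$dlogits[, , 2, 1][ig] == 0))
  all_ignore <- trimap_stub(0, 0, 1600)
  expect_input_error(trimap_loss(probs, all_ignore, c(1, 1)))
})

test_that("loss scales linearly with the class-weight vector", {
  set.seed(32)
  lab <- trimap_stub(500, 700, 400)
  probs <- array(runif(40 * 40 * 2, 0.05, 0.95), c(40, 40, 2))
  s <- probs[, , 1] + probs[, , 2]
  probs[, , 1] <- probs[, , 1] / s; probs[, , 2] <- probs[, , 2] / s
  w <- c(2.3, 1)
  for (k in c(0.1, 2, 17)) {
    expect_equal(trimap_loss(probs, lab, k * w),
                 k * trimap_loss(probs, lab, w), tolerance = 1e-9)
  }
})

test_that("two-round training enforces its data contract", {
  ph <- micro_phantoms(n_patients = 4)
  net <- build_multistream(micro_spec(2), seed = 1)
  cfg <- micro_train_config()
  ids <- unique(ph$patient_id)
  weak <- dplyr::filter(ph, patient_id %in% ids[1:3])
  ann <- dplyr::filter(ph, patient_id %in% ids[3:4]) # overlaps patient 3
  expect_input_error(train_two_round(net, weak, ann, cfg))
  expect_input_error(train_two_round(net, weak[0, ],
                                     dplyr::filter(ph, patient_id == ids[4]),
                                     cfg))
  many <- dplyr::bind_rows(purrr::map(1:25, function(i)
    dplyr::mutate(ph[1, ], patient_id = sprintf("q%02d", i))))
  expect_input_error(
    train_two_round(net, weak, many, cfg))
})

test_that("seeded two-round training is reproducible and learns the phantom", {
  ph <- micro_phantoms(n_patients = 6, seed = 17)
  ids <- unique(ph$patient_id)
  weak <- dplyr::filter(ph, patient_id %in% ids[1:4])
  ann <- dplyr::filter(ph, patient_id %in% ids[5]) |>
    dplyr::mutate(annotated = TRUE)
  test <- dplyr::filter(ph, patient_id %in% ids[6])
  cfg <- micro_train_config(epochs_round1 = 5, epochs_round2 = 5)
  m1 <- train_two_round(build_multistream(micro_spec(2), seed = 1),
                        weak, ann, cfg)
  m2 <- train_two_round(build_multistream(micro_spec(2), seed = 1),
                        weak, ann, cfg)
  expect_equal(tidy(m1)$loss, tidy(m2)$loss, tolerance = 1e-12)
  h <- tidy(m1)
  expect_setequal(unique(h$round), c("coarse", "refine"))
  expect_lt(h$loss[h$round == "coarse"][5], h$loss[h$round == "coarse"][1])
  # refinement improves the fit on annotated-style labels
  r <- evaluate_model(m1, test)
  expect_gt(r$dice, 0.5)
  expect_equal(glance(m1)$n_rounds, 2L)
})

test_that("coarse training reaches high accuracy on held-out trimap pixels", {
  ph <- micro_phantoms(n_patients = 7, seed = 23, noise_sigma = 0,
                       irregularity = 0)
  ids <- unique(ph$patient_id)
  weak <- dplyr::filter(ph, patient_id %in% ids[1:6])
  ann <- dplyr::filter(ph, patient_id %in% ids[7])
  cfg <- micro_train_config(epochs_round1 = 6, epochs_round2 = 0)
  m <- train_two_round(build_multistream(micro_spec(2), seed = 2), weak,
                       dplyr::mutate(ann, annotated = TRUE), cfg)
  held <- predict_slices(m, ann)
  accs <- purrr::map_dbl(seq_len(nrow(held)), function(k) {
    lab <- held$trimap[[k]]$labels
    counted <- lab != TRIMAP_IGNORE
    mean((held$pred_mask[[k]] == lab)[counted])
  })
  expect_gte(mean(accs), 0.95)
})

test_that("weak-only training suffices on exactly elliptical tumors", {
  # balanced class weights isolate the geometric question (does ellipse-box
  # supervision pin the boundary?) from the recall-oriented bias that
  # inverse-frequency weighting adds and the refinement round later corrects
  ph <- micro_phantoms(n_patients = 12, seed = 29, irregularity = 0,
                       noise_sigma = 0.02, n_slices = 3, size = 64)
  ids <- unique(ph$patient_id)
  weak <- dplyr::filter(ph, patient_id %in% ids[1:9])
  ann <- dplyr::filter(ph, patient_id == ids[10]) |>
    dplyr::mutate(annotated = TRUE)
  test <- dplyr::filter(ph, patient_id %in% ids[11:12])
  cfg <- micro_train_config(epochs_round1 = 12, epochs_round2 = 0,
                            class_weights = c(1, 1))
  m <- train_two_round(build_multistream(
    network_spec(2, input_size = 64, channels = c(8, 16, 32, 64, 128)),
    seed = 3), weak, ann, cfg)
  expect_gte(evaluate_model(m, test)$dice, 0.9)
})

test_that("refinement improves irregular-tumor dice, paired across seeds", {
  deltas <- purrr::map_dbl(1:5, function(s) {
    ph <- micro_phantoms(n_patients = 7, seed = 100 + s, irregularity = 1.5)
    ids <- unique(ph$patient_id)
    weak <- dplyr::filter(ph, patient_id %in% ids[1:5])
    ann <- dplyr::filter(ph, patient_id == ids[6]) |>
      dplyr::mutate(annotated = TRUE)
    test <- dplyr::filter(ph, patient_id == ids[7])
    cfg1 <- micro_train_config(epochs_round1 = 5, epochs_round2 = 0, seed = s)
    round1 <- train_two_round(build_multistream(micro_spec(2), seed = s),
                              weak, ann, cfg1)
    cfg2 <- micro_train_config(epochs_round1 = 0, epochs_round2 = 6, seed = s)
    round2 <- transfer_refine(round1, ann, cfg2)
    evaluate_model(round2, test)$dice - evaluate_model(round1, test)$dice
  })
  expect_gt(mean(deltas), 0)
})

test_that("transfer refinement updates every layer and keeps the contract", {
  ph <- micro_phantoms(n_patients = 3, seed = 41)
  ann <- dplyr::mutate(ph, annotated = TRUE)
  pre <- build_multistream(micro_spec(2), seed = 7)
  cfg <- micro_train_config(epochs_round2 = 2)
  ref <- transfer_refine(pre, ann, cfg)
  deltas <- purrr::map_dbl(names(pre$params),
                           ~ max(abs(ref$params[[.x]] - pre$params[[.x]])))
  expect_true(all(deltas > 0))
  # zero refinement epochs leave the weights untouched
  same <- transfer_refine(pre, ann, micro_train_config(epochs_round2 = 0))
  expect_identical(same$params, pre$params)
  mono <- micro_phantoms(n_patients = 1, seed = 42)
  mono$image <- purrr::map(mono$image, ~ .x[, , 1, drop = FALSE])
  expect_input_error(transfer_refine(pre, mono, cfg))
})

test_that("fully supervised training demands annotated records", {
  ph <- micro_phantoms(n_patients = 3, seed = 43)
  net <- build_multistream(micro_spec(2), seed = 1)
  cfg <- micro_train_config(epochs_round2 = 2)
  expect_input_error(train_fully_supervised(net, ph, cfg)) # annotated FALSE
  expect_input_error(train_fully_supervised(net, ph[0, ], cfg))
  ann <- dplyr::mutate(ph, annotated = TRUE)
  m1 <- train_fully_supervised(net, ann, cfg)
  m2 <- train_fully_supervised(net, ann, cfg)
  expect_equal(tidy(m1)$loss, tidy(m2)$loss, tolerance = 1e-12)
  expect_equal(unique(tidy(m1)$round), "full")
})
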