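#' Training configuration
#'
#' Defaults follow the protocol's standard settings: learning rate 1e-3 with the
#' Adagrad optimizer, batch size 16, 70 coarse epochs and 150 refinement
#' epochs, L2 penalty 1e-3 on convolution kernels, inverse-frequency class
#' weighting computed from the data, and flip/shear/scale augmentation during
#' training.
#'
#' @param learning_rate Positive learning rate.
#' @param optimizer Only `"adagrad"` is implemented.
#' @param batch_size Slices per gradient step.
#' @param epochs_round1 Coarse (trimap) training epochs.
#' @param epochs_round2 Refinement (mask) training epochs.
#' @param class_weights `"auto"` (inverse pixel-frequency, computed from the
#'   training data before each round) or a numeric `(w_fg, w_bg)`.
#' @param l2_penalty L2 regularization weight on convolution kernels.
#' @param augment Apply random augmentation during training.
#' @param round2_class_weights Recompute class weights from mask frequencies
#'   for the refinement round; if `FALSE` round 2 uses weights `(1, 1)`.
#' @param seed Integer seed covering shuffling, augmentation and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, optimizer = "adagrad",
                         batch_size = 16, epochs_round1 = 70,
                         epochs_round2 = 150, class_weights = "auto",
                         l2_penalty = 1e-3, augment = TRUE,
                         round2_class_weights = TRUE, seed = 1L) {
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  if (!identical(optimizer, "adagrad"))
    abort_config("`optimizer` must be 'adagrad'", field = "optimizer")
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(epochs_round1, "epochs_round1", lower = 0, integer = TRUE)
  check_number(epochs_round2, "epochs_round2", lower = 0, integer = TRUE)
  if (!identical(class_weights, "auto")) {
    if (length(class_weights) != 2L || any(class_weights <= 0))
      abort_config("`class_weights` must be 'auto' or two positive numbers",
                   field = "class_weights")
  }
  check_number(l2_penalty, "l2_penalty", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 epochs_round1 = as.integer(epochs_round1),
                 epochs_round2 = as.integer(epochs_round2),
                 class_weights = class_weights, l2_penalty = l2_penalty,
                 augment = isTRUE(augment),
                 round2_class_weights = isTRUE(round2_class_weights),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-frequency class weights from weak or full labels
#'
#' The foreground weight is the ratio of the average background pixel count
#' to the average foreground pixel count per record, normalised so the
#' background weight is 1. Ignore pixels are excluded from both counts.
#'
#' @param records Slice tibble with a `trimap` (preferred) or `mask` column.
#' @return Named numeric `(w_fg, w_bg)`.
#' @export
compute_class_weights <- function(records) {
  targets <- slice_targets(records,
                           if ("trimap" %in% names(records)) "trimap" else "mask")
  fg <- vapply(targets, function(t) sum(t == TRIMAP_FG), numeric(1))
  bg <- vapply(targets, function(t) sum(t == TRIMAP_BG), numeric(1))
  if (sum(fg) == 0) abort_input("no foreground pixels in any record")
  if (sum(bg) == 0) abort_input("no background pixels in any record")
  c(w_fg = mean(bg) / mean(fg), w_bg = 1)
}

#' Weighted cross-entropy over a trimap's counted pixels
#'
#' Mean weighted categorical cross-entropy over foreground and background
#' pixels; ignore pixels contribute exactly zero to the loss and its gradient.
#'
#' @param probabilities `H x W x 2` per-pixel class probabilities
#'   (background, foreground).
#' @param trimap A [make_trimap()] result (or an `H x W` matrix of 0/1/2).
#' @param weights Numeric `(w_fg, w_bg)`.
#' @return Scalar loss.
#' @export
trimap_loss <- function(probabilities, trimap, weights = c(1, 1)) {
  labels <- if (inherits(trimap, "trimap")) trimap$labels else trimap
  if (!all(dim(probabilities)[1:2] == dim(labels)))
    abort_input("probability map and trimap shapes differ")
  seg_loss_grad(as_tensor(probabilities), labels, weights, grad = FALSE)$loss
}

slice_targets <- function(slices, label_type) {
  purrr::map(seq_len(nrow(slices)), function(k) {
    t <- switch(label_type,
                trimap = slices$trimap[[k]]$labels,
                mask = slices$mask[[k]])
    if (is.null(t))
      abort_input(sprintf("record %d has no %s label", k, label_type))
    t
  })
}

adagrad_update <- function(params, grads, state, lr, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state[[nm]])) state[[nm]] <- g * 0
    state[[nm]] <- state[[nm]] + g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

kernel_names <- function(params) {
  grep("\\.(W1|W2|Wt)$|^fuse\\.W$", names(params), value = TRUE)
}

# one optimisation round over `slices` with `label_type` targets; mutates and
# returns the net plus an epoch-level history tibble. Runs under the caller's
# RNG stream (shuffling, augmentation draws, dropout).
run_round <- function(net, slices, label_type, weights, epochs, cfg, round_id) {
  n <- nrow(slices)
  if (n == 0) abort_input("training set is empty")
  hist <- vector("list", epochs)
  kn <- kernel_names(net$params)
  opt_state <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0; ep_count <- 0; n_batch <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      batch <- slices[idx, ]
      if (cfg$augment) {
        rows <- purrr::map(seq_len(nrow(batch)), function(k)
          augment(batch[k, ], seed = derive_seed(cfg$seed, round_id, ep,
                                                 idx[k])))
        batch <- dplyr::bind_rows(rows)
      }
      x <- simplify2array(batch$image)
      if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
      targets <- slice_targets(batch, label_type)
      tgt <- simplify2array(targets)
      fw <- msunet_forward(net, x, training = TRUE)
      net$bn_state <- fw$bn_state
      lg <- seg_loss_grad(fw$probs, tgt, weights)
      g <- msunet_backward(net, fw, lg$dlogits)
      if (cfg$l2_penalty > 0)
        for (nm in kn) g[[nm]] <- g[[nm]] + 2 * cfg$l2_penalty * net$params[[nm]]
      up <- adagrad_update(net$params, g, opt_state, cfg$learning_rate)
      net$params <- up$params
      opt_state <- up$state
      ep_loss <- ep_loss + lg$loss
      n_batch <- n_batch + 1
      tgt_arr <- array(tgt, dim(fw$probs)[c(1, 2, 4)])
      counted <- tgt_arr != TRIMAP_IGNORE
      pred_fg <- array(fw$probs[, , 2, ] > fw$probs[, , 1, ],
                       dim(fw$probs)[c(1, 2, 4)])
      ep_correct <- ep_correct + sum((pred_fg == (tgt_arr == 1))[counted])
      ep_count <- ep_count + sum(counted)
    }
    hist[[ep]] <- tibble::tibble(
      round = round_id, epoch = ep, loss = ep_loss / n_batch,
      pixel_accuracy = ep_correct / ep_count)
  }
  list(net = net, history = dplyr::bind_rows(hist))
}

resolve_weights <- function(cfg, slices, label_type, use_auto = TRUE) {
  if (identical(cfg$class_weights, "auto")) {
    if (!use_auto) return(c(w_fg = 1, w_bg = 1))
    compute_class_weights(
      if (label_type == "trimap") slices["trimap"] else slices["mask"])
  } else {
    setNames(as.numeric(cfg$class_weights), c("w_fg", "w_bg"))
  }
}

check_channels <- function(net, slices) {
  cdat <- dim(slices$image[[1]])[3]
  if (cdat != net$spec$n_streams)
    abort_input(sprintf("data has %d modalities but the network has %d streams",
                        cdat, net$spec$n_streams))
}

#' Two-round weakly supervised training
#'
#' Round 1 (coarse) minimises the weighted trimap cross-entropy on the
#' weakly labelled set for `epochs_round1` epochs; round 2 (refinement)
#' minimises per-pixel weighted cross-entropy against full masks on the small
#' annotated set for `epochs_round2` epochs. All layers are trainable in both
#' rounds and the optimizer state is reset between rounds.
#'
#' @param model An untrained [build_multistream()] network.
#' @param weak_set Slice tibble with `trimap` labels; its patients must be
#'   disjoint from `annotated_set`'s.
#' @param annotated_set Slice tibble with ground-truth `mask` labels; fewer
#'   than 20 patients unless `allow_large_annotated = TRUE`.
#' @param config A [train_config()].
#' @param allow_large_annotated Lift the `< 20` annotated-patient check.
#' @return A trained `msunet` with a `history` tibble (per round and epoch)
#'   and provenance recording the training patients and configuration.
#' @export
train_two_round <- function(model, weak_set, annotated_set, config,
                            allow_large_annotated = FALSE) {
  stopifnot(inherits(model, "msunet"), inherits(config, "train_config"))
  if (nrow(weak_set) == 0 || nrow(annotated_set) == 0)
    abort_input("both the weak and the annotated set must be non-empty")
  shared <- intersect(unique(weak_set$patient_id),
                      unique(annotated_set$patient_id))
  if (length(shared) > 0)
    abort_input(sprintf("weak and annotated sets share patients: %s",
                        paste(shared, collapse = ", ")))
  n_ann <- length(unique(annotated_set$patient_id))
  if (n_ann >= 20 && !allow_large_annotated)
    abort_input(sprintf("annotated set has %d patients; the protocol expects fewer than 20",
                        n_ann))
  check_channels(model, weak_set)
  net <- model
  hist <- with_seed(derive_seed(config$seed, "train2r"), {
    w1 <- resolve_weights(config, weak_set, "trimap")
    r1 <- run_round(net, weak_set, "trimap", w1, config$epochs_round1, config,
                    "coarse")
    net <- r1$net
    w2 <- resolve_weights(config, annotated_set, "mask",
                          use_auto = config$round2_class_weights)
    r2 <- run_round(net, annotated_set, "mask", w2, config$epochs_round2,
                    config, "refine")
    net <- r2$net
    dplyr::bind_rows(r1$history, r2$history)
  })
  net$history <- hist
  net$provenance <- c(net$provenance, list(
    config = config,
    train_patients = union(unique(weak_set$patient_id),
                           unique(annotated_set$patient_id)),
    protocol = "weak_two_round"))
  net
}

#' Transfer refinement of a pretrained network on a small annotated dataset
#'
#' Initialises from the pretrained weights and refine-trains on the small
#' annotated set, updating the weights of every layer (no frozen layers) --
#' unlike classical transfer learning that only retrains top layers, because
#' domain mismatch between datasets affects low-level features too.
#'
#' @param pretrained A trained `msunet`; its stream count must match the
#'   target data's modality count.
#' @param small_annotated_set Slice tibble with `mask` labels.
#' @param config A [train_config()]; `epochs_round2` refinement epochs are
#'   used.
#' @return The refined `msunet`.
#' @export
transfer_refine <- function(pretrained, small_annotated_set, config) {
  stopifnot(inherits(pretrained, "msunet"), inherits(config, "train_config"))
  if (nrow(small_annotated_set) == 0)
    abort_input("the annotated set must be non-empty")
  check_channels(pretrained, small_annotated_set)
  net <- pretrained
  hist <- with_seed(derive_seed(config$seed, "transfer"), {
    w <- resolve_weights(config, small_annotated_set, "mask",
                         use_auto = config$round2_class_weights)
    r <- run_round(net, small_annotated_set, "mask", w, config$epochs_round2,
                   config, "transfer")
    net <- r$net
    r$history
  })
  net$history <- dplyr::bind_rows(pretrained$history, hist)
  net$provenance <- c(net$provenance, list(
    transfer_config = config,
    transfer_patients = unique(small_annotated_set$patient_id),
    protocol = "transfer_refine"))
  net
}

#' Fully supervised baseline training
#'
#' Trains the identical architecture in a single round on fully annotated
#' masks; the comparison baseline for quantifying the cost of weak
#' supervision.
#'
#' @param model An untrained `msunet`.
#' @param annotated_set Slice tibble where every record is annotated.
#' @param config A [train_config()]; `epochs_round2` epochs are used.
#' @return A trained `msunet`.
#' @export
train_fully_supervised <- function(model, annotated_set, config) {
  stopifnot(inherits(model, "msunet"), inherits(config, "train_config"))
  if (nrow(annotated_set) == 0) abort_input("the annotated set is empty")
  if (!all(annotated_set$annotated))
    abort_input("all records must be annotated for fully supervised training")
  check_channels(model, annotated_set)
  net <- model
  hist <- with_seed(derive_seed(config$seed, "full"), {
    w <- resolve_weights(config, annotated_set, "mask",
                         use_auto = config$round2_class_weights)
    r <- run_round(net, annotated_set, "mask", w, config$epochs_round2,
                   config, "full")
    net <- r$net
    r$history
  })
  net$history <- hist
  net$provenance <- c(net$provenance, list(
    config = config, train_patients = unique(annotated_set$patient_id),
    protocol = "fully_supervised"))
  net
}

#' @rdname train_two_round
#' @param x A trained `msunet`.
#' @param ... Unused.
#' @method tidy msunet
#' @export
tidy.msunet <- function(x, ...) {
  x$history %||% tibble::tibble(round = character(), epoch = integer(),
                                loss = numeric(), pixel_accuracy = numeric())
}

#' @rdname train_two_round
#' @method glance msunet
#' @export
glance.msunet <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    n_streams = x$spec$n_streams, input_size = x$spec$input_size,
    n_parameters = n_parameters(x),
    n_rounds = length(unique(h$round)),
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_pixel_accuracy = if (nrow(h)) h$pixel_accuracy[nrow(h)] else NA_real_)
}

#' Save / load a model checkpoint
#'
#' @param net An `msunet`.
#' @param path Checkpoint path (RDS).
#' @return `path` invisibly; `load_msunet` returns the model.
#' @export
save_msunet <- function(net, path) {
  stopifnot(inherits(net, "msunet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_msunet
#' @export
load_msunet <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no checkpoint at %s", path))
  net <- readRDS(path)
  if (!inherits(net, "msunet")) abort_io(sprintf("%s is not a model", path))
  net
}
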