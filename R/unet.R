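#' Specification of the volumetric segmentation network
#'
#' A compact 3D U-Net: `depth` encoder blocks of 3x3x3 convolutions
#' (leaky-ReLU activations), each followed by 2x2x2 max-pooling, with the
#' filter count starting at `base_filters` and doubling per block; a
#' mirrored decoder with nearest-neighbour upsampling and skip
#' concatenation; and a 1x1x1 output head with softmax (multi-class cut
#' segmentation, weighted categorical cross-entropy) or sigmoid (binary
#' pelvis mask, Dice-CE loss). Training uses Adam under a piecewise-constant
#' learning-rate schedule.
#'
#' Defaults are the multi-class cut segmenter: 5 output channels
#' (background + 4 osteotomies), class weights `c(10, 270, 260, 270, 260)`,
#' 40 epochs with lr 1e-4 for the first 10 epochs and 1e-5 afterwards.
#' `pelvis_segmenter_spec()` returns the binary variant (sigmoid head,
#' Dice-CE loss, lr 1e-4 / 1e-5 / 1e-6 over epochs 1-20 / 21-30 / 31-40).
#'
#' @param n_classes Output channels (5 multi-class, 1 binary).
#' @param depth Number of encoder blocks (input shape must be divisible by
#'   `2^depth`).
#' @param base_filters Filters of the first block (doubled per block).
#' @param epochs Training epochs.
#' @param lr_schedule List of `c(first_epoch, last_epoch, rate)` rows
#'   covering all epochs, rates > 0.
#' @param class_weights Per-class loss weights (softmax head only).
#' @param final `"softmax"` or `"sigmoid"`.
#' @param input_shape Grid the network operates on.
#' @param leaky_alpha Negative-slope of the hidden activations.
#' @return List of class `segmenter_spec`.
#' @export
segmenter_spec <- function(n_classes = 5, depth = 5, base_filters = 16,
                           epochs = 40,
                           lr_schedule = list(c(1, 10, 1e-4),
                                              c(11, epochs, 1e-5)),
                           class_weights = c(10, 270, 260, 270, 260),
                           final = c("softmax", "sigmoid"),
                           input_shape = c(128, 128, 128),
                           leaky_alpha = 0.01) {
  final <- match.arg(final)
  covered <- integer(0)
  for (row in lr_schedule) {
    if (length(row) != 3 || row[3] <= 0)
      stop("lr_schedule rows are c(first_epoch, last_epoch, rate), rate > 0")
    covered <- c(covered, seq(row[1], row[2]))
  }
  if (!all(seq_len(epochs) %in% covered))
    stop("lr_schedule must cover all epochs")
  if (final == "softmax" && length(class_weights) != n_classes)
    stop("need one class weight per output channel")
  if (any(input_shape %% 2^depth != 0))
    stop("input_shape must be divisible by 2^depth")
  structure(list(n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 class_weights = class_weights, final = final,
                 input_shape = as.integer(input_shape),
                 leaky_alpha = leaky_alpha),
            class = "segmenter_spec")
}

#' @rdname segmenter_spec
#' @param ... Overrides passed to [segmenter_spec()].
#' @export
pelvis_segmenter_spec <- function(epochs = 40, ...) {
  segmenter_spec(n_classes = 1, final = "sigmoid", epochs = epochs,
                 lr_schedule = list(c(1, min(20, epochs), 1e-4),
                                    c(min(21, epochs), min(30, epochs), 1e-5),
                                    c(min(31, epochs), epochs, 1e-6)),
                 class_weights = 1, ...)
}

lr_at_epoch <- function(spec, epoch) {
  for (row in spec$lr_schedule)
    if (epoch >= row[1] && epoch <= row[2]) return(row[3])
  spec$lr_schedule[[length(spec$lr_schedule)]][3]
}

unet_channels <- function(spec) {
  enc <- spec$base_filters * 2^(seq_len(spec$depth) - 1)
  dec <- pmax(spec$base_filters, enc %/% 2)
  dec[1] <- spec$base_filters
  list(enc = enc, dec = dec)
}

unet_init <- function(spec, in_channels = 1, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ch <- unet_channels(spec)
  he <- function(fan_in, nr, nc)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  params <- list(enc = list(), dec = list())
  cin <- in_channels
  for (s in seq_len(spec$depth)) {
    params$enc[[s]] <- list(W = he(27 * cin, 27 * cin, ch$enc[s]),
                            b = numeric(ch$enc[s]))
    cin <- ch$enc[s]
  }
  for (s in rev(seq_len(spec$depth))) {
    up_ch <- if (s == spec$depth) ch$enc[spec$depth] else ch$dec[s + 1]
    cin <- up_ch + ch$enc[s]
    params$dec[[s]] <- list(W = he(27 * cin, 27 * cin, ch$dec[s]),
                            b = numeric(ch$dec[s]))
  }
  params$head <- list(W = he(ch$dec[1], ch$dec[1], spec$n_classes),
                      b = numeric(spec$n_classes))
  params
}

# per-level dims and nearest-neighbour upsampling index maps
unet_grids <- function(spec) {
  dims <- vector("list", spec$depth + 1)
  dims[[1]] <- spec$input_shape
  for (s in seq_len(spec$depth)) dims[[s + 1]] <- dims[[s]] %/% 2L
  upmap <- vector("list", spec$depth)
  for (s in seq_len(spec$depth)) {
    fine <- dims[[s]]; coarse <- dims[[s + 1]]
    idx <- arrayInd(seq_len(prod(fine)), fine) - 1L
    cidx <- idx %/% 2L
    upmap[[s]] <- 1L + cidx[, 1] + coarse[1] * (cidx[, 2] + coarse[2] * cidx[, 3])
  }
  list(dims = dims, upmap = upmap)
}

leaky <- function(z, a) ifelse(z > 0, z, a * z)
leaky_grad <- function(z, a) ifelse(z > 0, 1, a)

unet_forward <- function(params, spec, x, grids, keep = FALSE) {
  a <- spec$leaky_alpha
  h <- x  # 1 x N matrix
  enc_act <- vector("list", spec$depth)
  enc_in <- vector("list", spec$depth)
  enc_z <- vector("list", spec$depth)
  pool_arg <- vector("list", spec$depth)
  for (s in seq_len(spec$depth)) {
    enc_in[[s]] <- h
    z <- cpp_conv3d_fwd(h, grids$dims[[s]], params$enc[[s]]$W, params$enc[[s]]$b)
    enc_z[[s]] <- z
    act <- leaky(z, a)
    enc_act[[s]] <- act
    pooled <- cpp_maxpool_fwd(act, grids$dims[[s]])
    h <- pooled$y
    pool_arg[[s]] <- pooled$argmax
  }
  dec_in <- vector("list", spec$depth)
  dec_z <- vector("list", spec$depth)
  for (s in rev(seq_len(spec$depth))) {
    h_up <- h[, grids$upmap[[s]], drop = FALSE]
    cat_in <- rbind(h_up, enc_act[[s]])
    dec_in[[s]] <- cat_in
    z <- cpp_conv3d_fwd(cat_in, grids$dims[[s]], params$dec[[s]]$W,
                        params$dec[[s]]$b)
    dec_z[[s]] <- z
    h <- leaky(z, a)
  }
  logits <- crossprod(params$head$W, h) + params$head$b
  out <- if (spec$final == "softmax") {
    e <- exp(sweep(logits, 2, apply(logits, 2, max), `-`))
    sweep(e, 2, colSums(e), `/`)
  } else {
    1 / (1 + exp(-logits))
  }
  res <- list(prob = out)
  if (keep)
    res <- c(res, list(enc_in = enc_in, enc_z = enc_z, enc_act = enc_act,
                       pool_arg = pool_arg, dec_in = dec_in, dec_z = dec_z,
                       head_in = h))
  res
}

unet_backward_chain <- function(params, spec, fwd, dlogits, grids) {
  a <- spec$leaky_alpha
  grads <- list(enc = vector("list", spec$depth),
                dec = vector("list", spec$depth))
  grads$head <- list(W = fwd$head_in %*% t(dlogits), b = rowSums(dlogits))
  dh <- params$head$W %*% dlogits  # gradient at dec level 1 activation
  d_skip_acc <- vector("list", spec$depth)   # gradient into enc_act[s] via skip
  d_coarse_next <- NULL
  for (s in seq_len(spec$depth)) {
    dz <- dh * leaky_grad(fwd$dec_z[[s]], a)
    bw <- cpp_conv3d_bwd(fwd$dec_in[[s]], grids$dims[[s]], params$dec[[s]]$W, dz)
    grads$dec[[s]] <- list(W = bw$dW, b = as.numeric(bw$db))
    up_ch <- nrow(fwd$dec_in[[s]]) - nrow(fwd$enc_act[[s]])
    d_up <- bw$dx[seq_len(up_ch), , drop = FALSE]
    d_skip_acc[[s]] <- bw$dx[-seq_len(up_ch), , drop = FALSE]
    d_pooled <- t(rowsum(t(d_up), group = grids$upmap[[s]]))
    if (s < spec$depth) {
      dh <- d_pooled  # gradient at dec level s+1 activation
    } else {
      d_coarse_next <- d_pooled  # gradient at the bottom pooled map
    }
  }
  # encoder, top of the chain last: go from the bottleneck upwards
  d_pool_out <- d_coarse_next
  for (s in rev(seq_len(spec$depth))) {
    d_act <- cpp_maxpool_bwd(d_pool_out, fwd$pool_arg[[s]],
                             prod(grids$dims[[s]])) + d_skip_acc[[s]]
    dz_e <- d_act * leaky_grad(fwd$enc_z[[s]], a)
    bw_e <- cpp_conv3d_bwd(fwd$enc_in[[s]], grids$dims[[s]],
                           params$enc[[s]]$W, dz_e)
    grads$enc[[s]] <- list(W = bw_e$dW, b = as.numeric(bw_e$db))
    if (s > 1) d_pool_out <- bw_e$dx
  }
  grads
}

adam_init <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_step <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      mh <- m2 / (1 - b1^t)
      vh <- v2 / (1 - b2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, state$m, state$v)
}

prepare_case <- function(vol, spec) {
  v <- normalize_intensity(vol)
  if (!all(vol_shape(v) == spec$input_shape))
    v <- resample(v, spec$input_shape, "linear")
  matrix(as.numeric(v$values), nrow = 1)
}

prepare_target <- function(labels, spec) {
  lb <- labels
  if (!all(vol_shape(lb) == spec$input_shape))
    lb <- resample(lb, spec$input_shape, "nearest")
  lab <- as.integer(lb$values)
  if (spec$final == "sigmoid") {
    matrix(as.numeric(lab > 0), nrow = 1)
  } else {
    tgt <- matrix(0, spec$n_classes, length(lab))
    tgt[cbind(lab + 1L, seq_along(lab))] <- 1
    tgt
  }
}

loss_and_dlogits <- function(spec, prob, target) {
  n <- ncol(prob)
  if (spec$final == "softmax") {
    loss <- wcce_loss(t(target), t(prob), weights = spec$class_weights)
    wt <- spec$class_weights * target             # w_i t_i per voxel
    dlog <- (sweep(prob, 2, colSums(wt), `*`) - wt) / n
  } else {
    loss <- dice_ce_loss(as.numeric(prob), as.numeric(target))
    p <- as.numeric(prob); tg <- as.numeric(target)
    eps <- 1e-7
    den <- sum(p) + sum(tg) + eps
    d_dice_dp <- -2 * (tg * den - sum(p * tg)) / den^2
    pc <- pmin(pmax(p, eps), 1 - eps)
    d_ce_dz <- (pc - tg) / n
    dlog <- matrix(0.5 * d_ce_dz + 0.5 * d_dice_dp * p * (1 - p), nrow = 1)
  }
  list(loss = loss, dlogits = dlog)
}

#' Train a volumetric segmenter on labelled cases
#'
#' Stochastic training (one case per step, Adam) of the U-Net defined by a
#' [segmenter_spec()]. Inputs are min-max normalized and resampled to the
#' spec's grid; targets are one-hot (softmax head) or binary (sigmoid
#' head). Fully deterministic for a given seed.
#'
#' @param spec A [segmenter_spec()].
#' @param cases List of cases, each a list with elements `volume` (CT
#'   [volume()]) and `labels` ([label_volume()]).
#' @param seed Integer seed for weight initialization and case order.
#' @param verbose Print per-epoch losses.
#' @return A trained segmenter handle: list with `spec`, `params`,
#'   `loss_trace` (mean loss per epoch, element 0 = pre-training loss).
#' @export
train_segmenter <- function(spec, cases, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "segmenter_spec"), length(cases) >= 1)
  xs <- lapply(cases, function(cs) prepare_case(cs$volume, spec))
  ts <- lapply(cases, function(cs) prepare_target(cs$labels, spec))
  grids <- unet_grids(spec)
  params <- unet_init(spec, in_channels = 1, seed = seed)
  state <- list(m = adam_init(params), v = adam_init(params))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed + 1L)
  init_loss <- mean(vapply(seq_along(xs), function(i) {
    fwd <- unet_forward(params, spec, xs[[i]], grids, keep = FALSE)
    loss_and_dlogits(spec, fwd$prob, ts[[i]])$loss
  }, numeric(1)))
  trace <- init_loss
  t_step <- 0
  for (epoch in seq_len(spec$epochs)) {
    lr <- lr_at_epoch(spec, epoch)
    order_ <- sample(seq_along(xs))
    losses <- numeric(length(order_))
    for (ii in seq_along(order_)) {
      i <- order_[ii]
      fwd <- unet_forward(params, spec, xs[[i]], grids, keep = TRUE)
      ld <- loss_and_dlogits(spec, fwd$prob, ts[[i]])
      losses[ii] <- ld$loss
      grads <- unet_backward_chain(params, spec, fwd, ld$dlogits, grids)
      t_step <- t_step + 1
      upd <- adam_step(params, grads, state, lr, t_step)
      params <- upd$p
      state <- list(m = upd$m, v = upd$v)
    }
    trace <- c(trace, mean(losses))
    if (verbose)
      message(sprintf("epoch %d: loss %.5f (lr %g)", epoch, mean(losses), lr))
  }
  structure(list(spec = spec, params = params, loss_trace = trace),
            class = "postop_segmenter")
}

#' @rdname train_segmenter
#' @param model A trained segmenter handle.
#' @param ct Input CT [volume()].
#' @return For `segment_with_network`: a [label_volume()] on the input grid
#'   (argmax labels for the softmax head, 0/1 at probability 0.5 for the
#'   sigmoid head).
#' @export
segment_with_network <- function(model, ct) {
  stopifnot(inherits(model, "postop_segmenter"))
  spec <- model$spec
  grids <- unet_grids(spec)
  x <- prepare_case(ct, spec)
  fwd <- unet_forward(model$params, spec, x, grids, keep = FALSE)
  lab <- if (spec$final == "softmax") {
    max.col(t(fwd$prob)) - 1L
  } else {
    as.integer(fwd$prob[1, ] > 0.5)
  }
  net_spacing <- ct$spacing * vol_shape(ct) / spec$input_shape
  net_origin <- ct$origin + as.numeric(ct$axes %*% ((net_spacing - ct$spacing) / 2))
  lv <- label_volume(array(lab, spec$input_shape),
                     spacing = net_spacing, origin = net_origin,
                     axes = ct$axes,
                     labels = 0:max(1, spec$n_classes - 1))
  if (all(vol_shape(ct) == spec$input_shape)) {
    lv
  } else {
    out <- resample(lv, vol_shape(ct), "nearest")
    label_volume(out$values, ct$spacing, ct$origin, ct$axes, labels = lv$labels)
  }
}
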