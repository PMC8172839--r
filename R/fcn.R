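#' A small trainable fully convolutional network
#'
#' Four convolutional blocks (3x3 conv + ReLU, three of them, then a 1x1
#' conv + sigmoid head) operating at constant spatial resolution, trained
#' with ADAM on the hybrid Dice + cross-entropy loss. It fulfils the
#' predictor contract and exists so the full pipeline — patch sampling,
#' training schedule, stitching, uncertainty — can be exercised end to
#' end on a CPU; large pretrained encoder-decoder backbones plug in
#' behind the same [predict_patch] contract.
#'
#' The first two conv blocks form the "encoder" parameter group, the rest
#' the "decoder", so the encoder-freezing schedule used with pretrained
#' encoders is testable (`pretrained_encoder = TRUE` freezes them for the
#' first two epochs by default).
#'
#' @param channels hidden channel width.
#' @param seed seed for He-normal weight initialization.
#' @param pretrained_encoder declare the encoder as pretrained (enables
#'   encoder freezing during early epochs).
#' @param norm_mean,norm_sd per-channel input normalization constants
#'   stored in the bundle.
#' @return a `mini_fcn` predictor.
#' @export
mini_fcn <- function(channels = 8L, seed = 1L, pretrained_encoder = FALSE,
                     norm_mean = c(0.5, 0.5, 0.5), norm_sd = c(0.25, 0.25, 0.25)) {
  spec <- list(list(k = 3L, cin = 3L, cout = channels, act = "relu"),
               list(k = 3L, cin = channels, cout = channels, act = "relu"),
               list(k = 3L, cin = channels, cout = channels, act = "relu"),
               list(k = 1L, cin = channels, cout = 1L, act = "sigmoid"))
  layers <- with_seed(seed, lapply(spec, function(s) {
    fan_in <- s$k^2 * s$cin
    list(W = matrix(rnorm(fan_in * s$cout, 0, sqrt(2 / fan_in)), fan_in, s$cout),
         b = rep(0, s$cout), k = s$k, act = s$act)
  }))
  structure(list(layers = layers, encoder_layers = c(1L, 2L),
                 pretrained_encoder = pretrained_encoder,
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = c("mini_fcn", "predictor"))
}

fcn_forward <- function(net, x) {
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1]] <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    z <- conv2d_forward(acts[[i]], ly$W, ly$b, ly$k)
    acts[[i + 1]] <- if (ly$act == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

#' @export
predict_patch.mini_fcn <- function(predictor, patch, ...) {
  x <- normalize_patch(patch, predictor$norm_mean, predictor$norm_sd)
  acts <- fcn_forward(predictor, x)
  out <- acts[[length(acts)]]
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Training schedule configuration
#'
#' @param lr initial ADAM learning rate.
#' @param lr_decay_every,lr_decay_factor stepwise deterministic decay:
#'   the rate is multiplied by the factor every so many epochs.
#' @param max_epochs upper bound on epochs.
#' @param patience consecutive validation-loss increases tolerated before
#'   stopping (default 1: stop at the first increase).
#' @param freeze_encoder_epochs epochs during which a declared-pretrained
#'   encoder stays frozen (decoder-only training).
#' @param weights a [loss_weights] for the hybrid loss.
#' @param seed shuffling seed.
#' @export
train_config <- function(lr = 1e-4, lr_decay_every = 4L, lr_decay_factor = 0.5,
                         max_epochs = 10L, patience = 1L,
                         freeze_encoder_epochs = 2L,
                         weights = loss_weights(), seed = 1L) {
  structure(as.list(environment()), class = "train_config")
}

adam_init <- function(layers) {
  lapply(layers, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(ly, st, gW, gb, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$mW <- b1 * st$mW + (1 - b1) * gW
  st$vW <- b2 * st$vW + (1 - b2) * gW^2
  st$mb <- b1 * st$mb + (1 - b1) * gb
  st$vb <- b2 * st$vb + (1 - b2) * gb^2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  ly$W <- ly$W - lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
  ly$b <- ly$b - lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
  list(layer = ly, state = st)
}

fcn_loss_and_grads <- function(net, x, g, w) {
  acts <- fcn_forward(net, x)
  nlay <- length(net$layers)
  p <- matrix(acts[[nlay + 1]], dim(x)[1], dim(x)[2])
  loss <- hybrid_loss(p, g, w)
  dp <- hybrid_loss_grad(p, g, w)
  delta <- array(dp * p * (1 - p), dim = c(dim(x)[1], dim(x)[2], 1L))
  grads <- vector("list", nlay)
  for (i in nlay:1) {
    ly <- net$layers[[i]]
    bk <- conv2d_backward(acts[[i]], ly$W, delta, ly$k)
    grads[[i]] <- list(gW = bk$gW, gb = as.numeric(bk$gb))
    if (i > 1) {
      relu_mask <- (acts[[i]] > 0) + 0
      delta <- bk$gx * relu_mask
    }
  }
  list(loss = loss, grads = grads)
}

fcn_eval_loss <- function(net, patches, masks, w) {
  mean(vapply(seq_along(patches), function(i) {
    x <- normalize_patch(patches[[i]], net$norm_mean, net$norm_sd)
    acts <- fcn_forward(net, x)
    p <- matrix(acts[[length(acts)]], dim(x)[1], dim(x)[2])
    hybrid_loss(p, masks[[i]], w)
  }, 0))
}

#' Train a segmentation predictor on patch/mask pairs
#'
#' ADAM minimization of the hybrid loss with per-patch updates, stepwise
#' deterministic learning-rate decay, optional encoder freezing for the
#' first epochs when the model declares a pretrained encoder, and early
#' stopping on the first validation-loss increase (configurable
#' patience). Returns the weights of the best-validation epoch together
#' with the per-epoch loss history. Fully deterministic for a fixed
#' configuration seed.
#'
#' @param model a [mini_fcn] (or any model with the same layer layout).
#' @param train_patches,train_masks lists of RGB patches and aligned
#'   binary masks.
#' @param val_patches,val_masks held-out pairs driving early stopping.
#' @param config a [train_config].
#' @return list(model, history) where history is a data.frame with
#'   epoch, train_loss, val_loss, lr.
#' @export
train_segmentation_model <- function(model, train_patches, train_masks,
                                     val_patches, val_masks,
                                     config = train_config()) {
  stopifnot(length(train_patches) >= 1,
            length(train_patches) == length(train_masks))
  st <- adam_init(model$layers)
  t_step <- 0L
  best <- list(val = Inf, layers = model$layers, epoch = 0L)
  bad_epochs <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr * config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
    frozen <- if (isTRUE(model$pretrained_encoder) &&
                  epoch <= config$freeze_encoder_epochs)
      model$encoder_layers else integer()
    ord <- with_seed(config$seed + epoch, sample(seq_along(train_patches)))
    losses <- numeric(length(ord))
    for (s in seq_along(ord)) {
      i <- ord[s]
      x <- normalize_patch(train_patches[[i]], model$norm_mean, model$norm_sd)
      lg <- fcn_loss_and_grads(model, x, train_masks[[i]], config$weights)
      losses[s] <- lg$loss
      t_step <- t_step + 1L
      for (li in seq_along(model$layers)) {
        if (li %in% frozen) next
        up <- adam_step(model$layers[[li]], st[[li]],
                        lg$grads[[li]]$gW, lg$grads[[li]]$gb, lr, t_step)
        model$layers[[li]] <- up$layer
        st[[li]] <- up$state
      }
    }
    val_loss <- if (length(val_patches))
      fcn_eval_loss(model, val_patches, val_masks, config$weights) else mean(losses)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_loss = val_loss, lr = lr))
    if (val_loss < best$val) {
      best <- list(val = val_loss, layers = model$layers, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model$layers <- best$layers
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Save / load a predictor bundle
#'
#' The bundle is a directory holding the layer weights (RDS) and a JSON
#' manifest with normalization constants and architecture metadata.
#' @param model a `mini_fcn`.
#' @param path bundle directory.
#' @export
save_predictor_bundle <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$layers, file.path(path, "weights.rds"))
  meta <- list(class = "mini_fcn", norm_mean = model$norm_mean,
               norm_sd = model$norm_sd,
               pretrained_encoder = model$pretrained_encoder,
               encoder_layers = model$encoder_layers)
  jsonlite::write_json(meta, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_predictor_bundle
#' @export
load_predictor_bundle <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "bundle.json"), simplifyVector = TRUE)
  structure(list(layers = readRDS(file.path(path, "weights.rds")),
                 encoder_layers = meta$encoder_layers,
                 pretrained_encoder = meta$pretrained_encoder,
                 norm_mean = meta$norm_mean, norm_sd = meta$norm_sd),
            class = c("mini_fcn", "predictor"))
}
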