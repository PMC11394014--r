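#' Iterations per training epoch
#'
#' One epoch visits the training pool once in minibatches:
#' `floor(pool_size / minibatch)` iterations (e.g. 86,400 patch samples at
#' minibatch 16 give 5,400 iterations per epoch).
#'
#' @param pool_size Number of training samples in one domain pool.
#' @param minibatch Minibatch size.
#' @return Integer iteration count.
#' @export
iterations_per_epoch <- function(pool_size, minibatch) {
  check_scalar(pool_size, "pool_size", positive = TRUE)
  check_scalar(minibatch, "minibatch", positive = TRUE)
  as.integer(pool_size %/% minibatch)
}

patches_as_array <- function(x, name) {
  if (inherits(x, "patch_batch")) x <- x$patches
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stopf("'%s' must be an H x W x N patch stack", name)
  x
}

# Image-history buffer for discriminator updates (classic cycleGAN trick):
# returns either the incoming fake or a randomly swapped older one.
pool_query <- function(pool, fake) {
  if (pool$capacity <= 0L) return(fake)
  if (length(pool$items) < pool$capacity) {
    pool$items[[length(pool$items) + 1L]] <- fake
    return(fake)
  }
  if (runif(1) < 0.5) {
    i <- sample.int(length(pool$items), 1L)
    old <- pool$items[[i]]
    pool$items[[i]] <- fake
    return(old)
  }
  fake
}

#' Train an unpaired object-to-reference cycleGAN
#'
#' Trains two generator/discriminator pairs on unpaired pools of low-dose
#' ("object") and reference-dose patches with the least-squares adversarial
#' loss, L1 cycle-consistency loss and an SSIM fidelity loss between each
#' translated patch and its input, optimised by Adam. A held-out fraction of
#' the object pool provides a per-epoch validation MSE between object
#' patches and their translated outputs; [select_optimal_epoch()] picks its
#' minimum.
#'
#' @param ref_patches,obj_patches Reference-domain and object-domain training
#'   pools: [extract_patches()] results or `H x W x N` arrays.
#' @param gen_spec [generator_spec()] shared by both generators.
#' @param disc_spec [discriminator_spec()] shared by both discriminators.
#' @param n_epochs Number of epochs.
#' @param lambda_adv,lambda_cycle,lambda_fidelity Non-negative loss weights
#'   (cycleGAN-convention defaults 1 / 10 / 5); at least one must be > 0.
#' @param learning_rate,beta1,beta2 Adam settings (defaults 1e-4, 0.5, 0.999).
#' @param minibatch Minibatch size (default 16).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   image pool; fixed seed gives bit-reproducible training.
#' @param val_fraction Fraction of the object pool held out for validation.
#' @param data_range SSIM dynamic range of the patches.
#' @param pool_capacity Discriminator image-history buffer size (0 disables).
#' @param keep_checkpoints Keep per-epoch generator weights in the result.
#' @param verbose Print per-epoch losses.
#' @return Object of class `"cyclegan_fit"`: generators `G` (object to
#'   reference) and `F` (reference to object), discriminators, `history`
#'   (per-epoch data frame of loss components and validation MSE),
#'   `checkpoints`, `optimal_epoch`, and the materialized `config`.
#' @export
train_cyclegan <- function(ref_patches, obj_patches,
                           gen_spec = generator_spec(depth = 2L,
                                                     base_channels = 8L),
                           disc_spec = discriminator_spec(base_channels = 8L),
                           n_epochs = 3L,
                           lambda_adv = 1, lambda_cycle = 10,
                           lambda_fidelity = 5,
                           learning_rate = 1e-4, beta1 = 0.5, beta2 = 0.999,
                           minibatch = 16L, seed = 1L, val_fraction = 0.1,
                           data_range = 1, pool_capacity = 50L,
                           keep_checkpoints = TRUE, verbose = FALSE) {
  ref <- patches_as_array(ref_patches, "ref_patches")
  obj <- patches_as_array(obj_patches, "obj_patches")
  if (dim(ref)[3] < 1L || dim(obj)[3] < 1L) stopf("empty training pool")
  if (lambda_adv < 0 || lambda_cycle < 0 || lambda_fidelity < 0 ||
      lambda_adv + lambda_cycle + lambda_fidelity <= 0)
    stopf("loss weights must be non-negative with at least one positive")
  minibatch <- as.integer(minibatch)
  n_epochs <- as.integer(n_epochs)

  n_obj <- dim(obj)[3]
  n_val <- max(1L, min(n_obj - 1L, ceiling(val_fraction * n_obj)))
  val_idx <- seq_len(n_val)                 # deterministic head of the pool
  train_obj_idx <- setdiff(seq_len(n_obj), val_idx)
  train_ref_idx <- seq_len(dim(ref)[3])
  n_iter <- max(1L, min(length(train_obj_idx), length(train_ref_idx)) %/%
                  minibatch)

  G <- build_generator(gen_spec, seed)            # object -> reference
  F_ <- build_generator(gen_spec, seed + 1L)      # reference -> object
  D_ref <- build_discriminator(disc_spec, seed + 2L)
  D_obj <- build_discriminator(disc_spec, seed + 3L)
  optG <- adam_new(G, learning_rate, beta1, beta2)
  optF <- adam_new(F_, learning_rate, beta1, beta2)
  optDr <- adam_new(D_ref, learning_rate, beta1, beta2)
  optDo <- adam_new(D_obj, learning_rate, beta1, beta2)

  pool_ref <- new.env(); pool_ref$items <- list(); pool_ref$capacity <- pool_capacity
  pool_obj <- new.env(); pool_obj$items <- list(); pool_obj$capacity <- pool_capacity

  take <- function(arr, idx) {
    d <- dim(arr)
    array(arr[, , idx], c(d[1], d[2], 1L, length(idx)))
  }
  # One translate-and-backprop pass through generator `gen` (assisted by
  # `other` for the cycle), accumulating both generators' gradients; returns
  # the loss components and the detached fake batch.
  gen_pass <- function(gen, other, disc, x) {
    fake <- gen$forward(x)
    cyc <- other$forward(fake)
    cg <- cycle_loss_grad(cyc, x)
    g_fake <- other$backward(lambda_cycle * cg$grad)
    l_adv <- 0
    if (lambda_adv > 0) {
      sc <- disc$forward(fake)
      ag <- adversarial_loss_grad(sc, TRUE)
      g_fake <- g_fake + disc$backward(lambda_adv * ag$grad)
      l_adv <- ag$loss
    }
    l_fid <- 0
    if (lambda_fidelity > 0) {
      sg <- ssim_with_grad(fake, x, data_range)
      g_fake <- g_fake + lambda_fidelity * sg$grad
      l_fid <- sg$loss
    }
    gen$backward(g_fake)
    list(adv = l_adv, cycle = cg$loss, fid = l_fid, fake = fake)
  }
  disc_pass <- function(disc, opt, real, fake) {
    zero_grads(disc)
    sr <- disc$forward(real)
    gr <- adversarial_loss_grad(sr, TRUE)
    disc$backward(0.5 * gr$grad)
    sf <- disc$forward(fake)
    gf <- adversarial_loss_grad(sf, FALSE)
    disc$backward(0.5 * gf$grad)
    adam_step(opt)
    0.5 * (gr$loss + gf$loss)
  }
  val_mse <- function() {
    xs <- take(obj, val_idx)
    mse(G$forward(xs), xs)
  }

  history <- data.frame()
  checkpoints <- list()
  with_seed(seed + 7L, {
    for (epoch in seq_len(n_epochs)) {
      ord_o <- sample(train_obj_idx)
      ord_r <- sample(train_ref_idx)
      acc <- c(G_total = 0, adv = 0, cycle = 0, fid = 0, D = 0)
      for (it in seq_len(n_iter)) {
        io <- ord_o[((it - 1L) * minibatch + 1L):(it * minibatch)]
        ir <- ord_r[((it - 1L) * minibatch + 1L):(it * minibatch)]
        x <- take(obj, io)                  # object (low dose)
        y <- take(ref, ir)                  # reference
        zero_grads(G); zero_grads(F_)
        px <- gen_pass(G, F_, D_ref, x)
        py <- gen_pass(F_, G, D_obj, y)
        adam_step(optG); adam_step(optF)
        l_d <- 0
        if (lambda_adv > 0) {
          l_d <- disc_pass(D_ref, optDr, y, pool_query(pool_ref, px$fake)) +
                 disc_pass(D_obj, optDo, x, pool_query(pool_obj, py$fake))
        }
        zero_grads(D_ref); zero_grads(D_obj)
        g_tot <- lambda_adv * (px$adv + py$adv) +
                 lambda_cycle * (px$cycle + py$cycle) +
                 lambda_fidelity * (px$fid + py$fid)
        acc <- acc + c(g_tot, px$adv + py$adv, px$cycle + py$cycle,
                       px$fid + py$fid, l_d)
      }
      acc <- acc / n_iter
      vm <- val_mse()
      history <- rbind(history, data.frame(
        epoch = epoch, loss_G_total = acc[["G_total"]],
        loss_adv = acc[["adv"]], loss_cycle = acc[["cycle"]],
        loss_fidelity = acc[["fid"]], loss_D = acc[["D"]], val_mse = vm))
      if (keep_checkpoints)
        checkpoints[[epoch]] <- list(G = get_weights(G), F = get_weights(F_))
      if (verbose)
        message(sprintf("epoch %d: G %.4f (adv %.4f cyc %.4f fid %.4f) D %.4f val MSE %.5f",
                        epoch, acc[["G_total"]], acc[["adv"]], acc[["cycle"]],
                        acc[["fid"]], acc[["D"]], vm))
    }
  })
  rownames(history) <- NULL
  structure(list(G = G, F = F_, D_ref = D_ref, D_obj = D_obj,
                 history = history, checkpoints = checkpoints,
                 optimal_epoch = select_optimal_epoch(history$val_mse),
                 config = list(gen_spec = gen_spec, disc_spec = disc_spec,
                               n_epochs = n_epochs, lambda_adv = lambda_adv,
                               lambda_cycle = lambda_cycle,
                               lambda_fidelity = lambda_fidelity,
                               learning_rate = learning_rate, beta1 = beta1,
                               beta2 = beta2, minibatch = minibatch,
                               seed = as.integer(seed),
                               iterations_per_epoch = n_iter,
                               val_fraction = val_fraction,
                               data_range = data_range,
                               pool_capacity = pool_capacity)),
            class = "cyclegan_fit")
}

#' @export
print.cyclegan_fit <- function(x, ...) {
  cat(sprintf("cycleGAN fit (%s generators): %d epochs x %d iterations, optimal epoch %d\n",
              x$config$gen_spec$kind, nrow(x$history),
              x$config$iterations_per_epoch, x$optimal_epoch))
  print(x$history, digits = 4)
  invisible(x)
}

#' Restore generator weights from a stored checkpoint
#'
#' @param fit A [train_cyclegan()] result with kept checkpoints.
#' @param epoch Epoch index; defaults to `fit$optimal_epoch`.
#' @return The fit, with both generators set to the checkpointed weights.
#' @export
restore_checkpoint <- function(fit, epoch = fit$optimal_epoch) {
  stopifnot(inherits(fit, "cyclegan_fit"))
  if (epoch < 1L || epoch > length(fit$checkpoints) ||
      is.null(fit$checkpoints[[epoch]]))
    stopf("no checkpoint stored for epoch %s", epoch)
  set_weights(fit$G, fit$checkpoints[[epoch]]$G)
  set_weights(fit$F, fit$checkpoints[[epoch]]$F)
  invisible(fit)
}
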