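# Minimal reverse-mode network layers on (H, W, C, N) tensors.
#
# Each layer is an environment with $fwd(x), $bwd(gy) and, when it owns
# parameters, $par and $grad (parallel named lists of arrays).  Backward
# passes ACCUMULATE into $grad, so callers zero grads between optimizer
# steps.  Modules (nn-blocks.R) compose layers and expose the same protocol.

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e
}

zero_like <- function(p) lapply(p, function(a) { a[] <- 0; a })

#' @noRd
nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = k %/% 2L,
                    gain = sqrt(2)) {
  l <- new_layer("conv")
  sd0 <- gain / sqrt(k * k * in_ch)
  l$par <- list(w = array(rnorm(k * k * in_ch * out_ch, sd = sd0),
                          c(k, k, in_ch, out_ch)),
                b = numeric(out_ch))
  l$grad <- zero_like(l$par)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$fwd <- function(x) {
    x <- as_tensor(x)
    l$x <- x
    l$y_dim <- NULL
    y <- conv2d_fwd_cpp(x, dim(x), l$par$w, dim(l$par$w), l$par$b,
                        l$stride, l$pad)
    l$y_dim <- dim(y)
    y
  }
  l$bwd <- function(gy) {
    gy <- as_tensor(gy)
    gw <- conv2d_bwd_weight_cpp(l$x, dim(l$x), gy, dim(gy), dim(l$par$w),
                                l$stride, l$pad)
    l$grad$w <- l$grad$w + gw$gw
    l$grad$b <- l$grad$b + gw$gb
    conv2d_bwd_input_cpp(gy, dim(gy), l$par$w, dim(l$par$w), dim(l$x),
                         l$stride, l$pad)
  }
  l
}

#' @noRd
nn_inorm <- function(ch, eps = 1e-5) {
  l <- new_layer("inorm")
  l$par <- list(g = rep(1, ch), b = numeric(ch))
  l$grad <- zero_like(l$par)
  l$eps <- eps
  l$fwd <- function(x) {
    x <- as_tensor(x)
    d <- dim(x); hw <- d[1] * d[2]; cn <- d[3] * d[4]
    xm <- matrix(x, hw, cn)
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    sdv <- sqrt(pmax(v, 0) + l$eps)
    xhat <- sweep(sweep(xm, 2, mu, "-"), 2, sdv, "/")
    gc_ <- rep(l$par$g, times = d[4]); bc <- rep(l$par$b, times = d[4])
    y <- sweep(sweep(xhat, 2, gc_, "*"), 2, bc, "+")
    l$xhat <- xhat; l$sdv <- sdv; l$gc <- gc_; l$d <- d
    array(y, d)
  }
  l$bwd <- function(gy) {
    d <- l$d; hw <- d[1] * d[2]
    gym <- matrix(as_tensor(gy), hw, d[3] * d[4])
    gg <- rowSums(matrix(colSums(gym * l$xhat), d[3], d[4]))
    gb <- rowSums(matrix(colSums(gym), d[3], d[4]))
    l$grad$g <- l$grad$g + gg
    l$grad$b <- l$grad$b + gb
    dxh <- sweep(gym, 2, l$gc, "*")
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * l$xhat)
    gx <- sweep(sweep(dxh, 2, m1, "-") - sweep(l$xhat, 2, m2, "*"),
                2, l$sdv, "/")
    array(gx, d)
  }
  l
}

#' @noRd
nn_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(x) { x <- as_tensor(x); l$mask <- x > 0; x * l$mask }
  l$bwd <- function(gy) as_tensor(gy) * l$mask
  l
}

#' @noRd
nn_lrelu <- function(alpha = 0.2) {
  l <- new_layer("lrelu")
  l$alpha <- alpha
  l$fwd <- function(x) {
    x <- as_tensor(x); l$mask <- x > 0
    x * ifelse(l$mask, 1, l$alpha)
  }
  l$bwd <- function(gy) as_tensor(gy) * ifelse(l$mask, 1, l$alpha)
  l
}

#' @noRd
nn_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$fwd <- function(x) { l$y <- 1 / (1 + exp(-as_tensor(x))); l$y }
  l$bwd <- function(gy) as_tensor(gy) * l$y * (1 - l$y)
  l
}

#' @noRd
nn_upsample2 <- function() {
  l <- new_layer("upsample2")
  l$fwd <- function(x) {
    x <- as_tensor(x); d <- dim(x)
    l$d <- d
    y <- x[rep(seq_len(d[1]), each = 2L),
           rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
    y
  }
  l$bwd <- function(gy) {
    gy <- as_tensor(gy); d <- l$d
    r1 <- seq(1L, 2L * d[1], by = 2L); c1 <- seq(1L, 2L * d[2], by = 2L)
    gy[r1, c1, , , drop = FALSE] + gy[r1 + 1L, c1, , , drop = FALSE] +
      gy[r1, c1 + 1L, , , drop = FALSE] + gy[r1 + 1L, c1 + 1L, , , drop = FALSE]
  }
  l
}

# 1-D linear-interpolation matrix mapping a length-`from` axis to `to`
# samples (pixel-centre alignment, clamped at the ends).
resize_matrix <- function(to, from) {
  if (to == from) return(diag(from))
  M <- matrix(0, to, from)
  for (i in seq_len(to)) {
    s <- (i - 0.5) * from / to + 0.5   # fractional source index, 1-based
    s0 <- floor(s); f <- s - s0
    s0 <- min(max(s0, 1L), from)
    s1 <- min(s0 + 1L, from)
    M[i, s0] <- M[i, s0] + (1 - f)
    M[i, s1] <- M[i, s1] + f
  }
  M
}

# Bilinear spatial resize (per channel/sample) with exact adjoint backward.
nn_resize <- function(target_hw) {
  l <- new_layer("resize")
  l$target <- as.integer(target_hw)
  l$fwd <- function(x) {
    x <- as_tensor(x); d <- dim(x)
    l$d <- d
    if (all(d[1:2] == l$target)) { l$identity <- TRUE; return(x) }
    l$identity <- FALSE
    l$Ry <- resize_matrix(l$target[1], d[1])
    l$Rx <- resize_matrix(l$target[2], d[2])
    y <- array(0, c(l$target, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      y[, , c, n] <- l$Ry %*% x[, , c, n] %*% t(l$Rx)
    y
  }
  l$bwd <- function(gy) {
    gy <- as_tensor(gy)
    if (l$identity) return(gy)
    d <- l$d
    gx <- array(0, d)
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      gx[, , c, n] <- t(l$Ry) %*% gy[, , c, n] %*% l$Rx
    gx
  }
  l
}

# --- parameter plumbing -----------------------------------------------------

# Depth-first collection of parameterised layer environments from a layer or
# module (modules expose $children, a list of layers/modules).
collect_param_layers <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is.list(e)) { lapply(e, walk); return(invisible()) }
    if (!is.environment(e)) return(invisible())
    if (!is.null(e$par)) out[[length(out) + 1L]] <<- e
    if (!is.null(e$children)) walk(e$children)
  }
  walk(x)
  out
}

#' Number of trainable parameters in a network
#' @param net A network built by [build_generator()] or
#'   [build_discriminator()].
#' @return Integer parameter count.
#' @export
count_params <- function(net) {
  sum(vapply(collect_param_layers(net),
             function(l) sum(vapply(l$par, length, integer(1))), numeric(1)))
}

zero_grads <- function(net) {
  for (l in collect_param_layers(net)) l$grad <- zero_like(l$grad)
  invisible(net)
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(net, lr = 1e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_param_layers(net)
  st <- new.env(parent = emptyenv())
  st$layers <- layers
  st$m <- lapply(layers, function(l) zero_like(l$par))
  st$v <- lapply(layers, function(l) zero_like(l$par))
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$layers)) {
    l <- st$layers[[i]]
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      st$m[[i]][[nm]] <- st$beta1 * st$m[[i]][[nm]] + (1 - st$beta1) * g
      st$v[[i]][[nm]] <- st$beta2 * st$v[[i]][[nm]] + (1 - st$beta2) * g * g
      mh <- st$m[[i]][[nm]] / bc1
      vh <- st$v[[i]][[nm]] / bc2
      l$par[[nm]] <- l$par[[nm]] - st$lr * mh / (sqrt(vh) + st$eps)
    }
  }
  invisible(st)
}

# Snapshot / restore of all parameters (checkpointing).
get_weights <- function(net) lapply(collect_param_layers(net), function(l) l$par)

set_weights <- function(net, weights) {
  layers <- collect_param_layers(net)
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) layers[[i]]$par <- weights[[i]]
  invisible(net)
}
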