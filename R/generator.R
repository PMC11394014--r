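#' Generator architecture specification
#'
#' Declarative description of the three interchangeable generators: `"rSEAG"`
#' (residual U-Net with a squeeze-and-excitation bridge and an attention gate
#' on every skip connection), `"ResUNet"` (residual U-Net, no SE/AG) and
#' `"U-Net"` (plain double-conv blocks, no residual paths). All three share
#' the same input/output contract: one-channel images in, one-channel images
#' of the same size out, linear final activation.
#'
#' @param kind One of `"rSEAG"`, `"ResUNet"`, `"U-Net"`.
#' @param depth Number of encoder/decoder levels (>= 1); inputs must be
#'   divisible by `2^depth`.
#' @param base_channels Channels at the first level; doubled per level.
#' @param in_channels,out_channels Image channels (default 1).
#' @param se_reduction Bottleneck reduction ratio of the SE block.
#' @return Object of class `"generator_spec"`.
#' @export
generator_spec <- function(kind = c("rSEAG", "ResUNet", "U-Net"),
                           depth = 4L, base_channels = 64L,
                           in_channels = 1L, out_channels = 1L,
                           se_reduction = 16L) {
  kind <- match.arg(kind)
  depth <- as.integer(depth); base_channels <- as.integer(base_channels)
  if (depth < 1L) stopf("'depth' must be >= 1")
  if (base_channels < 1L) stopf("'base_channels' must be >= 1")
  structure(list(kind = kind, depth = depth, base_channels = base_channels,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 norm = "instance", final_activation = "linear",
                 se_reduction = as.integer(se_reduction)),
            class = "generator_spec")
}

#' Build a generator network
#'
#' Instantiates the network graph of a [generator_spec()] with He-normal
#' initial weights drawn deterministically from `seed`. The rSEAG graph is:
#' encoder residual blocks with strided-conv downsampling, a residual bridge
#' followed by a squeeze-and-excitation block, and a decoder of
#' nearest-neighbour upsampling convolutions whose skip connections each pass
#' through an attention gate (gated by the decoder-side signal) before
#' concatenation.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `"dbt_network"` with `$forward(x)` and
#'   `$backward(gy)` closures operating on `(H, W, C, N)` tensors, plus
#'   structural fields `n_attention_gates` and `n_se_blocks`.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth
  chans <- spec$base_channels * 2^(0:d)     # level i has chans[i]; bridge chans[d+1]
  residual <- spec$kind %in% c("rSEAG", "ResUNet")
  block <- if (residual) mod_residual_block else mod_double_conv

  net <- with_seed(seed, {
    enc <- list(); down <- list(); up <- list(); fuse <- list(); ag <- list()
    for (i in seq_len(d)) {
      enc[[i]] <- block(if (i == 1L) spec$in_channels else chans[i],
                        chans[i])
      down[[i]] <- mod_seq(nn_conv(chans[i], chans[i + 1L], stride = 2L),
                           nn_inorm(chans[i + 1L]), nn_relu())
      up[[i]] <- mod_seq(nn_upsample2(), nn_conv(chans[i + 1L], chans[i]),
                         nn_inorm(chans[i]), nn_relu())
      fuse[[i]] <- mod_seq(nn_conv(2L * chans[i], chans[i]),
                           nn_inorm(chans[i]), nn_relu())
      if (spec$kind == "rSEAG")
        ag[[i]] <- mod_attention_gate(chans[i], chans[i])
    }
    bridge <- block(chans[d + 1L], chans[d + 1L])
    se <- if (spec$kind == "rSEAG") mod_se(chans[d + 1L], spec$se_reduction)
    final <- nn_conv(chans[1L], spec$out_channels)
    list(enc = enc, down = down, bridge = bridge, se = se, up = up,
         ag = ag, fuse = fuse, final = final)
  })

  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$seed <- as.integer(seed)
  e$children <- net
  e$n_attention_gates <- length(net$ag)
  e$n_se_blocks <- if (is.null(net$se)) 0L else 1L
  e$n_residual_blocks <- if (residual) d + 1L else 0L

  e$forward <- function(x) {
    x <- as_tensor(x)
    hw <- dim(x)[1:2]
    if (any(hw %% 2^d != 0L))
      stopf("input size %d x %d not divisible by 2^depth = %d",
            hw[1], hw[2], 2^d)
    s <- vector("list", d)
    for (i in seq_len(d)) {
      s[[i]] <- net$enc[[i]]$fwd(x)
      x <- net$down[[i]]$fwd(s[[i]])
    }
    x <- net$bridge$fwd(x)
    if (!is.null(net$se)) x <- net$se$fwd(x)
    for (i in rev(seq_len(d))) {
      u <- net$up[[i]]$fwd(x)
      skip <- if (spec$kind == "rSEAG") net$ag[[i]]$fwd2(s[[i]], u)
              else s[[i]]
      dd <- dim(u); c_i <- chans[i]
      cc <- array(0, c(dd[1], dd[2], 2L * c_i, dd[4]))
      cc[, , seq_len(c_i), ] <- skip
      cc[, , c_i + seq_len(c_i), ] <- u
      x <- net$fuse[[i]]$fwd(cc)
    }
    net$final$fwd(x)
  }

  e$backward <- function(gy) {
    g <- net$final$bwd(as_tensor(gy))
    gskip <- vector("list", d)
    for (i in seq_len(d)) {               # decoder ran i = d..1; reverse
      gcc <- net$fuse[[i]]$bwd(g)
      c_i <- chans[i]
      gs <- gcc[, , seq_len(c_i), , drop = FALSE]
      gu <- gcc[, , c_i + seq_len(c_i), , drop = FALSE]
      if (spec$kind == "rSEAG") {
        r <- net$ag[[i]]$bwd2(gs)
        gskip[[i]] <- r$gy
        gu <- gu + r$gomega
      } else gskip[[i]] <- gs
      g <- net$up[[i]]$bwd(gu)
    }
    if (!is.null(net$se)) g <- net$se$bwd(g)
    g <- net$bridge$bwd(g)
    for (i in rev(seq_len(d))) {
      g <- net$down[[i]]$bwd(g) + gskip[[i]]
      g <- net$enc[[i]]$bwd(g)
    }
    g
  }
  class(e) <- "dbt_network"
  e
}

#' PatchGAN discriminator specification
#'
#' @param base_channels Channels of the first convolution.
#' @param n_layers Number of stride-2 downsampling convolutions.
#' @param in_channels Image channels.
#' @return Object of class `"discriminator_spec"`.
#' @export
discriminator_spec <- function(base_channels = 64L, n_layers = 2L,
                               in_channels = 1L) {
  base_channels <- as.integer(base_channels); n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stopf("'n_layers' must be >= 1")
  structure(list(base_channels = base_channels, n_layers = n_layers,
                 in_channels = as.integer(in_channels), norm = "instance"),
            class = "discriminator_spec")
}

#' Build a PatchGAN discriminator
#'
#' Stack of 4x4 convolutions (stride 2 for the first `n_layers`, then two
#' stride-1 layers) with instance normalization and leaky ReLU, ending in a
#' one-channel map of patch realness scores: the output is a spatial score
#' map, never a scalar.
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `"dbt_network"` with `$forward` / `$backward`.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  b <- spec$base_channels
  net <- with_seed(seed, {
    layers <- list(nn_conv(spec$in_channels, b, k = 4L, stride = 2L, pad = 1L),
                   nn_lrelu())
    ch <- b
    if (spec$n_layers > 1L) for (i in 2:spec$n_layers) {
      layers <- c(layers, list(nn_conv(ch, 2L * ch, k = 4L, stride = 2L,
                                       pad = 1L),
                               nn_inorm(2L * ch), nn_lrelu()))
      ch <- 2L * ch
    }
    layers <- c(layers,
                list(nn_conv(ch, 2L * ch, k = 4L, stride = 1L, pad = 1L),
                     nn_inorm(2L * ch), nn_lrelu(),
                     nn_conv(2L * ch, 1L, k = 4L, stride = 1L, pad = 1L)))
    do.call(mod_seq, layers)
  })
  e <- new.env(parent = emptyenv())
  e$spec <- spec
  e$seed <- as.integer(seed)
  e$children <- list(net)
  e$forward <- function(x) net$fwd(as_tensor(x))
  e$backward <- function(gy) net$bwd(as_tensor(gy))
  class(e) <- "dbt_network"
  e
}

#' @export
print.dbt_network <- function(x, ...) {
  kind <- if (inherits(x$spec, "generator_spec")) x$spec$kind else "PatchGAN"
  cat(sprintf("%s network, %d parameters (seed %d)\n",
              kind, count_params(x), x$seed))
  invisible(x)
}

#' Run a network on a stack of images
#'
#' Convenience wrapper: accepts a matrix, an `H x W x N` stack or a 4-D
#' tensor, and returns the network output with singleton channel dropped
#' (matrix in, matrix out).
#'
#' @param net A `"dbt_network"`.
#' @param images Matrix, 3-D stack or 4-D tensor.
#' @return Output of matching arrangement.
#' @export
network_apply <- function(net, images) {
  if (is.matrix(images)) {
    y <- net$forward(as_tensor(images))
    return(y[, , 1L, 1L])
  }
  if (length(dim(images)) == 3L) {
    d <- dim(images)
    x <- array(images, c(d[1], d[2], 1L, d[3]))
    y <- net$forward(x)
    return(array(y[, , 1L, ], c(dim(y)[1], dim(y)[2], d[3])))
  }
  net$forward(images)
}
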