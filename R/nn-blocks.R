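# Composite network modules (residual block, SE, attention gate) plus
# exported functional forms of the attention gate and SE transform used for
# direct numerical checks.

new_module <- function(type, children) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- children
  e
}

mod_seq <- function(...) {
  m <- new_module("seq", list(...))
  m$fwd <- function(x) { for (l in m$children) x <- l$fwd(x); x }
  m$bwd <- function(gy) { for (l in rev(m$children)) gy <- l$bwd(gy); gy }
  m
}

# Pre-activation-free residual block: conv-IN-ReLU-conv-IN plus a (possibly
# projected) identity path, ReLU on the sum.
mod_residual_block <- function(in_ch, out_ch) {
  ch <- list(c1 = nn_conv(in_ch, out_ch), n1 = nn_inorm(out_ch),
             r1 = nn_relu(), c2 = nn_conv(out_ch, out_ch),
             n2 = nn_inorm(out_ch), rout = nn_relu())
  if (in_ch != out_ch) ch$proj <- nn_conv(in_ch, out_ch, k = 1L, pad = 0L)
  m <- new_module("residual_block", ch)
  m$fwd <- function(x) {
    x <- as_tensor(x)
    h <- ch$n2$fwd(ch$c2$fwd(ch$r1$fwd(ch$n1$fwd(ch$c1$fwd(x)))))
    s <- if (is.null(ch$proj)) x else ch$proj$fwd(x)
    ch$rout$fwd(h + s)
  }
  m$bwd <- function(gy) {
    g <- ch$rout$bwd(gy)
    gs <- if (is.null(ch$proj)) g else ch$proj$bwd(g)
    gm <- ch$c1$bwd(ch$n1$bwd(ch$r1$bwd(ch$c2$bwd(ch$n2$bwd(g)))))
    gm + gs
  }
  m
}

# Plain U-Net style double conv (no residual path).
mod_double_conv <- function(in_ch, out_ch) {
  mod_seq(nn_conv(in_ch, out_ch), nn_inorm(out_ch), nn_relu(),
          nn_conv(out_ch, out_ch), nn_inorm(out_ch), nn_relu())
}

# Squeeze-and-excitation: global average pool -> bottleneck MLP (as 1x1
# convs) -> sigmoid channel weights -> rescale.
mod_se <- function(ch, reduction = 16L) {
  cr <- max(1L, ch %/% reduction)
  kids <- list(fc1 = nn_conv(ch, cr, k = 1L, pad = 0L), r = nn_relu(),
               fc2 = nn_conv(cr, ch, k = 1L, pad = 0L), s = nn_sigmoid())
  m <- new_module("se", kids)
  m$fwd <- function(x) {
    x <- as_tensor(x); d <- dim(x)
    m$x <- x; m$d <- d
    z <- array(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])),
               c(1L, 1L, d[3], d[4]))
    s <- kids$s$fwd(kids$fc2$fwd(kids$r$fwd(kids$fc1$fwd(z))))
    m$s <- s
    m$sb <- array(rep(as.vector(s), each = d[1] * d[2]), d)
    x * m$sb
  }
  m$bwd <- function(gy) {
    d <- m$d; hw <- d[1] * d[2]
    gy <- as_tensor(gy)
    gs <- array(colSums(matrix(gy * m$x, hw, d[3] * d[4])),
                c(1L, 1L, d[3], d[4]))
    gz <- kids$fc1$bwd(kids$r$bwd(kids$fc2$bwd(kids$s$bwd(gs))))
    gy * m$sb + array(rep(as.vector(gz) / hw, each = hw), d)
  }
  m
}

# Additive attention gate on a skip connection.  The gating signal is
# resampled to the skip grid bilinearly, both inputs pass through 1x1 maps,
# and the sigmoid of a 1x1 projection of the ReLU sum gives per-pixel
# coefficients in (0,1) that rescale the skip features.
mod_attention_gate <- function(ch_y, ch_g, inter = max(1L, ch_y %/% 2L)) {
  kids <- list(wy = nn_conv(ch_y, inter, k = 1L, pad = 0L),
               wg = nn_conv(ch_g, inter, k = 1L, pad = 0L),
               r = nn_relu(),
               psi = nn_conv(inter, 1L, k = 1L, pad = 0L),
               s = nn_sigmoid())
  m <- new_module("attention_gate", kids)
  m$fwd2 <- function(y, omega) {
    y <- as_tensor(y); omega <- as_tensor(omega)
    d <- dim(y)
    m$rs <- nn_resize(d[1:2])
    wr <- m$rs$fwd(omega)
    f <- kids$r$fwd(kids$wy$fwd(y) + kids$wg$fwd(wr))
    beta <- kids$s$fwd(kids$psi$fwd(f))
    m$y <- y; m$beta <- beta
    m$bb <- beta[, , rep(1L, d[3]), , drop = FALSE]
    y * m$bb
  }
  m$bwd2 <- function(gy_out) {
    gy_out <- as_tensor(gy_out)
    d <- dim(m$y)
    gb_full <- gy_out * m$y
    dim(gb_full) <- c(d[1] * d[2], d[3], d[4])
    gbeta <- array(apply(gb_full, c(1, 3), sum), c(d[1], d[2], 1L, d[4]))
    g <- kids$r$bwd(kids$psi$bwd(kids$s$bwd(gbeta)))
    gy2 <- kids$wy$bwd(g)
    gomega <- m$rs$bwd(kids$wg$bwd(g))
    list(gy = gy_out * m$bb + gy2, gomega = gomega)
  }
  m
}

# --- exported functional forms ---------------------------------------------

ensure_hwc <- function(x, name) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stopf("'%s' must be an H x W x C array", name)
  x
}

as_linmap <- function(W, name) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L)
  if (!is.matrix(W)) stopf("'%s' must be a matrix (channels_in x channels_out)", name)
  W
}

#' Additive attention gate (functional form)
#'
#' Computes `f = ReLU(W_y y + W_omega omega)` pixelwise after bilinear
#' resampling of the gating signal `omega` to the grid of the skip features
#' `y`, then attention coefficients `beta = sigmoid(psi(f))`, strictly inside
#' (0, 1), and returns `y` rescaled by `beta` (broadcast over channels).
#'
#' @param y Skip feature map, `H x W x C` array (a matrix is taken as C = 1).
#' @param omega Gating feature map, `H' x W' x C'` array; resampled to
#'   `H x W` bilinearly if the grids differ.
#' @param params List with 1x1 linear maps `W_y` (C x K), `W_omega` (C' x K)
#'   and `psi` (K x 1 or length-K vector); optional biases `b_y`, `b_omega`,
#'   `b_psi` (default 0). Scalars are accepted for single-channel maps.
#' @return List with `output` (gated `y`, same shape) and `beta`
#'   (`H x W` matrix of attention coefficients).
#' @export
attention_gate <- function(y, omega, params) {
  y <- ensure_hwc(y, "y"); omega <- ensure_hwc(omega, "omega")
  Wy <- as_linmap(params$W_y, "W_y")
  Ww <- as_linmap(params$W_omega, "W_omega")
  psi <- params$psi
  if (is.null(dim(psi))) psi <- matrix(psi, ncol = 1L)
  dy <- dim(y); dw <- dim(omega)
  if (nrow(Wy) != dy[3]) stopf("W_y rows (%d) != channels of y (%d)", nrow(Wy), dy[3])
  if (nrow(Ww) != dw[3]) stopf("W_omega rows (%d) != channels of omega (%d)",
                               nrow(Ww), dw[3])
  if (ncol(Wy) != ncol(Ww) || ncol(Wy) != nrow(psi))
    stopf("inter-channel dimensions of W_y, W_omega and psi must agree")
  if (!all(dw[1:2] == dy[1:2])) {
    Ry <- resize_matrix(dy[1], dw[1]); Rx <- resize_matrix(dy[2], dw[2])
    om <- array(0, c(dy[1], dy[2], dw[3]))
    for (c in seq_len(dw[3])) om[, , c] <- Ry %*% omega[, , c] %*% t(Rx)
    omega <- om
  }
  b_y <- if (is.null(params$b_y)) 0 else params$b_y
  b_w <- if (is.null(params$b_omega)) 0 else params$b_omega
  b_p <- if (is.null(params$b_psi)) 0 else params$b_psi
  n <- dy[1] * dy[2]
  f <- sweep(matrix(y, n) %*% Wy, 2, b_y, "+") +
       sweep(matrix(omega, n) %*% Ww, 2, b_w, "+")
  f <- pmax(f, 0)
  beta <- matrix(1 / (1 + exp(-(f %*% psi + b_p))), dy[1], dy[2])
  out <- y * array(beta, dy)
  list(output = out, beta = beta)
}

#' Squeeze-and-excitation channel reweighting (functional form)
#'
#' Per-channel global average ("squeeze"), bottleneck MLP with ReLU and
#' sigmoid ("excitation"), then channelwise rescaling of the input; every
#' channel weight lies strictly in (0, 1).
#'
#' @param x Feature map, `H x W x C` array (matrix taken as C = 1).
#' @param params List with `W1` (C x C/r), `b1`, `W2` (C/r x C), `b2`;
#'   biases default to 0.
#' @return List with `output` (rescaled map) and `weights` (length-C channel
#'   weights).
#' @export
se_block <- function(x, params) {
  x <- ensure_hwc(x, "x")
  W1 <- as_linmap(params$W1, "W1"); W2 <- as_linmap(params$W2, "W2")
  b1 <- if (is.null(params$b1)) 0 else params$b1
  b2 <- if (is.null(params$b2)) 0 else params$b2
  d <- dim(x)
  if (nrow(W1) != d[3]) stopf("W1 rows (%d) != channels (%d)", nrow(W1), d[3])
  z <- colMeans(matrix(x, d[1] * d[2], d[3]))
  h <- pmax(drop(z %*% W1) + b1, 0)
  w <- 1 / (1 + exp(-(drop(h %*% W2) + b2)))
  out <- x * array(rep(w, each = d[1] * d[2]), d)
  list(output = out, weights = w)
}
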