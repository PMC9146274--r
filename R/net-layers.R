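# Thin R wrappers over the compiled layer primitives, plus batch norm and
# ReLU.  Activations are (H, W, C, N) arrays; kernels (k, k, Cin, Cout).

conv_fwd <- function(x, w, b, stride, pad) .conv_fwd_cpp(x, w, b, stride, pad)
conv_bwd <- function(x, w, dy, stride, pad) .conv_bwd_cpp(x, w, dy, stride, pad)
upconv_fwd <- function(x, w, b) .upconv_fwd_cpp(x, w, b)
upconv_bwd <- function(x, w, dy) .upconv_bwd_cpp(x, w, dy)

relu <- function(x) .relu_cpp(x)

relu_bwd <- function(dy, pre) .relu_bwd_cpp(dy, pre)

bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  if (training) {
    st <- .bn_stats_cpp(x)
    mu <- st$mu; va <- st$var
    m <- dim(x)[1] * dim(x)[2] * dim(x)[4]
    rmean <- (1 - momentum) * rmean + momentum * mu
    # unbiased variance accumulated in the running estimate
    rvar <- (1 - momentum) * rvar + momentum * va * m / max(m - 1, 1)
  } else {
    mu <- rmean; va <- rvar
  }
  inv <- 1 / sqrt(va + eps)
  ap <- .bn_apply_cpp(x, mu, inv, gamma, beta)
  list(y = ap$y, xhat = ap$xhat, inv = inv, rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache, gamma)
  .bn_bwd_cpp(dy, cache$xhat, cache$inv, gamma)

# fan-in-scaled uniform initialisation, U(-sqrt(6/fan_in), +sqrt(6/fan_in))
init_kernel <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin))
  array(runif(k * k * cin * cout, -lim, lim), dim = c(k, k, cin, cout))
}

as_batch <- function(x) {
  # promote a matrix or (H, W, C) array to (H, W, C, N)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}
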