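#' Architecture of the reference three-level U-net baseline
#'
#' A classical U-net with 3 encoder levels, adapted for regression:
#' each encoder block is two (3x3 convolution, ReLU, batch-norm) units
#' followed by 2x2 max pooling; the deepest block applies dropout
#' (p = 0.5) before its pooling; a bridge of two further units at 64
#' channels; decoder blocks of a 2x2 stride-2 transposed convolution
#' plus ReLU, channel concatenation with the matching encoder block, and
#' two (convolution, ReLU, batch-norm) units; a final 1x1 convolution
#' produces the single-channel output.  The batch-norm layers are an
#' addition to the stock design, without which the plain network fails
#' to learn this regression task.  Channel widths are (8, 16, 32)
#' down, 64 at the bridge and (32, 16, 8) up.
#'
#' @param depth number of encoder levels (default 3).
#' @param f0 filter count of the first block (default 8).
#' @param dropout dropout probability before the deepest pooling
#'   (default 0.5).
#' @return An object of class `baseline_unet_spec`.
#' @export
baseline_unet_spec <- function(depth = 3, f0 = 8, dropout = 0.5) {
  stopifnot(depth >= 1, f0 >= 1, dropout >= 0, dropout < 1)
  structure(list(depth = as.integer(depth), f0 = as.integer(f0),
                 dropout = dropout,
                 channels = as.integer(f0 * 2^(seq_len(depth) - 1)),
                 bridge = as.integer(f0 * 2^depth)),
            class = "baseline_unet_spec")
}

#' Build the baseline U-net
#'
#' @param spec a [baseline_unet_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `baseline_unet` (also `restoration_net`).
#' @examples
#' count_parameters(build_baseline_unet())  # 121385
#' @export
build_baseline_unet <- function(spec = baseline_unet_spec(), seed = 1) {
  stopifnot(inherits(spec, "baseline_unet_spec"))
  D <- spec$depth
  ch <- c(1L, spec$channels)
  with_seed(seed, {
    params <- list()
    running <- list()
    unit <- function(tag, cin, cout) {
      params[[paste0(tag, "_w")]] <<- init_kernel(3, cin, cout)
      params[[paste0(tag, "_b")]] <<- numeric(cout)
      params[[paste0(tag, "_gamma")]] <<- rep(1, cout)
      params[[paste0(tag, "_beta")]] <<- numeric(cout)
      running[[paste0(tag, "_mean")]] <<- numeric(cout)
      running[[paste0(tag, "_var")]] <<- rep(1, cout)
    }
    for (i in seq_len(D)) {
      unit(paste0("e", i, "c1"), ch[i], ch[i + 1])
      unit(paste0("e", i, "c2"), ch[i + 1], ch[i + 1])
    }
    unit("brc1", spec$channels[D], spec$bridge)
    unit("brc2", spec$bridge, spec$bridge)
    up_in <- spec$bridge
    for (j in seq_len(D)) {
      cskip <- spec$channels[D - j + 1]
      params[[paste0("d", j, "up_w")]] <- init_kernel(2, up_in, cskip)
      params[[paste0("d", j, "up_b")]] <- numeric(cskip)
      unit(paste0("d", j, "c1"), 2 * cskip, cskip)
      unit(paste0("d", j, "c2"), cskip, cskip)
      up_in <- cskip
    }
    params[["head_w"]] <- init_kernel(1, spec$f0, 1)
    params[["head_b"]] <- numeric(1)
    structure(list(spec = spec, params = params, running = running,
                   eps = 1e-5, momentum = 0.1),
              class = c("baseline_unet", "restoration_net"))
  })
}

#' @export
print.baseline_unet <- function(x, ...) {
  cat(sprintf("Baseline U-net: depth %d, channels %s (bridge %d), %s parameters\n",
              x$spec$depth, paste(x$spec$channels, collapse = "-"),
              x$spec$bridge, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
coef.baseline_unet <- function(object, ...) object$params

.ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

baseline_forward <- function(net, x, training = FALSE, cache = FALSE) {
  sp <- net$spec
  D <- sp$depth
  p <- net$params
  d <- dim(x)
  .check_input_size(d[1], d[2], D)
  cc <- list(units = list(), pools = list(), skips = list())
  run_unit <- function(tag, a) {
    z <- conv_fwd(a, p[[paste0(tag, "_w")]], p[[paste0(tag, "_b")]], 1L, 1L)
    r <- relu(z)
    bn <- bn_fwd(r, p[[paste0(tag, "_gamma")]], p[[paste0(tag, "_beta")]],
                 net$running[[paste0(tag, "_mean")]],
                 net$running[[paste0(tag, "_var")]],
                 training, net$momentum, net$eps)
    if (training) {
      net$running[[paste0(tag, "_mean")]] <<- bn$rmean
      net$running[[paste0(tag, "_var")]] <<- bn$rvar
    }
    if (cache)
      cc$units[[tag]] <<- list(conv_in = a, conv_pre = z,
                               xhat = bn$xhat, inv = bn$inv)
    bn$y
  }
  a <- x
  for (i in seq_len(D)) {
    a <- run_unit(paste0("e", i, "c1"), a)
    a <- run_unit(paste0("e", i, "c2"), a)
    if (i == D && sp$dropout > 0 && training) {
      mask <- array(runif(length(a)) >= sp$dropout, dim(a)) / (1 - sp$dropout)
      a <- a * mask
      if (cache) cc$dropout_mask <- mask
    }
    cc$skips[[i]] <- a
    mp <- .maxpool_fwd_cpp(a)
    if (cache) cc$pools[[i]] <- list(arg = mp$argmax, H = dim(a)[1],
                                     W = dim(a)[2])
    a <- mp$y
  }
  a <- run_unit("brc1", a)
  a <- run_unit("brc2", a)
  for (j in seq_len(D)) {
    tag <- paste0("d", j)
    u_pre <- upconv_fwd(a, p[[paste0(tag, "up_w")]], p[[paste0(tag, "up_b")]])
    if (cache) cc[[paste0(tag, "_up")]] <- list(x = a, pre = u_pre)
    u <- relu(u_pre)
    skip <- cc$skips[[D - j + 1]]
    a <- .ccat(u, skip)
    if (cache) cc[[paste0(tag, "_ccat")]] <- c(dim(u)[3], dim(skip)[3])
    a <- run_unit(paste0(tag, "c1"), a)
    a <- run_unit(paste0(tag, "c2"), a)
  }
  head_pre <- conv_fwd(a, p$head_w, p$head_b, 1L, 0L)
  if (!cache) return(list(y = head_pre, net = net))
  cc$head_in <- a
  list(y = head_pre, net = net, cache = cc)
}

baseline_backward <- function(net, cache, dy) {
  sp <- net$spec
  D <- sp$depth
  p <- net$params
  g <- list()
  unit_bwd <- function(tag, dout) {
    u <- cache$units[[tag]]
    bb <- bn_bwd(dout, list(xhat = u$xhat, inv = u$inv),
                 p[[paste0(tag, "_gamma")]])
    g[[paste0(tag, "_gamma")]] <<- bb$dgamma
    g[[paste0(tag, "_beta")]] <<- bb$dbeta
    dr <- relu_bwd(bb$dx, u$conv_pre)
    bc <- conv_bwd(u$conv_in, p[[paste0(tag, "_w")]], dr, 1L, 1L)
    g[[paste0(tag, "_w")]] <<- bc$dw
    g[[paste0(tag, "_b")]] <<- bc$db
    bc$dx
  }
  bh <- conv_bwd(cache$head_in, p$head_w, dy, 1L, 0L)
  g$head_w <- bh$dw
  g$head_b <- bh$db
  da <- bh$dx
  dskip <- vector("list", D)
  for (j in rev(seq_len(D))) {
    tag <- paste0("d", j)
    da <- unit_bwd(paste0(tag, "c2"), da)
    da <- unit_bwd(paste0(tag, "c1"), da)
    nc <- cache[[paste0(tag, "_ccat")]]
    du <- da[, , seq_len(nc[1]), , drop = FALSE]
    dskip[[D - j + 1]] <- da[, , nc[1] + seq_len(nc[2]), , drop = FALSE]
    up <- cache[[paste0(tag, "_up")]]
    du <- relu_bwd(du, up$pre)
    bu <- upconv_bwd(up$x, p[[paste0(tag, "up_w")]], du)
    g[[paste0(tag, "up_w")]] <- bu$dw
    g[[paste0(tag, "up_b")]] <- bu$db
    da <- bu$dx
  }
  da <- unit_bwd("brc2", da)
  da <- unit_bwd("brc1", da)
  for (i in rev(seq_len(D))) {
    pool <- cache$pools[[i]]
    dpre <- .maxpool_bwd_cpp(da, pool$arg, pool$H, pool$W)
    dpre <- dpre + dskip[[i]]
    if (i == D && !is.null(cache$dropout_mask))
      dpre <- dpre * cache$dropout_mask
    dpre <- unit_bwd(paste0("e", i, "c2"), dpre)
    da <- unit_bwd(paste0("e", i, "c1"), dpre)
  }
  g
}
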