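#' Architecture of the up-convolutional restoration network
#'
#' The network has `L` contracting blocks, each a 3x3 stride-2
#' convolution (mirror padding 1, the edge pixel itself is not
#' duplicated) followed by batch normalisation and ReLU, with channel
#' widths `f0 * 2^(l-1)`.  The expanding path has `L` blocks of a 2x2
#' stride-2 transposed convolution followed by ReLU, with output widths
#' halving from `f0 * 2^(L-1)` down to `f0`.  Every contracting block `l`
#' additionally feeds a dedicated channel-preserving 2x2 stride-2
#' transposed convolution (plus ReLU) whose output is added element-wise
#' to the expanding block producing maps one spatial level finer than the
#' contracting block's own output.  A final 1x1 convolution with ReLU
#' collapses the remaining `f0` maps into the restored frame, which is
#' therefore non-negative by construction.
#'
#' @param L number of blocks (default 5; use 4 for 256x256 frames).
#' @param f0 filter count of the first block (default 8).
#' @return An object of class `upunet_spec`.
#' @examples
#' s <- upunet_spec()
#' s$channels  # 8 16 32 64 128
#' @export
upunet_spec <- function(L = 5, f0 = 8) {
  stopifnot(L >= 1, f0 >= 1)
  structure(list(L = as.integer(L), f0 = as.integer(f0),
                 channels = as.integer(f0 * 2^(seq_len(L) - 1)),
                 decoder_channels = as.integer(f0 * 2^(L - seq_len(L)))),
            class = "upunet_spec")
}

#' Build the up-convolutional restoration network
#'
#' Allocates and seeds all learnable parameters (convolution and
#' transposed-convolution weights and biases, batch-norm scale and
#' offset) for the architecture described in [upunet_spec()].
#'
#' @param spec an [upunet_spec()].
#' @param seed RNG seed for the fan-in-scaled uniform weight
#'   initialisation.
#' @return An object of class `upunet` (also `restoration_net`).
#' @examples
#' net <- build_upunet(upunet_spec(), seed = 1)
#' count_parameters(net)  # 295593
#' @export
build_upunet <- function(spec = upunet_spec(), seed = 1) {
  stopifnot(inherits(spec, "upunet_spec"))
  L <- spec$L
  ch <- c(1L, spec$channels)
  with_seed(seed, {
    params <- list()
    running <- list()
    for (l in seq_len(L)) {
      params[[paste0("enc", l, "_w")]] <- init_kernel(3, ch[l], ch[l + 1])
      params[[paste0("enc", l, "_b")]] <- numeric(ch[l + 1])
      params[[paste0("enc", l, "_gamma")]] <- rep(1, ch[l + 1])
      params[[paste0("enc", l, "_beta")]] <- numeric(ch[l + 1])
      running[[paste0("enc", l, "_mean")]] <- numeric(ch[l + 1])
      running[[paste0("enc", l, "_var")]] <- rep(1, ch[l + 1])
    }
    dch <- c(spec$channels[L], spec$decoder_channels)
    for (j in seq_len(L)) {
      params[[paste0("dec", j, "_w")]] <- init_kernel(2, dch[j], dch[j + 1])
      params[[paste0("dec", j, "_b")]] <- numeric(dch[j + 1])
    }
    for (l in seq_len(L)) {
      cl <- spec$channels[l]
      params[[paste0("skip", l, "_w")]] <- init_kernel(2, cl, cl)
      params[[paste0("skip", l, "_b")]] <- numeric(cl)
    }
    params[["head_w"]] <- init_kernel(1, spec$f0, 1)
    params[["head_b"]] <- numeric(1)
    structure(list(spec = spec, params = params, running = running,
                   eps = 1e-5, momentum = 0.1),
              class = c("upunet", "restoration_net"))
  })
}

.check_input_size <- function(H, W, L) {
  if (H %% 2^L != 0 || W %% 2^L != 0)
    stop("input spatial size ", H, "x", W,
         " is not divisible by 2^L = ", 2^L)
}

# Forward pass; with cache = TRUE all intermediates needed by
# upunet_backward are retained.
upunet_forward <- function(net, x, training = FALSE, cache = FALSE) {
  sp <- net$spec
  L <- sp$L
  p <- net$params
  d <- dim(x)
  .check_input_size(d[1], d[2], L)
  E <- vector("list", L)
  bn_caches <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    z <- conv_fwd(a, p[[paste0("enc", l, "_w")]], p[[paste0("enc", l, "_b")]],
                  2L, 1L)
    bn <- bn_fwd(z, p[[paste0("enc", l, "_gamma")]],
                 p[[paste0("enc", l, "_beta")]],
                 net$running[[paste0("enc", l, "_mean")]],
                 net$running[[paste0("enc", l, "_var")]],
                 training, net$momentum, net$eps)
    if (training) {
      net$running[[paste0("enc", l, "_mean")]] <- bn$rmean
      net$running[[paste0("enc", l, "_var")]] <- bn$rvar
    }
    conv_in <- a
    a <- .relu_ip_cpp(bn$y)  # post-activation sign doubles as the mask
    if (cache)
      bn_caches[[l]] <- list(xhat = bn$xhat, inv = bn$inv,
                             conv_in = conv_in)
    E[[l]] <- a
  }
  dec_in <- vector("list", L)
  dec_post <- vector("list", L)
  skip_post <- vector("list", L)
  z <- E[[L]]
  for (j in seq_len(L)) {
    l <- L - j + 1
    u <- .relu_ip_cpp(upconv_fwd(z, p[[paste0("dec", j, "_w")]],
                                 p[[paste0("dec", j, "_b")]]))
    s <- .relu_ip_cpp(upconv_fwd(E[[l]], p[[paste0("skip", l, "_w")]],
                                 p[[paste0("skip", l, "_b")]]))
    if (cache) {
      dec_in[[j]] <- z
      dec_post[[j]] <- u
      skip_post[[l]] <- s
    }
    z <- .add_cpp(u, s)
  }
  y <- .relu_ip_cpp(conv_fwd(z, p$head_w, p$head_b, 1L, 0L))
  if (!cache) return(list(y = y, net = net))
  list(y = y, net = net,
       cache = list(x = x, E = E, bn = bn_caches, dec_in = dec_in,
                    dec_post = dec_post, skip_post = skip_post,
                    head_in = z, head_out = y))
}

# Backpropagation through the whole graph; returns gradients named like
# the parameters.
upunet_backward <- function(net, cache, dy) {
  sp <- net$spec
  L <- sp$L
  p <- net$params
  g <- list()
  dy <- .relu_bwd_mask_cpp(dy, cache$head_out)
  bh <- conv_bwd(cache$head_in, p$head_w, dy, 1L, 0L)
  g$head_w <- bh$dw
  g$head_b <- bh$db
  dz <- bh$dx
  dE <- vector("list", L)  # gradient w.r.t. encoder activations
  for (j in rev(seq_len(L))) {
    l <- L - j + 1
    du <- .relu_bwd_mask_cpp(dz, cache$dec_post[[j]])
    ds <- .relu_bwd_ip_cpp(dz, cache$skip_post[[l]])  # dz dead after this
    bs <- upconv_bwd(cache$E[[l]], p[[paste0("skip", l, "_w")]], ds)
    g[[paste0("skip", l, "_w")]] <- bs$dw
    g[[paste0("skip", l, "_b")]] <- bs$db
    dE[[l]] <- bs$dx
    bu <- upconv_bwd(cache$dec_in[[j]], p[[paste0("dec", j, "_w")]], du)
    g[[paste0("dec", j, "_w")]] <- bu$dw
    g[[paste0("dec", j, "_b")]] <- bu$db
    dz <- bu$dx
  }
  # dz now targets E[[L]] through the decoder chain; add its skip use
  dE[[L]] <- .add_cpp(dE[[L]], dz)
  da <- NULL
  for (l in rev(seq_len(L))) {
    d_act <- if (is.null(da)) dE[[l]] else .add_cpp(dE[[l]], da)
    d_bn <- .relu_bwd_ip_cpp(d_act, cache$E[[l]])
    bb <- bn_bwd(d_bn, cache$bn[[l]], p[[paste0("enc", l, "_gamma")]])
    g[[paste0("enc", l, "_gamma")]] <- bb$dgamma
    g[[paste0("enc", l, "_beta")]] <- bb$dbeta
    bc <- conv_bwd(cache$bn[[l]]$conv_in, p[[paste0("enc", l, "_w")]],
                   bb$dx, 2L, 1L)
    g[[paste0("enc", l, "_w")]] <- bc$dw
    g[[paste0("enc", l, "_b")]] <- bc$db
    da <- bc$dx
  }
  g
}

#' Count learnable parameters
#'
#' Sums convolution and transposed-convolution weights and biases and
#' batch-norm scale/offset pairs; batch-norm running statistics are not
#' learnable and are excluded.
#'
#' @param net a network built by [build_upunet()] or
#'   [build_baseline_unet()].
#' @return Integer total.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "restoration_net"))
  sum(vapply(net$params, length, integer(1)))
}

#' Restore a single frame
#'
#' Runs one inference-mode forward pass (batch norm uses accumulated
#' running statistics).  The frame side lengths must be divisible by
#' `2^L`.
#'
#' @param net a trained (or freshly built) network.
#' @param frame numeric matrix on the training intensity scale
#'   (`[0, 255]`).
#' @return The restored matrix, element-wise non-negative.
#' @export
restore_frame <- function(net, frame) {
  stopifnot(is.matrix(frame))
  out <- net_forward(net, as_batch(frame), training = FALSE)
  matrix(out$y, nrow(frame), ncol(frame))
}

# forward dispatcher shared by upunet and baseline
net_forward <- function(net, x, training = FALSE, cache = FALSE) {
  if (inherits(net, "upunet")) upunet_forward(net, x, training, cache)
  else baseline_forward(net, x, training, cache)
}

net_backward <- function(net, cache, dy) {
  if (inherits(net, "upunet")) upunet_backward(net, cache, dy)
  else baseline_backward(net, cache, dy)
}

#' @export
print.upunet <- function(x, ...) {
  cat(sprintf("upU-net: %d blocks, channels %s, %s parameters\n",
              x$spec$L, paste(x$spec$channels, collapse = "-"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @rdname summary.restoration_net
#' @export
summary.upunet <- function(object, ...) {
  tab <- layer_table(object)
  cat("upU-net architecture\n")
  print(tab, row.names = FALSE)
  cat(sprintf("Total learnable parameters: %d\n", sum(tab$params)))
  invisible(tab)
}

#' Per-layer parameter table
#'
#' @param object a restoration network.
#' @param ... unused.
#' @return Invisibly, a data frame with one row per parameter tensor
#'   (name, shape, parameter count).
#' @export
summary.restoration_net <- function(object, ...) {
  tab <- layer_table(object)
  print(tab, row.names = FALSE)
  invisible(tab)
}

layer_table <- function(net) {
  data.frame(
    tensor = names(net$params),
    shape = vapply(net$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"),
      character(1)),
    params = vapply(net$params, length, integer(1)),
    row.names = NULL)
}

#' @export
coef.upunet <- function(object, ...) object$params

#' Predict method: restore frames
#'
#' @param object a network.
#' @param newdata a matrix (one frame), a list of matrices, or a
#'   `bead_dataset` (its input frames are restored).
#' @param ... unused.
#' @return A matrix or list of matrices of restored frames.
#' @export
predict.restoration_net <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(restore_frame(object, newdata))
  if (inherits(newdata, "bead_dataset"))
    newdata <- lapply(newdata$pairs, `[[`, "input")
  lapply(newdata, function(f) restore_frame(object, f))
}
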