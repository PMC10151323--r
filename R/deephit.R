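#' Architecture of the hitting-time network
#'
#' Two input branches feed a shared trunk with three cause-specific heads.
#' The image branch applies two convolution blocks (3x3 kernels, batch
#' normalization, leaky-ReLU, 2x2 max-pooling, dropout) to the five-channel
#' 28 x 36 polar-map stack, then a fully connected layer with
#' `image_dense_width` nodes; the 15 clinical features pass through a
#' separate fully connected layer with `clinical_dense_width` nodes.  The
#' concatenated branches feed one shared layer and one layer per event, and
#' a final linear map to the `K x T` logit grid, softmax-normalized over all
#' cells so the output is a joint event-time distribution.
#'
#' @param conv_channels Channel counts of the two convolution blocks.
#' @param image_dense_width Width of the image branch's dense layer.
#' @param clinical_dense_width Width of the clinical branch's dense layer.
#' @param shared_width Width of the shared trunk layer.
#' @param head_width Width of each event-specific layer.
#' @param n_events Number of competing event types K.
#' @param n_clinical Number of clinical features.
#' @param dropout Dropout rate in the convolution blocks.
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @param use_images FALSE builds the clinical-only comparator: the same
#'   network minus the convolutional branch and its dense layer.
#' @return Object of class `arch_config`.
#' @export
arch_config <- function(conv_channels = c(16, 32),
                        image_dense_width = 512,
                        clinical_dense_width = 32,
                        shared_width = 256,
                        head_width = 256,
                        n_events = 3,
                        n_clinical = 15,
                        dropout = 0.3,
                        leaky_slope = 0.01,
                        use_images = TRUE) {
  stopifnot(length(conv_channels) == 2, all(conv_channels > 0),
            n_events >= 1, dropout >= 0, dropout < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 image_dense_width = as.integer(image_dense_width),
                 clinical_dense_width = as.integer(clinical_dense_width),
                 shared_width = as.integer(shared_width),
                 head_width = as.integer(head_width),
                 n_events = as.integer(n_events),
                 n_clinical = as.integer(n_clinical),
                 dropout = dropout, leaky_slope = leaky_slope,
                 use_images = isTRUE(use_images),
                 map_dim = c(5L, 28L, 36L)),
            class = "arch_config")
}

#' Initialize model parameters
#'
#' He-normal weight initialization, zero biases, unit batch-norm scale;
#' deterministic for a given seed.
#'
#' @param arch An [arch_config()].
#' @param grid A [time_grid()].
#' @param seed Integer seed.
#' @return Object of class `deephit_model` holding parameters, running
#'   batch-norm statistics, the architecture and the grid.
#' @export
init_model <- function(arch = arch_config(), grid = time_grid(), seed = 1) {
  C0 <- arch$map_dim[1]; H <- arch$map_dim[2]; W <- arch$map_dim[3]
  C1 <- arch$conv_channels[1]; C2 <- arch$conv_channels[2]
  T_ <- grid$n_bins; K <- arch$n_events
  p <- list()
  with_seed(sub_seed(seed, "init_model"), {
    if (arch$use_images) {
      p$conv1_W <- .he_init(9 * C0, C1, fan_in = 9 * C0)
      p$conv1_b <- numeric(C1)
      p$bn1_g <- rep(1, C1); p$bn1_b <- numeric(C1)
      p$conv2_W <- .he_init(9 * C1, C2, fan_in = 9 * C1)
      p$conv2_b <- numeric(C2)
      p$bn2_g <- rep(1, C2); p$bn2_b <- numeric(C2)
      flat <- C2 * (H %/% 4) * (W %/% 4)
      p$fc_img_W <- .he_init(arch$image_dense_width, flat, fan_in = flat)
      p$fc_img_b <- numeric(arch$image_dense_width)
    }
    p$fc_clin_W <- .he_init(arch$clinical_dense_width, arch$n_clinical,
                            fan_in = arch$n_clinical)
    p$fc_clin_b <- numeric(arch$clinical_dense_width)
    concat <- arch$clinical_dense_width +
      if (arch$use_images) arch$image_dense_width else 0L
    p$shared_W <- .he_init(arch$shared_width, concat, fan_in = concat)
    p$shared_b <- numeric(arch$shared_width)
    for (k in seq_len(K)) {
      p[[paste0("head", k, "_W1")]] <- .he_init(arch$head_width,
                                                arch$shared_width,
                                                fan_in = arch$shared_width)
      p[[paste0("head", k, "_b1")]] <- numeric(arch$head_width)
      p[[paste0("head", k, "_W2")]] <- .he_init(T_, arch$head_width,
                                                fan_in = arch$head_width)
      p[[paste0("head", k, "_b2")]] <- numeric(T_)
    }
  })
  run <- list()
  if (arch$use_images) {
    run$bn1_mean <- numeric(C1); run$bn1_var <- rep(1, C1)
    run$bn2_mean <- numeric(C2); run$bn2_var <- rep(1, C2)
  }
  structure(list(params = p, running = run, arch = arch, grid = grid,
                 seed = seed, preprocess = NULL),
            class = "deephit_model")
}

#' @export
print.deephit_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("deephit_model: %s branch, K=%d, T=%d, %d parameters\n",
              if (x$arch$use_images) "image+clinical" else "clinical-only",
              x$arch$n_events, x$grid$n_bins, np))
  invisible(x)
}

#' Count of trainable parameters
#' @param model A `deephit_model`.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, 0L))

# full forward pass; maps: (n, 5, 28, 36) array (ignored by the
# clinical-only architecture), clinical: n x 15 matrix of normalized values.
# Returns logits (K*T x n), pmf, and (when cache=TRUE) every intermediate
# needed by the backward pass.
.net_forward <- function(model, maps, clinical, training = FALSE,
                         cache = FALSE) {
  a <- model$arch; p <- model$params
  H <- a$map_dim[2]; W <- a$map_dim[3]; C0 <- a$map_dim[1]
  C1 <- a$conv_channels[1]; C2 <- a$conv_channels[2]
  n <- nrow(clinical)
  cc <- list()
  if (a$use_images) {
    if (is.null(maps)) stop("this architecture requires polar maps")
    H2 <- H %/% 2L; W2 <- W %/% 2L; H4 <- H %/% 4L; W4 <- W %/% 4L
    X <- aperm(maps, c(3, 4, 1, 2))          # (H, W, n, C)
    cv1 <- conv_fwd_direct(X, p$conv1_W, p$conv1_b, H, W, n, C0)
    if (training) {
      bl1 <- bn_lrelu_fwd_train(cv1, C1, p$bn1_g, p$bn1_b, a$leaky_slope,
                                1e-5)
    } else {
      bl1 <- list(out = bn_lrelu_fwd_eval(cv1, C1, p$bn1_g, p$bn1_b,
                                          model$running$bn1_mean,
                                          model$running$bn1_var,
                                          a$leaky_slope, 1e-5))
    }
    pl1 <- pool_fwd(bl1$out, H, W, n, C1)
    dr1 <- .dropout_forward(pl1$out, a$dropout, training)
    cv2 <- conv_fwd_direct(dr1$out, p$conv2_W, p$conv2_b, H2, W2, n, C1)
    if (training) {
      bl2 <- bn_lrelu_fwd_train(cv2, C2, p$bn2_g, p$bn2_b, a$leaky_slope,
                                1e-5)
    } else {
      bl2 <- list(out = bn_lrelu_fwd_eval(cv2, C2, p$bn2_g, p$bn2_b,
                                          model$running$bn2_mean,
                                          model$running$bn2_var,
                                          a$leaky_slope, 1e-5))
    }
    pl2 <- pool_fwd(bl2$out, H2, W2, n, C2)
    dr2 <- .dropout_forward(pl2$out, a$dropout, training)
    # per-sample feature vectors: (H4, W4, n, C2) -> (H4, W4, C2, n)
    flat <- matrix(aperm(dr2$out, c(1, 2, 4, 3)), ncol = n)
    fi_pre <- .dense_forward(flat, p$fc_img_W, p$fc_img_b)
    fi <- .lrelu_forward(fi_pre, a$leaky_slope)
  }
  Xc <- t(clinical)                          # 15 x n
  fc_pre <- .dense_forward(Xc, p$fc_clin_W, p$fc_clin_b)
  fc <- .lrelu_forward(fc_pre, a$leaky_slope)
  Z0 <- if (a$use_images) rbind(fi, fc) else fc
  sh_pre <- .dense_forward(Z0, p$shared_W, p$shared_b)
  sh <- .lrelu_forward(sh_pre, a$leaky_slope)
  T_ <- model$grid$n_bins
  logits <- matrix(0, a$n_events * T_, n)
  heads <- vector("list", a$n_events)
  for (k in seq_len(a$n_events)) {
    h_pre <- .dense_forward(sh, p[[paste0("head", k, "_W1")]],
                            p[[paste0("head", k, "_b1")]])
    h <- .lrelu_forward(h_pre, a$leaky_slope)
    out_k <- .dense_forward(h, p[[paste0("head", k, "_W2")]],
                            p[[paste0("head", k, "_b2")]])
    # interleave so logit rows run over events fastest: row (k + K*(t-1))
    logits[k + a$n_events * (seq_len(T_) - 1L), ] <- out_k
    heads[[k]] <- list(h_pre = h_pre, h = h)
  }
  pmf <- .softmax_cols(logits)
  res <- list(logits = logits, pmf = pmf, n = n)
  if (training) {
    # updated running statistics travel back to the caller
    mom <- 0.9
    res$running <- if (a$use_images)
      list(bn1_mean = mom * model$running$bn1_mean + (1 - mom) * bl1$mu,
           bn1_var = mom * model$running$bn1_var + (1 - mom) * bl1$var,
           bn2_mean = mom * model$running$bn2_mean + (1 - mom) * bl2$mu,
           bn2_var = mom * model$running$bn2_var + (1 - mom) * bl2$var)
      else list()
  }
  if (cache) {
    res$cache <- list(Xc = Xc, fc_pre = fc_pre, fc = fc, Z0 = Z0,
                      sh_pre = sh_pre, sh = sh, heads = heads)
    if (a$use_images)
      res$cache <- c(res$cache,
                     list(X = X, bl1 = bl1, pl1 = pl1, dr1 = dr1,
                          bl2 = bl2, pl2 = pl2, dr2 = dr2, flat = flat,
                          fi_pre = fi_pre, fi = fi))
  }
  res
}

# gradient of the scalar loss wrt every parameter, given dL/dlogits
.net_backward <- function(model, fw, dlogits) {
  a <- model$arch; p <- model$params; cc <- fw$cache
  H <- a$map_dim[2]; W <- a$map_dim[3]; C0 <- a$map_dim[1]
  C1 <- a$conv_channels[1]; C2 <- a$conv_channels[2]
  n <- fw$n; T_ <- model$grid$n_bins; K <- a$n_events
  g <- list()
  dsh <- matrix(0, a$shared_width, n)
  for (k in seq_len(K)) {
    dout_k <- dlogits[k + K * (seq_len(T_) - 1L), , drop = FALSE]
    hd <- cc$heads[[k]]
    b2 <- .dense_backward(dout_k, hd$h, p[[paste0("head", k, "_W2")]])
    g[[paste0("head", k, "_W2")]] <- b2$dW
    g[[paste0("head", k, "_b2")]] <- b2$db
    dh_pre <- .lrelu_backward(b2$dX, hd$h_pre, a$leaky_slope)
    b1 <- .dense_backward(dh_pre, cc$sh, p[[paste0("head", k, "_W1")]])
    g[[paste0("head", k, "_W1")]] <- b1$dW
    g[[paste0("head", k, "_b1")]] <- b1$db
    dsh <- dsh + b1$dX
  }
  dsh_pre <- .lrelu_backward(dsh, cc$sh_pre, a$leaky_slope)
  bs <- .dense_backward(dsh_pre, cc$Z0, p$shared_W)
  g$shared_W <- bs$dW; g$shared_b <- bs$db
  if (a$use_images) {
    dfi <- bs$dX[seq_len(a$image_dense_width), , drop = FALSE]
    dfc <- bs$dX[a$image_dense_width + seq_len(a$clinical_dense_width), ,
                 drop = FALSE]
  } else {
    dfc <- bs$dX
  }
  dfc_pre <- .lrelu_backward(dfc, cc$fc_pre, a$leaky_slope)
  bc <- .dense_backward(dfc_pre, cc$Xc, p$fc_clin_W)
  g$fc_clin_W <- bc$dW; g$fc_clin_b <- bc$db
  if (a$use_images) {
    H2 <- H %/% 2L; W2 <- W %/% 2L; H4 <- H %/% 4L; W4 <- W %/% 4L
    dfi_pre <- .lrelu_backward(dfi, cc$fi_pre, a$leaky_slope)
    bi <- .dense_backward(dfi_pre, cc$flat, p$fc_img_W)
    g$fc_img_W <- bi$dW; g$fc_img_b <- bi$db
    ddr2 <- aperm(array(bi$dX, dim = c(H4, W4, C2, n)), c(1, 2, 4, 3))
    dpl2 <- if (is.null(cc$dr2$mask)) ddr2 else ddr2 * cc$dr2$mask
    da2 <- pool_bwd(dpl2, cc$pl2$idx, H2, W2, n, C2)
    bb2 <- bn_lrelu_bwd(da2, cc$bl2$out, cc$bl2$xhat, cc$bl2$inv_sd,
                        p$bn2_g, a$leaky_slope, C2)
    g$bn2_g <- bb2$dg; g$bn2_b <- bb2$db
    cb2 <- conv_bwd_direct(cc$dr1$out, bb2$dX, p$conv2_W, H2, W2, n, C1,
                           TRUE)
    g$conv2_W <- cb2$dK; g$conv2_b <- cb2$db
    ddr1 <- cb2$dX
    dpl1 <- if (is.null(cc$dr1$mask)) ddr1 else ddr1 * cc$dr1$mask
    da1 <- pool_bwd(dpl1, cc$pl1$idx, H, W, n, C1)
    bb1 <- bn_lrelu_bwd(da1, cc$bl1$out, cc$bl1$xhat, cc$bl1$inv_sd,
                        p$bn1_g, a$leaky_slope, C1)
    g$bn1_g <- bb1$dg; g$bn1_b <- bb1$db
    cb1 <- conv_bwd_direct(cc$X, bb1$dX, p$conv1_W, H, W, n, C0, FALSE)
    g$conv1_W <- cb1$dK; g$conv1_b <- cb1$db
  }
  g
}

#' Forward pass: predict risk surfaces
#'
#' Applies the network in inference mode (batch-norm running statistics, no
#' dropout) and returns the joint probability grid per patient.
#'
#' @param model A `deephit_model`.
#' @param maps Array `n x 5 x 28 x 36` of *normalized* polar maps (values in
#'   `[0, 1]`); may be NULL for the clinical-only architecture.
#' @param clinical `n x 15` matrix of normalized clinical features.
#' @return A [risk_surface()] for the batch.
#' @export
forward <- function(model, maps, clinical) {
  stopifnot(inherits(model, "deephit_model"))
  if (is.data.frame(clinical)) clinical <- as.matrix(clinical)
  fw <- .net_forward(model, maps, clinical, training = FALSE)
  risk_surface(fw$pmf, model$grid,
               events = c("ACS", "death", "revascularization")[
                 seq_len(model$arch$n_events)])
}
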