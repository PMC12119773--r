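# Compact convolutional network engine (internal).
#
# Two fixed architectures back the desk-scale pipeline:
#  * classifier "cnn_small":  conv3x3 -> relu -> pool2 -> conv3x3 -> relu ->
#      pool2 -> conv3x3 -> relu -> global max pool -> dense -> softmax
#      (a max readout detects localized hot features -- focal myocardial
#      uptake -- that an average readout would dilute)
#  * segmenter "unet_small":  conv3x3 -> relu -> conv3x3 -> relu -> conv1x1
#      producing a per-pixel logit map (sigmoid + Dice/BCE loss)
# Convolutions use stride 1 and zero "same" padding; pooling is 2x2/stride 2.
# All parameters live in plain R arrays; conv/pool forward and backward are
# the Rcpp kernels in src/convnet.cpp. Optimization is Adam with a piecewise
# exponential learning-rate decay.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.he_init <- function(k, ci, co) {
  array(rnorm(k * k * ci * co, 0, sqrt(2 / (k * k * ci))), c(k, k, ci, co))
}

nn_init_cls <- function(in_channels = 1L, channels = c(8L, 16L, 16L),
                        n_classes = 2L, seed = 1L) {
  with_seed(seed, {
    list(
      W1 = .he_init(3, in_channels, channels[1]), b1 = numeric(channels[1]),
      W2 = .he_init(3, channels[1], channels[2]), b2 = numeric(channels[2]),
      W3 = .he_init(3, channels[2], channels[3]), b3 = numeric(channels[3]),
      Wd = matrix(rnorm(n_classes * channels[3], 0, sqrt(1 / channels[3])),
                  n_classes, channels[3]),
      bd = numeric(n_classes))
  })
}

# x: (H, W, Cin) array. Returns logits and, when keep = TRUE, every
# intermediate needed for the backward pass (and for GradCAM: a3 is the last
# convolutional stage).
nn_cls_forward <- function(net, x, keep = FALSE) {
  z1 <- .cn_conv2d_fwd(x, net$W1, net$b1); a1 <- relu(z1)
  p1 <- .cn_maxpool2_fwd(a1)
  z2 <- .cn_conv2d_fwd(p1$out, net$W2, net$b2); a2 <- relu(z2)
  p2 <- .cn_maxpool2_fwd(a2)
  z3 <- .cn_conv2d_fwd(p2$out, net$W3, net$b3); a3 <- relu(z3)
  d3 <- dim(a3)
  am <- matrix(a3, d3[1] * d3[2], d3[3])
  gi <- max.col(t(am), ties.method = "first")
  g <- am[cbind(gi, seq_len(d3[3]))]
  logits <- as.numeric(net$Wd %*% g + net$bd)
  if (!keep) return(list(logits = logits))
  list(logits = logits, x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2, a2 = a2,
       p2 = p2, z3 = z3, a3 = a3, g = g, gi = gi)
}

nn_cls_backward <- function(net, cache, dlogits) {
  g <- cache$g
  dWd <- outer(dlogits, g)
  dbd <- dlogits
  dg <- as.numeric(t(net$Wd) %*% dlogits)
  d3 <- dim(cache$a3)
  # max readout: gradient reaches only each channel's argmax location
  dm <- matrix(0, d3[1] * d3[2], d3[3])
  dm[cbind(cache$gi, seq_len(d3[3]))] <- dg
  da3 <- array(dm, d3)
  dz3 <- da3 * (cache$z3 > 0)
  b3g <- .cn_conv2d_bwd(cache$p2$out, net$W3, dz3)
  dp2 <- .cn_maxpool2_bwd(b3g$gin, cache$p2$idx,
                          dim(cache$a2)[1], dim(cache$a2)[2],
                          dim(cache$a2)[3])
  dz2 <- dp2 * (cache$z2 > 0)
  b2g <- .cn_conv2d_bwd(cache$p1$out, net$W2, dz2)
  dp1 <- .cn_maxpool2_bwd(b2g$gin, cache$p1$idx,
                          dim(cache$a1)[1], dim(cache$a1)[2],
                          dim(cache$a1)[3])
  dz1 <- dp1 * (cache$z1 > 0)
  b1g <- .cn_conv2d_bwd(cache$x, net$W1, dz1)
  list(W1 = b1g$gw, b1 = b1g$gb, W2 = b2g$gw, b2 = b2g$gb,
       W3 = b3g$gw, b3 = b3g$gb, Wd = dWd, bd = dbd)
}

nn_init_fcn <- function(in_channels = 3L, hidden = c(8L, 8L), seed = 1L) {
  with_seed(seed, {
    list(
      W1 = .he_init(3, in_channels, hidden[1]), b1 = numeric(hidden[1]),
      W2 = .he_init(3, hidden[1], hidden[2]), b2 = numeric(hidden[2]),
      W3 = .he_init(1, hidden[2], 1L), b3 = numeric(1))
  })
}

nn_fcn_forward <- function(net, x, keep = FALSE) {
  z1 <- .cn_conv2d_fwd(x, net$W1, net$b1); a1 <- relu(z1)
  z2 <- .cn_conv2d_fwd(a1, net$W2, net$b2); a2 <- relu(z2)
  z3 <- .cn_conv2d_fwd(a2, net$W3, net$b3)
  logit <- z3[, , 1]
  if (!keep) return(list(logit = logit))
  list(logit = logit, x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

nn_fcn_backward <- function(net, cache, dlogit) {
  dz3 <- array(dlogit, c(dim(dlogit), 1L))
  b3g <- .cn_conv2d_bwd(cache$a2, net$W3, dz3)
  dz2 <- b3g$gin * (cache$z2 > 0)
  b2g <- .cn_conv2d_bwd(cache$a1, net$W2, dz2)
  dz1 <- b2g$gin * (cache$z1 > 0)
  b1g <- .cn_conv2d_bwd(cache$x, net$W1, dz1)
  list(W1 = b1g$gw, b1 = b1g$gb, W2 = b2g$gw, b2 = b2g$gb,
       W3 = b3g$gw, b3 = b3g$gb)
}

adam_init <- function(net) {
  list(m = lapply(net, function(w) w * 0), v = lapply(net, function(w) w * 0),
       t = 0L)
}

adam_step <- function(net, opt, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(net)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    net[[nm]] <- net[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(net = net, opt = opt)
}

grad_accumulate <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_scale <- function(g, s) {
  for (nm in names(g)) g[[nm]] <- g[[nm]] * s
  g
}

# Dice + binary cross-entropy loss on a logit map; returns loss value and
# gradient wrt the logits.
seg_loss_grad <- function(logit, target, eps = 1e-6) {
  p <- 1 / (1 + exp(-logit))
  n <- length(p)
  bce <- -mean(target * log(p + 1e-12) + (1 - target) * log(1 - p + 1e-12))
  sp <- sum(p); st <- sum(target); spt <- sum(p * target)
  dice <- (2 * spt + eps) / (sp + st + eps)
  ddice_dp <- (2 * target * (sp + st + eps) - (2 * spt + eps)) /
    (sp + st + eps)^2
  # d(bce)/dlogit = (p - t)/n; dice term via chain rule through the sigmoid
  dlogit <- (p - target) / n - ddice_dp * p * (1 - p)
  list(loss = bce + (1 - dice), dlogit = dlogit)
}

lr_at_epoch <- function(lr0, decay, step, epoch) {
  lr0 * decay^((epoch - 1) %/% step)
}
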