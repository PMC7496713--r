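# Compact fully convolutional network engine.
#
# Layers are plain lists; a model is a list of layers plus its config.
# Tensors are arrays (H, W, C) handed to the C++ im2col/GEMM kernels.
# Weight matrices have shape (C_out, kh*kw*C_in) with column index
# ((c_in * kh + dy) * kw + dx), matching src/conv_ops.cpp.

he_conv <- function(in_ch, out_ch, kh, kw) {
  fan_in <- kh * kw * in_ch
  list(type = "conv",
       W = matrix(stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
                  out_ch, fan_in),
       b = numeric(out_ch),
       k = c(kh, kw), in_ch = in_ch, out_ch = out_ch)
}

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  l <- he_conv(in_ch, out_ch, k, k)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function(k = 2L, stride = 2L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride))
}
layer_dropout <- function(p) list(type = "dropout", p = p)

layer_resblock <- function(in_ch, out_ch, stride = 1L) {
  l <- list(type = "resblock",
            conv1 = layer_conv(in_ch, out_ch, 3L, stride, 1L),
            conv2 = layer_conv(out_ch, out_ch, 3L, 1L, 1L),
            proj = NULL)
  if (stride != 1L || in_ch != out_ch) {
    l$proj <- layer_conv(in_ch, out_ch, 1L, stride, 0L)
  }
  l
}

conv_fwd <- function(l, x) {
  nn_conv_fwd(x, l$W, l$b, l$k[1], l$k[2], l$stride, l$pad)
}
conv_bwd <- function(l, x, gy) {
  nn_conv_bwd(x, l$W, gy, l$k[1], l$k[2], l$stride, l$pad)
}

# Forward pass. train = TRUE enables dropout (seeded by the caller's RNG
# state); returns the pre-softmax logit cube and per-layer caches needed
# for the backward pass.
nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    cache <- list(x = x)
    if (l$type == "conv") {
      x <- conv_fwd(l, x)
    } else if (l$type == "relu") {
      x <- pmax(x, 0)
      cache$y <- x
    } else if (l$type == "maxpool") {
      mp <- nn_maxpool_fwd(x, l$k, l$stride)
      cache$amax <- mp$amax
      x <- mp$y
    } else if (l$type == "dropout") {
      if (train && l$p > 0) {
        mask <- array(stats::runif(length(x)) >= l$p, dim(x)) / (1 - l$p)
        cache$mask <- mask
        x <- x * mask
      }
    } else if (l$type == "resblock") {
      h1 <- conv_fwd(l$conv1, x)
      a1 <- pmax(h1, 0)
      h2 <- conv_fwd(l$conv2, a1)
      sc <- if (is.null(l$proj)) x else conv_fwd(l$proj, x)
      s <- h2 + sc
      cache$a1 <- a1; cache$s <- s
      x <- pmax(s, 0)
    } else {
      stopf("unknown layer type '%s'", l$type)
    }
    caches[[i]] <- cache
  }
  list(out = x, caches = caches)
}

# Backward pass; returns grads mirroring the layer list (W/b entries for
# parameterised layers) plus nothing for stateless ones.
nn_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cache <- caches[[i]]
    if (l$type == "conv") {
      g <- conv_bwd(l, cache$x, gy)
      grads[[i]] <- list(W = g$gw, b = as.numeric(g$gb))
      gy <- g$gx
    } else if (l$type == "relu") {
      gy <- gy * (cache$y > 0)
    } else if (l$type == "maxpool") {
      gy <- nn_maxpool_bwd(cache$amax, gy, dim(cache$x)[1], dim(cache$x)[2])
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) gy <- gy * cache$mask
    } else if (l$type == "resblock") {
      gs <- gy * (cache$s > 0)
      g2 <- conv_bwd(l$conv2, cache$a1, gs)
      ga1 <- g2$gx * (cache$a1 > 0)
      g1 <- conv_bwd(l$conv1, cache$x, ga1)
      gx <- g1$gx
      gproj <- NULL
      if (is.null(l$proj)) {
        gx <- gx + gs
      } else {
        gp <- conv_bwd(l$proj, cache$x, gs)
        gx <- gx + gp$gx
        gproj <- list(W = gp$gw, b = as.numeric(gp$gb))
      }
      grads[[i]] <- list(conv1 = list(W = g1$gw, b = as.numeric(g1$gb)),
                         conv2 = list(W = g2$gw, b = as.numeric(g2$gb)),
                         proj = gproj)
      gy <- gx
    }
  }
  grads
}

# Per-cell softmax over the class axis of a (rows, cols, K) logit cube.
softmax_cells <- function(logits) {
  m <- apply(logits, c(1, 2), max)
  e <- exp(sweep(logits, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

# Class-weighted cross-entropy over grid cells. `target` is an integer
# matrix with codes 0 = background, 1 = DSF, 2 = DSM. Returns the scalar
# loss and its gradient w.r.t. the logits.
cell_ce_loss <- function(logits, target, weights = c(1, 1, 1)) {
  d <- dim(logits)
  if (d[1] != nrow(target) || d[2] != ncol(target)) {
    stopf("target grid %d x %d does not match logits %d x %d",
          nrow(target), ncol(target), d[1], d[2])
  }
  n <- d[1] * d[2]
  lmat <- matrix(logits, n, d[3])
  y <- as.integer(target) + 1L
  w <- weights[y]
  m <- apply(lmat, 1, max)
  z <- lmat - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  loss <- sum(-w * logp[cbind(seq_len(n), y)]) / sum(w)
  p <- exp(logp)
  grad <- p
  grad[cbind(seq_len(n), y)] <- grad[cbind(seq_len(n), y)] - 1
  grad <- grad * w / sum(w)
  list(loss = loss, grad = array(grad, d))
}

# --- Adam ------------------------------------------------------------------

# Walk the layer tree collecting references to every (W, b) pair so the
# optimiser can treat an arbitrary architecture uniformly.
param_paths <- function(layers) {
  paths <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      paths[[length(paths) + 1]] <- list(i)
    } else if (l$type == "resblock") {
      paths[[length(paths) + 1]] <- list(i, "conv1")
      paths[[length(paths) + 1]] <- list(i, "conv2")
      if (!is.null(l$proj)) paths[[length(paths) + 1]] <- list(i, "proj")
    }
  }
  paths
}

get_path <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}
set_path <- function(tree, path, value) {
  if (length(path) == 1) {
    tree[[path[[1]]]] <- value
  } else {
    tree[[path[[1]]]] <- set_path(tree[[path[[1]]]], path[-1], value)
  }
  tree
}

adam_init <- function(layers) {
  paths <- param_paths(layers)
  state <- lapply(paths, function(p) {
    l <- get_path(layers, p)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(paths = paths, state = state, t = 0L)
}

adam_step <- function(layers, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (j in seq_along(opt$paths)) {
    p <- opt$paths[[j]]
    l <- get_path(layers, p)
    g <- get_path(grads, p)
    s <- opt$state[[j]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    l$W <- l$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    l$b <- l$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$state[[j]] <- s
    layers <- set_path(layers, p, l)
  }
  list(layers = layers, opt = opt)
}

# Accumulate two gradient trees (same shape).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (!is.null(b[[i]]$W)) {
      a[[i]]$W <- a[[i]]$W + b[[i]]$W
      a[[i]]$b <- a[[i]]$b + b[[i]]$b
    } else {
      for (nm in names(b[[i]])) {
        if (is.null(b[[i]][[nm]])) next
        a[[i]][[nm]]$W <- a[[i]][[nm]]$W + b[[i]][[nm]]$W
        a[[i]][[nm]]$b <- a[[i]][[nm]]$b + b[[i]][[nm]]$b
      }
    }
  }
  a
}

grads_scale <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    if (!is.null(g[[i]]$W)) {
      g[[i]]$W <- g[[i]]$W * s
      g[[i]]$b <- g[[i]]$b * s
    } else {
      for (nm in names(g[[i]])) {
        if (is.null(g[[i]][[nm]])) next
        g[[i]][[nm]]$W <- g[[i]][[nm]]$W * s
        g[[i]][[nm]]$b <- g[[i]][[nm]]$b * s
      }
    }
  }
  g
}
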