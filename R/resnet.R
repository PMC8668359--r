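# Minimal inference-path ResNet-50/101 in plain R.
#
# Implements the bottleneck residual architecture exactly as far as tensor
# shapes are concerned: 7x7/2 stem, 3x3/2 max pool, four bottleneck stages
# ((3,4,6,3) for depth 50, (3,4,23,3) for depth 101), global average pooling
# to a 2048-wide feature vector. Weights are He-initialised from a seed —
# the point is the architecture contract (feature geometry and widths), not
# trained representations. Batch normalisation in inference mode with unit
# statistics and identity affine parameters is a no-op, so it is omitted;
# convolutions are bias-free as in the original architecture.
#
# Convolutions run as im2col + one BLAS matrix multiply per layer, which
# keeps a full forward pass tractable on a single CPU core.

resnet_stage_blocks <- function(architecture) {
  switch(architecture,
         resnet50 = c(3L, 4L, 6L, 3L),
         resnet101 = c(3L, 4L, 23L, 3L),
         stop("unknown residual architecture: ", architecture, call. = FALSE))
}

he_weight <- function(kh, kw, cin, cout) {
  matrix(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
         kh * kw * cin, cout)
}

conv_spec <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  list(kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, pad = pad, W = he_weight(kh, kw, cin, cout))
}

# Seeded random-init weights for the full network.
init_resnet_weights <- function(architecture, seed) {
  blocks <- resnet_stage_blocks(architecture)
  mids <- c(64L, 128L, 256L, 512L)
  outs <- mids * 4L
  with_seed(seed, {
    w <- list(stem = conv_spec(7L, 7L, 3L, 64L, stride = 2L, pad = 3L),
              stages = vector("list", 4L))
    cin <- 64L
    for (s in 1:4) {
      stage <- vector("list", blocks[s])
      for (b in seq_len(blocks[s])) {
        stride <- if (b == 1L && s > 1L) 2L else 1L
        blk <- list(
          conv1 = conv_spec(1L, 1L, cin, mids[s]),
          conv2 = conv_spec(3L, 3L, mids[s], mids[s], stride = stride,
                            pad = 1L),
          conv3 = conv_spec(1L, 1L, mids[s], outs[s]))
        if (b == 1L) {
          blk$shortcut <- conv_spec(1L, 1L, cin, outs[s], stride = stride)
        }
        stage[[b]] <- blk
        cin <- outs[s]
      }
      w$stages[[s]] <- stage
    }
    w$architecture <- architecture
    w
  })
}

pad_hw <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# im2col: one column block per kernel offset, sliced from the padded tensor.
im2col <- function(x, kh, kw, stride, pad, fill = 0) {
  xp <- pad_hw(x, pad, fill)
  d <- dim(xp)
  ho <- (d[1] - kh) %/% stride + 1L
  wo <- (d[2] - kw) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  M <- matrix(NA_real_, ho * wo, kh * kw * d[3])
  col <- 1L
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      patch <- xp[ri + ki - 1L, ci + kj - 1L, , drop = FALSE]
      M[, col:(col + d[3] - 1L)] <- matrix(patch, ho * wo, d[3])
      col <- col + d[3]
    }
  }
  list(M = M, ho = ho, wo = wo)
}

conv_forward <- function(x, cs) {
  ic <- im2col(x, cs$kh, cs$kw, cs$stride, cs$pad)
  array(ic$M %*% cs$W, c(ic$ho, ic$wo, cs$cout))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

maxpool3 <- function(x, stride = 2L) {
  xp <- pad_hw(x, 1L, fill = -Inf)
  d <- dim(xp)
  ho <- (d[1] - 3L) %/% stride + 1L
  wo <- (d[2] - 3L) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  out <- array(-Inf, c(ho, wo, d[3]))
  for (kj in 1:3) for (ki in 1:3) {
    out <- pmax(out, xp[ri + ki - 1L, ci + kj - 1L, , drop = FALSE])
  }
  out
}

bottleneck_forward <- function(x, blk) {
  y <- relu(conv_forward(x, blk$conv1))
  y <- relu(conv_forward(y, blk$conv2))
  y <- conv_forward(y, blk$conv3)
  sc <- if (is.null(blk$shortcut)) x else conv_forward(x, blk$shortcut)
  relu(y + sc)
}

# Full forward pass to the global average pooling tap: 2048-vector.
resnet_forward_features <- function(weights, px) {
  x <- relu(conv_forward(px, weights$stem))
  x <- maxpool3(x)
  for (stage in weights$stages) {
    for (blk in stage) x <- bottleneck_forward(x, blk)
  }
  apply(x, 3, mean)
}
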