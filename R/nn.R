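# Minimal neural-network core: im2col convolutions with hand-written
# backward passes, SiLU activations, nearest-neighbor upsampling, sinusoidal
# time embeddings, and Adam. Batches are stored as H x W x C x N arrays
# (column-major, spatial-first), all in double precision.
#
# The design is deliberately functional: every forward primitive returns its
# output plus the cache its backward pass needs; gradients are exact and are
# verified against finite differences in the test suite.

.idx_cache <- new.env(parent = emptyenv())

# im2col gather-index for a padded single-sample, multi-channel tensor.
# Returns a (Ho*Wo) x (k*k*C) integer matrix of linear indices into the
# padded [Hp, Wp, C] block; column order is (patch offset) within (channel).
im2col_index <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oy <- rep(seq_len(Ho), Wo)
  ox <- rep(seq_len(Wo), each = Ho)
  iy0 <- (oy - 1L) * stride
  ix0 <- (ox - 1L) * stride
  # patch offsets, row-fastest within the k x k window
  off_y <- rep(seq_len(k), k)
  off_x <- rep(seq_len(k), each = k)
  base <- matrix(0L, Ho * Wo, k * k)
  for (j in seq_len(k * k)) {
    base[, j] <- (ix0 + off_x[j] - 1L) * Hp + (iy0 + off_y[j])
  }
  idx <- matrix(0L, Ho * Wo, k * k * C)
  for (c in seq_len(C)) {
    idx[, (c - 1L) * k * k + seq_len(k * k)] <- base + (c - 1L) * Hp * Wp
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              H = H, W = W, C = C, k = k, stride = stride, pad = pad)
  .idx_cache[[key]] <- out
  out
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# Batched gather index: the single-sample index replicated with per-sample
# block offsets, cached per batch size.
batch_index <- function(info, N) {
  key <- paste(info$H, info$W, info$C, info$k, info$stride, info$pad, N,
               sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  block <- info$Hp * info$Wp * info$C
  P <- info$Ho * info$Wo
  off <- rep((seq_len(N) - 1L) * block, each = P)
  big <- info$idx[rep(seq_len(P), N), , drop = FALSE] + off
  # stored as a dimensionless vector so `x[big]` is always linear indexing
  out <- list(v = as.vector(big), nr = P * N, nc = ncol(info$idx))
  .idx_cache[[key]] <- out
  out
}

# Unfold a batch into the im2col matrix [(Ho*Wo*N) x (k*k*C)], sample-major
# row blocks.
im2col <- function(x, info) {
  N <- dim(x)[4]
  xp <- pad_spatial(x, info$pad)
  big <- batch_index(info, N)
  out <- xp[big$v]  # linear-index gather, no intermediate copy
  dim(out) <- c(big$nr, big$nc)
  out
}

# Forward/backward convolution; the kernels live in src/conv.cpp.
conv_fwd <- function(x, W, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  k <- as.integer(sqrt(nrow(W) / d[3]))
  y <- conv_fwd_cpp(x, W, b, k, as.integer(stride), as.integer(pad))
  list(y = y,
       cache = list(x = x, W = W, k = k,
                    stride = as.integer(stride), pad = as.integer(pad)))
}

conv_bwd <- function(dy, cache) {
  conv_bwd_cpp(dy, cache$x, cache$W, cache$k, cache$stride, cache$pad)
}

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}

silu_bwd <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  H <- d[1] %/% 2L; W <- d[2] %/% 2L
  o1 <- seq(1L, d[1], by = 2L); o2 <- seq(2L, d[1], by = 2L)
  p1 <- seq(1L, d[2], by = 2L); p2 <- seq(2L, d[2], by = 2L)
  dy[o1, p1, , , drop = FALSE] + dy[o2, p1, , , drop = FALSE] +
    dy[o1, p2, , , drop = FALSE] + dy[o2, p2, , , drop = FALSE]
}

# Per-(sample, channel) additive bias used for time conditioning:
# y = x + tb[n, c] broadcast over space.
chanbias_add <- function(x, tb) {
  d <- dim(x)
  x + array(rep(as.vector(t(tb)), each = d[1] * d[2]), d)
}

chanbias_bwd <- function(dy) {
  d <- dim(dy)
  m <- matrix(dy, d[1] * d[2], d[3] * d[4])
  t(matrix(colSums(m), d[3], d[4]))  # [N, C]
}

# Sinusoidal embedding of (integer) timesteps, dimension must be even.
sin_embed <- function(tvec, dim = 16L) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(1L, half - 1L))
  ang <- outer(as.numeric(tvec), freqs)
  cbind(sin(ang), cos(ang))
}

init_mat <- function(nr, nc, scale = sqrt(2 / nr)) {
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

#' @keywords internal
unet_init <- function(c_in, c_out, widths, temb_dim = 32L, sin_dim = 16L,
                      use_temb = TRUE, zero_head = TRUE, seed = 1L) {
  L <- length(widths)
  with_seed(seed, {
    p <- list()
    if (use_temb) {
      p$temb_W <- init_mat(sin_dim, temb_dim)
      p$temb_b <- numeric(temb_dim)
    }
    add_conv <- function(name, cin, cout, zero = FALSE) {
      p[[paste0(name, "_W")]] <<- if (zero) matrix(0, 9 * cin, cout) else
        init_mat(9 * cin, cout, sqrt(2 / (9 * cin)))
      p[[paste0(name, "_b")]] <<- numeric(cout)
    }
    add_tproj <- function(name, cout) {
      if (use_temb) p[[paste0(name, "_T")]] <<- init_mat(temb_dim, cout, 0.1)
    }
    add_conv("stem", c_in, widths[1]); add_tproj("stem", widths[1])
    for (l in seq_len(L - 1L)) {
      add_conv(paste0("down", l), widths[l], widths[l + 1])
      add_tproj(paste0("down", l), widths[l + 1])
      add_conv(paste0("mid", l), widths[l + 1], widths[l + 1])
    }
    for (l in rev(seq_len(L - 1L))) {
      add_conv(paste0("up", l), widths[l + 1], widths[l])
      add_conv(paste0("fuse", l), 2L * widths[l], widths[l])
      add_tproj(paste0("fuse", l), widths[l])
    }
    add_conv("head", widths[1], c_out, zero = zero_head)
    structure(
      list(params = p, widths = widths, c_in = c_in, c_out = c_out,
           temb_dim = temb_dim, sin_dim = sin_dim, use_temb = use_temb),
      class = "hsisynth_unet"
    )
  })
}

# Forward pass. x: [H, W, c_in, N]; tvec: numeric length N or NULL.
# Spatial dims must be divisible by 2^(L-1).
unet_forward <- function(net, x, tvec = NULL, keep_cache = FALSE) {
  p <- net$params
  L <- length(net$widths)
  cache <- list()
  temb <- NULL
  if (net$use_temb) {
    e <- sin_embed(tvec, net$sin_dim)
    pre <- sweep(e %*% p$temb_W, 2L, p$temb_b, "+")
    a <- silu_fwd(pre)
    temb <- a$y
    cache$temb <- list(e = e, act = a)
  }
  conv_block <- function(x, name, stride = 1L, tname = NULL) {
    cf <- conv_fwd(x, p[[paste0(name, "_W")]], p[[paste0(name, "_b")]],
                   stride = stride, pad = 1L)
    if (!net$use_temb) tname <- NULL
    h <- cf$y
    if (!is.null(tname)) {
      tb <- temb %*% p[[paste0(tname, "_T")]]
      h <- chanbias_add(h, tb)
    }
    a <- silu_fwd(h)
    list(y = a$y, cf = cf, act = a, tname = tname)
  }
  b <- conv_block(x, "stem", tname = "stem")
  cache$stem <- b
  feats <- list(b$y)
  h <- b$y
  for (l in seq_len(L - 1L)) {
    bd <- conv_block(h, paste0("down", l), stride = 2L, tname = paste0("down", l))
    bm <- conv_block(bd$y, paste0("mid", l))
    cache[[paste0("down", l)]] <- bd
    cache[[paste0("mid", l)]] <- bm
    h <- bm$y
    feats[[l + 1L]] <- h
  }
  for (l in rev(seq_len(L - 1L))) {
    hu <- upsample2_fwd(h)
    bu <- conv_block(hu, paste0("up", l))
    skip <- feats[[l]]
    hcat <- abind4(bu$y, skip)
    bf <- conv_block(hcat, paste0("fuse", l), tname = paste0("fuse", l))
    cache[[paste0("up", l)]] <- bu
    cache[[paste0("fuse", l)]] <- list(block = bf, c1 = dim(bu$y)[3])
    h <- bf$y
  }
  cf <- conv_fwd(h, p$head_W, p$head_b, stride = 1L, pad = 1L)
  cache$head <- cf
  out <- cf$y
  if (keep_cache) list(y = out, cache = cache) else list(y = out)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Backward pass; returns gradients for every parameter (same names) plus dx.
unet_backward <- function(net, cache, dy) {
  p <- net$params
  L <- length(net$widths)
  g <- list()
  dtemb <- NULL
  add_temb_grad <- function(d) {
    if (is.null(dtemb)) dtemb <<- d else dtemb <<- dtemb + d
  }
  block_bwd <- function(b, dy, name) {
    da <- silu_bwd(dy, b$act$cache)
    if (!is.null(b$tname)) {
      dtb <- chanbias_bwd(da)
      g[[paste0(b$tname, "_T")]] <<- crossprod(cache$temb$act$y, dtb)
      add_temb_grad(tcrossprod(dtb, p[[paste0(b$tname, "_T")]]))
    }
    cb <- conv_bwd(da, b$cf$cache)
    g[[paste0(name, "_W")]] <<- cb$dW
    g[[paste0(name, "_b")]] <<- cb$db
    cb$dx
  }
  cbh <- conv_bwd(dy, cache$head$cache)
  g$head_W <- cbh$dW; g$head_b <- cbh$db
  dh <- cbh$dx
  # decoder in reverse application order (fuse1/up1 were applied last)
  dskips <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    fc <- cache[[paste0("fuse", l)]]
    dcat <- block_bwd(fc$block, dh, paste0("fuse", l))
    c1 <- fc$c1
    dbu <- dcat[, , seq_len(c1), , drop = FALSE]
    dskips[[l]] <- dcat[, , c1 + seq_len(dim(dcat)[3] - c1), , drop = FALSE]
    dhu <- block_bwd(cache[[paste0("up", l)]], dbu, paste0("up", l))
    dh <- upsample2_bwd(dhu)
  }
  # dh is now the gradient at the deepest encoder feature; walk the encoder
  # back down, merging each level's skip gradient where it branched off
  for (l in rev(seq_len(L - 1L))) {
    dfeat <- dh
    if (l + 1L <= L - 1L) dfeat <- dfeat + dskips[[l + 1L]]
    dmid <- block_bwd(cache[[paste0("mid", l)]], dfeat, paste0("mid", l))
    dh <- block_bwd(cache[[paste0("down", l)]], dmid, paste0("down", l))
  }
  dstem <- dh + dskips[[1L]]
  dx <- block_bwd(cache$stem, dstem, "stem")
  if (net$use_temb) {
    dpre <- silu_bwd(dtemb, cache$temb$act$cache)
    g$temb_W <- crossprod(cache$temb$e, dpre)
    g$temb_b <- colSums(dpre)
  }
  list(dx = dx, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 1.0) {
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
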