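## Minimal convolutional-network engine used by the cGAN reconstructor.
##
## Feature maps are stored as (B*H*W, C) double matrices: a batch of B
## square images, column-major spatial flattening, stacked along rows.
## Convolutions are evaluated as im2col + GEMM so the heavy lifting runs in
## BLAS and the per-layer interpreter overhead is amortized over the batch;
## index structures are precomputed per (geometry, batch) and cached.

.nn_cache <- new.env(parent = emptyenv())

## Index structures for a batched convolution geometry.
.conv_geom <- function(H, W, k, stride, pad, B) {
  key <- paste("cv", H, W, k, stride, pad, B, sep = "_")
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k)
  j <- 0L
  for (b in seq_len(k)) for (a in seq_len(k)) {
    j <- j + 1L
    idx[, j] <- ((co - 1L) * stride + b - 1L) * Hp + (ro - 1L) * stride + a
  }
  offs <- (seq_len(B) - 1L) * (Hp * Wp)
  ## gather vector ordered: pixel fastest, then image, then kernel offset
  av <- array(0L, c(Ho * Wo, B, k * k))
  for (b in seq_len(B)) av[, b, ] <- idx + offs[b]
  idxvec <- as.vector(av)
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  pidx1 <- (cc + pad - 1L) * Hp + r + pad
  g <- list(idxvec = idxvec,
            pidx = rep(pidx1, B) + rep(offs, each = H * W),
            Ho = Ho, Wo = Wo, npad = B * Hp * Wp, k = k)
  .nn_cache[[key]] <- g
  g
}

.up_geom <- function(H, W, B) {
  key <- paste("up", H, W, B, sep = "_")
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  r2 <- rep(seq_len(2 * H), times = 2 * W)
  c2 <- rep(seq_len(2 * W), each = 2 * H)
  src1 <- ((c2 + 1L) %/% 2L - 1L) * H + (r2 + 1L) %/% 2L
  src <- rep(src1, B) + rep((seq_len(B) - 1L) * (H * W), each = 4L * H * W)
  ## the four output positions fed by each source pixel (for the backward
  ## pass: a sum of four gathers instead of a scatter)
  pos <- split(seq_along(src), src)
  back <- matrix(unlist(pos, use.names = FALSE), nrow = 4L)
  g <- list(src = src, back = back)
  .nn_cache[[key]] <- g
  g
}

.img_group <- function(n, B) {
  key <- paste("gr", n, B, sep = "_")
  g <- .nn_cache[[key]]
  if (!is.null(g)) return(g)
  g <- rep(seq_len(B), each = n)
  .nn_cache[[key]] <- g
  g
}

## One convolution module. Weight rows are ordered (kernel offset fastest,
## then input channel); N(0, 0.02) initialization as is customary for
## image-translation GANs.
nn_conv <- function(cin, cout, k, stride, pad, norm = FALSE,
                    act = c("lrelu", "relu", "linear")) {
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, norm = norm, act = match.arg(act),
       W = matrix(rnorm(k * k * cin * cout, 0, 0.02), k * k * cin, cout),
       b = rep(0, cout),
       g = if (norm) rep(1, cout), gb = if (norm) rep(0, cout))
}

.act_fwd <- function(x, act) {
  switch(act,
         lrelu = list(y = x * (x > 0) + 0.2 * x * (x <= 0), mask = x > 0),
         relu = list(y = x * (x > 0), mask = x > 0),
         linear = list(y = x, mask = NULL))
}

.act_bwd <- function(dy, act, mask) {
  switch(act,
         lrelu = dy * (mask + 0.2 * !mask),
         relu = dy * mask,
         linear = dy)
}

## Forward through conv (+ optional per-image instance norm + activation).
## x: (B*H*W, cin). Returns list(y, H, W, cache).
conv_forward <- function(mod, x, H, W, B = 1L) {
  g <- .conv_geom(H, W, mod$k, mod$stride, mod$pad, B)
  n_out <- g$Ho * g$Wo
  N <- B * n_out
  fw <- cpp_conv_fwd(x, g$pidx, g$idxvec, g$npad, N, mod$W, mod$b)
  y <- fw$y
  cache <- list(xc = fw$xc, g = g, N = N, B = B)
  if (mod$norm) {
    grp <- .img_group(n_out, B)
    m <- rowsum(y, grp, reorder = TRUE) / n_out
    yc <- y - m[grp, , drop = FALSE]
    v <- rowsum(yc * yc, grp, reorder = TRUE) / n_out
    isd <- 1 / sqrt(v + 1e-5)
    yh <- yc * isd[grp, , drop = FALSE]
    y <- yh * matrix(mod$g, N, mod$cout, byrow = TRUE) +
      matrix(mod$gb, N, mod$cout, byrow = TRUE)
    cache$yh <- yh; cache$isd <- isd; cache$grp <- grp; cache$n_px <- n_out
  }
  a <- .act_fwd(y, mod$act)
  cache$amask <- a$mask
  list(y = a$y, H = g$Ho, W = g$Wo, cache = cache)
}

## Backward; returns list(dx, dW, db, dg, dgb). `need_dx = FALSE` skips the
## input-gradient GEMM and scatter (first layers); `need_weights = FALSE`
## skips the weight gradients (pure input-gradient chains).
conv_backward <- function(mod, cache, dy, need_dx = TRUE,
                          need_weights = TRUE) {
  N <- cache$N
  dy <- .act_bwd(dy, mod$act, cache$amask)
  dg <- NULL; dgb <- NULL
  if (mod$norm) {
    yh <- cache$yh; grp <- cache$grp
    if (need_weights) {
      dg <- colSums(dy * yh)
      dgb <- colSums(dy)
    }
    dyh <- dy * matrix(mod$g, N, mod$cout, byrow = TRUE)
    m1 <- rowsum(dyh, grp, reorder = TRUE) / cache$n_px
    m2 <- rowsum(dyh * yh, grp, reorder = TRUE) / cache$n_px
    dy <- (dyh - m1[grp, , drop = FALSE] - yh * m2[grp, , drop = FALSE]) *
      cache$isd[grp, , drop = FALSE]
  }
  dW <- NULL; db <- NULL
  if (need_weights) {
    dW <- cpp_conv_dW(cache$xc, dy)
    db <- colSums(dy)
  }
  if (!need_dx)
    return(list(dx = NULL, dW = dW, db = db, dg = dg, dgb = dgb))
  g <- cache$g
  list(dx = cpp_conv_bwd_dx(dy, mod$W, g$idxvec, g$npad, g$pidx, mod$k^2),
       dW = dW, db = db, dg = dg, dgb = dgb)
}

up2_forward <- function(x, H, W, B = 1L) {
  g <- .up_geom(H, W, B)
  list(y = x[g$src, , drop = FALSE], H = 2L * H, W = 2L * W)
}

up2_backward <- function(dy, H, W, B = 1L) {
  g <- .up_geom(H, W, B)
  dy[g$back[1, ], , drop = FALSE] + dy[g$back[2, ], , drop = FALSE] +
    dy[g$back[3, ], , drop = FALSE] + dy[g$back[4, ], , drop = FALSE]
}

## --- Adam -------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, grad, st, lr, beta1, beta2, t, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad * grad
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

.module_params <- function(mods) {
  out <- list()
  for (i in seq_along(mods)) {
    for (nm in c("W", "b", "g", "gb")) {
      if (!is.null(mods[[i]][[nm]]))
        out[[paste(i, nm, sep = ".")]] <- mods[[i]][[nm]]
    }
  }
  out
}

.apply_grads <- function(mods, grads, opt, lr, beta1, beta2, t) {
  for (key in names(grads)) {
    if (is.null(grads[[key]])) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1]); nm <- parts[2]
    res <- adam_step(mods[[i]][[nm]], grads[[key]], opt[[key]],
                     lr, beta1, beta2, t)
    mods[[i]][[nm]] <- res$p
    opt[[key]] <- res$st
  }
  list(mods = mods, opt = opt)
}

## Stable binary cross-entropy on logits; target is 0 or 1 (scalar).
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}
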