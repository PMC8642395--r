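# Internal neural-network engine.
#
# Activations are 3-d arrays dim (H, W, B*C), slice s = (b-1)*C + c, the
# layout the C++ conv/pool primitives expect. Parameters live in a flat
# named list of numeric arrays; gradients mirror it. Batch norm keeps
# running statistics in a parallel "state" list.

relu_fwd <- function(x) { x[x < 0] <- 0; x }

bn_fwd <- function(x, gamma, beta, C, B, training, rmean, rvar,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n_el <- d[1] * d[2] * B
  if (training) {
    sums <- channel_sums(x, x, d, C)
    m <- sums[, 1] / n_el
    v <- pmax(sums[, 2] / n_el - m * m, 0)
    rmean <- (1 - momentum) * rmean + momentum * m
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    m <- rmean; v <- rvar
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- channel_affine(x, d, inv_std, -m * inv_std, C)
  y <- channel_affine(xhat, d, gamma, beta, C)
  list(y = y, xhat = xhat, inv_std = inv_std,
       rmean = rmean, rvar = rvar, dims = d)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  C <- length(gamma)
  B <- d[3] / C
  n_el <- d[1] * d[2] * B
  sums <- channel_sums(dy, cache$xhat, d, C)
  dbeta <- sums[, 1]
  dgamma <- sums[, 2]
  g_is <- gamma * cache$inv_std
  # dx = g/std * (dy - mean(dy) - xhat * mean(dy * xhat)), means per channel
  t1 <- channel_affine(cache$xhat, d, -dgamma / n_el, -dbeta / n_el, C)
  dx <- channel_affine(dy + t1, d, g_is, rep(0, C), C)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- ResNet-18 architecture -------------------------------------------

#' @noRd
resnet_arch <- function(width_scale = 0.25, in_h = 50, in_w = 1024,
                        conv1_time_stride = 4) {
  widths <- pmax(round(c(64, 128, 256, 512) * width_scale), 1)
  list(width_scale = width_scale, widths = widths, blocks = c(2, 2, 2, 2),
       in_h = in_h, in_w = in_w, conv1_time_stride = conv1_time_stride)
}

he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

init_resnet <- function(arch, seed = 1L) {
  with_seed(seed, {
    p <- list(); s <- list()
    w1 <- arch$widths[1]
    p[["conv1.w"]] <- he_init(w1, 49)
    p[["bn1.gamma"]] <- rep(1, w1); p[["bn1.beta"]] <- rep(0, w1)
    s[["bn1.mean"]] <- rep(0, w1); s[["bn1.var"]] <- rep(1, w1)
    cin <- w1
    for (i in 1:4) {
      cout <- arch$widths[i]
      for (j in seq_len(arch$blocks[i])) {
        pf <- sprintf("s%db%d", i, j)
        p[[paste0(pf, ".conv_a")]] <- he_init(cout, cin * 9)
        p[[paste0(pf, ".bn_a.gamma")]] <- rep(1, cout)
        p[[paste0(pf, ".bn_a.beta")]] <- rep(0, cout)
        s[[paste0(pf, ".bn_a.mean")]] <- rep(0, cout)
        s[[paste0(pf, ".bn_a.var")]] <- rep(1, cout)
        p[[paste0(pf, ".conv_b")]] <- he_init(cout, cout * 9)
        p[[paste0(pf, ".bn_b.gamma")]] <- rep(1, cout)
        p[[paste0(pf, ".bn_b.beta")]] <- rep(0, cout)
        s[[paste0(pf, ".bn_b.mean")]] <- rep(0, cout)
        s[[paste0(pf, ".bn_b.var")]] <- rep(1, cout)
        if (j == 1 && (i > 1 || cin != cout)) {
          p[[paste0(pf, ".conv_d")]] <- he_init(cout, cin)
          p[[paste0(pf, ".bn_d.gamma")]] <- rep(1, cout)
          p[[paste0(pf, ".bn_d.beta")]] <- rep(0, cout)
          s[[paste0(pf, ".bn_d.mean")]] <- rep(0, cout)
          s[[paste0(pf, ".bn_d.var")]] <- rep(1, cout)
        }
        cin <- cout
      }
    }
    p[["fc.w"]] <- rnorm(cin, sd = 1 / sqrt(cin))
    p[["fc.b"]] <- 0
    list(params = p, state = s)
  })
}

block_fwd <- function(x, pf, cin, cout, stride, p, st, B, training) {
  cache <- list(x = x, pf = pf, cin = cin, cout = cout, stride = stride)
  a <- conv2d_fwd(x, dim(x), p[[paste0(pf, ".conv_a")]], B, cin, cout,
                  3L, 3L, stride, stride, 1L, 1L)
  ba <- bn_fwd(a, p[[paste0(pf, ".bn_a.gamma")]], p[[paste0(pf, ".bn_a.beta")]],
               cout, B, training,
               st[[paste0(pf, ".bn_a.mean")]], st[[paste0(pf, ".bn_a.var")]])
  st[[paste0(pf, ".bn_a.mean")]] <- ba$rmean
  st[[paste0(pf, ".bn_a.var")]] <- ba$rvar
  ar <- relu_fwd(ba$y)
  b <- conv2d_fwd(ar, dim(ar), p[[paste0(pf, ".conv_b")]], B, cout, cout,
                  3L, 3L, 1L, 1L, 1L, 1L)
  bb <- bn_fwd(b, p[[paste0(pf, ".bn_b.gamma")]], p[[paste0(pf, ".bn_b.beta")]],
               cout, B, training,
               st[[paste0(pf, ".bn_b.mean")]], st[[paste0(pf, ".bn_b.var")]])
  st[[paste0(pf, ".bn_b.mean")]] <- bb$rmean
  st[[paste0(pf, ".bn_b.var")]] <- bb$rvar
  has_d <- !is.null(p[[paste0(pf, ".conv_d")]])
  if (has_d) {
    sd_ <- conv2d_fwd(x, dim(x), p[[paste0(pf, ".conv_d")]], B, cin, cout,
                      1L, 1L, stride, stride, 0L, 0L)
    bd <- bn_fwd(sd_, p[[paste0(pf, ".bn_d.gamma")]],
                 p[[paste0(pf, ".bn_d.beta")]], cout, B, training,
                 st[[paste0(pf, ".bn_d.mean")]], st[[paste0(pf, ".bn_d.var")]])
    st[[paste0(pf, ".bn_d.mean")]] <- bd$rmean
    st[[paste0(pf, ".bn_d.var")]] <- bd$rvar
    skip <- bd$y
    cache$bd <- bd
  } else skip <- x
  pre <- bb$y + skip
  y <- relu_fwd(pre)
  cache$ba <- ba; cache$bb <- bb; cache$ar <- ar; cache$pre <- pre
  cache$has_d <- has_d
  list(y = y, cache = cache, state = st)
}

block_bwd <- function(dy, cache, p, B) {
  g <- list()
  pf <- cache$pf
  dy <- dy * (cache$pre > 0)
  dskip <- dy
  bbw <- bn_bwd(dy, cache$bb, p[[paste0(pf, ".bn_b.gamma")]])
  g[[paste0(pf, ".bn_b.gamma")]] <- bbw$dgamma
  g[[paste0(pf, ".bn_b.beta")]] <- bbw$dbeta
  cb <- conv2d_bwd(cache$ar, dim(cache$ar), p[[paste0(pf, ".conv_b")]],
                   bbw$dx, B, cache$cout, cache$cout, 3L, 3L, 1L, 1L, 1L, 1L)
  g[[paste0(pf, ".conv_b")]] <- cb$dw
  dar <- cb$dx * (cache$ba$y > 0)
  baw <- bn_bwd(dar, cache$ba, p[[paste0(pf, ".bn_a.gamma")]])
  g[[paste0(pf, ".bn_a.gamma")]] <- baw$dgamma
  g[[paste0(pf, ".bn_a.beta")]] <- baw$dbeta
  ca <- conv2d_bwd(cache$x, dim(cache$x), p[[paste0(pf, ".conv_a")]],
                   baw$dx, B, cache$cin, cache$cout, 3L, 3L,
                   cache$stride, cache$stride, 1L, 1L)
  g[[paste0(pf, ".conv_a")]] <- ca$dw
  dx <- ca$dx
  if (cache$has_d) {
    bdw <- bn_bwd(dskip, cache$bd, p[[paste0(pf, ".bn_d.gamma")]])
    g[[paste0(pf, ".bn_d.gamma")]] <- bdw$dgamma
    g[[paste0(pf, ".bn_d.beta")]] <- bdw$dbeta
    cd <- conv2d_bwd(cache$x, dim(cache$x), p[[paste0(pf, ".conv_d")]],
                     bdw$dx, B, cache$cin, cache$cout, 1L, 1L,
                     cache$stride, cache$stride, 0L, 0L)
    g[[paste0(pf, ".conv_d")]] <- cd$dw
    dx <- dx + cd$dx
  } else dx <- dx + dskip
  list(dx = dx, grads = g)
}

resnet_fwd <- function(p, st, arch, X, training = FALSE) {
  B <- if (length(dim(X)) == 3) dim(X)[3] else 1L
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  if (dim(X)[1] != arch$in_h || dim(X)[2] != arch$in_w)
    stop("input geometry must be ", arch$in_h, " x ", arch$in_w)
  w1 <- arch$widths[1]
  cache <- list(X = X, B = B)
  h <- conv2d_fwd(X, dim(X), p[["conv1.w"]], B, 1L, w1, 7L, 7L,
                  2L, arch$conv1_time_stride, 3L, 3L)
  b1 <- bn_fwd(h, p[["bn1.gamma"]], p[["bn1.beta"]], w1, B, training,
               st[["bn1.mean"]], st[["bn1.var"]])
  st[["bn1.mean"]] <- b1$rmean; st[["bn1.var"]] <- b1$rvar
  r1 <- relu_fwd(b1$y)
  mp <- maxpool_fwd(r1, dim(r1), 3L, 3L, 2L, 2L, 1L, 1L)
  cache$b1 <- b1; cache$r1_dim <- dim(r1); cache$mp_idx <- mp$idx
  x <- mp$y
  cin <- w1
  caches <- list()
  for (i in 1:4) for (j in seq_len(arch$blocks[i])) {
    stride <- if (i > 1 && j == 1) 2L else 1L
    bl <- block_fwd(x, sprintf("s%db%d", i, j), cin, arch$widths[i],
                    stride, p, st, B, training)
    x <- bl$y; st <- bl$state
    caches[[sprintf("s%db%d", i, j)]] <- bl$cache
    cin <- arch$widths[i]
  }
  d <- dim(x); hw <- d[1] * d[2]; C <- cin
  xm <- x; dim(xm) <- c(hw, d[3])
  feat <- t(matrix(colMeans(xm), C, B))          # B x C
  logit <- as.numeric(feat %*% p[["fc.w"]]) + p[["fc.b"]]
  prob <- stats::plogis(logit)
  cache$blocks <- caches; cache$feat <- feat; cache$last_dim <- d
  list(prob = prob, logit = logit, cache = cache, state = st)
}

resnet_bwd <- function(p, arch, cache, dlogit) {
  B <- cache$B
  g <- list()
  g[["fc.w"]] <- as.numeric(t(cache$feat) %*% dlogit)
  g[["fc.b"]] <- sum(dlogit)
  d <- cache$last_dim; hw <- d[1] * d[2]; C <- d[3] / B
  dfeat <- outer(dlogit, p[["fc.w"]])            # B x C
  dxm <- matrix(rep(as.numeric(t(dfeat)), each = hw) / hw, hw, d[3])
  dx <- dxm; dim(dx) <- d
  for (i in 4:1) for (j in rev(seq_len(arch$blocks[i]))) {
    bw <- block_bwd(dx, cache$blocks[[sprintf("s%db%d", i, j)]], p, B)
    dx <- bw$dx
    g <- c(g, bw$grads)
  }
  dr1 <- maxpool_bwd(dx, dim(dx), cache$mp_idx,
                     cache$r1_dim[1], cache$r1_dim[2])
  dr1 <- dr1 * (cache$b1$y > 0)
  b1w <- bn_bwd(dr1, cache$b1, p[["bn1.gamma"]])
  g[["bn1.gamma"]] <- b1w$dgamma; g[["bn1.beta"]] <- b1w$dbeta
  c1 <- conv2d_bwd(cache$X, dim(cache$X), p[["conv1.w"]], b1w$dx,
                   B, 1L, arch$widths[1],
                   7L, 7L, 2L, arch$conv1_time_stride, 3L, 3L)
  g[["conv1.w"]] <- c1$dw
  g
}

# ---- Adam with decoupled weight decay ---------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)

adam_step <- function(params, grads, opt, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gnm
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gnm^2
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && grepl("conv|fc\\.w", nm))
      step <- step + lr * weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, opt = opt)
}
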