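# Minimal neural-network engine backing the segmenter and the classifiers.
# No deep-learning framework exists in the target R library, so the few
# primitives needed (stride-1 "same" convolutions, instance normalisation,
# leaky ReLU, max/average pooling, nearest-neighbour upsampling) are
# implemented here with explicit backward passes over the C++ kernels.
# Tensors are 4D arrays (z, y, x, channel); 2D networks are 3D networks with
# a singleton z axis and kz = 1 kernels.

.IN_EPS <- 1e-5

.heInit <- function(k, ci, co) {
  fan_in <- prod(k) * ci
  array(rnorm(prod(k) * ci * co, sd = sqrt(2 / fan_in)), dim = c(k, ci, co))
}

.convBlockInit <- function(ci, co, k) {
  list(w = .heInit(k, ci, co), b = numeric(co),
       gamma = rep(1, co), beta = numeric(co))
}

.convInit <- function(ci, co, k) {
  list(w = .heInit(k, ci, co), b = numeric(co))
}

.ensure4d <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

.convFwd <- function(x, p) {
  .conv3d_fwd(x, dim(x), p$w, dim(p$w), p$b)
}

.convBwd <- function(x, p, dy) {
  gw <- .conv3d_bwd_weight(x, dim(x), dy, dim(p$w))
  dx <- .conv3d_bwd_input(dy, dim(x), p$w, dim(p$w))
  list(dx = dx, gw = gw$gw, gb = gw$gb)
}

# Instance norm over the spatial extent of each channel (one instance).
.inFwd <- function(x, gamma, beta) {
  d <- dim(x)
  C <- d[4]
  M <- matrix(x, ncol = C)
  mu <- colMeans(M)
  ctr <- sweep(M, 2, mu)
  istd <- 1 / sqrt(colMeans(ctr^2) + .IN_EPS)
  xhat <- sweep(ctr, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(y = y, xhat = xhat, istd = istd)
}

.inBwd <- function(dy, cache, gamma, d) {
  C <- d[4]
  DY <- matrix(dy, ncol = C)
  dxhat <- sweep(DY, 2, gamma, "*")
  xhat <- cache$xhat
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$istd, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = colSums(DY * xhat), dbeta = colSums(DY))
}

# leaky ReLU as arithmetic (ifelse() is far too slow on volume-sized arrays)
.lrelu <- function(x, pos, slope) x * (pos + slope * (1 - pos))

# conv -> instance norm -> leaky ReLU
.blockFwd <- function(x, p, slope) {
  cz <- .convFwd(x, p)
  innorm <- .inFwd(cz, p$gamma, p$beta)
  pos <- (innorm$y > 0) * 1
  y <- .lrelu(innorm$y, pos, slope)
  dim(y) <- dim(cz)
  list(y = y, x = x, conv = cz, innorm = innorm, pos = pos)
}

.blockBwd <- function(cache, p, dy, slope) {
  dn <- .lrelu(dy, cache$pos, slope)
  dim(dn) <- dim(dy)
  ib <- .inBwd(dn, cache$innorm, p$gamma, dim(cache$conv))
  cb <- .convBwd(cache$x, p, ib$dx)
  list(dx = cb$dx,
       grads = list(w = cb$gw, b = cb$gb, gamma = ib$dgamma, beta = ib$dbeta))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Average pooling by integer factors, via the summing upsample adjoint.
.avgpoolFwd <- function(x, f) {
  d <- dim(x)
  y <- .upsample3d_bwd(x, d, as.integer(f)) / prod(f)
  y
}

.avgpoolBwd <- function(dy, f) {
  .upsample3d_fwd(dy, dim(dy), as.integer(f)) / prod(f)
}

# ---- RMSprop over nested parameter lists ---------------------------------

.rmspropInit <- function(params) {
  rapply(params, function(x) array(0, dim = dim(x) %||% length(x)),
         how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# params, grads, state share one nested shape; returns list(params, state).
.rmspropStep <- function(params, grads, state, lr, decay = 0.9, eps = 1e-8,
                         clip = 5) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (i in seq_along(p)) {   # positional: parameter trees mix (un)named lists
        r <- walk(p[[i]], g[[i]], s[[i]])
        out_p[[i]] <- r$p; out_s[[i]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    g <- pmin(pmax(g, -clip), clip)
    s <- decay * s + (1 - decay) * g^2
    list(p = p - lr * g / (sqrt(s) + eps), s = s)
  }
  walk(params, grads, state)
}

# elementwise sum of two grad trees
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(.addGrads, a, b, SIMPLIFY = FALSE))
  a + b
}

.scaleGrads <- function(a, s) rapply(a, function(x) x * s, how = "replace")
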