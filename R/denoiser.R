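# Conditional epsilon-prediction U-Net, written in base R with explicit
# analytic gradients (no deep-learning framework is involved; convolutions
# are im2col gathers followed by BLAS GEMMs).
#
# Layout: feature maps are matrices of shape (H*W*N, C) with rows ordered
# pixel-fastest (column-major within each H x W image), samples stacked.
# Each encoder/decoder level runs two conv blocks (3x3 periodic conv ->
# instance norm -> [+ gamma-embedding projection, first block only] -> ReLU)
# wrapped in a residual connection (identity, or a learned 1x1 projection
# where the channel count changes). The residual path is essential: instance
# norm removes the per-sample mean of every feature map, and without an
# unnormalised path the network could not track the DC component of y_t --
# whose error the reverse chain amplifies by 1/sqrt(gamma_T).
# Levels are joined by 2x2 average pooling down and factor-2 bilinear
# upsampling + skip concatenation up; a final 3x3 conv maps to one channel.

# ---- geometry: precomputed index maps for one (H, W, N) problem ----------

shiftPerm <- function(H, W, N, dy, dx) {
  y <- rep(0:(H - 1), times = W)
  x <- rep(0:(W - 1), each = H)
  pin <- ((y + dy) %% H) + ((x + dx) %% W) * H + 1L
  as.vector(outer(pin, (0:(N - 1)) * (H * W), `+`))
}

levelGeom <- function(H, W, N) {
  perms <- list(); invs <- list()
  k <- 1L
  for (dx in -1:1) for (dy in -1:1) {
    p <- shiftPerm(H, W, N, dy, dx)
    inv <- integer(length(p)); inv[p] <- seq_along(p)
    perms[[k]] <- p; invs[[k]] <- inv
    k <- k + 1L
  }
  list(H = H, W = W, N = N, perms = perms, invs = invs)
}

poolGeom <- function(H, W, N) {
  Hc <- H %/% 2L; Wc <- W %/% 2L
  yc <- rep(1:Hc, times = Wc); xc <- rep(1:Wc, each = Hc)
  off <- (0:(N - 1)) * (H * W)
  ix <- function(py, px) as.vector(outer(py + (px - 1L) * H, off, `+`))
  list(i00 = ix(2L * yc - 1L, 2L * xc - 1L), i10 = ix(2L * yc, 2L * xc - 1L),
       i01 = ix(2L * yc - 1L, 2L * xc), i11 = ix(2L * yc, 2L * xc))
}

upGeom <- function(Hc, Wc, N) {
  # factor-2 bilinear, periodic: fine pixel 2j-1 mixes coarse (j, j-1),
  # fine pixel 2j mixes (j, j+1), weights 3/4 and 1/4 per axis
  H <- 2L * Hc; W <- 2L * Wc
  axisMaps <- function(nc) {
    i <- 1:(2L * nc)
    base <- (i - 1L) %/% 2L + 1L
    other <- ifelse(i %% 2L == 1L, (base - 2L) %% nc + 1L, base %% nc + 1L)
    list(base = base, other = other)
  }
  ay <- axisMaps(Hc); ax <- axisMaps(Wc)
  offc <- (0:(N - 1)) * (Hc * Wc)
  yIdx <- rep(1:H, times = W); xIdx <- rep(1:W, each = H)
  mk <- function(sy, sx) {
    pc <- sy[yIdx] + (sx[xIdx] - 1L) * Hc
    as.vector(outer(pc, offc, `+`))
  }
  list(maps = list(mk(ay$base, ax$base), mk(ay$other, ax$base),
                   mk(ay$base, ax$other), mk(ay$other, ax$other)),
       w = c(9, 3, 3, 1) / 16,
       nCoarseRows = Hc * Wc * N)
}

# full geometry for a denoiser of given depth on (H, W, N)
makeGeom <- function(H, W, N, depth) {
  if (H %% 2^(depth - 1) != 0 || W %% 2^(depth - 1) != 0)
    stop("image side must be divisible by 2^(depth - 1)")
  levels <- vector("list", depth)
  pools <- vector("list", depth - 1L)
  ups <- vector("list", depth - 1L)
  h <- H; w <- W
  for (l in seq_len(depth)) {
    levels[[l]] <- levelGeom(h, w, N)
    if (l < depth) {
      pools[[l]] <- poolGeom(h, w, N)
      ups[[l]] <- upGeom(h %/% 2L, w %/% 2L, N)
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  list(H = H, W = W, N = N, depth = depth, levels = levels, pools = pools,
       ups = ups, group = rep(seq_len(N), each = H * W))
}

# ---- primitive layers ----------------------------------------------------

im2col <- function(M, lg) {
  Cin <- ncol(M)
  X <- matrix(0, nrow(M), 9L * Cin)
  for (k in 1:9)
    X[, ((k - 1L) * Cin + 1L):(k * Cin)] <- M[lg$perms[[k]], , drop = FALSE]
  X
}

col2im <- function(dX, lg, Cin) {
  out <- dX[, 1:Cin, drop = FALSE][lg$invs[[1]], , drop = FALSE]
  for (k in 2:9)
    out <- out + dX[, ((k - 1L) * Cin + 1L):(k * Cin),
                    drop = FALSE][lg$invs[[k]], , drop = FALSE]
  out
}

# column-wise broadcast helpers (cheaper than matrix(..., byrow = TRUE))
colMul <- function(M, v) M * rep(v, each = nrow(M))
colAdd <- function(M, v) M + rep(v, each = nrow(M))

# conv blocks feeding instance norm carry no bias (the norm would discard
# it); only the output convolution has one
convFwd <- function(M, W, lg) {
  X <- im2col(M, lg)
  list(Y = X %*% W, X = X)
}

convBwd <- function(dY, X, W, lg, Cin) {
  list(dM = col2im(dY %*% t(W), lg, Cin),
       dW = crossprod(X, dY))
}

inormFwd <- function(M, g, be, group, npix, eps = 1e-5) {
  mu <- rowsum(M, group, reorder = TRUE) / npix
  Mc <- M - mu[group, , drop = FALSE]
  v <- rowsum(Mc * Mc, group, reorder = TRUE) / npix
  istd <- 1 / sqrt(v + eps)
  xh <- Mc * istd[group, , drop = FALSE]
  list(Y = colAdd(colMul(xh, g), be), xh = xh, istd = istd)
}

inormBwd <- function(dY, cache, g, group, npix) {
  xh <- cache$xh
  dxh <- colMul(dY, g)
  m1 <- rowsum(dxh, group, reorder = TRUE) / npix
  m2 <- rowsum(dxh * xh, group, reorder = TRUE) / npix
  dM <- (dxh - m1[group, , drop = FALSE] -
         xh * m2[group, , drop = FALSE]) * cache$istd[group, , drop = FALSE]
  list(dM = dM, dg = colSums(dY * xh), dbe = colSums(dY))
}

poolFwd <- function(M, pg)
  (M[pg$i00, , drop = FALSE] + M[pg$i10, , drop = FALSE] +
   M[pg$i01, , drop = FALSE] + M[pg$i11, , drop = FALSE]) / 4

poolBwd <- function(dY, pg, nFineRows) {
  dM <- matrix(0, nFineRows, ncol(dY))
  q <- dY / 4
  dM[pg$i00, ] <- q; dM[pg$i10, ] <- q
  dM[pg$i01, ] <- q; dM[pg$i11, ] <- q
  dM
}

upFwd <- function(M, ug) {
  out <- ug$w[1] * M[ug$maps[[1]], , drop = FALSE]
  for (k in 2:4) out <- out + ug$w[k] * M[ug$maps[[k]], , drop = FALSE]
  out
}

upBwd <- function(dY, ug) {
  out <- matrix(0, ug$nCoarseRows, ncol(dY))
  for (k in 1:4) {
    acc <- rowsum(dY, ug$maps[[k]], reorder = TRUE)
    out <- out + ug$w[k] * acc
  }
  out
}

#' Sinusoidal embedding of the continuous noise level gamma_t
#'
#' @param gamma numeric vector of gamma values in (0, 1].
#' @param embDim even embedding dimension.
#' @return matrix (length(gamma), embDim) of sin/cos features at log-spaced
#'   frequencies.
#' @export
gammaEmbedding <- function(gamma, embDim = 64) {
  half <- embDim %/% 2L
  freqs <- exp(seq(0, log(5000), length.out = half))
  ang <- outer(gamma, freqs)
  cbind(sin(ang), cos(ang))
}

# ---- parameter construction ----------------------------------------------

initConvW <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  matrix(stats::rnorm(9 * cin * cout, sd = sd), 9 * cin, cout)
}

initBlock <- function(cin, cout, embDim, withEmb) {
  p <- list(W = initConvW(cin, cout), g = rep(1, cout), be = numeric(cout))
  if (withEmb) p$Wt <- matrix(0, embDim, cout)
  p
}

# 1x1 projection for residual paths with a channel-count change
initProj <- function(cin, cout)
  matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)

#' Trained/initialised conditional denoiser
#'
#' @slot spec a [DenoiserSpec-class].
#' @slot params nested list of weight matrices.
#' @export
setClass("Denoiser", representation(spec = "DenoiserSpec", params = "list"))

setMethod("show", "Denoiser", function(object) {
  n <- length(unlist(object@params))
  cat(sprintf("Denoiser: depth=%d, channels=%d, %d parameters\n",
              object@spec@depth, object@spec@baseChannels, n))
})

#' Initialise a denoiser network
#'
#' Weights are He-initialised; the output convolution starts at zero so the
#' untrained network predicts zero noise.
#'
#' @param spec a [DenoiserSpec-class].
#' @param seed integer seed for the weight draw.
#' @return A [Denoiser-class].
#' @export
initDenoiser <- function(spec = denoiserSpec(), seed = 1) {
  set.seed(as.integer(seed))
  C <- spec@baseChannels; D <- spec@depth; E <- spec@embDim
  enc <- vector("list", D)
  for (l in seq_len(D)) {
    cin <- if (l == 1L) spec@inChannels else C
    enc[[l]] <- list(a = initBlock(cin, C, E, TRUE),
                     b = initBlock(C, C, E, FALSE))
    if (cin != C) enc[[l]]$P <- initProj(cin, C)
  }
  dec <- if (D > 1L) lapply(seq_len(D - 1L), function(l)
    list(a = initBlock(2L * C, C, E, TRUE),
         b = initBlock(C, C, E, FALSE),
         P = initProj(2L * C, C))) else list()
  out <- list(W = matrix(0, 9L * C, 1L), b = 0)
  new("Denoiser", spec = spec,
      params = list(enc = enc, dec = dec, out = out))
}

# ---- forward / backward ---------------------------------------------------

blockFwd <- function(M, bp, lg, emb, group, npix, keep) {
  cv <- convFwd(M, bp$W, lg)
  inm <- inormFwd(cv$Y, bp$g, bp$be, group, npix)
  Y <- inm$Y
  if (!is.null(bp$Wt)) {
    P <- emb %*% bp$Wt
    Y <- Y + P[group, , drop = FALSE]
  }
  mask <- Y > 0
  list(Y = Y * mask,
       cache = if (keep) list(X = cv$X, inm = inm, mask = mask) else NULL)
}

blockBwd <- function(dY, cache, bp, lg, emb, group, npix, cin) {
  dY <- dY * cache$mask
  gr <- list()
  if (!is.null(bp$Wt)) {
    dP <- rowsum(dY, group, reorder = TRUE)
    gr$Wt <- crossprod(emb, dP)
  }
  inb <- inormBwd(dY, cache$inm, bp$g, group, npix)
  gr$g <- inb$dg; gr$be <- inb$dbe
  cb <- convBwd(inb$dM, cache$X, bp$W, lg, cin)
  gr$W <- cb$dW
  list(dM = cb$dM, grads = gr[c("W", "g", "be",
                                if (!is.null(bp$Wt)) "Wt")])
}

# Forward pass. yt, x: (H*W*N) vectors already flattened; gamma length N.
denoiserFwd <- function(net, ytv, xv, gamma, geom, keep = FALSE) {
  spec <- net@spec; P <- net@params
  D <- spec@depth; C <- spec@baseChannels
  emb <- gammaEmbedding(gamma, spec@embDim)
  groups <- lapply(seq_len(D), function(l) {
    lg <- geom$levels[[l]]
    rep(seq_len(lg$N), each = lg$H * lg$W)
  })
  M <- cbind(ytv, xv)
  cache <- if (keep) list(enc = vector("list", D),
                          dec = vector("list", max(D - 1L, 0L))) else NULL
  skips <- vector("list", D)
  for (l in seq_len(D)) {
    lg <- geom$levels[[l]]; npix <- lg$H * lg$W
    a <- blockFwd(M, P$enc[[l]]$a, lg, emb, groups[[l]], npix, keep)
    b <- blockFwd(a$Y, P$enc[[l]]$b, lg, emb, groups[[l]], npix, keep)
    res <- if (is.null(P$enc[[l]]$P)) M else M %*% P$enc[[l]]$P
    Y <- b$Y + res
    if (keep) cache$enc[[l]] <- list(a = a$cache, b = b$cache, inM = M)
    skips[[l]] <- Y
    if (l < D) M <- poolFwd(Y, geom$pools[[l]])
  }
  M <- skips[[D]]
  for (l in seq(D - 1L, 1L, length.out = max(D - 1L, 0L))) {
    lg <- geom$levels[[l]]; npix <- lg$H * lg$W
    up <- upFwd(M, geom$ups[[l]])
    M2 <- cbind(up, skips[[l]])
    a <- blockFwd(M2, P$dec[[l]]$a, lg, emb, groups[[l]], npix, keep)
    b <- blockFwd(a$Y, P$dec[[l]]$b, lg, emb, groups[[l]], npix, keep)
    if (keep) cache$dec[[l]] <- list(a = a$cache, b = b$cache, inM = M2)
    M <- b$Y + M2 %*% P$dec[[l]]$P
  }
  lg1 <- geom$levels[[1]]
  cv <- convFwd(M, P$out$W, lg1)
  list(out = cv$Y[, 1] + P$out$b,
       cache = if (keep) c(cache, list(outX = cv$X,
       emb = emb, groups = groups)) else NULL)
}

# Backward pass: dOut is d(loss)/d(output vector).
denoiserBwd <- function(net, dOut, geom, cache) {
  spec <- net@spec; P <- net@params
  D <- spec@depth; C <- spec@baseChannels
  emb <- cache$emb; groups <- cache$groups
  grads <- list(enc = vector("list", D), dec = vector("list", max(D - 1L, 0L)),
                out = NULL)
  lg1 <- geom$levels[[1]]
  dOutM <- matrix(dOut, ncol = 1L)
  cb <- convBwd(dOutM, cache$outX, P$out$W, lg1, C)
  grads$out <- list(W = cb$dW, b = sum(dOut))
  dM <- cb$dM
  dSkips <- vector("list", D)
  for (l in seq(1L, D - 1L, length.out = max(D - 1L, 0L))) {
    lg <- geom$levels[[l]]; npix <- lg$H * lg$W
    bb <- blockBwd(dM, cache$dec[[l]]$b, P$dec[[l]]$b, lg, emb, groups[[l]],
                   npix, C)
    ba <- blockBwd(bb$dM, cache$dec[[l]]$a, P$dec[[l]]$a, lg, emb,
                   groups[[l]], npix, 2L * C)
    inM2 <- cache$dec[[l]]$inM
    dM2 <- ba$dM + dM %*% t(P$dec[[l]]$P)
    grads$dec[[l]] <- list(a = ba$grads, b = bb$grads,
                           P = crossprod(inM2, dM))
    dUp <- dM2[, 1:C, drop = FALSE]
    dSkips[[l]] <- dM2[, (C + 1L):(2L * C), drop = FALSE]
    dM <- upBwd(dUp, geom$ups[[l]])
  }
  # dM now sits at the deepest level; walk the encoder back up
  for (l in seq(D, 1L)) {
    lg <- geom$levels[[l]]; npix <- lg$H * lg$W
    dY <- dM
    if (l < D) dY <- dY + dSkips[[l]]
    bb <- blockBwd(dY, cache$enc[[l]]$b, P$enc[[l]]$b, lg, emb, groups[[l]],
                   npix, C)
    cin <- if (l == 1L) spec@inChannels else C
    ba <- blockBwd(bb$dM, cache$enc[[l]]$a, P$enc[[l]]$a, lg, emb,
                   groups[[l]], npix, cin)
    grads$enc[[l]] <- list(a = ba$grads, b = bb$grads)
    dIn <- ba$dM
    if (is.null(P$enc[[l]]$P)) {
      dIn <- dIn + dY
    } else {
      dIn <- dIn + dY %*% t(P$enc[[l]]$P)
      grads$enc[[l]]$P <- crossprod(cache$enc[[l]]$inM, dY)
    }
    if (l > 1L) {
      lgPrev <- geom$levels[[l - 1L]]
      dM <- poolBwd(dIn, geom$pools[[l - 1L]],
                    lgPrev$H * lgPrev$W * lgPrev$N)
    }
  }
  grads
}

#' Predict the noise component epsilon from a noised state
#'
#' @param object a [Denoiser-class].
#' @param yt noised image (matrix) or batch (H x W x N array).
#' @param x conditioning observation, same shape as yt.
#' @param gamma scalar noise level gamma_t in (0, 1] (or vector of length N).
#' @return prediction with the shape of yt; deterministic given weights and
#'   inputs.
#' @export
setGeneric("epsPredict", function(object, yt, x, gamma)
  standardGeneric("epsPredict"))

#' @rdname epsPredict
setMethod("epsPredict", "Denoiser", function(object, yt, x, gamma) {
  single <- is.matrix(yt)
  if (single) { H <- nrow(yt); W <- ncol(yt); N <- 1L }
  else { d <- dim(yt); H <- d[1]; W <- d[2]; N <- d[3] }
  if (!identical(dim(yt), dim(x))) stop("yt and x must share a shape")
  if (length(gamma) == 1L) gamma <- rep(gamma, N)
  geom <- makeGeom(H, W, N, object@spec@depth)
  o <- denoiserFwd(object, as.vector(yt), as.vector(x), gamma, geom)$out
  if (single) matrix(o, H, W) else array(o, dim = c(H, W, N))
})
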