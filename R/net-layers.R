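## Network layer primitives.  Feature volumes are H x W x C arrays (batch
## size is always 1).  Every layer has a forward returning list(out, cache)
## and a backward returning list(dx, <param grads>); gradients are verified
## against central differences in the test suite.

EPS_NORM <- 1e-6   # epsilon inside every standardization

## ---- elementwise -----------------------------------------------------------

.eluFw <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- expm1(x[neg])
  y
}

## derivative expressed through the output (elu'(x) = 1 for x>0, y+1 else)
.eluBw <- function(y, dy) {
  g <- dy
  neg <- y < 0
  g[neg] <- dy[neg] * (y[neg] + 1)
  g
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- convolution (C++ kernels) ---------------------------------------------

.convFw <- function(x, w, b, k) .conv2dForward(x, w, b, as.integer(k))

.convBw <- function(x, dout, w, k, needDx = TRUE) {
  g <- .conv2dBackward(x, dout, w, as.integer(k), needDx)
  if (!needDx) g$dx <- NULL
  g
}

.convInit <- function(cin, cout, k, scale = 1) {
  fan <- k * k * cin
  list(w = matrix(stats::rnorm(fan * cout, sd = scale * sqrt(2 / fan)),
                  fan, cout),
       b = numeric(cout))
}

## ---- maxout ----------------------------------------------------------------

#' Maxout channel reduction
#'
#' Reduces the channel count by a factor `groups` by taking the elementwise
#' maximum within consecutive channel groups (channels `1..g` feed output
#' channel 1, and so on).  Used right after the input convolution to reduce
#' dimensionality.
#'
#' @param x H x W x C feature volume with C divisible by `groups`.
#' @param groups group size (default 2).
#' @return H x W x (C / groups) volume.
#' @export
maxout <- function(x, groups = 2L) {
  .maxoutFw(x, groups)$out
}

.maxoutFw <- function(x, groups) {
  d <- dim(x)
  if (d[3L] %% groups != 0L)
    stop("maxout group mismatch: ", d[3L], " channels, group size ", groups)
  cout <- d[3L] %/% groups
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  out <- matrix(-Inf, d[1L] * d[2L], cout)
  arg <- matrix(1L, d[1L] * d[2L], cout)
  for (s in seq_len(groups)) {
    col <- (seq_len(cout) - 1L) * groups + s
    cand <- xm[, col, drop = FALSE]
    upd <- cand > out
    arg[upd] <- s
    out[upd] <- cand[upd]
  }
  list(out = array(out, c(d[1L], d[2L], cout)),
       cache = list(arg = arg, dimIn = d, groups = groups))
}

.maxoutBw <- function(cache, dout) {
  d <- cache$dimIn
  cout <- d[3L] %/% cache$groups
  dm <- matrix(dout, d[1L] * d[2L], cout)
  dx <- matrix(0, d[1L] * d[2L], d[3L])
  for (s in seq_len(cache$groups)) {
    col <- (seq_len(cout) - 1L) * cache$groups + s
    sel <- cache$arg == s
    tmp <- dx[, col, drop = FALSE]
    tmp[sel] <- dm[sel]
    dx[, col] <- tmp
  }
  array(dx, d)
}

## ---- standardization branches (row / column / instance) --------------------

## mean over the normalization set of a (H,W,C) volume; axis: "row" (over j),
## "col" (over i), "inst" (over i and j).  Returns the reduced values and a
## broadcaster back to full shape.
.normStats <- function(x, axis) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  if (axis == "row") {
    red <- function(v) colMeans(matrix(aperm(v, c(2L, 1L, 3L)), W, H * C))
    bc <- function(r) aperm(array(r, c(H, C, W)), c(1L, 3L, 2L))
    m <- H * C  # number of reduced entries; set size is W
    list(red = red, bc = bc, setSize = W)
  } else if (axis == "col") {
    red <- function(v) colMeans(matrix(v, H, W * C))
    bc <- function(r) array(rep(r, each = H), c(H, W, C))
    list(red = red, bc = bc, setSize = H)
  } else {
    red <- function(v) colMeans(matrix(v, H * W, C))
    bc <- function(r) array(rep(r, each = H * W), c(H, W, C))
    list(red = red, bc = bc, setSize = H * W)
  }
}

## channel-wise affine broadcast helper
.chBc <- function(v, d) array(rep(v, each = d[1L] * d[2L]), d)

.standardizeFw <- function(x, gamma, beta, axis) {
  st <- .normStats(x, axis)
  mu <- st$red(x)
  mub <- st$bc(mu)
  va <- st$red((x - mub)^2)
  sig <- st$bc(sqrt(va + EPS_NORM))
  xhat <- (x - mub) / sig
  d <- dim(x)
  y <- .chBc(gamma, d) * xhat + .chBc(beta, d)
  list(out = y, cache = list(xhat = xhat, sig = sig, axis = axis))
}

.standardizeBw <- function(cache, dy, gamma) {
  d <- dim(dy)
  st <- .normStats(dy, cache$axis)
  gfull <- .chBc(gamma, d)
  dxhat <- dy * gfull
  m1 <- st$bc(st$red(dxhat))
  m2 <- st$bc(st$red(dxhat * cache$xhat))
  dx <- (dxhat - m1 - cache$xhat * m2) / cache$sig
  # channel-wise parameter grads (sum over all positions)
  dgamma <- colSums(matrix(dy * cache$xhat, d[1L] * d[2L], d[3L]))
  dbeta <- colSums(matrix(dy, d[1L] * d[2L], d[3L]))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- RCIN normalization block ----------------------------------------------

.rcinInit <- function(C) {
  fuse <- .convInit(3L * C, C, 1L)
  list(row.gamma = rep(1, C), row.beta = numeric(C),
       col.gamma = rep(1, C), col.beta = numeric(C),
       inst.gamma = rep(1, C), inst.beta = numeric(C),
       fuse.w = fuse$w, fuse.b = fuse$b)
}

## parameter-free default: unit affine, fusion = average of the 3 branches
.rcinIdentityParams <- function(C) {
  w <- matrix(0, 3L * C, C)
  for (c in seq_len(C)) w[c(c, C + c, 2L * C + c), c] <- 1 / 3
  list(row.gamma = rep(1, C), row.beta = numeric(C),
       col.gamma = rep(1, C), col.beta = numeric(C),
       inst.gamma = rep(1, C), inst.beta = numeric(C),
       fuse.w = w, fuse.b = numeric(C))
}

.rcinFw <- function(x, p) {
  d <- dim(x)
  r <- .standardizeFw(x, p$row.gamma, p$row.beta, "row")
  c_ <- .standardizeFw(x, p$col.gamma, p$col.beta, "col")
  n <- .standardizeFw(x, p$inst.gamma, p$inst.beta, "inst")
  cat3 <- array(c(r$out, c_$out, n$out), c(d[1L], d[2L], 3L * d[3L]))
  out <- .convFw(cat3, p$fuse.w, p$fuse.b, 1L)
  list(out = out,
       cache = list(r = r$cache, c = c_$cache, n = n$cache, cat3 = cat3,
                    dimIn = d))
}

.rcinBw <- function(cache, dout, p) {
  d <- cache$dimIn
  C <- d[3L]
  cg <- .convBw(cache$cat3, dout, p$fuse.w, 1L)
  dcat <- cg$dx
  dr <- dcat[, , seq_len(C), drop = FALSE]
  dc <- dcat[, , C + seq_len(C), drop = FALSE]
  dn <- dcat[, , 2L * C + seq_len(C), drop = FALSE]
  br <- .standardizeBw(cache$r, dr, p$row.gamma)
  bc <- .standardizeBw(cache$c, dc, p$col.gamma)
  bn <- .standardizeBw(cache$n, dn, p$inst.gamma)
  list(dx = br$dx + bc$dx + bn$dx,
       grads = list(row.gamma = br$dgamma, row.beta = br$dbeta,
                    col.gamma = bc$dgamma, col.beta = bc$dbeta,
                    inst.gamma = bn$dgamma, inst.beta = bn$dbeta,
                    fuse.w = cg$dw, fuse.b = cg$db))
}

#' RCIN feature-map normalization
#'
#' Three parallel standardization branches — per-row (RN), per-column (CN)
#' and per-channel whole-map instance normalization (IN), each with a
#' learnable channel-wise affine — are concatenated and fused back to the
#' input channel count by a 1x1 convolution.  With `params = NULL` a
#' parameter-free default is used (unit affine, fusion = branch average),
#' which makes the operation deterministic for inspection.
#'
#' @param x H x W x C feature volume.
#' @param params optional parameter list as produced internally by the
#'   network builder.
#' @return H x W x C normalized volume.
#' @export
rcinNormalize <- function(x, params = NULL) {
  if (is.null(params)) params <- .rcinIdentityParams(dim(x)[3L])
  .rcinFw(x, params)$out
}

## ---- squeeze-and-excitation channel attention ------------------------------

.seInit <- function(C, reduction) {
  Cr <- max(1L, C %/% reduction)
  list(w1 = matrix(stats::rnorm(C * Cr, sd = sqrt(2 / (C + Cr))), C, Cr),
       b1 = numeric(Cr),
       w2 = matrix(stats::rnorm(Cr * C, sd = sqrt(2 / (C + Cr))), Cr, C),
       b2 = numeric(C))
}

.seFw <- function(x, p) {
  d <- dim(x)
  s <- colMeans(matrix(x, d[1L] * d[2L], d[3L]))     # squeeze: spatial mean
  z1 <- drop(s %*% p$w1) + p$b1
  a1 <- .eluFw(z1)
  z2 <- drop(a1 %*% p$w2) + p$b2
  g <- .sigmoid(z2)                                  # excitation gates
  out <- x * .chBc(g, d)
  list(out = out, cache = list(x = x, s = s, a1 = a1, g = g, d = d))
}

.seBw <- function(cache, dout, p) {
  d <- cache$d
  g <- cache$g
  dx <- dout * .chBc(g, d)
  dg <- colSums(matrix(dout * cache$x, d[1L] * d[2L], d[3L]))
  dz2 <- dg * g * (1 - g)
  dw2 <- outer(cache$a1, dz2)
  db2 <- dz2
  da1 <- drop(p$w2 %*% dz2)
  dz1 <- .eluBw(cache$a1, da1)
  dw1 <- outer(cache$s, dz1)
  db1 <- dz1
  ds <- drop(p$w1 %*% dz1)
  dx <- dx + .chBc(ds / (d[1L] * d[2L]), d)
  list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

#' Squeeze-and-excitation channel attention
#'
#' Computes a per-channel gate in (0, 1) from the spatial mean of each
#' channel through a two-layer bottleneck (reduction ratio `reduction`) with
#' a sigmoid output, then rescales each channel by its gate.  This lets the
#' network weight informative feature channels (e.g. the co-evolution
#' channels) over noisy ones.
#'
#' @param x H x W x C feature volume.
#' @param reduction bottleneck reduction ratio (default 16).
#' @param params optional parameter list; when `NULL`, parameters are drawn
#'   deterministically (seed 0).
#' @return Gated H x W x C volume.
#' @export
seAttention <- function(x, reduction = 16L, params = NULL) {
  if (is.null(params))
    params <- withSeed(0L, .seInit(dim(x)[3L], reduction))
  .seFw(x, params)$out
}

## run expr under a temporary seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## ---- spatial attention ------------------------------------------------------

.spaInit <- function() .convInit(2L, 1L, 3L)

.spaFw <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  mMean <- rowMeans(xm)
  arg <- max.col(xm, ties.method = "first")
  mMax <- xm[cbind(seq_len(nrow(xm)), arg)]
  pooled <- array(c(mMean, mMax), c(d[1L], d[2L], 2L))
  z <- .convFw(pooled, p$w, p$b, 3L)
  g <- .sigmoid(z[, , 1L])
  out <- x * array(g, d)
  list(out = out, cache = list(x = x, pooled = pooled, g = g, arg = arg, d = d))
}

.spaBw <- function(cache, dout, p) {
  d <- cache$d
  gfull <- array(cache$g, d)
  dx <- dout * gfull
  dg <- rowSums(matrix(dout * cache$x, d[1L] * d[2L], d[3L]))
  dz <- array(dg * cache$g * (1 - cache$g), c(d[1L], d[2L], 1L))
  cg <- .convBw(cache$pooled, dz, p$w, 3L)
  dpool <- cg$dx
  dmean <- dpool[, , 1L] / d[3L]
  dx <- dx + array(dmean, d)
  dmax <- as.vector(dpool[, , 2L])
  dxm <- matrix(0, d[1L] * d[2L], d[3L])
  dxm[cbind(seq_len(length(dmax)), cache$arg)] <- dmax
  dx <- dx + array(dxm, d)
  list(dx = dx, grads = list(w = cg$dw, b = cg$db))
}

#' Spatial attention
#'
#' Pools the feature volume across channels (mean and max), passes the two
#' pooled maps through a 3x3 convolution and a sigmoid to obtain a
#' single-channel positional gate in (0, 1), and rescales every channel by
#' it.  Applied right after the channel attention block, it highlights
#' residue-pair positions carrying signal.
#'
#' @param x H x W x C feature volume.
#' @param params optional parameter list; when `NULL`, parameters are drawn
#'   deterministically (seed 0).
#' @return Gated H x W x C volume.
#' @export
spatialAttention <- function(x, params = NULL) {
  if (is.null(params)) params <- withSeed(0L, .spaInit())
  .spaFw(x, params)$out
}

## ---- softmax over the bin dimension ----------------------------------------

.softmaxBins <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1L] * d[2L], d[3L])
  mx <- do.call(pmax, as.data.frame(m))
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, d)
}
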