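## Model builder, forward pass and (internal) backward pass.
##
## Layer-counting convention for the published 156-convolution budget:
##   1 input conv + nBlocks x 2 trunk convs + 1 shared pre-head conv
##   + 2 head convs  =  totalConvLayers.
## Auxiliary 1x1 fusion convs (RCIN), SE bottleneck layers and the spatial
## attention conv are not counted; the default 156 therefore implies 76
## residual blocks.  networkSummary() reports the counted layers so the
## convention is inspectable.

#' Network configuration
#'
#' @param totalConvLayers total number of counted 2D convolution layers
#'   (default 156; must satisfy `totalConvLayers = 4 + 2 * nBlocks`).
#' @param filters channels per trunk convolution (default 64).
#' @param bins output distance bins per head (42 for the published
#'   discretization; other values trigger a warning, not an error).
#' @param maxoutGroups Maxout group size after the input convolution
#'   (default 2).
#' @param seReduction squeeze-and-excitation bottleneck ratio (default 16).
#' @param kernel trunk kernel size (default 3).
#' @param seed integer seed controlling parameter initialization.
#' @return A validated `NetworkConfig` list.
#' @export
networkConfig <- function(totalConvLayers = 156L, filters = 64L, bins = 42L,
                          maxoutGroups = 2L, seReduction = 16L, kernel = 3L,
                          seed = 0L) {
  totalConvLayers <- as.integer(totalConvLayers)
  if (totalConvLayers < 4L)
    stop("totalConvLayers must be at least 4 (input, pre-head, two heads)")
  if ((totalConvLayers - 4L) %% 2L != 0L)
    stop("totalConvLayers must equal 4 + 2 * nBlocks")
  if (filters < 1L) stop("filters must be positive")
  if (bins != 42L)
    warning("bins != 42: the published discretization and loss use 42 bins")
  cfg <- list(totalConvLayers = totalConvLayers, filters = as.integer(filters),
              bins = as.integer(bins), maxoutGroups = as.integer(maxoutGroups),
              seReduction = as.integer(seReduction), kernel = as.integer(kernel),
              seed = as.integer(seed),
              nBlocks = (totalConvLayers - 4L) %/% 2L)
  class(cfg) <- "NetworkConfig"
  cfg
}

.blockName <- function(b) sprintf("b%03d", b)

## gather sub-parameters "prefix.*" into a list without the prefix
.pp <- function(params, prefix) {
  nm <- names(params)
  sel <- startsWith(nm, prefix)
  out <- params[sel]
  names(out) <- substring(nm[sel], nchar(prefix) + 1L)
  out
}

#' Build the distogram network
#'
#' Constructs the full parameter set: input convolution + Maxout reduction,
#' `nBlocks` attention-powered residual blocks (RCIN normalization, two
#' trunk convolutions with ELU, SE channel attention, spatial attention,
#' residual skip), a shared pre-head convolution and two 42-bin softmax
#' distogram heads (minimum heavy-atom distance and Cb-Cb distance).
#' Initialization is deterministic given `config$seed`.
#'
#' @param config a [networkConfig()] list.
#' @return A `DistogramNetwork` list with elements `config` and `params`.
#' @examples
#' net <- buildNetwork(networkConfig(totalConvLayers = 8, filters = 4))
#' networkSummary(net)$convLayers
#' @export
buildNetwork <- function(config = networkConfig()) {
  stopifnot(inherits(config, "NetworkConfig"))
  nf <- config$filters; k <- config$kernel; g <- config$maxoutGroups
  params <- withSeed(config$seed, {
    p <- list()
    inc <- .convInit(N_INPUT_CHANNELS, nf * g, k)
    p[["in.conv.w"]] <- inc$w; p[["in.conv.b"]] <- inc$b
    for (b in seq_len(config$nBlocks)) {
      pn <- .blockName(b)
      rc <- .rcinInit(nf)
      for (nm in names(rc)) p[[paste0(pn, ".rcin.", nm)]] <- rc[[nm]]
      c1 <- .convInit(nf, nf, k); c2 <- .convInit(nf, nf, k)
      p[[paste0(pn, ".conv1.w")]] <- c1$w; p[[paste0(pn, ".conv1.b")]] <- c1$b
      p[[paste0(pn, ".conv2.w")]] <- c2$w; p[[paste0(pn, ".conv2.b")]] <- c2$b
      se <- .seInit(nf, config$seReduction)
      for (nm in names(se)) p[[paste0(pn, ".se.", nm)]] <- se[[nm]]
      sp <- .spaInit()
      p[[paste0(pn, ".spa.w")]] <- sp$w; p[[paste0(pn, ".spa.b")]] <- sp$b
    }
    ph <- .convInit(nf, nf, k)
    p[["prehead.conv.w"]] <- ph$w; p[["prehead.conv.b"]] <- ph$b
    hh <- .convInit(nf, config$bins, k); hc <- .convInit(nf, config$bins, k)
    p[["head.heavy.w"]] <- hh$w; p[["head.heavy.b"]] <- hh$b
    p[["head.cb.w"]] <- hc$w; p[["head.cb.b"]] <- hc$b
    p
  })
  model <- list(config = config, params = params)
  class(model) <- "DistogramNetwork"
  model
}

#' @export
print.DistogramNetwork <- function(x, ...) {
  s <- networkSummary(x)
  cat(sprintf(paste0("DistogramNetwork: %d counted conv layers (%d residual ",
                     "blocks), %d filters, %d bins/head, %d input channels, ",
                     "%s parameters\n"),
              s$convLayers, x$config$nBlocks, s$filters, s$bins,
              s$inputChannels, format(s$nParameters, big.mark = ",")))
  invisible(x)
}

#' Architecture introspection
#'
#' Reports the counted convolution layers (see the counting convention in
#' the package vignette), the filter width of every trunk convolution, the
#' number of output bins per head, the expected input channel count and the
#' total parameter count.
#'
#' @param model a `DistogramNetwork`.
#' @return List with `convLayers`, `countedLayerNames`, `trunkFilters`,
#'   `filters`, `bins`, `inputChannels`, `nParameters`.
#' @export
networkSummary <- function(model) {
  p <- model$params
  counted <- grep("^(in\\.conv|b[0-9]+\\.conv[12]|prehead\\.conv|head\\.(heavy|cb))\\.w$",
                  names(p), value = TRUE)
  trunk <- grep("^b[0-9]+\\.conv[12]\\.w$", names(p), value = TRUE)
  list(convLayers = length(counted),
       countedLayerNames = sub("\\.w$", "", counted),
       trunkFilters = vapply(p[trunk], ncol, integer(1)),
       filters = model$config$filters,
       bins = model$config$bins,
       inputChannels = N_INPUT_CHANNELS,
       nParameters = sum(vapply(p, length, integer(1))))
}

## full forward pass; needCache = TRUE retains everything backward needs
.forwardFull <- function(model, x, needCache = FALSE) {
  cfg <- model$config; p <- model$params; k <- cfg$kernel
  cache <- if (needCache) list(x0 = x) else NULL
  h <- .convFw(x, p[["in.conv.w"]], p[["in.conv.b"]], k)
  mx <- .maxoutFw(h, cfg$maxoutGroups)
  cur <- mx$out
  if (needCache) cache$maxout <- mx$cache
  for (b in seq_len(cfg$nBlocks)) {
    pn <- .blockName(b)
    skip <- cur
    rc <- .rcinFw(cur, .pp(p, paste0(pn, ".rcin.")))
    c1 <- .convFw(rc$out, p[[paste0(pn, ".conv1.w")]],
                  p[[paste0(pn, ".conv1.b")]], k)
    a1 <- .eluFw(c1)
    c2 <- .convFw(a1, p[[paste0(pn, ".conv2.w")]],
                  p[[paste0(pn, ".conv2.b")]], k)
    se <- .seFw(c2, .pp(p, paste0(pn, ".se.")))
    sp <- .spaFw(se$out, .pp(p, paste0(pn, ".spa.")))
    if (needCache)
      cache[[pn]] <- list(skip = skip, rcin = rc, c1in = rc$out, a1 = a1,
                          c2in = a1, se = se$cache, spa = sp$cache)
    cur <- sp$out + skip
  }
  ph <- .convFw(cur, p[["prehead.conv.w"]], p[["prehead.conv.b"]], k)
  pa <- .eluFw(ph)
  lheavy <- .convFw(pa, p[["head.heavy.w"]], p[["head.heavy.b"]], k)
  lcb <- .convFw(pa, p[["head.cb.w"]], p[["head.cb.b"]], k)
  if (needCache) { cache$trunkOut <- cur; cache$pa <- pa }
  list(heavyProbs = .softmaxBins(lheavy), cbProbs = .softmaxBins(lcb),
       cache = cache)
}

## backward pass from per-head logit gradients; returns flat gradient list
.backwardFull <- function(model, cache, dheavy, dcb) {
  cfg <- model$config; p <- model$params; k <- cfg$kernel
  g <- list()
  hh <- .convBw(cache$pa, dheavy, p[["head.heavy.w"]], k)
  hc <- .convBw(cache$pa, dcb, p[["head.cb.w"]], k)
  g[["head.heavy.w"]] <- hh$dw; g[["head.heavy.b"]] <- hh$db
  g[["head.cb.w"]] <- hc$dw; g[["head.cb.b"]] <- hc$db
  dpa <- hh$dx + hc$dx
  dph <- .eluBw(cache$pa, dpa)
  pb <- .convBw(cache$trunkOut, dph, p[["prehead.conv.w"]], k)
  g[["prehead.conv.w"]] <- pb$dw; g[["prehead.conv.b"]] <- pb$db
  dcur <- pb$dx
  for (b in rev(seq_len(cfg$nBlocks))) {
    pn <- .blockName(b)
    bc <- cache[[pn]]
    sb <- .spaBw(bc$spa, dcur, .pp(p, paste0(pn, ".spa.")))
    for (nm in names(sb$grads)) g[[paste0(pn, ".spa.", nm)]] <- sb$grads[[nm]]
    eb <- .seBw(bc$se, sb$dx, .pp(p, paste0(pn, ".se.")))
    for (nm in names(eb$grads)) g[[paste0(pn, ".se.", nm)]] <- eb$grads[[nm]]
    c2b <- .convBw(bc$c2in, eb$dx, p[[paste0(pn, ".conv2.w")]], k)
    g[[paste0(pn, ".conv2.w")]] <- c2b$dw; g[[paste0(pn, ".conv2.b")]] <- c2b$db
    da1 <- .eluBw(bc$a1, c2b$dx)
    c1b <- .convBw(bc$c1in, da1, p[[paste0(pn, ".conv1.w")]], k)
    g[[paste0(pn, ".conv1.w")]] <- c1b$dw; g[[paste0(pn, ".conv1.b")]] <- c1b$db
    rb <- .rcinBw(bc$rcin$cache, c1b$dx, .pp(p, paste0(pn, ".rcin.")))
    for (nm in names(rb$grads)) g[[paste0(pn, ".rcin.", nm)]] <- rb$grads[[nm]]
    dcur <- rb$dx + dcur          # residual skip
  }
  dmx <- .maxoutBw(cache$maxout, dcur)
  ib <- .convBw(cache$x0, dmx, p[["in.conv.w"]], k, needDx = FALSE)
  g[["in.conv.w"]] <- ib$dw; g[["in.conv.b"]] <- ib$db
  g
}

#' Run the network on a feature stack
#'
#' Deterministic inference pass: the input tensor flows through the input
#' convolution + Maxout, the residual trunk and both softmax heads, yielding
#' per-cell probability distributions over the 42 distance bins for the
#' heavy-atom and Cb distance definitions.
#'
#' @param model a `DistogramNetwork` from [buildNetwork()].
#' @param stack a [FeatureStack-class] (or a bare n x n x 186 array, in which
#'   case both chain lengths are taken as n).
#' @return A [DistogramPrediction-class].
#' @export
forwardPass <- function(model, stack) {
  if (is(stack, "FeatureStack")) {
    x <- featureTensor(stack)
    lengths <- chainLengths(stack)
  } else {
    x <- stack
    lengths <- c(dim(x)[1L], dim(x)[1L])
  }
  d <- dim(x)
  if (length(d) != 3L || d[3L] != N_INPUT_CHANNELS)
    stop("feature shape mismatch: expected n x n x ", N_INPUT_CHANNELS,
         " input, got ", paste(d, collapse = " x "))
  f <- .forwardFull(model, x, needCache = FALSE)
  new("DistogramPrediction", heavyProbs = f$heavyProbs, cbProbs = f$cbProbs,
      lengths = as.integer(lengths))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are tensor archives holding the flat parameter list plus the
#' network configuration as metadata.
#'
#' @param model a `DistogramNetwork`.
#' @param file checkpoint path.
#' @return `saveCheckpoint`: `file`, invisibly.  `loadCheckpoint`: the
#'   restored `DistogramNetwork`.
#' @export
saveCheckpoint <- function(model, file) {
  writeTensorArchive(model$params, file,
                     metadata = list(config = unclass(model$config)))
  invisible(file)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(file) {
  obj <- readTensorArchive(file)
  cfg <- obj$metadata$config
  config <- do.call(networkConfig, cfg[c("totalConvLayers", "filters", "bins",
                                         "maxoutGroups", "seReduction",
                                         "kernel", "seed")])
  model <- list(config = config, params = obj$arrays)
  class(model) <- "DistogramNetwork"
  model
}
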