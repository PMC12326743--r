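# Trainable 3D convolutional embedding backbones.
#
# Networks are represented as nested lists of layers (conv / batch-norm /
# ReLU / max-pool / global-average-pool / linear / residual blocks), each
# carrying its parameter arrays. Forward passes record per-layer caches so
# an exact reverse-mode backward pass can produce parameter gradients for
# the episodic SGD loop. Convolution and pooling use compiled kernels;
# batch-norm and the small layers are vectorized R.
#
# Tensor convention: batches are (N, C, D, H, W) double arrays; embeddings
# are (N, embed_dim) matrices.

# ---- layer constructors ----------------------------------------------------

layer_conv <- function(cin, cout, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                       pad = c(1L, 1L, 1L)) {
  k <- rep(as.integer(k), length.out = 3)
  sd <- sqrt(2 / (cin * prod(k))) # He initialization for ReLU nets
  w <- array(stats::rnorm(cout * cin * prod(k), sd = sd),
             dim = c(cout, cin, k))
  list(type = "conv", w = w, b = numeric(cout),
       stride = rep(as.integer(stride), length.out = 3),
       pad = rep(as.integer(pad), length.out = 3))
}

layer_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       eps = eps, momentum = momentum)
}

layer_relu <- function() list(type = "relu")

layer_pool <- function(size = c(2L, 2L, 2L), stride = NULL) {
  size <- rep(as.integer(size), length.out = 3)
  if (is.null(stride)) stride <- size
  list(type = "pool", size = size, stride = rep(as.integer(stride), length.out = 3))
}

layer_gap <- function() list(type = "gap")

layer_linear <- function(nin, nout) {
  list(type = "linear",
       w = matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

layer_res <- function(main, down = NULL) {
  list(type = "res", main = main, down = down)
}

# ---- forward / backward ----------------------------------------------------

# Per-channel sums without transposing the (N, C, D, H, W) tensor: the flat
# layout groups (n, c) pairs contiguously, so a length-N*C vector recycles
# across the spatial blocks in plain vector arithmetic.
bn_channel_sums <- function(v, N, C, V) {
  s <- .rowSums(v, N * C, V)
  .colSums(matrix(s, N, C), N, C)
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      y <- conv3d_fwd(x, layer$w, layer$b, layer$stride, layer$pad)
      list(out = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      N <- d[1]; C <- d[2]; V <- prod(d[3:5])
      if (train) {
        mu <- bn_channel_sums(x, N, C, V) / (N * V)
        v <- bn_channel_sums(x * x, N, C, V) / (N * V) - mu^2
        v[v < 0] <- 0 # guard rounding on near-constant channels
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      scale <- layer$gamma * invstd
      shift <- layer$beta - mu * scale
      y <- x * rep(scale, each = N) + rep(shift, each = N)
      list(out = y,
           cache = list(x = x, mu = mu, invstd = invstd, d = d, train = train),
           layer = layer)
    },
    relu = {
      list(out = pmax(x, 0), cache = list(mask = x > 0), layer = layer)
    },
    pool = {
      r <- maxpool3d_fwd(x, layer$size, layer$stride)
      list(out = r$y, cache = list(argmax = r$argmax, xdim = dim(x)),
           layer = layer)
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, nrow = d[1] * d[2])
      list(out = matrix(rowMeans(m), d[1], d[2]), cache = list(d = d),
           layer = layer)
    },
    linear = {
      list(out = x %*% t(layer$w) + matrix(layer$b, nrow(x), length(layer$b),
                                           byrow = TRUE),
           cache = list(x = x), layer = layer)
    },
    res = {
      main_caches <- vector("list", length(layer$main))
      h <- x
      for (i in seq_along(layer$main)) {
        r <- layer_forward(layer$main[[i]], h, train)
        h <- r$out; main_caches[[i]] <- r$cache; layer$main[[i]] <- r$layer
      }
      down_caches <- NULL
      s <- x
      if (!is.null(layer$down)) {
        down_caches <- vector("list", length(layer$down))
        for (i in seq_along(layer$down)) {
          r <- layer_forward(layer$down[[i]], s, train)
          s <- r$out; down_caches[[i]] <- r$cache; layer$down[[i]] <- r$layer
        }
      }
      y <- h + s
      list(out = pmax(y, 0),
           cache = list(main = main_caches, down = down_caches, mask = y > 0),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, gy, need_gx = TRUE) {
  switch(layer$type,
    conv = {
      r <- conv3d_bwd(cache$x, layer$w, gy, layer$stride, layer$pad, need_gx)
      list(gin = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    bn = {
      d <- cache$d
      N <- d[1]; C <- d[2]; V <- prod(d[3:5])
      xhat <- (cache$x - rep(cache$mu, each = N)) * rep(cache$invstd, each = N)
      dgamma <- bn_channel_sums(gy * xhat, N, C, V)
      dbeta <- bn_channel_sums(gy, N, C, V)
      a <- layer$gamma * cache$invstd
      if (cache$train) {
        gx <- gy * rep(a, each = N) -
          rep(a * dbeta / (N * V), each = N) -
          xhat * rep(a * dgamma / (N * V), each = N)
      } else {
        gx <- gy * rep(a, each = N)
      }
      list(gin = gx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(gin = gy * cache$mask, grads = NULL),
    pool = list(gin = maxpool3d_bwd(gy, cache$argmax, cache$xdim), grads = NULL),
    gap = {
      d <- cache$d
      nvox <- prod(d[3:5])
      gx <- array(rep(as.vector(gy) / nvox, nvox), dim = d)
      list(gin = gx, grads = NULL)
    },
    linear = {
      list(gin = gy %*% layer$w,
           grads = list(w = t(gy) %*% cache$x, b = colSums(gy)))
    },
    res = {
      g <- gy * cache$mask
      gm <- g
      main_grads <- vector("list", length(layer$main))
      for (i in rev(seq_along(layer$main))) {
        r <- layer_backward(layer$main[[i]], cache$main[[i]], gm)
        gm <- r$gin; main_grads[i] <- list(r$grads)
      }
      gs <- g
      down_grads <- NULL
      if (!is.null(layer$down)) {
        down_grads <- vector("list", length(layer$down))
        for (i in rev(seq_along(layer$down))) {
          r <- layer_backward(layer$down[[i]], cache$down[[i]], gs)
          gs <- r$gin; down_grads[i] <- list(r$grads)
        }
      }
      list(gin = gm + gs, grads = list(main = main_grads, down = down_grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], h, train)
    h <- r$out; caches[[i]] <- r$cache; net$layers[[i]] <- r$layer
  }
  list(out = h, caches = caches, net = net)
}

net_backward <- function(net, caches, gout) {
  grads <- vector("list", length(net$layers))
  g <- gout
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], g, need_gx = i > 1)
    g <- r$gin; grads[i] <- list(r$grads)
  }
  list(grads = grads, gin = g)
}

# ---- parameter access ------------------------------------------------------

.PARAM_FIELDS <- c("w", "b", "gamma", "beta")
.BUFFER_FIELDS <- c("run_mean", "run_var")

collect_weights <- function(layers, prefix, include_buffers = TRUE) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    path <- paste0(prefix, i)
    if (l$type == "res") {
      out <- c(out, collect_weights(l$main, paste0(path, ".main."), include_buffers))
      if (!is.null(l$down)) {
        out <- c(out, collect_weights(l$down, paste0(path, ".down."), include_buffers))
      }
    } else {
      fields <- .PARAM_FIELDS
      if (include_buffers) fields <- c(fields, .BUFFER_FIELDS)
      for (f in fields) {
        if (!is.null(l[[f]])) out[[paste0(path, ".", l$type, ".", f)]] <- l[[f]]
      }
    }
  }
  out
}

assign_weights <- function(layers, prefix, w) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    path <- paste0(prefix, i)
    if (l$type == "res") {
      l$main <- assign_weights(l$main, paste0(path, ".main."), w)
      if (!is.null(l$down)) {
        l$down <- assign_weights(l$down, paste0(path, ".down."), w)
      }
    } else {
      for (f in c(.PARAM_FIELDS, .BUFFER_FIELDS)) {
        nm <- paste0(path, ".", l$type, ".", f)
        if (!is.null(l[[f]]) && !is.null(w[[nm]])) {
          old <- l[[f]]
          new <- w[[nm]]
          if (length(old) != length(new) ||
              !identical(dim(old), dim(new))) {
            stop("shape mismatch loading weights for ", nm)
          }
          l[[f]] <- new
        }
      }
    }
    layers[[i]] <- l
  }
  layers
}

#' Extract a backbone's weights as an ordered name/array mapping
#'
#' The returned list (class `model_weights`) is the unit of federated
#' exchange: parameter and batch-norm running-statistic arrays keyed by
#' stable layer-path names, in a deterministic order shared by all builds of
#' the same architecture.
#'
#' @param net A backbone built by [build_backbone()].
#' @return Named list of numeric arrays, class `model_weights`.
#' @export
get_weights <- function(net) {
  structure(collect_weights(net$layers, "l"), class = "model_weights")
}

#' Load weights into a backbone
#'
#' Arrays are matched by name and must agree in shape; names absent from
#' `weights` keep their current values.
#'
#' @param net A backbone built by [build_backbone()].
#' @param weights Named list of arrays as returned by [get_weights()].
#' @return The backbone with weights installed.
#' @export
set_weights <- function(net, weights) {
  known <- names(collect_weights(net$layers, "l"))
  extra <- setdiff(names(weights), known)
  if (length(extra) > 0) {
    stop("unknown parameter name(s) in weights: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  net$layers <- assign_weights(net$layers, "l", weights)
  net
}

#' Count trainable parameters of a backbone
#' @param net A backbone.
#' @return Integer number of scalar parameters (batch-norm running
#'   statistics excluded).
#' @export
n_parameters <- function(net) {
  w <- collect_weights(net$layers, "l", include_buffers = FALSE)
  sum(vapply(w, length, numeric(1)))
}

# ---- architectures ---------------------------------------------------------

basic_block <- function(cin, cout, stride) {
  down <- NULL
  if (stride != 1 || cin != cout) {
    down <- list(layer_conv(cin, cout, k = 1, stride = stride, pad = 0),
                 layer_bn(cout))
  }
  layer_res(
    main = list(
      layer_conv(cin, cout, k = 3, stride = stride, pad = 1),
      layer_bn(cout), layer_relu(),
      layer_conv(cout, cout, k = 3, stride = 1, pad = 1),
      layer_bn(cout)
    ),
    down = down
  )
}

bottleneck_block <- function(cin, planes, stride) {
  cout <- planes * 4L
  down <- NULL
  if (stride != 1 || cin != cout) {
    down <- list(layer_conv(cin, cout, k = 1, stride = stride, pad = 0),
                 layer_bn(cout))
  }
  layer_res(
    main = list(
      layer_conv(cin, planes, k = 1, stride = 1, pad = 0),
      layer_bn(planes), layer_relu(),
      layer_conv(planes, planes, k = 3, stride = stride, pad = 1),
      layer_bn(planes), layer_relu(),
      layer_conv(planes, cout, k = 1, stride = 1, pad = 0),
      layer_bn(cout)
    ),
    down = down
  )
}

resnet3d_layers <- function(blocks, bottleneck) {
  layers <- list(
    layer_conv(3L, 64L, k = 7, stride = c(1L, 2L, 2L), pad = 3),
    layer_bn(64L), layer_relu(),
    layer_pool(c(2L, 2L, 2L))
  )
  planes <- c(64L, 128L, 256L, 512L)
  cin <- 64L
  for (s in 1:4) {
    stride <- if (s == 1) 1L else 2L
    for (b in seq_len(blocks[s])) {
      st <- if (b == 1) stride else 1L
      if (bottleneck) {
        layers <- c(layers, list(bottleneck_block(cin, planes[s], st)))
        cin <- planes[s] * 4L
      } else {
        layers <- c(layers, list(basic_block(cin, planes[s], st)))
        cin <- planes[s]
      }
    }
  }
  list(layers = c(layers, list(layer_gap())), out_dim = cin)
}

#' Build a volumetric embedding backbone
#'
#' Available architectures:
#' \describe{
#'   \item{`tiny3d`}{Three conv/batch-norm/ReLU/max-pool blocks followed by
#'     global average pooling; the desk-scale default (input slices may be
#'     as small as 32 pixels). Default `embed_dim` 64.}
#'   \item{`resnet3d-10/-18/-34/-50`}{3D residual networks (basic blocks for
#'     10/18/34, bottleneck blocks for 50) with a 7x7x7 stem. Natural output
#'     widths are 512 (basic) and 2048 (bottleneck); passing a different
#'     `embed_dim` appends a linear projection head.}
#' }
#' Initialization is He-normal and fully determined by `seed`; external
#' weights can be installed afterwards by name/shape matching.
#'
#' @param name Architecture name.
#' @param embed_dim Embedding dimension (default: 64 for `tiny3d`, the
#'   natural width for the residual nets).
#' @param seed Integer seed for the initialization stream.
#' @param init_weights Optional named weight list (see [get_weights()]).
#' @return A backbone object (class `embedding_network`).
#' @export
build_backbone <- function(name = c("tiny3d", "resnet3d-10", "resnet3d-18",
                                    "resnet3d-34", "resnet3d-50"),
                           embed_dim = NULL, seed = 0L, init_weights = NULL) {
  name <- match.arg(name)
  rng <- rng_stream(derive_seed(seed, paste0("init/", name)))
  net <- with_rng(rng, {
    if (name == "tiny3d") {
      if (is.null(embed_dim)) embed_dim <- 64L
      layers <- list(
        layer_conv(3L, 8L, k = 3, stride = c(1L, 2L, 2L), pad = 1),
        layer_bn(8L), layer_relu(), layer_pool(c(2L, 2L, 2L)),
        layer_conv(8L, 16L, k = 3, stride = 1, pad = 1),
        layer_bn(16L), layer_relu(), layer_pool(c(2L, 2L, 2L)),
        layer_conv(16L, as.integer(embed_dim), k = 3, stride = 1, pad = 1),
        layer_bn(as.integer(embed_dim)), layer_relu(), layer_gap()
      )
      list(layers = layers, embed_dim = as.integer(embed_dim))
    } else {
      spec <- switch(name,
        "resnet3d-10" = list(blocks = c(1L, 1L, 1L, 1L), bottleneck = FALSE),
        "resnet3d-18" = list(blocks = c(2L, 2L, 2L, 2L), bottleneck = FALSE),
        "resnet3d-34" = list(blocks = c(3L, 4L, 6L, 3L), bottleneck = FALSE),
        "resnet3d-50" = list(blocks = c(3L, 4L, 6L, 3L), bottleneck = TRUE)
      )
      r <- resnet3d_layers(spec$blocks, spec$bottleneck)
      layers <- r$layers
      dim_out <- r$out_dim
      if (!is.null(embed_dim) && as.integer(embed_dim) != dim_out) {
        layers <- c(layers, list(layer_linear(dim_out, as.integer(embed_dim))))
        dim_out <- as.integer(embed_dim)
      }
      list(layers = layers, embed_dim = dim_out)
    }
  })
  out <- structure(
    list(name = name, embed_dim = net$embed_dim, layers = net$layers,
         seed = as.integer(seed)),
    class = "embedding_network"
  )
  if (!is.null(init_weights)) out <- set_weights(out, init_weights)
  out
}

#' @export
print.embedding_network <- function(x, ...) {
  cat(sprintf("<embedding_network> %s  embed_dim=%d  parameters=%s\n",
              x$name, x$embed_dim, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Embed a batch of volumes
#'
#' Runs the backbone forward in evaluation mode (batch-norm uses running
#' statistics), mapping a `(N, 3, depth, H, W)` batch to `(N, embed_dim)`.
#'
#' @param net A backbone.
#' @param batch Numeric array `(N, 3, depth, H, W)` (a single volume
#'   `(3, depth, H, W)` is promoted to a batch of one).
#' @return Matrix of embeddings, one row per volume.
#' @export
embed_volumes <- function(net, batch) {
  if (length(dim(batch)) == 4) {
    batch <- array(batch, dim = c(1L, dim(batch)))
  }
  net_forward(net, batch, train = FALSE)$out
}
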