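test_that("backbone initialization is seed-deterministic and weights round-trip", {
  n1 <- build_backbone("tiny3d", seed = 3)
  n2 <- build_backbone("tiny3d", seed = 3)
  expect_same_weights(get_weights(n1), get_weights(n2))
  n3 <- build_backbone("tiny3d", seed = 4)
  expect_false(identical(get_weights(n1)[[1]], get_weights(n3)[[1]]))

  # install external weights by name, reject shape mismatches
  w <- get_weights(n3)
  n4 <- build_backbone("tiny3d", seed = 3, init_weights = w)
  expect_same_weights(get_weights(n4), w)
  bad <- w
  bad[[1]] <- array(0, dim = c(2, 2, 2, 2, 2))
  expect_error(set_weights(n1, bad), "shape mismatch")
  names(bad)[1] <- "nonexistent.param"
  expect_error(set_weights(n1, bad), "unknown parameter")
  expect_error(build_backbone("vgg"), "arg")
})

test_that("tiny3d maps volume batches to embedding vectors deterministically", {
  net <- build_backbone("tiny3d", seed = 1)
  x <- with_rng(rng_stream(2), array(rnorm(4 * 3 * 15 * 32 * 32),
                                     dim = c(4, 3, 15, 32, 32)))
  e <- embed_volumes(net, x)
  expect_identical(dim(e), c(4L, 64L))
  expect_true(all(is.finite(e)))
  expect_identical(e, embed_volumes(net, x))
  # a single volume is promoted to a batch of one
  e1 <- embed_volumes(net, x[2, , , , ])
  expect_equal(as.vector(e1), as.vector(e[2, ]))
  # configurable embedding width
  expect_identical(ncol(embed_volumes(build_backbone("tiny3d", embed_dim = 16,
                                                     seed = 1), x)), 16L)
})

test_that("deeper residual variants have more parameters and run forward", {
  p10 <- n_parameters(build_backbone("resnet3d-10", seed = 0))
  p18 <- n_parameters(build_backbone("resnet3d-18", seed = 0))
  expect_gt(p18, p10)
  p50 <- n_parameters(build_backbone("resnet3d-50", seed = 0))
  expect_gt(p50, p10)

  r10 <- build_backbone("resnet3d-10", seed = 2)
  x <- with_rng(rng_stream(5), array(rnorm(1 * 3 * 8 * 16 * 16),
                                     dim = c(1, 3, 8, 16, 16)))
  e <- embed_volumes(r10, x)
  expect_identical(dim(e), c(1L, 512L))
  expect_true(all(is.finite(e)))
})

# Central correctness check: analytic parameter gradients match central
# finite differences through the full network + episode loss.
grad_check <- function(net, x, picks, tol = 1e-5) {
  slab <- c(0L, 1L)
  qlab <- c(0L, 1L)
  lossfun <- function(nn) {
    fw <- protofed:::net_forward(nn, x, train = TRUE)
    emb <- fw$out
    protofed:::episode_loss_grad(emb[1:2, , drop = FALSE], slab,
                                 emb[3:4, , drop = FALSE], qlab)$loss
  }
  fw <- protofed:::net_forward(net, x, train = TRUE)
  emb <- fw$out
  lg <- protofed:::episode_loss_grad(emb[1:2, , drop = FALSE], slab,
                                     emb[3:4, , drop = FALSE], qlab)
  bw <- protofed:::net_backward(fw$net, fw$caches,
                                rbind(lg$grad_support, lg$grad_query))
  for (pk in picks) {
    path <- pk[[1]]
    field <- pk[[2]]
    idx <- pk[[3]]
    ana <- bw$grads
    for (p in path) ana <- ana[[p]]
    ana <- ana[[field]][idx]
    eps <- 1e-5
    bump <- function(nn, delta) {
      # walk down the nested layer lists to perturb one coordinate
      setter <- function(lst, path) {
        if (length(path) == 1) {
          lst[[path[[1]]]][[field]][idx] <-
            lst[[path[[1]]]][[field]][idx] + delta
          return(lst)
        }
        lst[[path[[1]]]] <- setter(lst[[path[[1]]]], path[-1])
        lst
      }
      nn$layers <- setter(nn$layers, path)
      nn
    }
    num <- (lossfun(bump(net, eps)) - lossfun(bump(net, -eps))) / (2 * eps)
    expect_equal(ana, num, tolerance = tol,
                 label = sprintf("analytic grad (%s/%s[%d])",
                                 paste(unlist(path), collapse = "."),
                                 field, idx))
  }
}

test_that("backpropagated gradients match finite differences (plain stack)", {
  net <- build_backbone("tiny3d", embed_dim = 8, seed = 3)
  x <- with_rng(rng_stream(11),
                array(rnorm(4 * 3 * 6 * 8 * 8), dim = c(4, 3, 6, 8, 8)))
  grad_check(net, x, list(
    list(1, "w", 5), list(2, "gamma", 3), list(2, "beta", 2),
    list(5, "w", 100), list(6, "gamma", 7), list(9, "w", 50),
    list(10, "beta", 4)
  ))
})

test_that("backpropagated gradients match finite differences (residual block)", {
  # minimal residual network: stem conv + one downsampling basic block + GAP
  net <- with_rng(rng_stream(8), structure(
    list(name = "tiny-res", embed_dim = 6, seed = 8, layers = list(
      protofed:::layer_conv(3L, 4L, k = 3, stride = 1, pad = 1),
      protofed:::layer_bn(4L), protofed:::layer_relu(),
      protofed:::basic_block(4L, 6L, 2L),
      protofed:::layer_gap()
    )), class = "embedding_network"))
  x <- with_rng(rng_stream(12),
                array(rnorm(4 * 3 * 4 * 6 * 6), dim = c(4, 3, 4, 6, 6)))
  grad_check(net, x, list(
    list(1, "w", 7),
    list(list(4, "main", 1), "w", 11),     # conv inside the residual path
    list(list(4, "main", 2), "gamma", 2),  # batch norm inside the block
    list(list(4, "down", 1), "w", 3)       # projection shortcut
  ))
})
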