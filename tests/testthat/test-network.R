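test_that("network construction is seeded and counts parameters exactly", {
  n1 <- build_network("fcn", 16, 8, hidden = 32, seed = 5)
  n2 <- build_network("fcn", 16, 8, hidden = 32, seed = 5)
  expect_identical(n1$params, n2$params)
  n3 <- build_network("fcn", 16, 8, hidden = 32, seed = 6)
  expect_false(identical(n1$params, n3$params))
  # closed-form parameter count for the FCN: dense-in + dense-out
  expect_equal(n_params(n1), (256 * 32 + 32) + (32 * 8 + 8))
  # CNN: conv + dense layers on the pooled feature map
  cn <- build_network("cnn", 16, 8, filters = 4, kernel = 5, hidden = 16,
                      seed = 1)
  feat <- (16 - 5 + 1 - 1)^2 * 4
  expect_equal(n_params(cn), (25 * 4 + 4) + (feat * 16 + 16) + (16 * 8 + 8))
})

test_that("forward pass respects activation ranges and batching", {
  set.seed(19)
  imgs <- array(runif(16 * 16 * 7), c(16, 16, 7),
                dimnames = list(NULL, NULL, sprintf("s%d", 1:7)))
  cn <- build_network("cnn", 16, 6, filters = 4, hidden = 16, seed = 2)
  E <- embed_images(cn, imgs)
  expect_equal(dim(E), c(7, 6))
  expect_true(all(E >= -1 & E <= 1))  # tanh output
  expect_equal(rownames(E), sprintf("s%d", 1:7))
  # inference determinism and batch invariance
  E2 <- embed_images(cn, imgs)
  expect_equal(unclass(E), unclass(E2), ignore_attr = TRUE)
  one_by_one <- do.call(rbind, lapply(1:7, function(i)
    embed_images(cn, imgs[, , i, drop = FALSE])))
  expect_equal(unname(unclass(one_by_one)[, ]), unname(unclass(E)[, ]),
               ignore_attr = TRUE)
  E3 <- embed_images(cn, imgs, batch_size = 3)
  expect_equal(unclass(E3)[, ], unclass(E)[, ], ignore_attr = TRUE)
  # FCN output is ReLU: non-negative
  fn <- build_network("fcn", 16, 6, hidden = 16, seed = 2)
  expect_true(all(embed_images(fn, imgs) >= 0))
  expect_error(embed_images(cn, array(0, c(8, 8, 2))), "dim")
})

test_that("analytic gradients match finite differences", {
  set.seed(20)
  imgs <- array(runif(8 * 8 * 4), c(8, 8, 4))
  for (arch in c("cnn", "fcn")) {
    net <- build_network(arch, 8, 5, filters = 3, kernel = 3, hidden = 6,
                         dropout = 0, seed = 3)
    gidx <- list(2L, 3L, 4L)
    cfg <- ladder_config(M = 3)
    lossfun <- function(n) {
      E <- dnaembed:::net_forward(n, imgs)$out
      dnaembed:::ladder_objective(E, gidx, cfg$alphas, cfg$betas,
                                  want_grad = FALSE)$loss
    }
    fw <- dnaembed:::net_forward(net, imgs, train = TRUE)
    obj <- dnaembed:::ladder_objective(fw$out, gidx, cfg$alphas, cfg$betas)
    gr <- dnaembed:::net_backward(net, fw$cache, obj$dE)
    for (nm in names(gr)) {
      idx <- sample(length(net$params[[nm]]), min(4, length(net$params[[nm]])))
      for (i in idx) {
        h <- 1e-5
        np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + h
        nm_ <- net; nm_$params[[nm]][i] <- nm_$params[[nm]][i] - h
        num <- (lossfun(np) - lossfun(nm_)) / (2 * h)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("a zero learning rate leaves the weights unchanged", {
  ranked <- toy_ranked(4)
  d <- generate_dataset(toy_spec(4))
  im <- cgr_images(d, 16)
  fit <- neural_embedder(ranked, im, "ladder", "cnn", d = 8,
                         config = ladder_config(epochs = 1,
                                                learning_rate = 0,
                                                dropout = 0),
                         optimizer = "sgd", filters = 2, hidden = 8,
                         seed = 9)
  # with lr = 0 the parameters never move off the initialisation, so a
  # longer run with the same seed ends at identical weights
  fit2 <- neural_embedder(ranked, im, "ladder", "cnn", d = 8,
                          config = ladder_config(epochs = 2,
                                                 learning_rate = 0,
                                                 dropout = 0),
                          optimizer = "sgd", filters = 2, hidden = 8,
                          seed = 9)
  expect_identical(coef(fit), coef(fit2))
  expect_equal(nrow(fit$history), 1)
})

test_that("gradient steps reduce the loss on a fixed batch", {
  ok <- vapply(1:5, function(seed) {
    set.seed(seed)
    imgs <- array(runif(12 * 12 * 6), c(12, 12, 6))
    net <- build_network("cnn", 12, 6, filters = 3, hidden = 8,
                         dropout = 0, seed = seed)
    gidx <- list(2:3, 4:5, 6L)
    cfg <- ladder_config(M = 3)
    loss0 <- NA; lossN <- NA
    for (step in 1:50) {
      fw <- dnaembed:::net_forward(net, imgs, train = TRUE)
      obj <- dnaembed:::ladder_objective(fw$out, gidx, cfg$alphas, cfg$betas)
      if (step == 1) loss0 <- obj$loss
      lossN <- obj$loss
      gr <- dnaembed:::net_backward(net, fw$cache, obj$dE)
      net$params <- dnaembed:::sgd_step(net$params, gr, 1e-3)
    }
    lossN < loss0
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("training improves held-out ranking over the untrained network", {
  spec <- family_spec(n_families = 4, members_per_family = 6,
                      ancestor_length = 200,
                      mutation_tiers = seq(0, 0.25, length.out = 6),
                      seed = 2)
  d <- generate_dataset(spec)
  ranked <- build_ranked_dataset(d)
  im <- cgr_images(d, 16)
  sp <- split_anchors(ranked, 0.8, seed = 2)
  fit <- suppressMessages(
    neural_embedder(ranked, im, "ladder", "cnn", d = 32,
                    anchors = sp$train, epochs = 8, learning_rate = 2e-3,
                    filters = 8, hidden = 64, seed = 2))
  trained <- rank_scores(predict(fit, im), ranked,
                         anchors = sp$test)$mean_ndcg
  untrained_net <- build_network("cnn", 16, 32, filters = 8, kernel = 5,
                                 hidden = 64, seed = 2)
  untrained <- rank_scores(embed_images(untrained_net, im), ranked,
                           anchors = sp$test)$mean_ndcg
  expect_gt(trained, untrained)
})

test_that("training history records both losses and early stopping works", {
  ranked <- toy_ranked(6)
  d <- generate_dataset(toy_spec(6))
  im <- cgr_images(d, 16)
  fit <- suppressMessages(
    neural_embedder(ranked, im, "triplet", "fcn", d = 8, epochs = 3,
                    learning_rate = 1e-3, hidden = 16, seed = 1))
  expect_s3_class(fit, "neural_embedder")
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                    names(fit$history)))
  expect_lte(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_output(print(fit), "Siamese FCN")
  expect_output(summary(fit), "validation anchors")
})
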