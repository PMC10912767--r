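test_that("spec validity rejects illegal configurations", {
  expect_error(architectureSpec(depth = 1), "depth")
  expect_error(architectureSpec(width = 1, n_junctions = 2), "width")
  expect_error(architectureSpec(k1 = 4), "odd")
  expect_s4_class(architectureSpec(depth = 2, width = 1), "ArchitectureSpec")
})

test_that("the minimal legal graph builds and runs", {
  sp <- architectureSpec(depth = 2, width = 1, n_junctions = 0,
                         n_short_paths = 0, c1 = 4, k1 = 3,
                         fc_channels = 8, seed = 1)
  g <- buildArchitecture(sp)
  x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  s <- predictGraph(g, x)
  expect_identical(dim(s), c(2L, 2L))
  expect_equal(rowSums(s), c(1, 1), tolerance = 1e-6)
})

test_that("same spec and seed rebuild an identical graph", {
  sp <- architectureSpec("inception", depth = 4, width = 2,
                         n_junctions = 2, n_short_paths = 1, c1 = 6,
                         k1 = 3, fc_channels = 10, seed = 77)
  g1 <- buildArchitecture(sp)
  g2 <- buildArchitecture(sp)
  expect_identical(g1@nodes, g2@nodes)
  expect_identical(g1@meta, g2@meta)
  expect_identical(countParameters(g1), countParameters(g2))
})

test_that("stem convolution parameter count matches the hand tally", {
  sp <- architectureSpec(depth = 2, width = 1, c1 = 32, k1 = 5, seed = 1)
  g <- buildArchitecture(sp)
  stemConv <- g@nodes[[1]]
  expect_identical(stemConv$op, "conv")
  ## 5*5*3*32 weights + 32 biases
  expect_identical(length(stemConv$p$W) + length(stemConv$p$b), 2432L)
})

test_that("countParameters equals brute-force enumeration of trainable scalars", {
  for (bt in c("vgg", "inception", "residual", "soft_attention")) {
    sp <- architectureSpec(bt, depth = 3, width = 2, n_junctions = 1,
                           n_short_paths = 1, c1 = 4, k1 = 3,
                           fc_channels = 6, seed = 5)
    g <- buildArchitecture(sp)
    manual <- 2L   # interpolation weights
    for (nd in g@nodes) {
      ps <- if (nd$op == "transformer") unlist(nd$p$blocks,
                                               recursive = FALSE) else nd$p
      for (p in ps) manual <- manual + length(p)
    }
    expect_identical(countParameters(g), manual)
  }
})

test_that("adding a weighted junction strictly increases the parameter count", {
  for (j in 0:2) {
    sp0 <- architectureSpec(depth = 4, width = 2, n_junctions = j,
                            c1 = 4, k1 = 3, fc_channels = 6, seed = 9)
    sp1 <- architectureSpec(depth = 4, width = 2, n_junctions = j + 1,
                            c1 = 4, k1 = 3, fc_channels = 6, seed = 9)
    expect_gt(countParameters(buildArchitecture(sp1)),
              countParameters(buildArchitecture(sp0)))
  }
})

test_that("graphs are acyclic for many random seeded specs", {
  ## node inputs may only reference earlier nodes (or the input tensor),
  ## which certifies the topological order and hence acyclicity
  blocks <- c("vgg", "inception", "residual", "soft_attention")
  for (i in 1:1000) {
    withr::with_seed(i, {
      sp <- architectureSpec(
        block_type = sample(blocks, 1),
        depth = sample(2:4, 1), width = sample(1:3, 1),
        n_junctions = 0, n_short_paths = sample(0:2, 1),
        c1 = sample(2:4, 1), k1 = 3, fc_channels = 4, seed = i)
      if (sp@width >= 2)
        sp@n_junctions <- sample(0:2, 1)
    })
    g <- buildArchitecture(sp)
    seen <- "in"
    ok <- TRUE
    for (nd in g@nodes) {
      if (!all(nd$inputs %in% seen)) { ok <- FALSE; break }
      seen <- c(seen, nd$id)
    }
    expect_true(ok, info = paste("seed", i))
  }
})

test_that("transformer specs run forward with the reshape contract", {
  sp <- architectureSpec("inception", depth = 3, width = 2,
                         n_junctions = 1, n_short_paths = 1, c1 = 8,
                         k1 = 3, fc_channels = 12, transformer = c(2, 4),
                         seed = 3)
  g <- buildArchitecture(sp)
  s <- predictGraph(g, array(runif(2 * 24 * 24 * 3), c(2, 24, 24, 3)))
  expect_equal(rowSums(s), c(1, 1), tolerance = 1e-6)
  ## heads must divide the concatenated channels
  bad <- architectureSpec("vgg", depth = 2, width = 1, c1 = 5, k1 = 3,
                          transformer = c(1, 4), seed = 3)
  expect_error(buildArchitecture(bad), "divide")
})

test_that("the published prostate-cancer configuration runs on a full 512x512 patch", {
  sp <- table3Specs(seed = 1)$pca
  expect_identical(sp@block_type, "inception")
  expect_identical(sp@depth, 7L)
  expect_identical(sp@width, 2L)
  g <- buildArchitecture(sp)
  s <- predictGraph(g, array(runif(512 * 512 * 3), c(1, 512, 512, 3)))
  expect_identical(dim(s), c(1L, 2L))
  expect_equal(sum(s), 1, tolerance = 1e-6)
})

test_that("ensemble prediction is the equal-weight mean of positive scores", {
  sp1 <- architectureSpec(depth = 2, width = 1, c1 = 3, k1 = 3,
                          fc_channels = 4, seed = 11)
  sp2 <- architectureSpec(depth = 2, width = 1, c1 = 3, k1 = 3,
                          fc_channels = 4, seed = 22)
  g1 <- buildArchitecture(sp1); g2 <- buildArchitecture(sp2)
  x <- array(runif(3 * 16 * 16 * 3), c(3, 16, 16, 3))
  s1 <- predictGraph(g1, x)[, 2]; s2 <- predictGraph(g2, x)[, 2]
  expect_equal(ensemblePredict(list(g1), x), s1)
  expect_equal(ensemblePredict(list(g1, g2), x), (s1 + s2) / 2)
  e <- ensemblePredict(list(g1, g2), x)
  expect_true(all(e >= 0 & e <= 1))
  expect_error(ensemblePredict(list(), x), "empty")
})
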