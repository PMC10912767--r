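## PlexusNet graph construction.
##
## A built graph is an ordered list of primitive nodes (the order is a
## topological sort by construction). Each node is
##   list(id, op, inputs = character ids, p = params, cfg = list, state)
## and the special input id "in" denotes the preprocessed input batch
## (optional central crop -> Eq. 1 interpolation -> Eq. 2 rescale).

#' Construct a PlexusNet architecture specification
#'
#' Collects the hyperparameters of one PlexusNet model: block type, depth
#' (number of levels, minimum 2), width (end-to-end paths), number of
#' weighted junctions between paths, number of transitory short paths, the
#' stem layer (`c1` channels, `k1` kernel, stride `s1`), central-crop flag,
#' per-path channel growth factor, global pooling, fully-connected width,
#' output head, optional transformer blocks, and the seed that fixes the
#' seeded-random junction and short-path placement.
#'
#' @param block_type `"vgg"`, `"inception"`, `"residual"` or
#'   `"soft_attention"`.
#' @param depth number of levels, >= 2.
#' @param width number of end-to-end paths.
#' @param n_junctions number of weighted cross edges (requires width >= 2).
#' @param n_short_paths number of transitory short paths.
#' @param c1,k1,s1 stem channels, kernel size (odd) and stride.
#' @param crop_center take the central 256x256 crop of the input first.
#' @param initial_filter_factor per-level channel growth factor; together
#'   with `gamma` it sets the channel schedule
#'   `C_l = roundHalfUp(c1 * (factor * gamma)^(l-1))`.
#' @param gamma compression rate in (0,1] (default 0.5).
#' @param normalization `"batch"` or `"layer"`.
#' @param global_pooling `"max"` or `"avg"`.
#' @param fc_channels width of the first fully connected layer.
#' @param output `"softmax"` or `"sigmoid"`.
#' @param n_classes output categories (ignored and set to 1 for sigmoid).
#' @param transformer `c(n_blocks, n_heads)`; `c(0, 0)` disables.
#' @param seed integer seed for topology sampling and weight init.
#' @param label free-text label.
#' @return an [ArchitectureSpec-class].
#' @examples
#' sp <- architectureSpec("inception", depth = 3, width = 2, n_junctions = 1,
#'                        n_short_paths = 1, c1 = 8, seed = 7)
#' sp
#' @export
architectureSpec <- function(block_type = "vgg", depth = 2, width = 1,
                             n_junctions = 0, n_short_paths = 0,
                             c1 = 8, k1 = 5, s1 = 2, crop_center = FALSE,
                             initial_filter_factor = 2, gamma = 0.5,
                             normalization = "batch", global_pooling = "max",
                             fc_channels = 32, output = "softmax",
                             n_classes = 2, transformer = c(0, 0),
                             seed = 1, label = "") {
  if (output == "sigmoid") n_classes <- 1
  new("ArchitectureSpec", block_type = block_type, depth = as.integer(depth),
      width = as.integer(width), n_junctions = as.integer(n_junctions),
      n_short_paths = as.integer(n_short_paths), c1 = as.integer(c1),
      k1 = as.integer(k1), s1 = as.integer(s1),
      crop_center = isTRUE(crop_center),
      initial_filter_factor = as.numeric(initial_filter_factor),
      gamma = as.numeric(gamma), normalization = normalization,
      global_pooling = global_pooling, fc_channels = as.integer(fc_channels),
      output = output, n_classes = as.integer(n_classes),
      transformer = as.integer(transformer), seed = as.integer(seed),
      label = label)
}

## per-level channel schedule with round-half-up
channelSchedule <- function(spec) {
  l <- seq_len(spec@depth)
  pmax(1L, as.integer(roundHalfUp(
    spec@c1 * (spec@initial_filter_factor * spec@gamma)^(l - 1))))
}

heInit <- function(nin, nout, k = 1L) {
  matrix(rnorm(k * k * nin * nout, sd = sqrt(2 / (k * k * nin))),
         k * k * nin, nout)
}

## builder state: env with nodes list, id counter
newBuilder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$i <- 0L
  env
}

addNode <- function(env, op, inputs, p = list(), cfg = list(),
                    state = NULL) {
  env$i <- env$i + 1L
  id <- sprintf("n%04d", env$i)
  env$nodes[[id]] <- list(id = id, op = op, inputs = inputs, p = p,
                          cfg = cfg, state = state)
  id
}

addConv <- function(env, input, cin, cout, k, stride = 1L) {
  pad <- (k - 1L) %/% 2L
  addNode(env, "conv", input,
          p = list(W = heInit(cin, cout, k), b = numeric(cout)),
          cfg = list(k = as.integer(k), stride = as.integer(stride),
                     pad = pad, cin = cin, cout = cout))
}

addNorm <- function(env, input, ch, kind) {
  if (kind == "batch")
    addNode(env, "bn", input, p = list(gamma = rep(1, ch),
                                       beta = numeric(ch)),
            cfg = list(ch = ch),
            state = list(mean = numeric(ch), var = rep(1, ch)))
  else
    addNode(env, "ln", input, p = list(gamma = rep(1, ch),
                                       beta = numeric(ch)),
            cfg = list(ch = ch))
}

addCBR <- function(env, input, cin, cout, k, norm, stride = 1L) {
  id <- addConv(env, input, cin, cout, k, stride)
  id <- addNorm(env, id, cout, norm)
  addNode(env, "relu", id)
}

## one block: cin -> cout, spatial size preserved
addBlock <- function(env, input, cin, cout, spec) {
  norm <- spec@normalization
  cb <- max(1L, as.integer(roundHalfUp(spec@gamma * cout)))
  switch(spec@block_type,
    vgg = {
      id <- addCBR(env, input, cin, cout, 3L, norm)
      addCBR(env, id, cout, cout, 3L, norm)
    },
    inception = {
      b1 <- addCBR(env, input, cin, cb, 1L, norm)
      b3 <- addCBR(env, input, cin, cb, 3L, norm)
      b5 <- addCBR(env, input, cin, cb, 5L, norm)
      cc <- addNode(env, "concat", c(b1, b3, b5),
                    cfg = list(chs = c(cb, cb, cb)))
      addCBR(env, cc, 3L * cb, cout, 1L, norm)
    },
    residual = {
      id <- addCBR(env, input, cin, cb, 1L, norm)
      id <- addCBR(env, id, cb, cb, 3L, norm)
      id <- addConv(env, id, cb, cout, 1L)
      id <- addNorm(env, id, cout, norm)
      skip <- if (cin == cout) input else addConv(env, input, cin, cout, 1L)
      s <- addNode(env, "add", c(id, skip))
      addNode(env, "relu", s)
    },
    soft_attention = {
      f <- addCBR(env, input, cin, cout, 3L, norm)
      a <- addConv(env, f, cout, 1L, 1L)
      a <- addNode(env, "sigmoid_act", a)
      addNode(env, "mulattn", c(f, a))
    })
}

#' Build a PlexusNet model graph
#'
#' Materialises an [ArchitectureSpec-class] into a directed acyclic
#' multigraph: a convolutional stem populating the channels from 3 to `c1`,
#' `width` end-to-end paths of `depth` block levels connected by 2x2 average
#' pooling between consecutive levels, `n_junctions` weighted cross edges
#' (1x1 convolutions) between two paths at seeded-random positions,
#' `n_short_paths` transitory paths of seeded-random depth branching from
#' the stem and channel-concatenating into the root path (path 1), final
#' concatenation of all end-to-end path outputs, optional transformer
#' encoder blocks, global pooling, a fully connected layer and the output
#' head. Topology and initial weights are deterministic given `spec@seed`.
#'
#' @param spec an [ArchitectureSpec-class].
#' @return a [ModelGraph-class].
#' @examples
#' g <- buildArchitecture(architectureSpec(depth = 2, width = 1, c1 = 4,
#'                                         fc_channels = 8, seed = 1))
#' countParameters(g)
#' @export
buildArchitecture <- function(spec) {
  validObject(spec)
  chans <- channelSchedule(spec)
  withr::with_seed(spec@seed, {
    env <- newBuilder()
    meta <- list(channels = chans, junctions = list(), short_paths = list())

    ## sample topology first so the draw order is stable
    if (spec@n_junctions > 0L) {
      for (j in seq_len(spec@n_junctions)) {
        lev <- if (spec@depth > 2L) sample(seq_len(spec@depth - 1L), 1L)
               else 1L
        pq <- sample(seq_len(spec@width), 2L)
        meta$junctions[[j]] <- list(level = lev, from = pq[1], to = pq[2])
      }
    }
    if (spec@n_short_paths > 0L) {
      for (s in seq_len(spec@n_short_paths)) {
        lev <- if (spec@depth > 2L) sample(2:spec@depth, 1L) else 2L
        dep <- if (lev > 2L) sample(seq_len(lev - 1L), 1L) else 1L
        meta$short_paths[[s]] <- list(level = lev, depth = dep)
      }
    }

    stem <- addConv(env, "in", 3L, spec@c1, spec@k1, spec@s1)
    stem <- addNorm(env, stem, spec@c1, spec@normalization)
    stem <- addNode(env, "relu", stem)

    ## transitory short paths, built from the stem output
    shortOut <- list()   # insertion level -> ids to concat into root path
    shortCh <- integer(spec@depth + 1L)
    for (s in seq_along(meta$short_paths)) {
      sp <- meta$short_paths[[s]]
      id <- stem; cin <- spec@c1
      for (b in seq_len(sp$depth)) {
        id <- addBlock(env, id, cin, chans[b], spec)
        id <- addNode(env, "avgpool", id)
        cin <- chans[b]
      }
      extra <- (sp$level - 1L) - sp$depth
      for (e in seq_len(max(0L, extra))) id <- addNode(env, "avgpool", id)
      shortOut[[as.character(sp$level)]] <-
        c(shortOut[[as.character(sp$level)]], id)
      shortCh[sp$level] <- shortCh[sp$level] + cin
    }

    ## end-to-end paths, level by level (junctions apply between levels)
    cur <- rep(stem, spec@width)        # current input id per path
    curCh <- rep(spec@c1, spec@width)
    for (l in seq_len(spec@depth)) {
      nxt <- character(spec@width)
      for (p in seq_len(spec@width)) {
        inId <- cur[p]; cin <- curCh[p]
        if (p == 1L && !is.null(shortOut[[as.character(l)]])) {
          ids <- c(inId, shortOut[[as.character(l)]])
          inId <- addNode(env, "concat", ids,
                          cfg = list(chs = c(cin, rep(NA, length(ids) - 1L))))
          cin <- cin + shortCh[l]
        }
        nxt[p] <- addBlock(env, inId, cin, chans[l], spec)
      }
      curCh <- rep(chans[l], spec@width)
      if (l < spec@depth) {
        for (p in seq_len(spec@width))
          nxt[p] <- addNode(env, "avgpool", nxt[p])
        for (j in seq_along(meta$junctions)) {
          jn <- meta$junctions[[j]]
          if (jn$level == l) {
            w <- addConv(env, nxt[jn$from], chans[l], chans[l], 1L)
            nxt[jn$to] <- addNode(env, "add", c(nxt[jn$to], w))
          }
        }
      }
      cur <- nxt
    }

    out <- if (spec@width > 1L)
      addNode(env, "concat", cur, cfg = list(chs = curCh))
    else cur[1]
    outCh <- sum(curCh)

    if (spec@transformer[1] > 0L) {
      nh <- spec@transformer[2]
      if (outCh %% nh != 0L)
        stop("transformer heads must divide the concatenated channel count (",
             outCh, " %% ", nh, " != 0)")
      blocks <- lapply(seq_len(spec@transformer[1]), function(b) {
        list(Wq = heInit(outCh, outCh), bq = numeric(outCh),
             Wk = heInit(outCh, outCh), bk = numeric(outCh),
             Wv = heInit(outCh, outCh), bv = numeric(outCh),
             Wo = heInit(outCh, outCh), bo = numeric(outCh),
             ln1_g = rep(1, outCh), ln1_b = numeric(outCh),
             ln2_g = rep(1, outCh), ln2_b = numeric(outCh),
             W1 = heInit(outCh, 2L * outCh), b1 = numeric(2L * outCh),
             W2 = heInit(2L * outCh, outCh), b2 = numeric(outCh))
      })
      out <- addNode(env, "transformer", out, p = list(blocks = blocks),
                     cfg = list(n_heads = nh, ch = outCh))
    }

    out <- addNode(env, "gpool", out, cfg = list(kind = spec@global_pooling))
    out <- addNode(env, "dense", out,
                   p = list(W = heInit(outCh, spec@fc_channels),
                            b = numeric(spec@fc_channels)),
                   cfg = list(din = outCh, dout = spec@fc_channels))
    out <- addNode(env, "relu", out)
    out <- addNode(env, "dense", out,
                   p = list(W = heInit(spec@fc_channels, spec@n_classes),
                            b = numeric(spec@n_classes)),
                   cfg = list(din = spec@fc_channels,
                              dout = spec@n_classes))
    addNode(env, "head", out, cfg = list(kind = spec@output))

    new("ModelGraph", spec = spec, nodes = env$nodes,
        interp = c(0, 0), meta = meta)
  })
}

#' Count trainable parameters of a model graph
#'
#' Exact count of trainable scalars: all convolution/dense weights and
#' biases, normalisation scale/shift pairs, transformer block weights, and
#' the two input-interpolation weights. Batch-norm running statistics are
#' state, not parameters.
#'
#' @param graph a [ModelGraph-class].
#' @return integer parameter count.
#' @export
countParameters <- function(graph) {
  stopifnot(is(graph, "ModelGraph"))
  n <- 2L   # omega1, omega2
  for (nd in graph@nodes) {
    if (nd$op == "transformer") {
      for (b in nd$p$blocks) n <- n + sum(vapply(b, length, 0L))
    } else if (length(nd$p)) {
      n <- n + sum(vapply(nd$p, length, 0L))
    }
  }
  n
}

## preprocessed input: optional central 256-crop, Eq. 1, Eq. 2
preprocessInput <- function(graph, batch) {
  d <- dim(batch)
  if (length(d) != 4L || d[4] != 3L)
    stop("batch must be a (n, height, width, 3) array")
  if (any(batch < 0) || any(batch > 1))
    stop("raw input values must lie in [0, 1]")
  if (graph@spec@crop_center && d[2] > 256L && d[3] > 256L) {
    r0 <- (d[2] - 256L) %/% 2L; c0 <- (d[3] - 256L) %/% 2L
    batch <- batch[, (r0 + 1L):(r0 + 256L), (c0 + 1L):(c0 + 256L), ,
                   drop = FALSE]
  }
  xh <- interpolateInput(batch, graph@interp[1], graph@interp[2])
  lo <- min(xh); hi <- max(xh)
  if (hi == lo) list(x = xh * 0, raw = batch, scale = 0)
  else list(x = 2 * (xh - lo) / (hi - lo) - 1, raw = batch,
            scale = 2 / (hi - lo))
}

## forward over the node list; keep = TRUE retains per-node caches for
## backprop, train toggles batch-norm batch statistics
graphForward <- function(graph, batch, train = FALSE, keep = FALSE) {
  pre <- preprocessInput(graph, batch)
  acts <- new.env(parent = emptyenv())
  caches <- if (keep) new.env(parent = emptyenv()) else NULL
  assign("in", pre$x, acts)
  nodes <- graph@nodes
  for (nd in nodes) {
    get1 <- function(i) get(nd$inputs[i], acts)
    out <- switch(nd$op,
      conv = {
        r <- convForward(get1(1), nd$p$W, nd$p$b, nd$cfg$k, nd$cfg$stride,
                         nd$cfg$pad)
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      bn = {
        r <- bnForward(get1(1), nd$p$gamma, nd$p$beta, nd$state, train)
        if (train) nodes[[nd$id]]$state <- r$state
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      ln = {
        r <- lnForward(get1(1), nd$p$gamma, nd$p$beta)
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      relu = {
        r <- reluForward(get1(1))
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      sigmoid_act = {
        r <- sigmoidForward(get1(1))
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      avgpool = {
        r <- avgpoolForward(get1(1))
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      add = get1(1) + get1(2),
      concat = {
        xs <- lapply(seq_along(nd$inputs), get1)
        if (keep) assign(nd$id, vapply(xs, function(a) dim(a)[4], 0),
                         caches)
        do.call(abind4, xs)
      },
      mulattn = {
        f <- get1(1); a <- get1(2)
        if (keep) assign(nd$id, list(f = f, a = a), caches)
        f * array(a, dim(f))     # broadcast (N,H,W,1) over channels
      },
      transformer = {
        x <- get1(1); d <- dim(x)
        z <- array(aperm(x, c(1, 2, 3, 4)), c(d[1], d[2] * d[3], d[4]))
        for (b in nd$p$blocks)
          z <- transformerForward(z, b, nd$cfg$n_heads)
        array(z, d)
      },
      gpool = {
        r <- globalPoolForward(get1(1), nd$cfg$kind)
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      dense = {
        r <- denseForward(get1(1), nd$p$W, nd$p$b)
        if (keep) assign(nd$id, r$cache, caches)
        r$out
      },
      head = {
        z <- get1(1)
        if (keep) assign(nd$id, z, caches)
        if (nd$cfg$kind == "softmax") softmaxRows(z)
        else 1 / (1 + exp(-z))
      },
      stop("unknown op: ", nd$op))
    assign(nd$id, out, acts)
  }
  lastId <- nodes[[length(nodes)]]$id
  list(out = get(lastId, acts), acts = acts, caches = caches,
       nodes = nodes, pre = pre)
}

## channelwise concat of (N,H,W,C_i) arrays
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  chs <- vapply(xs, function(a) dim(a)[4], 0)
  out <- array(0, c(d[1], d[2], d[3], sum(chs)))
  at <- 0L
  for (a in xs) {
    ca <- dim(a)[4]
    out[, , , (at + 1L):(at + ca)] <- a
    at <- at + ca
  }
  out
}

#' Forward pass through a built model
#'
#' Runs the preprocessing (optional central crop, trainable interpolation,
#' min-max rescale to `[-1, 1]`) and the full graph on an image batch.
#'
#' @param graph a [ModelGraph-class].
#' @param batch `(n, height, width, 3)` array of values in `[0, 1]`.
#' @return `(n, k)` score matrix; softmax rows sum to 1, a sigmoid head
#'   yields a single column in `[0, 1]`.
#' @export
predictGraph <- function(graph, batch) {
  graphForward(graph, batch, train = FALSE, keep = FALSE)$out
}

#' Equal-weight ensemble prediction
#'
#' Arithmetic mean of per-model positive-class scores. For a two-class
#' softmax head the positive class is the second column; a sigmoid head
#' contributes its single column.
#'
#' @param models nonempty list of [ModelGraph-class] objects.
#' @param batch `(n, height, width, 3)` array in `[0, 1]`.
#' @return numeric vector of length `n` with values in `[0, 1]`.
#' @export
ensemblePredict <- function(models, batch) {
  if (!length(models)) stop("ensemblePredict: empty model list")
  scores <- vapply(models, function(m) {
    s <- predictGraph(m, batch)
    if (ncol(s) == 1L) s[, 1] else s[, 2]
  }, numeric(dim(batch)[1]))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  rowMeans(scores)
}
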