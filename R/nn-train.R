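## Backpropagation over the node tape and a small Adam trainer.
## The tape order is a topological sort, so a single reverse sweep with
## gradient accumulation at fan-out points is exact.

graphBackward <- function(fw, dz) {
  nodes <- fw$nodes
  grads <- new.env(parent = emptyenv())   # d loss / d node-output
  pgrads <- list()                        # node id -> param grads
  nn <- length(nodes)
  head <- nodes[[nn]]
  stopifnot(head$op == "head")
  assign(head$inputs[1], dz, grads)
  addGrad <- function(id, g) {
    if (exists(id, grads)) assign(id, get(id, grads) + g, grads)
    else assign(id, g, grads)
  }
  for (i in rev(seq_len(nn - 1L))) {
    nd <- nodes[[i]]
    if (!exists(nd$id, grads)) next     # dead branch (none by construction)
    dout <- get(nd$id, grads)
    cache <- if (!is.null(fw$caches) && exists(nd$id, fw$caches))
      get(nd$id, fw$caches) else NULL
    switch(nd$op,
      conv = {
        r <- convBackward(dout, cache, nd$p$W, nd$cfg$k, nd$cfg$stride,
                          nd$cfg$pad)
        pgrads[[nd$id]] <- list(W = r$dW, b = r$db)
        addGrad(nd$inputs[1], r$dx)
      },
      bn = {
        r <- bnBackward(dout, cache, nd$p$gamma)
        pgrads[[nd$id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addGrad(nd$inputs[1], r$dx)
      },
      ln = {
        r <- lnBackward(dout, cache, nd$p$gamma)
        pgrads[[nd$id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        addGrad(nd$inputs[1], r$dx)
      },
      relu = addGrad(nd$inputs[1], reluBackward(dout, cache)),
      sigmoid_act = addGrad(nd$inputs[1], sigmoidBackward(dout, cache)),
      avgpool = addGrad(nd$inputs[1], avgpoolBackward(dout, cache)),
      add = {
        addGrad(nd$inputs[1], dout)
        addGrad(nd$inputs[2], dout)
      },
      concat = {
        chs <- cache
        at <- 0L
        for (k in seq_along(nd$inputs)) {
          addGrad(nd$inputs[k],
                  dout[, , , (at + 1L):(at + chs[k]), drop = FALSE])
          at <- at + chs[k]
        }
      },
      mulattn = {
        f <- cache$f; a <- cache$a
        addGrad(nd$inputs[1], dout * array(a, dim(f)))
        s <- dout * f
        d <- dim(f)
        da <- array(rowSums(matrix(s, prod(d[1:3]), d[4])),
                    c(d[1], d[2], d[3], 1L))
        addGrad(nd$inputs[2], da)
      },
      gpool = addGrad(nd$inputs[1], globalPoolBackward(dout, cache)),
      dense = {
        r <- denseBackward(dout, cache, nd$p$W)
        pgrads[[nd$id]] <- list(W = r$dW, b = r$db)
        addGrad(nd$inputs[1], r$dx)
      },
      transformer = stop("backprop through transformer blocks is not supported"),
      stop("unknown op in backward: ", nd$op))
  }
  list(pgrads = pgrads,
       din = if (exists("in", grads)) get("in", grads) else NULL)
}

#' Train a small PlexusNet classifier on labeled patches
#'
#' Plain cross-entropy training with Adam for binary patch classification:
#' the full graph (including the two interpolation weights of the input
#' layer) is trained end to end. Intended for toy-scale experiments on
#' synthetic texture patches; it is deterministic given `seed` and records
#' the per-epoch mean loss. The min/max of the `[-1, 1]` rescale step are
#' treated as constants during backpropagation. Specs with transformer
#' blocks are rejected.
#'
#' @param spec an [ArchitectureSpec-class] (no transformer blocks).
#' @param x `(n, height, width, 3)` array of patches in `[0, 1]`.
#' @param y length-`n` vector of 0/1 labels.
#' @param epochs number of passes over the data (0 returns the freshly
#'   built, untrained graph).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling (weight init is fixed by
#'   `spec@seed`).
#' @return list with elements `graph` (the trained [ModelGraph-class]) and
#'   `history` (numeric per-epoch mean loss).
#' @export
trainToyClassifier <- function(spec, x, y, epochs = 10, learning_rate = 1e-3,
                               batch_size = 16, seed = 1) {
  if (length(dim(x)) != 4L || dim(x)[1] != length(y))
    stop("x must be (n, h, w, 3) with one label per patch")
  if (length(y) == 0L) stop("empty dataset")
  if (spec@transformer[1] > 0L)
    stop("trainToyClassifier does not support transformer blocks")
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  graph <- buildArchitecture(spec)
  if (epochs == 0) return(list(graph = graph, history = numeric()))

  nodes <- graph@nodes
  interp <- graph@interp
  ## Adam state, keyed like pgrads
  mState <- list(); vState <- list()
  mI <- c(0, 0); vI <- c(0, 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  n <- length(y)

  history <- withr::with_seed(seed, {
    vapply(seq_len(epochs), function(ep) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , , , drop = FALSE]
        yb <- y[idx]
        g <- graph; g@nodes <- nodes; g@interp <- interp
        fw <- graphForward(g, xb, train = TRUE, keep = TRUE)
        nodes <<- fw$nodes               # updated bn running stats
        nb <- length(idx)
        if (g@spec@output == "softmax") {
          probs <- fw$out
          pick <- cbind(seq_len(nb), yb + 1L)
          loss <- -mean(log(pmax(probs[pick], 1e-12)))
          dz <- probs
          dz[pick] <- dz[pick] - 1
          dz <- dz / nb
        } else {
          s <- fw$out[, 1]
          loss <- -mean(yb * log(pmax(s, 1e-12)) +
                        (1 - yb) * log(pmax(1 - s, 1e-12)))
          dz <- matrix((s - yb) / nb, ncol = 1L)
        }
        bp <- graphBackward(fw, dz)
        step <<- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (id in names(bp$pgrads)) {
          for (pn in names(bp$pgrads[[id]])) {
            gmat <- bp$pgrads[[id]][[pn]]
            key <- paste0(id, ".", pn)
            m <- if (is.null(mState[[key]])) gmat * 0 else mState[[key]]
            v <- if (is.null(vState[[key]])) gmat * 0 else vState[[key]]
            m <- b1 * m + (1 - b1) * gmat
            v <- b2 * v + (1 - b2) * gmat^2
            mState[[key]] <<- m; vState[[key]] <<- v
            nodes[[id]]$p[[pn]] <<- nodes[[id]]$p[[pn]] -
              learning_rate * corr * m / (sqrt(v) + eps)
          }
        }
        if (!is.null(bp$din)) {
          gI <- interpGrad(fw$pre$raw, interp[1], interp[2], bp$din,
                           fw$pre$scale)
          mI <<- b1 * mI + (1 - b1) * gI
          vI <<- b2 * vI + (1 - b2) * gI^2
          interp <<- pmin(1, pmax(-1, interp -
            learning_rate * corr * mI / (sqrt(vI) + eps)))
        }
        losses <- c(losses, loss)
      }
      mean(losses)
    }, numeric(1))
  })
  graph@nodes <- nodes
  graph@interp <- interp
  list(graph = graph, history = history)
}
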