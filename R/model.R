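#' Construct a retention-time model configuration
#'
#' Defaults follow the published architecture family for sequence-property
#' prediction: a 64-dimensional embedding, one bidirectional GRU with 256
#' units per direction, attention pooling, a (512, 256) dense head with
#' dropout 0.3 at every dropout site, Adam at 1e-3 on mean squared error,
#' up to 100 epochs with 20-epoch early-stopping patience. All dimensions
#' are configurable; analyses in this package typically run reduced
#' configurations sized for a single CPU.
#'
#' @param vocab named integer residue -> index map; index 0 is padding.
#' @param maxLength maximal sequence length (right padding).
#' @param embeddingDim,recurrentUnits,denseUnits architecture sizes.
#' @param dropoutRate dropout probability in `[0, 1)`.
#' @param learningRate,batchSize,maxEpochs,patience training schedule.
#' @param seed initialization and training seed.
#' @return an [RTModelConfig-class].
#' @export
rtModelConfig <- function(vocab = stats::setNames(seq_along(RESIDUES),
                                                  RESIDUES),
                          maxLength = 30L, embeddingDim = 64L,
                          recurrentUnits = 256L, denseUnits = c(512L, 256L),
                          dropoutRate = 0.3, learningRate = 1e-3,
                          batchSize = 1024L, maxEpochs = 100L,
                          patience = 20L, seed = 42L) {
  new("RTModelConfig", vocab = as.integer(vocab) |>
        stats::setNames(names(vocab)),
      maxLength = as.integer(maxLength),
      embeddingDim = as.integer(embeddingDim),
      recurrentUnits = as.integer(recurrentUnits),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      seed = as.integer(seed))
}

#' Encode peptide sequences as padded index matrices
#'
#' Rows are right-padded with the padding index 0. When `x` carries an
#' `rt_normalized` column the targets are attached.
#'
#' @param x character vector of sequences or a peptide record data.frame.
#' @param config an [RTModelConfig-class].
#' @return list with `x` (integer matrix, n x maxLength) and `y` (numeric
#'   targets or NULL).
#' @export
encodeSequences <- function(x, config) {
  seqs <- if (is.data.frame(x)) x$sequence else x
  y <- if (is.data.frame(x) && "rt_normalized" %in% names(x)) {
    x$rt_normalized
  } else NULL
  if (!length(seqs)) {
    return(list(x = matrix(0L, 0, config@maxLength), y = numeric(0)))
  }
  chars <- strsplit(seqs, "")
  lens <- lengths(chars)
  over <- lens > config@maxLength
  if (any(over)) {
    stop("sequence(s) exceed maxLength ", config@maxLength, ": ",
         paste(utils::head(seqs[over], 3), collapse = ", "))
  }
  idx <- lapply(chars, function(ch) {
    i <- config@vocab[ch]
    if (anyNA(i)) stop("invalid residue in sequence: ",
                       paste(ch, collapse = ""))
    i
  })
  X <- matrix(0L, length(seqs), config@maxLength)
  for (i in seq_along(idx)) X[i, seq_len(lens[i])] <- idx[[i]]
  storage.mode(X) <- "integer"
  list(x = X, y = y)
}

#' Decode an index matrix back to sequences
#'
#' @param X integer matrix from [encodeSequences()].
#' @param config an [RTModelConfig-class].
#' @return character vector.
#' @export
decodeSequences <- function(X, config) {
  rev <- character(max(config@vocab))
  rev[config@vocab] <- names(config@vocab)
  apply(X, 1, function(row) paste(rev[row[row > 0]], collapse = ""))
}

#' Build an untrained retention-time model
#'
#' Seeded Glorot-uniform initialization of the embedding, bidirectional GRU,
#' attention vector and dense head. Identical config (incl. seed) yields
#' identical initial weights.
#'
#' @param config an [RTModelConfig-class].
#' @return an untrained [RTModel-class].
#' @export
buildRTModel <- function(config) {
  validObject(config)
  params <- withr::with_seed(config@seed, .initParams(config))
  new("RTModel", config = config, params = params,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()),
      trainedOn = NA_character_, pretrainedFrom = NA_character_,
      finalValLoss = NA_real_, trained = FALSE)
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.initParams <- function(config) {
  E <- config@embeddingDim
  H <- config@recurrentUnits
  V <- max(config@vocab)
  gru <- function(prefix) {
    p <- list(.glorot(E, H), .glorot(E, H), .glorot(E, H),
              .glorot(H, H), .glorot(H, H), .glorot(H, H),
              matrix(0, 1, H), matrix(0, 1, H), matrix(0, 1, H))
    names(p) <- paste0(prefix, c("Wz", "Wr", "Wn", "Uz", "Ur", "Un",
                                 "bz", "br", "bn"))
    p
  }
  dims <- c(2 * H, config@denseUnits, 1)
  denseW <- list()
  denseB <- list()
  for (i in seq_len(length(dims) - 1)) {
    denseW[[i]] <- .glorot(dims[i], dims[i + 1])
    denseB[[i]] <- matrix(0, 1, dims[i + 1])
  }
  c(list(Emb = matrix(stats::rnorm((V + 1) * E, 0, 0.05), V + 1, E)),
    gru("f_"), gru("b_"),
    list(attn_v = stats::rnorm(2 * H, 0, 1 / sqrt(2 * H)),
         denseW = denseW, denseB = denseB))
}

# dropout masks (inverted scaling); all-ones when rate is 0
.dropMasks <- function(n, config) {
  H2 <- 2L * config@recurrentUnits
  p <- config@dropoutRate
  mk <- function(d) {
    if (p <= 0) matrix(1, n, d)
    else matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
  }
  list(ctx = mk(H2), dense = lapply(config@denseUnits, mk))
}

.onesMasks <- function(n, config) {
  list(ctx = matrix(1, n, 2L * config@recurrentUnits),
       dense = lapply(config@denseUnits, function(d) matrix(1, n, d)))
}

# forward pass in chunks; masks NULL = dropout off
.forwardChunks <- function(params, X, config, chunk = 2048L,
                           withDropout = FALSE) {
  n <- nrow(X)
  if (!n) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1, n, by = chunk)
  for (s in starts) {
    e <- min(n, s + chunk - 1)
    idx <- s:e
    masks <- if (withDropout) .dropMasks(length(idx), config)
             else .onesMasks(length(idx), config)
    res <- rtnet_eval(params, X[idx, , drop = FALSE], numeric(0),
                      masks$ctx, masks$dense, FALSE)
    out[idx] <- res$pred
  }
  out
}

# recursive Adam over the nested parameter list
.adamInit <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else array(0, dim = dim(x) %||% length(x))
  }
  list(m = zero(params), v = zero(params), t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      # C++ returns column/row vectors for 1-d parameters; match p's shape
      g <- array(as.numeric(g), dim = dim(p) %||% length(p))
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mh <- m / (1 - b1^t)
      vh <- v / (1 - b2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- Map(walk, params, grads[names(params)], state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

#' Train a retention-time model
#'
#' Minimizes mean squared error of the normalized retention time with Adam,
#' recording per-epoch train/validation loss (epoch 0 is the validation
#' loss of the initial weights, before any update). Training stops at
#' `maxEpochs` or once the validation loss has not improved (strict decrease
#' by at least 1e-6) for `patience` consecutive epochs; the best-validation
#' weights are restored. Dropout is active during training only; validation
#' loss is computed with dropout off.
#'
#' @param model an [RTModel-class] (untrained, or a transfer source copy).
#' @param train,val peptide record data.frames with `rt_normalized`, or
#'   encoded lists from [encodeSequences()]. Train/validation must be
#'   disjoint by sequence.
#' @param trainedOn identifier stored in the model.
#' @param seed optional override of the training-stream seed (shuffling and
#'   dropout); defaults to the config seed.
#' @param verbose print per-epoch losses.
#' @return the trained [RTModel-class] with history.
#' @export
trainRTModel <- function(model, train, val, trainedOn = "dataset",
                         seed = NULL, verbose = FALSE) {
  config <- model@config
  enc <- function(d) if (is.list(d) && !is.data.frame(d)) d
                     else encodeSequences(d, config)
  tr <- enc(train)
  va <- enc(val)
  if (!length(tr$y) || !length(va$y)) {
    stop("training and validation sets must be nonempty with rt_normalized")
  }
  seed <- as.integer(seed %||% config@seed)
  fit <- withr::with_seed(seed,
    .trainLoop(model@params, tr, va, config, verbose))
  model@params <- fit$params
  model@history <- fit$history
  model@finalValLoss <- fit$bestVal
  model@trainedOn <- trainedOn
  model@trained <- TRUE
  model
}

.trainLoop <- function(params, tr, va, config, verbose = FALSE) {
  n <- nrow(tr$x)
  state <- .adamInit(params)
  valLoss0 <- mean((.forwardChunks(params, va$x, config) - va$y)^2)
  history <- data.frame(epoch = 0L, train_loss = NA_real_,
                        val_loss = valLoss0)
  bestVal <- valLoss0
  bestParams <- params
  wait <- 0L
  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config@batchSize)
    batchLoss <- numeric(length(starts))
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(n, starts[k] + config@batchSize - 1)]
      masks <- .dropMasks(length(idx), config)
      res <- rtnet_eval(params, tr$x[idx, , drop = FALSE], tr$y[idx],
                        masks$ctx, masks$dense, TRUE)
      if (!is.finite(res$loss)) {
        stop("training aborted: non-finite loss at epoch ", epoch,
             ", batch ", k, " (consider lowering the learning rate)")
      }
      batchLoss[k] <- res$loss
      upd <- .adamStep(params, res$grads, state, config@learningRate)
      params <- upd$params
      state <- upd$state
    }
    valLoss <- mean((.forwardChunks(params, va$x, config) - va$y)^2)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(batchLoss), val_loss = valLoss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5g  val %.5g", epoch,
                      mean(batchLoss), valLoss))
    }
    if (valLoss < bestVal - 1e-6) {
      bestVal <- valLoss
      bestParams <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config@patience) break
    }
  }
  list(params = bestParams, history = history, bestVal = bestVal)
}

#' Predict normalized retention times
#'
#' Deterministic inference with dropout disabled; chunked, and chunking
#' does not change the result.
#'
#' @param model a trained [RTModel-class].
#' @param newdata peptide records, character sequences, or an encoded list.
#' @param chunkSize rows per forward pass.
#' @return numeric prediction vector.
#' @export
predictRt <- function(model, newdata, chunkSize = 2048L) {
  if (!model@trained) stop("model is untrained; call trainRTModel() first")
  enc <- if (is.list(newdata) && !is.data.frame(newdata)) newdata
         else encodeSequences(newdata, model@config)
  .forwardChunks(model@params, enc$x, model@config, chunk = chunkSize)
}

#' Evaluate retention-time predictions
#'
#' Reports the retention-time error RTdelta (the average absolute
#' difference between predicted and observed values), mean squared error,
#' mean absolute error, and additionally the 95th-percentile absolute
#' deviation `dt95` (a percentile-window variant of the time-delta metric,
#' reported as an extra column, never as the headline).
#'
#' @param predictions,targets equal-length numeric vectors.
#' @return one-row data.frame: `rt_delta`, `mse`, `mae`, `dt95`, `n`.
#' @examples
#' evaluateRt(c(0.1, 0.2), c(0.15, 0.25))
#' @export
evaluateRt <- function(predictions, targets) {
  if (length(predictions) != length(targets)) {
    stop("predictions and targets differ in length")
  }
  if (!length(predictions)) stop("need at least one prediction")
  d <- predictions - targets
  data.frame(rt_delta = mean(abs(d)), mse = mean(d^2), mae = mean(abs(d)),
             dt95 = unname(stats::quantile(abs(d), 0.95)),
             n = length(d))
}

#' Transfer a trained model to a new dataset
#'
#' Initializes every weight from the source model (verifiably equal before
#' the first update), then trains on the new data under the same schedule.
#' The architectures must match exactly.
#'
#' @param source a trained [RTModel-class].
#' @param train,val new training/validation data.
#' @param trainedOn identifier of the new dataset.
#' @param seed optional training-stream seed.
#' @param verbose print per-epoch losses.
#' @return a trained [RTModel-class] with `pretrainedFrom` recorded.
#' @export
transferRTModel <- function(source, train, val, trainedOn = "transfer",
                            seed = NULL, verbose = FALSE) {
  if (!source@trained) stop("transfer source must be trained")
  model <- new("RTModel", config = source@config, params = source@params,
               history = data.frame(epoch = integer(),
                                    train_loss = numeric(),
                                    val_loss = numeric()),
               trainedOn = NA_character_,
               pretrainedFrom = source@trainedOn,
               finalValLoss = NA_real_, trained = FALSE)
  out <- trainRTModel(model, train, val, trainedOn = trainedOn, seed = seed,
                      verbose = verbose)
  out@pretrainedFrom <- source@trainedOn
  out
}

#' Check that two model configurations share an architecture
#'
#' @param a,b [RTModelConfig-class] objects.
#' @return TRUE, or an error listing the differing fields.
#' @export
assertSameArchitecture <- function(a, b) {
  fields <- c("vocab", "maxLength", "embeddingDim", "recurrentUnits",
              "denseUnits", "dropoutRate")
  differ <- fields[!vapply(fields, function(f) {
    identical(slot(a, f), slot(b, f))
  }, logical(1))]
  if (length(differ)) {
    stop("model architectures differ in: ", paste(differ, collapse = ", "))
  }
  TRUE
}
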