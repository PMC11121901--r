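#' Toy text encoder satisfying the encoder contract
#'
#' The classifier treats its encoder as a contract: any object that maps a
#' text to per-token `d_model`-vectors with a designated sequence-start
#' token, whose final hidden state is the document representation. This toy
#' encoder makes the package trainable and testable without a pretrained
#' transformer: tokens are lowercased whitespace runs, hashed into a fixed
#' random embedding table, and the start-token state is
#' `tanh(start + mean(token embeddings))` — a deterministic stand-in for
#' attention pooling. All weights are frozen and fully determined by
#' `seed`.
#'
#' @param d_model Embedding width (the published model uses 768; desk-scale
#'   tests use 32).
#' @param hash_size Number of hash buckets in the embedding table.
#' @param seed Seed generating the (frozen) embedding table.
#' @return A `text_encoder` with fields `d_model` and
#'   `encode(texts, max_tokens)` returning one start-token state per text
#'   (rows of an n × d_model matrix). Texts that tokenize to zero tokens
#'   are an error.
#' @export
toy_encoder <- function(d_model = 32L, hash_size = 1024L, seed = 42L) {
  weights <- withr::with_seed(seed, {
    list(
      embeddings = matrix(stats::runif(hash_size * d_model, -0.5, 0.5) /
                            sqrt(d_model),
                          nrow = hash_size, ncol = d_model),
      start = stats::runif(d_model, -0.5, 0.5) / sqrt(d_model)
    )
  })
  hash_token <- function(tok) {
    h <- Reduce(function(h, ch) (h * 31 + ch) %% hash_size,
                as.numeric(utf8ToInt(tok)), 0)
    as.integer(h %% hash_size) + 1L
  }
  encode <- function(texts, max_tokens = 512L) {
    truncated <- FALSE
    out <- matrix(0, nrow = length(texts), ncol = d_model)
    for (i in seq_along(texts)) {
      toks <- stringr::str_extract_all(tolower(texts[i]), "\\S+")[[1]]
      if (length(toks) == 0) {
        abort(sprintf("text %d tokenizes to zero tokens", i))
      }
      if (length(toks) > max_tokens) {
        toks <- toks[seq_len(max_tokens)]
        truncated <- TRUE
      }
      idx <- vapply(toks, hash_token, integer(1), USE.NAMES = FALSE)
      pooled <- colMeans(weights$embeddings[idx, , drop = FALSE])
      out[i, ] <- tanh(weights$start + pooled)
    }
    if (truncated) {
      inform(sprintf("some inputs exceeded max_tokens = %d and were truncated",
                     max_tokens))
    }
    out
  }
  structure(list(d_model = as.integer(d_model),
                 hash_size = as.integer(hash_size),
                 seed = as.integer(seed),
                 type = "toy",
                 encode = encode),
            class = "text_encoder")
}

#' @export
print.text_encoder <- function(x, ...) {
  cat(sprintf("<text_encoder:%s> d_model=%d hash_size=%d seed=%d\n",
              x$type, x$d_model, x$hash_size, x$seed))
  invisible(x)
}

#' Model configuration for the classification head
#'
#' The head mirrors the standard transformer sequence-classification head:
#' dropout, a `d_model x d_model` dense layer with tanh activation, dropout
#' again, then a `d_model x K` projection and softmax over the K classes.
#'
#' @param n_classes Number of classes K (default 3: rare, non-rare, other).
#' @param dropout_rate Dropout probability in `[0, 1)`; identity at
#'   evaluation time. Default 0.1, the convention of this head.
#' @param max_tokens Truncation length fed to the encoder (default 512).
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes = 3L, dropout_rate = 0.1,
                         max_tokens = 512L) {
  if (n_classes < 2) abort("n_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1)")
  }
  structure(list(n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 max_tokens = as.integer(max_tokens)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the published fine-tuning regime: Adam, batch size 32,
#' learning rate 3e-5, 10 epochs, best epoch selected by validation
#' micro-F1 with the background class excluded. When training only a
#' freshly initialised head on frozen toy-encoder features, a conventional
#' head-scale learning rate (1e-3 to 1e-2) is appropriate instead.
#'
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Number of passes over the training data.
#' @param seed Seed for shuffling and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 3e-5,
                         max_epochs = 10L, seed = 1L) {
  if (batch_size < 1 || max_epochs < 1 || learning_rate <= 0) {
    abort("batch_size, max_epochs and learning_rate must be positive")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a three-class text classifier
#'
#' Couples an encoder (see [toy_encoder()]) with the classification head.
#' Head weights are initialised from `init_seed` with symmetric uniform
#' draws scaled by `1/sqrt(d_model)`; biases start at zero.
#'
#' @param encoder A `text_encoder`.
#' @param config A [model_config()].
#' @param init_seed Seed for head initialisation.
#' @return A `rare_classifier` object.
#' @export
classifier_model <- function(encoder, config = model_config(),
                             init_seed = 0L) {
  d <- encoder$d_model
  k <- config$n_classes
  params <- withr::with_seed(init_seed, list(
    W1 = matrix(stats::runif(d * d, -1, 1) / sqrt(d), d, d),
    b1 = numeric(d),
    W2 = matrix(stats::runif(d * k, -1, 1) / sqrt(d), d, k),
    b2 = numeric(k)
  ))
  structure(list(encoder = encoder, config = config, params = params,
                 init_seed = as.integer(init_seed),
                 trace = NULL, best_epoch = NA_integer_),
            class = "rare_classifier")
}

#' @export
print.rare_classifier <- function(x, ...) {
  cat(sprintf("<rare_classifier> d_model=%d K=%d dropout=%.2f%s\n",
              x$encoder$d_model, x$config$n_classes, x$config$dropout_rate,
              if (is.na(x$best_epoch)) " (untrained)"
              else sprintf(" (best epoch %d)", x$best_epoch)))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# head forward on pre-encoded start-token states X (n x d).
# In training mode applies inverted dropout with freshly sampled masks
# (consumes the current RNG stream); in eval mode dropout is the identity.
head_forward <- function(params, X, dropout_rate, training = FALSE) {
  if (training && dropout_rate > 0) {
    m1 <- matrix(stats::rbinom(length(X), 1, 1 - dropout_rate),
                 nrow(X)) / (1 - dropout_rate)
  } else {
    m1 <- NULL
  }
  X1 <- if (is.null(m1)) X else X * m1
  A <- sweep(X1 %*% params$W1, 2, params$b1, "+")
  Z <- tanh(A)
  if (training && dropout_rate > 0) {
    m2 <- matrix(stats::rbinom(length(Z), 1, 1 - dropout_rate),
                 nrow(Z)) / (1 - dropout_rate)
  } else {
    m2 <- NULL
  }
  Z1 <- if (is.null(m2)) Z else Z * m2
  logits <- sweep(Z1 %*% params$W2, 2, params$b2, "+")
  list(probs = softmax_rows(logits),
       cache = list(X1 = X1, Z = Z, Z1 = Z1, m1 = m1, m2 = m2))
}

# cross-entropy gradient through the head; Y is an n x K one-hot matrix
head_backward <- function(params, fwd, Y, dropout_rate) {
  n <- nrow(Y)
  dlogits <- (fwd$probs - Y) / n
  dW2 <- t(fwd$cache$Z1) %*% dlogits
  db2 <- colSums(dlogits)
  dZ1 <- dlogits %*% t(params$W2)
  dZ <- if (is.null(fwd$cache$m2)) dZ1 else dZ1 * fwd$cache$m2
  dA <- dZ * (1 - fwd$cache$Z^2)
  dW1 <- t(fwd$cache$X1) %*% dA
  db1 <- colSums(dA)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_init <- function(params) {
  list(m = purrr::map(params, function(p) p * 0),
       v = purrr::map(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Forward pass: class probabilities for one text
#'
#' Encodes the text, takes the start-token state, and applies the head
#' (dropout layers are the identity in evaluation mode). The output is a
#' probability vector over the classes summing to 1.
#'
#' @param model A `rare_classifier`.
#' @param text A single nonempty string.
#' @return Named numeric vector of class probabilities.
#' @export
forward <- function(model, text) {
  stopifnot(length(text) == 1L)
  X <- model$encoder$encode(text, model$config$max_tokens)
  p <- head_forward(model$params, X, model$config$dropout_rate,
                    training = FALSE)$probs
  setNames(drop(p), class_levels()[seq_len(model$config$n_classes)])
}

#' Predict labels and probabilities for a batch of texts
#'
#' Labels are the argmax of [forward()]; exact ties resolve to the lowest
#' class index. A text that fails to encode (e.g. tokenizes to zero
#' tokens) yields an `NA` row and the batch continues.
#'
#' @param model A `rare_classifier`.
#' @param texts Character vector (may be empty).
#' @return Tibble with `.pred` (factor) and one `p_<class>` column per
#'   class.
#' @export
predict_batch <- function(model, texts) {
  k <- model$config$n_classes
  lv <- class_levels()[seq_len(k)]
  prob_cols <- setNames(rep(list(numeric(0)), k), paste0("p_", lv))
  if (length(texts) == 0) {
    return(tibble(.pred = factor(character(), levels = lv), !!!prob_cols))
  }
  probs <- matrix(NA_real_, length(texts), k)
  failed <- character()
  for (i in seq_along(texts)) {
    p <- tryCatch(forward(model, texts[i]), error = function(e) {
      failed <<- c(failed, sprintf("item %d: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(p)) probs[i, ] <- p
  }
  if (length(failed) > 0) {
    warn(paste0("prediction failed for ", length(failed), " item(s):\n  ",
                paste(failed, collapse = "\n  ")))
  }
  pred <- apply(probs, 1, function(row) {
    if (anyNA(row)) NA_integer_ else which.max(row)
  })
  tibble(.pred = factor(lv[pred], levels = lv),
         !!!setNames(purrr::map(seq_len(k), function(j) probs[, j]),
                     paste0("p_", lv)))
}

#' Train the classifier head with Adam
#'
#' Runs `max_epochs` epochs of minibatch cross-entropy optimization over
#' all classes (background exclusion applies only to the selection metric,
#' never the loss). At the end of every epoch the model is evaluated on the
#' validation set by micro-averaged F1 with the background class excluded,
#' and the returned model carries the parameters of the best epoch
#' (earliest epoch wins ties) together with the full per-epoch trace.
#' Shuffling and dropout masks are driven by the training seed, so runs are
#' reproducible. The encoder is frozen; only head parameters are updated.
#'
#' @param model A `rare_classifier`.
#' @param train_set,val_set Tibbles with `text` and `label` columns.
#' @param tc A [train_config()].
#' @param background Label excluded from the selection metric
#'   (default `"OTHER"`).
#' @return The trained `rare_classifier`, with `$trace` (tibble `epoch`,
#'   `loss`, `val_micro_f1_excl_bg`) and `$best_epoch` filled in.
#' @export
train_classifier <- function(model, train_set, val_set, tc = train_config(),
                             background = "OTHER") {
  if (nrow(train_set) == 0 || nrow(val_set) == 0) {
    abort("train_set and val_set must be nonempty")
  }
  k <- model$config$n_classes
  y <- label_to_code(train_set$label) + 1L
  Xtr <- model$encoder$encode(train_set$text, model$config$max_tokens)
  Xval <- model$encoder$encode(val_set$text, model$config$max_tokens)
  yval <- as_class_factor(val_set$label)
  Y <- matrix(0, nrow(Xtr), k)
  Y[cbind(seq_along(y), y)] <- 1

  params <- model$params
  state <- adam_init(params)
  best <- list(metric = -Inf, epoch = NA_integer_, params = params)
  trace <- vector("list", tc$max_epochs)

  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- sample.int(nrow(Xtr))
      losses <- c()
      for (start in seq(1, length(idx), by = tc$batch_size)) {
        b <- idx[start:min(start + tc$batch_size - 1L, length(idx))]
        fwd <- head_forward(params, Xtr[b, , drop = FALSE],
                            model$config$dropout_rate, training = TRUE)
        loss <- -mean(log(pmax(fwd$probs[cbind(seq_along(b), y[b])], 1e-12)))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d; aborting", epoch))
        }
        losses <- c(losses, loss)
        grads <- head_backward(params, fwd, Y[b, , drop = FALSE],
                               model$config$dropout_rate)
        upd <- adam_step(params, grads, state, tc$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      val_probs <- head_forward(params, Xval, model$config$dropout_rate,
                                training = FALSE)$probs
      val_pred <- factor(class_levels()[apply(val_probs, 1, which.max)],
                         levels = class_levels())
      cm <- confusion_matrix(yval, val_pred)
      metric <- averaged_metrics(cm, exclude_background = TRUE,
                                 background = background)
      metric <- metric$f1[metric$average == "micro"]
      trace[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                               val_micro_f1_excl_bg = metric)
      if (metric > best$metric) {
        best <- list(metric = metric, epoch = epoch, params = params)
      }
    }
  })

  model$params <- best$params
  model$best_epoch <- best$epoch
  model$trace <- dplyr::bind_rows(trace)
  model
}

#' Save/load a classifier checkpoint as JSON
#'
#' The checkpoint stores the head weights at full precision together with
#' the model configuration and the toy-encoder specification (type,
#' dimensions, seed); the encoder's frozen weights are regenerated from
#' that seed on load, so the file is plain text.
#'
#' @param model A `rare_classifier` (toy encoder only).
#' @param path Output/input JSON path.
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` the restored `rare_classifier`.
#' @export
write_classifier <- function(model, path) {
  if (!identical(model$encoder$type, "toy")) {
    abort("only toy-encoder checkpoints serialize to JSON")
  }
  payload <- list(
    config = unclass(model$config),
    encoder = list(type = "toy", d_model = model$encoder$d_model,
                   hash_size = model$encoder$hash_size,
                   seed = model$encoder$seed),
    init_seed = model$init_seed,
    best_epoch = model$best_epoch,
    trace = model$trace,
    params = purrr::map(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = length(p), data = as.numeric(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  enc <- toy_encoder(payload$encoder$d_model, payload$encoder$hash_size,
                     payload$encoder$seed)
  cfg <- model_config(payload$config$n_classes, payload$config$dropout_rate,
                      payload$config$max_tokens)
  model <- classifier_model(enc, cfg, payload$init_seed %||% 0L)
  model$params <- purrr::imap(payload$params, function(p, nm) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  model$best_epoch <- payload$best_epoch %||% NA_integer_
  if (!is.null(payload$trace) && length(payload$trace) > 0) {
    model$trace <- as_tibble(payload$trace)
  }
  model
}

#' @rdname tidy_raremesh
#' @method tidy rare_classifier
#' @export
tidy.rare_classifier <- function(x, ...) {
  if (is.null(x$trace)) {
    abort("model has no training trace; train it first")
  }
  x$trace
}

#' @rdname tidy_raremesh
#' @method glance rare_classifier
#' @export
glance.rare_classifier <- function(x, ...) {
  tibble(
    d_model = x$encoder$d_model,
    n_classes = x$config$n_classes,
    dropout_rate = x$config$dropout_rate,
    trained = !is.na(x$best_epoch),
    best_epoch = x$best_epoch,
    best_val_micro_f1_excl_bg = if (is.null(x$trace)) NA_real_ else
      x$trace$val_micro_f1_excl_bg[x$best_epoch]
  )
}

#' Plot the training trace
#'
#' @param object A trained `rare_classifier`.
#' @param ... Unused.
#' @return A ggplot of loss and selection metric per epoch.
#' @method autoplot rare_classifier
#' @export
autoplot.rare_classifier <- function(object, ...) {
  trace <- tidy(object) |>
    tidyr::pivot_longer(c("loss", "val_micro_f1_excl_bg"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training trace (dashed line: selected epoch)") +
    ggplot2::theme_minimal()
}
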