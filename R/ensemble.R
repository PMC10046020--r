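#' Define a window-classifier architecture
#'
#' An architecture is a stack of a symbol embedding, an optional 1-D
#' convolution (kernel 3, ReLU), a number of LSTM layers (hidden width 8)
#' and a number of additive self-attention layers, followed by global
#' average pooling and a sigmoid head. The five default architectures are
#' returned by [default_model_specs()].
#'
#' @param name Model name.
#' @param embedding_dim Embedding dimension for the 21-symbol vocabulary.
#' @param conv_units Convolution filter count (0 = no convolution layer).
#' @param lstm_layers Number of stacked LSTM layers (0 = none).
#' @param attention_layers Number of stacked attention layers (>= 1).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, embedding_dim, conv_units = 0L,
                       lstm_layers = 0L, attention_layers = 1L) {
  stopifnot(embedding_dim >= 1, conv_units >= 0,
            lstm_layers >= 0, attention_layers >= 0)
  structure(list(
    name = as.character(name),
    embedding_dim = as.integer(embedding_dim),
    conv_units = as.integer(conv_units),
    lstm_layers = as.integer(lstm_layers),
    attention_layers = as.integer(attention_layers)
  ), class = "model_spec")
}

#' The five default ensemble member architectures
#'
#' Embedding dimension / convolution units / LSTM layers / attention layers:
#' Model 1 = 10/15/2/3, Model 2 = 10/15/0/2, Model 3 = 10/15/3/6,
#' Model 4 = 3/0/0/1, Model 5 = 6/0/0/1. Members with different shapes make
#' different errors on the same window, which is what ensemble averaging
#' exploits.
#'
#' @return A named list of five [model_spec()] objects.
#' @export
default_model_specs <- function() {
  list(
    Model1 = model_spec("Model1", 10L, 15L, 2L, 3L),
    Model2 = model_spec("Model2", 10L, 15L, 0L, 2L),
    Model3 = model_spec("Model3", 10L, 15L, 3L, 6L),
    Model4 = model_spec("Model4", 3L, 0L, 0L, 1L),
    Model5 = model_spec("Model5", 6L, 0L, 0L, 1L)
  )
}

#' Training configuration
#'
#' @param epochs Training epochs (default 1000; desk-scale runs use far
#'   fewer).
#' @param learning_rate Adam learning rate (default 0.005).
#' @param batch_size Mini-batch size (default 256).
#' @param negative_subsample_ratio Proteome negatives drawn per positive in
#'   each epoch, resampled every epoch (default 2; 0 disables proteome
#'   negatives).
#' @param seed Integer seed; fully determines initialization, shuffling and
#'   subsampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.005,
                         batch_size = 256L, negative_subsample_ratio = 2,
                         seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            negative_subsample_ratio >= 0)
  structure(list(
    epochs = as.integer(epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    negative_subsample_ratio = negative_subsample_ratio,
    seed = as.integer(seed)
  ), class = "train_config")
}

#' Build an untrained window classifier
#'
#' Instantiates the architecture of `spec` with seeded random weights.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `cpp_model` (untrained).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  arch <- nn_arch(spec)
  params <- nn_init_params(arch, seed)
  structure(list(spec = spec, arch = arch, params = params,
                 loss = numeric(0), trained = FALSE),
            class = "cpp_model")
}

#' @export
print.cpp_model <- function(x, ...) {
  s <- x$spec
  cat("<cpp_model ", s$name, "> emb=", s$embedding_dim,
      " conv=", s$conv_units, " lstm=", s$lstm_layers,
      " attn=", s$attention_layers,
      if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

# Score a batch of encoded windows (integer matrix) with one member.
score_model <- function(model, X) UseMethod("score_model")

#' @export
score_model.cpp_model <- function(model, X) {
  out <- numeric(nrow(X))
  chunk <- 4096L
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    out[s:e] <- nn_forward(model$params, model$arch,
                           X[s:e, , drop = FALSE])$prob
  }
  out
}

# Constant-score member, used as a controllable stand-in in tests.
#' @export
score_model.constant_model <- function(model, X) {
  rep(model$value, nrow(X))
}

#' Train a window classifier
#'
#' Mini-batch Adam on binary cross-entropy over the fragment windows.
#' Curated fragments are used every epoch; proteome-derived negatives are
#' subsampled afresh each epoch at `negative_subsample_ratio` per positive,
#' so the model sees a changing sample of the (potentially huge) proteome
#' background without being swamped by it.
#'
#' @param model A `cpp_model` from [build_model()].
#' @param dataset A `fragment_dataset` containing both labels.
#' @param config A [train_config()].
#' @return The trained `cpp_model`, with the per-epoch mean loss in
#'   `$loss`.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "cpp_model"), inherits(config, "train_config"))
  curated <- dataset[dataset$origin != "proteome", , drop = FALSE]
  proteome <- dataset[dataset$origin == "proteome", , drop = FALSE]
  if (config$negative_subsample_ratio == 0) {
    proteome <- proteome[0, , drop = FALSE]
  }
  y_cur <- curated$label
  if (length(unique(c(y_cur, proteome$label))) < 2) {
    stop("training data must contain both labels", call. = FALSE)
  }
  X_cur <- encode_windows(curated$window)
  X_pro <- if (nrow(proteome) > 0) encode_windows(proteome$window) else NULL
  n_pos <- sum(y_cur == 1L)
  n_draw <- min(nrow(proteome),
                ceiling(config$negative_subsample_ratio * n_pos))

  withr::local_seed(derive_seed(config$seed,
                                paste0("train_", model$spec$name)))
  params <- model$params
  state <- adam_init(params)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    if (!is.null(X_pro) && n_draw > 0) {
      take <- sample.int(nrow(X_pro), n_draw)
      X_ep <- rbind(X_cur, X_pro[take, , drop = FALSE])
      y_ep <- c(y_cur, rep(0L, n_draw))
    } else {
      X_ep <- X_cur
      y_ep <- y_cur
    }
    ord <- sample.int(nrow(X_ep))
    X_ep <- X_ep[ord, , drop = FALSE]
    y_ep <- y_ep[ord]
    starts <- seq(1L, nrow(X_ep), by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      e <- min(s + config$batch_size - 1L, nrow(X_ep))
      Xb <- X_ep[s:e, , drop = FALSE]
      yb <- y_ep[s:e]
      fwd <- nn_forward(params, model$arch, Xb, keep_cache = TRUE)
      ep_loss <- ep_loss + bce_loss(fwd$prob, yb) * length(yb)
      grads <- nn_backward(params, model$arch, fwd$cache, yb)
      upd <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    losses[ep] <- ep_loss / nrow(X_ep)
  }
  model$params <- params
  model$loss <- losses
  model$trained <- TRUE
  model
}

#' Train the five-member ensemble
#'
#' Builds and trains one classifier per spec (each with its own derived
#' seed) on the same fragment dataset. The ensemble's score for a window is
#' the arithmetic mean of the five member scores.
#'
#' @param dataset A `fragment_dataset`.
#' @param specs List of [model_spec()]s (default [default_model_specs()]).
#' @param config A [train_config()].
#' @return A `cpp_ensemble`.
#' @export
train_ensemble <- function(dataset, specs = default_model_specs(),
                           config = train_config()) {
  members <- vector("list", length(specs))
  names(members) <- vapply(specs, function(s) s$name, character(1))
  for (i in seq_along(specs)) {
    m <- build_model(specs[[i]],
                     seed = derive_seed(config$seed,
                                        paste0("init_", specs[[i]]$name)))
    members[[i]] <- train_model(m, dataset, config)
  }
  new_cpp_ensemble(members, config, fingerprint = dataset_fingerprint(dataset))
}

new_cpp_ensemble <- function(members, config = NULL, fingerprint = NA_character_) {
  structure(list(members = members,
                 vocabulary = aa_vocabulary(),
                 config = config,
                 fingerprint = fingerprint),
            class = "cpp_ensemble")
}

dataset_fingerprint <- function(dataset) {
  rlang::hash(list(dataset$window, dataset$label))
}

#' @export
print.cpp_ensemble <- function(x, ...) {
  cat("<cpp_ensemble> ", length(x$members), " members: ",
      paste(names(x$members), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score 9-mer windows with an ensemble
#'
#' @param ensemble A `cpp_ensemble`.
#' @param windows Character vector of length-9 strings over the 21-symbol
#'   vocabulary (20 amino acids + `-`).
#' @param per_member Also return each member's scores.
#' @return By default a numeric vector of ensemble scores (mean of member
#'   scores), in input order. With `per_member = TRUE`, a tibble with one
#'   column per member plus `ensemble`.
#' @export
predict_windows <- function(ensemble, windows, per_member = FALSE) {
  stopifnot(inherits(ensemble, "cpp_ensemble"))
  if (length(windows) == 0) {
    return(if (per_member) tibble::tibble() else numeric(0))
  }
  X <- encode_windows(windows)
  member_scores <- lapply(ensemble$members, function(m) score_model(m, X))
  avg <- Reduce(`+`, member_scores) / length(member_scores)
  if (per_member) {
    out <- tibble::as_tibble(member_scores)
    out$ensemble <- avg
    out
  } else {
    avg
  }
}

#' Save an ensemble to a model bundle directory
#'
#' Writes a JSON manifest (specs, training config, vocabulary, data
#' fingerprint) plus one JSON weight file per member. Everything is plain
#' text; weights are stored at full precision.
#'
#' @param ensemble A `cpp_ensemble`.
#' @param path Bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(ensemble, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    members = lapply(ensemble$members, function(m) unclass(m$spec)),
    config = if (is.null(ensemble$config)) NULL else unclass(ensemble$config),
    vocabulary = as.list(ensemble$vocabulary),
    fingerprint = ensemble$fingerprint
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(ensemble$members)) {
    m <- ensemble$members[[nm]]
    ser <- lapply(m$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p))
    })
    jsonlite::write_json(list(params = ser, loss = m$loss),
                         file.path(path, paste0(nm, ".json")),
                         digits = NA)
  }
  invisible(path)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param path Bundle directory.
#' @param expect_fingerprint Optional data fingerprint to check against the
#'   manifest; a mismatch gives a warning, not an error.
#' @return A `cpp_ensemble`.
#' @export
load_ensemble <- function(path, expect_fingerprint = NULL) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("no model bundle at '", path, "'", call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  members <- list()
  for (nm in names(manifest$members)) {
    sp <- manifest$members[[nm]]
    spec <- model_spec(sp$name, sp$embedding_dim, sp$conv_units,
                       sp$lstm_layers, sp$attention_layers)
    raw <- jsonlite::read_json(file.path(path, paste0(nm, ".json")),
                               simplifyVector = FALSE)
    params <- lapply(raw$params, function(p) {
      dims <- unlist(p$dim)
      vals <- unlist(p$data)
      if (length(dims) == 2) matrix(vals, dims[1], dims[2]) else vals
    })
    # scalars stored as length-1 vectors
    params$head_b <- as.numeric(params$head_b)
    members[[nm]] <- structure(
      list(spec = spec, arch = nn_arch(spec), params = params,
           loss = as.numeric(unlist(raw$loss)), trained = TRUE),
      class = "cpp_model")
  }
  cfg <- manifest$config
  config <- if (is.null(cfg)) NULL else {
    train_config(cfg$epochs, cfg$learning_rate, cfg$batch_size,
                 cfg$negative_subsample_ratio, cfg$seed)
  }
  fp <- manifest$fingerprint
  if (!is.null(expect_fingerprint) && !identical(expect_fingerprint, fp)) {
    warning("model bundle fingerprint does not match the supplied data ",
            "fingerprint", call. = FALSE)
  }
  ens <- new_cpp_ensemble(members, config,
                          fingerprint = if (is.null(fp)) NA_character_ else fp)
  ens
}
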