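#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a propensity profile
#'
#' @param x A `cpp_profile`.
#' @param ... Unused.
#' @return The per-residue tibble (`id`, `position`, `residue`, `score`,
#'   `n_windows`).
#' @export
tidy.cpp_profile <- function(x, ...) {
  dplyr::mutate(x$residues, id = x$id, .before = 1)
}

#' @rdname tidy.cpp_profile
#' @export
glance.cpp_profile <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    length = nchar(x$sequence),
    n_windows = nrow(x$windows),
    mean_score = mean(x$residues$score),
    max_score = max(x$residues$score)
  )
}

#' Tidy a trained ensemble
#'
#' @param x A `cpp_ensemble`.
#' @param ... Unused.
#' @return One row per member: architecture fields, parameter count and
#'   final training loss.
#' @export
tidy.cpp_ensemble <- function(x, ...) {
  purrr::map_dfr(x$members, function(m) {
    tibble::tibble(
      model = m$spec$name,
      embedding_dim = m$spec$embedding_dim,
      conv_units = m$spec$conv_units,
      lstm_layers = m$spec$lstm_layers,
      attention_layers = m$spec$attention_layers,
      n_parameters = sum(vapply(m$params, length, integer(1))),
      final_loss = if (length(m$loss)) m$loss[length(m$loss)] else NA_real_
    )
  })
}

#' @rdname tidy.cpp_ensemble
#' @export
glance.cpp_ensemble <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    epochs = if (is.null(x$config)) NA_integer_ else x$config$epochs,
    seed = if (is.null(x$config)) NA_integer_ else x$config$seed,
    fingerprint = x$fingerprint
  )
}

#' One-row metrics tibble
#'
#' @param x A `cpp_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble with the six metrics, confusion counts, `n` and
#'   `threshold`.
#' @export
glance.cpp_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname glance.cpp_metrics
#' @export
tidy.cpp_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "acc", "sen", "spe", "pre", "mcc"),
    value = c(x$auc, x$acc, x$sen, x$spe, x$pre, x$mcc)
  )
}

#' Tidy a position frequency matrix
#'
#' @param x A `cpp_pfm`.
#' @param ... Unused.
#' @return A long tibble (`position`, `residue`, `frequency`).
#' @export
tidy.cpp_pfm <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n_sequences") <- NULL
  tibble::tibble(
    position = rep(seq_len(ncol(m)), each = nrow(m)),
    residue = rep(rownames(m), ncol(m)),
    frequency = as.numeric(m)
  )
}

#' Plot a propensity profile
#'
#' Per-residue propensity along the sequence, with an optional threshold
#' line.
#'
#' @param object A `cpp_profile`.
#' @param threshold Optional horizontal reference line (default 0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpp_profile <- function(object, threshold = 0.8, ...) {
  df <- object$residues
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue position", y = "Cell-penetration propensity",
                  title = object$id) +
    ggplot2::theme_minimal()
}

#' Plot the score histogram of a sequence-space scan
#'
#' @param object A `cpp_space_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpp_space_scan <- function(object, ...) {
  df <- object$histogram
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = 0.045, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Peptide score", y = "Mutant count") +
    ggplot2::theme_minimal()
}

#' Logo-style plot of a position frequency matrix
#'
#' Stacked residue letters per position, letter height proportional to the
#' residue's frequency at that position (raw frequencies, largest residue
#' on top).
#'
#' @param object A `cpp_pfm`.
#' @param min_frequency Hide residues below this frequency (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpp_pfm <- function(object, min_frequency = 0.01, ...) {
  df <- tidy.cpp_pfm(object) |>
    dplyr::filter(.data$frequency >= min_frequency) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$frequency, .by_group = TRUE) |>
    dplyr::mutate(top = cumsum(.data$frequency),
                  mid = .data$top - .data$frequency / 2) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue,
                                    size = .data$frequency,
                                    colour = .data$residue),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1.5, 8)) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object))) +
    ggplot2::labs(x = "Position", y = "Cumulative frequency") +
    ggplot2::theme_minimal()
}

#' Plot training loss trajectories of an ensemble
#'
#' @param object A `cpp_ensemble` with trained members.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean loss, one line per member.
#' @export
autoplot.cpp_ensemble <- function(object, ...) {
  df <- purrr::map_dfr(object$members, function(m) {
    tibble::tibble(model = m$spec$name, epoch = seq_along(m$loss),
                   loss = m$loss)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Binary cross-entropy") +
    ggplot2::theme_minimal()
}
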