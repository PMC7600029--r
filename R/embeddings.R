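# Code-level (skip-gram) and window-level (distributed bag-of-words)
# embeddings, trained on pan-therapeutic training windows only.

# guard: embedding corpora must never contain oversampled or bone-health
# windows (training-set provenance contract)
assert_embedding_corpus <- function(windows) {
  if (!is.null(windows$cohort_tag) && any(windows$cohort_tag != "pan_therapeutic")) {
    stopf("embedding corpora must come from the pan-therapeutic cohort only")
  }
  if (!is.null(windows$origin) && any(windows$origin == "oversampled")) {
    stopf("embedding corpora must not contain oversampled windows")
  }
  invisible(TRUE)
}

# convert token sequences to in-vocabulary index sequences for the
# embedding trainers (OOV tokens are dropped from embedding corpora)
corpus_indices <- function(sequences, vocab, min_len = 1L) {
  idx <- lapply(sequences, function(s) {
    i <- token_indices(vocab, s)
    i[i > 0L]
  })
  idx[vapply(idx, length, 1L) >= min_len]
}

#' Train skip-gram code embeddings
#'
#' Learns a dense vector per vocabulary token with the skip-gram
#' negative-sampling architecture over the chronological code sequences of
#' the pan-therapeutic training windows. Codes that occur in similar
#' contexts end near each other in cosine distance. Single-threaded and
#' deterministic given the seed.
#'
#' @param sequences list of token vectors (or a windows table, whose
#'   `codes` column is used after a provenance check).
#' @param vocab a [build_vocabulary()] result.
#' @param dim embedding dimension (default 100).
#' @param window context window size (default 10).
#' @param negative negative samples per positive pair (default 5).
#' @param epochs training epochs (default 5).
#' @param lr initial learning rate (linearly decayed).
#' @param seed integer seed.
#' @return a `code_embedding`: token-by-`dim` matrix plus config. Unknown /
#'   padding tokens map to the zero vector.
#' @export
train_code_embedding <- function(sequences, vocab, dim = 100L, window = 10L,
                                 negative = 5L, epochs = 5L, lr = 0.025,
                                 seed = 1L) {
  if (is.data.frame(sequences)) {
    assert_embedding_corpus(sequences)
    sequences <- sequences$codes
  }
  if (length(sequences) == 0L) stopf("empty embedding corpus")
  idx <- corpus_indices(sequences, vocab, min_len = 2L)
  if (length(idx) == 0L) {
    stopf("no sequence has >= 2 in-vocabulary tokens; cannot train embeddings")
  }
  mat <- cpp_sgns_train(idx, length(vocab$tokens), as.integer(dim),
                        as.integer(window), as.integer(negative),
                        as.integer(epochs), lr, vocab$counts, as.integer(seed))
  rownames(mat) <- vocab$tokens
  structure(list(vocab = vocab, matrix = mat,
                 config = list(dim = as.integer(dim), window = as.integer(window),
                               negative = as.integer(negative),
                               epochs = as.integer(epochs), lr = lr,
                               seed = as.integer(seed))),
            class = "code_embedding")
}

#' @export
print.code_embedding <- function(x, ...) {
  cat(sprintf("<code_embedding> %d tokens x %d dims (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$config$seed))
  invisible(x)
}

#' Nearest codes by cosine similarity
#'
#' @param embedding a `code_embedding`.
#' @param token query token (must be in vocabulary).
#' @param k number of neighbours.
#' @return `data.table` of `token`, `similarity` in descending cosine order
#'   (ties broken by token); the query is never its own neighbour.
#' @export
nearest_codes <- function(embedding, token, k = 10L) {
  m <- embedding$matrix
  if (!(token %in% rownames(m))) stopf("token not in vocabulary: %s", token)
  if (k <= 0L) {
    return(data.table::data.table(token = character(), similarity = numeric()))
  }
  q <- m[token, ]
  norms <- sqrt(rowSums(m^2))
  sims <- as.numeric(m %*% q) / (norms * sqrt(sum(q^2)))
  sims[norms == 0] <- -Inf
  query <- token
  out <- data.table::data.table(token = rownames(m), similarity = sims)
  out <- out[token != query]
  data.table::setorder(out, -similarity, token)
  utils::head(out, k)
}

#' Project code embeddings to two dimensions for qualitative QC
#'
#' A principal-component projection of the embedding matrix onto its first
#' two components, with a deterministic sign convention (the loading of
#' largest magnitude on each axis is positive). A quality-control artifact
#' for eyeballing whether related codes collocate; it carries no accuracy
#' contract.
#'
#' @param embedding a `code_embedding`.
#' @param seed accepted for interface symmetry; the projection is
#'   deterministic.
#' @return `data.table` with `token`, `x`, `y`.
#' @export
project_embedding_2d <- function(embedding, seed = 1L) {
  m <- embedding$matrix
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = 2L)
  xy <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    peak <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[peak, j] < 0) xy[, j] <- -xy[, j]
  }
  data.table::data.table(token = rownames(m), x = xy[, 1], y = xy[, 2])
}

#' Plot the 2-d code-embedding projection
#'
#' @param projection output of [project_embedding_2d()].
#' @param highlight optional character vector of tokens to colour.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_embedding_projection <- function(projection, highlight = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  projection <- data.table::copy(projection)
  projection[, group := if (is.null(highlight)) "code" else
    ifelse(token %in% highlight, "highlighted", "code")]
  ggplot2::ggplot(projection, ggplot2::aes(x = x, y = y, colour = group)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "component 1", y = "component 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Train the distributed bag-of-words window embedding
#'
#' Learns one vector per training window that predicts the window's member
#' tokens (distributed bag of words), yielding a fixed-length summary of a
#' 2-year episode of patient history. Inference for unseen windows fits a
#' fresh document vector against the frozen output weights; each window's
#' inference stream is seeded from its token content, so inferred vectors
#' do not depend on batch composition or order.
#'
#' @inheritParams train_code_embedding
#' @param dim embedding dimension (default 128).
#' @param epochs training epochs (default 20).
#' @return a `window_embedding_model`.
#' @export
train_window_embedding <- function(sequences, vocab, dim = 128L, negative = 5L,
                                   epochs = 20L, lr = 0.05, seed = 1L) {
  if (is.data.frame(sequences)) {
    assert_embedding_corpus(sequences)
    sequences <- sequences$codes
  }
  if (length(sequences) == 0L) stopf("empty embedding corpus")
  idx <- corpus_indices(sequences, vocab, min_len = 1L)
  if (length(idx) == 0L) stopf("no sequence has in-vocabulary tokens")
  fit <- cpp_dbow_train(idx, length(vocab$tokens), as.integer(dim),
                        as.integer(negative), as.integer(epochs), lr,
                        vocab$counts, as.integer(seed))
  structure(list(vocab = vocab, out_matrix = fit$out, doc_matrix = fit$doc,
                 config = list(dim = as.integer(dim),
                               negative = as.integer(negative),
                               epochs = as.integer(epochs), lr = lr,
                               seed = as.integer(seed),
                               infer_epochs = 40L)),
            class = "window_embedding_model")
}

#' @export
print.window_embedding_model <- function(x, ...) {
  cat(sprintf("<window_embedding_model> %d-d over %d tokens (seed %d)\n",
              x$config$dim, length(x$vocab$tokens), x$config$seed))
  invisible(x)
}

#' Infer window vectors from a fitted window-embedding model
#'
#' @param model a `window_embedding_model`.
#' @param sequences list of token vectors.
#' @param seed integer seed (combined with each window's content hash).
#' @return numeric matrix, one `dim`-length row per sequence. Sequences
#'   with no in-vocabulary tokens get the zero vector with a warning.
#' @export
infer_window_vectors <- function(model, sequences, seed = 1L) {
  idx <- lapply(sequences, function(s) {
    i <- token_indices(model$vocab, s)
    i[i > 0L]
  })
  n_empty <- sum(vapply(idx, length, 1L) == 0L)
  if (n_empty > 0L) {
    warnf("%d sequence(s) had no in-vocabulary tokens; returning zero vectors",
          n_empty)
  }
  cpp_dbow_infer(idx, model$out_matrix, model$vocab$counts,
                 model$config$negative, model$config$infer_epochs,
                 model$config$lr, as.integer(seed))
}

#' Infer the vector of one window
#' @inheritParams infer_window_vectors
#' @param sequence a token vector.
#' @return numeric vector of length `dim`.
#' @export
infer_window_vector <- function(model, sequence, seed = 1L) {
  drop(infer_window_vectors(model, list(sequence), seed))
}

#' Embed one window's code sequence as a fixed-length matrix
#'
#' Keeps the most recent `max_len` tokens (truncating the oldest first),
#' front-pads shorter sequences with zero rows, and maps out-of-vocabulary
#' tokens to the zero (unknown) vector. The pre-truncation diagnosis count
#' is returned alongside, because truncation and padding are only visible
#' to the classifier through that static feature.
#'
#' @param codes chronologically ordered token vector of one window.
#' @param embedding a `code_embedding`.
#' @param max_len fixed sequence length (default 200).
#' @return list with `matrix` (`max_len` x dim) and `dx_count`.
#' @export
embed_sequence <- function(codes, embedding, max_len = 200L) {
  stopifnot(max_len > 0L)
  dim <- ncol(embedding$matrix)
  dx_count <- length(codes)
  kept <- if (dx_count > max_len) codes[(dx_count - max_len + 1L):dx_count] else codes
  idx <- token_indices(embedding$vocab, kept)
  mat <- matrix(0, nrow = max_len, ncol = dim)
  if (length(kept) > 0L) {
    rows <- (max_len - length(kept) + 1L):max_len
    inv <- idx > 0L
    mat[rows[inv], ] <- embedding$matrix[idx[inv], , drop = FALSE]
  }
  list(matrix = mat, dx_count = dx_count)
}
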