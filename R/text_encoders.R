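# Text encoders satisfying a common contract:
#   $encode(texts, training = FALSE) -> n x dim matrix, one row per string
#   $backward(dY)                    -> accumulate parameter gradients
#   $params                          -> list of trainable nn_param (may be empty)
#   $dim, $max_tokens                -> output width / truncation policy
# Identical strings always map to identical rows in inference mode. Texts
# longer than max_tokens are truncated with a warning.

simple_tokenize <- function(text, max_tokens = 256) {
  toks <- regmatches(tolower(text), gregexpr("[a-z0-9']+", tolower(text)))[[1]]
  if (length(toks) > max_tokens) {
    warning("text truncated to ", max_tokens, " tokens")
    toks <- toks[seq_len(max_tokens)]
  }
  toks
}

# Deterministic 32-bit FNV-1a string hash (R implementation, no deps).
# Arithmetic is done in doubles; the 32-bit product h * 16777619 is split
# into 16-bit halves so every intermediate stays below 2^53.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)   # xor on the low byte
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Deterministic hashing bag-of-words text encoder
#'
#' Feature-hashing sentence embedder: each token is hashed to a bucket in
#' `1..dim` with a deterministic sign, the bucket counts are accumulated and
#' the vector L2-normalized. No parameters, no randomness, fully
#' reproducible offline -- the workhorse for tests and synthetic training
#' runs (the projection head on top of it is still trainable).
#'
#' @param dim embedding width (default 96).
#' @param max_tokens truncation limit per text (default 256).
#' @return a text encoder object (class `text_encoder`).
#' @export
hash_text_encoder <- function(dim = 96, max_tokens = 256) {
  self <- new.env()
  self$dim <- dim
  self$max_tokens <- max_tokens
  self$params <- list()
  self$kind <- "hash"
  self$encode <- function(texts, training = FALSE) {
    n <- length(texts)
    out <- matrix(0, n, dim)
    if (n == 0) return(out)
    for (i in seq_len(n)) {
      toks <- simple_tokenize(texts[i], max_tokens)
      for (tk in toks) {
        h <- fnv1a(tk)
        j <- (h %% dim) + 1
        s <- if (((h %/% dim) %% 2) == 0) 1 else -1
        out[i, j] <- out[i, j] + s
      }
      nrm <- sqrt(sum(out[i, ]^2))
      if (nrm > 0) out[i, ] <- out[i, ] / nrm
    }
    out
  }
  self$backward <- function(dY) invisible(NULL)
  class(self) <- "text_encoder"
  self
}

#' Trainable token-embedding averaging text encoder
#'
#' A tiny trainable encoder for synthetic end-to-end runs: a learned
#' embedding table over a fixed vocabulary; a sentence is encoded as the
#' mean of its token vectors (out-of-vocabulary tokens are skipped; an
#' all-OOV or empty sentence maps to the zero row). Gradients flow into the
#' embedding table.
#'
#' @param vocab_texts character vector whose tokens define the vocabulary.
#' @param dim embedding width (default 32).
#' @param max_tokens truncation limit per text.
#' @return a text encoder object with one trainable parameter matrix.
#' @export
avg_embedding_text_encoder <- function(vocab_texts, dim = 32,
                                       max_tokens = 256) {
  vocab <- unique(unlist(lapply(vocab_texts, simple_tokenize,
                                max_tokens = Inf)))
  if (!length(vocab)) stop("empty vocabulary")
  self <- new.env()
  self$dim <- dim
  self$max_tokens <- max_tokens
  self$vocab <- vocab
  self$kind <- "avg_embedding"
  self$E <- new_param(matrix(stats::rnorm(length(vocab) * dim, sd = 0.3),
                             length(vocab), dim), name = "text.E")
  self$params <- list(self$E)
  self$encode <- function(texts, training = FALSE) {
    n <- length(texts)
    out <- matrix(0, n, dim)
    idx <- vector("list", n)
    for (i in seq_len(n)) {
      toks <- simple_tokenize(texts[i], self$max_tokens)
      ii <- match(toks, self$vocab)
      ii <- ii[!is.na(ii)]
      idx[[i]] <- ii
      if (length(ii)) {
        out[i, ] <- colMeans(self$E$val[ii, , drop = FALSE])
      }
    }
    self$last_idx <- idx
    out
  }
  self$backward <- function(dY) {
    for (i in seq_along(self$last_idx)) {
      ii <- self$last_idx[[i]]
      if (!length(ii)) next
      g <- dY[i, ] / length(ii)
      for (j in ii) self$E$grad[j, ] <- self$E$grad[j, ] + g
    }
    invisible(NULL)
  }
  class(self) <- "text_encoder"
  self
}

#' Pretrained transformer text encoder (contract stub)
#'
#' The full framework is designed around a pretrained BERT-family sentence
#' encoder fine-tuned at a reduced learning rate. Such checkpoints cannot be
#' bundled with this package; this constructor therefore accepts a
#' user-supplied encoding function (e.g. wrapping an external service or a
#' locally exported embedding matrix) and adapts it to the text-encoder
#' contract. Without `encode_fn` it fails with an informative error.
#'
#' @param encode_fn function mapping a character vector to an `n x dim`
#'   numeric matrix.
#' @param dim embedding width of `encode_fn`'s output.
#' @param max_tokens truncation limit (enforcement is left to `encode_fn`).
#' @return a text encoder object (frozen: no trainable parameters here).
#' @export
pretrained_text_encoder <- function(encode_fn = NULL, dim = NULL,
                                    max_tokens = 512) {
  if (is.null(encode_fn) || is.null(dim)) {
    stop("no pretrained checkpoint is bundled with this package; supply ",
         "encode_fn (character vector -> n x dim matrix) and dim, or use ",
         "hash_text_encoder() / avg_embedding_text_encoder()")
  }
  self <- new.env()
  self$dim <- dim
  self$max_tokens <- max_tokens
  self$params <- list()
  self$kind <- "pretrained"
  self$encode <- function(texts, training = FALSE) {
    out <- encode_fn(texts)
    if (!is.matrix(out) || nrow(out) != length(texts) || ncol(out) != dim) {
      stop("encode_fn must return a length(texts) x ", dim, " matrix")
    }
    out
  }
  self$backward <- function(dY) invisible(NULL)
  class(self) <- "text_encoder"
  self
}

#' Encode texts with any text encoder
#'
#' @param encoder a text encoder satisfying the contract.
#' @param texts character vector (may be empty).
#' @return `length(texts) x dim` matrix.
#' @export
text_encode <- function(encoder, texts) {
  encoder$encode(as.character(texts), training = FALSE)
}
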