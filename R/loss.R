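#' Cosine similarity matrix between two sets of projections
#'
#' Rows of `x` and `y` are L2-normalized (zero rows map to the zero vector)
#' and the full `n x n` matrix of dot products is returned, so entry `(i,j)`
#' is the cosine similarity of EEG projection `i` and text projection `j`.
#'
#' @param x `n x d` matrix.
#' @param y `n x d` matrix.
#' @return `n x n` similarity matrix.
#' @export
similarity_matrix <- function(x, y) {
  nx <- l2_normalize_rows(x, warn = FALSE)$y
  ny <- l2_normalize_rows(y, warn = FALSE)$y
  tcrossprod(nx, ny)
}

#' Paired-projection contrastive batch
#'
#' Bundles matched EEG and text projections with their similarity matrix
#' and the softmax temperature, the unit consumed by [contrastive_loss()].
#'
#' @param x `n x d` EEG projections (rows need not be pre-normalized).
#' @param y `n x d` text projections.
#' @param tau positive softmax temperature.
#' @return object of class `contrastive_batch` with fields `x`, `y`, `sim`,
#'   `tau`.
#' @export
contrastive_batch <- function(x, y, tau = 1) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  structure(list(x = x, y = y, sim = similarity_matrix(x, y), tau = tau),
            class = "contrastive_batch")
}

# Row-wise log-softmax cross-entropy against the diagonal:
# mean_i [ -log softmax(logits[i, ])_i ]. Numerically stabilized.
.infonce_direction <- function(logits) {
  mx <- apply(logits, 1, max)
  z <- exp(logits - mx)
  rs <- rowSums(z)
  p <- z / rs
  loss <- mean(-(diag(logits) - mx - log(rs)))
  grad <- p
  diag(grad) <- diag(grad) - 1
  list(loss = loss, grad = grad / nrow(logits))   # d loss / d logits
}

#' InfoNCE contrastive alignment loss
#'
#' The temperature-scaled softmax objective over in-batch negatives:
#' for matched pairs `(x_i, y_i)`,
#' `L = (1/N) * sum_i -log[ exp(sim(x_i, y_i)/tau) / sum_j exp(sim(x_i, y_j)/tau) ]`.
#' The one-directional form normalizes over text candidates for each EEG
#' anchor (rows of `sim`); the symmetric form (default, the CLIP
#' convention) averages this with the text-to-EEG direction (columns).
#'
#' The value is non-negative, equals `log(N)` when all similarities are
#' equal, and is invariant to scaling `sim` and `tau` by the same constant.
#'
#' @param batch a [contrastive_batch()], or a plain `n x n` similarity
#'   matrix (then `tau` must be supplied).
#' @param symmetric average the two directions (default `TRUE`).
#' @param tau temperature override when `batch` is a bare matrix.
#' @param grad if `TRUE`, also return the gradient of the loss w.r.t. the
#'   similarity matrix (and w.r.t. `log(1/tau)`).
#' @return scalar loss, or (with `grad = TRUE`) list with `loss`,
#'   `grad_sim`, `grad_log_scale`.
#' @export
contrastive_loss <- function(batch, symmetric = TRUE, tau = NULL,
                             grad = FALSE) {
  if (inherits(batch, "contrastive_batch")) {
    sim <- batch$sim
    if (is.null(tau)) tau <- batch$tau
  } else {
    sim <- as.matrix(batch)
    if (is.null(tau)) stop("tau must be given when batch is a bare matrix")
  }
  n <- nrow(sim)
  if (n < 2L) stop("contrastive loss needs n >= 2 pairs (no negatives)")
  if (ncol(sim) != n) stop("similarity matrix must be square")
  if (tau <= 0) stop("tau must be positive")
  logits <- sim / tau
  fwd <- .infonce_direction(logits)
  if (symmetric) {
    bwd <- .infonce_direction(t(logits))
    loss <- (fwd$loss + bwd$loss) / 2
    glogits <- (fwd$grad + t(bwd$grad)) / 2
  } else {
    loss <- fwd$loss
    glogits <- fwd$grad
  }
  if (!grad) return(loss)
  list(loss = loss,
       grad_sim = glogits / tau,
       # d loss / d log(scale) where logits = exp(log_scale) * sim
       grad_log_scale = sum(glogits * logits))
}
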