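#' Mask low-coverage bins by their log-scale marginal
#'
#' Standard Hi-C hygiene before balancing. A bin is masked if its marginal
#' (row sum over currently valid bins) is zero, or if its log marginal falls
#' below the median by more than `mad_k` median absolute deviations (raw MAD,
#' constant 1). Masking is idempotent and never touches stored counts, so
#' `total_contacts` is conserved.
#'
#' @param m A `contact_map`.
#' @param mad_k Positive MAD multiplier (default 5).
#' @return The map with an updated mask (weights reset to undefined).
#' @export
mask_low_coverage <- function(m, mad_k = 5) {
  stopifnot(mad_k > 0)
  valid <- m$mask
  marg <- rowSums(m$counts[, valid, drop = FALSE])
  marg[!valid] <- 0
  new_mask <- valid & marg > 0
  if (any(new_mask)) {
    l <- log(marg[new_mask])
    med <- stats::median(l)
    mad_raw <- stats::median(abs(l - med))
    new_mask[new_mask] <- l >= med - mad_k * mad_raw
  }
  if (!any(new_mask)) stop("matrix empty after masking", call. = FALSE)
  m$mask <- new_mask
  m$weights <- ifelse(new_mask & m$expected, 1, NA_real_)
  m$balance <- NULL
  m
}

#' Iteratively balance a contact map (ICE / Sinkhorn)
#'
#' Computes per-bin weights `w` such that the marginals of `w_i * O_ij * w_j`
#' over unmasked bins are equal (relative spread below `tol`), diagonal
#' included. Weights are scaled so the mean balanced marginal is 1. Masked
#' bins keep undefined weights. Non-convergence is reported with a warning and
#' recorded in the result's `balance` field, never silently accepted.
#'
#' @param m A `contact_map`, masked (bins with zero marginal must already be
#'   masked; see [mask_low_coverage()]).
#' @param max_iter Maximum iterations (default 200).
#' @param tol Relative marginal spread `(max - min) / mean` to declare
#'   convergence (default 1e-5).
#' @return The map with `weights` filled and a `balance` status list
#'   (`converged`, `iterations`, `spread`).
#' @export
ic_balance <- function(m, max_iter = 200, tol = 1e-5) {
  valid <- m$mask
  O <- m$counts[valid, valid, drop = FALSE]
  marg0 <- rowSums(O)
  if (any(marg0 == 0)) {
    stop("zero-marginal bins present; apply mask_low_coverage() first",
         call. = FALSE)
  }
  w <- rep(1, nrow(O))
  spread <- Inf
  iter <- 0L
  while (iter < max_iter) {
    r <- w * as.vector(O %*% w)
    spread <- (max(r) - min(r)) / mean(r)
    if (spread < tol) break
    w <- w / sqrt(r / mean(r))
    iter <- iter + 1L
  }
  r <- w * as.vector(O %*% w)
  spread <- (max(r) - min(r)) / mean(r)
  w <- w / sqrt(mean(r))
  converged <- spread < tol
  if (!converged) {
    warning(sprintf("ic_balance did not converge: spread %.3g > tol %.3g after %d iterations",
                    spread, tol, max_iter), call. = FALSE)
  }
  weights <- rep(NA_real_, nrow(m$bins))
  weights[valid] <- w
  m$weights <- weights
  m$balance <- list(converged = converged, iterations = iter, spread = spread)
  m
}
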