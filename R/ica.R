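#' Remove artifact components by ICA
#'
#' Decomposes the recording into independent components (extended Infomax
#' ICA with natural-gradient block updates and learning-rate annealing,
#' after PCA whitening), automatically flags artifactual components,
#' zeroes them, and reconstructs the signal.
#' A component is flagged when
#' * the absolute correlation of its time course with a frontal blink proxy
#'   (mean of Fp1/Fp2 if present, otherwise the most anterior channels)
#'   exceeds `cor_threshold`, or
#' * its time-course kurtosis (fourth moment over squared variance) exceeds
#'   `kurt_threshold` - blink and cardiac transients are strongly
#'   super-Gaussian.
#'
#' ICA directions are sign/permutation indeterminate; the reconstruction is
#' not. Uses R's RNG for the block permutations, so results are
#' reproducible under [set.seed()].
#'
#' @param rec An `eeg_recording`; should have many more samples than
#'   channels (20x or more recommended).
#' @param n_components Number of components (default: number of channels).
#' @param cor_threshold Blink-proxy correlation threshold.
#' @param kurt_threshold Kurtosis threshold.
#' @param max_iter Maximum number of training passes.
#' @param tol Convergence tolerance on the unmixing-matrix change per pass.
#' @return The cleaned `eeg_recording`, with the rejection report (a list
#'   with `flagged`, `reason`, `correlation`, `kurtosis`, `n_components`,
#'   `iterations`) attached as attribute `"ica_report"`.
#' @export
remove_artifact_components <- function(rec, n_components = NULL,
                                       cor_threshold = 0.7,
                                       kurt_threshold = 8,
                                       max_iter = 512, tol = 1e-6) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$signal
  n_ch <- nrow(x)
  n <- ncol(x)
  if (n < 5 * n_ch)
    stop("too few samples for a stable ICA decomposition (need >> channels)")
  k <- min(n_components %||% n_ch, n_ch)

  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  k <- min(k, sum(pos))
  keep <- seq_len(k)
  wh <- diag(1 / sqrt(eg$values[keep]), k) %*% t(eg$vectors[, keep, drop = FALSE])
  dewh <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]), k)
  z <- wh %*% xc  # whitened, k x n

  dec <- infomax_ica(z, max_iter = max_iter, tol = tol)
  if (!dec$converged)
    stop("ICA did not converge in ", max_iter,
         " passes; provide more data or fewer components")

  unmix <- dec$W %*% wh          # k x channels
  s <- unmix %*% xc              # component time courses
  mix <- dewh %*% solve(dec$W)   # channels x k

  proxy <- blink_proxy(rec)
  cors <- as.numeric(abs(stats::cor(t(s), proxy)))
  kurt <- apply(s, 1, function(v) mean((v - mean(v))^4) / stats::var(v)^2)
  flagged <- which(cors > cor_threshold | kurt > kurt_threshold)
  reason <- ifelse(cors[flagged] > cor_threshold, "blink_proxy", "kurtosis")

  keep_c <- setdiff(seq_len(k), flagged)
  y <- mix[, keep_c, drop = FALSE] %*% s[keep_c, , drop = FALSE] + mu
  out <- eeg_recording(y, rec$fs, rec$labels, rec$events, rec$subject_id,
                       rec$hand, rec$cohort)
  attr(out, "ica_report") <- list(
    flagged = flagged, reason = reason,
    correlation = cors, kurtosis = kurt,
    n_components = k, iterations = dec$iterations
  )
  out
}

# Extended Infomax on whitened data z (k x n): natural-gradient updates
# W <- W + lr (I - K tanh(u) u' - u u') W over random sample blocks, with
# the per-component sign matrix K (+1 super-Gaussian, -1 sub-Gaussian)
# re-estimated each pass and the learning rate annealed whenever successive
# update directions turn by more than 60 degrees. Terminates when the
# per-pass weight change drops below `tol`.
infomax_ica <- function(z, max_iter = 512, tol = 1e-6) {
  k <- nrow(z)
  n <- ncol(z)
  W <- diag(k)
  block <- max(8L, min(256L, floor(sqrt(n / 3))))
  lr <- 0.00065 / log(max(k, 3))
  old_dW <- NULL
  converged <- FALSE
  it <- 0
  signs <- rep(1, k)
  for (it in seq_len(max_iter)) {
    perm <- sample(n)
    W_old <- W
    u_all <- W %*% z
    # extended-Infomax source-sign estimate
    signs <- sign(colMeans(t(1 - tanh(u_all)^2)) * rowMeans(u_all^2) -
                    rowMeans(u_all * tanh(u_all)))
    signs[signs == 0] <- 1
    K <- diag(signs, k)
    for (s0 in seq(1, n - block + 1, by = block)) {
      idx <- perm[s0:(s0 + block - 1)]
      u <- W %*% z[, idx, drop = FALSE]
      y <- tanh(u)
      grad <- (diag(k) * block - K %*% (y %*% t(u)) - u %*% t(u)) %*% W
      W <- W + (lr / block) * grad
      if (!all(is.finite(W))) stop("ICA diverged (non-finite weights)")
    }
    dW <- W - W_old
    wchange <- sqrt(sum(dW^2))
    if (!is.null(old_dW)) {
      denom <- sqrt(sum(dW^2)) * sqrt(sum(old_dW^2))
      if (denom > 0) {
        angle <- acos(max(-1, min(1, sum(dW * old_dW) / denom)))
        if (angle > pi / 3) lr <- lr * 0.9
      }
    }
    lr <- lr * 0.98  # unconditional anneal guarantees termination
    old_dW <- dW
    if (wchange < tol) { converged <- TRUE; break }
  }
  list(W = W, iterations = it, converged = converged, signs = signs)
}

blink_proxy <- function(rec) {
  lab <- rec$labels
  fp <- intersect(c("Fp1", "Fp2"), lab)
  if (length(fp) == 0) fp <- lab[grepl("^(Fp|AF)", lab)]
  if (length(fp) == 0) {
    # fall back to the most anterior channels of the matching montage
    mn <- tryCatch(load_montage(default_montage_name(rec$cohort)),
                   error = function(e) NULL)
    if (!is.null(mn) && all(lab %in% mn$labels)) {
      y <- mn$positions[lab, "y"]
      fp <- lab[order(-y)][1:2]
    } else fp <- lab[1:2]
  }
  colMeans(rec$signal[fp, , drop = FALSE])
}
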