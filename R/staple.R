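# STAPLE: simultaneous truth and performance level estimation.
#
# Binary EM model: each rater j labels voxel i foreground with probability
# p_j (sensitivity) when the latent truth T_i = 1 and background with
# probability q_j (specificity) when T_i = 0; raters are conditionally
# independent given T.  The E-step computes the posterior weight
# W_i = P(T_i = 1 | D, p, q); the M-step re-estimates (p_j, q_j) from the
# weighted agreement with W.  All products are carried in log space and the
# parameters clamped away from {0, 1} for numerical stability.

#' STAPLE consensus estimation
#'
#' Expectation-maximization estimate of a latent consensus segmentation and
#' the per-rater performance levels (sensitivity `p_j`, specificity `q_j`)
#' from J candidate binary masks of one image.
#'
#' E-step: `W_i = a_i / (a_i + b_i)` with
#' `a_i = prior * prod_j p_j^D_ij (1-p_j)^(1-D_ij)` and
#' `b_i = (1-prior) * prod_j q_j^(1-D_ij) (1-q_j)^D_ij`.
#' M-step: `p_j = sum_i W_i D_ij / sum_i W_i`,
#' `q_j = sum_i (1-W_i)(1-D_ij) / sum_i (1-W_i)`.
#' Convergence is declared when the change in `sum_i W_i` between
#' iterations, normalised by the voxel count, falls below `tol`.
#'
#' @param masks list of J [binary_mask()] objects on a common grid (J >= 2
#'   recommended; J = 1 is allowed and converges to that rater's mask).
#' @param prior scalar foreground prior `P(T_i = 1)` in (0, 1); default is
#'   the mean foreground fraction over the input masks (spatially uniform).
#' @param init_p,init_q initial sensitivity/specificity, in (0, 1).
#' @param tol convergence tolerance on the normalised change of `sum W`.
#' @param max_iter iteration cap; hitting it is reported, not an error.
#' @return object of class `staple_fit`: a list with
#'   \describe{
#'     \item{W}{[probability_map()] of consensus weights,}
#'     \item{performance}{`data.frame(model_id, sensitivity, specificity,
#'       iterations_used)`,}
#'     \item{log_likelihood}{observed-data log-likelihood trace, one value
#'       per iteration (non-decreasing, an EM guarantee),}
#'     \item{prior, iterations, converged}{fit metadata.}
#'   }
#' @references Warfield, Zou & Wells, IEEE TMI 23(7):903-921 (2004).
#' @seealso [staple_mask()] to binarise the weight field.
#' @export
staple <- function(masks, prior = NULL, init_p = 0.9, init_q = 0.9,
                   tol = 1e-6, max_iter = 100L) {
  check_mask_list(masks, min_n = 1L)
  if (init_p <= 0 || init_p >= 1 || init_q <= 0 || init_q >= 1) {
    stop("init_p and init_q must lie strictly inside (0, 1)", call. = FALSE)
  }
  J <- length(masks)
  dims <- dim(masks[[1]]$voxels)
  N <- prod(dims)
  D <- vapply(masks, function(m) as.double(m$voxels), numeric(N))  # N x J
  if (is.null(prior)) prior <- mean(D)
  if (!is.numeric(prior) || length(prior) != 1 || prior <= 0 || prior >= 1) {
    stop("prior must be a single value strictly inside (0, 1)", call. = FALSE)
  }

  eps <- 1e-7
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  p <- rep(clamp(init_p), J)
  q <- rep(clamp(init_q), J)
  rsD <- rowSums(D)  # number of raters voting foreground per voxel

  W <- NULL
  last_sumW <- NA_real_
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step (log space): log a_i, log b_i are affine in the vote counts
    la <- log(prior) + D %*% log(p / (1 - p)) + sum(log(1 - p))
    lb <- log1p(-prior) + D %*% log((1 - q) / q) + sum(log(q))
    m <- pmax(la, lb)
    lse <- m + log(exp(la - m) + exp(lb - m))
    loglik <- c(loglik, sum(lse))
    W <- as.vector(exp(la - lse))

    sumW <- sum(W)
    if (!is.na(last_sumW) && abs(sumW - last_sumW) / N < tol) {
      converged <- TRUE
      break
    }
    last_sumW <- sumW

    # M-step
    sumWD <- crossprod(D, W)           # J x 1: sum_i W_i D_ij
    colD <- colSums(D)
    p <- clamp(as.vector(sumWD) / sumW)
    q <- clamp((N - sumW - colD + as.vector(sumWD)) / (N - sumW))
  }

  ids <- vapply(seq_len(J), function(j) {
    lb <- masks[[j]]$label
    if (!is.null(lb) && nzchar(lb)) lb else paste0("model_", j)
  }, "")
  structure(list(
    W = probability_map(array(W, dims), spacing = masks[[1]]$spacing,
                        provenance = ids),
    performance = data.frame(model_id = ids, sensitivity = p, specificity = q,
                             iterations_used = iter, stringsAsFactors = FALSE),
    log_likelihood = loglik,
    prior = prior,
    iterations = iter,
    converged = converged
  ), class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("STAPLE fit: %d raters, %d iterations (%s), prior %.4f\n",
              nrow(x$performance), x$iterations,
              if (x$converged) "converged" else "max_iter reached", x$prior))
  print(x$performance, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.staple_fit <- function(object, ...) {
  m <- as.matrix(object$performance[, c("sensitivity", "specificity")])
  rownames(m) <- object$performance$model_id
  m
}

#' Binarise a STAPLE weight field
#'
#' Thresholds the consensus probability field at `p_thr` (default 0.5; for
#' a sharply converged fit any threshold well inside (0, 1) gives nearly
#' the same mask).
#'
#' @param W a `staple_fit` or the [probability_map()] of weights.
#' @param p_thr threshold in (0, 1]; ties count as foreground.
#' @return a [binary_mask()] labelled "staple".
#' @export
staple_mask <- function(W, p_thr = 0.5) {
  if (inherits(W, "staple_fit")) W <- W$W
  threshold_mask(W, p_thr = p_thr, label = "staple")
}
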