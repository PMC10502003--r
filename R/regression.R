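# Regression-based model selection: predict each candidate's Dice with the
# (unknown) ground truth from its pairwise Dices with the other candidates,
# then pick the candidate with the highest predicted score.

#' Fit the pairwise-Dice regression combiner
#'
#' For each model m, ordinary least squares of its ground-truth Dice on its
#' J-1 pairwise Dices across training images:
#' `DSC(S^m, S^GT) = alpha_m + sum_{n != m} beta_mn DSC(S^m, S^n)`.
#'
#' @param model_masks list over training images; each element a list of that
#'   image's J candidate [binary_mask()] objects, in a fixed model order.
#' @param references list of reference masks, one per training image.
#' @param model_ids optional character vector of J model ids; defaults to
#'   the first image's mask names or `model_1..J`.
#' @param ridge optional non-negative ridge penalty added to the normal
#'   equations for near-collinear ensembles; default 0 (plain least
#'   squares).
#' @return object of class `regression_combiner`: per-model intercepts
#'   `alpha`, coefficient matrix `beta` (J x (J-1), row m over n != m in
#'   model order), `model_ids`, `n_train` and per-model residual RMS.
#' @export
fit_regression_combiner <- function(model_masks, references, model_ids = NULL,
                                    ridge = 0) {
  n_train <- length(model_masks)
  if (n_train < 1 || length(references) != n_train) {
    stop("need the same positive number of training images and references", call. = FALSE)
  }
  J <- length(model_masks[[1]])
  if (J < 2) stop("the regression combiner needs at least 2 models", call. = FALSE)
  if (n_train < J) {
    stop("underdetermined fit: ", n_train, " training images for ", J,
         " models (need n_train >= J)", call. = FALSE)
  }
  if (is.null(model_ids)) {
    model_ids <- names(model_masks[[1]]) %||% paste0("model_", seq_len(J))
  }
  if (ridge < 0) stop("ridge penalty must be non-negative", call. = FALSE)

  # pairwise Dice among candidates and against the reference, per image
  pair <- array(NA_real_, c(n_train, J, J))
  y <- matrix(NA_real_, n_train, J)
  for (i in seq_len(n_train)) {
    cand <- model_masks[[i]]
    if (length(cand) != J) stop("image ", i, " has ", length(cand), " masks, expected ", J, call. = FALSE)
    for (m in seq_len(J)) {
      y[i, m] <- dice(cand[[m]], references[[i]])
      if (m < J) for (n in (m + 1):J) {
        d <- dice(cand[[m]], cand[[n]])
        pair[i, m, n] <- d
        pair[i, n, m] <- d
      }
    }
  }

  alpha <- numeric(J)
  beta <- matrix(NA_real_, J, J - 1)
  rms <- numeric(J)
  for (m in seq_len(J)) {
    X <- cbind(1, matrix(pair[, m, -m], nrow = n_train))
    if (ridge == 0) {
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        stop("rank-deficient design for model '", model_ids[m],
             "' (candidates too similar across training images); ",
             "consider a positive ridge penalty", call. = FALSE)
      }
      cf <- qr.coef(qrX, y[, m])
    } else {
      XtX <- crossprod(X) + diag(c(0, rep(ridge, J - 1)))
      cf <- solve(XtX, crossprod(X, y[, m]))
    }
    cf <- as.vector(cf)
    alpha[m] <- cf[1]
    beta[m, ] <- cf[-1]
    rms[m] <- sqrt(mean((y[, m] - X %*% cf)^2))
  }
  structure(list(alpha = alpha, beta = beta, model_ids = model_ids,
                 n_train = n_train, residual_rms = rms, ridge = ridge),
            class = "regression_combiner")
}

#' @export
print.regression_combiner <- function(x, ...) {
  cat(sprintf("Pairwise-Dice regression combiner: %d models, %d training images\n",
              length(x$model_ids), x$n_train))
  cat("per-model residual RMS:",
      paste(sprintf("%s=%.4f", x$model_ids, x$residual_rms), collapse = ", "), "\n")
  invisible(x)
}

#' Predicted ground-truth Dice scores for a new image's candidates
#'
#' @param object a fitted `regression_combiner`.
#' @param candidates list of J candidate masks in the fitted model order.
#' @param ... unused.
#' @return named numeric vector of predicted DSC(S^m, S^GT).
#' @export
predict.regression_combiner <- function(object, candidates, ...) {
  J <- length(object$model_ids)
  if (length(candidates) != J) {
    stop("expected ", J, " candidate masks (fitted model order), got ",
         length(candidates), call. = FALSE)
  }
  check_mask_list(candidates)
  pair <- matrix(NA_real_, J, J)
  for (m in seq_len(J - 1)) for (n in (m + 1):J) {
    d <- dice(candidates[[m]], candidates[[n]])
    pair[m, n] <- d
    pair[n, m] <- d
  }
  scores <- vapply(seq_len(J), function(m) {
    object$alpha[m] + sum(object$beta[m, ] * pair[m, -m])
  }, numeric(1))
  stats::setNames(scores, object$model_ids)
}

#' Select the best candidate by predicted ground-truth Dice
#'
#' Applies a fitted combiner to one image's candidates and returns the
#' candidate with the highest predicted score (ties broken by the lowest
#' model index, deterministically).
#'
#' @param model a fitted `regression_combiner`.
#' @param candidates list of J candidate masks in the fitted model order.
#' @return list with `selected_id`, `selected_index`, `mask` (the winning
#'   candidate) and `scores` (all predictions).
#' @export
apply_regression_combiner <- function(model, candidates) {
  scores <- predict(model, candidates)
  idx <- unname(which.max(scores))  # first maximum = lowest index on ties
  list(selected_id = model$model_ids[idx], selected_index = idx,
       mask = candidates[[idx]], scores = scores)
}
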