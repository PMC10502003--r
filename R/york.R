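# Straight-line fit with known errors in both coordinates (York's
# iteratively reweighted least squares, zero x-y error correlation).

#' York errors-in-both-variables line fit
#'
#' Fits `y = a + b x` when both coordinates carry known standard
#' deviations, by minimising `sum_i W_i(b) (y_i - a - b x_i)^2` with
#' `W_i(b) = 1 / (sy_i^2 + b^2 sx_i^2)`.  The slope is iterated from the
#' ordinary-least-squares estimate until `|delta b| < tol`; parameter
#' standard deviations come from the standard York variance expressions
#' (adjusted-point form).  With `sx = 0` and constant `sy` the estimate
#' reduces exactly to ordinary least squares.
#'
#' @param x,y coordinates (length n >= 3).
#' @param sx,sy standard deviations of `x` and `y` (scalars are recycled;
#'   zeros are allowed in either coordinate, not both of a point).
#' @param tol convergence tolerance on the slope.
#' @param max_iter iteration cap.
#' @return object of class `york_fit` with `slope`, `intercept`,
#'   `slope_sd`, `intercept_sd`, `iterations`, `converged`.
#' @references York, Evensen, Lopez Martinez & De Basabe Delgado,
#'   Am. J. Phys. 72, 367 (2004).
#' @export
york_fit <- function(x, y, sx = 0, sy = 1, tol = 1e-10, max_iter = 200L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (n < 3) stop("york_fit needs at least 3 points", call. = FALSE)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  sx <- rep_len(as.numeric(sx), n)
  sy <- rep_len(as.numeric(sy), n)
  if (any(sx < 0) || any(sy < 0)) stop("sx and sy must be non-negative", call. = FALSE)
  if (any(sx == 0 & sy == 0)) {
    # a point with no error in either coordinate would get infinite weight
    stop("every point needs sx > 0 or sy > 0", call. = FALSE)
  }

  # OLS initialisation
  b <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(b)) stop("degenerate x values (zero variance)", call. = FALSE)

  converged <- FALSE
  iter <- 0L
  W <- U <- V <- beta <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- 1 / (sy^2 + b^2 * sx^2)
    xbar <- sum(W * x) / sum(W)
    ybar <- sum(W * y) / sum(W)
    U <- x - xbar
    V <- y - ybar
    # beta_i = W_i (U_i sy_i^2 + b V_i sx_i^2)   (r = 0)
    beta <- W * (U * sy^2 + b * V * sx^2)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (!is.finite(b_new)) stop("York iteration diverged (degenerate weights)", call. = FALSE)
    delta <- abs(b_new - b)
    b <- b_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  W <- 1 / (sy^2 + b^2 * sx^2)
  xbar <- sum(W * x) / sum(W)
  ybar <- sum(W * y) / sum(W)
  a <- ybar - b * xbar
  beta <- W * ((x - xbar) * sy^2 + b * (y - ybar) * sx^2)
  x_adj <- xbar + beta
  u <- x_adj - sum(W * x_adj) / sum(W)
  sb2 <- 1 / sum(W * u^2)
  sa2 <- 1 / sum(W) + (sum(W * x_adj) / sum(W))^2 * sb2
  structure(list(slope = b, intercept = a,
                 slope_sd = sqrt(sb2), intercept_sd = sqrt(sa2),
                 iterations = iter, converged = converged,
                 n = n),
            class = "york_fit")
}

#' @export
print.york_fit <- function(x, ...) {
  cat(sprintf("York line fit (n = %d): y = %.6g + %.6g x\n", x$n, x$intercept, x$slope))
  cat(sprintf("  slope sd %.3g, intercept sd %.3g, %d iteration(s)%s\n",
              x$slope_sd, x$intercept_sd, x$iterations,
              if (x$converged) "" else " [max_iter reached]"))
  invisible(x)
}

#' @export
coef.york_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
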