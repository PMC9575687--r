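#' @include AllClasses.R
NULL

#' Fit a conic section to a 2D point cloud
#'
#' Two modes. `"parabola"` performs ordinary least squares of
#' `y = a x^2 + b x + c` (x is the first column) with the standard
#' coefficient of determination; this is the workhorse for clean and noisy
#' parabolic point clouds. `"general"` fits the implicit conic
#' `a x^2 + b xy + c y^2 + d x + e y + f = 0` by algebraic least squares
#' with a unit-norm coefficient constraint (smallest right singular vector
#' of the design matrix), which accommodates parabolic-like trajectories
#' with elliptic or hyperbolic features such as the inward curling induced
#' by the CTF; its R^2 is one minus the mean squared algebraic distance
#' normalized by that of the best straight-line fit.
#'
#' Near-collinear input in general mode is flagged degenerate and the
#' linear fit's functional R^2 is reported instead.
#'
#' @param points N x 2 matrix.
#' @param constraint "parabola" (N >= 3) or "general" (N >= 6).
#' @return a [ConicFit-class]. In parabola mode the fitted functional
#'   coefficients are also attached as `attr(fit, "parabola")` = c(a, b, c).
#' @examples
#' x <- seq(-1, 1, length.out = 20)
#' fitConic(cbind(x, x^2))@r2
#' @export
fitConic <- function(points, constraint = c("parabola", "general")) {
  constraint <- match.arg(constraint)
  points <- as.matrix(points)
  x <- points[, 1]; y <- points[, 2]
  n <- length(x)
  if (constraint == "parabola") {
    if (n < 3) stop("parabola fit needs at least 3 points")
    X <- cbind(x^2, x, 1)
    beta <- tryCatch(qr.solve(X, y), error = function(e) c(0, 0, mean(y)))
    res <- y - X %*% beta
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst < 1e-300) {
      if (sum(res^2) < 1e-20) 1 else -Inf
    } else 1 - sum(res^2) / sst
    co <- c(a = beta[1], b = 0, c = 0, d = beta[2], e = -1, f = beta[3])
    co <- co / sqrt(sum(co^2))
    fit <- new("ConicFit", coefficients = co, r2 = r2,
               subspace = c(1L, 2L), mode = "parabola", degenerate = FALSE)
    attr(fit, "parabola") <- as.numeric(beta)
    return(fit)
  }
  if (n < 6) stop("general conic fit needs at least 6 points")
  ## center/scale for conditioning, fit, report R^2 in scaled frame
  mx <- mean(x); my <- mean(y)
  s <- stats::sd(c(x - mx, y - my)); if (s < 1e-300) s <- 1
  xs <- (x - mx) / s; ys <- (y - my) / s
  Dm <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  sv <- svd(Dm)
  co <- sv$v[, 6]
  co <- co / sqrt(sum(co^2))
  msConic <- mean((Dm %*% co)^2)
  Lm <- cbind(xs, ys, 1)
  svl <- svd(Lm)
  lco <- svl$v[, 3]
  lco <- lco / sqrt(sum(lco^2))
  msLine <- mean((Lm %*% lco)^2)
  degenerate <- msLine < 1e-12
  r2 <- if (degenerate) {
    lf <- stats::lm.fit(cbind(1, xs), ys)
    sst <- sum((ys - mean(ys))^2)
    if (sst < 1e-300) 1 else 1 - sum(lf$residuals^2) / sst
  } else 1 - msConic / msLine
  names(co) <- c("a", "b", "c", "d", "e", "f")
  new("ConicFit", coefficients = co, r2 = r2, subspace = c(1L, 2L),
      mode = "general", degenerate = degenerate)
}
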