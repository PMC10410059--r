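#' Spline knots from empirical quantiles
#'
#' Places knots for the restricted cubic spline basis at empirical quantiles
#' of the observed EYO distribution (default: the 0.10, 0.50 and 0.90
#' quantiles, the placement used for all nonlinear trajectory models in this
#' package).
#'
#' @param x numeric vector of observed values (typically EYO, in years).
#' @param probs strictly increasing probabilities in (0, 1).
#' @return numeric vector of strictly increasing knot locations.
#' @examples
#' knots_from_quantiles(seq(-25, 10, by = 0.5))
#' @export
knots_from_quantiles <- function(x, probs = c(0.10, 0.50, 0.90)) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 10L)
    stop("need at least 10 distinct finite values to place knots", call. = FALSE)
  if (length(probs) < 3L || any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1))
    stop("'probs' must be strictly increasing probabilities in (0, 1)", call. = FALSE)
  k <- unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
  if (any(diff(k) <= 0))
    stop("tied data collapse the knots; use the linear EYO form instead",
         call. = FALSE)
  k
}

#' Restricted cubic spline basis
#'
#' Truncated-power construction of the restricted (natural) cubic spline
#' basis: with k knots the basis has k-1 columns, the first being `x` itself
#' and the remainder nonlinear terms that vanish for `x` at or below the
#' first knot. The fitted function is constrained to be linear beyond the
#' boundary knots.
#'
#' For interior index j = 1, ..., k-2 and knots t_1 < ... < t_k the
#' nonlinear column is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'        + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2}
#' with the conventional division by the squared knot span so that all
#' columns share the scale of `x` (disable with `normalize = FALSE`).
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector, length >= 3.
#' @param normalize divide nonlinear columns by (t_k - t_1)^2.
#' @return numeric matrix with `length(knots) - 1` columns named
#'   `"c1"`, `"c2"`, ...
#' @examples
#' b <- rcs_basis(seq(-25, 10, 1), knots = c(-20.9, -6.2, 3.2))
#' stopifnot(all(b[b[, 1] <= -20.9, 2] == 0))
#' @export
rcs_basis <- function(x, knots, normalize = TRUE) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L)
    stop("restricted cubic spline needs at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("'knots' must be strictly increasing", call. = FALSE)
  k <- length(knots)
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(NA_real_, length(x), k - 1L,
                dimnames = list(NULL, paste0("c", seq_len(k - 1L))))
  out[, 1L] <- x
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  scl <- if (normalize) (tk - knots[1L])^2 else 1
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cub(x - tj) -
                        cub(x - tk1) * (tk - tj) / (tk - tk1) +
                        cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scl
  }
  out
}
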