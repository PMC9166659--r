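#' Anscombe residuals for binary outcomes
#'
#' The Anscombe transform for a binomial proportion is
#' `A(u) = integral from 0 to u of t^(-1/3) (1-t)^(-1/3) dt`, the
#' variance-stabilising transform of the binomial family; it equals
#' `B(2/3, 2/3) * pbeta(u, 2/3, 2/3)` (a scaled incomplete beta function),
#' which is how it is evaluated here (no quadrature at run time). The
#' residual for a binary observation `y` with fitted probability `mu` is
#' `(A(y) - A(mu)) / (mu (1 - mu))^(1/6)`.
#'
#' These residuals are the recommended first-stage residual for two-stage
#' residual inclusion with rare binary outcomes; see [fit_2sri()].
#'
#' @param y Binary outcome vector (0/1).
#' @param mu Fitted probabilities, strictly inside (0, 1). Values at or
#'   outside the boundary are a hard error; upstream code clips fitted
#'   probabilities (with a logged count) before calling this, see
#'   [fit_2sri()].
#' @return Numeric vector of residuals, same length as `y` (inputs are
#'   recycled as usual).
#' @export
#' @examples
#' anscombe_residual(c(0, 1), c(0.1, 0.1))
anscombe_residual <- function(y, mu) {
  if (any(!y %in% c(0, 1))) abort("y must be binary (0/1)")
  if (any(mu <= 0 | mu >= 1)) {
    abort("fitted probabilities must lie strictly inside (0, 1); clip first")
  }
  (anscombe_transform(y) - anscombe_transform(mu)) / (mu * (1 - mu))^(1 / 6)
}

#' @rdname anscombe_residual
#' @param u Value(s) in \[0, 1\] at which to evaluate the transform.
#' @export
anscombe_transform <- function(u) {
  beta(2 / 3, 2 / 3) * pbeta(u, 2 / 3, 2 / 3)
}

# First-stage residual of the requested kind for a binary regressor.
stage1_residual <- function(kind, x, mu) {
  switch(kind,
    anscombe = anscombe_residual(x, mu),
    deviance = sign(x - mu) *
      sqrt(-2 * (x * log(mu) + (1 - x) * log(1 - mu))),
    raw = x - mu,
    abort(glue::glue("unknown residual kind `{kind}`"))
  )
}
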