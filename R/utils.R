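#' @importFrom stats pnorm qnorm pchisq pt dnorm rnorm optimize var ks.test p.adjust quantile sd
#' @importFrom utils head
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log values
#' @return log(sum(exp(x)))
#' @keywords internal
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# two-sided normal p from a Z score
z_to_p <- function(z) 2 * pnorm(-abs(z))

stop_input <- function(...) stop(..., call. = FALSE)

# Cholesky with escalating diagonal jitter for numerically semi-definite
# correlation matrices (e.g. duplicated features).
chol_jitter <- function(C, jitters = c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
  for (j in jitters) {
    U <- tryCatch(chol(C + diag(j, nrow(C))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop_input("correlation matrix is not positive semidefinite even after ridge")
}

# solve(A, b) with a ridge fallback; used wherever a feature-correlation
# submatrix can be singular (near-duplicate features)
solve_ridge <- function(A, b, ridge = 1e-6) {
  tryCatch(solve(A, b), error = function(e) {
    message("singular system: adding ridge ", ridge, " to the diagonal")
    solve(A + diag(ridge, nrow(A)), b)
  })
}
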