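#' Fast non-negative least squares on normal equations
#'
#' Active-set NNLS in the formulation of Bro & de Jong (1997): solves
#' `min_{x >= 0} ||Z x - d||^2` given only the cross-products `ZtZ = Z'Z`
#' and `Ztd = Z'd`. Working on the normal equations makes repeated solves
#' over a regularization scan cheap, since adding `alpha I` to `ZtZ` is the
#' ridge-augmented problem.
#'
#' @param ZtZ Symmetric positive (semi-)definite cross-product matrix.
#' @param Ztd Right-hand side cross-product vector.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @param max_iter Safety cap on outer iterations.
#' @return Non-negative solution vector.
#' @export
fnnls <- function(ZtZ, Ztd, tol = NULL, max_iter = 30 * length(Ztd)) {
  n <- length(Ztd)
  stopifnot(nrow(ZtZ) == n, ncol(ZtZ) == n)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(diag(ZtZ))) * n
  x <- numeric(n)
  passive <- logical(n)
  w <- Ztd  # gradient of -0.5*||.||^2 at x = 0
  iter <- 0
  repeat {
    candidates <- which(!passive & w > tol)
    if (length(candidates) == 0) break
    passive[which.max(replace(w, passive | w <= tol, -Inf))] <- TRUE
    repeat {
      iter <- iter + 1
      if (iter > max_iter) {
        warning("fnnls: iteration cap reached; returning current feasible point")
        return(x)
      }
      s <- numeric(n)
      p <- which(passive)
      sp <- tryCatch(
        drop(solve(ZtZ[p, p, drop = FALSE], Ztd[p])),
        error = function(e) {
          # rank-deficient passive block: fall back to a minutely ridged
          # system; the outer loop still converges on the feasible set
          ridge <- 1e-10 * mean(diag(ZtZ)[p])
          drop(solve(ZtZ[p, p, drop = FALSE] + diag(ridge, length(p)), Ztd[p]))
        })
      s[p] <- sp
      if (all(sp > 0)) { x <- s; break }
      viol <- p[sp <= 0]
      step <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + step * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- Ztd - drop(ZtZ %*% x)
  }
  x
}
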