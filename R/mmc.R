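#' Kernel matrix
#'
#' Builds the n x n Gram matrix for the feature matrix \code{X}. The
#' default RBF form is \code{exp(-||x - x'|| / sigma^2)} with the
#' *unsquared* Euclidean norm — the form the clustering stage uses
#' throughout; the conventional squared-exponential
#' \code{exp(-||x - x'||^2 / sigma^2)} and a linear kernel are selectable.
#'
#' @param X numeric matrix (rows = samples).
#' @param kind \code{"rbf_printed"} (unsquared norm, default),
#'   \code{"rbf_squared"}, or \code{"linear"}.
#' @param sigma bandwidth (> 0) for the RBF kinds.
#' @return Symmetric n x n matrix with unit diagonal for RBF kinds.
#' @export
kernelMatrix <- function(X, kind = c("rbf_printed", "rbf_squared", "linear"),
                         sigma = 1) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  stopIfNot(nrow(X) >= 2, "need at least 2 samples")
  stopIfNot(all(is.finite(X)), "X must be finite")
  if (kind == "linear") {
    K <- tcrossprod(X); dimnames(K) <- NULL
    return(K)
  }
  stopIfNot(sigma > 0, "sigma must be positive for RBF kernels")
  D <- as.matrix(stats::dist(X))
  K <- if (kind == "rbf_printed") exp(-D / sigma^2) else exp(-D^2 / sigma^2)
  K <- (K + t(K)) / 2
  dimnames(K) <- NULL
  K
}

# median-heuristic bandwidth for the unsquared-norm RBF, widened so the
# median off-diagonal kernel value is exp(-1/9) ~ 0.9: a deliberately
# smooth kernel, under which the LS-SVM scores of a candidate labeling
# average over neighbours and the bias/label refinement can see cluster
# structure instead of memorizing the labels
medianSigma <- function(X) {
  d <- stats::dist(as.matrix(X))
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else 3 * sqrt(m)
}

#' Least-squares SVM inner solve for a fixed labeling
#'
#' Minimizes the square-loss margin objective
#' \deqn{J = 1/2 ||w||^2 + C/2 \sum_i \eta_i^2,\quad
#'       y_i (w\cdot\phi(x_i) + b) = 1 - \eta_i}
#' for fixed labels \code{y} by solving the KKT linear system of the
#' equality-constrained problem (the classical least-squares SVM system)
#' \deqn{[0, y'; y, \Omega + I/C] [b; \alpha] = [0; 1],\quad
#'       \Omega_{ij} = y_i y_j K_{ij}.}
#' A per-sample slack is used; a single shared slack would make the
#' system degenerate. Near-singular systems get a 1e-10 ridge with a
#' message.
#'
#' @param K kernel matrix.
#' @param y labels in \{-1, +1\}.
#' @param C regularization constant (> 0).
#' @param kernel list describing the kernel (stored in the model).
#' @return An [MMCModel-class]: dual coefficients, bias, raw scores
#'   \code{w.phi(x_i)}, slacks, objective J and affinity F = exp(-J).
#' @export
innerSolve <- function(K, y, C, kernel = list(kind = "precomputed")) {
  y <- as.numeric(y)
  n <- length(y)
  stopIfNot(all(y %in% c(-1, 1)), "y must be in {-1, +1}")
  stopIfNot(C > 0, "C must be positive")
  stopIfNot(nrow(K) == n && ncol(K) == n, "K must be n x n")
  Om <- (y %o% y) * K
  A <- rbind(c(0, y), cbind(y, Om + diag(n) / C))
  rhs <- c(0, rep(1, n))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    message("KKT system near-singular; adding 1e-10 ridge")
    solve(A + diag(1e-10, n + 1), rhs)
  })
  sol <- unname(sol)
  b <- sol[1]; alpha <- sol[-1]
  ay <- alpha * y
  scores <- as.numeric(K %*% ay)          # w . phi(x_i)
  eta <- 1 - y * (scores + b)
  wnorm2 <- sum(ay * scores)
  J <- max(0, 0.5 * wnorm2 + C / 2 * sum(eta^2))
  m <- methods::new("MMCModel")   # slot name C would partial-match new()'s Class
  m@alpha <- alpha; m@b <- b; m@y <- y; m@scores <- scores; m@eta <- eta
  m@C <- C; m@kernel <- kernel; m@J <- J; m@F <- affinityFromObjective(J)
  methods::validObject(m)
  m
}

#' Affinity of an objective value
#'
#' Maps the margin objective J of a candidate labeling to its immune
#' affinity \code{F = exp(-J)}: strictly decreasing in J, in (0, 1],
#' equal to 1 only for a zero objective.
#'
#' @param J non-negative objective value(s).
#' @return Affinity value(s) in (0, 1].
#' @export
affinityFromObjective <- function(J) {
  stopIfNot(all(is.finite(J)), "J must be finite")
  exp(-J)
}

#' Refine bias and labels for fixed w
#'
#' With the hyperplane direction fixed, improves the clustering by
#' minimizing \eqn{\sum_i (s_i + b - y_i)^2} over the bias and a balanced
#' labeling, where \code{s_i} are the raw scores. Sorting the scores, each
#' admissible split position p (p scores below the boundary) corresponds
#' to one threshold labeling; candidates violating the class balance
#' \eqn{|\sum_i y_i| \le \ell} — equivalently p outside
#' \eqn{[(n-\ell)/2, (n+\ell)/2]} — are discarded (with the bound rounded
#' outward when n and \eqn{\ell} have different parity, so the candidate
#' set is never empty). For each surviving labeling the optimal bias is
#' the closed-form minimizer \code{b = mean(y - s)}; an exchange argument
#' shows the joint optimum over all balanced labelings is attained at a
#' threshold labeling, so this search is exact.
#'
#' @param scores numeric vector of raw decision values (n >= 2).
#' @param l balance bound (>= 0).
#' @return list with \code{b}, \code{y} (in input order, zeros of
#'   \code{s + b} mapped to +1), and the attained \code{objective}.
#' @export
refineBiasLabels <- function(scores, l) {
  s <- as.numeric(scores)
  n <- length(s)
  stopIfNot(n >= 2, "need at least 2 scores")
  stopIfNot(l >= 0, "balance bound must be >= 0")
  if (max(s) - min(s) < 1e-12)
    stop("all scores identical: no split separates the clusters", call. = FALSE)
  ord <- order(s)
  leff <- max(l, (n + l) %% 2)   # round outward on parity mismatch
  ps <- seq_len(n - 1)
  ps <- ps[abs(n - 2 * ps) <= leff]
  best <- NULL
  for (p in ps) {
    y <- rep(1, n); y[ord[seq_len(p)]] <- -1
    b <- mean(y - s)
    obj <- sum((s + b - y)^2)
    if (is.null(best) || obj < best$objective - 1e-15)
      best <- list(b = b, y = y, objective = obj)
  }
  # sign convention: zeros of s + b map to +1
  best$y[s + best$b == 0] <- 1
  best
}
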