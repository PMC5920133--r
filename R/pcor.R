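#' Pearson correlations for all metabolite pairs
#'
#' Zero-order partial correlation is identical to the Pearson correlation,
#' so this matrix is both the baseline statistic and the order-0 special
#' case of [partial_pairs()]. Constant metabolite profiles have no defined
#' correlation and raise an error naming the offending variable.
#'
#' @param metabolites A metabolite [omics_matrix()] (or variables-by-samples
#'   matrix).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_pairs <- function(metabolites) {
  vals <- if (inherits(metabolites, "omics_matrix")) metabolites$values
          else as.matrix(metabolites)
  if (ncol(vals) < 3)
    stop("need at least 3 samples for correlation", call. = FALSE)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop("constant metabolite profile: ",
         paste(rownames(vals)[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(t(vals))
  diag(r) <- 1
  r
}

#' Partial correlation by the recursive formula
#'
#' Computes the order-k partial correlation of `x` and `y` given the control
#' vectors in `controls` by recursively eliminating one control at a time:
#' with `Z` the last control and `V\\Z` the remainder,
#' \deqn{r_{XY.V} = \frac{r_{XY.V \setminus Z} - r_{XZ.V \setminus Z}\,
#'   r_{YZ.V \setminus Z}}{\sqrt{(1 - r^2_{XZ.V \setminus Z})
#'   (1 - r^2_{YZ.V \setminus Z})}}}
#' until order zero, which is the Pearson correlation. The result does not
#' depend on the elimination order (asserted in the test suite).
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls List of control vectors of the same length (a set of
#'   per-sample principal component scores, typically); may be empty or
#'   a numeric matrix with controls as columns.
#' @return Partial correlation in `[-1, 1]`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, list())       # Pearson
#' partial_correlation(x, y, list(z))      # near zero
#' @export
partial_correlation <- function(x, y, controls = list()) {
  controls <- .as_control_list(controls, length(x))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ord <- length(controls)
  if (length(x) - 2L - ord < 1L)
    stop("insufficient degrees of freedom: n = ", length(x),
         ", order = ", ord, call. = FALSE)
  .pcor_rec(x, y, controls)
}

.pcor_rec <- function(x, y, controls) {
  k <- length(controls)
  if (k == 0L) return(stats::cor(x, y))
  z <- controls[[k]]
  rest <- controls[-k]
  r_xy <- .pcor_rec(x, y, rest)
  r_xz <- .pcor_rec(x, z, rest)
  r_yz <- .pcor_rec(y, z, rest)
  den_x <- 1 - r_xz^2
  den_y <- 1 - r_yz^2
  if (den_x < 1e-12 || den_y < 1e-12)
    stop("collinearity: control ", k, " is (near-)perfectly correlated with ",
         if (den_x < 1e-12) "x" else "y", call. = FALSE)
  val <- (r_xy - r_xz * r_yz) / sqrt(den_x * den_y)
  max(-1, min(1, val))
}

#' Partial correlation by residual regression (reference oracle)
#'
#' Independent formulation used for verification: regress `x` and `y` each
#' on the controls plus an intercept by least squares, and return the
#' Pearson correlation of the two residual vectors. Agrees with
#' [partial_correlation()] to numerical precision; retained for tests and
#' `--verify` style cross-checks, not used on the main computational path.
#'
#' @inheritParams partial_correlation
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation_oracle <- function(x, y, controls = list()) {
  controls <- .as_control_list(controls, length(x))
  if (length(controls) == 0L) return(stats::cor(x, y))
  Z <- do.call(cbind, controls)
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1L)
    stop("collinearity: rank-deficient control design", call. = FALSE)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (stats::sd(rx) < 1e-10 * stats::sd(x) || stats::sd(x) == 0)
    stop("collinearity: x is (near-)exactly explained by the controls",
         call. = FALSE)
  if (stats::sd(ry) < 1e-10 * stats::sd(y) || stats::sd(y) == 0)
    stop("collinearity: y is (near-)exactly explained by the controls",
         call. = FALSE)
  stats::cor(rx, ry)
}

#' Partial correlation from the inverse correlation matrix
#'
#' Third formulation: invert the correlation matrix of `(x, y, controls)`
#' and read off \eqn{-P_{12} / \sqrt{P_{11} P_{22}}}. Used in the
#' three-way equivalence checks.
#'
#' @inheritParams partial_correlation
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation_inverse <- function(x, y, controls = list()) {
  controls <- .as_control_list(controls, length(x))
  R <- stats::cor(do.call(cbind, c(list(x, y), controls)))
  P <- tryCatch(solve(R),
                error = function(e) stop("collinearity: singular correlation ",
                                         "matrix", call. = FALSE))
  val <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  max(-1, min(1, val))
}

#' Partial correlations for all metabolite pairs given a control set
#'
#' Computes the matrix of partial correlations of every unordered metabolite
#' pair given the same controls. Internally this conditions the metabolite
#' correlation matrix on the control block through its Schur complement
#' (one small matrix inversion per dataset), which is algebraically
#' identical to the recursive formula applied pair by pair — the agreement
#' is enforced in the test suite.
#'
#' @inheritParams pearson_pairs
#' @param controls List of control vectors (or matrix with controls as
#'   columns); empty controls reproduce [pearson_pairs()] exactly.
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_pairs <- function(metabolites, controls = list()) {
  vals <- if (inherits(metabolites, "omics_matrix")) metabolites$values
          else as.matrix(metabolites)
  n <- ncol(vals)
  controls <- .as_control_list(controls, n)
  k <- length(controls)
  if (k == 0L) return(pearson_pairs(vals))
  if (n - 2L - k < 1L)
    stop("insufficient degrees of freedom: n = ", n, ", order = ", k,
         call. = FALSE)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop("constant metabolite profile: ",
         paste(rownames(vals)[sds == 0], collapse = ", "), call. = FALSE)
  m <- nrow(vals)
  Z <- do.call(cbind, controls)
  R <- stats::cor(cbind(t(vals), Z))
  Rmm <- R[seq_len(m), seq_len(m), drop = FALSE]
  Rmz <- R[seq_len(m), m + seq_len(k), drop = FALSE]
  Rzz <- R[m + seq_len(k), m + seq_len(k), drop = FALSE]
  cond <- Rmm - Rmz %*% tryCatch(solve(Rzz, t(Rmz)),
    error = function(e) stop("collinearity: singular control correlation ",
                             "matrix", call. = FALSE))
  d <- diag(cond)
  if (any(d < 1e-12))
    stop("collinearity: metabolite ",
         paste(rownames(vals)[d < 1e-12], collapse = ", "),
         " is (near-)exactly explained by the controls", call. = FALSE)
  out <- cond / sqrt(outer(d, d))
  out[out > 1] <- 1
  out[out < -1] <- -1
  diag(out) <- 1
  dimnames(out) <- list(rownames(vals), rownames(vals))
  out
}

# Normalize controls to a list of numeric vectors and validate.
.as_control_list <- function(controls, n) {
  if (is.null(controls)) return(list())
  if (is.matrix(controls))
    controls <- lapply(seq_len(ncol(controls)), function(j) controls[, j])
  if (!is.list(controls))
    controls <- list(controls)
  for (i in seq_along(controls)) {
    v <- controls[[i]]
    if (!is.numeric(v) || length(v) != n)
      stop("control ", i, " must be a numeric vector of length ", n,
           call. = FALSE)
    if (stats::sd(v) == 0)
      stop("control ", i, " is constant", call. = FALSE)
  }
  controls
}
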