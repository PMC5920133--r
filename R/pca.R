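#' Principal component analysis of an omics layer
#'
#' Decomposes a variables-by-samples layer with samples as observations and
#' variables as features. By default variables are standardized (z-scored),
#' i.e. the decomposition is of the correlation matrix: transcript scales are
#' heterogeneous and the Kaiser-Guttman retention criterion is classically
#' stated for correlation PCA. Computation goes through the singular value
#' decomposition of the centered (and scaled) data with divisor n - 1, which
#' is numerically stable when variables far outnumber samples.
#'
#' Zero-variance variables cannot be standardized and are dropped with a
#' warning; they carry no information for component estimation either way.
#'
#' @param x An [omics_matrix()] (or a plain variables-by-samples numeric
#'   matrix).
#' @param standardize Scale each variable to unit variance (default `TRUE`).
#'
#' @return Object of class `pca_decomp` with elements:
#'   \describe{
#'     \item{eigenvalues}{Component variances, sorted descending; length
#'       `min(n_variables, n_samples - 1)`.}
#'     \item{scores}{Samples-by-components matrix of per-sample component
#'       values (the controlling variables for partial correlation).}
#'     \item{proportion_variance}{Eigenvalues normalized to sum 1.}
#'     \item{n_variables}{Number of variables retained in the decomposition;
#'       with `standardize = TRUE` the eigenvalues sum to this number.}
#'     \item{n_samples}{Number of observations.}
#'   }
#' @examples
#' x <- omics_matrix(matrix(rnorm(200), 20, 10), layer = "transcript")
#' p <- fit_pca(x)
#' sum(p$eigenvalues)  # equals 20 for standardized PCA
#' @export
fit_pca <- function(x, standardize = TRUE) {
  vals <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  n <- ncol(vals)
  if (n < 3)
    stop("PCA requires at least 3 samples, got ", n, call. = FALSE)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0),
            " zero-variance variable(s) before PCA", call. = FALSE)
    vals <- vals[sds > 0, , drop = FALSE]
  }
  m <- nrow(vals)
  if (m < 1) stop("no variables with nonzero variance", call. = FALSE)
  X <- t(vals)                       # samples x variables
  X <- scale(X, center = TRUE, scale = standardize)
  k <- min(m, n - 1L)
  sv <- svd(X, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  eigenvalues <- d^2 / (n - 1)
  scores <- sv$u %*% diag(d, nrow = k)
  rownames(scores) <- colnames(vals)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = eigenvalues,
                 scores = scores,
                 proportion_variance = eigenvalues / sum(eigenvalues),
                 n_variables = m,
                 n_samples = n,
                 standardized = standardize),
            class = "pca_decomp")
}

#' @export
print.pca_decomp <- function(x, ...) {
  cat(sprintf("<pca_decomp> %d components (%d variables, %d samples)\n",
              length(x$eigenvalues), x$n_variables, x$n_samples))
  k <- min(5L, length(x$eigenvalues))
  cat("  leading proportions of variance:",
      paste(sprintf("%.3f", x$proportion_variance[seq_len(k)]),
            collapse = " "), "\n")
  invisible(x)
}

#' Broken-stick expected proportions
#'
#' Expected relative segment lengths of a unit stick broken at random into
#' `p` pieces, sorted descending: `b_i = sum_{k=i}^{p} 1/k`, normalized by
#' `p`. These sum to 1 exactly.
#'
#' @param p Number of pieces.
#' @return Numeric vector of length `p` summing to 1.
#' @export
broken_stick_proportions <- function(p) {
  stopifnot(p >= 1)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' Broken-Stick component count
#'
#' Retains the leading run of components whose observed proportion of
#' variance exceeds the broken-stick expectation `b_i / p`. The comparison
#' stops at the first component falling at or below its expectation.
#'
#' @param eigenvalues Nonnegative eigenvalues sorted descending.
#' @param p Number of pieces used for the broken-stick distribution; defaults
#'   to `length(eigenvalues)`. Pass the number of variables to compare
#'   against the full-dimensional stick when the decomposition is
#'   rank-limited by the sample count.
#' @return Integer count of retained components.
#' @examples
#' broken_stick_count(c(0.70, 0.20, 0.10))  # 1
#' broken_stick_count(c(0.62, 0.30, 0.08))  # 2
#' @export
broken_stick_count <- function(eigenvalues, p = length(eigenvalues)) {
  .check_eigenvalues(eigenvalues)
  props <- eigenvalues / sum(eigenvalues)
  k <- min(length(eigenvalues), p)
  bs <- broken_stick_proportions(p)[seq_len(k)]
  above <- props[seq_len(k)] > bs
  .leading_run(above)
}

#' Kaiser-Guttman component count
#'
#' Counts eigenvalues strictly greater than the mean eigenvalue. For
#' correlation-matrix PCA the mean over all `p` variables is exactly 1, so
#' the criterion reduces to "eigenvalue above 1"; pass `p` as the number of
#' variables so that rank-truncated decompositions (more variables than
#' samples) include the implicit zero eigenvalues in the mean.
#'
#' @param eigenvalues Nonnegative eigenvalues sorted descending.
#' @param p Divisor for the mean; defaults to `length(eigenvalues)`.
#' @return Integer count.
#' @examples
#' kaiser_guttman_count(c(2.5, 1.2, 0.8, 0.5))  # mean 1.25 -> 1
#' @export
kaiser_guttman_count <- function(eigenvalues, p = length(eigenvalues)) {
  .check_eigenvalues(eigenvalues)
  sum(eigenvalues > sum(eigenvalues) / p)
}

#' Horn's parallel analysis component count
#'
#' Compares each observed eigenvalue against the distribution of the
#' same-rank eigenvalue obtained from randomized data in which every
#' variable's values are independently permuted across samples (destroying
#' all between-variable covariance while preserving marginals). A component
#' is significant when its observed eigenvalue strictly exceeds the given
#' percentile of its null distribution; the returned count is the leading
#' consecutive run of significant components.
#'
#' @param x An [omics_matrix()] or variables-by-samples matrix.
#' @param n_randomizations Number of randomized datasets (default 1000).
#' @param percentile Null percentile a component must exceed (default 99).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param standardize Passed to [fit_pca()].
#' @return Integer count of significant leading components.
#' @export
horn_parallel_count <- function(x, n_randomizations = 1000L, percentile = 99,
                                seed = 1L, standardize = TRUE) {
  if (n_randomizations < 20)
    stop("need at least 20 randomizations for a usable null, got ",
         n_randomizations, call. = FALSE)
  stopifnot(percentile > 0, percentile < 100)
  vals <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  obs <- fit_pca(vals, standardize = standardize)$eigenvalues
  k <- length(obs)
  null_ev <- matrix(0, nrow = n_randomizations, ncol = k)
  n <- ncol(vals)
  for (b in seq_len(n_randomizations)) {
    set.seed(.substream_seed(seed, b))
    perm <- vals
    for (i in seq_len(nrow(perm))) perm[i, ] <- perm[i, sample.int(n)]
    ev <- suppressWarnings(fit_pca(perm, standardize = standardize)$eigenvalues)
    null_ev[b, seq_len(min(k, length(ev)))] <- ev[seq_len(min(k, length(ev)))]
  }
  cuts <- apply(null_ev, 2, stats::quantile, probs = percentile / 100,
                names = FALSE)
  .leading_run(obs > cuts)
}

#' Select the number of transcript principal components
#'
#' Reports the component counts suggested by the Broken-Stick model, the
#' Kaiser-Guttman criterion and Horn's parallel analysis, and fixes the
#' number of components used downstream: the configured `n_pcs` when set
#' (default 3, a compromise between explained transcriptional variance and
#' run time), otherwise the maximum of the three criterion counts with a
#' floor of 1.
#'
#' @param x Transcript [omics_matrix()].
#' @param config A [tppc_control()] list; `config$n_pcs = NULL` requests the
#'   criterion-based choice.
#' @return Object of class `pc_selection` with the three counts and
#'   `chosen_p`.
#' @export
select_num_pcs <- function(x, config = tppc_control()) {
  dec <- fit_pca(x, standardize = config$standardize)
  bs <- broken_stick_count(dec$eigenvalues, p = dec$n_variables)
  kg <- kaiser_guttman_count(dec$eigenvalues, p = dec$n_variables)
  horn <- horn_parallel_count(x, n_randomizations = config$horn_randomizations,
                              percentile = config$horn_percentile,
                              seed = config$seed,
                              standardize = config$standardize)
  chosen <- if (!is.null(config$n_pcs)) as.integer(config$n_pcs)
            else max(1L, bs, kg, horn)
  structure(list(broken_stick_count = bs,
                 kaiser_guttman_count = kg,
                 horn_count = horn,
                 chosen_p = chosen),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat("PC retention criteria:\n")
  cat(sprintf("  Broken-Stick:    %d\n", x$broken_stick_count))
  cat(sprintf("  Kaiser-Guttman:  %d\n", x$kaiser_guttman_count))
  cat(sprintf("  Horn's PA:       %d\n", x$horn_count))
  cat(sprintf("  chosen p:        %d\n", x$chosen_p))
  invisible(x)
}

.check_eigenvalues <- function(ev) {
  if (length(ev) < 1 || all(ev <= 0))
    stop("degenerate input: need at least one positive eigenvalue",
         call. = FALSE)
  if (any(ev < -1e-12))
    stop("eigenvalues must be nonnegative", call. = FALSE)
  if (is.unsorted(rev(ev)))
    stop("eigenvalues must be sorted descending", call. = FALSE)
  invisible(TRUE)
}

# Length of the leading TRUE run of a logical vector.
.leading_run <- function(flags) {
  if (!length(flags) || !flags[1]) return(0L)
  r <- rle(flags)
  as.integer(r$lengths[1])
}

# Deterministic per-iteration seed derived from a master seed and a counter,
# kept inside the 32-bit integer range. Results are therefore independent of
# execution order across iterations.
.substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}
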