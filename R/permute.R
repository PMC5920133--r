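#' Analysis configuration
#'
#' Bundles the tunable parameters of the TPC/PPC pipeline with their
#' defaults: 3 transcript principal components as controlling variables,
#' 5000 component-wise permutations, and Benjamini-Hochberg control at
#' \eqn{\alpha = 0.01}.
#'
#' @param n_pcs Number of transcript PCs used as controls (default 3); set
#'   `NULL` to let [select_num_pcs()] choose from the retention criteria.
#' @param n_permutations Number of component-wise permutations for the null
#'   distributions (default 5000; at least 100).
#' @param alpha Significance level for the BH-adjusted q-values (default
#'   0.01).
#' @param horn_randomizations,horn_percentile Parameters of Horn's parallel
#'   analysis (defaults 1000 and 99).
#' @param seed Master integer seed; every random draw in the pipeline is
#'   derived from it, so identical configurations give identical results.
#' @param standardize Standardize transcripts before PCA (default `TRUE`).
#' @param ppc_require_pearson Require a significant Pearson correlation in
#'   addition to the PPC rule (default `FALSE`).
#' @param permute_layers Which layers are permuted when building the null:
#'   `"both"` (default; transcripts and metabolites, PCA refit per
#'   permutation) or `"metabolites"` (metabolites permuted against the fixed
#'   observed PCs).
#' @param min_samples Minimum sample overlap for [align_samples()].
#' @return A list of class `tppc_control`.
#' @export
tppc_control <- function(n_pcs = 3L, n_permutations = 5000L, alpha = 0.01,
                         horn_randomizations = 1000L, horn_percentile = 99,
                         seed = 1L, standardize = TRUE,
                         ppc_require_pearson = FALSE,
                         permute_layers = c("both", "metabolites"),
                         min_samples = 5L) {
  permute_layers <- match.arg(permute_layers)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_permutations < 100)
    stop("n_permutations must be at least 100", call. = FALSE)
  if (!is.null(n_pcs) && n_pcs < 1) stop("n_pcs must be >= 1", call. = FALSE)
  structure(list(n_pcs = if (is.null(n_pcs)) NULL else as.integer(n_pcs),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha,
                 horn_randomizations = as.integer(horn_randomizations),
                 horn_percentile = horn_percentile,
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 ppc_require_pearson = isTRUE(ppc_require_pearson),
                 permute_layers = permute_layers,
                 min_samples = as.integer(min_samples)),
            class = "tppc_control")
}

#' Component-wise permutation of a matched dataset
#'
#' Independently permutes each variable's values across samples, in both
#' layers, using the current state of R's random number generator. This
#' destroys all between-variable dependence (metabolite-metabolite and
#' transcript-metabolite alike) while preserving each variable's marginal
#' value multiset, yielding the joint null used for all three pipeline
#' statistics.
#'
#' @param dataset A [align_samples()] matched dataset.
#' @return A matched dataset of identical shape and identifiers with
#'   permuted values.
#' @export
permute_componentwise <- function(dataset) {
  stopifnot(inherits(dataset, "matched_dataset"))
  n <- dataset$n_samples
  shuffle <- function(vals) {
    for (i in seq_len(nrow(vals))) vals[i, ] <- vals[i, sample.int(n)]
    vals
  }
  out <- dataset
  out$transcripts$values <- shuffle(dataset$transcripts$values)
  out$metabolites$values <- shuffle(dataset$metabolites$values)
  out
}

#' Build per-pair permutation null distributions
#'
#' For each of `config$n_permutations` permutations: permute the dataset
#' component-wise, refit the transcript PCA, take the first `n_pcs` score
#' columns as controls, and recompute all-pairs Pearson correlations,
#' partial correlations and absolute differences. Collinearity failures are
#' caught and the permutation redrawn (counted; a redraw rate above 1%
#' triggers a warning). Results are deterministic given `config$seed`:
#' per-permutation seeds are derived by counter, so they do not depend on
#' execution order.
#'
#' @param dataset Matched dataset.
#' @param config A [tppc_control()].
#' @param progress Emit a [message()] every 500 permutations (default
#'   `FALSE`).
#' @return Object of class `permutation_null`: list with matrices
#'   `null_pearson`, `null_partial`, `null_diff` (permutations in rows,
#'   metabolite pairs in columns, upper-triangle order), `pair_names`,
#'   `n_permutations` and `redraws`.
#' @export
build_null <- function(dataset, config = tppc_control(), progress = FALSE) {
  stopifnot(inherits(dataset, "matched_dataset"))
  n_pcs <- config$n_pcs
  if (is.null(n_pcs)) n_pcs <- select_num_pcs(dataset$transcripts,
                                              config)$chosen_p
  n <- dataset$n_samples
  if (n - 2L - n_pcs < 1L)
    stop("insufficient samples (", n, ") for order-", n_pcs,
         " partial correlation", call. = FALSE)
  m <- nrow(dataset$metabolites$values)
  ut <- upper.tri(matrix(0, m, m))
  ids <- dataset$metabolites$variable_ids
  idx <- which(ut, arr.ind = TRUE)
  pair_names <- paste(ids[idx[, 1]], ids[idx[, 2]], sep = " | ")
  B <- config$n_permutations
  np <- matrix(NA_real_, B, sum(ut))
  nq <- matrix(NA_real_, B, sum(ut))
  redraws <- 0L
  fixed_controls <- NULL
  if (config$permute_layers == "metabolites") {
    dec <- fit_pca(dataset$transcripts, standardize = config$standardize)
    fixed_controls <- dec$scores[, seq_len(n_pcs), drop = FALSE]
  }
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      set.seed(.substream_seed(config$seed, b * 1000L + attempt))
      res <- tryCatch({
        perm <- permute_componentwise(dataset)
        controls <- if (is.null(fixed_controls)) {
          dec <- fit_pca(perm$transcripts, standardize = config$standardize)
          dec$scores[, seq_len(n_pcs), drop = FALSE]
        } else fixed_controls
        pe <- pearson_pairs(perm$metabolites)
        pa <- partial_pairs(perm$metabolites, controls)
        list(pe = pe[ut], pa = pa[ut])
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 50L)
        stop("permutation ", b, " failed repeatedly: ",
             conditionMessage(res), call. = FALSE)
    }
    np[b, ] <- res$pe
    nq[b, ] <- res$pa
    if (progress && b %% 500L == 0L)
      message(sprintf("[%s] permutation %d/%d",
                      format(Sys.time(), "%H:%M:%S"), b, B))
  }
  if (redraws > 0.01 * B)
    warning("high permutation redraw rate: ", redraws, " redraws for ", B,
            " permutations", call. = FALSE)
  structure(list(null_pearson = np, null_partial = nq,
                 null_diff = abs(np - nq),
                 pair_names = pair_names,
                 n_permutations = B, redraws = redraws),
            class = "permutation_null")
}

#' Empirical permutation p-value
#'
#' Two-sided estimator `p = (1 + #\{|null| >= |observed|\}) / (n_null + 1)`,
#' guaranteed to lie in `(0, 1]` (a permutation test can never return an
#' exact zero).
#'
#' @param observed Observed statistic (scalar).
#' @param null_samples Numeric vector of null statistics.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_samples) {
  if (length(null_samples) < 1)
    stop("empty null distribution", call. = FALSE)
  (1 + sum(abs(null_samples) >= abs(observed))) / (length(null_samples) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (capped at 1) in the original input order.
#' Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

# Vectorized two-sided empirical p-values: null matrix B x P, observed
# vector of length P.
.empirical_pvalues <- function(observed, null_matrix) {
  B <- nrow(null_matrix)
  exceed <- colSums(abs(null_matrix) >=
                      matrix(abs(observed), B, length(observed), byrow = TRUE))
  (1 + exceed) / (B + 1)
}
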