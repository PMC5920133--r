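#' Specification for a synthetic matched dataset
#'
#' Describes a transcript/metabolite dataset with known ground truth:
#' transcripts share a low-rank latent factor structure, metabolite pairs
#' are planted whose coupling is either mediated by those transcript factors
#' (transcriptional, "TPC") or by a fresh latent vector independent of them
#' (post-transcriptional, "PPC"), and all remaining metabolites are mutually
#' independent noise. The defaults mirror the structure of the kind of
#' paired experiments the method targets: a few hundred transcripts over a
#' handful of latent factors, far fewer metabolites, and a modest number of
#' samples.
#'
#' @param n_samples Number of samples (default 60).
#' @param n_transcripts Number of transcript variables (default 300).
#' @param n_metabolites Number of metabolites (default 32).
#' @param n_factors Rank of the transcript latent structure (default 3).
#' @param n_tpc_pairs,n_ppc_pairs Planted pair counts (default 8 each);
#'   planted pairs use disjoint metabolites so labels are unambiguous, hence
#'   `2 * (n_tpc_pairs + n_ppc_pairs) <= n_metabolites`.
#' @param loading_scale Standard deviation of transcript factor loadings
#'   (default 1).
#' @param coupling_strength Coefficient of the shared latent signal in each
#'   planted metabolite, in `(0, 1]` (default 0.85).
#' @param noise_sd Standard deviation of the independent noise added to
#'   transcripts and planted metabolites (default 0.4).
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_transcripts = 300L,
                           n_metabolites = 32L, n_factors = 3L,
                           n_tpc_pairs = 8L, n_ppc_pairs = 8L,
                           loading_scale = 1, coupling_strength = 0.85,
                           noise_sd = 0.4, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_transcripts = as.integer(n_transcripts),
               n_metabolites = as.integer(n_metabolites),
               n_factors = as.integer(n_factors),
               n_tpc_pairs = as.integer(n_tpc_pairs),
               n_ppc_pairs = as.integer(n_ppc_pairs),
               loading_scale = loading_scale,
               coupling_strength = coupling_strength,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  if (2L * (spec$n_tpc_pairs + spec$n_ppc_pairs) > spec$n_metabolites)
    stop("planted pairs need disjoint metabolites: 2*(n_tpc_pairs + ",
         "n_ppc_pairs) must not exceed n_metabolites", call. = FALSE)
  if (spec$n_factors >= spec$n_samples)
    stop("n_factors must be smaller than n_samples", call. = FALSE)
  if (spec$coupling_strength <= 0 || spec$coupling_strength > 1)
    stop("coupling_strength must lie in (0, 1]", call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic matched dataset with planted pair couplings
#'
#' Draws a latent factor matrix `F` (`n_factors` x `n_samples`, standard
#' normal) and builds:
#' \itemize{
#'   \item transcripts = `loadings \%*\% F + noise`, loadings i.i.d. normal
#'     with sd `loading_scale`, noise sd `noise_sd`;
#'   \item each planted TPC pair: both metabolites equal
#'     `coupling_strength * s + noise`, where `s` is a (unit-variance)
#'     random linear combination of the rows of `F` shared by the pair —
#'     the association is mediated by the transcript factors and collapses
#'     once the leading transcript PCs are partialled out;
#'   \item each planted PPC pair: the same construction with a fresh latent
#'     vector independent of `F`, so the association survives removal of
#'     the transcript components;
#'   \item remaining metabolites: independent standard normal noise.
#' }
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a matched dataset) and `truth` (data frame
#'   `metabolite_1`, `metabolite_2`, `label`; lexicographic pair order, the
#'   planted ground truth).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  k <- spec$n_factors
  Fm <- matrix(stats::rnorm(k * n), k, n)
  loadings <- matrix(stats::rnorm(spec$n_transcripts * k,
                                  sd = spec$loading_scale),
                     spec$n_transcripts, k)
  tr <- loadings %*% Fm +
    matrix(stats::rnorm(spec$n_transcripts * n, sd = spec$noise_sd),
           spec$n_transcripts, n)
  met <- matrix(stats::rnorm(spec$n_metabolites * n), spec$n_metabolites, n)
  met_ids <- sprintf("met%03d", seq_len(spec$n_metabolites))
  sample_ids <- sprintf("s%03d", seq_len(n))
  tr_ids <- sprintf("tr%04d", seq_len(spec$n_transcripts))
  truth <- data.frame(metabolite_1 = character(), metabolite_2 = character(),
                      label = character(), stringsAsFactors = FALSE)
  next_free <- 1L
  plant <- function(label, met, truth, next_free) {
    npairs <- if (label == "TPC") spec$n_tpc_pairs else spec$n_ppc_pairs
    for (p in seq_len(npairs)) {
      s <- if (label == "TPC") {
        w <- stats::rnorm(k)
        drop(w %*% Fm)
      } else {
        stats::rnorm(n)
      }
      s <- s / stats::sd(s)
      i <- next_free
      j <- next_free + 1L
      met[i, ] <- spec$coupling_strength * s +
        stats::rnorm(n, sd = spec$noise_sd)
      met[j, ] <- spec$coupling_strength * s +
        stats::rnorm(n, sd = spec$noise_sd)
      truth <- rbind(truth,
                     data.frame(metabolite_1 = met_ids[i],
                                metabolite_2 = met_ids[j],
                                label = label, stringsAsFactors = FALSE))
      next_free <- next_free + 2L
    }
    list(met = met, truth = truth, next_free = next_free)
  }
  r <- plant("TPC", met, truth, next_free)
  r <- plant("PPC", r$met, r$truth, r$next_free)
  met <- r$met
  truth <- r$truth
  dimnames(tr) <- list(tr_ids, sample_ids)
  dimnames(met) <- list(met_ids, sample_ids)
  dataset <- align_samples(omics_matrix(tr, layer = "transcript"),
                           omics_matrix(met, layer = "metabolite"),
                           min_samples = 3L)
  truth <- truth[order(truth$metabolite_1, truth$metabolite_2,
                       method = "radix"), , drop = FALSE]
  rownames(truth) <- NULL
  list(dataset = dataset, truth = truth)
}

#' Recovery metrics of a classification against planted ground truth
#'
#' Per planted label (TPC, PPC): recall (fraction of planted pairs
#' recovered with the right label), precision among predictions of that
#' label (`NaN` when there are no predictions — undefined, not zero), and
#' the cross-assignment rate (planted pairs recovered with the *other*
#' label). Also counts classifications among unplanted pairs (false
#' discoveries).
#'
#' @param predicted Classified pair table (e.g. `fit$pairs`).
#' @param truth Ground-truth data frame from [generate_dataset()].
#' @return List of class `tppc_recovery` with elements `per_label` (data
#'   frame: `label`, `n_planted`, `recall`, `precision`, `cross_rate`),
#'   `false_discoveries` (count among unplanted pairs),
#'   `n_unplanted_pairs`, and `false_discovery_fraction`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = " | ")
  pred_key <- key(predicted$metabolite_1, predicted$metabolite_2)
  truth_key <- key(truth$metabolite_1, truth$metabolite_2)
  pred_cat <- as.character(predicted$category)
  per_label <- lapply(c("TPC", "PPC"), function(lab) {
    planted <- truth_key[truth$label == lab]
    got <- pred_cat[match(planted, pred_key)]
    other <- setdiff(c("TPC", "PPC"), lab)
    n_pred <- sum(pred_cat == lab, na.rm = TRUE)
    data.frame(label = lab, n_planted = length(planted),
               recall = if (length(planted)) mean(got == lab, na.rm = TRUE)
                        else NaN,
               precision = if (n_pred)
                 sum(got == lab, na.rm = TRUE) / n_pred else NaN,
               cross_rate = if (length(planted))
                 mean(got == other, na.rm = TRUE) else NaN,
               stringsAsFactors = FALSE)
  })
  unplanted <- !(pred_key %in% truth_key)
  fd <- sum(pred_cat[unplanted] != "none")
  structure(list(per_label = do.call(rbind, per_label),
                 false_discoveries = fd,
                 n_unplanted_pairs = sum(unplanted),
                 false_discovery_fraction =
                   if (sum(unplanted)) fd / sum(unplanted) else NaN),
            class = "tppc_recovery")
}

#' @export
print.tppc_recovery <- function(x, ...) {
  print(x$per_label, digits = 3, row.names = FALSE)
  cat(sprintf("false discoveries among %d unplanted pairs: %d (%.3f)\n",
              x$n_unplanted_pairs, x$false_discoveries,
              x$false_discovery_fraction))
  invisible(x)
}

#' Write the ground-truth table of a synthetic dataset
#'
#' @param truth Data frame from [generate_dataset()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an omics layer as a delimited table
#'
#' Inverse of [read_omics_table()]: variables as rows, header row of sample
#' identifiers, first column `id`.
#'
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return The path, invisibly.
#' @export
write_omics_table <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "omics_matrix"))
  out <- data.frame(id = x$variable_ids, x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
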