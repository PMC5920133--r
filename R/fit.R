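#' Per-pair observed statistics with permutation p-values
#'
#' For every unordered metabolite pair computes the Pearson correlation
#' `r_pearson`, the partial correlation `r_partial` given the first `n_pcs`
#' principal component scores of the observed transcript layer, and the
#' difference statistic `d = |r_pearson - r_partial|`. Each statistic gets a
#' two-sided empirical p-value against its own pair's permutation null (see
#' [build_null()]) and a BH-adjusted q-value, adjusted separately within
#' each statistic family across all pairs.
#'
#' @param dataset Matched dataset from [align_samples()] or
#'   [generate_dataset()].
#' @param config A [tppc_control()].
#' @param null Optional precomputed [build_null()] result (must match
#'   `dataset` and `config`); built on the fly when `NULL`.
#' @param progress Passed to [build_null()].
#' @return Data frame with one row per pair: `metabolite_1 < metabolite_2`
#'   lexicographically, `r_pearson`, `r_partial`, `p_pearson`, `p_partial`,
#'   `p_diff`, `q_pearson`, `q_partial`, `q_diff`.
#' @export
compute_pair_statistics <- function(dataset, config = tppc_control(),
                                    null = NULL, progress = FALSE) {
  stopifnot(inherits(dataset, "matched_dataset"))
  n_pcs <- config$n_pcs
  if (is.null(n_pcs)) n_pcs <- select_num_pcs(dataset$transcripts,
                                              config)$chosen_p
  dec <- fit_pca(dataset$transcripts, standardize = config$standardize)
  if (n_pcs > ncol(dec$scores))
    stop("n_pcs = ", n_pcs, " exceeds the ", ncol(dec$scores),
         " available components", call. = FALSE)
  controls <- dec$scores[, seq_len(n_pcs), drop = FALSE]
  pe <- pearson_pairs(dataset$metabolites)
  pa <- partial_pairs(dataset$metabolites, controls)
  m <- nrow(pe)
  ut <- upper.tri(pe)
  idx <- which(ut, arr.ind = TRUE)
  ids <- dataset$metabolites$variable_ids
  r_pearson <- pe[ut]
  r_partial <- pa[ut]
  d <- abs(r_pearson - r_partial)
  if (is.null(null)) null <- build_null(dataset, config, progress = progress)
  stopifnot(ncol(null$null_pearson) == length(r_pearson))
  p_pearson <- .empirical_pvalues(r_pearson, null$null_pearson)
  p_partial <- .empirical_pvalues(r_partial, null$null_partial)
  p_diff <- .empirical_pvalues(d, null$null_diff)
  a <- ids[idx[, 1]]
  b <- ids[idx[, 2]]
  swap <- a > b
  out <- data.frame(metabolite_1 = ifelse(swap, b, a),
                    metabolite_2 = ifelse(swap, a, b),
                    r_pearson = r_pearson, r_partial = r_partial,
                    p_pearson = p_pearson, p_partial = p_partial,
                    p_diff = p_diff,
                    q_pearson = bh_adjust(p_pearson),
                    q_partial = bh_adjust(p_partial),
                    q_diff = bh_adjust(p_diff),
                    stringsAsFactors = FALSE)
  out <- out[order(out$metabolite_1, out$metabolite_2, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "redraws") <- null$redraws
  out
}

#' Classify metabolite pairs as TPC, PPC or neither
#'
#' Applies the two decision rules at level `alpha` to BH-adjusted q-values:
#' \describe{
#'   \item{TPC}{significant Pearson correlation, *non*-significant partial
#'     correlation, and significant Pearson-vs-partial difference — the
#'     association collapses once transcriptional variance is removed, so it
#'     is attributed to transcriptional regulation.}
#'   \item{PPC}{significant partial correlation and significant difference
#'     (optionally also a significant Pearson correlation when
#'     `ppc_require_pearson`) — the association survives removal of the
#'     transcript components, so it is attributed to post-transcriptional
#'     regulation.}
#' }
#' The two rules condition oppositely on the partial-correlation q-value,
#' so the TPC and PPC sets are disjoint by construction.
#'
#' @param stats Data frame from [compute_pair_statistics()].
#' @param config A [tppc_control()] supplying `alpha` and
#'   `ppc_require_pearson`.
#' @return `stats` with an added `category` factor in
#'   `c("TPC", "PPC", "none")`.
#' @export
classify_pairs <- function(stats, config = tppc_control()) {
  a <- config$alpha
  sig_pe <- stats$q_pearson <= a
  sig_pa <- stats$q_partial <= a
  sig_d <- stats$q_diff <= a
  tpc <- sig_pe & !sig_pa & sig_d
  ppc <- sig_pa & sig_d & (!config$ppc_require_pearson | sig_pe)
  category <- rep("none", nrow(stats))
  category[tpc] <- "TPC"
  category[ppc] <- "PPC"
  stats$category <- factor(category, levels = c("TPC", "PPC", "none"))
  stats
}

#' Fit the TPC/PPC classification to a matched dataset
#'
#' The main entry point: computes the transcript principal components,
#' all-pairs Pearson and partial correlations, component-wise permutation
#' nulls, BH-adjusted significance and the TPC/PPC categories, and returns
#' everything as a classed fit object.
#'
#' @param transcripts Transcript [omics_matrix()], or an already matched
#'   dataset (in which case `metabolites` is ignored).
#' @param metabolites Metabolite [omics_matrix()].
#' @param config A [tppc_control()]; individual `...` arguments override
#'   its entries (e.g. `tppc(tr, mb, n_permutations = 500, seed = 7)`).
#' @param ... Named [tppc_control()] arguments overriding `config`.
#' @param progress Passed to [build_null()].
#' @param pc_report Also compute the three component-retention criteria when
#'   `n_pcs` is fixed in the configuration (default `FALSE`: the criteria —
#'   including Horn's parallel analysis, the costly one — are evaluated only
#'   when they actually decide `n_pcs`).
#' @return Object of class `tppc` with elements `pairs` (classified pair
#'   table), `pc_selection`, `config`, `dims`, and `redraws`.
#' @examples
#' \donttest{
#' sim <- generate_dataset(synthetic_spec(n_samples = 40, n_transcripts = 60,
#'                                        n_metabolites = 10, n_tpc_pairs = 2,
#'                                        n_ppc_pairs = 2, seed = 1))
#' fit <- tppc(sim$dataset, n_permutations = 100, seed = 1,
#'             horn_randomizations = 50)
#' summary(fit)
#' }
#' @export
tppc <- function(transcripts, metabolites = NULL, config = tppc_control(),
                 ..., pc_report = FALSE, progress = FALSE) {
  dots <- list(...)
  if (length(dots)) {
    base <- unclass(config)
    base[names(dots)] <- dots
    config <- do.call(tppc_control, base[names(base) != "n_pcs"])
    config$n_pcs <- if ("n_pcs" %in% names(dots)) dots$n_pcs else base$n_pcs
    if (!is.null(config$n_pcs)) config$n_pcs <- as.integer(config$n_pcs)
  }
  dataset <- if (inherits(transcripts, "matched_dataset")) transcripts
             else align_samples(transcripts, metabolites,
                                min_samples = config$min_samples)
  sel <- if (is.null(config$n_pcs) || pc_report) {
    select_num_pcs(dataset$transcripts, config)
  } else {
    structure(list(broken_stick_count = NA_integer_,
                   kaiser_guttman_count = NA_integer_,
                   horn_count = NA_integer_, chosen_p = config$n_pcs),
              class = "pc_selection")
  }
  cfg <- config
  cfg$n_pcs <- sel$chosen_p
  stats <- compute_pair_statistics(dataset, cfg, progress = progress)
  pairs <- classify_pairs(stats, cfg)
  structure(list(pairs = pairs,
                 pc_selection = sel,
                 config = cfg,
                 dims = c(n_transcripts = nrow(dataset$transcripts$values),
                          n_metabolites = nrow(dataset$metabolites$values),
                          n_samples = dataset$n_samples),
                 redraws = attr(stats, "redraws")),
            class = "tppc")
}

#' @export
print.tppc <- function(x, ...) {
  tab <- table(x$pairs$category)
  cat(sprintf(paste0("TPC/PPC classification of %d metabolite pairs ",
                     "(%d metabolites, %d samples)\n"),
              nrow(x$pairs), x$dims[["n_metabolites"]],
              x$dims[["n_samples"]]))
  cat(sprintf("  controls: first %d transcript PCs of %d transcripts\n",
              x$config$n_pcs, x$dims[["n_transcripts"]]))
  cat(sprintf("  permutations: %d, alpha = %g (BH)\n",
              x$config$n_permutations, x$config$alpha))
  cat(sprintf("  TPC: %d   PPC: %d   none: %d\n",
              tab[["TPC"]], tab[["PPC"]], tab[["none"]]))
  invisible(x)
}

#' @export
summary.tppc <- function(object, ...) {
  out <- list(counts = table(object$pairs$category),
              direction = summarize_direction_changes(object$pairs),
              thresholds = count_thresholds(object$pairs),
              pc_selection = object$pc_selection,
              config = object$config,
              dims = object$dims,
              redraws = object$redraws)
  class(out) <- "summary.tppc"
  out
}

#' @export
print.summary.tppc <- function(x, ...) {
  cat("Category counts:\n")
  print(x$counts)
  cat("\n")
  print(x$pc_selection)
  cat("\nDirection of change from Pearson to partial (|r|):\n")
  print(x$direction, digits = 3)
  cat("\nSignificant partial correlations beyond thresholds:\n")
  print(x$thresholds)
  if (!is.null(x$redraws) && x$redraws > 0)
    cat("\npermutation redraws:", x$redraws, "\n")
  invisible(x)
}

#' Extract correlations from a fit
#'
#' @param object A [tppc()] fit.
#' @param type `"partial"` (default) or `"pearson"`.
#' @param ... Unused.
#' @return Named numeric vector over pairs (`"a | b"` names).
#' @export
coef.tppc <- function(object, type = c("partial", "pearson"), ...) {
  type <- match.arg(type)
  v <- if (type == "partial") object$pairs$r_partial else object$pairs$r_pearson
  names(v) <- paste(object$pairs$metabolite_1, object$pairs$metabolite_2,
                    sep = " | ")
  v
}

#' Plot the direction-of-change summary of a fit
#'
#' Stacked barplot, per category and Pearson-correlation sign, of the
#' fraction of significant pairs whose absolute correlation increased
#' versus decreased from Pearson to partial.
#'
#' @param x A [tppc()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.tppc <- function(x, ...) {
  d <- summarize_direction_changes(x$pairs)
  keep <- d$n > 0
  if (!any(keep)) {
    warning("no classified pairs to plot", call. = FALSE)
    return(invisible(x))
  }
  d <- d[keep, , drop = FALSE]
  h <- rbind(increased = d$increased, decreased = d$decreased)
  graphics::barplot(h, names.arg = paste(d$category, d$sign),
                    col = c("steelblue", "firebrick"),
                    ylab = "fraction of significant pairs",
                    legend.text = rownames(h), ...)
  invisible(x)
}

#' Tally increases and decreases of |r| from Pearson to partial
#'
#' For each classified category (TPC, PPC) and each sign of the Pearson
#' correlation, reports the fraction of pairs whose absolute correlation
#' increased, decreased, or was tied after partialling out the transcript
#' components. Empty cells report `NaN` fractions (undefined, not zero).
#'
#' @param stats Classified pair table ([classify_pairs()] output or the
#'   `pairs` element of a fit).
#' @return Data frame with columns `category`, `sign`, `n`, `increased`,
#'   `decreased`, `tied`.
#' @export
summarize_direction_changes <- function(stats) {
  grid <- expand.grid(category = c("TPC", "PPC"), sign = c("+", "-"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- stats$category == grid$category[i] &
      (if (grid$sign[i] == "+") stats$r_pearson >= 0 else stats$r_pearson < 0)
    n <- sum(sel)
    inc <- abs(stats$r_partial[sel]) > abs(stats$r_pearson[sel])
    dec <- abs(stats$r_partial[sel]) < abs(stats$r_pearson[sel])
    data.frame(category = grid$category[i], sign = grid$sign[i], n = n,
               increased = if (n) mean(inc) else NaN,
               decreased = if (n) mean(dec) else NaN,
               tied = if (n) mean(!inc & !dec) else NaN)
  })
  do.call(rbind, rows)
}

#' Count significant partial correlations beyond thresholds
#'
#' For each positive threshold `t`, counts classified pairs with partial
#' correlation above `t`; for each negative threshold, pairs below `t` —
#' per category.
#'
#' @param stats Classified pair table.
#' @param thresholds Numeric thresholds; defaults to
#'   `0.9 ... 0.4, -0.4 ... -0.7`.
#' @return Data frame with columns `threshold`, `TPC`, `PPC`.
#' @export
count_thresholds <- function(stats,
                             thresholds = c(seq(0.9, 0.4, by = -0.1),
                                            seq(-0.4, -0.7, by = -0.1))) {
  count_one <- function(cat, t) {
    r <- stats$r_partial[stats$category == cat]
    if (t > 0) sum(r > t) else sum(r < t)
  }
  data.frame(threshold = thresholds,
             TPC = vapply(thresholds, function(t) count_one("TPC", t), 0L),
             PPC = vapply(thresholds, function(t) count_one("PPC", t), 0L))
}
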