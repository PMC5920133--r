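#' Construct an omics data layer
#'
#' An `omics_matrix` holds one molecular layer — transcript or metabolite
#' abundances — as a numeric matrix with variables (genes, metabolites) as
#' rows and samples as columns, together with unique identifiers for both
#' dimensions. Values are assumed to be pre-normalized by the upstream
#' measurement pipeline; the package performs no normalization of raw
#' instrument data.
#'
#' @param values Numeric matrix, variables as rows, samples as columns.
#' @param variable_ids Character vector of unique variable identifiers,
#'   one per row. Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param layer Either `"transcript"` or `"metabolite"`.
#'
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   (dimnamed numeric matrix), `variable_ids`, `sample_ids` and `layer`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' omics_matrix(m, layer = "metabolite")
#' @export
omics_matrix <- function(values, variable_ids = rownames(values),
                         sample_ids = colnames(values),
                         layer = c("transcript", "metabolite")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(variable_ids))
    variable_ids <- paste0("v", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(ncol(values)))
  variable_ids <- as.character(variable_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(variable_ids))
    stop("number of rows (", nrow(values), ") does not match number of ",
         "variable identifiers (", length(variable_ids), ")", call. = FALSE)
  if (ncol(values) != length(sample_ids))
    stop("number of columns (", ncol(values), ") does not match number of ",
         "sample identifiers (", length(sample_ids), ")", call. = FALSE)
  if (anyDuplicated(variable_ids))
    stop("duplicate variable identifier: ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(values))
    stop("values must be numeric", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all values must be finite; found ", sum(!is.finite(values)),
         " non-finite entries", call. = FALSE)
  dimnames(values) <- list(variable_ids, sample_ids)
  structure(list(values = values, variable_ids = variable_ids,
                 sample_ids = sample_ids, layer = layer),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s layer: %d variables x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read a delimited omics table
#'
#' Parses a TSV/CSV table into an [omics_matrix()]. The expected layout is
#' the omics convention: first column variable identifiers, header row of
#' sample identifiers, one numeric cell per (variable, sample). Tables stored
#' with samples as rows can be transposed on read via `orientation`.
#'
#' @param path Path to a delimited UTF-8 text file.
#' @param layer `"transcript"` or `"metabolite"`.
#' @param delimiter Field separator; default tab.
#' @param orientation `"variables_rows"` (default) or `"samples_rows"`
#'   (table is transposed after reading).
#' @param na_policy How to treat missing cells: `"reject"` (default; any
#'   missing value is a parse error, since partial correlation requires
#'   complete vectors) or `"drop_variable"` (variables containing a missing
#'   entry are removed with a warning).
#'
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, layer = c("transcript", "metabolite"),
                             delimiter = "\t",
                             orientation = c("variables_rows", "samples_rows"),
                             na_policy = c("reject", "drop_variable")) {
  layer <- match.arg(layer)
  orientation <- match.arg(orientation)
  na_policy <- match.arg(na_policy)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                      row.names = NULL, colClasses = "character",
                      comment.char = "", quote = "\"", fill = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("malformed table in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(raw) < 2)
    stop("table must have a variable-id column and at least one sample column",
         call. = FALSE)
  var_ids <- raw[[1]]
  samp_ids <- colnames(raw)[-1]
  if (anyDuplicated(var_ids))
    stop("duplicate variable identifier in ", path, ": ",
         paste(unique(var_ids[duplicated(var_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samp_ids))
    stop("duplicate sample identifier in ", path, ": ",
         paste(unique(samp_ids[duplicated(samp_ids)]), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(num) & !is.na(cells) & !(trimws(cells) %in% c("NA", "NaN", ""))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell \"", cells[idx[1], idx[2]], "\" at variable \"",
         var_ids[idx[1]], "\", sample \"", samp_ids[idx[2]], "\"",
         call. = FALSE)
  }
  miss <- is.na(num)
  if (any(miss)) {
    if (na_policy == "reject") {
      idx <- which(miss, arr.ind = TRUE)[1, ]
      stop("missing value at variable \"", var_ids[idx[1]], "\", sample \"",
           samp_ids[idx[2]], "\" (na_policy = \"reject\")", call. = FALSE)
    }
    drop <- rowSums(miss) > 0
    warning("dropping ", sum(drop), " variable(s) with missing values",
            call. = FALSE)
    num <- num[!drop, , drop = FALSE]
    var_ids <- var_ids[!drop]
  }
  dimnames(num) <- list(var_ids, samp_ids)
  if (orientation == "samples_rows") {
    num <- t(num)
  }
  omics_matrix(num, layer = layer)
}

#' Align transcript and metabolite layers on shared samples
#'
#' Restricts both layers to the intersection of their sample identifiers,
#' ordered by the transcript layer's sample order (so alignment is
#' deterministic), and bundles them into a `matched_dataset`. Both layers of
#' a matched dataset have identical sample order, the prerequisite for
#' computing cross-layer statistics.
#'
#' @param transcripts,metabolites [omics_matrix()] objects.
#' @param min_samples Minimum acceptable number of shared samples (default 5).
#'
#' @return An object of class `matched_dataset`: list with `transcripts`,
#'   `metabolites` (both restricted and ordered identically) and `n_samples`.
#' @examples
#' tr <- omics_matrix(matrix(rnorm(9), 3, 3,
#'                    dimnames = list(letters[1:3], c("s1", "s2", "s3"))),
#'                    layer = "transcript")
#' mb <- omics_matrix(matrix(rnorm(6), 2, 3,
#'                    dimnames = list(c("m1", "m2"), c("s2", "s3", "s4"))),
#'                    layer = "metabolite")
#' align_samples(tr, mb, min_samples = 2)
#' @export
align_samples <- function(transcripts, metabolites, min_samples = 5L) {
  stopifnot(inherits(transcripts, "omics_matrix"),
            inherits(metabolites, "omics_matrix"))
  shared <- transcripts$sample_ids[transcripts$sample_ids %in%
                                     metabolites$sample_ids]
  if (length(shared) < min_samples)
    stop("insufficient sample overlap: ", length(shared),
         " shared samples, need at least ", min_samples, call. = FALSE)
  tr <- omics_matrix(transcripts$values[, shared, drop = FALSE],
                     layer = transcripts$layer)
  mb <- omics_matrix(metabolites$values[, shared, drop = FALSE],
                     layer = metabolites$layer)
  structure(list(transcripts = tr, metabolites = mb,
                 n_samples = length(shared)),
            class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat(sprintf(paste0("<matched_dataset> %d shared samples; %d transcripts, ",
                     "%d metabolites\n"),
              x$n_samples, nrow(x$transcripts$values),
              nrow(x$metabolites$values)))
  invisible(x)
}

#' Write a metabolite pair statistics table
#'
#' Serializes the per-pair results (correlations, permutation p-values,
#' BH-adjusted q-values and TPC/PPC category) to a TSV file with a fixed
#' column schema and deterministic row order (lexicographic by pair).
#' Floating point values are printed with 6 significant digits.
#'
#' @param pairs Data frame of pair statistics as produced by
#'   [compute_pair_statistics()] / [classify_pairs()] (or the `pairs`
#'   element of a [tppc()] fit).
#' @param path Output file path.
#' @return The path, invisibly.
#' @seealso [read_pair_table()]
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("metabolite_1", "metabolite_2", "pearson_r", "partial_r",
            "p_pearson", "p_partial", "p_diff",
            "q_pearson", "q_partial", "q_diff", "category")
  out <- data.frame(metabolite_1 = character(), metabolite_2 = character(),
                    stringsAsFactors = FALSE)
  if (NROW(pairs) > 0) {
    map <- c(pearson_r = "r_pearson", partial_r = "r_partial")
    out <- data.frame(metabolite_1 = pairs$metabolite_1,
                      metabolite_2 = pairs$metabolite_2,
                      stringsAsFactors = FALSE)
    for (cl in cols[3:10]) {
      src <- if (cl %in% names(map)) map[[cl]] else cl
      val <- if (src %in% names(pairs)) pairs[[src]] else rep(NA_real_, nrow(out))
      out[[cl]] <- signif(val, 6)
    }
    out$category <- if ("category" %in% names(pairs))
      as.character(pairs$category) else rep("none", nrow(out))
    out <- out[order(out$metabolite_1, out$metabolite_2, method = "radix"), ,
               drop = FALSE]
  } else {
    for (cl in cols[3:10]) out[[cl]] <- numeric()
    out$category <- character()
  }
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pair statistics table written by [write_pair_table()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `metabolite_1`, `metabolite_2`,
#'   `r_pearson`, `r_partial`, the three p-values, three q-values and
#'   `category`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[names(tab) == "pearson_r"] <- "r_pearson"
  names(tab)[names(tab) == "partial_r"] <- "r_partial"
  tab
}
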