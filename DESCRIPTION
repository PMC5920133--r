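Package: tppc
Title: Transcriptional and Post-Transcriptional Classification of Metabolite Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pairwise metabolite associations as transcriptionally
    or post-transcriptionally controlled by combining partial correlation with
    principal component analysis of a matched transcriptomics matrix. The
    leading principal components of the transcript layer serve as controlling
    variables; pairs whose Pearson correlation is significant but collapses to
    a non-significant partial correlation are labelled transcriptionally
    dependent (TPC), while pairs whose partial correlation survives the removal
    of transcriptional variance are labelled post-transcriptionally dependent
    (PPC). Significance is assessed by component-wise permutation testing with
    Benjamini-Hochberg false discovery rate control. Includes component-count
    selection by the Broken-Stick model, the Kaiser-Guttman criterion and
    Horn's parallel analysis, a synthetic data generator with planted pair
    couplings for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
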