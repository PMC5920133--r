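test_that("synthetic_spec enforces its invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(n_metabolites = 10, n_tpc_pairs = 3,
                              n_ppc_pairs = 3), "disjoint metabolites")
  expect_error(synthetic_spec(n_factors = 60, n_samples = 60), "n_factors")
  expect_error(synthetic_spec(coupling_strength = 0), "coupling_strength")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("generate_dataset is deterministic and shapes match the spec", {
  spec <- synthetic_spec(n_samples = 30, n_transcripts = 50,
                         n_metabolites = 12, n_tpc_pairs = 3, n_ppc_pairs = 2,
                         seed = 17)
  sim <- generate_dataset(spec)
  expect_equal(sim$dataset$n_samples, 30L)
  expect_equal(dim(sim$dataset$transcripts$values), c(50L, 30L))
  expect_equal(dim(sim$dataset$metabolites$values), c(12L, 30L))
  expect_equal(nrow(sim$truth), 5L)
  expect_equal(sort(table(sim$truth$label), decreasing = TRUE),
               sort(c(TPC = 3L, PPC = 2L), decreasing = TRUE),
               ignore_attr = TRUE)
  # planted pairs use disjoint metabolites
  mets <- c(sim$truth$metabolite_1, sim$truth$metabolite_2)
  expect_equal(anyDuplicated(mets), 0L)
  sim2 <- generate_dataset(spec)
  expect_identical(sim$dataset$transcripts$values,
                   sim2$dataset$transcripts$values)
  expect_identical(sim$dataset$metabolites$values,
                   sim2$dataset$metabolites$values)
  expect_identical(sim$truth, sim2$truth)
})

test_that("zero planted pairs give an empty truth table", {
  sim <- generate_dataset(synthetic_spec(n_metabolites = 6, n_tpc_pairs = 0,
                                         n_ppc_pairs = 0, n_transcripts = 20,
                                         n_samples = 20, seed = 2))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("planted couplings have the intended correlation structure", {
  # large n so sampling error is small; controls = true factor count of PCs
  spec <- synthetic_spec(n_samples = 200, n_transcripts = 100,
                         n_metabolites = 12, n_tpc_pairs = 2, n_ppc_pairs = 2,
                         coupling_strength = 0.9, noise_sd = 0.3, seed = 23)
  sim <- generate_dataset(spec)
  dec <- fit_pca(sim$dataset$transcripts)
  controls <- dec$scores[, 1:3, drop = FALSE]
  pe <- pearson_pairs(sim$dataset$metabolites)
  pa <- partial_pairs(sim$dataset$metabolites, controls)
  get <- function(m, pair) m[pair$metabolite_1, pair$metabolite_2]
  for (i in which(sim$truth$label == "TPC")) {
    pair <- sim$truth[i, ]
    expect_gt(abs(get(pe, pair)), 0.5)
    # transcription-mediated association collapses under the transcript PCs
    expect_lt(abs(get(pa, pair)), abs(get(pe, pair)))
    expect_lt(abs(get(pa, pair)), 0.3)
  }
  for (i in which(sim$truth$label == "PPC")) {
    pair <- sim$truth[i, ]
    expect_gt(abs(get(pe, pair)), 0.5)
    # association independent of the factors survives
    expect_lt(abs(get(pe, pair) - get(pa, pair)), 0.1)
  }
})

test_that("evaluate_recovery computes recall, precision and cross rates", {
  truth <- data.frame(metabolite_1 = c("m01", "m03", "m05"),
                      metabolite_2 = c("m02", "m04", "m06"),
                      label = c("TPC", "TPC", "PPC"),
                      stringsAsFactors = FALSE)
  pred <- data.frame(metabolite_1 = c("m01", "m03", "m05", "m07"),
                     metabolite_2 = c("m02", "m04", "m06", "m08"),
                     category = factor(c("TPC", "PPC", "PPC", "none"),
                                       levels = c("TPC", "PPC", "none")),
                     stringsAsFactors = FALSE)
  rec <- evaluate_recovery(pred, truth)
  tpc <- rec$per_label[rec$per_label$label == "TPC", ]
  expect_equal(tpc$recall, 0.5)
  expect_equal(tpc$precision, 1)
  expect_equal(tpc$cross_rate, 0.5)       # one TPC pair labelled PPC
  ppc <- rec$per_label[rec$per_label$label == "PPC", ]
  expect_equal(ppc$recall, 1)
  expect_equal(ppc$precision, 0.5)        # one of two PPC calls is planted
  expect_equal(rec$false_discoveries, 0L)
  # exact prediction gives perfect scores
  exact <- data.frame(metabolite_1 = truth$metabolite_1,
                      metabolite_2 = truth$metabolite_2,
                      category = factor(truth$label,
                                        levels = c("TPC", "PPC", "none")))
  rec2 <- evaluate_recovery(exact, truth)
  expect_equal(rec2$per_label$recall, c(1, 1))
  expect_equal(rec2$per_label$precision, c(1, 1))
  # no predictions at all: recall 0, precision undefined (NaN, not 0)
  none <- exact
  none$category <- factor("none", levels = c("TPC", "PPC", "none"))
  rec3 <- evaluate_recovery(none, truth)
  expect_equal(rec3$per_label$recall, c(0, 0))
  expect_true(all(is.nan(rec3$per_label$precision)))
})
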