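# Build a minimal pair-statistics frame with prescribed q-values.
stats_frame <- function(q) {
  n <- nrow(q)
  data.frame(metabolite_1 = sprintf("a%02d", seq_len(n)),
             metabolite_2 = sprintf("b%02d", seq_len(n)),
             r_pearson = rep(0.5, n), r_partial = rep(0.1, n),
             p_pearson = q$pe, p_partial = q$pa, p_diff = q$d,
             q_pearson = q$pe, q_partial = q$pa, q_diff = q$d,
             stringsAsFactors = FALSE)
}

test_that("classification implements the TPC and PPC decision rules", {
  q <- data.frame(pe = c(0.001, 0.001, 0.001, 0.5, 0.001, 0.5),
                  pa = c(0.500, 0.001, 0.001, 0.001, 0.5, 0.5),
                  d  = c(0.001, 0.001, 0.500, 0.001, 0.5, 0.001))
  out <- classify_pairs(stats_frame(q), tppc_control(alpha = 0.01))
  expect_equal(as.character(out$category),
               c("TPC",   # sig pearson, non-sig partial, sig diff
                 "PPC",   # sig partial + sig diff
                 "none",  # sig pearson & partial but no diff
                 "PPC",   # partial + diff significant, pearson not needed
                 "none", "none"))
  # requiring a significant Pearson removes the Pearson-free PPC call
  out2 <- classify_pairs(stats_frame(q),
                         tppc_control(alpha = 0.01,
                                      ppc_require_pearson = TRUE))
  expect_equal(as.character(out2$category)[4], "none")
  expect_equal(as.character(out2$category)[2], "PPC")
})

test_that("TPC and PPC are disjoint for every possible significance pattern", {
  flags <- expand.grid(pe = c(0.001, 0.5), pa = c(0.001, 0.5),
                       d = c(0.001, 0.5))
  for (req in c(TRUE, FALSE)) {
    out <- classify_pairs(stats_frame(flags),
                          tppc_control(alpha = 0.01,
                                       ppc_require_pearson = req))
    expect_equal(sum(out$category == "TPC" & out$category == "PPC"), 0L)
    tpc <- out$metabolite_1[out$category == "TPC"]
    ppc <- out$metabolite_1[out$category == "PPC"]
    expect_length(intersect(tpc, ppc), 0L)
  }
})

test_that("compute_pair_statistics covers all unordered pairs", {
  ds <- small_dataset(n_metabolites = 7, n_transcripts = 30, n_samples = 30,
                      seed = 71)
  cfg <- tppc_control(n_permutations = 100, seed = 5)
  st <- compute_pair_statistics(ds, cfg)
  expect_equal(nrow(st), choose(7, 2))
  expect_true(all(st$metabolite_1 < st$metabolite_2))
  expect_true(all(st$r_pearson >= -1 & st$r_pearson <= 1))
  expect_true(all(st$p_pearson > 0 & st$p_pearson <= 1))
  expect_true(all(st$q_pearson >= st$p_pearson))
  expect_true(all(st$q_partial >= st$p_partial))
  expect_true(all(st$q_diff >= st$p_diff))
})

test_that("uninformative transcripts leave partial close to Pearson", {
  # metabolites correlated among themselves, transcripts independent noise
  set.seed(81)
  n <- 60
  u <- rnorm(n)
  vals <- rbind(m1 = 0.9 * u + rnorm(n, sd = 0.4),
                m2 = 0.9 * u + rnorm(n, sd = 0.4),
                m3 = rnorm(n), m4 = rnorm(n))
  colnames(vals) <- sprintf("s%03d", seq_len(n))
  ds <- align_samples(noise_layer(50, n, "transcript", seed = 82),
                      omics_matrix(vals, layer = "metabolite"),
                      min_samples = 3)
  cfg <- tppc_control(n_permutations = 100, seed = 5)
  st <- compute_pair_statistics(ds, cfg)
  row <- st[st$metabolite_1 == "m1" & st$metabolite_2 == "m2", ]
  expect_gt(abs(row$r_pearson), 0.5)
  expect_lt(abs(row$r_pearson - row$r_partial), 0.1)
})

test_that("metabolites driven by the transcript factors lose correlation", {
  set.seed(91)
  n <- 60
  lt <- latent_transcripts(150, n, n_factors = 2, noise_sd = 0.3, seed = 91)
  s <- lt$factors[1, ] / sd(lt$factors[1, ])
  vals <- rbind(m1 = 0.9 * s + rnorm(n, sd = 0.4),
                m2 = 0.9 * s + rnorm(n, sd = 0.4),
                m3 = rnorm(n), m4 = rnorm(n))
  colnames(vals) <- lt$layer$sample_ids
  ds <- align_samples(lt$layer, omics_matrix(vals, layer = "metabolite"),
                      min_samples = 3)
  cfg <- tppc_control(n_pcs = 2, n_permutations = 100, seed = 5)
  st <- compute_pair_statistics(ds, cfg)
  row <- st[st$metabolite_1 == "m1" & st$metabolite_2 == "m2", ]
  expect_gt(abs(row$r_pearson), 0.6)
  expect_lt(abs(row$r_partial), 0.25)
})

test_that("direction-change tallies compare absolute correlations", {
  stats <- data.frame(
    metabolite_1 = c("a", "a", "b", "c"),
    metabolite_2 = c("b", "c", "c", "d"),
    r_pearson = c(0.30, -0.42, 0.50, 0.20),
    r_partial = c(0.25, -0.39, 0.55, 0.20),
    category = factor(c("TPC", "TPC", "PPC", "PPC"),
                      levels = c("TPC", "PPC", "none")))
  d <- summarize_direction_changes(stats)
  tp <- d[d$category == "TPC" & d$sign == "+", ]
  expect_equal(tp$n, 1)
  expect_equal(tp$decreased, 1)
  tn <- d[d$category == "TPC" & d$sign == "-", ]
  expect_equal(tn$decreased, 1)     # |-0.39| < |-0.42|
  pp <- d[d$category == "PPC" & d$sign == "+", ]
  expect_equal(pp$n, 2)
  expect_equal(pp$increased, 0.5)
  expect_equal(pp$tied, 0.5)
  expect_true(all(d$increased + d$decreased <= 1, na.rm = TRUE))
  # empty categories are undefined, not zero
  empty <- summarize_direction_changes(stats[stats$category == "none", ])
  expect_true(all(is.nan(empty$increased)))
})

test_that("threshold counts nest as thresholds tighten", {
  stats <- data.frame(
    metabolite_1 = letters[1:3], metabolite_2 = LETTERS[1:3],
    r_partial = c(0.95, 0.85, 0.45),
    category = factor(rep("PPC", 3), levels = c("TPC", "PPC", "none")))
  ct <- count_thresholds(stats, thresholds = c(0.9, 0.4))
  expect_equal(ct$PPC, c(1L, 3L))
  expect_equal(ct$TPC, c(0L, 0L))
  ct2 <- count_thresholds(stats)
  # counts can only grow as the positive threshold drops (0.9 down to 0.4)
  pos <- ct2$PPC[ct2$threshold > 0]
  expect_true(all(diff(pos) >= 0))
})

test_that("the fitted object carries config, dims and methods", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_transcripts = 40,
                                         n_metabolites = 8, n_tpc_pairs = 2,
                                         n_ppc_pairs = 1, seed = 5))
  fit <- tppc(sim$dataset, n_permutations = 100, seed = 5)
  expect_s3_class(fit, "tppc")
  expect_equal(unname(fit$dims), c(40, 8, 40))
  expect_equal(fit$config$n_pcs, 3L)
  expect_equal(nrow(fit$pairs), choose(8, 2))
  expect_length(coef(fit), choose(8, 2))
  expect_identical(unname(coef(fit, "pearson")), fit$pairs$r_pearson)
  s <- summary(fit)
  expect_s3_class(s, "summary.tppc")
  expect_output(print(fit), "TPC/PPC classification")
  expect_output(print(s), "Category counts")
  # disjointness end-to-end
  expect_equal(sum(fit$pairs$category == "TPC" &
                     fit$pairs$category == "PPC"), 0L)
})

test_that("null p-values are close to uniform (super-uniform one-sided)", {
  # fully independent layers: every pair is a true null, so the empirical
  # CDF of the p-values must not exceed the uniform CDF by more than the
  # sampling slack of 45 (dependent) pairs at 200 permutations
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_transcripts = 60,
                                         n_metabolites = 10, n_tpc_pairs = 0,
                                         n_ppc_pairs = 0, seed = 111))
  st <- compute_pair_statistics(sim$dataset,
                                tppc_control(n_permutations = 200,
                                             seed = 111))
  tgrid <- seq(0.05, 0.95, by = 0.05)
  for (fam in c("p_pearson", "p_partial", "p_diff")) {
    dplus <- max(vapply(tgrid, function(t) mean(st[[fam]] <= t) - t,
                        numeric(1)))
    expect_lt(dplus, 0.25)
  }
})
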