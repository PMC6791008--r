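test_that("peak tables parse per sample with the 23-subgroup vocabulary enforced", {
  cfg <- small_config(seed = 3)
  cohort <- generate_cohort(cfg)
  peaks <- generate_peak_table(cohort, cfg)
  two <- peaks[peaks$sample_id %in% c("pHIVy_01", "HC_01"), ]
  path <- tempfile(fileext = ".tsv")
  write.table(two, path, sep = "\t", row.names = FALSE, quote = FALSE)
  parsed <- parse_peak_table(path)
  expect_length(parsed, 2)
  expect_true(all(vapply(parsed, function(d) length(unique(d$trbv)),
                         integer(1)) == 23))
  # within each (sample, trbv) fragment sizes are strictly increasing
  for (d in parsed) {
    for (sub in split(d, d$trbv)) {
      expect_true(all(diff(sub$fragment_size) > 0))
    }
  }

  empty <- tempfile(fileext = ".tsv")
  write.table(two[0, ], empty, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(p0 <- parse_peak_table(empty), "empty")
  expect_length(p0, 0)

  bad <- two
  bad$trbv[1] <- "TRBV99"
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_peak_table(path), "TRBV99")

  write.table(two[, -3], path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_peak_table(path), "missing column")
})

test_that("normalization floors sub-threshold peaks and renormalizes", {
  d <- normalize_distribution(c(10, 10, 20), min_total_area = 1)
  expect_equal(d$rel_area, c(0.25, 0.25, 0.5))
  expect_true(d$detected)

  d2 <- normalize_distribution(c(100, 1), min_peak_frac = 0.02,
                               min_total_area = 1)
  expect_equal(d2$rel_area, c(1, 0))  # 1/101 < 2% of the total

  d3 <- normalize_distribution(c(0, 0, 0))
  expect_false(d3$detected)
  expect_error(count_peaks(d3), "undetected")
})

test_that("peak counting counts positive ladder positions", {
  expect_equal(count_peaks(rep(1 / 8, 8)), 8)
  expect_equal(count_peaks(c(0.5, 0, 0.5, 0, 0)), 2)
  prof <- generate_spectratype_profile("normal", seed = 11)
  expect_gte(count_peaks(normalize_distribution(prof)), 7)
})

test_that("classification follows dominance, peak count, then Gaussian fit", {
  # 8-point binomial(7, 1/2) weights are near-Gaussian: check with an
  # independent 3-parameter least-squares fit before asserting the class
  p <- choose(7, 0:7) / 2^7
  oracle_r2 <- local({
    pos <- 1:8
    rss <- function(th) {
      g <- th[1] * exp(-(pos - th[2])^2 / (2 * th[3]^2))
      sum((p - g)^2)
    }
    fit <- optim(c(max(p), 4.5, 1.5), rss, control = list(reltol = 1e-12))
    1 - fit$value / sum((p - mean(p))^2)
  })
  expect_gt(oracle_r2, 0.99)
  cls <- classify_profile(p)
  expect_equal(cls$class, "normal")
  expect_gt(cls$diagnostics$gaussian_fit_score, 0.99)
  # implementation matches the independent oracle fit
  expect_equal(gaussian_fit_score(p), oracle_r2, tolerance = 1e-4)

  expect_equal(classify_profile(c(1, 0, 0, 0, 0, 0, 0, 0))$class,
               "mono_oligoclonal")
  expect_equal(classify_profile(c(0.2, 0.2, 0.2, 0.2, 0.2, 0, 0, 0))$class,
               "restricted")
  # dominance precedes peak count: 7 peaks but one towering
  tower <- c(0.70, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0)
  expect_equal(classify_profile(tower)$class, "mono_oligoclonal")
  # order invariance of the inputs that feed classification
  prof <- generate_spectratype_profile("shifted", seed = 5)
  shuffled <- prof[sample(nrow(prof)), ]
  expect_identical(classify_profile(normalize_distribution(prof))$class,
                   classify_profile(normalize_distribution(shuffled))$class)
})

test_that("perturbation is the total-variation distance in percent", {
  expect_equal(perturbation_score(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(perturbation_score(c(1, 0), c(0, 1)), 100)
  expect_equal(perturbation_score(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 50)
  # symmetry
  expect_equal(perturbation_score(c(0.8, 0.2, 0), c(0.1, 0.3, 0.6)),
               perturbation_score(c(0.1, 0.3, 0.6), c(0.8, 0.2, 0)))
})

test_that("perturbation matches a brute-force oracle and is a metric", {
  set.seed(71)
  for (i in 1:200) {
    p <- random_distribution(8, zeros = sample(0:3, 1))
    r <- random_distribution(8, zeros = sample(0:3, 1))
    q <- random_distribution(8)
    oracle <- 100 * sum(abs(p - r)) / 2
    expect_equal(perturbation_score(p, r), oracle, tolerance = 1e-9)
    # metric properties on the shared ladder
    expect_equal(perturbation_score(p, p), 0)
    expect_lte(perturbation_score(p, r),
               perturbation_score(p, q) + perturbation_score(q, r) + 1e-12)
  }
})

test_that("distributions on different ladders align on the union of positions", {
  a <- normalize_distribution(data.frame(fragment_size = c(160, 163, 166),
                                         area = c(50, 100, 50)),
                              min_total_area = 1)
  b <- normalize_distribution(data.frame(fragment_size = c(163, 166, 169),
                                         area = c(100, 50, 50)),
                              min_total_area = 1)
  # union ladder 160,163,166,169: |0.25-0|+|0.5-0.5|+|0.25-0.25|+|0-0.25|
  expect_equal(perturbation_score(a, b), 50 * (0.25 + 0 + 0 + 0.25))
})

test_that("the healthy-control reference averages profiles and scores all HC", {
  mk <- function(rel, lengths = seq_along(rel)) {
    normalize_distribution(data.frame(fragment_size = lengths,
                                      area = rel * 1000),
                           min_total_area = 1)
  }
  # 12 identical HC profiles -> SD 0, mean equals the common profile
  prof <- list(TRBV2 = mk(c(0.25, 0.5, 0.25)))
  hc <- setNames(rep(list(prof), 12), sprintf("HC_%02d", 1:12))
  ref <- build_reference(hc, n_ref = 12, seed = 1)
  expect_equal(ref$mean_dist$TRBV2$rel_area, c(0.25, 0.5, 0.25))
  expect_equal(unname(ref$pert_sd["TRBV2"]), 0)
  expect_equal(unname(ref$pert_mean["TRBV2"]), 0)

  # hand-made 2-HC toy: distributions (1,0) and (0,1)
  hc2 <- list(HC_A = list(TRBV2 = mk(c(1, 0))),
              HC_B = list(TRBV2 = mk(c(0, 1))))
  ref2 <- build_reference(hc2, n_ref = 2, seed = 1)
  expect_equal(ref2$mean_dist$TRBV2$rel_area, c(0.5, 0.5))
  expect_equal(unname(ref2$hc_scores[, "TRBV2"]), c(50, 50))

  expect_error(build_reference(hc2, n_ref = 12), "at least 12")

  # reproducibility of the seeded reference draw
  hc20 <- setNames(rep(list(prof), 20), sprintf("HC_%02d", 1:20))
  expect_identical(build_reference(hc20, seed = 9)$ref_ids,
                   build_reference(hc20, seed = 9)$ref_ids)
})

test_that("over-perturbation flags use strict mean+2SD/mean+3SD bounds", {
  ref <- structure(list(pert_mean = setNames(rep(10, 23), trbv_subgroups()),
                        pert_sd = setNames(rep(2, 23), trbv_subgroups())),
                   class = "reference_repertoire")
  d <- setNames(rep(10 + 2 * 2, 23), trbv_subgroups())  # exactly mean+2SD
  res <- flag_overperturbed(d, ref)
  expect_true(all(res$per_trbv$flag == "none"))
  expect_equal(res$n_overperturbed, 0)

  d[1] <- 10 + 2.5 * 2
  d[2] <- 10 + 3.5 * 2
  res2 <- flag_overperturbed(d, ref)
  expect_equal(res2$per_trbv$flag[1], "over2sd")
  expect_equal(res2$per_trbv$flag[2], "over3sd")
  expect_equal(res2$n_overperturbed, 2)

  # saturation and the 3SD => 2SD implication (monotone flagging)
  d3 <- setNames(rep(10 + 4 * 2, 23), trbv_subgroups())
  res3 <- flag_overperturbed(d3, ref)
  expect_equal(res3$n_overperturbed, 23)
  expect_true(all(res3$per_trbv$d > 10 + 2 * 2))

  names(d)[1] <- "TRBVX"
  expect_error(flag_overperturbed(d, ref), "no reference statistics")
})

test_that("category summaries pool subject x TRBV units and report medians", {
  class_df <- data.frame(sample_id = "A", trbv = trbv_subgroups(),
                         class = "normal")
  pert_df <- data.frame(sample_id = c("A", "B"),
                        global_perturbation = c(10, 20))
  groups <- c(A = "HC", B = "HC")
  s <- summarize_categories(class_df, pert_df, groups)
  expect_equal(unname(s$category_proportions["HC", "normal"]), 100)
  expect_equal(s$perturbation_summary$median, 15)
})

test_that("TRBV usage is each subgroup's share of total area", {
  mk_sample <- function(id, areas) {
    data.frame(sample_id = id, trbv = names(areas), fragment_size = 160,
               height = 1, area = unname(areas))
  }
  eq <- setNames(rep(10, 23), trbv_subgroups())
  u <- trbv_usage(list(S1 = mk_sample("S1", eq)))
  expect_equal(unname(u$per_subject[1, ]), rep(1 / 23, 23))

  one <- setNames(c(100, rep(0, 22)), trbv_subgroups())
  u2 <- trbv_usage(list(S1 = mk_sample("S1", one)))
  expect_equal(unname(u2$per_subject[1, "TRBV2"]), 1)
  expect_equal(sum(u2$per_subject), 1)

  toy <- setNames(c(2, 1, 1), c("TRBV2", "TRBV3", "TRBV4"))
  u3 <- trbv_usage(list(S1 = mk_sample("S1", toy)))
  expect_equal(unname(u3$per_subject[1, c("TRBV2", "TRBV3", "TRBV4")]),
               c(0.5, 0.25, 0.25))
})
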