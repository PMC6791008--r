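test_that("default configuration yields 21 + 19 + 40 subjects deterministically", {
  cfg <- cohort_config(seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(as.numeric(table(cohort$subjects$group)[c("pHIVy", "npHIVy", "HC")]),
               c(21, 19, 40))
  expect_identical(cohort, generate_cohort(cfg))
  # invariants of the subject records
  expect_true(all(abs(cohort$subjects$cd4_cd8_ratio -
                        cohort$subjects$cd4_abs / cohort$subjects$cd8_abs) <
                    1e-6 * cohort$subjects$cd4_cd8_ratio))
  expect_true(all(cohort$subjects$cd4_pct >= 0 & cohort$subjects$cd4_pct <= 100))
  expect_true(all(cohort$truth$clinical$ts_true > 0))
  expect_true(all(cohort$truth$classes %in%
                    c("normal", "shifted", "restricted", "mono_oligoclonal")))
})

test_that("simulated study files are byte-identical for a fixed seed", {
  cfg <- small_config(seed = 7)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  p1 <- simulate_study(cfg, d1)
  p2 <- simulate_study(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("file", k))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("adding subjects to one group never perturbs other subjects' draws", {
  base <- cohort_config(group_sizes = c(pHIVy = 5, npHIVy = 5, HC = 13), seed = 2)
  bigger <- cohort_config(group_sizes = c(pHIVy = 9, npHIVy = 5, HC = 13), seed = 2)
  a <- generate_cohort(base)$subjects
  b <- generate_cohort(bigger)$subjects
  shared <- a$subject_id
  expect_identical(a, b[match(shared, b$subject_id), ],
                   ignore_attr = "row.names")
})

test_that("zero-correlation configuration gives near-independent draws", {
  targets <- data.frame(var1 = "trec", var2 = "cd4_abs", group = "pHIVy", r = 0)
  cfg <- cohort_config(group_sizes = c(pHIVy = 500, npHIVy = 2, HC = 2),
                       seed = 11, correlation_targets = targets)
  cohort <- generate_cohort(cfg)
  ph <- merge(cohort$subjects, cohort$truth$clinical)
  ph <- ph[ph$group == "pHIVy", ]
  expect_lt(abs(cor(ph$trec_per_ml, ph$cd4_abs)), 2 / sqrt(500))
})

test_that("the copula hits a 0.75 TREC-CD4 correlation at n = 2000", {
  targets <- data.frame(var1 = "trec", var2 = "cd4_abs", group = "pHIVy",
                        r = 0.75)
  cfg <- cohort_config(group_sizes = c(pHIVy = 2000, npHIVy = 2, HC = 2),
                       seed = 13, correlation_targets = targets)
  cohort <- generate_cohort(cfg)
  ph <- merge(cohort$subjects, cohort$truth$clinical)
  ph <- ph[ph$group == "pHIVy", ]
  r <- cor(ph$trec_per_ml, ph$cd4_abs)
  expect_gte(r, 0.70)
  expect_lte(r, 0.80)
})

test_that("invalid correlation configurations raise configuration errors", {
  bad_group <- data.frame(var1 = "trec", var2 = "cd4_abs", group = "nosuch",
                          r = 0.5)
  expect_error(cohort_config(correlation_targets = bad_group), "unknown group")
  bad_var <- data.frame(var1 = "trec", var2 = "nosuch", group = "all", r = 0.5)
  expect_error(cohort_config(correlation_targets = bad_var),
               "unknown variable")
  expect_error(cohort_config(group_sizes = c(pHIVy = 0, HC = 2)), "positive")
  # jointly unattainable triangle: r(a,b)=r(b,c)=0.95, r(a,c)=-0.95
  tri <- data.frame(var1 = c("trec", "krec", "trec"),
                    var2 = c("krec", "ts", "ts"),
                    group = "all", r = c(0.95, 0.95, -0.95))
  cfg <- cohort_config(group_sizes = c(pHIVy = 3, npHIVy = 3, HC = 3),
                       correlation_targets = tri)
  expect_error(generate_cohort(cfg), "offending pair|unattainable")
})

test_that("spectratype archetypes satisfy their defining properties", {
  norm <- generate_spectratype_profile("normal", 8, seed = 7)
  dn <- normalize_distribution(norm)
  expect_gte(count_peaks(dn), 7)
  expect_gte(gaussian_fit_score(dn$rel_area), 0.90)

  mono <- generate_spectratype_profile("mono_oligoclonal", 8, seed = 7)
  dm <- normalize_distribution(mono)
  srt <- sort(dm$rel_area, decreasing = TRUE)
  expect_true(srt[1] >= 0.40 || sum(srt[1:2]) >= 0.60)

  restr <- generate_spectratype_profile("restricted", 8, seed = 7)
  dr <- normalize_distribution(restr)
  expect_lt(count_peaks(dr), 7)

  shift <- generate_spectratype_profile("shifted", 8, seed = 7)
  ds <- normalize_distribution(shift)
  expect_gte(count_peaks(ds), 7)
  expect_lt(gaussian_fit_score(ds$rel_area), 0.90)

  expect_error(generate_spectratype_profile("polyclonal", 8), "unknown")
  expect_error(generate_spectratype_profile("normal", 2), "n_lengths")
  expect_true(all(generate_spectratype_profile("normal", 8, seed = 1)$area > 0))
})

test_that("generated class labels are recovered with >= 95% accuracy", {
  classes <- c("normal", "shifted", "restricted", "mono_oligoclonal")
  n_per <- 150
  hits <- 0
  allowed_confusion <- TRUE
  for (cl in classes) {
    for (i in seq_len(n_per)) {
      prof <- generate_spectratype_profile(cl, seed = 5000 * match(cl, classes) + i)
      got <- classify_profile(normalize_distribution(prof))$class
      if (got == cl) hits <- hits + 1
      else if (!(cl %in% c("normal", "shifted") && got %in% c("normal", "shifted"))) {
        allowed_confusion <- FALSE
      }
    }
  }
  expect_gte(hits / (length(classes) * n_per), 0.95)
  expect_true(allowed_confusion)
})

test_that("noiseless plates refit the configured curve and round-trip truth", {
  cfg <- small_config(seed = 5, qpcr_noise_sd = 0)
  cohort <- generate_cohort(cfg)
  truth <- cohort$truth$clinical
  plate <- generate_qpcr_plate(truth, "telomere", cfg, seed = 1)
  std <- plate[plate$role == "standard" & plate$target == "TEL", ]
  curve <- fit_standard_curve(std$quantity, std$cq)
  expect_equal(curve$slope, unname(cfg$curve_params$TEL["slope"]),
               tolerance = 1e-9)
  expect_equal(curve$intercept, unname(cfg$curve_params$TEL["intercept"]),
               tolerance = 1e-9)
  expect_equal(min(std$quantity), 0.1640625)

  for (i in c(1, 10, 21)) {
    res <- compute_ts_ratio(plate, truth$subject_id[i])
    expect_equal(res$ts_ratio, truth$ts_true[i], tolerance = 1e-9)
  }
  pe <- generate_qpcr_plate(truth, "excision", cfg, seed = 2)
  for (i in c(2, 12)) {
    res <- quantify_excision_circles(pe, truth$subject_id[i],
                                     cells_per_ml = cfg$cells_per_ml,
                                     cells_per_reaction = cfg$cells_per_reaction)
    expect_equal(res$trec_copies_per_ml / truth$trec_per_ml[i], 1,
                 tolerance = 1e-9)
    expect_equal(res$krec_copies_per_ml / truth$krec_per_ml[i], 1,
                 tolerance = 1e-9)
  }
})

test_that("with Cq noise 0.05 the recovered T/S is unbiased across runs", {
  truth <- data.frame(sample_id = "S1", ts_true = 1.0)
  cfg <- cohort_config(qpcr_noise_sd = 0.05)
  recovered <- vapply(1:500, function(s) {
    plate <- generate_qpcr_plate(truth, "telomere", cfg, seed = s)
    compute_ts_ratio(plate, "S1")$ts_ratio
  }, numeric(1))
  med <- median(recovered, na.rm = TRUE)
  expect_gte(med, 0.97)
  expect_lte(med, 1.03)
  # inter-run CV is finite and modest
  cv <- 100 * sd(recovered, na.rm = TRUE) / mean(recovered, na.rm = TRUE)
  expect_true(is.finite(cv))
})

test_that("QC accepts and rejects replicate groups exactly as a direct CV oracle", {
  set.seed(99)
  agree <- TRUE
  for (i in 1:200) {
    q <- rlnorm(3, 0, runif(1, 0.01, 0.3))
    oracle_cv <- 100 * sd(q) / mean(q)
    qc <- replicate_qc(q, threshold_pct = 15)
    if (qc$accepted != (oracle_cv <= 15)) agree <- FALSE
  }
  expect_true(agree)
})

test_that("category mixes reproduce the configured group proportions", {
  # healthy-control mix at n = 40 subjects x 23 subgroups: the pooled normal
  # proportion stays within binomial sampling error of the configured 27.5%
  cfg <- cohort_config(group_sizes = c(pHIVy = 2, npHIVy = 2, HC = 40),
                       seed = 17)
  cohort <- generate_cohort(cfg)
  cls <- cohort$truth$classes[cohort$subjects$subject_id[
    cohort$subjects$group == "HC"], ]
  prop_normal <- 100 * mean(cls == "normal")
  expect_lt(abs(prop_normal - 27.5), 5)  # ~3.4 SE of a 920-unit binomial
})
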