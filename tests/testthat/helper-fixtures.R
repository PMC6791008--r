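# Build a noiseless qPCR plate by hand for a set of true quantities on a
# known curve; used to test interpolation and QC independently of the
# generator.
manual_plate <- function(target, slope, intercept, ladder, sample_quantities,
                         sample_id = "S1", ntc_cq = NA_real_) {
  cq_of <- function(q) intercept + slope * log10(q)
  rows <- rbind(
    data.frame(target = target, role = "standard",
               replicate_group = paste0("STD_", target),
               quantity = ladder, cq = cq_of(ladder)),
    data.frame(target = target, role = "sample", replicate_group = sample_id,
               quantity = NA_real_, cq = cq_of(sample_quantities)),
    data.frame(target = target, role = "ntc",
               replicate_group = paste0("NTC_", target),
               quantity = NA_real_, cq = ntc_cq)
  )
  rows$well <- sprintf("%s%02d", target, seq_len(nrow(rows)))
  rows[, c("well", "target", "role", "replicate_group", "quantity", "cq")]
}

# Random relative-area distribution on k ladder positions (normalized gamma,
# i.e. Dirichlet-distributed).
random_distribution <- function(k, zeros = 0) {
  w <- stats::rgamma(k, 1)
  if (zeros > 0) w[sample.int(k, zeros)] <- 0
  w / sum(w)
}

# Tiny cohort configuration for fast end-to-end tests.
small_config <- function(seed = 1, ...) {
  cohort_config(group_sizes = c(pHIVy = 4, npHIVy = 4, HC = 13),
                seed = seed, ...)
}
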