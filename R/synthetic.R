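# Synthetic cohort generator emulating the study design: three groups
# (perinatally HIV-infected youths, non-perinatally infected youths, healthy
# controls), per-subject clinical covariates with copula-induced
# correlations, per-TRBV clonality classes, spectratype peak tables and qPCR
# plates, all with known ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: group sizes 21/19/40, Table-1
#' marginals (median/IQR), Fig.-3a clonality-category mixes, a telomere T/S
#' shift between the HIV groups and healthy controls, equal TREC/KREC levels
#' across groups, and the reported clinical correlations in the perinatal
#' group (TREC-CD4 r = 0.75, T/S-CD4 r = 0.75, perturbation vs CD4/CD8
#' r = -0.81, perturbation vs CD4 r = -0.63).
#'
#' Continuous marginals are given as c(median, q1, q3); cell counts, T/S and
#' excision-circle copies are modelled lognormal, ages and percentages
#' normal. Correlation targets are Pearson correlations on the measurement
#' scale; the latent Gaussian-copula correlation is calibrated numerically so
#' the realized correlation hits the target despite skewed marginals.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param seed Master seed; every subject draws from a counter-based
#'   substream so adding subjects never perturbs earlier subjects' data.
#' @param age,cd4_abs,cd4_pct,cd8_abs,cd8_pct Per-group lists of
#'   c(median, q1, q3).
#' @param male_frac Per-group male fraction.
#' @param ts_median Per-group true T/S median; `ts_sdlog10` its log10 spread.
#' @param trec_log10,krec_log10 c(mean, sd) of log10 copies/ml (same for all
#'   groups by default: thymic and bone-marrow output do not differ).
#' @param category_mix Group x class matrix of clonality-class probabilities
#'   (columns normal, shifted, restricted, mono_oligoclonal; rows sum to 1).
#' @param correlation_targets Data frame with columns `var1`, `var2`,
#'   `group` ("all" or a group name) and `r`.
#' @param propensity_beta Group x c(shape1, shape2) matrix of the Beta
#'   marginal of the repertoire perturbation propensity; the HIV groups sit
#'   higher than healthy controls, reproducing the group shift in global
#'   perturbation.
#' @param perturbation_shift_max Maximal positional shift (ladder positions)
#'   a subject's profiles receive at propensity 1; the shift moves the
#'   generalized Hamming distance without touching the clonality-class
#'   diagnostics.
#' @param qpcr_noise_sd Cq noise SD (cycles) for simulated plates.
#' @param curve_params Named list of c(slope, intercept) per qPCR target.
#' @param s_ng Reference-matched beta-globin input per telomere reaction (ng).
#' @param cells_per_ml,cells_per_reaction Blood normalization factors for the
#'   excision-circle assay.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    group_sizes = c(pHIVy = 21, npHIVy = 19, HC = 40),
    seed = 1,
    age = list(pHIVy = c(27, 24, 29), npHIVy = c(27, 24, 29), HC = c(28, 24, 31)),
    cd4_abs = list(pHIVy = c(803, 526, 1052), npHIVy = c(818, 688, 1024),
                   HC = c(851, 643, 1099)),
    cd4_pct = list(pHIVy = c(33.8, 28.7, 38.8), npHIVy = c(38.1, 31.9, 42),
                   HC = c(42.9, 39.7, 49.4)),
    cd8_abs = list(pHIVy = c(850, 713, 1131), npHIVy = c(728, 631, 812),
                   HC = c(415, 344, 571)),
    cd8_pct = list(pHIVy = c(42.8, 32.7, 51), npHIVy = c(32.3, 28, 40.3),
                   HC = c(22.2, 22.0, 22.6)),
    male_frac = c(pHIVy = 7 / 21, npHIVy = 12 / 19, HC = 19 / 40),
    ts_median = c(pHIVy = 0.80, npHIVy = 0.80, HC = 1.00),
    ts_sdlog10 = 0.06,
    trec_log10 = c(mean = 3.7, sd = 0.35),
    krec_log10 = c(mean = 3.9, sd = 0.35),
    category_mix = rbind(
      pHIVy  = c(normal = 0.168, shifted = 0.277, restricted = 0.495,
                 mono_oligoclonal = 0.060),
      npHIVy = c(normal = 0.188, shifted = 0.300, restricted = 0.398,
                 mono_oligoclonal = 0.114),
      HC     = c(normal = 0.275, shifted = 0.341, restricted = 0.355,
                 mono_oligoclonal = 0.029)),
    correlation_targets = default_correlation_targets(),
    propensity_beta = rbind(pHIVy = c(3, 2), npHIVy = c(3, 2), HC = c(2, 3)),
    perturbation_shift_max = 0.9,
    qpcr_noise_sd = 0.05,
    curve_params = list(TEL = c(slope = -3.05, intercept = 18),
                        BG = c(slope = -3.22, intercept = 22),
                        TREC = c(slope = -3.40, intercept = 40),
                        KREC = c(slope = -3.40, intercept = 39.5)),
    s_ng = 10,
    cells_per_ml = 2e6,
    cells_per_reaction = 1e5) {
  groups <- names(group_sizes)
  if (is.null(groups) || any(groups == "")) stop("group_sizes must be named")
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  if (any(abs(rowSums(category_mix) - 1) > 1e-9)) {
    stop("category_mix rows must each sum to 1")
  }
  if (any(category_mix < 0)) stop("category_mix probabilities must be >= 0")
  if (any(abs(correlation_targets$r) > 1)) stop("|r| must be <= 1")
  if (qpcr_noise_sd < 0) stop("qpcr_noise_sd must be >= 0")
  known_groups <- c(groups, "all")
  bad_g <- setdiff(correlation_targets$group, known_groups)
  if (length(bad_g) > 0) {
    stop("configuration error: unknown group in correlation_targets: ",
         paste(bad_g, collapse = ", "))
  }
  vars <- c(copula_variables(), "cd4_cd8_ratio")
  bad_v <- setdiff(c(correlation_targets$var1, correlation_targets$var2), vars)
  if (length(bad_v) > 0) {
    stop("configuration error: unknown variable in correlation_targets: ",
         paste(bad_v, collapse = ", "))
  }
  cfg <- list(group_sizes = group_sizes, seed = as.integer(seed), age = age,
              cd4_abs = cd4_abs, cd4_pct = cd4_pct, cd8_abs = cd8_abs,
              cd8_pct = cd8_pct, male_frac = male_frac, ts_median = ts_median,
              ts_sdlog10 = ts_sdlog10, trec_log10 = trec_log10,
              krec_log10 = krec_log10, category_mix = category_mix,
              correlation_targets = correlation_targets,
              propensity_beta = propensity_beta,
              perturbation_shift_max = perturbation_shift_max,
              qpcr_noise_sd = qpcr_noise_sd, curve_params = curve_params,
              s_ng = s_ng, cells_per_ml = cells_per_ml,
              cells_per_reaction = cells_per_reaction)
  class(cfg) <- "cohort_config"
  cfg
}

#' Default clinical correlation targets
#'
#' The perinatal-group targets are the correlations the study reports
#' (TREC-CD4 and T/S-CD4 r = 0.75, perturbation propensity vs CD4/CD8 ratio
#' r = -0.81 and vs CD4 count r = -0.63); the remaining entries are
#' biologically motivated fillers (paired absolute/percent measurements,
#' TREC-KREC coupling, diversity tracking thymic output) that keep the latent
#' correlation matrix positive definite.
#'
#' @return Data frame with columns var1, var2, group, r.
#' @export
default_correlation_targets <- function() {
  data.frame(
    var1 = c("cd4_abs", "cd8_abs", "trec",
             "trec", "ts", "trec", "trec", "ts",
             "propensity", "propensity", "propensity", "propensity",
             "propensity", "trec"),
    var2 = c("cd4_pct", "cd8_pct", "krec",
             "cd4_abs", "cd4_abs", "ts", "cd4_pct", "cd4_pct",
             "cd4_cd8_ratio", "cd4_abs", "cd4_pct", "trec",
             "ts", "cd4_abs"),
    group = c("all", "all", "all",
              "pHIVy", "pHIVy", "pHIVy", "pHIVy", "pHIVy",
              "pHIVy", "pHIVy", "pHIVy", "pHIVy",
              "pHIVy", "npHIVy"),
    r = c(0.7, 0.7, 0.7,
          0.75, 0.75, 0.6, 0.6, 0.6,
          -0.81, -0.63, -0.6, -0.5,
          -0.5, 0.3),
    stringsAsFactors = FALSE
  )
}

copula_variables <- function() {
  c("age", "cd4_abs", "cd4_pct", "cd8_abs", "cd8_pct",
    "trec", "krec", "ts", "propensity")
}

# median/IQR -> (meanlog, sdlog) of a lognormal, or (mean, sd) of a normal.
lnorm_params <- function(miqr) {
  c(meanlog = log(miqr[1]),
    sdlog = (log(miqr[3]) - log(miqr[2])) / (2 * stats::qnorm(0.75)))
}
norm_params <- function(miqr) {
  c(mean = miqr[1], sd = (miqr[3] - miqr[2]) / (2 * stats::qnorm(0.75)))
}

# Quantile functions per variable for one group, on the measurement scale.
group_quantile_funs <- function(config, g) {
  ln_qf <- function(miqr) {
    p <- lnorm_params(miqr)
    function(u) stats::qlnorm(u, p[1], p[2])
  }
  n_qf <- function(miqr, lo = -Inf, hi = Inf) {
    p <- norm_params(miqr)
    function(u) pmin(hi, pmax(lo, stats::qnorm(u, p[1], p[2])))
  }
  list(
    age = local({ f <- n_qf(config$age[[g]], lo = 18); function(u) round(f(u)) }),
    cd4_abs = ln_qf(config$cd4_abs[[g]]),
    cd4_pct = n_qf(config$cd4_pct[[g]], lo = 0.5, hi = 99.5),
    cd8_abs = ln_qf(config$cd8_abs[[g]]),
    cd8_pct = n_qf(config$cd8_pct[[g]], lo = 0.5, hi = 99.5),
    trec = function(u) 10^stats::qnorm(u, config$trec_log10["mean"],
                                       config$trec_log10["sd"]),
    krec = function(u) 10^stats::qnorm(u, config$krec_log10["mean"],
                                       config$krec_log10["sd"]),
    ts = function(u) 10^stats::qnorm(u, log10(config$ts_median[[g]]),
                                     config$ts_sdlog10),
    propensity = function(u) stats::qbeta(u, config$propensity_beta[g, 1],
                                          config$propensity_beta[g, 2])
  )
}

# Fixed bivariate standard-normal draws for copula calibration, generated
# once per session without disturbing the caller's RNG stream.
.copula_env <- new.env(parent = emptyenv())

copula_mc_draws <- function(n = 20000) {
  if (is.null(.copula_env$z)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(200406)
    .copula_env$z <- matrix(stats::rnorm(2 * n), ncol = 2)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  .copula_env$z
}

# Latent correlation that realizes `target_r` (Pearson, measurement scale)
# between two marginals under a Gaussian copula. Monotone in the latent rho,
# solved by bisection on fixed Monte-Carlo draws; memoised.
calibrate_latent_rho <- function(target_r, qf1, qf2, key = NULL) {
  if (target_r == 0) return(0)
  if (!is.null(key) && !is.null(.copula_env$cache[[key]])) {
    return(.copula_env$cache[[key]])
  }
  z <- copula_mc_draws()
  x1 <- qf1(stats::pnorm(z[, 1]))
  realized <- function(rho) {
    x2 <- qf2(stats::pnorm(rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]))
    stats::cor(x1, x2)
  }
  upper <- realized(0.9999)
  lower <- realized(-0.9999)
  if (target_r > upper || target_r < lower) {
    stop("configuration error: correlation target ", target_r,
         " is unattainable for these marginals (attainable range ",
         sprintf("%.3f..%.3f", lower, upper), ")")
  }
  rho <- stats::uniroot(function(r) realized(r) - target_r,
                        interval = c(-0.9999, 0.9999), tol = 1e-4)$root
  if (!is.null(key)) {
    if (is.null(.copula_env$cache)) .copula_env$cache <- list()
    .copula_env$cache[[key]] <- rho
  }
  rho
}

# Latent correlation matrix for one group from the calibrated pair targets.
# cd4_cd8_ratio targets are mapped onto the cd4/cd8 latents through the
# log-ratio contrast (the ratio of two lognormals is lognormal).
build_latent_matrix <- function(config, g, qfs) {
  vars <- copula_variables()
  k <- length(vars)
  M <- diag(k)
  dimnames(M) <- list(vars, vars)
  tg <- config$correlation_targets
  tg <- tg[tg$group %in% c("all", g), , drop = FALSE]
  plain <- tg[tg$var1 != "cd4_cd8_ratio" & tg$var2 != "cd4_cd8_ratio", ,
              drop = FALSE]
  ratio <- tg[tg$var1 == "cd4_cd8_ratio" | tg$var2 == "cd4_cd8_ratio", ,
              drop = FALSE]
  pair_names <- character(0)
  for (i in seq_len(nrow(plain))) {
    v1 <- plain$var1[i]; v2 <- plain$var2[i]; r <- plain$r[i]
    if (v1 == v2) stop("configuration error: self-correlation target for ", v1)
    key <- paste("plain", g, v1, v2, r, sep = "|")
    rho <- calibrate_latent_rho(r, qfs[[v1]], qfs[[v2]], key)
    M[v1, v2] <- rho
    M[v2, v1] <- rho
    pair_names <- c(pair_names, paste0(v1, "~", v2))
  }
  if (nrow(ratio) > 0) {
    p4 <- lnorm_params(config$cd4_abs[[g]])
    p8 <- lnorm_params(config$cd8_abs[[g]])
    s4 <- p4["sdlog"]; s8 <- p8["sdlog"]
    sr <- sqrt(s4^2 + s8^2)
    qf_ratio <- function(u) stats::qlnorm(u, p4["meanlog"] - p8["meanlog"], sr)
    for (i in seq_len(nrow(ratio))) {
      v <- if (ratio$var1[i] == "cd4_cd8_ratio") ratio$var2[i] else ratio$var1[i]
      r <- ratio$r[i]
      key <- paste("ratio", g, v, r, sep = "|")
      rho_contrast <- calibrate_latent_rho(r, qfs[[v]], qf_ratio, key)
      # rho(v, (s4*z4 - s8*z8)/sr) = rho_contrast, given rho(v, z4) already set
      a <- M[v, "cd4_abs"]
      b <- (s4 * a - sr * rho_contrast) / s8
      if (abs(b) > 0.999) {
        stop("configuration error: ratio correlation target for pair (", v,
             ", cd4_cd8_ratio) in group ", g, " is unattainable")
      }
      M[v, "cd8_abs"] <- b
      M["cd8_abs", v] <- b
      pair_names <- c(pair_names, paste0(v, "~cd4_cd8_ratio"))
    }
  }
  fixed <- diag(k) > 0
  dimnames(fixed) <- dimnames(M)
  for (i in seq_len(nrow(plain))) {
    fixed[plain$var1[i], plain$var2[i]] <- TRUE
    fixed[plain$var2[i], plain$var1[i]] <- TRUE
  }
  if (nrow(ratio) > 0) {
    for (i in seq_len(nrow(ratio))) {
      v <- if (ratio$var1[i] == "cd4_cd8_ratio") ratio$var2[i] else ratio$var1[i]
      fixed[v, "cd8_abs"] <- TRUE
      fixed["cd8_abs", v] <- TRUE
    }
  }
  Mc <- complete_pd(M, fixed)
  if (is.null(Mc)) {
    # identify an offending pair: first target whose removal restores PD
    for (i in seq_len(nrow(tg))) {
      M2 <- M
      v1 <- tg$var1[i]; v2 <- tg$var2[i]
      if (v1 == "cd4_cd8_ratio") v1 <- "cd8_abs"
      if (v2 == "cd4_cd8_ratio") v2 <- "cd8_abs"
      M2[v1, v2] <- 0; M2[v2, v1] <- 0
      fx <- fixed; fx[v1, v2] <- FALSE; fx[v2, v1] <- FALSE
      if (!is.null(complete_pd(M2, fx))) {
        stop("configuration error: correlation targets are jointly ",
             "unattainable (non-positive-definite latent matrix); offending ",
             "pair: (", tg$var1[i], ", ", tg$var2[i], ") in group ", g)
      }
    }
    stop("configuration error: correlation targets are jointly unattainable ",
         "(non-positive-definite latent matrix) in group ", g)
  }
  Mc
}

# Positive-definite completion of a partially specified correlation matrix.
# Entries marked in `fixed` (targets and the diagonal) are held exactly; the
# unspecified entries start at 0 and are moved the minimal amount (penalized
# least squares with an eigenvalue floor) needed to reach the PD cone.
# Returns NULL when no PD completion is found. Memoised on the fixed entries.
complete_pd <- function(M, fixed, eps = 0.02, maxit = 600) {
  free_idx <- which(upper.tri(M) & !fixed)
  if (length(free_idx) == 0 ||
      min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >= eps) {
    return(if (min(eigen(M, symmetric = TRUE,
                         only.values = TRUE)$values) > 0) M else NULL)
  }
  key <- paste0("pd|", paste(round(M[fixed], 6), collapse = ","), "|",
                paste(free_idx, collapse = ","))
  if (!is.null(.copula_env$cache[[key]])) return(.copula_env$cache[[key]])
  fill <- function(th) {
    X <- M
    X[free_idx] <- tanh(th)
    X[lower.tri(X)] <- t(X)[lower.tri(X)]
    X
  }
  obj <- function(th) {
    lam <- min(eigen(fill(th), symmetric = TRUE, only.values = TRUE)$values)
    sum(th^2) + 1e4 * max(0, eps - lam)^2
  }
  opt <- stats::optim(rep(0, length(free_idx)), obj, method = "BFGS",
                      control = list(maxit = maxit))
  X <- fill(opt$par)
  lam <- min(eigen(X, symmetric = TRUE, only.values = TRUE)$values)
  out <- if (lam > 0) X else NULL
  if (is.null(.copula_env$cache)) .copula_env$cache <- list()
  .copula_env$cache[[key]] <- out
  out
}

# Counter-based per-subject seed: a fixed function of the master seed and the
# subject's (group index, within-group index), so enlarging one group never
# perturbs any other subject's draws.
subject_seed <- function(seed, group_index, subject_index, stream = 0L) {
  (as.numeric(seed) * 7L + group_index * 31000000 + subject_index * 3100 +
     stream * 7 + 11) %% 2147483647
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject clinical covariates (Table-1 style marginals) with the
#' configured correlations induced by a Gaussian copula, plus the hidden
#' truth used for recovery testing: true T/S, true TREC/KREC copies/ml, the
#' per-subject repertoire perturbation propensity and the per-(subject, TRBV)
#' clonality class labels.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` (metadata data frame) and `truth` (list:
#'   `clinical` data frame, `classes` subject x TRBV character matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_sizes)
  vars <- copula_variables()
  classes <- colnames(config$category_mix)
  subj_rows <- list()
  truth_rows <- list()
  class_rows <- list()
  ids <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    qfs <- group_quantile_funs(config, g)
    R <- chol(build_latent_matrix(config, g, qfs))
    for (si in seq_len(config$group_sizes[[g]])) {
      sid <- sprintf("%s_%02d", g, si)
      set.seed(subject_seed(config$seed, gi, si, stream = 0L))
      z <- as.numeric(t(R) %*% stats::rnorm(length(vars)))
      names(z) <- vars
      u <- stats::pnorm(z)
      gender <- if (stats::runif(1) < config$male_frac[[g]]) "M" else "F"
      vals <- vapply(vars, function(v) qfs[[v]](u[[v]]), numeric(1))
      subj_rows[[sid]] <- data.frame(
        subject_id = sid, group = g, age = vals[["age"]], gender = gender,
        cd4_abs = vals[["cd4_abs"]], cd4_pct = vals[["cd4_pct"]],
        cd8_abs = vals[["cd8_abs"]], cd8_pct = vals[["cd8_pct"]],
        cd4_cd8_ratio = vals[["cd4_abs"]] / vals[["cd8_abs"]],
        stringsAsFactors = FALSE)
      truth_rows[[sid]] <- data.frame(
        subject_id = sid, group = g,
        ts_true = vals[["ts"]], trec_per_ml = vals[["trec"]],
        krec_per_ml = vals[["krec"]], propensity = vals[["propensity"]],
        stringsAsFactors = FALSE)
      set.seed(subject_seed(config$seed, gi, si, stream = 1L))
      class_rows[[sid]] <- sample(classes, length(trbv_subgroups()),
                                  replace = TRUE,
                                  prob = config$category_mix[g, ])
      ids <- c(ids, sid)
    }
  }
  class_mat <- do.call(rbind, class_rows)
  dimnames(class_mat) <- list(ids, trbv_subgroups())
  list(
    subjects = do.call(rbind, c(subj_rows, list(make.row.names = FALSE))),
    truth = list(
      clinical = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
      classes = class_mat
    )
  )
}

# Canonical polyclonal CDR3 shape over an n-position 3-nt ladder.
polyclonal_base <- function(n = 8) {
  w <- stats::dnorm(seq_len(n), (n + 1) / 2, 1.95)
  w / sum(w)
}

#' Generate one TRBV subgroup's spectratype profile
#'
#' Emits fragment peaks of one of the four clonality archetypes over an
#' in-frame 3-nt ladder:
#' * `normal` — >= 7 peaks, discretized Gaussian with jittered mean/width and
#'   mild multiplicative noise;
#' * `shifted` — >= 7 peaks, bimodal departure from the Gaussian shape;
#' * `restricted` — 4-6 detectable peaks of comparable size;
#' * `mono_oligoclonal` — one or two peaks dominating the area.
#'
#' @param class_label One of "normal", "shifted", "restricted",
#'   "mono_oligoclonal".
#' @param n_lengths Ladder length (>= 3; default 8, so the ">= 7 peaks =
#'   normal" rule has headroom).
#' @param seed Optional seed.
#' @param amplitude Distortion amplitude multiplier (scales the noise of
#'   normal/shifted archetypes; 1 = default separation).
#' @param shift Positional offset (ladder positions, may be fractional or
#'   negative) applied to the archetype's location: the Gaussian mean, the
#'   bimodal centers, the restricted block or the dominant peak. Moves the
#'   distribution along the ladder without changing its clonality class.
#' @param size_offset Fragment size (nt) of the first ladder position.
#' @param spacing Ladder spacing in nt (3 for in-frame CDR3 lengths).
#' @param total_area Total area to distribute (default lognormal around 2e5).
#' @return Data frame with `fragment_size`, `height`, `area`.
#' @export
generate_spectratype_profile <- function(class_label, n_lengths = 8,
                                         seed = NULL, amplitude = 1,
                                         shift = 0, size_offset = 160,
                                         spacing = 3, total_area = NULL) {
  if (n_lengths < 3) stop("n_lengths must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  n <- n_lengths
  pos <- seq_len(n)
  noise <- function(sd) exp(stats::rnorm(n, 0, sd))
  w <- switch(
    class_label,
    normal = {
      mu <- (n + 1) / 2 + shift + stats::runif(1, -0.3, 0.3)
      sg <- stats::runif(1, 1.8, 2.1)
      stats::dnorm(pos, mu, sg) * noise(0.10 * amplitude)
    },
    shifted = {
      c1 <- 2.5 + shift + stats::runif(1, -0.3, 0.3)
      c2 <- n - 2 + shift + stats::runif(1, -0.3, 0.3)
      w1 <- stats::runif(1, 0.45, 0.55)
      (w1 * stats::dnorm(pos, c1, 0.95) +
         (1 - w1) * stats::dnorm(pos, c2, 0.95)) * noise(0.10 * amplitude)
    },
    restricted = {
      k <- min(sample(4:6, 1), n - 1)
      # block sits at the ladder center, displaced by the (amplified)
      # positional shift: coarse integer structure needs a larger lever arm
      start <- round((n - k) / 2 + 1) + round(shift * 3.3)
      start <- min(max(start, 1L), n - k + 1L)
      w0 <- numeric(n)
      w0[start:(start + k - 1)] <- stats::runif(k, 0.7, 1)
      w0
    },
    mono_oligoclonal = {
      n_dom <- sample(1:2, 1)
      w0 <- polyclonal_base(n) * stats::runif(1, 0.05, 0.2)
      if (n_dom == 1) {
        i <- min(max(round((n + 1) / 2) + round(shift * 3.3), 1L), n)
        dom <- stats::runif(1, 0.45, 0.8)
        w0 <- w0 / sum(w0) * (1 - dom)
        w0[i] <- w0[i] + dom
      } else {
        i <- min(max(round(n / 2) + round(shift * 3.3), 1L), n - 1L)
        dom <- stats::runif(1, 0.65, 0.88)
        split <- stats::runif(1, 0.45, 0.55)
        w0 <- w0 / sum(w0) * (1 - dom)
        w0[i] <- w0[i] + dom * split
        w0[i + 1] <- w0[i + 1] + dom * (1 - split)
      }
      w0
    },
    stop("unknown clonality class label: ", class_label)
  )
  w <- w / sum(w)
  if (is.null(total_area)) total_area <- stats::rlnorm(1, log(2e5), 0.3)
  area <- w * total_area
  data.frame(
    fragment_size = size_offset + spacing * (pos - 1),
    height = area / 2.5,
    area = area
  )
}

#' Generate the cohort's spectratype peak table
#'
#' One profile per (subject, TRBV) from the subject's true class labels. The
#' subject's perturbation propensity scales both the within-class noise
#' amplitude (0.6-1.4x) and, more importantly, the positional shift of each
#' profile along the CDR3 ladder (alternating sign across TRBV subgroups,
#' magnitude `perturbation_shift_max * propensity`). The shift moves the
#' generalized Hamming distance monotonically with propensity while leaving
#' every clonality-class diagnostic untouched, so class mixes stay exactly as
#' configured while per-subject global perturbation varies with the clinical
#' covariates.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The [cohort_config()] used to generate the cohort.
#' @return Data frame of peak records (`sample_id`, `trbv`, `fragment_size`,
#'   `height`, `area`) with attribute `perturbation_truth`: subject x TRBV
#'   matrix of true perturbations (percent) of each generated distribution
#'   against the canonical polyclonal shape.
#' @export
generate_peak_table <- function(cohort, config) {
  trbvs <- trbv_subgroups()
  groups <- names(config$group_sizes)
  base <- polyclonal_base(8)
  rows <- vector("list", nrow(cohort$truth$clinical) * length(trbvs))
  truth_mat <- matrix(NA_real_, nrow(cohort$truth$clinical), length(trbvs),
                      dimnames = list(cohort$truth$clinical$subject_id, trbvs))
  k <- 0L
  for (r in seq_len(nrow(cohort$truth$clinical))) {
    sid <- cohort$truth$clinical$subject_id[r]
    g <- cohort$truth$clinical$group[r]
    gi <- match(g, groups)
    si <- as.integer(sub(".*_", "", sid))
    prop <- cohort$truth$clinical$propensity[r]
    amp <- 0.6 + 0.8 * prop
    for (t in seq_along(trbvs)) {
      # shift direction varies per (subject, TRBV) so the reference mean
      # stays centered and D grows monotonically with |shift|
      set.seed(subject_seed(config$seed, gi, si, stream = 200L + t))
      sgn <- sample(c(-1L, 1L), 1)
      prof <- generate_spectratype_profile(
        cohort$truth$classes[sid, trbvs[t]], n_lengths = 8,
        seed = subject_seed(config$seed, gi, si, stream = 1L + t),
        amplitude = amp, shift = sgn * config$perturbation_shift_max * prop,
        size_offset = 120 + 4 * t)
      prof$sample_id <- sid
      prof$trbv <- trbvs[t]
      k <- k + 1L
      rows[[k]] <- prof
      d <- normalize_distribution(prof)
      truth_mat[sid, trbvs[t]] <- if (d$detected) {
        50 * sum(abs(d$rel_area - base))
      } else NA_real_
    }
  }
  peaks <- do.call(rbind, rows)
  peaks <- peaks[, c("sample_id", "trbv", "fragment_size", "height", "area")]
  attr(peaks, "perturbation_truth") <- truth_mat
  peaks
}

#' Simulate a qPCR plate from known true quantities
#'
#' Emits standard wells (the 8-point 1:2 ladder from 21 ng for the telomere /
#' beta-globin assay; a 6-point 10-fold ladder from 1e6 copies for the
#' TREC/KREC duplex), triplicate sample wells and one no-template control per
#' target. Each well's Cq is `intercept + slope * log10(quantity) +
#' N(0, noise_sd)`.
#'
#' @param truth Data frame of true quantities: for `assay = "telomere"`
#'   columns `sample_id`, `ts_true`; for `assay = "excision"` columns
#'   `sample_id`, `trec_per_ml`, `krec_per_ml`.
#' @param assay "telomere" or "excision".
#' @param config A [cohort_config()] supplying curve parameters, noise SD,
#'   reference input mass and blood normalization.
#' @param seed Seed for the Cq noise.
#' @return Plate data frame (`well`, `target`, `role`, `replicate_group`,
#'   `quantity`, `cq`).
#' @export
generate_qpcr_plate <- function(truth, assay = c("telomere", "excision"),
                                config = cohort_config(), seed = 1) {
  assay <- match.arg(assay)
  if (!"sample_id" %in% names(truth) && "subject_id" %in% names(truth)) {
    truth$sample_id <- truth$subject_id
  }
  noise_sd <- config$qpcr_noise_sd
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cp <- config$curve_params
  for (tgt in names(cp)) {
    if (cp[[tgt]]["slope"] >= 0) stop("curve slope for ", tgt, " must be < 0")
  }
  set.seed(seed)
  cq_of <- function(target, quantity) {
    if (any(quantity <= 0)) stop("true quantities must be positive")
    cp[[target]]["intercept"] + cp[[target]]["slope"] * log10(quantity) +
      stats::rnorm(length(quantity), 0, noise_sd)
  }
  rows <- list()
  add <- function(target, role, group, quantity, cq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, role = role, replicate_group = group,
      quantity = quantity, cq = cq, stringsAsFactors = FALSE)
  }
  if (assay == "telomere") {
    targets <- c("TEL", "BG")
    ladder <- standard_ladder(21, 8, 2)
    stopifnot(all(c("sample_id", "ts_true") %in% names(truth)))
    for (tgt in targets) {
      add(tgt, "standard", paste0("STD_", tgt), ladder, cq_of(tgt, ladder))
    }
    for (i in seq_len(nrow(truth))) {
      t_ng <- truth$ts_true[i] * config$s_ng
      add("TEL", "sample", truth$sample_id[i], NA_real_,
          cq_of("TEL", rep(t_ng, 3)))
      add("BG", "sample", truth$sample_id[i], NA_real_,
          cq_of("BG", rep(config$s_ng, 3)))
    }
  } else {
    targets <- c("TREC", "KREC")
    ladder <- 10^(6:1)
    stopifnot(all(c("sample_id", "trec_per_ml", "krec_per_ml") %in% names(truth)))
    per_rxn <- config$cells_per_reaction / config$cells_per_ml
    for (tgt in targets) {
      add(tgt, "standard", paste0("STD_", tgt), ladder, cq_of(tgt, ladder))
    }
    for (i in seq_len(nrow(truth))) {
      add("TREC", "sample", truth$sample_id[i], NA_real_,
          cq_of("TREC", rep(truth$trec_per_ml[i] * per_rxn, 3)))
      add("KREC", "sample", truth$sample_id[i], NA_real_,
          cq_of("KREC", rep(truth$krec_per_ml[i] * per_rxn, 3)))
    }
  }
  for (tgt in targets) add(tgt, "ntc", paste0("NTC_", tgt), NA_real_, NA_real_)
  plate <- do.call(rbind, rows)
  plate$well <- sprintf("W%03d", seq_len(nrow(plate)))
  plate[, c("well", "target", "role", "replicate_group", "quantity", "cq")]
}

#' Write a complete simulated study to disk
#'
#' Writes the cohort metadata CSV, spectratype peak table TSV, telomere and
#' excision-circle plate CSVs, and the ground-truth JSON. Byte-identical for
#' a fixed configuration seed.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_study <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  peaks <- generate_peak_table(cohort, config)
  plate_tel <- generate_qpcr_plate(cohort$truth$clinical, "telomere", config,
                                   seed = subject_seed(config$seed, 0L, 0L, 2L))
  plate_exc <- generate_qpcr_plate(cohort$truth$clinical, "excision", config,
                                   seed = subject_seed(config$seed, 0L, 0L, 3L))
  paths <- list(
    cohort = file.path(outdir, "cohort.csv"),
    peaks = file.path(outdir, "peaks.tsv"),
    plate_telomere = file.path(outdir, "plate_telomere.csv"),
    plate_excision = file.path(outdir, "plate_excision.csv"),
    ground_truth = file.path(outdir, "ground_truth.json")
  )
  utils::write.csv(cohort$subjects, paths$cohort, row.names = FALSE)
  utils::write.table(peaks, paths$peaks, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(plate_tel, paths$plate_telomere, row.names = FALSE)
  utils::write.csv(plate_exc, paths$plate_excision, row.names = FALSE)
  truth <- list(
    clinical = cohort$truth$clinical,
    classes = as.data.frame(cohort$truth$classes),
    perturbation_truth = as.data.frame(attr(peaks, "perturbation_truth"))
  )
  jsonlite::write_json(truth, paths$ground_truth, digits = NA, pretty = TRUE)
  invisible(paths)
}
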