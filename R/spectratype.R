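#' The 23 TRBV subgroups resolved by the multiplex spectratyping assay
#'
#' IMGT nomenclature; the multiplex CDR3 spectratyping panel amplifies the 23
#' functional TRBV subgroups.
#'
#' @return Character vector of 23 subgroup names.
#' @export
trbv_subgroups <- function() {
  paste0("TRBV", c(2, 3, 4, 5, 6, 7, 9, 10, 11, 12, 13, 14, 15, 16,
                   18, 19, 20, 24, 25, 27, 28, 29, 30))
}

#' Parse a fragment-analysis peak table
#'
#' Reads a GeneMapper-export style TSV with columns `sample_id`, `trbv`,
#' `fragment_size`, `height`, `area`, validates TRBV names against the
#' 23-subgroup panel, and groups records per sample. Within each
#' (sample, trbv) the records are sorted by fragment size.
#'
#' @param path Path to the TSV file.
#' @return Named list (one element per sample) of data frames of peak records.
#' @export
parse_peak_table <- function(path) {
  peaks <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "trbv", "fragment_size", "height", "area")
  missing_c <- setdiff(need, names(peaks))
  if (length(missing_c) > 0) {
    stop("peak table format error: missing column(s) ",
         paste(missing_c, collapse = ", "))
  }
  if (nrow(peaks) == 0) {
    warning("peak table is empty")
    return(stats::setNames(list(), character(0)))
  }
  bad <- setdiff(unique(peaks$trbv), trbv_subgroups())
  if (length(bad) > 0) {
    stop("unknown TRBV subgroup(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(trbv_subgroups(), collapse = ", "))
  }
  if (any(peaks$area < 0)) stop("peak areas must be non-negative")
  peaks <- peaks[order(peaks$sample_id, peaks$trbv, peaks$fragment_size), ]
  split(peaks, peaks$sample_id)
}

#' Normalize one TRBV subgroup's peaks to a CDR3 length distribution
#'
#' Peaks whose area falls below `min_peak_frac` of the subgroup total are
#' treated as undetectable (zeroed); the remaining areas are renormalized to
#' sum to 1. A subgroup whose total area is below `min_total_area` is marked
#' undetected.
#'
#' @param peaks Data frame of peak records for a single TRBV subgroup
#'   (columns `fragment_size`, `area`), or a numeric vector of areas.
#' @param min_peak_frac Detectability floor as a fraction of total area.
#' @param min_total_area Total-area floor below which the subgroup is
#'   undetected.
#' @return An object of class `trbv_distribution`: `trbv`, `lengths`,
#'   `rel_area` (sums to 1 when detected), `detected`.
#' @export
normalize_distribution <- function(peaks, min_peak_frac = 0.02,
                                   min_total_area = 100) {
  if (is.numeric(peaks)) {
    peaks <- data.frame(fragment_size = seq_along(peaks), area = peaks)
  }
  trbv <- if ("trbv" %in% names(peaks)) peaks$trbv[1] else NA_character_
  if ("trbv" %in% names(peaks) && length(unique(peaks$trbv)) > 1) {
    stop("normalize_distribution expects peaks of a single TRBV subgroup")
  }
  ord <- order(peaks$fragment_size)
  lengths <- peaks$fragment_size[ord]
  area <- peaks$area[ord]
  if (anyDuplicated(lengths)) stop("duplicate fragment sizes within a subgroup")
  total <- sum(area)
  if (!is.finite(total) || total < min_total_area) {
    out <- list(trbv = trbv, lengths = lengths,
                rel_area = rep(NA_real_, length(area)), detected = FALSE)
    class(out) <- "trbv_distribution"
    return(out)
  }
  area[area < min_peak_frac * total] <- 0
  rel <- area / sum(area)
  out <- list(trbv = trbv, lengths = lengths, rel_area = rel, detected = TRUE)
  class(out) <- "trbv_distribution"
  out
}

#' Count detectable peaks in a CDR3 length distribution
#'
#' @param dist A `trbv_distribution` (or numeric vector of relative areas).
#' @return Number of ladder positions with positive relative area.
#' @export
count_peaks <- function(dist) {
  rel <- if (inherits(dist, "trbv_distribution")) {
    if (!dist$detected) stop("undefined peak count: subgroup undetected")
    dist$rel_area
  } else dist
  sum(rel > 0)
}

# Cache of discrete-Gaussian candidate grids, one per ladder length.
.gauss_grid_cache <- new.env(parent = emptyenv())

gauss_grid <- function(k) {
  key <- as.character(k)
  if (!is.null(.gauss_grid_cache[[key]])) return(.gauss_grid_cache[[key]])
  pos <- seq_len(k)
  mu <- seq(0.5, k + 0.5, by = 0.05)
  sigma <- seq(0.4, max(4, k / 2), by = 0.05)
  par <- expand.grid(mu = mu, sigma = sigma)
  G <- exp(-0.5 * outer(par$mu, pos, "-")^2 / par$sigma^2)
  grid <- list(par = par, G = G, Gss = rowSums(G^2))
  .gauss_grid_cache[[key]] <- grid
  grid
}

#' Goodness of a discrete-Gaussian fit to a CDR3 length distribution
#'
#' Least-squares fit of a three-parameter discrete Gaussian (amplitude, mean,
#' width) to the relative-area vector over the ladder positions; returns the
#' coefficient of determination R^2. Polyclonal (approximately Gaussian)
#' profiles score near 1.
#'
#' @param rel_area Relative-area vector over the ladder (zeros included).
#' @return R^2 of the best fit, in (-Inf, 1].
#' @export
gaussian_fit_score <- function(rel_area) {
  p <- as.numeric(rel_area)
  k <- length(p)
  if (k < 3) return(NA_real_)
  sst <- sum((p - mean(p))^2)
  if (sst == 0) return(0)
  grid <- gauss_grid(k)
  gp <- as.numeric(grid$G %*% p)
  # best amplitude per candidate shape: A* = <g,p>/<g,g>; residual SS follows
  ssr <- sum(p^2) - gp^2 / grid$Gss
  best <- which.min(ssr)
  # local refinement from the best grid point
  pos <- seq_len(k)
  obj <- function(th) {
    g <- exp(-0.5 * ((pos - th[1]) / max(th[2], 1e-6))^2)
    gg <- sum(g^2)
    if (gg < 1e-12) return(sum(p^2))
    sum(p^2) - sum(g * p)^2 / gg
  }
  opt <- stats::optim(c(grid$par$mu[best], grid$par$sigma[best]), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-10))
  1 - min(ssr[best], opt$value) / sst
}

#' Classify a CDR3 length distribution into the four clonality categories
#'
#' Decision order: (1) mono/oligoclonal if the largest peak holds at least
#' `top1` of the area or the two largest hold at least `top2`; else (2)
#' restricted if fewer than `min_peaks` detectable peaks; else (3) normal
#' (polyclonal) if the discrete-Gaussian fit R^2 reaches `gaussian_r2`,
#' otherwise shifted. Dominance is tested before the peak count so a 7-peak
#' profile with one towering peak is still called mono/oligoclonal.
#'
#' @param dist A `trbv_distribution` (or numeric relative-area vector).
#' @param top1,top2 Dominance thresholds for the mono/oligoclonal call.
#' @param min_peaks Minimum peak count of a normal/shifted profile.
#' @param gaussian_r2 R^2 threshold separating normal from shifted.
#' @return An object of class `profile_class`: `class` (one of "normal",
#'   "shifted", "restricted", "mono_oligoclonal") and `diagnostics`
#'   (`peak_count`, `gaussian_fit_score`, `top1_share`, `top2_share`).
#' @export
classify_profile <- function(dist, top1 = 0.40, top2 = 0.60,
                             min_peaks = 7, gaussian_r2 = 0.90) {
  rel <- if (inherits(dist, "trbv_distribution")) {
    if (!dist$detected) stop("cannot classify an undetected subgroup")
    dist$rel_area
  } else as.numeric(dist)
  srt <- sort(rel, decreasing = TRUE)
  t1 <- srt[1]
  t2 <- sum(srt[1:min(2, length(srt))])
  npk <- sum(rel > 0)
  gfs <- NA_real_
  cls <- if (t1 >= top1 || t2 >= top2) {
    "mono_oligoclonal"
  } else if (npk < min_peaks) {
    "restricted"
  } else {
    gfs <- gaussian_fit_score(rel)
    if (gfs >= gaussian_r2) "normal" else "shifted"
  }
  out <- list(class = cls,
              diagnostics = list(peak_count = npk, gaussian_fit_score = gfs,
                                 top1_share = t1, top2_share = t2))
  class(out) <- "profile_class"
  out
}

#' @export
print.profile_class <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("profile class: %s (peaks=%d, top1=%.2f, top2=%.2f, gaussR2=%s)\n",
              x$class, d$peak_count, d$top1_share, d$top2_share,
              if (is.na(d$gaussian_fit_score)) "-" else
                sprintf("%.3f", d$gaussian_fit_score)))
  invisible(x)
}

# Internal: align two distributions on the union of their ladders (absent = 0).
align_distributions <- function(dist, ref) {
  as_pair <- function(d) {
    if (inherits(d, "trbv_distribution")) list(l = d$lengths, p = d$rel_area)
    else list(l = seq_along(d), p = as.numeric(d))
  }
  a <- as_pair(dist); b <- as_pair(ref)
  lad <- sort(union(a$l, b$l))
  pa <- stats::setNames(numeric(length(lad)), lad)
  pb <- pa
  pa[as.character(a$l)] <- a$p
  pb[as.character(b$l)] <- b$p
  list(lengths = lad, p = pa, r = pb)
}

#' Generalized Hamming distance (perturbation) between CDR3 distributions
#'
#' The perturbation of a subject's CDR3 length distribution relative to a
#' reference mean distribution: half the summed absolute difference of the
#' relative-area vectors, in percent. 0 means identical, 100 means disjoint
#' supports (total-variation distance scaled to percent). Symmetric in its
#' arguments. Distributions on different ladders are aligned on the union of
#' positions with absent positions counted as 0.
#'
#' @param dist,ref_mean `trbv_distribution` objects or numeric relative-area
#'   vectors (same ladder assumed for plain vectors of equal length).
#' @return Perturbation in percent, in \[0, 100\].
#' @export
perturbation_score <- function(dist, ref_mean) {
  if (inherits(dist, "trbv_distribution") && !dist$detected) {
    stop("no perturbation score for an undetected subgroup")
  }
  if (!inherits(dist, "trbv_distribution") && !inherits(ref_mean, "trbv_distribution") &&
      length(dist) == length(ref_mean)) {
    return(50 * sum(abs(as.numeric(dist) - as.numeric(ref_mean))))
  }
  al <- align_distributions(dist, ref_mean)
  50 * sum(abs(al$p - al$r))
}

#' Build the healthy-control reference repertoire
#'
#' Draws `n_ref` reference subjects from the healthy-control pool (seeded,
#' since the assignment is a design choice), averages their per-TRBV relative
#' CDR3 length distributions, and then scores every healthy control
#' (reference members included) against the reference mean to obtain the
#' per-TRBV perturbation mean and SD used for mean+2SD / mean+3SD flagging.
#'
#' @param hc_profiles Named list: subject id -> named list of
#'   `trbv_distribution` objects (one per TRBV subgroup).
#' @param n_ref Number of reference subjects (default 12).
#' @param seed Seed for the reference-subject draw.
#' @return An object of class `reference_repertoire`: `ref_ids`,
#'   `mean_dist` (named list of `trbv_distribution`), `pert_mean`,
#'   `pert_sd` (named numeric per TRBV), `hc_scores` (matrix HC x TRBV).
#' @export
build_reference <- function(hc_profiles, n_ref = 12, seed = 1) {
  if (length(hc_profiles) < n_ref) {
    stop("need at least ", n_ref, " healthy-control subjects, got ",
         length(hc_profiles))
  }
  set.seed(seed)
  ref_ids <- sort(sample(names(hc_profiles), n_ref))
  trbvs <- Reduce(union, lapply(hc_profiles, names))
  mean_dist <- stats::setNames(vector("list", length(trbvs)), trbvs)
  for (tv in trbvs) {
    members <- Filter(function(p) !is.null(p[[tv]]) && p[[tv]]$detected,
                      hc_profiles[ref_ids])
    if (length(members) == 0) next
    lad <- sort(Reduce(union, lapply(members, function(p) p[[tv]]$lengths)))
    acc <- stats::setNames(numeric(length(lad)), lad)
    for (p in members) {
      d <- p[[tv]]
      acc[as.character(d$lengths)] <- acc[as.character(d$lengths)] + d$rel_area
    }
    md <- list(trbv = tv, lengths = lad, rel_area = unname(acc) / length(members),
               detected = TRUE)
    class(md) <- "trbv_distribution"
    mean_dist[[tv]] <- md
  }
  hc_scores <- matrix(NA_real_, nrow = length(hc_profiles), ncol = length(trbvs),
                      dimnames = list(names(hc_profiles), trbvs))
  for (sid in names(hc_profiles)) {
    for (tv in trbvs) {
      d <- hc_profiles[[sid]][[tv]]
      if (!is.null(d) && d$detected && !is.null(mean_dist[[tv]])) {
        hc_scores[sid, tv] <- perturbation_score(d, mean_dist[[tv]])
      }
    }
  }
  out <- list(
    ref_ids = ref_ids,
    mean_dist = mean_dist,
    pert_mean = apply(hc_scores, 2, mean, na.rm = TRUE),
    pert_sd = apply(hc_scores, 2, stats::sd, na.rm = TRUE),
    hc_scores = hc_scores
  )
  class(out) <- "reference_repertoire"
  out
}

#' Score one subject's repertoire against the reference
#'
#' @param profiles Named list of `trbv_distribution` objects for one subject.
#' @param reference A `reference_repertoire`.
#' @return Named numeric vector of per-TRBV perturbations (percent); NA for
#'   undetected subgroups.
#' @export
score_subject <- function(profiles, reference) {
  trbvs <- names(reference$mean_dist)
  vapply(trbvs, function(tv) {
    d <- profiles[[tv]]
    if (is.null(d) || !d$detected || is.null(reference$mean_dist[[tv]])) {
      return(NA_real_)
    }
    perturbation_score(d, reference$mean_dist[[tv]])
  }, numeric(1))
}

#' Flag over-perturbed TRBV subgroups for one subject
#'
#' A subgroup is flagged `over3sd` when its perturbation exceeds the
#' healthy-control mean + 3SD for that subgroup, else `over2sd` when it
#' exceeds the mean + 2SD; the comparisons are strict ("higher than").
#' `n_overperturbed` counts subgroups flagged at the 2SD level or beyond.
#'
#' @param d_scores Named per-TRBV perturbation vector (percent), as from
#'   [score_subject()].
#' @param reference A `reference_repertoire`.
#' @param sample_id Optional subject identifier.
#' @return An object of class `perturbation_result`: `per_trbv` data frame
#'   (trbv, d, flag), `global_perturbation` (mean D over evaluated
#'   subgroups), `n_evaluated`, `n_overperturbed`.
#' @export
flag_overperturbed <- function(d_scores, reference, sample_id = NA_character_) {
  trbvs <- names(d_scores)
  missing_ref <- trbvs[!is.na(d_scores) &
                         !(trbvs %in% names(reference$pert_mean))]
  if (length(missing_ref) > 0) {
    stop("no reference statistics for subgroup(s): ",
         paste(missing_ref, collapse = ", "))
  }
  m <- reference$pert_mean[trbvs]
  s <- reference$pert_sd[trbvs]
  flag <- ifelse(is.na(d_scores), NA_character_,
                 ifelse(d_scores > m + 3 * s, "over3sd",
                        ifelse(d_scores > m + 2 * s, "over2sd", "none")))
  out <- list(
    sample_id = sample_id,
    per_trbv = data.frame(trbv = trbvs, d = unname(d_scores),
                          flag = unname(flag), stringsAsFactors = FALSE),
    global_perturbation = mean(d_scores, na.rm = TRUE),
    n_evaluated = sum(!is.na(d_scores)),
    n_overperturbed = sum(flag %in% c("over2sd", "over3sd"))
  )
  class(out) <- "perturbation_result"
  out
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("perturbation [%s]: global %.2f%% over %d subgroups, %d over-perturbed\n",
              x$sample_id, x$global_perturbation, x$n_evaluated,
              x$n_overperturbed))
  invisible(x)
}

#' Summarize clonality categories and perturbation by group
#'
#' Pools classification calls over (subject x detected TRBV) units per group
#' and reports the proportion of each of the four categories, plus per-group
#' median and IQR of the subjects' global perturbation.
#'
#' @param class_df Data frame with columns `sample_id`, `trbv`, `class`.
#' @param pert_df Data frame with columns `sample_id`, `global_perturbation`.
#' @param groups Named character vector mapping sample_id -> group.
#' @return List with `category_proportions` (group x class, percent),
#'   `per_subject_nonnormal` (data frame), `perturbation_summary`
#'   (group, n, median, q1, q3).
#' @export
summarize_categories <- function(class_df, pert_df, groups) {
  class_df$group <- groups[class_df$sample_id]
  classes <- c("normal", "shifted", "restricted", "mono_oligoclonal")
  tab <- table(factor(class_df$group, levels = unique(groups)),
               factor(class_df$class, levels = classes))
  props <- 100 * prop.table(tab, margin = 1)
  nn <- do.call(rbind, lapply(split(class_df, class_df$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               n_detected = nrow(d),
               frac_nonnormal = mean(d$class != "normal"),
               stringsAsFactors = FALSE)
  }))
  rownames(nn) <- NULL
  ps <- NULL
  if (!is.null(pert_df)) {
    pert_df$group <- groups[pert_df$sample_id]
    ps <- do.call(rbind, lapply(split(pert_df, pert_df$group), function(d) {
      q <- stats::quantile(d$global_perturbation, c(0.25, 0.5, 0.75),
                           type = 6, names = FALSE)
      data.frame(group = d$group[1], n = nrow(d), median = q[2],
                 q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
    }))
    rownames(ps) <- NULL
  }
  list(category_proportions = props,
       per_subject_nonnormal = nn,
       perturbation_summary = ps)
}

#' Relative TRBV subgroup usage
#'
#' Per subject, each subgroup's share of the total area across the panel;
#' group-level medians per subgroup.
#'
#' @param peaks_by_sample Named list of peak-record data frames (one per
#'   sample), as returned by [parse_peak_table()].
#' @param groups Named character vector mapping sample_id -> group (optional).
#' @return List with `per_subject` (sample x TRBV share matrix) and
#'   `group_medians` (group x TRBV matrix, NULL without groups).
#' @export
trbv_usage <- function(peaks_by_sample, groups = NULL) {
  trbvs <- trbv_subgroups()
  shares <- t(vapply(peaks_by_sample, function(d) {
    tot <- tapply(d$area, factor(d$trbv, levels = trbvs), sum, default = 0)
    tot[is.na(tot)] <- 0
    as.numeric(tot) / sum(tot)
  }, numeric(length(trbvs))))
  colnames(shares) <- trbvs
  gm <- NULL
  if (!is.null(groups)) {
    g <- groups[rownames(shares)]
    gm <- apply(shares, 2, function(col) tapply(col, g, stats::median))
  }
  list(per_subject = shares, group_medians = gm)
}

#' Full repertoire analysis of a cohort peak table
#'
#' Normalizes every (subject, TRBV) peak set, classifies the profiles, builds
#' the healthy-control reference, scores perturbations and flags
#' over-perturbed subgroups.
#'
#' @param peaks_by_sample Named list of peak data frames per sample (from
#'   [parse_peak_table()]) .
#' @param groups Named character vector mapping sample_id -> group.
#' @param ref_group Group providing the reference pool (default "HC").
#' @param n_ref Reference-group size (default 12).
#' @param seed Seed for the reference-subject draw.
#' @param min_peak_frac,min_total_area Passed to [normalize_distribution()].
#' @return List with `profiles`, `classes` (data frame sample_id/trbv/class),
#'   `reference`, `perturbation` (list of `perturbation_result`),
#'   `per_subject` (data frame with global perturbation and counts).
#' @export
analyze_repertoire <- function(peaks_by_sample, groups, ref_group = "HC",
                               n_ref = 12, seed = 1,
                               min_peak_frac = 0.02, min_total_area = 100) {
  profiles <- lapply(peaks_by_sample, function(d) {
    ds <- lapply(split(d, d$trbv), normalize_distribution,
                 min_peak_frac = min_peak_frac, min_total_area = min_total_area)
    ds
  })
  class_rows <- list()
  for (sid in names(profiles)) {
    for (tv in names(profiles[[sid]])) {
      d <- profiles[[sid]][[tv]]
      if (!d$detected) next
      class_rows[[length(class_rows) + 1L]] <- data.frame(
        sample_id = sid, trbv = tv, class = classify_profile(d)$class,
        stringsAsFactors = FALSE)
    }
  }
  classes <- do.call(rbind, class_rows)
  hc_ids <- names(groups)[groups == ref_group]
  hc_ids <- intersect(hc_ids, names(profiles))
  reference <- build_reference(profiles[hc_ids], n_ref = n_ref, seed = seed)
  perturbation <- lapply(stats::setNames(names(profiles), names(profiles)),
                         function(sid) {
    flag_overperturbed(score_subject(profiles[[sid]], reference), reference,
                       sample_id = sid)
  })
  per_subject <- do.call(rbind, lapply(perturbation, function(p) {
    data.frame(sample_id = p$sample_id, group = unname(groups[p$sample_id]),
               global_perturbation = p$global_perturbation,
               n_evaluated = p$n_evaluated,
               n_overperturbed = p$n_overperturbed,
               stringsAsFactors = FALSE)
  }))
  rownames(per_subject) <- NULL
  list(profiles = profiles, classes = classes, reference = reference,
       perturbation = perturbation, per_subject = per_subject)
}

#' Fig.-4 style over-perturbation flag matrix
#'
#' @param perturbation List of `perturbation_result` objects.
#' @return Character matrix (subjects x TRBV) of none/over2sd/over3sd with
#'   attribute `row_sums` (per-subject over-perturbed counts) and `col_sums`
#'   (per-TRBV number of subjects flagged).
#' @export
flag_matrix <- function(perturbation) {
  trbvs <- perturbation[[1]]$per_trbv$trbv
  m <- t(vapply(perturbation, function(p) p$per_trbv$flag,
                character(length(trbvs))))
  colnames(m) <- trbvs
  rownames(m) <- vapply(perturbation, function(p) p$sample_id, character(1))
  attr(m, "row_sums") <- rowSums(m == "over2sd" | m == "over3sd", na.rm = TRUE)
  attr(m, "col_sums") <- colSums(m == "over2sd" | m == "over3sd", na.rm = TRUE)
  m
}
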