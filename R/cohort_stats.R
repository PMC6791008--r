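#' Dunn's post-hoc pairwise rank test
#'
#' Tie-corrected Dunn z-tests on the pooled ranks, with multiplicity
#' adjustment (Bonferroni by default, matching the Prism workflow the
#' omnibus test mirrors).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.character(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- sort(names(rbar))
  pairs <- utils::combn(gl, 2)
  res <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ng[[pr[1]]] + 1 / ng[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Compare a variable across groups (Kruskal-Wallis + Dunn)
#'
#' Kruskal-Wallis H test with tie correction; when the omnibus p-value is at
#' or below `alpha` and there are more than two groups, Dunn's pairwise
#' z-tests with corrected p-values are added. With exactly two groups the
#' omnibus p-value itself is the reported comparison.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param alpha Significance level gating the post-hoc tests (default 0.05).
#' @param variable Variable name carried through to the result.
#' @param p_adjust Post-hoc adjustment method (default "bonferroni").
#' @return An object of class `group_comparison`: `variable`, `summary`
#'   (per-group n/median/IQR), `kw_h`, `kw_df`, `kw_p`, `pairwise` (data
#'   frame or NULL).
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           variable = NA_character_, p_adjust = "bonferroni") {
  groups <- as.character(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  ng <- table(groups)
  if (length(ng) < 2) stop("need at least 2 groups")
  if (any(ng < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(ng)[ng < 2], collapse = ", "))
  }
  if (stats::var(values) == 0) {
    # degenerate case: every observation tied; no evidence of any difference
    kw <- list(statistic = c(H = 0), parameter = c(df = length(ng) - 1),
               p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
  }
  summ <- do.call(rbind, lapply(split(values, groups), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  pairwise <- NULL
  if (length(ng) > 2 && is.finite(kw$p.value) && kw$p.value <= alpha) {
    pairwise <- dunn_posthoc(values, groups, p_adjust)
  }
  out <- list(variable = variable, summary = summ,
              kw_h = unname(kw$statistic), kw_df = unname(kw$parameter),
              kw_p = kw$p.value, alpha = alpha, pairwise = pairwise)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis [%s]: H = %.3f (df %d), p = %.4g\n",
              x$variable, x$kw_h, x$kw_df, x$kw_p))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-8s n=%-3d median %.4g (IQR %.4g-%.4g)\n",
                s$group, s$n, s$median, s$q1, s$q3))
  }
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      p <- x$pairwise[i, ]
      cat(sprintf("  Dunn %s vs %s: z = %.3f, adj. p = %.4g\n",
                  p$group1, p$group2, p$z, p$p_adj))
    }
  }
  invisible(x)
}

#' Pearson correlations, optionally per stratum
#'
#' @param x,y Paired numeric vectors.
#' @param strata Optional stratum labels (e.g. group or gender); one result
#'   per stratum, plus "all" when strata are absent.
#' @return Data frame with `stratum`, `n`, `r`, `p`, `defined` (FALSE when a
#'   variable has zero variance within the stratum).
#' @export
correlate <- function(x, y, strata = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(strata)) strata <- rep("all", length(x))
  do.call(rbind, lapply(split(seq_along(x), strata), function(idx) {
    xi <- x[idx]; yi <- y[idx]
    ok <- is.finite(xi) & is.finite(yi)
    xi <- xi[ok]; yi <- yi[ok]
    if (length(xi) < 3) stop("need n >= 3 per stratum for correlation")
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) {
      return(data.frame(stratum = strata[idx][1], n = length(xi),
                        r = NA_real_, p = NA_real_, defined = FALSE))
    }
    ct <- stats::cor.test(xi, yi, method = "pearson")
    data.frame(stratum = strata[idx][1], n = length(xi),
               r = unname(ct$estimate), p = ct$p.value, defined = TRUE,
               stringsAsFactors = FALSE)
  }))
}

#' Table-1 style cohort summary
#'
#' Medians and IQRs (the (n+1) percentile convention) for continuous
#' variables, counts and percentages for categorical ones, and pairwise
#' between-group p-values: unpaired t-test for continuous variables, Fisher
#' exact test for categorical ones.
#'
#' @param metadata Cohort metadata data frame; must contain `subject_id`,
#'   `group`, and the variables to summarize.
#' @param continuous Names of continuous columns.
#' @param categorical Names of categorical columns.
#' @return List with `continuous` (variable/group/n/median/q1/q3),
#'   `categorical` (variable/level/group/count/pct) and `tests`
#'   (variable/group1/group2/test/p).
#' @export
summarize_table1 <- function(metadata,
                             continuous = c("age", "cd4_abs", "cd4_pct",
                                            "cd8_abs", "cd8_pct",
                                            "cd4_cd8_ratio"),
                             categorical = "gender") {
  need <- c("subject_id", "group", continuous, categorical)
  missing_c <- setdiff(need, names(metadata))
  if (length(missing_c) > 0) {
    stop("metadata format error: missing column(s) ",
         paste(missing_c, collapse = ", "))
  }
  gl <- unique(metadata$group)
  cont <- do.call(rbind, lapply(continuous, function(v) {
    do.call(rbind, lapply(gl, function(g) {
      vals <- metadata[[v]][metadata$group == g]
      q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
      data.frame(variable = v, group = g, n = length(vals),
                 median = q[2], q1 = q[1], q3 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  cat_rows <- do.call(rbind, lapply(categorical, function(v) {
    tab <- table(metadata$group, metadata[[v]])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("group", "level", "count")
    df$variable <- v
    df$pct <- 100 * df$count / as.numeric(table(metadata$group)[df$group])
    df[, c("variable", "level", "group", "count", "pct")]
  }))
  pairs <- utils::combn(gl, 2)
  tests <- do.call(rbind, apply(pairs, 2, function(pr) {
    sub <- metadata[metadata$group %in% pr, ]
    rows <- lapply(continuous, function(v) {
      p <- tryCatch(
        stats::t.test(sub[[v]][sub$group == pr[1]],
                      sub[[v]][sub$group == pr[2]])$p.value,
        error = function(e) NA_real_)
      data.frame(variable = v, group1 = pr[1], group2 = pr[2],
                 test = "t", p = p, stringsAsFactors = FALSE)
    })
    rows_c <- lapply(categorical, function(v) {
      tab <- table(sub$group, sub[[v]])
      p <- if (all(dim(tab) >= 2)) stats::fisher.test(tab)$p.value else NA_real_
      data.frame(variable = v, group1 = pr[1], group2 = pr[2],
                 test = "fisher", p = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, rows_c))
  }))
  list(continuous = cont, categorical = cat_rows, tests = tests)
}

#' Compare the per-subject fraction of non-normal TRBV subgroups across groups
#'
#' For each subject, the within-patient proportion of detected TRBV subgroups
#' whose profile is shifted, restricted or mono/oligoclonal (pooled, i.e.
#' anything but normal polyclonal) is compared across groups with the
#' Kruskal-Wallis/Dunn machinery.
#'
#' @param class_df Data frame with columns `sample_id`, `trbv`, `class`.
#' @param groups Named character vector mapping sample_id -> group.
#' @param alpha Significance level for the post-hoc gate.
#' @return A `group_comparison` on the per-subject non-normal fraction, with
#'   the per-subject values attached as attribute `per_subject`.
#' @export
category_proportion_test <- function(class_df, groups, alpha = 0.05) {
  per <- lapply(split(class_df, class_df$sample_id), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(sample_id = d$sample_id[1],
               frac_nonnormal = mean(d$class != "normal"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  skipped <- setdiff(names(groups), per$sample_id)
  if (length(skipped) > 0) {
    warning("subject(s) with zero detected subgroups excluded: ",
            paste(skipped, collapse = ", "))
  }
  per$group <- groups[per$sample_id]
  out <- compare_groups(per$frac_nonnormal, per$group, alpha = alpha,
                        variable = "frac_nonnormal")
  attr(out, "per_subject") <- per
  out
}
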