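#' Serial-dilution standard ladder
#'
#' Quantities of a serial dilution standard curve, e.g. the telomere /
#' beta-globin reference ladder of eight 1:2 dilutions starting at 21 ng per
#' well (ending at 0.1640625 ng).
#'
#' @param top Quantity of the most concentrated standard (ng or copies).
#' @param n Number of dilution points.
#' @param factor Dilution factor between consecutive points.
#' @return Numeric vector of length `n`, decreasing.
#' @export
standard_ladder <- function(top = 21, n = 8, factor = 2) {
  stopifnot(top > 0, n >= 1, factor > 1)
  top / factor^(seq_len(n) - 1)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(known quantity) for the standard
#' wells of one target. The amplification efficiency is derived from the
#' slope.
#'
#' @param quantity Known quantities of the standard wells (ng or copies).
#' @param cq Quantification cycles for the same wells.
#' @param target Target label carried through to the result (e.g. "TEL").
#' @return An object of class `standard_curve` with elements `target`,
#'   `slope` (cycles per log10 quantity), `intercept` (cycles), `r2`,
#'   `efficiency_pct` and `range` (quantity range spanned by the standards).
#' @export
fit_standard_curve <- function(quantity, cq, target = NA_character_) {
  if (is.data.frame(quantity)) {
    df <- quantity
    if (is.na(target) && "target" %in% names(df)) target <- df$target[1]
    cq <- df$cq
    quantity <- df$quantity
  }
  keep <- is.finite(quantity) & is.finite(cq)
  quantity <- quantity[keep]
  cq <- cq[keep]
  if (length(unique(quantity)) < 3) {
    stop("insufficient standards: need >= 3 distinct dilution points, got ",
         length(unique(quantity)))
  }
  if (any(quantity <= 0)) stop("standard quantities must be positive")
  x <- log10(quantity)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop("assay failure: fitted standard-curve slope is non-negative (",
         format(slope), "); Cq must decrease with input quantity")
  }
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  out <- list(
    target = target,
    slope = slope,
    intercept = intercept,
    r2 = r2,
    efficiency_pct = efficiency_from_slope(slope),
    range = range(quantity)
  )
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve [%s]\n", x$target))
  cat(sprintf("  slope %.4f cycles/log10, intercept %.3f, r^2 %.4f\n",
              x$slope, x$intercept, x$r2))
  cat(sprintf("  efficiency %.2f%%, standards %g-%g\n",
              x$efficiency_pct, x$range[1], x$range[2]))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' Efficiency (percent per cycle) is `100 * (10^(-1/slope) - 1)`; a slope of
#' -3.3219 cycles per log10 corresponds to perfect doubling (100%).
#'
#' @param slope Standard-curve slope in cycles per log10 quantity (negative).
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stop("slope must be finite and negative, got ", paste(slope, collapse = ", "))
  }
  100 * (10^(-1 / slope) - 1)
}

#' Interpolate input quantity from a Cq value
#'
#' Inverts the standard curve: `quantity = 10^((cq - intercept) / slope)`.
#' Results more than one log10 outside the standards' range are flagged with
#' an `extrapolated` attribute (a warning flag, not an error).
#'
#' @param curve A `standard_curve`.
#' @param cq Quantification cycle(s).
#' @return Quantity on the standards' scale (ng or copies), with attribute
#'   `extrapolated` (logical vector).
#' @export
interpolate_quantity <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((cq - curve$intercept) / curve$slope)
  lo <- curve$range[1] / 10
  hi <- curve$range[2] * 10
  attr(q, "extrapolated") <- !is.na(q) & (q < lo | q > hi)
  q
}

#' Replicate coefficient-of-variation quality control
#'
#' CV is computed on interpolated quantities with the sample (n-1) standard
#' deviation. A replicate group is accepted iff CV <= threshold; the
#' rejection rule is strict (> threshold rejects, equality passes).
#'
#' @param values Interpolated quantities of one replicate group.
#' @param threshold_pct Acceptance threshold in percent (default 15).
#' @param replicate_group Optional label.
#' @return An object of class `replicate_qc` with `n`, `mean`, `sd`,
#'   `cv_pct`, `accepted`.
#' @export
replicate_qc <- function(values, threshold_pct = 15, replicate_group = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    stop("insufficient replicates: need >= 2 finite values, got ", length(values))
  }
  if (any(values <= 0)) stop("replicate quantities must be positive")
  m <- mean(values)
  s <- stats::sd(values)
  cv <- 100 * s / m
  out <- list(
    replicate_group = replicate_group,
    n = length(values),
    mean = m,
    sd = s,
    cv_pct = cv,
    accepted = cv <= threshold_pct
  )
  class(out) <- "replicate_qc"
  out
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat(sprintf("replicate QC [%s]: n=%d mean=%.4g CV=%.2f%% -> %s\n",
              x$replicate_group, x$n, x$mean, x$cv_pct,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Check no-template controls for contamination
#'
#' A no-template control with a detectable Cq below the cutoff indicates
#' plate contamination and aborts quantification.
#'
#' @param plate Plate data frame (see [read_qpcr_plate()]).
#' @param cutoff Cq below which an NTC signal is treated as contamination.
#' @return Invisibly `TRUE`; stops on contamination.
#' @export
check_ntc <- function(plate, cutoff = 38) {
  ntc <- plate[plate$role == "ntc", , drop = FALSE]
  bad <- is.finite(ntc$cq) & ntc$cq < cutoff
  if (any(bad)) {
    stop("plate contaminated: no-template control well(s) ",
         paste(ntc$well[bad], collapse = ", "),
         " amplified at Cq < ", cutoff)
  }
  invisible(TRUE)
}

# Internal: fit curves for the requested targets from a plate's standard wells.
plate_curves <- function(plate, targets) {
  missing_t <- setdiff(targets, unique(plate$target))
  if (length(missing_t) > 0) {
    stop("plate format error: missing target(s) ", paste(missing_t, collapse = ", "))
  }
  lapply(stats::setNames(targets, targets), function(tg) {
    std <- plate[plate$role == "standard" & plate$target == tg, , drop = FALSE]
    if (nrow(std) == 0) stop("plate format error: no standards for target ", tg)
    fit_standard_curve(std$quantity, std$cq, target = tg)
  })
}

# Internal: interpolated quantities of one sample's replicate wells on a curve.
sample_quantities <- function(plate, curve, sample_id) {
  w <- plate[plate$role == "sample" & plate$target == curve$target &
               plate$replicate_group == sample_id, , drop = FALSE]
  if (nrow(w) == 0) {
    stop("plate format error: no sample wells for ", sample_id,
         " / target ", curve$target)
  }
  as.numeric(interpolate_quantity(curve, w$cq))
}

#' Compute the telomere T/S ratio for one sample
#'
#' T is the amount (ng) of reference DNA matching the sample's telomere
#' signal, S the amount matching its beta-globin (single copy gene) signal;
#' both are the median of the replicate interpolations and each replicate
#' group must pass CV quality control. T/S is their ratio.
#'
#' @param plate Plate data frame containing TEL and BG standards and the
#'   sample's triplicate wells for both targets.
#' @param sample_id Replicate-group identifier of the sample.
#' @param threshold_pct Replicate CV acceptance threshold (percent).
#' @param ntc_cutoff Cq cutoff for no-template control contamination.
#' @return An object of class `ts_result` with `sample_id`, `t_ng`, `s_ng`,
#'   `ts_ratio` (NA when invalid), `valid`, and QC records `qc_t`, `qc_s`.
#' @export
compute_ts_ratio <- function(plate, sample_id, threshold_pct = 15, ntc_cutoff = 38) {
  check_ntc(plate, ntc_cutoff)
  curves <- plate_curves(plate, c("TEL", "BG"))
  qt <- sample_quantities(plate, curves$TEL, sample_id)
  qs <- sample_quantities(plate, curves$BG, sample_id)
  qc_t <- replicate_qc(qt, threshold_pct, paste0(sample_id, "/TEL"))
  qc_s <- replicate_qc(qs, threshold_pct, paste0(sample_id, "/BG"))
  valid <- qc_t$accepted && qc_s$accepted
  t_ng <- stats::median(qt)
  s_ng <- stats::median(qs)
  out <- list(
    sample_id = sample_id,
    t_ng = t_ng,
    s_ng = s_ng,
    ts_ratio = if (valid) t_ng / s_ng else NA_real_,
    valid = valid,
    qc_t = qc_t,
    qc_s = qc_s,
    curves = curves
  )
  class(out) <- "ts_result"
  out
}

#' @export
print.ts_result <- function(x, ...) {
  cat(sprintf("T/S [%s]: %s (T=%.4g ng, S=%.4g ng; CV %.1f%%/%.1f%%)%s\n",
              x$sample_id,
              if (x$valid) sprintf("%.4f", x$ts_ratio) else "invalid",
              x$t_ng, x$s_ng, x$qc_t$cv_pct, x$qc_s$cv_pct,
              if (x$valid) "" else " [replicate CV > threshold]"))
  invisible(x)
}

#' Quantify TREC and KREC copies per ml of blood
#'
#' Interpolates copies per reaction for both excision-circle targets from the
#' same duplex plate and scales to copies/ml of blood:
#' `copies/ml = copies_per_reaction * cells_per_ml / cells_per_reaction`.
#' A target whose replicate group fails CV quality control is reported as
#' absent (`NA`) with the reason, not as zero.
#'
#' @param plate Plate data frame with TREC and KREC standards (copies) and
#'   the sample's triplicate wells.
#' @param sample_id Replicate-group identifier of the sample.
#' @param cells_per_ml Blood cell concentration used for normalization
#'   (cells per ml).
#' @param cells_per_reaction Cell equivalents of DNA per reaction.
#' @param threshold_pct Replicate CV acceptance threshold (percent).
#' @param ntc_cutoff Cq cutoff for no-template control contamination.
#' @return An object of class `excision_circle_result` with
#'   `trec_copies_per_ml`, `krec_copies_per_ml`, QC records and reasons.
#' @export
quantify_excision_circles <- function(plate, sample_id,
                                      cells_per_ml, cells_per_reaction,
                                      threshold_pct = 15, ntc_cutoff = 38) {
  if (missing(cells_per_ml) || missing(cells_per_reaction) ||
      !is.finite(cells_per_ml) || !is.finite(cells_per_reaction) ||
      cells_per_ml <= 0 || cells_per_reaction <= 0) {
    stop("configuration error: blood normalization factors (cells_per_ml, ",
         "cells_per_reaction) must be positive")
  }
  check_ntc(plate, ntc_cutoff)
  curves <- plate_curves(plate, c("TREC", "KREC"))
  scale <- cells_per_ml / cells_per_reaction
  one <- function(tg) {
    q <- sample_quantities(plate, curves[[tg]], sample_id)
    qc <- replicate_qc(q, threshold_pct, paste0(sample_id, "/", tg))
    list(
      qc = qc,
      value = if (qc$accepted) stats::median(q) * scale else NA_real_,
      reason = if (qc$accepted) NA_character_ else
        sprintf("replicate CV %.1f%% > %.1f%%", qc$cv_pct, threshold_pct)
    )
  }
  trec <- one("TREC")
  krec <- one("KREC")
  out <- list(
    sample_id = sample_id,
    trec_copies_per_ml = trec$value,
    krec_copies_per_ml = krec$value,
    qc_trec = trec$qc,
    qc_krec = krec$qc,
    reason_trec = trec$reason,
    reason_krec = krec$reason,
    curves = curves
  )
  class(out) <- "excision_circle_result"
  out
}

#' @export
print.excision_circle_result <- function(x, ...) {
  fmt <- function(v, r) if (is.na(v)) paste0("absent (", r, ")") else sprintf("%.0f", v)
  cat(sprintf("excision circles [%s]: TREC %s, KREC %s copies/ml\n",
              x$sample_id,
              fmt(x$trec_copies_per_ml, x$reason_trec),
              fmt(x$krec_copies_per_ml, x$reason_krec)))
  invisible(x)
}

#' Read a qPCR plate CSV
#'
#' Expected columns: `well`, `target` (TEL|BG|TREC|KREC|REF), `role`
#' (standard|sample|ntc|internal_control), `replicate_group`, `quantity`
#' (known ng or copies; NA for samples and NTCs) and `cq`.
#'
#' @param path Path to the CSV file.
#' @return Plate data frame.
#' @export
read_qpcr_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "target", "role", "replicate_group", "quantity", "cq")
  missing_c <- setdiff(need, names(plate))
  if (length(missing_c) > 0) {
    stop("plate format error: missing column(s) ", paste(missing_c, collapse = ", "))
  }
  plate
}
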