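#' Quality-control thresholds for a screening plate
#'
#' @param responsiveness_min_ratio minimum raw DMSO / positive-control
#'   mean phospho-tau intensity ratio for a plate to count as responsive
#'   (default 1.3).
#' @param ci_level confidence level of the field-exclusion bound
#'   (default 0.95).
#' @param toxicity_max_decrease maximum tolerated fractional decrease of
#'   neurite area before a compound is flagged neurotoxic (default 0.20).
#' @param positive_control_dose nominal dose of the reference inhibitor in
#'   positive-control wells (micromolar; default 11).
#' @param ci_method `"percentile"` (empirical lower tail quantile of the
#'   field values; default) or `"mean"` (lower bound of the t-based CI of
#'   the mean). The percentile bound excludes only the outlying low-area
#'   tail; the mean bound sits just below the group mean and removes a
#'   large fraction of ordinary fields once n is moderate.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(responsiveness_min_ratio = 1.3,
                          ci_level = 0.95,
                          toxicity_max_decrease = 0.20,
                          positive_control_dose = 11,
                          ci_method = c("percentile", "mean")) {
  ci_method <- match.arg(ci_method)
  stopifnot(responsiveness_min_ratio > 1,
            ci_level > 0, ci_level < 1,
            toxicity_max_decrease > 0, toxicity_max_decrease < 1)
  structure(list(responsiveness_min_ratio = responsiveness_min_ratio,
                 ci_level = ci_level,
                 toxicity_max_decrease = toxicity_max_decrease,
                 positive_control_dose = positive_control_dose,
                 ci_method = ci_method),
            class = "qc_thresholds")
}

#' Plate responsiveness check
#'
#' A plate is responsive when the ratio of raw (un-normalized) mean
#' phospho-tau neurite intensity, DMSO fields over positive-control
#' fields, reaches the responsiveness threshold; unresponsive plates are
#' excluded from analysis.
#'
#' @param dmso_values,pos_values raw `mean_ptau_neurite` field values of
#'   the DMSO and positive-control groups.
#' @param thresholds a [qc_thresholds()].
#' @return list: `responsive` (logical) and `ratio`.
#' @export
plate_responsiveness <- function(dmso_values, pos_values,
                                 thresholds = qc_thresholds()) {
  dmso_values <- dmso_values[is.finite(dmso_values)]
  pos_values <- pos_values[is.finite(pos_values)]
  if (!length(dmso_values) || !length(pos_values)) stop("missing control")
  ratio <- mean(dmso_values) / mean(pos_values)
  list(responsive = ratio >= thresholds$responsiveness_min_ratio,
       ratio = ratio)
}

#' Lower confidence bound used for field exclusion
#'
#' Lower bound of the t-based confidence interval of the mean:
#' `mean - t_{(1+level)/2, n-1} * SD / sqrt(n)`. With
#' `method = "percentile"` the empirical `(1-level)/2` quantile is used
#' instead.
#'
#' @param values numeric measurements (n >= 2).
#' @param level confidence level (default 0.95).
#' @param method `"mean"` or `"percentile"`.
#' @return the lower bound.
#' @export
ci_lower <- function(values, level = 0.95, method = c("mean", "percentile")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("insufficient fields")
  if (method == "percentile")
    return(quantile(values, (1 - level) / 2, names = FALSE))
  mean(values) - qt((1 + level) / 2, df = n - 1) * sd(values) / sqrt(n)
}

#' Apply per-field quality-control rules to a plate
#'
#' Rule b: within each well, fields with `neurite_area` below the lower
#' confidence bound of that well's field areas are excluded. Rule c:
#' fields with `neurite_area` below the lower confidence bound of all DMSO
#' fields on the plate are excluded. Both rules are evaluated on the
#' original (pre-exclusion) field set and the union of exclusions is
#' taken, so the rules commute. Degenerate fields (empty quantification
#' regions) are excluded with reason `degenerate`.
#'
#' @param metrics per-field metrics data.frame with columns `well_id`,
#'   `field_index`, `neurite_area`, `excluded`, and a `kind` column
#'   naming each well's treatment.
#' @param thresholds a [qc_thresholds()].
#' @return list: `metrics` (input with `qc_excluded`, `qc_reason` added)
#'   and `counts` (exclusions per rule).
#' @export
apply_field_qc <- function(metrics, thresholds = qc_thresholds()) {
  m <- metrics
  m$qc_excluded <- FALSE
  m$qc_reason <- ""
  degen <- m$excluded | !is.finite(m$neurite_area)
  add_reason <- function(reason, hit) {
    m$qc_excluded[hit] <<- TRUE
    m$qc_reason[hit] <<- ifelse(m$qc_reason[hit] == "", reason,
                                paste(m$qc_reason[hit], reason, sep = ";"))
  }
  add_reason("degenerate", degen)
  # rule b: within-well bound, on the original field set
  for (w in unique(m$well_id)) {
    iw <- which(m$well_id == w & !degen)
    if (length(iw) < 2) next
    bound <- ci_lower(m$neurite_area[iw], thresholds$ci_level,
                      thresholds$ci_method)
    add_reason("within_well_ci", iw[m$neurite_area[iw] < bound])
  }
  # rule c: plate DMSO bound, on the original field set
  idmso <- which(m$kind == "dmso" & !degen)
  if (length(idmso) >= 2) {
    bound_c <- ci_lower(m$neurite_area[idmso], thresholds$ci_level,
                        thresholds$ci_method)
    ii <- which(!degen)
    add_reason("dmso_ci", ii[m$neurite_area[ii] < bound_c])
  }
  counts <- c(degenerate = sum(grepl("degenerate", m$qc_reason)),
              within_well_ci = sum(grepl("within_well_ci", m$qc_reason)),
              dmso_ci = sum(grepl("dmso_ci", m$qc_reason)))
  list(metrics = m, counts = counts)
}

#' Fold change of field values against the pooled DMSO reference
#'
#' Each field value is divided by the mean of the plate's pooled DMSO
#' reference values, so DMSO itself normalizes to mean 1 by construction.
#'
#' @param values per-field measurements of one well/treatment.
#' @param dmso_reference pooled DMSO field values of the plate.
#' @return per-field fold changes.
#' @export
fold_change_vs_dmso <- function(values, dmso_reference) {
  dmso_reference <- dmso_reference[is.finite(dmso_reference)]
  if (!length(dmso_reference)) stop("invalid reference")
  ref <- mean(dmso_reference)
  if (!is.finite(ref) || ref <= 0) stop("invalid reference")
  values / ref
}

#' Z'-factor screening-window statistic
#'
#' `1 - 3 (SD_pos + SD_neg) / |mean_pos - mean_neg|`, computed on
#' well-level means (one value per control well).
#'
#' @param positive,negative well-level values of the positive and
#'   negative control groups (each n >= 2).
#' @return dimensionless score (1 is a perfect assay window).
#' @export
z_factor <- function(positive, negative) {
  positive <- positive[is.finite(positive)]
  negative <- negative[is.finite(negative)]
  if (length(positive) < 2 || length(negative) < 2)
    stop("need >= 2 wells per group")
  delta <- abs(mean(positive) - mean(negative))
  if (delta == 0) stop("zero dynamic range")
  1 - 3 * (sd(positive) + sd(negative)) / delta
}

#' Neurotoxicity flag from the neurite-area fold change
#'
#' A compound is neurotoxic when it decreases total neurite area by more
#' than `toxicity_max_decrease` (default: > 20% decrease, i.e. fold
#' change below 0.8).
#'
#' @param area_fold_change neurite-area fold change vs DMSO.
#' @param thresholds a [qc_thresholds()].
#' @return logical.
#' @export
flag_toxicity <- function(area_fold_change, thresholds = qc_thresholds()) {
  area_fold_change < 1 - thresholds$toxicity_max_decrease
}

#' Call screening hits against the positive-control effect
#'
#' A compound is a hit when its phospho-tau fold change lies below the
#' positive-control fold change in BOTH the cell-body and the neurite
#' compartment, it is not neurotoxic, and it passed QC. Compounds active
#' in the neurite compartment only are reported as neurite-selective, not
#' as hits.
#'
#' @param table data.frame with per-compound columns `fold_ptau_neurite`,
#'   `fold_ptau_soma`, `toxic`, `qc_pass`.
#' @param control_fold list/vector with elements `neurite` and `soma`:
#'   positive-control fold changes per compartment.
#' @return input with `hit` and `neurite_selective` logical columns.
#' @export
call_hits <- function(table, control_fold) {
  below_n <- !is.na(table$fold_ptau_neurite) &
    table$fold_ptau_neurite < control_fold[["neurite"]]
  below_s <- !is.na(table$fold_ptau_soma) &
    table$fold_ptau_soma < control_fold[["soma"]]
  ok <- !table$toxic & table$qc_pass
  table$hit <- below_n & below_s & ok
  table$neurite_selective <- below_n & !below_s & ok
  table
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(dose)) * hill))`
#' (the log(agonist)-vs-response, variable-slope family), with
#' multi-start initialization over Hill slopes and the observed log-dose
#' range.
#'
#' @param doses concentrations (> 0), at least 4 distinct values.
#' @param responses responses (fold changes), same length.
#' @param top_bounds,bottom_bounds box constraints; defaults keep `top`
#'   in `[0.5, 1.5]` and `bottom >= 0` for fold-change responses.
#' @return object of class `dose_response_fit`: `top`, `bottom`,
#'   `log_ic50`, `ic50`, `hill_slope`, `residual_sse`, `converged`,
#'   `n_points`.
#' @export
fit_dose_response <- function(doses, responses,
                              top_bounds = c(0.5, 1.5),
                              bottom_bounds = c(0, Inf)) {
  stopifnot(length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4) stop("need >= 4 distinct doses")
  if (sd(responses) == 0) stop("no dose dependence")
  x <- log10(doses)
  f4pl <- function(x, top, bottom, log_ic50, hill)
    bottom + (top - bottom) / (1 + 10 ^ ((log_ic50 - x) * hill))
  lower <- c(top = top_bounds[1], bottom = bottom_bounds[1],
             log_ic50 = min(x) - 3, hill = -10)
  upper <- c(top = top_bounds[2], bottom = bottom_bounds[2],
             log_ic50 = max(x) + 3, hill = 10)
  top0 <- min(max(max(responses), top_bounds[1]), top_bounds[2])
  bot0 <- min(max(min(responses), bottom_bounds[1]), bottom_bounds[2])
  starts <- expand.grid(log_ic50 = seq(min(x), max(x), length.out = 5),
                        hill = c(-2, -1, -0.5, 0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ f4pl(x, top, bottom, log_ic50, hill),
        start = list(top = top0, bottom = bot0,
                     log_ic50 = starts$log_ic50[i], hill = starts$hill[i]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          log_ic50 = NA_real_, ic50 = NA_real_,
                          hill_slope = NA_real_, residual_sse = NA_real_,
                          converged = FALSE, n_points = length(doses)),
                     class = "dose_response_fit"))
  cf <- stats::coef(best$fit)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 log_ic50 = unname(cf["log_ic50"]),
                 ic50 = 10 ^ unname(cf["log_ic50"]),
                 hill_slope = unname(cf["hill"]),
                 residual_sse = best$sse,
                 converged = TRUE, n_points = length(doses)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: top %.4g, bottom %.4g, logIC50 %.4g ",
                     "(IC50 %.4g), hill %.4g, SSE %.3g, n=%d%s\n"),
              x$top, x$bottom, x$log_ic50, x$ic50, x$hill_slope,
              x$residual_sse, x$n_points,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Run the full screen analysis on a plate of field metrics
#'
#' Plate responsiveness (rule a), per-field QC (rules b and c), pooled
#' DMSO normalization of mean phospho-tau per compartment and of neurite
#' area, well/compound summaries with SEM, Z'-factors (well-level means,
#' for mean phospho-tau and the phospho/total ratio in both
#' compartments), toxicity flags, and hit calls against the
#' positive-control effect.
#'
#' @param metrics per-field metrics with treatment columns (`kind`,
#'   `compound_id`, `dose`), e.g. from [simulate_plate_metrics()].
#' @param thresholds a [qc_thresholds()].
#' @return list of class `screen_result`: `qc` (responsiveness + per-rule
#'   counts + flagged metrics), `wells` (per-well summaries),
#'   `screen_table` (per compound x dose with fold changes, SEM, toxicity,
#'   hit and selectivity flags), `z_factors`, `control_fold`.
#' @export
run_screen <- function(metrics, thresholds = qc_thresholds()) {
  resp <- plate_responsiveness(
    metrics$mean_ptau_neurite[metrics$kind == "dmso"],
    metrics$mean_ptau_neurite[metrics$kind == "positive_control"],
    thresholds)
  qc <- apply_field_qc(metrics, thresholds)
  # intensity measures use fully QC-passed fields; the neurite-area fold
  # change (health/toxicity readout) is computed before the area-based
  # exclusion rules, on all non-degenerate fields, since those rules would
  # otherwise remove exactly the fields a toxic compound produces
  ok_area <- !grepl("degenerate", qc$metrics$qc_reason)
  m_area <- qc$metrics[ok_area, , drop = FALSE]
  m <- qc$metrics[!qc$metrics$qc_excluded, , drop = FALSE]

  dmso <- m[m$kind == "dmso", ]
  dmso_area_ref <- m_area$neurite_area[m_area$kind == "dmso"]
  fold_cols <- c(fold_ptau_neurite = "mean_ptau_neurite",
                 fold_ptau_soma = "mean_ptau_soma",
                 fold_ratio_neurite = "ratio_ptau_ttau_neurite",
                 fold_ratio_soma = "ratio_ptau_ttau_soma")
  for (fc in names(fold_cols))
    m[[fc]] <- fold_change_vs_dmso(m[[fold_cols[fc]]],
                                   dmso[[fold_cols[fc]]])
  m_area$fold_area <- fold_change_vs_dmso(m_area$neurite_area, dmso_area_ref)

  # well-level means of fold changes
  wells <- lapply(split(m_area, m_area$well_id), function(wa) {
    w <- m[m$well_id == wa$well_id[1], , drop = FALSE]
    out <- data.frame(well_id = wa$well_id[1], kind = wa$kind[1],
                      compound_id = wa$compound_id[1], dose = wa$dose[1],
                      n_fields_used = nrow(w), stringsAsFactors = FALSE)
    for (fc in names(fold_cols)) {
      out[[fc]] <- if (nrow(w)) mean(w[[fc]]) else NA_real_
      out[[paste0(fc, "_sem")]] <- if (nrow(w) >= 2)
        sd(w[[fc]]) / sqrt(nrow(w)) else NA_real_
    }
    out$fold_area <- mean(wa$fold_area)
    out$fold_area_sem <- if (nrow(wa) >= 2)
      sd(wa$fold_area) / sqrt(nrow(wa)) else NA_real_
    out
  })
  wells <- do.call(rbind, wells)
  rownames(wells) <- NULL

  zf <- function(col) {
    pos <- wells[[col]][wells$kind == "positive_control"]
    neg <- wells[[col]][wells$kind == "dmso"]
    tryCatch(z_factor(pos, neg), error = function(e) NA_real_)
  }
  z_factors <- c(mean_ptau_neurite = zf("fold_ptau_neurite"),
                 mean_ptau_soma = zf("fold_ptau_soma"),
                 ratio_ptau_ttau_neurite = zf("fold_ratio_neurite"),
                 ratio_ptau_ttau_soma = zf("fold_ratio_soma"))

  pos_wells <- wells[wells$kind == "positive_control", ]
  control_fold <- c(neurite = mean(pos_wells$fold_ptau_neurite),
                    soma = mean(pos_wells$fold_ptau_soma))

  cmp <- wells[wells$kind == "compound", ]
  tab <- NULL
  if (nrow(cmp)) {
    tab <- lapply(split(cmp, paste(cmp$compound_id, cmp$dose)), function(g) {
      data.frame(compound_id = g$compound_id[1], dose = g$dose[1],
                 n_wells = nrow(g),
                 fold_ptau_neurite = mean(g$fold_ptau_neurite, na.rm = TRUE),
                 fold_ptau_neurite_sem = if (nrow(g) >= 2)
                   sd(g$fold_ptau_neurite) / sqrt(nrow(g)) else
                     g$fold_ptau_neurite_sem[1],
                 fold_ptau_soma = mean(g$fold_ptau_soma, na.rm = TRUE),
                 fold_ptau_soma_sem = if (nrow(g) >= 2)
                   sd(g$fold_ptau_soma) / sqrt(nrow(g)) else
                     g$fold_ptau_soma_sem[1],
                 fold_area = mean(g$fold_area),
                 qc_pass = TRUE, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tab)
    rownames(tab) <- NULL
    tab$toxic <- flag_toxicity(tab$fold_area, thresholds)
    tab$qc_pass <- tab$qc_pass & resp$responsive
    tab <- call_hits(tab, control_fold)
    tab <- tab[order(tab$fold_ptau_neurite), ]  # waterfall order
    rownames(tab) <- NULL
  }

  structure(list(qc = list(responsive = resp$responsive,
                           ratio = resp$ratio, counts = qc$counts,
                           metrics = qc$metrics),
                 wells = wells, screen_table = tab,
                 z_factors = z_factors, control_fold = control_fold),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: plate %s (DMSO/positive ratio %.3f)\n",
              if (x$qc$responsive) "responsive" else "UNRESPONSIVE",
              x$qc$ratio))
  cat("  field exclusions:",
      paste(names(x$qc$counts), x$qc$counts, sep = "=", collapse = ", "),
      "\n")
  cat("  Z'-factors:",
      paste(names(x$z_factors), sprintf("%.3f", x$z_factors),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$screen_table))
    cat(sprintf("  %d compounds: %d hits, %d neurite-selective, %d toxic\n",
                nrow(x$screen_table), sum(x$screen_table$hit),
                sum(x$screen_table$neurite_selective),
                sum(x$screen_table$toxic)))
  invisible(x)
}
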