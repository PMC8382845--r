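#' Mean intensity over a compartment mask
#'
#' Total channel intensity over the mask pixels divided by the mask pixel
#' count (field-level pooled-pixel mean, matching the total-over-total-area
#' construction of the assay's mean intensities).
#'
#' @param channel numeric intensity matrix.
#' @param mask logical (or 0/1, or label) matrix on the same grid.
#' @return intensity per pixel, or `NA_real_` for an empty mask (an empty
#'   compartment is undefined, never zero).
#' @export
compartment_mean <- function(channel, mask) {
  if (!all(dim(channel) == dim(mask))) stop("mask geometry mismatch")
  m <- mask > 0
  n <- sum(m)
  if (n == 0) return(NA_real_)
  sum(channel[m]) / n
}

#' Per-field compartment metrics
#'
#' Computes the raw per-field measures from finalized masks: compartment
#' areas, total and mean intensities of phospho-tau and total tau in the
#' neurite field and in cell bodies, the phospho/total mean-intensity
#' ratios, and the neuronal cell count. Neurite measures use the neurite
#' quantification mask (cell bodies and clumps subtracted); cell-body
#' measures use soma quantification labels (neurite crossings and clumps
#' subtracted). A field whose neurite or soma quantification region is
#' empty is flagged `excluded` with a reason code, since its means are
#' undefined.
#'
#' @param field a [field_image()].
#' @param masks a `segmentation_masks` object ([segment_field()]).
#' @return one-row data.frame (class `field_metrics`).
#' @export
field_metrics <- function(field, masks) {
  nmask <- masks$neurite_quant_mask
  smask <- masks$soma_quant_labels > 0
  ptau <- field$channels$p_tau
  ttau <- field$channels$total_tau
  n_area <- sum(nmask)
  s_area <- sum(smask)
  tp_n <- sum(ptau[nmask]); tt_n <- sum(ttau[nmask])
  tp_s <- sum(ptau[smask]); tt_s <- sum(ttau[smask])
  mp_n <- if (n_area > 0) tp_n / n_area else NA_real_
  mt_n <- if (n_area > 0) tt_n / n_area else NA_real_
  mp_s <- if (s_area > 0) tp_s / s_area else NA_real_
  mt_s <- if (s_area > 0) tt_s / s_area else NA_real_
  n_cells <- if (is.null(masks$nuclei)) NA_integer_ else
    sum(masks$nuclei$class == "neuronal_live")
  excluded <- n_area == 0 || s_area == 0
  reason <- if (!excluded) "" else "degenerate"
  data.frame(well_id = field$well_id, field_index = field$field_index,
             neurite_area = n_area, soma_area = s_area,
             total_ptau_neurite = tp_n, total_ptau_soma = tp_s,
             total_ttau_neurite = tt_n, total_ttau_soma = tt_s,
             mean_ptau_neurite = mp_n, mean_ptau_soma = mp_s,
             mean_ttau_neurite = mt_n, mean_ttau_soma = mt_s,
             ratio_ptau_ttau_neurite =
               if (n_area > 0 && mt_n > 0) mp_n / mt_n else NA_real_,
             ratio_ptau_ttau_soma =
               if (s_area > 0 && mt_s > 0) mp_s / mt_s else NA_real_,
             n_neuronal_cells = n_cells,
             excluded = excluded, exclude_reason = reason,
             stringsAsFactors = FALSE)
}

METRIC_COLS <- c("neurite_area", "soma_area",
                 "total_ptau_neurite", "total_ptau_soma",
                 "total_ttau_neurite", "total_ttau_soma",
                 "mean_ptau_neurite", "mean_ptau_soma",
                 "mean_ttau_neurite", "mean_ttau_soma",
                 "ratio_ptau_ttau_neurite", "ratio_ptau_ttau_soma",
                 "n_neuronal_cells")

#' Aggregate field metrics to a well summary
#'
#' Per-metric mean, SD and usable-field count over the non-excluded fields
#' of one well. SD is `NA` (flagged, not fabricated) when fewer than two
#' usable fields exist; a well with zero usable fields is flagged
#' unusable.
#'
#' @param fields data.frame of [field_metrics()] rows, one well.
#' @return one-row data.frame with `<metric>_mean`, `<metric>_sd` columns,
#'   `n_fields_used`, `n_fields_excluded`, `usable`.
#' @export
aggregate_well <- function(fields) {
  stopifnot(length(unique(fields$well_id)) <= 1)
  use <- fields[!fields$excluded, , drop = FALSE]
  out <- data.frame(well_id = if (nrow(fields)) fields$well_id[1] else NA,
                    n_fields_used = nrow(use),
                    n_fields_excluded = nrow(fields) - nrow(use),
                    usable = nrow(use) > 0,
                    stringsAsFactors = FALSE)
  for (mcol in intersect(METRIC_COLS, names(fields))) {
    v <- use[[mcol]]
    out[[paste0(mcol, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(mcol, "_sd")]] <- if (length(v) >= 2) sd(v) else NA_real_
  }
  out
}
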