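# shared fixtures and oracles for the suite

iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# quick simulator config for unit tests (desk-scale field)
small_cfg <- function(seed = 1, ...) {
  synth_field_config(grid_shape = c(192L, 192L), n_neurons = 5L,
                     n_nonneuronal = 3L, n_dead = 2L, clump_fraction = 0,
                     seed = seed, ...)
}

# per-label centroids of a label grid, rows = label id as character
label_centroids <- function(lab) {
  nr <- nrow(lab)
  ii <- which(lab > 0)
  if (!length(ii)) return(matrix(numeric(0), ncol = 2))
  t(sapply(split(ii, lab[ii]),
           function(v) c(mean((v - 1) %% nr + 1), mean((v - 1) %/% nr + 1))))
}

# soma detection F1 against truth, matching objects at IoU >= 0.5;
# somata sitting mostly inside a clump are excluded on both sides since
# the pipeline deliberately removes clumped regions from quantification
soma_f1_counts <- function(masks, truth) {
  slabs <- setdiff(unique(as.integer(masks$soma_labels)), 0L)
  tlabs <- setdiff(unique(as.integer(truth$soma_labels)), 0L)
  tout <- Filter(function(l) {
    m <- truth$soma_labels == l
    sum(m) > 0 && mean(truth$clump_mask[m]) < 0.5
  }, tlabs)
  sout <- Filter(function(l) {
    m <- masks$soma_labels == l
    mean(masks$clump_mask[m]) < 0.5
  }, slabs)
  tp <- 0L
  for (tl in tout) {
    tm <- truth$soma_labels == tl
    best <- 0
    for (sl in sout) best <- max(best, iou(masks$soma_labels == sl, tm))
    if (best >= 0.5) tp <- tp + 1L
  }
  c(tp = tp, n_seg = length(sout), n_truth = length(tout))
}

# classify each truth nucleus by the segmentation object at its centroid
truth_class_map <- function(masks, truth) {
  cen <- label_centroids(truth$nucleus_labels)
  out <- data.frame(label = as.integer(rownames(cen)),
                    truth_class = truth$nucleus_classes$class[
                      match(as.integer(rownames(cen)),
                            truth$nucleus_classes$label)],
                    seg_class = NA_character_,
                    in_clump = FALSE)
  for (k in seq_len(nrow(cen))) {
    r <- round(cen[k, 1]); c <- round(cen[k, 2])
    out$in_clump[k] <- truth$clump_mask[r, c]
    sl <- masks$nucleus_labels[r, c]
    out$seg_class[k] <- if (sl == 0) "undetected" else
      masks$nuclei$class[masks$nuclei$label == sl]
  }
  out
}

# a minimal plate-metrics table for screen statistics, no imaging involved
toy_plate_metrics <- function(n_fields = 5, dmso_mean = 300, pos_mean = 200,
                              area = 4000, seed = 1) {
  set.seed(seed)
  rows <- list()
  add_well <- function(well, kind, cid, dose, mu) {
    for (f in seq_len(n_fields) - 1L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        well_id = well, kind = kind, compound_id = cid, dose = dose,
        field_index = f, neurite_area = area + rnorm(1, 0, area * 0.01),
        soma_area = area / 4,
        mean_ptau_neurite = mu * (1 + rnorm(1, 0, 0.02)),
        mean_ptau_soma = mu * (1 + rnorm(1, 0, 0.02)),
        mean_ttau_neurite = 350, mean_ttau_soma = 350,
        ratio_ptau_ttau_neurite = mu / 350,
        ratio_ptau_ttau_soma = mu / 350,
        excluded = FALSE, stringsAsFactors = FALSE)
    }
  }
  add_well("A1", "dmso", NA, NA, dmso_mean)
  add_well("A2", "dmso", NA, NA, dmso_mean)
  add_well("A3", "positive_control", NA, 11, pos_mean)
  add_well("A4", "positive_control", NA, 11, pos_mean)
  do.call(rbind, rows)
}
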