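#' Segmentation parameters
#'
#' Tunables of the field segmentation pipeline. Intensity cutoffs are
#' relative (to robust image statistics), never absolute counts, so the
#' pipeline is invariant to global gain changes; the up-to-three
#' `global_intensity_adjustments` are the only run-to-run knobs and
#' multiply the nucleus-edge, soma and neurite cutoffs respectively.
#'
#' @param edge_gradient_threshold nucleus edge cutoff as a fraction of the
#'   99.9th percentile of the DNA gradient magnitude.
#' @param min_object_area px^2; smaller detected objects are debris.
#' @param nucleus_area_range px^2 interval for live (intact) nuclei.
#' @param dead_area_max px^2; dead nuclei are significantly smaller.
#' @param dead_intensity_min multiple of the median live-nucleus DNA mean a
#'   dead nucleus must exceed (dead nuclei are significantly brighter).
#' @param dead_solidity_max solidity cutoff; dead nuclei have rugged,
#'   non-convex outlines.
#' @param soma_area_range px^2 interval for accepted cell bodies.
#' @param soma_intensity_factor soma pixels must exceed this multiple of
#'   the channel median in both the tubulin and total-tau channels.
#' @param soma_contiguity_min required fraction of soma pixels carrying
#'   contiguous tubulin AND total-tau signal.
#' @param soma_max_radius px; growth limit from the nucleus.
#' @param neurite_iterations number of extraction passes (default 10).
#' @param cutoff_schedule per-pass relative cutoffs, non-increasing, length
#'   `neurite_iterations`; default geometric relaxation 1 -> 0.4.
#' @param contrast_base base neurite cutoff in robust noise SDs of the
#'   ridge response.
#' @param major_width,minor_width expected neurite stroke widths (px).
#' @param gap_max_length px; maximum endpoint gap bridged.
#' @param gap_angle_tol radians; tangential agreement required to bridge.
#' @param minor_contrast_min minimum segment-mean / local-background-mean
#'   ratio for a detached (minor) segment to be kept.
#' @param minor_min_length px of skeleton; shorter detached segments drop.
#' @param clump_nucleus_count_min nuclei merged in one high-DNA region
#'   that constitute a clump.
#' @param clump_area_factor single objects larger than this multiple of
#'   the top of `nucleus_area_range` also count as clumps.
#' @param clump_dna_factor clump region cutoff as fraction of the median
#'   live-nucleus DNA mean.
#' @param clump_dilate px margin added around detected clumps.
#' @param global_intensity_adjustments named multipliers (at most 3:
#'   `nucleus`, `soma`, `neurite`) on the corresponding cutoffs.
#' @return object of class `seg_params`.
#' @export
seg_params <- function(edge_gradient_threshold = 0.2,
                       min_object_area = 25,
                       nucleus_area_range = c(150, 600),
                       dead_area_max = 100,
                       dead_intensity_min = 1.5,
                       dead_solidity_max = 0.85,
                       soma_area_range = c(200, 4000),
                       soma_intensity_factor = 3,
                       soma_contiguity_min = 0.6,
                       soma_max_radius = 20,
                       neurite_iterations = 10L,
                       cutoff_schedule = NULL,
                       contrast_base = 20,
                       major_width = 3L,
                       minor_width = 1L,
                       gap_max_length = 8,
                       gap_angle_tol = 0.35,
                       minor_contrast_min = 1.2,
                       minor_min_length = 15,
                       clump_nucleus_count_min = 3L,
                       clump_area_factor = 1.3,
                       clump_dna_factor = 0.3,
                       clump_dilate = 8,
                       global_intensity_adjustments =
                         c(nucleus = 1, soma = 1, neurite = 1)) {
  if (neurite_iterations < 1L) stop("neurite_iterations must be >= 1")
  if (is.null(cutoff_schedule))
    cutoff_schedule <- if (neurite_iterations == 1L) 1 else
      0.4 ^ ((seq_len(neurite_iterations) - 1) / (neurite_iterations - 1))
  if (length(cutoff_schedule) != neurite_iterations)
    stop("cutoff_schedule length must equal neurite_iterations")
  if (any(diff(cutoff_schedule) > 1e-12))
    stop("cutoff_schedule must be non-increasing")
  if (dead_area_max >= min(nucleus_area_range))
    stop("dead_area_max must lie below nucleus_area_range")
  if (length(global_intensity_adjustments) > 3L)
    stop("at most 3 global intensity adjustments are allowed")
  structure(as.list(environment()), class = "seg_params")
}

## ---- small image utilities ---------------------------------------------

mat <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

box_brush <- function(n) EBImage::makeBrush(n, shape = "box")
disc_brush <- function(n) EBImage::makeBrush(if (n %% 2) n else n + 1, "disc")

gsmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  mat(EBImage::gblur(m, sigma = sigma))
}

grad_mag <- function(m) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- mat(EBImage::filter2(m, kx))
  gy <- mat(EBImage::filter2(m, t(kx)))
  sqrt(gx^2 + gy^2)
}

# exact 8-connectivity labeling: 4-connected labels united across diagonals
label8 <- function(m) {
  lab <- mat(EBImage::bwlabel(m * 1))
  n <- max(lab)
  if (n <= 1L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
                 cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, numeric(1))
  map <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbor_count <- function(m) {
  s <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) s <- s + shift_mat(m, dr, dc)
  s
}

# Zhang-Suen thinning, vectorized over the grid
skeletonize <- function(m) {
  m <- m * 1L
  storage.mode(m) <- "integer"
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1L & b >= 2 & b <= 6 & a == 1
      cond <- cond & if (step == 1)
        (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

## ---- nuclei -------------------------------------------------------------

# convex hull area measured as rasterized pixel count so solidity <= 1
hull_solidity <- function(rows, cols, nr, nc) {
  if (length(rows) < 3) return(1)
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts)
  hull_px <- length(poly_idx(pts[h, 1], pts[h, 2], nr, nc))
  # pixels ON the hull boundary are part of the object but may fall outside
  # the even-odd interior; count the hull vertices' pixels in
  hull_px <- max(hull_px, length(rows))
  min(1, length(rows) / hull_px)
}

#' Detect and classify nuclei on the DNA channel
#'
#' Candidate nuclei are found by gradient-magnitude edge detection (Sobel
#' on a lightly smoothed DNA grid), closure and filling of the edge
#' contours, and 8-connectivity labeling. Each object is then refined to
#' its half-maximum intensity support, on which area, mean DNA intensity
#' and solidity are measured. Classification follows object-level mean
#' intensity rather than global thresholding: an object is `dead_excluded`
#' when it is small (`area <= dead_area_max`), bright (`dna_mean >=
#' dead_intensity_min x` the median DNA mean of area-qualified live
#' candidates) and rugged (`solidity <= dead_solidity_max`); otherwise it
#' is provisionally live.
#'
#' @param field a [field_image()].
#' @param params a [seg_params()].
#' @return list: `labels` (integer grid) and `nuclei` (data.frame with
#'   label, area, dna_mean, solidity, class).
#' @export
detect_nuclei <- function(field, params = seg_params()) {
  dna <- field$channels$dna
  nr <- nrow(dna); nc <- ncol(dna)
  s <- gsmooth(dna, 1.5)
  g <- grad_mag(s)
  adj <- params$global_intensity_adjustments[["nucleus"]] %|na|% 1
  q_top <- quantile(g, 0.999, names = FALSE)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      dna_mean = numeric(0), solidity = numeric(0),
                      class = character(0), row = numeric(0), col = numeric(0))
  # a field with real nuclei shows edge responses far above the gradient
  # noise scale; blank or pure-noise fields do not and yield no objects
  if (q_top <= 8 * mad(g))
    return(list(labels = matrix(0L, nr, nc), nuclei = empty))
  thr <- params$edge_gradient_threshold * q_top * adj
  edges <- g > thr
  if (!any(edges))
    return(list(labels = matrix(0L, nr, nc), nuclei = empty))
  closed <- mat(EBImage::fillHull(mat(EBImage::dilate(edges * 1, box_brush(3)))))
  obj <- mat(EBImage::erode(closed, box_brush(3))) > 0
  lab0 <- label8(obj)
  if (max(lab0) == 0)
    return(list(labels = matrix(0L, nr, nc), nuclei = empty))

  # per-object refinement happens on a lightly smoothed grid so that the
  # rugged outline of dead nuclei survives measurement
  sf <- gsmooth(dna, 0.5)
  bg <- median(sf)
  idx <- which(lab0 > 0)
  by_lab <- split(idx, lab0[idx])
  labels <- matrix(0L, nr, nc)
  recs <- list()
  next_lab <- 0L
  for (li in names(by_lab)) {
    ii <- by_lab[[li]]
    if (length(ii) < params$min_object_area) next
    # refine to the half-maximum support of this object's own intensity
    lev <- quantile(sf[ii], 0.9, names = FALSE)
    keep <- ii[sf[ii] >= bg + 0.5 * (lev - bg)]
    if (length(keep) < params$min_object_area) next
    next_lab <- next_lab + 1L
    labels[keep] <- next_lab
    rows <- (keep - 1L) %% nr + 1L
    cols <- (keep - 1L) %/% nr + 1L
    recs[[next_lab]] <- data.frame(
      label = next_lab, area = length(keep),
      dna_mean = mean(dna[keep]),
      solidity = hull_solidity(rows, cols, nr, nc),
      class = "live", row = mean(rows), col = mean(cols))
  }
  if (!length(recs))
    return(list(labels = matrix(0L, nr, nc), nuclei = empty))
  nuclei <- do.call(rbind, recs)
  qualified <- nuclei$area >= params$nucleus_area_range[1] &
    nuclei$area <= params$nucleus_area_range[2]
  med_live <- if (any(qualified)) median(nuclei$dna_mean[qualified]) else
    median(nuclei$dna_mean)
  dead <- nuclei$area <= params$dead_area_max &
    nuclei$dna_mean >= params$dead_intensity_min * med_live &
    nuclei$solidity <= params$dead_solidity_max
  nuclei$class[dead] <- "dead_excluded"
  list(labels = labels, nuclei = nuclei)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## ---- cell bodies --------------------------------------------------------

#' Segment neuronal cell bodies around live nuclei
#'
#' A soma is grown from each live nucleus into surrounding pixels where
#' both the tubulin and the total-tau channels exceed their cutoffs
#' contiguously, within `soma_max_radius` of the nucleus; competing nuclei
#' split contested territory by proximity ([EBImage::propagate()]).
#' Objects outside `soma_area_range`, or whose grown region lacks the
#' required fraction of dual-channel signal, emit no soma and their
#' nucleus is classed non-neuronal.
#'
#' @inheritParams detect_nuclei
#' @param nucleus_labels,nuclei output of [detect_nuclei()].
#' @return list: `soma_labels` (labels match nucleus labels) and updated
#'   `nuclei` (classes `neuronal_live` / `nonneuronal` resolved).
#' @export
segment_cell_bodies <- function(field, nucleus_labels, nuclei,
                                params = seg_params()) {
  nr <- nrow(nucleus_labels); nc <- ncol(nucleus_labels)
  soma <- matrix(0L, nr, nc)
  if (!nrow(nuclei)) return(list(soma_labels = soma, nuclei = nuclei))
  live <- nuclei$label[nuclei$class == "live"]
  if (!length(live)) {
    nuclei$class[nuclei$class == "live"] <- "nonneuronal"
    return(list(soma_labels = soma, nuclei = nuclei))
  }
  tub <- field$channels$tubulin
  tau <- field$channels$total_tau
  adj <- params$global_intensity_adjustments[["soma"]] %|na|% 1
  cut_t <- params$soma_intensity_factor * median(tub) * adj
  cut_k <- params$soma_intensity_factor * median(tau) * adj
  candidate <- tub >= cut_t & tau >= cut_k
  # open at a scale wider than a neurite so somata keep their body shape
  # but bright strokes cannot be claimed as cell-body territory
  body <- mat(EBImage::opening(candidate * 1,
                               disc_brush(2 * params$major_width + 1))) > 0

  seeds <- nucleus_labels
  seeds[!nucleus_labels %in% live] <- 0L
  allowed <- mat(EBImage::dilate((seeds > 0) * 1,
                                 disc_brush(2 * params$soma_max_radius + 1))) > 0
  grow_mask <- (body | seeds > 0) & allowed
  labs <- mat(EBImage::propagate(gsmooth(tub, 1), seeds = seeds,
                                 mask = grow_mask))
  storage.mode(labs) <- "integer"

  idx <- which(labs > 0)
  by_lab <- split(idx, labs[idx])
  for (li in names(by_lab)) {
    lab <- as.integer(li)
    ii <- by_lab[[li]]
    a <- length(ii)
    frac <- mean(candidate[ii])
    ok <- a >= params$soma_area_range[1] && a <= params$soma_area_range[2] &&
      frac >= params$soma_contiguity_min
    if (ok) {
      soma[ii] <- lab
      nuclei$class[nuclei$label == lab] <- "neuronal_live"
    } else {
      nuclei$class[nuclei$label == lab] <- "nonneuronal"
    }
  }
  nuclei$class[nuclei$class == "live"] <- "nonneuronal"
  list(soma_labels = soma, nuclei = nuclei)
}

## ---- neurites -----------------------------------------------------------

# grayscale top-hat; EBImage morphology expects intensities in [0, 1]
gray_tophat <- function(m, brush) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  mat(EBImage::whiteTopHat(m / mx, brush)) * mx
}

# no pre-smoothing: thin strokes keep their exact width and the robust
# cutoff absorbs pixel noise
neurite_response <- function(field, params) {
  im <- pmax(field$channels$tubulin, field$channels$total_tau,
             field$channels$p_tau)
  brush <- disc_brush(2 * (params$major_width + 2) + 1)
  list(response = gray_tophat(im, brush), smooth = im)
}

#' Iteratively extract the total neurite mask
#'
#' A ridge response ("localized shift in signal intensity": white top-hat
#' at the neurite scale) is computed on the per-pixel maximum of the
#' tubulin, total-tau and phospho-tau channels. Over `neurite_iterations`
#' passes with a non-increasing cutoff schedule, pass k thresholds the
#' response at `cutoff_schedule[k] * contrast_base` robust noise SDs and
#' keeps only candidate pixels 8-connected to the mask accumulated so far
#' or to a soma. Early passes catch bright/thick major neurites; later,
#' laxer passes recover dim/thin minor neurites and improve path
#' continuity. The accumulated mask grows monotonically with pass number.
#'
#' @inheritParams detect_nuclei
#' @param soma_labels soma label grid (seeds path continuity; not
#'   subtracted here).
#' @return logical matrix: total neurite mask (pre-subtraction).
#' @export
extract_neurite_mask <- function(field, soma_labels, params = seg_params()) {
  resp <- neurite_response(field, params)$response
  adj <- params$global_intensity_adjustments[["neurite"]] %|na|% 1
  sigma <- max(mad(resp), 1e-9)
  base_cut <- params$contrast_base * sigma * adj
  acc <- matrix(FALSE, nrow(resp), ncol(resp))
  seeds <- soma_labels > 0
  for (k in seq_len(params$neurite_iterations)) {
    cand <- resp >= params$cutoff_schedule[k] * base_cut
    pool <- cand | acc
    if (!any(pool)) next
    lab <- label8(pool)
    keep_labs <- unique(lab[(acc | seeds) & lab > 0])
    if (!length(keep_labs)) next
    acc <- pool & matrix(lab %in% keep_labs, nrow(lab), ncol(lab))
  }
  acc
}

#' Test detached neurite segments against local background
#'
#' Fine-tuning step separating true (minor) neurite segments from
#' antibody-dependent background: every connected segment of the candidate
#' mask that does not touch a soma is kept only if its mean intensity is at
#' least `minor_contrast_min` times the local background mean (an annulus
#' around the segment) and its skeleton is at least `minor_min_length`
#' pixels long.
#'
#' @inheritParams extract_neurite_mask
#' @param mask candidate neurite mask from [extract_neurite_mask()].
#' @return logical matrix: retained mask.
#' @export
test_neurite_segments <- function(mask, field, soma_labels,
                                  params = seg_params()) {
  if (!any(mask)) return(mask)
  im <- pmax(field$channels$tubulin, field$channels$total_tau,
             field$channels$p_tau)
  lab <- label8(mask)
  soma_touch <- mat(EBImage::dilate((soma_labels > 0) * 1, box_brush(3))) > 0
  attached <- unique(lab[soma_touch & lab > 0])
  detached <- setdiff(seq_len(max(lab)), attached)
  if (!length(detached)) return(mask)
  skel <- skeletonize(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(lab > 0)
  by_lab <- split(idx, lab[idx])
  for (li in detached) {
    ii <- by_lab[[as.character(li)]]
    seg <- matrix(FALSE, nr, nc)
    seg[ii] <- TRUE
    ring <- mat(EBImage::dilate(seg * 1, disc_brush(9))) > 0 & !mask &
      !(soma_labels > 0)
    bg <- if (any(ring)) mean(im[ring]) else median(im)
    contrast <- mean(im[ii]) / max(bg, 1e-9)
    skel_len <- sum(skel[ii])
    if (contrast < params$minor_contrast_min ||
        skel_len < params$minor_min_length)
      out[ii] <- FALSE
  }
  out
}

#' Close non-random gaps between neurite segments
#'
#' Pairs of skeleton endpoints closer than `gap_max_length` whose local
#' tangent directions agree within `gap_angle_tol` and point toward each
#' other, and which belong to different connected components, are bridged
#' by a straight 1-px path dilated to the local neurite width. Bridging
#' always requires the directional test, never distance alone, and the
#' operation is idempotent: bridged endpoints share a component on a
#' second application.
#'
#' @param mask neurite mask (after segment testing).
#' @param params a [seg_params()].
#' @return logical matrix with bridges added.
#' @export
close_gaps <- function(mask, params = seg_params()) {
  if (!any(mask)) return(mask)
  skel <- skeletonize(mask)
  ncnt <- neighbor_count(skel)
  ep <- which(skel & ncnt == 1L)
  if (length(ep) < 2) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  er <- (ep - 1L) %% nr + 1L
  ec <- (ep - 1L) %/% nr + 1L
  comp <- label8(mask)
  dm <- mat(EBImage::distmap(mask * 1))

  # outward tangent: endpoint minus a short walk back along the skeleton
  tangent <- function(k) {
    r <- er[k]; c <- ec[k]
    visited <- matrix(FALSE, 3, 3)  # placeholder; track coords instead
    path_r <- r; path_c <- c
    for (s in 1:5) {
      found <- FALSE
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (!dr && !dc) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (!skel[rr, cc]) next
          if (any(path_r == rr & path_c == cc)) next
          r <- rr; c <- cc
          path_r <- c(path_r, rr); path_c <- c(path_c, cc)
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found) break
    }
    v <- c(er[k] - r, ec[k] - c)
    n <- sqrt(sum(v^2))
    if (n < 1e-9) c(NA_real_, NA_real_) else v / n
  }
  tg <- t(vapply(seq_along(ep), tangent, numeric(2)))

  out <- mask
  n_ep <- length(ep)
  for (i in seq_len(n_ep - 1)) {
    for (j in (i + 1):n_ep) {
      if (comp[ep[i]] == comp[ep[j]]) next
      d <- c(er[j] - er[i], ec[j] - ec[i])
      len <- sqrt(sum(d^2))
      if (len > params$gap_max_length || len < 1e-9) next
      if (any(is.na(tg[i, ])) || any(is.na(tg[j, ]))) next
      u <- d / len
      ang_i <- acos(pmin(pmax(sum(tg[i, ] * u), -1), 1))
      ang_j <- acos(pmin(pmax(sum(tg[j, ] * -u), -1), 1))
      if (ang_i > params$gap_angle_tol || ang_j > params$gap_angle_tol) next
      half <- max(0L, as.integer(round(max(dm[ep[i]], dm[ep[j]])) - 1L))
      nstep <- max(2L, ceiling(len) + 1L)
      xs <- seq(er[i], er[j], length.out = nstep)
      ys <- seq(ec[i], ec[j], length.out = nstep)
      out[stroke_idx(xs, ys, half, nr, nc)] <- TRUE
      comp[comp == comp[ep[j]]] <- comp[ep[i]]  # merged for later pairs
    }
  }
  out
}

## ---- clumps -------------------------------------------------------------

#' Detect cell clumps for exclusion
#'
#' Contiguous high-DNA regions in which at least `clump_nucleus_count_min`
#' detected nuclei merge, or single objects exceeding `clump_area_factor`
#' times the top of the live-nucleus area range, are flagged as clumps and
#' dilated by `clump_dilate` px. Cell bodies and neurite sections falling
#' in this region are later excluded from quantification.
#'
#' @inheritParams segment_cell_bodies
#' @return logical clump mask.
#' @export
detect_clumps <- function(field, nucleus_labels, nuclei,
                          params = seg_params()) {
  nr <- nrow(nucleus_labels); nc <- ncol(nucleus_labels)
  clump <- matrix(FALSE, nr, nc)
  if (!nrow(nuclei)) return(clump)
  s <- gsmooth(field$channels$dna, 1.5)
  ref <- median(nuclei$dna_mean[nuclei$class != "dead_excluded"]) %|na|%
    median(nuclei$dna_mean)
  cut <- params$clump_dna_factor * ref
  hi <- label8(s >= cut)
  if (max(hi) == 0) return(clump)
  cen <- cbind(round(nuclei$row), round(nuclei$col))
  cen_lab <- hi[cbind(cen[, 1], cen[, 2])]
  counts <- table(cen_lab[cen_lab > 0])
  big_enough <- as.integer(names(counts))[counts >= params$clump_nucleus_count_min]
  # tightly fused nuclei are detected as a single object, so an oversized
  # high-DNA region containing at least one nucleus also counts as a clump
  areas <- tabulate(hi[hi > 0], nbins = max(hi))
  oversized <- which(areas > params$clump_area_factor *
                       params$nucleus_area_range[2])
  oversized <- intersect(oversized, unique(cen_lab[cen_lab > 0]))
  marks <- union(big_enough, oversized)
  if (!length(marks)) return(clump)
  region <- matrix(hi %in% marks, nr, nc)
  mat(EBImage::dilate(region * 1, disc_brush(2 * params$clump_dilate + 1))) > 0
}

## ---- final masks --------------------------------------------------------

#' Finalize quantification masks
#'
#' Image-math subtraction producing the two final quantification regions:
#' the neurite quantification mask is the total neurite mask minus cell
#' body pixels minus clumps; cell-body quantification is restricted to
#' soma areas not crossed by neurites, minus clumps.
#'
#' @param soma_labels soma label grid.
#' @param neurite_total logical total neurite mask.
#' @param clump_mask logical clump mask.
#' @param nucleus_labels,nuclei optional; carried through into the result.
#' @return object of class `segmentation_masks`.
#' @export
finalize_masks <- function(soma_labels, neurite_total, clump_mask,
                           nucleus_labels = NULL, nuclei = NULL) {
  if (!all(dim(soma_labels) == dim(neurite_total)) ||
      !all(dim(soma_labels) == dim(clump_mask)))
    stop("mask geometry mismatch")
  soma_bin <- soma_labels > 0
  neurite_quant <- neurite_total & !soma_bin & !clump_mask
  soma_quant <- soma_labels
  soma_quant[neurite_total | clump_mask] <- 0L
  structure(list(nucleus_labels = nucleus_labels,
                 nuclei = nuclei,
                 soma_labels = soma_labels,
                 neurite_mask_total = neurite_total,
                 neurite_mask_final = neurite_quant,
                 clump_mask = clump_mask,
                 soma_quant_labels = soma_quant,
                 neurite_quant_mask = neurite_quant),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf(paste0("segmentation_masks: %d nuclei (%d neuronal), ",
                     "%d somata, neurite area %d px, clump area %d px\n"),
              if (is.null(x$nuclei)) 0L else nrow(x$nuclei),
              if (is.null(x$nuclei)) 0L else
                sum(x$nuclei$class == "neuronal_live"),
              length(setdiff(unique(as.integer(x$soma_labels)), 0L)),
              sum(x$neurite_quant_mask), sum(x$clump_mask)))
  invisible(x)
}

#' Segment one field end to end
#'
#' Orchestrates nucleus detection and classification, cell-body
#' segmentation, iterative neurite extraction, minor-segment testing,
#' directional gap closing, clump detection, and final image-math
#' subtraction. Deterministic for fixed inputs and parameters. Nuclei
#' whose centroid falls in a clump are re-classed `clumped_excluded`.
#'
#' @inheritParams detect_nuclei
#' @return a `segmentation_masks` object.
#' @export
segment_field <- function(field, params = seg_params()) {
  nu <- detect_nuclei(field, params)
  cb <- segment_cell_bodies(field, nu$labels, nu$nuclei, params)
  total <- extract_neurite_mask(field, cb$soma_labels, params)
  total <- test_neurite_segments(total, field, cb$soma_labels, params)
  total <- close_gaps(total, params)
  clump <- detect_clumps(field, nu$labels, cb$nuclei, params)
  nuclei <- cb$nuclei
  if (nrow(nuclei)) {
    in_clump <- clump[cbind(round(nuclei$row), round(nuclei$col))]
    nuclei$class[in_clump & nuclei$class != "dead_excluded"] <-
      "clumped_excluded"
  }
  finalize_masks(cb$soma_labels, total, clump,
                 nucleus_labels = nu$labels, nuclei = nuclei)
}
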