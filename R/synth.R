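#' Synthetic field configuration
#'
#' Parameters of the simulator that emulates one imaged field of a dense
#' human neuronal culture: live neuronal nuclei with attached somata,
#' non-neuronal nuclei, small/bright/rugged dead nuclei, clumped-cell
#' regions, branching neurite trees with bright-thick major and dim-thin
#' minor processes, neurites crossing foreign somata, channel-specific
#' compartment intensities, Poisson shot noise plus Gaussian read noise,
#' and per-treatment multiplicative effects on phospho-tau and on neurite
#' area.
#'
#' Intensity units are arbitrary detector counts. The intensity model is a
#' channel x compartment table of mean clean (pre-noise) intensities; a
#' pixel covered by several compartments takes the maximum of their values,
#' which mimics fluorophores stacking in projection without letting
#' overlaps run away.
#'
#' @param grid_shape image size in pixels (rows, cols).
#' @param n_neurons number of live neuronal nuclei (each with soma and
#'   neurite trees).
#' @param n_nonneuronal number of non-neuronal nuclei (DNA signal only).
#' @param n_dead number of dead nuclei (small, bright, rugged outline).
#' @param clump_fraction probability that a neuron is placed inside a
#'   multi-cell clump instead of in isolation.
#' @param soma_radius,live_nucleus_radius,dead_nucleus_radius radius ranges
#'   in px; the dead range must lie strictly below the live range.
#' @param neurite_tree list of tree-growth parameters: `n_primary` (count
#'   range per neuron), `segment_length` (total tree path length range, px),
#'   `branch_prob` (per-step branching probability), `major_width`,
#'   `minor_width` (stroke widths, px), `minor_fraction` (fraction of trees
#'   that are minor: dim and thin), `curvature_sd` (radians per step),
#'   `crossing_prob` (probability a tree is routed through a foreign soma).
#' @param intensity_model list per channel of named compartment means; see
#'   defaults in the function body.
#' @param noise list: `gaussian_sd` (additive read noise) and `poisson`
#'   (logical, shot noise on the clean signal).
#' @param effect list of multipliers `p_tau_scale_neurite`,
#'   `p_tau_scale_soma` (on the p-tau channel of those compartments) and
#'   `neurite_area_scale` (on total tree length); all 1 means untreated.
#' @param seed integer RNG seed; fields are bit-reproducible per seed.
#' @return an object of class `synth_field_config`.
#' @export
synth_field_config <- function(grid_shape = c(1024L, 1024L),
                               n_neurons = 30L,
                               n_nonneuronal = 10L,
                               n_dead = 6L,
                               clump_fraction = 0.1,
                               soma_radius = c(12, 16),
                               live_nucleus_radius = c(8, 11),
                               dead_nucleus_radius = c(4, 5.5),
                               neurite_tree = list(),
                               intensity_model = list(),
                               noise = list(gaussian_sd = 10, poisson = TRUE),
                               effect = list(p_tau_scale_neurite = 1,
                                             p_tau_scale_soma = 1,
                                             neurite_area_scale = 1),
                               seed = 1L) {
  tree_def <- list(n_primary = c(2L, 4L), segment_length = c(80, 160),
                   branch_prob = 0.02, major_width = 3L, minor_width = 1L,
                   minor_fraction = 0.25, curvature_sd = 0.12,
                   crossing_prob = 0.05)
  neurite_tree <- modifyList(tree_def, neurite_tree)
  im_def <- list(
    dna       = c(background = 20, nucleus_live = 300, nucleus_nonneuronal = 300,
                  nucleus_dead = 900, soma = 25, neurite_major = 20,
                  neurite_minor = 20),
    tubulin   = c(background = 30, nucleus_live = 400, nucleus_nonneuronal = 30,
                  nucleus_dead = 35, soma = 400, neurite_major = 500,
                  neurite_minor = 250),
    total_tau = c(background = 30, nucleus_live = 350, nucleus_nonneuronal = 30,
                  nucleus_dead = 35, soma = 350, neurite_major = 450,
                  neurite_minor = 220),
    p_tau     = c(background = 25, nucleus_live = 300, nucleus_nonneuronal = 25,
                  nucleus_dead = 30, soma = 300, neurite_major = 400,
                  neurite_minor = 200))
  for (ch in names(intensity_model))
    im_def[[ch]][names(intensity_model[[ch]])] <- unlist(intensity_model[[ch]])
  noise <- modifyList(list(gaussian_sd = 10, poisson = TRUE), noise)
  effect <- modifyList(list(p_tau_scale_neurite = 1, p_tau_scale_soma = 1,
                            neurite_area_scale = 1), effect)
  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        n_neurons = as.integer(n_neurons),
                        n_nonneuronal = as.integer(n_nonneuronal),
                        n_dead = as.integer(n_dead),
                        clump_fraction = clump_fraction,
                        soma_radius = soma_radius,
                        live_nucleus_radius = live_nucleus_radius,
                        dead_nucleus_radius = dead_nucleus_radius,
                        neurite_tree = neurite_tree,
                        intensity_model = im_def,
                        noise = noise, effect = effect,
                        seed = as.integer(seed)),
                   class = "synth_field_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (max(cfg$dead_nucleus_radius) >= min(cfg$live_nucleus_radius))
    stop("dead nucleus radii must lie strictly below live radii")
  if (cfg$intensity_model$dna[["nucleus_dead"]] <=
      cfg$intensity_model$dna[["nucleus_live"]])
    stop("dead nuclei must be brighter than live in the DNA channel")
  for (ch in CHANNEL_ROLES)
    if (cfg$intensity_model[[ch]][["neurite_minor"]] >
        cfg$intensity_model[[ch]][["neurite_major"]])
      stop("minor neurites must be no brighter than major (channel ", ch, ")")
  if (any(unlist(cfg$effect) <= 0)) stop("effect multipliers must be > 0")
  invisible(cfg)
}

## ---- low-level raster helpers ------------------------------------------

# linear indices of a filled disc, clipped to the grid
disc_idx <- function(cx, cy, r, nr, nc) {
  ri <- seq.int(max(1, floor(cx - r)), min(nr, ceiling(cx + r)))
  ci <- seq.int(max(1, floor(cy - r)), min(nc, ceiling(cy + r)))
  if (!length(ri) || !length(ci)) return(integer(0))
  g <- expand.grid(r = ri, c = ci)
  keep <- (g$r - cx)^2 + (g$c - cy)^2 <= r^2
  (g$c[keep] - 1L) * nr + g$r[keep]
}

# linear indices of pixels whose centers fall inside a polygon (even-odd)
poly_idx <- function(px, py, nr, nc) {
  ri <- seq.int(max(1, floor(min(px))), min(nr, ceiling(max(px))))
  ci <- seq.int(max(1, floor(min(py))), min(nc, ceiling(max(py))))
  if (!length(ri) || !length(ci)) return(integer(0))
  g <- expand.grid(r = ri, c = ci)
  n <- length(px)
  inside <- rep(FALSE, nrow(g))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > g$c) != (py[j] > g$c)) &
      (g$r < (px[j] - px[i]) * (g$c - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  (g$c[inside] - 1L) * nr + g$r[inside]
}

# rugged star-like outline for dead nuclei: alternating radial spikes
rugged_poly_idx <- function(cx, cy, r, nr, nc, n_vertex = 12L, rough = 0.5) {
  th <- seq(0, 2 * pi, length.out = n_vertex + 1L)[-(n_vertex + 1L)] +
    runif(1, 0, 2 * pi)
  rad <- r * (1 + rough * rep_len(c(1, -1), n_vertex)) *
    exp(rnorm(n_vertex, 0, 0.08))
  poly_idx(cx + rad * cos(th), cy + rad * sin(th), nr, nc)
}

# indices stamped by a polyline with a (2k+1)-px square pen
stroke_idx <- function(xs, ys, half_width, nr, nc) {
  xi <- round(xs); yi <- round(ys)
  if (half_width > 0) {
    off <- expand.grid(dx = -half_width:half_width, dy = -half_width:half_width)
    xi <- rep(xi, each = nrow(off)) + off$dx
    yi <- rep(yi, each = nrow(off)) + off$dy
  }
  keep <- xi >= 1 & xi <= nr & yi >= 1 & yi <= nc
  unique((yi[keep] - 1L) * nr + xi[keep])
}

## ---- neurite tree growth ------------------------------------------------

# one tree as a set of stamped pixel indices; random walk with branching,
# optionally routed through a foreign soma to exercise crossing exclusion
grow_tree <- function(start_x, start_y, theta0, total_len, width, tree,
                      nr, nc, cross_target = NULL) {
  half <- (width - 1L) %/% 2L
  idx <- integer(0)
  # queue of segments: x, y, theta, remaining length
  queue <- list(list(x = start_x, y = start_y, th = theta0, len = total_len))
  first <- TRUE
  while (length(queue)) {
    sgm <- queue[[1]]; queue <- queue[-1]
    remaining <- sgm$len
    x <- sgm$x; y <- sgm$y; th <- sgm$th
    while (remaining > 1) {
      n_step <- min(remaining, rgeom_step(tree$branch_prob))
      if (first && !is.null(cross_target)) {
        # head straight for the foreign soma, gentle jitter
        aim <- atan2(cross_target[2] - y, cross_target[1] - x)
        dth <- rnorm(n_step, 0, tree$curvature_sd / 3)
        th_seq <- aim + cumsum(dth)
        first <- FALSE
      } else {
        th_seq <- th + cumsum(rnorm(n_step, 0, tree$curvature_sd))
      }
      xs <- x + cumsum(cos(th_seq))
      ys <- y + cumsum(sin(th_seq))
      # a tree reaching the border is clipped there: the walk terminates so
      # every rendered pixel stays connected to its soma
      out_of_grid <- xs < 2 | xs > nr - 1 | ys < 2 | ys > nc - 1
      if (any(out_of_grid)) {
        n_step <- which(out_of_grid)[1] - 1L
        remaining <- 0
        if (n_step == 0L) break
        xs <- xs[seq_len(n_step)]; ys <- ys[seq_len(n_step)]
        th_seq <- th_seq[seq_len(n_step)]
      }
      idx <- c(idx, stroke_idx(xs, ys, half, nr, nc))
      x <- xs[n_step]; y <- ys[n_step]; th <- th_seq[n_step]
      remaining <- max(remaining - n_step, 0)
      if (remaining > 8) {  # branch: split direction, halve what is left
        dth <- runif(1, 0.3, 0.8) * sample(c(-1, 1), 1)
        queue[[length(queue) + 1L]] <-
          list(x = x, y = y, th = th + dth, len = remaining / 2)
        th <- th - dth / 2
        remaining <- remaining / 2
      }
    }
  }
  unique(idx)
}

rgeom_step <- function(p) {
  if (p <= 0) return(10000L)
  1L + stats::rgeom(1, p)
}

## ---- field generation ---------------------------------------------------

#' Generate one synthetic field with ground truth
#'
#' Deterministic for a fixed `config$seed`. Returns the noisy four-channel
#' [field_image()] together with a ground-truth list carrying the true
#' nucleus/soma label grids, nucleus classes, neurite and clump masks, the
#' effect-scaled intensity model, and true compartment means computed on
#' the clean (pre-noise) image over the true quantification regions
#' (neurites minus somata minus clumps; somata minus neurite crossings
#' minus clumps).
#'
#' @param config a [synth_field_config()].
#' @param well_id,field_index identity stamped on the returned field.
#' @return list with elements `field` ([field_image()]) and `truth`.
#' @export
generate_field <- function(config, well_id = "A1", field_index = 0L) {
  stopifnot(inherits(config, "synth_field_config"))
  validate_synth_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  npx <- nr * nc
  tree <- config$neurite_tree

  nucleus_labels <- matrix(0L, nr, nc)
  soma_labels <- matrix(0L, nr, nc)
  neurite_major <- matrix(FALSE, nr, nc)
  neurite_minor <- matrix(FALSE, nr, nc)
  clump_mask <- matrix(FALSE, nr, nc)

  classes <- character(0)   # per nucleus label
  centers <- matrix(numeric(0), ncol = 2)
  placed_r <- numeric(0)

  # rejection placement keeping isolated nuclei apart; clump members overlap
  place <- function(r_obj, sep, n_try = 200) {
    margin <- r_obj + 2
    for (i in seq_len(n_try)) {
      x <- runif(1, margin, nr - margin); y <- runif(1, margin, nc - margin)
      if (!nrow(centers)) return(c(x, y))
      d <- sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2)
      if (all(d > sep + placed_r + r_obj)) return(c(x, y))
    }
    NULL
  }

  n_clumped <- if (config$n_neurons >= 3)
    stats::rbinom(1, config$n_neurons, config$clump_fraction) else 0L
  if (n_clumped > 0 && n_clumped < 3) n_clumped <- 0L  # a clump needs >= 3 cells
  n_iso <- config$n_neurons - n_clumped

  soma_info <- list()  # per neuronal nucleus: center, soma radius, label

  add_nucleus <- function(ctr, r_nuc, class, soma_r = NA) {
    lab <- length(classes) + 1L
    idx <- if (class == "dead")
      rugged_poly_idx(ctr[1], ctr[2], r_nuc, nr, nc)
    else disc_idx(ctr[1], ctr[2], r_nuc, nr, nc)
    nucleus_labels[idx] <<- lab
    classes[lab] <<- if (class == "dead") "dead" else
      if (class == "neuron") "neuronal_live" else "nonneuronal"
    centers <<- rbind(centers, ctr)
    placed_r <<- c(placed_r, if (is.na(soma_r)) r_nuc else soma_r)
    if (class == "neuron") {
      soma_labels[disc_idx(ctr[1], ctr[2], soma_r, nr, nc)] <<- lab
      soma_info[[length(soma_info) + 1L]] <<-
        list(label = lab, center = ctr, r = soma_r)
    }
    lab
  }

  # isolated neurons
  for (i in seq_len(n_iso)) {
    r_nuc <- runif(1, config$live_nucleus_radius[1], config$live_nucleus_radius[2])
    r_soma <- runif(1, config$soma_radius[1], config$soma_radius[2])
    ctr <- place(r_soma, sep = 6)
    if (is.null(ctr)) next
    add_nucleus(ctr, r_nuc, "neuron", soma_r = r_soma)
  }
  # clumps: groups of >= 3 tightly overlapping neurons with a halo of
  # elevated background; the halo disc is the true clump region
  clump_boost_idx <- integer(0)
  clump_member_labels <- integer(0)
  while (n_clumped >= 3) {
    k <- min(n_clumped, sample(3:5, 1))
    r_soma <- mean(config$soma_radius)
    ctr0 <- place(r_soma * 2.5, sep = 8)
    if (is.null(ctr0)) break
    # members stay within one nucleus radius of the cluster center so
    # outlines merge into one contiguous high-DNA region
    spread <- 1.3 * min(config$live_nucleus_radius)
    for (j in seq_len(k)) {
      ang <- runif(1, 0, 2 * pi)
      ctr <- ctr0 + runif(1, 0, spread) * c(cos(ang), sin(ang))
      r_nuc <- runif(1, config$live_nucleus_radius[1],
                     config$live_nucleus_radius[2])
      lab <- add_nucleus(ctr, r_nuc, "neuron",
                         soma_r = runif(1, config$soma_radius[1],
                                        config$soma_radius[2]))
      clump_member_labels <- c(clump_member_labels, lab)
    }
    halo <- disc_idx(ctr0[1], ctr0[2], spread + max(config$soma_radius) + 4,
                     nr, nc)
    clump_mask[halo] <- TRUE
    clump_boost_idx <- c(clump_boost_idx, halo)
    n_clumped <- n_clumped - k
  }
  # non-neuronal and dead nuclei
  for (i in seq_len(config$n_nonneuronal)) {
    r_nuc <- runif(1, config$live_nucleus_radius[1], config$live_nucleus_radius[2])
    ctr <- place(r_nuc, sep = 6)
    if (!is.null(ctr)) add_nucleus(ctr, r_nuc, "nonneuronal")
  }
  for (i in seq_len(config$n_dead)) {
    r_nuc <- runif(1, config$dead_nucleus_radius[1], config$dead_nucleus_radius[2])
    ctr <- place(r_nuc * 1.6, sep = 6)
    if (!is.null(ctr)) add_nucleus(ctr, r_nuc, "dead")
  }

  # neurite trees from each soma boundary; tree length scaled by the
  # neurite-area effect multiplier
  len_scale <- config$effect$neurite_area_scale
  for (s in soma_info) {
    n_tree <- sample(seq.int(tree$n_primary[1], tree$n_primary[2]), 1)
    for (t in seq_len(n_tree)) {
      minor <- runif(1) < tree$minor_fraction
      th0 <- runif(1, 0, 2 * pi)
      # start just inside the soma boundary so the tree is 8-connected to it
      sx <- s$center[1] + (s$r - 1) * cos(th0)
      sy <- s$center[2] + (s$r - 1) * sin(th0)
      L <- runif(1, tree$segment_length[1], tree$segment_length[2]) * len_scale
      target <- NULL
      if (length(soma_info) > 1 && runif(1) < tree$crossing_prob) {
        others <- Filter(function(o) o$label != s$label, soma_info)
        target <- others[[sample(length(others), 1)]]$center
      }
      w <- if (minor) tree$minor_width else tree$major_width
      idx <- grow_tree(sx, sy, th0, L, w, tree, nr, nc, cross_target = target)
      if (minor) neurite_minor[idx] <- TRUE else neurite_major[idx] <- TRUE
    }
  }
  neurite_minor[neurite_major] <- FALSE   # major takes precedence in overlap

  ## clean images: max-composite of compartment intensities over background
  eff <- config$effect
  scaled_model <- config$intensity_model
  scaled_model$p_tau[["neurite_major"]] <-
    scaled_model$p_tau[["neurite_major"]] * eff$p_tau_scale_neurite
  scaled_model$p_tau[["neurite_minor"]] <-
    scaled_model$p_tau[["neurite_minor"]] * eff$p_tau_scale_neurite
  scaled_model$p_tau[["soma"]] <-
    scaled_model$p_tau[["soma"]] * eff$p_tau_scale_soma
  scaled_model$p_tau[["nucleus_live"]] <-
    scaled_model$p_tau[["nucleus_live"]] * eff$p_tau_scale_soma

  idx_of <- list(
    neurite_minor = which(neurite_minor),
    neurite_major = which(neurite_major),
    soma = which(soma_labels > 0),
    nucleus_live = which(nucleus_labels > 0 &
                           matrix(classes[pmax(nucleus_labels, 1)] == "neuronal_live"
                                  & nucleus_labels > 0, nr, nc)),
    nucleus_nonneuronal = which(nucleus_labels > 0 &
                                  matrix(classes[pmax(nucleus_labels, 1)] == "nonneuronal"
                                         & nucleus_labels > 0, nr, nc)),
    nucleus_dead = which(nucleus_labels > 0 &
                           matrix(classes[pmax(nucleus_labels, 1)] == "dead"
                                  & nucleus_labels > 0, nr, nc)))

  clean <- list()
  for (ch in CHANNEL_ROLES) {
    m <- matrix(scaled_model[[ch]][["background"]], nr, nc)
    for (comp in names(idx_of)) {
      v <- scaled_model[[ch]][[comp]]
      ii <- idx_of[[comp]]
      if (length(ii)) m[ii] <- pmax(m[ii], v)
    }
    if (length(clump_boost_idx)) {
      # elevated local background in clumps: stacked cell debris raises
      # the DNA floor markedly, the other stains moderately
      boost <- if (ch == "dna") scaled_model[[ch]][["nucleus_live"]] * 0.4
               else scaled_model[[ch]][["background"]] * 1.5 + 10
      m[clump_boost_idx] <- pmax(m[clump_boost_idx], boost)
    }
    clean[[ch]] <- m
  }
  # stacked cells in clumps: clumped nuclei present higher DNA intensity
  if (length(clump_member_labels)) {
    mem <- which(matrix(nucleus_labels %in% clump_member_labels,
                        nr, nc))
    clean$dna[mem] <- clean$dna[mem] * 1.5
  }

  ## true compartment means on the clean image over true quant regions
  soma_bin <- soma_labels > 0
  neurite_bin <- neurite_major | neurite_minor
  neurite_quant_true <- neurite_bin & !soma_bin & !clump_mask
  soma_quant_true <- soma_bin & !neurite_bin & !clump_mask
  comp_means <- list()
  for (ch in CHANNEL_ROLES) {
    comp_means[[ch]] <- c(
      neurite = if (any(neurite_quant_true))
        mean(clean[[ch]][neurite_quant_true]) else NA_real_,
      soma = if (any(soma_quant_true))
        mean(clean[[ch]][soma_quant_true]) else NA_real_)
  }

  ## noise: Poisson shot noise then additive Gaussian read noise
  noisy <- lapply(clean, function(m) {
    v <- as.numeric(m)
    if (isTRUE(config$noise$poisson)) v <- rpois(npx, v)
    if (config$noise$gaussian_sd > 0)
      v <- v + rnorm(npx, 0, config$noise$gaussian_sd)
    matrix(pmax(v, 0), nr, nc)
  })

  truth <- list(nucleus_labels = nucleus_labels,
                nucleus_classes = data.frame(
                  label = seq_along(classes), class = classes,
                  stringsAsFactors = FALSE),
                soma_labels = soma_labels,
                neurite_mask = neurite_bin,
                neurite_major_mask = neurite_major,
                clump_mask = clump_mask,
                neurite_quant_mask = neurite_quant_true,
                soma_quant_mask = soma_quant_true,
                intensity = scaled_model,
                compartment_means = comp_means,
                effect = eff,
                clean = clean)
  list(field = field_image(noisy, well_id = well_id,
                           field_index = field_index),
       truth = truth)
}

## ---- plates -------------------------------------------------------------

# deterministic per-field substream seed from (master seed, well, field)
field_seed <- function(master, well_id, field_index) {
  m <- 2147483647
  idx <- match(toupper(well_id), WELL_IDS_96)
  h <- (as.double(master) %% m) * 48271 %% m
  h <- (h + idx * 100003 + as.double(field_index) * 7919) %% m
  h <- (h * 48271) %% m
  as.integer(max(h, 1))
}

#' Plan a synthetic plate
#'
#' Expands a plate layout into a deterministic per-field plan: every field
#' of every non-empty well gets a substream seed derived from the master
#' seed and its (well, field) identity, and the effect multipliers implied
#' by its treatment (multipliers 1 for DMSO). The heavy pixel data are not
#' materialized here; realize individual fields with [plate_field()] or run
#' the whole plate through [simulate_plate_metrics()].
#'
#' @param layout a [plate_layout()].
#' @param base a [synth_field_config()] used for every field (seed and
#'   effect are overridden per field).
#' @param compound_effects data.frame with columns `compound_id`, `dose`,
#'   `p_tau_scale_neurite`, `p_tau_scale_soma`, `neurite_area_scale`; one
#'   row per compound x dose present in the layout.
#' @param positive_control_effect effect list for positive-control wells
#'   (default: p-tau halved in both compartments, area untouched —
#'   emulating a GSK3 inhibitor such as CHIR-99021).
#' @param seed master seed.
#' @return object of class `plate_plan` with a `fields` data.frame.
#' @export
generate_plate <- function(layout, base, compound_effects = NULL,
                           positive_control_effect =
                             list(p_tau_scale_neurite = 0.5,
                                  p_tau_scale_soma = 0.5,
                                  neurite_area_scale = 1),
                           seed = 1L) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(base, "synth_field_config"))
  wells <- layout$wells[layout$wells$kind != "empty", ]
  rows <- list()
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    eff <- switch(w$kind,
      dmso = list(p_tau_scale_neurite = 1, p_tau_scale_soma = 1,
                  neurite_area_scale = 1),
      positive_control = positive_control_effect,
      compound = {
        if (is.null(compound_effects)) stop("unmapped treatment: ", w$compound_id)
        m <- compound_effects[compound_effects$compound_id == w$compound_id &
                                compound_effects$dose == w$dose, ]
        if (nrow(m) != 1)
          stop("unmapped treatment: ", w$compound_id, " @ ", w$dose)
        list(p_tau_scale_neurite = m$p_tau_scale_neurite,
             p_tau_scale_soma = m$p_tau_scale_soma,
             neurite_area_scale = m$neurite_area_scale)
      })
    for (f in seq_len(layout$fields_per_well) - 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = w$well_id, kind = w$kind,
        compound_id = w$compound_id, dose = w$dose, field_index = f,
        seed = field_seed(seed, w$well_id, f),
        p_tau_scale_neurite = eff$p_tau_scale_neurite,
        p_tau_scale_soma = eff$p_tau_scale_soma,
        neurite_area_scale = eff$neurite_area_scale,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(fields = do.call(rbind, rows), base = base,
                 plate_id = layout$plate_id), class = "plate_plan")
}

#' Realize one field of a plate plan
#' @param plan a `plate_plan` from [generate_plate()].
#' @param i row index into `plan$fields`.
#' @return list `(field, truth)` as from [generate_field()].
#' @export
plate_field <- function(plan, i) {
  row <- plan$fields[i, ]
  cfg <- plan$base
  cfg$seed <- row$seed
  cfg$effect <- list(p_tau_scale_neurite = row$p_tau_scale_neurite,
                     p_tau_scale_soma = row$p_tau_scale_soma,
                     neurite_area_scale = row$neurite_area_scale)
  generate_field(cfg, well_id = row$well_id, field_index = row$field_index)
}

#' Simulate a plate and return per-field metrics
#'
#' Runs the full loop generate -> segment -> quantify for every planned
#' field and collects the field metrics table consumed by the screen
#' statistics. With `measure = "truth"` the segmentation step is skipped
#' and metrics are read off the ground-truth masks instead (useful to
#' separate segmentation error from downstream statistics).
#'
#' @param plan a `plate_plan` from [generate_plate()].
#' @param params a [seg_params()] (ignored for `measure = "truth"`).
#' @param measure `"segment"` (default) or `"truth"`.
#' @param progress print a line every 25 fields.
#' @return data.frame: plan columns joined with [field_metrics()] columns.
#' @export
simulate_plate_metrics <- function(plan, params = seg_params(),
                                   measure = c("segment", "truth"),
                                   progress = FALSE) {
  measure <- match.arg(measure)
  out <- vector("list", nrow(plan$fields))
  for (i in seq_len(nrow(plan$fields))) {
    sim <- plate_field(plan, i)
    if (measure == "segment") {
      masks <- segment_field(sim$field, params)
    } else {
      masks <- truth_as_masks(sim$truth)
    }
    fm <- field_metrics(sim$field, masks)
    out[[i]] <- cbind(plan$fields[i, c("well_id", "kind", "compound_id",
                                       "dose", "field_index")],
                      fm[setdiff(names(fm), c("well_id", "field_index"))])
    if (progress && i %% 25 == 0)
      message(sprintf("  field %d/%d", i, nrow(plan$fields)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# view ground truth through the segmentation-mask interface
truth_as_masks <- function(truth) {
  soma_quant <- truth$soma_labels
  soma_quant[!truth$soma_quant_mask] <- 0L
  structure(list(nucleus_labels = truth$nucleus_labels,
                 nuclei = data.frame(
                   label = truth$nucleus_classes$label,
                   area = as.numeric(tabulate(truth$nucleus_labels[truth$nucleus_labels > 0],
                                              nbins = max(truth$nucleus_labels, 1))),
                   dna_mean = NA_real_, solidity = NA_real_,
                   class = ifelse(truth$nucleus_classes$class == "dead",
                                  "dead_excluded",
                                  ifelse(truth$nucleus_classes$class == "neuronal_live",
                                         "neuronal_live", "nonneuronal"))),
                 soma_labels = truth$soma_labels,
                 neurite_mask_total = truth$neurite_mask,
                 neurite_mask_final = truth$neurite_mask,
                 clump_mask = truth$clump_mask,
                 soma_quant_labels = soma_quant,
                 neurite_quant_mask = truth$neurite_quant_mask),
            class = "segmentation_masks")
}
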