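# a hand-built field: one live nucleus + soma + one straight neurite,
# one bare nucleus (no cytoskeleton), constant background
build_field <- function(nr = 128, nc = 128, neurite_cols = 40:110,
                        neurite_rows = 63:65, soma_ctr = c(64, 30),
                        bare_ctr = c(100, 100), noise_sd = 0, seed = 1) {
  set.seed(seed)
  bg <- list(dna = 20, tubulin = 30, total_tau = 30, p_tau = 25)
  ch <- lapply(bg, function(b) matrix(b, nr, nc))
  stamp_disc <- function(m, ctr, r, v) {
    m[tauHCS:::disc_idx(ctr[1], ctr[2], r, nr, nc)] <- v
    m
  }
  for (cn in c("tubulin", "total_tau", "p_tau")) {
    ch[[cn]] <- stamp_disc(ch[[cn]], soma_ctr, 13, 380)
    ch[[cn]][neurite_rows, neurite_cols] <- 450
  }
  ch$dna <- stamp_disc(ch$dna, soma_ctr, 9, 300)
  ch$dna <- stamp_disc(ch$dna, bare_ctr, 9, 300)
  if (noise_sd > 0)
    ch <- lapply(ch, function(m)
      matrix(pmax(m + rnorm(nr * nc, 0, noise_sd), 0), nr, nc))
  field_image(ch)
}

test_that("a pure-noise field yields no nuclei and almost no neurite area", {
  set.seed(8)
  nr <- 256
  ch <- lapply(list(dna = 20, tubulin = 30, total_tau = 30, p_tau = 25),
               function(b) matrix(pmax(rnorm(nr * nr, b, sqrt(b) + 5), 0),
                                  nr, nr))
  field <- field_image(ch)
  masks <- segment_field(field, seg_params())
  expect_equal(nrow(masks$nuclei), 0)
  # false-positive-averse stringency: under 0.1% of pixels
  expect_lt(sum(masks$neurite_mask_total), 0.001 * nr * nr)
  expect_equal(sum(masks$neurite_quant_mask), sum(masks$neurite_mask_total))
})

test_that("nuclei classification separates live, bare and dead objects", {
  field <- build_field()
  # add a small, bright, rugged object
  set.seed(3)
  idx <- tauHCS:::rugged_poly_idx(30, 100, 5, 128, 128)
  field$channels$dna[idx] <- 900
  nu <- detect_nuclei(field, seg_params())
  expect_equal(sum(nu$nuclei$class == "dead_excluded"), 1)
  dead <- nu$nuclei[nu$nuclei$class == "dead_excluded", ]
  expect_lte(dead$area, seg_params()$dead_area_max)
  expect_lte(dead$solidity, seg_params()$dead_solidity_max)
  expect_equal(sum(nu$nuclei$class == "live"), 2)
})

test_that("a nucleus without contiguous cytoskeletal signal gets no soma", {
  field <- build_field()
  nu <- detect_nuclei(field, seg_params())
  cb <- segment_cell_bodies(field, nu$labels, nu$nuclei, seg_params())
  expect_equal(sum(cb$nuclei$class == "neuronal_live"), 1)
  expect_equal(sum(cb$nuclei$class == "nonneuronal"), 1)
  # the surviving soma sits on the soma disc, not on the bare nucleus
  cen <- label_centroids(cb$soma_labels)
  expect_lt(sqrt(sum((cen[1, ] - c(64, 30))^2)), 4)
})

test_that("empty inputs propagate to empty soma and neurite masks", {
  blank <- field_image(lapply(
    setNames(c(20, 30, 30, 25), c("dna", "tubulin", "total_tau", "p_tau")),
    function(b) matrix(b, 64, 64)))
  nu <- detect_nuclei(blank, seg_params())
  expect_equal(nrow(nu$nuclei), 0)
  cb <- segment_cell_bodies(blank, nu$labels, nu$nuclei, seg_params())
  expect_equal(sum(cb$soma_labels), 0)
  expect_false(any(extract_neurite_mask(blank, cb$soma_labels, seg_params())))
})

test_that("neurite extraction recovers a straight major neurite", {
  field <- build_field(noise_sd = 8, seed = 6)
  nu <- detect_nuclei(field, seg_params())
  cb <- segment_cell_bodies(field, nu$labels, nu$nuclei, seg_params())
  mask <- extract_neurite_mask(field, cb$soma_labels, seg_params())
  truth <- matrix(FALSE, 128, 128)
  truth[63:65, 40:110] <- TRUE
  truth[tauHCS:::disc_idx(64, 30, 13, 128, 128)] <- FALSE
  expect_gt(iou(mask & !(cb$soma_labels > 0), truth), 0.8)
})

test_that("the accumulated neurite mask grows monotonically with iterations", {
  sim <- generate_field(small_cfg(seed = 13))
  p10 <- seg_params()
  nu <- detect_nuclei(sim$field, p10)
  cb <- segment_cell_bodies(sim$field, nu$labels, nu$nuclei, p10)
  m1 <- extract_neurite_mask(sim$field, cb$soma_labels,
                             seg_params(neurite_iterations = 1L))
  m10 <- extract_neurite_mask(sim$field, cb$soma_labels, p10)
  expect_true(all(m10[m1]))          # m1 subset of m10
  expect_gt(sum(m10), sum(m1))       # later passes recover dim structure
})

test_that("segment testing drops background blobs and keeps true minors", {
  field <- build_field(noise_sd = 0)
  soma <- matrix(0L, 128, 128)
  soma[tauHCS:::disc_idx(64, 30, 13, 128, 128)] <- 1L
  # candidate: true neurite + a 2-px near-background blob + a long segment
  # at contrast only 1.02x
  cand <- matrix(FALSE, 128, 128)
  cand[63:65, 40:110] <- TRUE
  cand[20, 20:21] <- TRUE
  cand[110, 10:60] <- TRUE
  field$channels$tubulin[20, 20:21] <- 31
  field$channels$tubulin[110, 10:60] <- 30 * 1.02
  kept <- test_neurite_segments(cand, field, soma, seg_params())
  expect_false(any(kept[20, 20:21]))
  expect_false(any(kept[110, 10:60]))
  expect_true(all(kept[64, 41:109]))
  # a detached minor neurite at 2x contrast and 40 px length is retained
  cand2 <- matrix(FALSE, 128, 128)
  cand2[40, 60:99] <- TRUE
  f2 <- build_field()
  f2$channels$tubulin[40, 60:99] <- 60
  kept2 <- test_neurite_segments(cand2, f2, soma, seg_params())
  expect_true(all(kept2[40, 60:99]))
})

test_that("gap closing is directional, non-random and idempotent", {
  p <- seg_params(gap_max_length = 6)
  m <- matrix(FALSE, 30, 30)
  m[15, 3:12] <- TRUE; m[15, 17:27] <- TRUE
  g <- close_gaps(m, p)
  expect_equal(max(tauHCS:::label8(g)), 1)          # collinear pair bridged
  expect_identical(close_gaps(g, p), g)             # idempotent

  perp <- matrix(FALSE, 30, 30)
  perp[15, 3:12] <- TRUE; perp[17:26, 15] <- TRUE
  expect_equal(max(tauHCS:::label8(close_gaps(perp, p))), 2)

  far <- matrix(FALSE, 30, 30)
  far[15, 3:12] <- TRUE; far[15, 21:27] <- TRUE     # 8 px gap > 6
  expect_equal(max(tauHCS:::label8(close_gaps(far, p))), 2)

  connected <- matrix(FALSE, 30, 30)
  connected[15, 3:25] <- TRUE
  expect_identical(close_gaps(connected, p), connected)
})

test_that("clumps are detected and excluded from both quantification masks", {
  cfg <- synth_field_config(grid_shape = c(256, 256), n_neurons = 9,
                            n_nonneuronal = 2, n_dead = 2,
                            clump_fraction = 0.5, seed = 17)
  sim <- generate_field(cfg)
  expect_gt(sum(sim$truth$clump_mask), 0)  # this seed does draw a clump
  masks <- segment_field(sim$field, seg_params())
  cover <- sum(masks$clump_mask & sim$truth$clump_mask) /
    sum(sim$truth$clump_mask)
  expect_gte(cover, 0.8)
  expect_false(any(masks$neurite_quant_mask & masks$clump_mask))
  expect_false(any(masks$soma_quant_labels > 0 & masks$clump_mask))
  # fused nuclei may detect as fewer objects; at least one is re-classed
  expect_gte(sum(masks$nuclei$class == "clumped_excluded"), 1)
})

test_that("finalized masks obey the subtraction arithmetic and invariants", {
  soma <- matrix(0L, 50, 50)
  soma[tauHCS:::disc_idx(25, 15, 8, 50, 50)] <- 1L
  neur <- matrix(FALSE, 50, 50)
  neur[40, 5:45] <- TRUE
  clump <- matrix(FALSE, 50, 50)
  # disjoint case: outputs equal inputs
  fin <- finalize_masks(soma, neur, clump)
  expect_identical(fin$neurite_quant_mask, neur)
  expect_identical(fin$soma_quant_labels, soma)

  # a neurite crossing the soma removes exactly the crossing pixels
  cross <- neur
  cross[25, 5:45] <- TRUE
  n_cross <- sum(soma[25, 5:45] > 0)
  fin2 <- finalize_masks(soma, cross, clump)
  expect_equal(sum(fin2$soma_quant_labels > 0), sum(soma > 0) - n_cross)
  expect_false(any(fin2$neurite_quant_mask & soma > 0))

  # a soma fully inside a clump disappears from quantification
  clump3 <- matrix(FALSE, 50, 50)
  clump3[tauHCS:::disc_idx(25, 15, 12, 50, 50)] <- TRUE
  fin3 <- finalize_masks(soma, neur, clump3)
  expect_equal(sum(fin3$soma_quant_labels), 0)

  expect_error(finalize_masks(soma, matrix(FALSE, 40, 40), clump),
               "mask geometry mismatch")
})

test_that("segmentation is deterministic and compartments never overlap", {
  sim <- generate_field(small_cfg(seed = 19))
  a <- segment_field(sim$field, seg_params())
  b <- segment_field(sim$field, seg_params())
  expect_identical(a$neurite_quant_mask, b$neurite_quant_mask)
  expect_identical(a$soma_quant_labels, b$soma_quant_labels)
  expect_identical(a$nuclei, b$nuclei)
  expect_false(any(a$neurite_quant_mask & a$soma_quant_labels > 0))
  expect_false(any(a$clump_mask &
                     (a$neurite_quant_mask | a$soma_quant_labels > 0)))
})

test_that("a global gain change with compensating adjustments is stable", {
  sim <- generate_field(small_cfg(seed = 23))
  base_area <- sum(segment_field(sim$field, seg_params())$neurite_quant_mask)
  for (gain in c(0.8, 1.25)) {
    f2 <- sim$field
    f2$channels <- lapply(f2$channels, function(m) m * gain)
    # relative cutoffs self-compensate; explicit adjustments stay at 1
    area <- sum(segment_field(f2, seg_params())$neurite_quant_mask)
    expect_lt(abs(area / base_area - 1), 0.05)
  }
})
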