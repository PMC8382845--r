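test_that("an empty field is pure background noise with empty truths", {
  cfg <- synth_field_config(grid_shape = c(64, 64), n_neurons = 0,
                            n_nonneuronal = 0, n_dead = 0, seed = 2)
  sim <- generate_field(cfg)
  expect_equal(sum(sim$truth$nucleus_labels), 0)
  expect_equal(sum(sim$truth$soma_labels), 0)
  expect_false(any(sim$truth$neurite_mask))
  expect_false(any(sim$truth$clump_mask))
  # intensities fluctuate around the background means only
  bg <- cfg$intensity_model$dna[["background"]]
  expect_lt(abs(mean(sim$field$channels$dna) - bg), 3)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_field(small_cfg(seed = 11))
  b <- generate_field(small_cfg(seed = 11))
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$nucleus_labels, b$truth$nucleus_labels)
  expect_identical(a$truth$neurite_mask, b$truth$neurite_mask)
  c2 <- generate_field(small_cfg(seed = 12))
  expect_false(identical(a$field$channels$dna, c2$field$channels$dna))
})

test_that("phospho-tau effect multipliers scale the true intensities exactly", {
  base <- small_cfg(seed = 4)
  treated <- small_cfg(seed = 4,
                       effect = list(p_tau_scale_neurite = 0.5,
                                     p_tau_scale_soma = 0.7))
  a <- generate_field(base)
  b <- generate_field(treated)
  expect_identical(b$truth$intensity$p_tau[["neurite_major"]] /
                     a$truth$intensity$p_tau[["neurite_major"]], 0.5)
  expect_identical(b$truth$intensity$p_tau[["soma"]] /
                     a$truth$intensity$p_tau[["soma"]], 0.7)
  # same geometry, so the clean-image compartment means scale likewise
  expect_equal(b$truth$compartment_means$p_tau[["soma"]] /
                 a$truth$compartment_means$p_tau[["soma"]], 0.7,
               tolerance = 1e-12)
  # non-p-tau channels untouched
  expect_identical(a$truth$intensity$tubulin, b$truth$intensity$tubulin)
})

test_that("lowering the neurite p-tau effect strictly lowers the true mean", {
  means <- sapply(c(1, 0.75, 0.5, 0.25), function(s) {
    sim <- generate_field(small_cfg(seed = 9,
                                    effect = list(p_tau_scale_neurite = s)))
    sim$truth$compartment_means$p_tau[["neurite"]]
  })
  expect_true(all(diff(means) < 0))
})

test_that("dead nuclei are smaller and brighter than live ones by construction", {
  sim <- generate_field(small_cfg(seed = 21))
  tr <- sim$truth
  lab <- tr$nucleus_labels
  cls <- tr$nucleus_classes
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  dna <- sim$truth$clean$dna
  means <- vapply(seq_len(max(lab)), function(l)
    mean(dna[lab == l]), numeric(1))
  dead <- cls$label[cls$class == "dead"]
  live <- cls$label[cls$class != "dead"]
  expect_true(max(areas[dead]) < min(areas[live]))
  expect_true(min(means[dead]) > max(means[live]))
})

test_that("every neurite component is attached to a soma before noise", {
  sim <- generate_field(small_cfg(seed = 31))
  tr <- sim$truth
  both <- tr$neurite_mask | tr$soma_labels > 0
  lab <- tauHCS:::label8(both)
  neur_comps <- unique(lab[tr$neurite_mask])
  soma_comps <- unique(lab[tr$soma_labels > 0])
  expect_true(all(neur_comps %in% soma_comps))
})

test_that("plate plans expand wells deterministically and validate effects", {
  lay <- plate_layout(data.frame(
    well_id = c("A1", "A2", "B1", "B2"),
    kind = c("dmso", "positive_control", "compound", "compound"),
    compound_id = c(NA, NA, "cmpA", "cmpB"),
    dose = c(NA, 11, 10, 10)), fields_per_well = 25L)
  eff <- data.frame(compound_id = c("cmpA", "cmpB"), dose = 10,
                    p_tau_scale_neurite = c(0.4, 1),
                    p_tau_scale_soma = c(0.4, 1),
                    neurite_area_scale = 1)
  plan <- generate_plate(lay, small_cfg(), eff, seed = 99)
  expect_equal(nrow(plan$fields), 100)
  plan2 <- generate_plate(lay, small_cfg(), eff, seed = 99)
  expect_identical(plan$fields, plan2$fields)
  # DMSO rows carry unit multipliers
  dm <- plan$fields[plan$fields$kind == "dmso", ]
  expect_true(all(dm$p_tau_scale_neurite == 1 & dm$neurite_area_scale == 1))
  # field seeds are distinct across wells and fields
  expect_equal(anyDuplicated(plan$fields$seed), 0)

  expect_error(generate_plate(lay, small_cfg(), eff[1, ], seed = 1),
               "unmapped treatment")
})

test_that("positive-control effect shows up in plate-level truth means", {
  lay <- plate_layout(data.frame(
    well_id = c("A1", "A2"), kind = c("dmso", "positive_control"),
    compound_id = NA, dose = c(NA, 11)), fields_per_well = 3L)
  plan <- generate_plate(lay, small_cfg(), seed = 5,
                         positive_control_effect =
                           list(p_tau_scale_neurite = 0.5,
                                p_tau_scale_soma = 0.5,
                                neurite_area_scale = 1))
  grab <- function(kind) {
    rows <- which(plan$fields$kind == kind)
    mean(sapply(rows, function(i)
      plate_field(plan, i)$truth$compartment_means$p_tau[["neurite"]]))
  }
  ratio <- grab("positive_control") / grab("dmso")
  expect_lt(abs(ratio - 0.5), 0.05)
})
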