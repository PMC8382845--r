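test_that("plate responsiveness applies the 1.3 ratio rule", {
  th <- qc_thresholds()
  r1 <- plate_responsiveness(rep(1.25, 10), rep(1.0, 10), th)
  expect_false(r1$responsive)
  expect_equal(r1$ratio, 1.25)
  r2 <- plate_responsiveness(rep(1.5, 10), rep(1.0, 10), th)
  expect_true(r2$responsive)
  r3 <- plate_responsiveness(rep(2, 5), rep(2, 5), th)
  expect_false(r3$responsive)
  expect_equal(r3$ratio, 1)
  expect_error(plate_responsiveness(numeric(0), rep(1, 5), th),
               "missing control")
})

test_that("ci_lower matches the t-based bound of the mean", {
  expect_equal(ci_lower(rep(5, 10)), 5)
  # {4, 6}: mean 5, SD sqrt(2), t_{0.975,1} = 12.7062...
  expect_equal(ci_lower(c(4, 6)), 5 - qt(0.975, 1) * sqrt(2) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(ci_lower(c(4, 6)), -7.7062047, tolerance = 1e-6)
  v <- c(3, 9, 1, 7, 5)
  expect_equal(ci_lower(v), ci_lower(rev(v)))
  expect_error(ci_lower(4), "insufficient fields")
})

test_that("field QC excludes low-area fields by the within-well and DMSO bounds", {
  # one well: 24 fields at the mean, one at 10% of it
  base <- data.frame(well_id = "B2", kind = "compound",
                     field_index = 0:24,
                     neurite_area = c(rep(4000, 24), 400),
                     excluded = FALSE)
  dmso <- data.frame(well_id = c(rep("A1", 10), rep("A2", 10)),
                     kind = "dmso", field_index = rep(0:9, 2),
                     neurite_area = 4000 + seq(-45, 50, length.out = 20),
                     excluded = FALSE)
  qc <- apply_field_qc(rbind(base, dmso), qc_thresholds())
  m <- qc$metrics
  low <- m$well_id == "B2" & m$neurite_area == 400
  expect_true(all(m$qc_excluded[low]))
  expect_match(m$qc_reason[low], "within_well_ci")
  expect_match(m$qc_reason[low], "dmso_ci")   # 400 also below the DMSO bound
  expect_false(any(m$qc_excluded[m$neurite_area == 4000]))
  # equal-area wells yield no rule-b exclusions
  eq <- data.frame(well_id = "C1", kind = "compound", field_index = 0:9,
                   neurite_area = 4000, excluded = FALSE)
  qc2 <- apply_field_qc(rbind(eq, dmso), qc_thresholds())
  expect_false(any(qc2$metrics$qc_excluded[qc2$metrics$well_id == "C1"]))
})

test_that("QC rules b and c are evaluated on the original field set (commute)", {
  set.seed(2)
  plate <- data.frame(
    well_id = rep(c("A1", "B1"), each = 12),
    kind = rep(c("dmso", "compound"), each = 12),
    field_index = rep(0:11, 2),
    neurite_area = c(4000 + rnorm(12, 0, 80), 3500 + c(rnorm(11, 0, 80), -2500)),
    excluded = FALSE)
  # exercised on the t-based bound of the mean explicitly
  qc <- apply_field_qc(plate, qc_thresholds(ci_method = "mean"))
  # recompute each rule independently from the raw table
  b_bound <- ci_lower(plate$neurite_area[13:24])
  c_bound <- ci_lower(plate$neurite_area[1:12])
  manual_b <- plate$neurite_area < ave(plate$neurite_area, plate$well_id,
                                       FUN = function(v) ci_lower(v))
  manual_c <- plate$neurite_area < c_bound
  expect_identical(qc$metrics$qc_excluded, manual_b | manual_c)
})

test_that("fold change normalizes against the pooled DMSO mean", {
  expect_equal(fold_change_vs_dmso(1, c(2, 2, 2)), 0.5)
  expect_equal(fold_change_vs_dmso(2, c(2, 2, 2)), 1.0)
  ref <- c(1.2, 0.9, 1.1, 0.8)
  expect_equal(mean(fold_change_vs_dmso(ref, ref)), 1, tolerance = 1e-15)
  expect_error(fold_change_vs_dmso(1, numeric(0)), "invalid reference")
  expect_error(fold_change_vs_dmso(1, c(0, 0)), "invalid reference")
})

test_that("z-factor matches the screening-window formula and its invariances", {
  # neg mean 1.0 SD 0.1; pos mean 0.4 SD 0.05 -> 1 - 3*0.15/0.6 = 0.25
  neg <- c(0.9, 1.1); pos <- c(0.35, 0.45)
  expect_equal(sd(neg), sqrt(0.02))
  z <- z_factor(pos, neg)
  expect_equal(z, 1 - 3 * (sd(pos) + sd(neg)) / 0.6, tolerance = 1e-15)
  expect_equal(z_factor(c(0.4, 0.4, 0.4), c(1, 1, 1)), 1)
  expect_error(z_factor(c(1, 1.2), c(1.2, 1)), "zero dynamic range")
  # translation and positive-scale invariance
  set.seed(9)
  a <- rnorm(10, 0.5, 0.05); b <- rnorm(10, 1, 0.05)
  expect_equal(z_factor(a, b), z_factor(a + 7, b + 7), tolerance = 1e-12)
  expect_equal(z_factor(a, b), z_factor(a * 13, b * 13), tolerance = 1e-12)
})

test_that("toxicity flags a > 20% neurite-area decrease", {
  th <- qc_thresholds()
  expect_true(flag_toxicity(0.75, th))
  expect_false(flag_toxicity(0.85, th))
  expect_false(flag_toxicity(1.1, th))
  expect_false(flag_toxicity(0.8, th))   # exactly 20% is tolerated
})

test_that("hit calling demands both compartments, no toxicity, QC pass", {
  tab <- data.frame(
    compound_id = c("both", "neurite_only", "toxic", "inert"),
    fold_ptau_neurite = c(0.5, 0.5, 0.3, 0.95),
    fold_ptau_soma = c(0.5, 0.9, 0.3, 1.0),
    toxic = c(FALSE, FALSE, TRUE, FALSE),
    qc_pass = TRUE)
  out <- call_hits(tab, c(neurite = 0.7, soma = 0.7))
  expect_identical(out$hit, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$neurite_selective, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("4PL fitting recovers parameters and flags flat data", {
  doses <- 10 ^ seq(-8, -4, length.out = 8)
  f4 <- function(x, top, bottom, l50, h)
    bottom + (top - bottom) / (1 + 10 ^ ((l50 - log10(x)) * h))
  y <- f4(doses, 1, 0.2, -6, 1)
  fit <- fit_dose_response(doses, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$top - 1), 1e-6)
  expect_lt(abs(fit$bottom - 0.2), 1e-6)
  expect_lt(abs(fit$log_ic50 + 6), 1e-6)
  expect_lt(abs(fit$hill_slope - 1), 1e-6)
  expect_equal(fit$ic50, 10 ^ fit$log_ic50)

  expect_error(fit_dose_response(doses, rep(1, 8)), "no dose dependence")
  expect_error(fit_dose_response(doses[1:3], y[1:3]), "4 distinct doses")

  set.seed(31)
  errs <- replicate(40, {
    yn <- y * (1 + rnorm(8, 0, 0.05))
    fit_dose_response(doses, yn)$log_ic50 + 6
  })
  expect_lte(median(abs(errs)), 0.1)
})

test_that("run_screen ties QC, normalization, z-factor and hits together", {
  m <- toy_plate_metrics(n_fields = 6)
  # add compounds: a strong active, an inert, a toxic one
  add <- function(m, well, cid, mu, area_scale = 1) {
    rows <- m[m$well_id == "A1", ]
    rows$well_id <- well; rows$kind <- "compound"
    rows$compound_id <- cid; rows$dose <- 10
    rows$mean_ptau_neurite <- mu * (1 + rnorm(6, 0, 0.02))
    rows$mean_ptau_soma <- mu * (1 + rnorm(6, 0, 0.02))
    rows$neurite_area <- rows$neurite_area * area_scale
    rbind(m, rows)
  }
  set.seed(4)
  m <- add(m, "B1", "active", 100)
  m <- add(m, "B2", "inert", 300)
  m <- add(m, "B3", "toxic", 80, area_scale = 0.5)
  res <- run_screen(m, qc_thresholds())
  expect_true(res$qc$responsive)
  expect_equal(res$qc$ratio, 1.5, tolerance = 0.05)
  tab <- res$screen_table
  expect_identical(tab$compound_id[tab$hit], "active")
  # toxicity is read off all non-degenerate fields, so a strong area
  # reduction is flagged even though rule c excludes those fields from
  # the intensity statistics
  expect_identical(tab$compound_id[tab$toxic], "toxic")
  expect_false(tab$hit[tab$compound_id == "toxic"])
  expect_gt(res$z_factors[["mean_ptau_neurite"]], 0)
  # DMSO wells normalize to 1 on average
  expect_equal(mean(res$wells$fold_ptau_neurite[res$wells$kind == "dmso"]),
               1, tolerance = 0.02)
})
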