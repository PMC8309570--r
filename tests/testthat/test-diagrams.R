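band <- function(lo, hi, rate, cv = 0) data.frame(f_lo = lo, f_hi = hi,
                                                  rate = rate, cv = cv)

test_that("identical groups yield an all-0.5 triangular diagram", {
  set.seed(1)
  wtc <- simulate_event_cohort(4, 4, duration_s = 60)
  # give both groups literally the same event streams
  wtc$events <- do.call(rbind, lapply(wtc$subjects$subject_id, function(s) {
    ev <- wtc$events[wtc$events$subject_id == wtc$events$subject_id[1], ]
    ev$subject_id <- s
    ev$group <- wtc$subjects$group[wtc$subjects$subject_id == s]
    ev
  }))
  d <- auc_diagram_2d(wtc, "frequency", lower_bounds = seq(1, 50, 5))
  expect_true(all(d$auc[!is.na(d$auc)] == 0.5))
  # triangular support: defined iff lower <= upper
  expect_identical(is.na(d$auc),
                   !outer(d$lower_bounds, d$upper_bounds, "<="))
  b <- best_cell(d)
  expect_equal(c(b$lower, b$upper), c(1, 46))
  expect_equal(b$auc, 0.5)
})

test_that("group relabelling mirrors every cell around 0.5", {
  set.seed(2)
  wtc <- simulate_event_cohort(5, 6, duration_s = 60,
                               bands = band(1, 50, 1),
                               patient_bands = band(1, 50, 1.5))
  d1 <- auc_diagram_2d(wtc, "frequency", lower_bounds = seq(1, 50, 2))
  d2 <- auc_diagram_2d(wtc, "frequency", lower_bounds = seq(1, 50, 2),
                       positive = "control", negative = "patient")
  expect_equal(d1$auc, 1 - d2$auc)
})

test_that("an injected band excess surfaces in the right cells", {
  set.seed(3)
  wtc <- simulate_event_cohort(8, 8, duration_s = 90,
                               bands = rbind(band(1, 50, 0.5),
                                             band(8, 20, 0.3)),
                               patient_bands = rbind(band(1, 50, 0.5),
                                                     band(8, 20, 0.9)))
  d <- auc_diagram_2d(wtc, "frequency")
  cell <- d$auc[d$lower_bounds == 8, d$upper_bounds == 20]
  expect_gt(cell, 0.8)
  # the (8,20) cell sits in the top decile of all defined cells
  expect_gte(cell, quantile(d$auc[!is.na(d$auc)], 0.9))
  # widening a range never decreases any subject's count: AUC at the
  # full range reflects the total-rate comparison
  full <- d$auc[d$lower_bounds == 1, d$upper_bounds == 50]
  r <- cohort_rates(wtc)
  expect_equal(full, roc_auc(r$rate[r$group == "patient"],
                             r$rate[r$group == "control"]))
  expect_error(auc_diagram_2d(wtc, "volume"), "arg")
})

test_that("constraints on the other parameters sharpen the diagram", {
  set.seed(4)
  wtc <- simulate_event_cohort(6, 6, duration_s = 90,
                               bands = band(1, 50, 3),
                               patient_bands = band(1, 50, 3))
  # patient excess only among high-psd events in 8-20 Hz, diluted by the
  # heavy shared background unless the PSD constraint strips it away
  extra <- simulate_event_cohort(6, 6, duration_s = 90,
                                 bands = band(8, 20, 1e-9),
                                 patient_bands = band(8, 20, 0.15))
  extra$events$psd_max <- extra$events$psd_max * 20
  wtc$events <- rbind(wtc$events, extra$events)
  d_all <- auc_diagram_2d(wtc, "frequency")
  d_hi <- auc_diagram_2d(wtc, "frequency",
                         constraints = parameter_box(min_psd = 300))
  c_all <- d_all$auc[d_all$lower_bounds == 8, d_all$upper_bounds == 20]
  c_hi <- d_hi$auc[d_hi$lower_bounds == 8, d_hi$upper_bounds == 20]
  expect_gt(c_hi, c_all)
  expect_gt(c_hi, 0.9)
})

test_that("best_cell applies the documented tie-breaks", {
  d <- structure(list(parameter = "frequency", lower_bounds = c(1, 5, 10),
                      upper_bounds = c(5, 10, 15),
                      auc = matrix(c(0.5, NA, NA,
                                     0.5, 0.5, NA,
                                     0.5, 0.5, 0.5), 3, 3),
                      n_positive = 5, n_negative = 5),
                 class = "auc_diagram_2d")
  b <- best_cell(d)
  expect_equal(c(b$lower, b$upper), c(1, 15))
  # single perturbed cell wins outright
  d$auc[2, 2] <- 0.9
  expect_equal(best_cell(d)$auc, 0.9)
  # symmetric 0.1 and 0.9: equal scores, widest range wins
  d$auc[2, 2] <- 0.5
  d$auc[1, 1] <- 0.9   # [1,5] width 4
  d$auc[2, 3] <- 0.1   # [5,15] width 10
  b3 <- best_cell(d)
  expect_equal(c(b3$lower, b3$upper, b3$auc), c(5, 15, 0.1))
})

test_that("core_cell reads the band off the near-diagonal run", {
  # an effect confined to [10,20]: each cell's AUC grows with the overlap
  # fraction of its range with the band, so wide cells containing the
  # band saturate while the diagonal dots mark the band itself
  lower <- seq(0, 30, 5)
  upper <- seq(0, 30, 5)
  auc <- matrix(NA_real_, 7, 7)
  for (i in 1:7) for (j in i:7) {
    if (lower[i] <= 10 && upper[j] >= 20) {
      auc[i, j] <- 1                       # saturated containing cells
    } else {
      ov <- max(0, min(upper[j], 20) - max(lower[i], 10))
      w <- max(upper[j] - lower[i], 5)
      auc[i, j] <- 0.5 + 0.45 * ov / w
    }
  }
  d <- structure(list(parameter = "frequency", lower_bounds = lower,
                      upper_bounds = upper, auc = auc,
                      n_positive = 10, n_negative = 10),
                 class = "auc_diagram_2d")
  # best_cell follows its widest-range tie-break into the saturated
  # family; the diagonal reading recovers the band
  expect_equal(best_cell(d)[c("lower", "upper")],
               list(lower = 0, upper = 30))
  cc <- core_cell(d)
  expect_equal(c(cc$lower, cc$upper), c(10, 20))
  # a flat diagram falls back to the best cell (full range)
  d0 <- d
  d0$auc[!is.na(d0$auc)] <- 0.5
  expect_equal(core_cell(d0)[c("lower", "upper")],
               best_cell(d0)[c("lower", "upper")])
  # a blue band reads the same way
  db <- d
  db$auc <- 1 - d$auc
  ccb <- core_cell(db)
  expect_equal(c(ccb$lower, ccb$upper), c(10, 20))
})

test_that("3D slices equal independently built 2D diagrams cell for cell", {
  set.seed(6)
  wtc <- simulate_event_cohort(5, 5, duration_s = 60,
                               bands = band(1, 50, 0.7),
                               patient_bands = rbind(band(1, 50, 0.7),
                                                     band(8, 20, 0.7)))
  d3 <- auc_diagram_3d(wtc, "frequency", range = c(1, 49),
                       resolutions = c(1, 4, 8))
  for (s in d3$slices) {
    edges <- seq(1, 49, length.out = s$R + 1)
    d2 <- auc_diagram_2d(wtc, "frequency", lower_bounds = edges[1:s$R],
                         upper_bounds = edges[-1], with_p = TRUE,
                         cells = "index")
    expect_identical(s$diagram$auc, d2$auc)
    expect_identical(s$diagram$p, d2$p)
    expect_equal(s$alpha_b,
                 bonferroni_alpha(0.05, correction_count(s$R)))
    expect_identical(s$significant, !is.na(d2$p) & d2$p <= s$alpha_b)
  }
  # R = 1: the single cell is the whole-range comparison
  s1 <- d3$slices[[1]]
  r <- cohort_rates(wtc, parameter_box(min_freq = 1, max_freq = 49))
  expect_equal(s1$diagram$auc[1, 1],
               roc_auc(r$rate[r$group == "patient"],
                       r$rate[r$group == "control"]))
  # long export carries one row per admissible cell
  df <- as.data.frame(d3)
  expect_equal(nrow(df), sum(correction_count(c(1, 4, 8))))
  expect_true(all(c("R", "alpha_b", "significant") %in% names(df)))
})

test_that("null cohorts rarely unmask any 3D cell; effects unmask many", {
  set.seed(7)
  nulls <- replicate(25, {
    wtc <- simulate_event_cohort(6, 6, duration_s = 60)
    d3 <- auc_diagram_3d(wtc, "frequency", range = c(1, 49),
                         resolutions = 1:6)
    any(vapply(d3$slices, function(s) any(s$significant), TRUE))
  })
  expect_lte(mean(nulls), 0.2)
  wtc <- simulate_event_cohort(8, 8, duration_s = 90,
                               bands = band(1, 50, 0.3),
                               patient_bands = rbind(band(1, 50, 0.3),
                                                     band(8, 20, 1.5)))
  d3 <- auc_diagram_3d(wtc, "frequency", range = c(1, 49),
                       resolutions = 1:6)
  expect_gt(sum(vapply(d3$slices, function(s) sum(s$significant), 0L)), 3)
})

test_that("refinement recovers a planted band and stops on null data", {
  set.seed(8)
  wtc <- simulate_event_cohort(8, 9, duration_s = 90,
                               bands = rbind(band(1, 50, 0.6, 0.3),
                                             band(8, 20, 0.4, 0.3)),
                               patient_bands = rbind(band(1, 50, 0.6, 0.3),
                                                     band(8, 20, 1.2, 0.3)))
  fit <- refine_wavetrains(wtc)
  expect_s3_class(fit, "wt_refinement")
  expect_gte(nrow(fit$history), 1)
  expect_true(fit$stop_reason %in% c("no_change", "degraded", "max_iter"))
  # the final box localizes the planted band
  expect_lt(abs(fit$box$min_freq - 8), 4)
  expect_lt(abs(fit$box$max_freq - 20), 4)
  # deterministic given fixed events
  fit2 <- refine_wavetrains(wtc)
  expect_identical(fit$box, fit2$box)
  expect_identical(fit$history, fit2$history)
  # refinement never widens past the initial grids
  g <- default_diagram_grids()
  expect_gte(fit$box$min_freq, min(g$frequency$lower))
  expect_lte(fit$box$max_freq, max(g$frequency$upper))
  # null cohort: one applied step, then no_change
  set.seed(9)
  null <- simulate_event_cohort(6, 6, duration_s = 60)
  fit0 <- refine_wavetrains(null)
  expect_equal(fit0$stop_reason, "no_change")
  expect_equal(nrow(fit0$history), 1)
  # degenerate cohorts are refused
  tiny <- simulate_event_cohort(1, 2, duration_s = 30)
  expect_error(refine_wavetrains(tiny), "2 subjects")
})

test_that("diagram rendering writes PNG heatmaps", {
  set.seed(10)
  wtc <- simulate_event_cohort(4, 4, duration_s = 30)
  d <- auc_diagram_2d(wtc, "frequency", lower_bounds = seq(1, 49, 4))
  path <- tempfile(fileext = ".png")
  render_diagram(d, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  img <- png::readPNG(path)
  expect_equal(dim(img)[3], 3)
  # an all-0.5 diagram renders as a uniform mid-colormap image
  d$auc[!is.na(d$auc)] <- 0.5
  p2 <- tempfile(fileext = ".png")
  render_diagram(d, p2)
  img2 <- png::readPNG(p2)
  px <- unique(round(cbind(c(img2[, , 1]), c(img2[, , 2]),
                           c(img2[, , 3])), 2))
  # at most two colors: white for undefined cells plus the mid-scale hue
  expect_lte(nrow(px), 2)
  # 3D export writes one file per slice
  d3 <- auc_diagram_3d(wtc, "frequency", range = c(1, 49),
                       resolutions = c(2, 3))
  p3 <- tempfile(fileext = ".png")
  paths <- render_diagram(d3, p3)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
  # long CSV export
  p4 <- tempfile(fileext = ".csv")
  write_diagram_csv(d, p4)
  expect_true(file.size(p4) > 0)
})
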