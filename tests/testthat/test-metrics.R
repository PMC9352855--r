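toy_structure <- function(rois, n_mrn, n_dmn, n_btw) {
  mrn <- rois$labels[rois$membership == "MRN"]
  dmn <- rois$labels[rois$membership == "DMN"]
  pick <- function(labels_a, labels_b, n) {
    grid <- expand.grid(source = labels_a, target = labels_b,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target, , drop = FALSE]
    grid <- rbind(
      cbind(grid, lag = 0L),
      cbind(grid, lag = 1L)
    )
    grid[seq_len(n), , drop = FALSE]
  }
  paths <- rbind(
    pick(mrn, mrn, n_mrn),
    pick(dmn, dmn, n_dmn),
    pick(mrn, dmn, n_btw)
  )
  network_structure(paths, rois, include_ar = TRUE)
}

test_that("the 35-connection toy reproduces the density profile", {
  rois <- default_roi_set()
  st <- toy_structure(rois, 12, 6, 7)
  met <- compute_metrics(st, rois)
  expect_equal(met$complexity, 35L)
  expect_equal(met$density_mrn, 12 / 35)
  expect_equal(met$density_dmn, 6 / 35)
  expect_equal(met$density_between, 7 / 35)
  # within-MRN > between >= within-DMN, the expected task-network profile
  expect_gt(met$density_mrn, met$density_between)
  expect_gte(met$density_between, met$density_dmn)
  # counting conservation: AR + the three blocks = complexity
  expect_equal(met$n_ar + met$n_within_mrn + met$n_within_dmn + met$n_between,
    met$complexity)
})

test_that("an AR-only network has complexity 10 and zero densities", {
  rois <- default_roi_set()
  met <- compute_metrics(null_structure(rois), rois)
  expect_equal(met$complexity, 10L)
  expect_equal(met$density_mrn, 0)
  expect_equal(met$density_dmn, 0)
  expect_equal(met$density_between, 0)
})

test_that("metrics are invariant under consistent relabeling", {
  rois <- default_roi_set()
  st <- toy_structure(rois, 5, 3, 4)
  met <- compute_metrics(st, rois)
  # rename every ROI; each new name inherits the old region's membership
  map <- setNames(paste0("region_", seq_along(rois$labels)), rois$labels)
  rois2p <- roi_set(unname(map), setNames(rois$membership, unname(map)))
  paths2 <- st$paths
  paths2$source <- unname(map[paths2$source])
  paths2$target <- unname(map[paths2$target])
  met2 <- compute_metrics(network_structure(paths2, rois2p), rois2p)
  expect_equal(met$complexity, met2$complexity)
  expect_equal(met$density_mrn, met2$density_mrn)
  expect_equal(met$density_dmn, met2$density_dmn)
  expect_equal(met$density_between, met2$density_between)
})

test_that("the AR counting rule behaves as configured", {
  rois <- default_roi_set()
  st <- toy_structure(rois, 4, 2, 2)
  m_default <- compute_metrics(st, rois, count_ar_in = "complexity")
  expect_equal(m_default$complexity, 18L)
  expect_equal(m_default$n_within_mrn, 4L)
  m_dens <- compute_metrics(st, rois, count_ar_in = "densities")
  expect_equal(m_dens$complexity, 18L)
  expect_equal(m_dens$n_within_mrn, 4L + 6L) # 6 MRN AR self-loops credited
  m_none <- compute_metrics(st, rois, count_ar_in = "neither")
  expect_equal(m_none$complexity, 8L)
  expect_equal(m_none$density_mrn, 4 / 8)
})

test_that("degenerate and invalid inputs are handled", {
  rois <- rois2()
  empty <- network_structure(NULL, rois, include_ar = FALSE)
  met <- compute_metrics(empty, rois)
  expect_equal(met$complexity, 0L)
  expect_equal(met$density_mrn, 0)
  expect_true(attr(met, "degenerate"))
  st <- network_structure(data.frame(source = "a", target = "b", lag = 0L), rois)
  other <- roi_set(c("x", "y"), c(x = "MRN", y = "DMN"))
  expect_error(compute_metrics(st, other), class = "usemnet_input_error")
})

test_that("sample summaries compute means and n-1 standard deviations", {
  m <- data.frame(
    participant_id = c("a", "b", "c"),
    complexity = c(33, 35, 37),
    density_mrn = c(0.3, 0.3, 0.3),
    density_dmn = c(0.1, 0.2, 0.3),
    density_between = c(0.2, 0.25, 0.3)
  )
  s <- summarize_sample(m)
  expect_equal(s$mean[s$metric == "complexity"], 35)
  expect_equal(s$sd[s$metric == "complexity"], 2)
  expect_equal(s$sd[s$metric == "density_mrn"], 0)
  # order-statistics bound, property-checked over random collections
  for (i in 1:20) {
    set.seed(i)
    mm <- m
    mm$complexity <- sample(20:50, 3)
    ss <- summarize_sample(mm)
    mu <- ss$mean[ss$metric == "complexity"]
    expect_gte(mu, min(mm$complexity))
    expect_lte(mu, max(mm$complexity))
  }
})
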