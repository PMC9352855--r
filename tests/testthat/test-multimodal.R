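make_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    estradiol = abs(rnorm(n, 1.3, 0.7)),
    progesterone = abs(rnorm(n, 239, 125)),
    testosterone = abs(rnorm(n, 133, 65)),
    pct_correct = pmin(pmax(rnorm(n, 75, 8), 0), 100),
    stringsAsFactors = FALSE
  )
}

make_metrics <- function(n, seed = 2) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    complexity = sample(30:40, n, replace = TRUE),
    density_mrn = runif(n, 0.2, 0.4),
    density_dmn = runif(n, 0.1, 0.3),
    density_between = runif(n, 0.1, 0.3),
    stringsAsFactors = FALSE
  )
}

test_that("descriptives reproduce simple arithmetic", {
  r <- make_records(3)
  r$pct_correct <- c(70, 75, 80)
  d <- describe_sample(r)
  expect_equal(d$mean[d$variable == "pct_correct"], 75)
  expect_equal(d$sd[d$variable == "pct_correct"], 5)
  r2 <- r
  r2$estradiol <- rep(1.5, 3)
  expect_equal(describe_sample(r2)$sd[1], 0)
})

test_that("record validation enforces the domain ranges", {
  r <- make_records(3)
  r$estradiol[1] <- -0.5
  expect_error(describe_sample(r), "nonnegative")
  r <- make_records(3)
  r$pct_correct[2] <- 105
  expect_error(describe_sample(r), "0, 100")
})

test_that("correlations match the direct Pearson formula", {
  r <- make_records(4)
  m <- make_metrics(4)
  r$pct_correct <- c(1, 2, 3, 4)
  m$complexity <- c(2, 1, 4, 3)
  cm <- correlate_multimodal(r, m)
  # direct formula oracle
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_direct, 0.6)
  expect_equal(cm$r["pct_correct", "complexity"], 0.6, tolerance = 1e-12)
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("a perfectly linear pair gives r exactly 1", {
  r <- make_records(3)
  m <- make_metrics(3)
  r$estradiol <- c(1, 2, 3)
  m$complexity <- c(2, 4, 6)
  cm <- correlate_multimodal(r, m)
  expect_equal(cm$r["estradiol", "complexity"], 1, tolerance = 1e-12)
})

test_that("affine transforms leave the correlation magnitude unchanged", {
  r <- make_records(8)
  m <- make_metrics(8)
  cm1 <- correlate_multimodal(r, m)
  r2 <- r
  r2$progesterone <- 3.7 * r2$progesterone + 11
  cm2 <- correlate_multimodal(r2, m)
  expect_equal(abs(cm1$r), abs(cm2$r), tolerance = 1e-12)
})

test_that("zero-variance variables yield missing coefficients with a warning", {
  r <- make_records(5)
  m <- make_metrics(5)
  r$testosterone <- rep(100, 5)
  expect_warning(cm <- correlate_multimodal(r, m), "zero-variance")
  expect_true(all(is.na(cm$r["testosterone", setdiff(colnames(cm$r), "testosterone")])))
  expect_equal(cm$r["testosterone", "testosterone"], 1)
})

test_that("the join must be total and per-cell n is recorded", {
  r <- make_records(5)
  m <- make_metrics(4)
  expect_error(correlate_multimodal(r, m), "join")
  r <- make_records(5)
  m <- make_metrics(5)
  r$estradiol[2] <- NA
  cm <- suppressWarnings(correlate_multimodal(r, m))
  expect_equal(cm$n["estradiol", "complexity"], 4)
  expect_equal(cm$n["progesterone", "complexity"], 5)
})

test_that("Spearman correlations are available by flag", {
  r <- make_records(6)
  m <- make_metrics(6)
  cm <- correlate_multimodal(r, m, method = "spearman")
  expect_equal(cm$method, "spearman")
  expect_equal(
    cm$r["pct_correct", "complexity"],
    cor(r$pct_correct, m$complexity, method = "spearman"),
    tolerance = 1e-12
  )
})

test_that("a planted positive behavior-complexity coupling is recovered in sign", {
  hits <- 0L
  for (k in 1:20) {
    tr <- generate_truth(truth_config(), seed = 2000 + k)
    cov <- generate_covariates(tr, hormone_behavior_params(), seed = 3000 + k)
    met <- do.call(rbind, lapply(tr$participants, function(id) {
      m <- compute_metrics(truth_structure(tr, id), tr$rois)
      m$participant_id <- id
      m
    }))
    cm <- correlate_multimodal(cov, met)
    if (cm$r["pct_correct", "complexity"] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
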