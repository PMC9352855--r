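test_that("a planted missing contemporaneous path attains the top score", {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.6 # a -> b omitted from the fitted structure
  Phi <- diag(0.4, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 2000, seed = 21)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- null_structure(rois3())
  mi <- modification_indices(s, st)
  expect_equal(mi$source[1], "a")
  expect_equal(mi$target[1], "b")
  expect_equal(mi$lag[1], 0L)
  expect_lt(mi$pvalue[1], 1e-10)
})

test_that("all scores are nonnegative and carry chi-square(1) p-values", {
  A <- matrix(0, 3, 3)
  Phi <- diag(0.4, 3)
  X <- sim_usem(A, Phi, rep(1, 3), 500, seed = 22)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  mi <- modification_indices(s, null_structure(rois3()))
  expect_true(all(mi$mi >= 0, na.rm = TRUE))
  ok <- is.finite(mi$mi)
  expect_equal(mi$pvalue[ok], pchisq(mi$mi[ok], 1, lower.tail = FALSE))
})

test_that("no candidate is scoreable on a just-identified model", {
  X <- sim_usem(matrix(0, 2, 2), diag(0.4, 2), c(1, 1), 300, seed = 23)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  mi <- modification_indices(s, saturated_structure(rois2()))
  # the remaining admissible additions would push df below 0
  expect_true(all(is.na(mi$mi)))
})

test_that("scores equal exact single-addition refit drops", {
  # acyclic base
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.5
  Phi <- diag(0.4, 3)
  Phi[1, 3] <- 0.3
  X <- sim_usem(A, Phi, rep(1, 3), 800, seed = 24)
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- network_structure(data.frame(source = "a", target = "b", lag = 0L), rois3())
  fit <- fit_usem(s, st, compute_se = FALSE)
  mi <- modification_indices(s, st, fit)
  bf <- brute_force_mi(s, st, mi)
  keep <- is.finite(mi$mi) & is.finite(bf) & bf > 0.5
  expect_true(all(abs(mi$mi[keep] - bf[keep]) / bf[keep] <= 0.10))
  small <- is.finite(mi$mi) & is.finite(bf) & bf <= 0.5
  expect_true(all(abs(mi$mi[small] - bf[small]) <= 0.2))
})

test_that("incremental cache reproduces full rescoring after an addition", {
  A <- matrix(0, 4, 4)
  A[2, 1] <- 0.5
  A[3, 2] <- 0.4
  Phi <- diag(0.4, 4)
  X <- sim_usem(A, Phi, rep(1, 4), 600, seed = 25, labels = c("a", "b", "c", "d"))
  s <- build_lagged_sample(participant_ts("P01", list(X)))
  st <- null_structure(rois4())
  state <- usemnet:::mi_state_init(s, st)
  mi0 <- state$mi
  best <- mi0[which.max(mi0$mi), ]
  st2 <- usemnet:::st_add_path(st, best$source, best$target, best$lag, "group")
  state2 <- usemnet:::mi_state_update(state, s, st2, best)
  full <- modification_indices(s, st2)
  key <- function(d) sprintf("%d:%s>%s", d$lag, d$source, d$target)
  m <- match(key(full), key(state2$mi))
  expect_equal(state2$mi$mi[m], full$mi, tolerance = 1e-8)
})
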