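# Shared fixtures: small ROI sets, directly simulated uSEM data (kept
# independent of the package generator so oracle tests do not lean on the
# code they check), and convenience wrappers.

rois2 <- function() roi_set(c("a", "b"), c(a = "MRN", b = "DMN"))

rois3 <- function() roi_set(c("a", "b", "c"), c(a = "MRN", b = "MRN", c = "DMN"))

rois4 <- function() {
  roi_set(c("a", "b", "c", "d"), c(a = "MRN", b = "MRN", c = "DMN", d = "DMN"))
}

# Simulate eta_t = (I - A)^-1 (Phi eta_{t-1} + zeta_t) directly.
sim_usem <- function(A, Phi, psi, n, seed, burn = 100, labels = NULL) {
  p <- nrow(A)
  set.seed(seed)
  M <- solve(diag(p) - A)
  X <- matrix(0, n + burn, p)
  eta <- numeric(p)
  Z <- matrix(rnorm((n + burn) * p), n + burn, p) %*% diag(sqrt(psi), p)
  for (t in seq_len(n + burn)) {
    eta <- as.numeric(M %*% (Phi %*% eta + Z[t, ]))
    X[t, ] <- eta
  }
  X <- X[(burn + 1):(burn + n), , drop = FALSE]
  colnames(X) <- labels %||% letters[seq_len(p)]
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A just-identified "saturated" structure: every lagged path plus one
# contemporaneous direction per pair (recursive ordering), giving df = 0.
saturated_structure <- function(rois) {
  labels <- if (inherits(rois, "roi_set")) rois$labels else rois
  p <- length(labels)
  lagged <- expand.grid(source = labels, target = labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lagged$lag <- 1L
  cont <- NULL
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      cont <- rbind(cont, data.frame(source = labels[i], target = labels[j],
        lag = 0L, stringsAsFactors = FALSE))
    }
  }
  network_structure(rbind(lagged, cont), rois, include_ar = TRUE)
}

# Exact single-addition chi-square drops by full refit (brute force).
brute_force_mi <- function(sample, structure, cands) {
  base <- fit_usem(sample, structure, compute_se = FALSE)
  vapply(seq_len(nrow(cands)), function(i) {
    st2 <- usemnet:::st_add_path(structure, cands$source[i], cands$target[i],
      cands$lag[i], "individual")
    f2 <- tryCatch(fit_usem(sample, st2, compute_se = FALSE), error = function(e) NULL)
    if (is.null(f2)) NA_real_ else max(base$fit$chi2 - f2$fit$chi2, 0)
  }, 0)
}
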