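# Shared fixtures, built once per test run.

# fast protocol: fewer trials, full leading baseline (keeps the default OD
# reference window valid), still > 3 * FIR order samples
quick_cfg <- function(..., n_trials = 10, seed = 42) {
  sim_config(n_trials = n_trials, seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

# 3-subject (2 strong, 1 weak) x 2 sessions x 2 runs study, short protocol
small_study <- function() {
  if (is.null(.fixtures$small_study)) {
    cfg <- quick_cfg(n_subjects = 3, seed = 99)
    set.seed(99)
    prof <- subject_profiles(cfg, 2, 1)
    .fixtures$small_study <- simulate_study(cfg, prof)
  }
  .fixtures$small_study
}

small_activation <- function() {
  if (is.null(.fixtures$small_activation)) {
    .fixtures$small_activation <- activation_table(small_study())
  }
  .fixtures$small_activation
}

# full-size study at the default conditions (15 subjects), used by the
# acceptance properties; built lazily so module tests stay fast
full_study <- function() {
  if (is.null(.fixtures$full_study)) {
    .fixtures$full_study <- simulate_study(sim_config(seed = 2024))
  }
  .fixtures$full_study
}

full_activation <- function() {
  if (is.null(.fixtures$full_activation)) {
    .fixtures$full_activation <- activation_table(full_study())
  }
  .fixtures$full_activation
}

# brute-force partially-constrained least squares by enumerating every
# support of the constrained columns (oracle for the active-set solver)
nnls_oracle_objective <- function(y, X, mask) {
  C <- which(mask)
  U <- which(!mask)
  best <- Inf
  for (size in 0:length(C)) {
    supports <- if (size == 0) list(integer(0)) else
      utils::combn(C, size, simplify = FALSE)
    for (S in supports) {
      cols <- c(U, S)
      b <- tryCatch(qr.solve(X[, cols, drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(b)) next
      if (length(S) > 0 && any(b[match(S, cols)] < 0)) next
      obj <- sum((y - X[, cols, drop = FALSE] %*% b)^2)
      best <- min(best, obj)
    }
  }
  best
}
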