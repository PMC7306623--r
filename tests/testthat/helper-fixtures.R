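# Shared fixtures and independent oracles for the test suite.

# Small montage (9 electrodes incl. FCz/Cz) for fast CSD and pipeline tests.
tiny_montage <- function() {
  m61 <- montage_61()
  keep <- c("Fz", "FCz", "Cz", "CPz", "Pz", "C3", "C4", "FC3", "FC4")
  montage(keep,
          x = m61$x[match(keep, m61$label)],
          y = m61$y[match(keep, m61$label)],
          z = m61$z[match(keep, m61$label)])
}

# Hand-built epoch set with known per-epoch waveforms (bypasses the pipeline
# order checks; for unit tests of measurement code only).
manual_epochs <- function(waves, times, labels, channels = c("FCz", "Cz"),
                          srate = 500, lock = "response") {
  n_ep <- length(waves)
  dat <- array(0, dim = c(n_ep, length(channels), length(times)))
  for (i in seq_len(n_ep)) dat[i, , ] <- waves[[i]]
  errmon:::new_epoch_set(
    data = dat, times = times, lock = lock, labels = labels,
    qc = tibble::tibble(epoch = seq_len(n_ep), trial = seq_len(n_ep) - 1L,
                        kept = TRUE, reason = NA_character_),
    channels = tibble::tibble(label = channels, kind = "scalp"),
    srate = srate, baseline = c(times[1], 0), artifact_checked = TRUE
  )
}

# A small trial table with every response category represented.
mixed_trials <- function() {
  tibble::tibble(
    trial = 0:5,
    block = c(0L, 0L, 0L, 1L, 1L, 1L),
    stimulus_kind = c("go", "go", "nogo", "nogo", "nogo", "go"),
    color_id = c(3L, 5L, 0L, 0L, 0L, 2L),
    stimulus_onset = c(1000, 3600, 6200, 8800, 11400, 14000),
    rt1 = c(420, NA, 352, 340, NA, 455),
    rt2 = c(NA, NA, 1500, 1100, NA, NA)
  )
}

# Independent dual-QP oracle for the linear soft-margin SVM: exact active-set
# enumeration of the dual problem
#   max sum(a) - 0.5 a' Q a   s.t. sum(a*y) = 0, 0 <= a <= C,
# with Q = (y y') * (X X'). Every variable is enumerated as zero, at the box
# bound C, or free; free variables are solved from the KKT system and each
# feasible configuration's objective is compared. Exact for small n (<= ~8).
qp_svm <- function(X, y, C = 1, tol = 1e-9) {
  lv <- sort(unique(as.character(y)))
  yy <- ifelse(as.character(y) == lv[2], 1, -1)
  n <- nrow(X)
  Q <- (yy %o% yy) * (X %*% t(X))
  best <- NULL
  best_obj <- -Inf
  states <- expand.grid(rep(list(0:2), n))  # 0 = zero, 1 = at C, 2 = free
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    a <- numeric(n)
    a[st == 1] <- C
    free <- which(st == 2)
    if (length(free)) {
      A <- rbind(cbind(Q[free, free, drop = FALSE], yy[free]),
                 c(yy[free], 0))
      rhs <- c(1 - if (any(st == 1)) {
        Q[free, st == 1, drop = FALSE] %*% rep(C, sum(st == 1))
      } else {
        rep(0, length(free))
      },
      -sum(yy[st == 1]) * C)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol[seq_along(free)]
      beta <- sol[length(sol)]
    } else {
      if (abs(sum(a * yy)) > tol) next
      # any beta satisfying the bound KKT conditions works; scan candidates
      grad <- 1 - as.vector(Q %*% a)
      cand <- grad / yy
      betas <- unique(c(cand, 0))
      beta <- NA
      for (bta in betas) {
        kkt <- grad - bta * yy
        if (all(kkt[st == 0] <= tol) && all(kkt[st == 1] >= -tol)) {
          beta <- bta
          break
        }
      }
      if (is.na(beta)) next
    }
    if (any(a < -tol) || any(a > C + tol)) next
    if (abs(sum(a * yy)) > tol) next
    grad <- 1 - as.vector(Q %*% a) - beta * yy
    if (any(grad[st == 0] > tol)) next      # zero vars: gradient must push down
    if (any(grad[st == 1] < -tol)) next     # bound vars: gradient pushes up
    obj <- sum(a) - 0.5 * sum(a * (Q %*% a))
    if (obj > best_obj + 1e-12) {
      best_obj <- obj
      best <- list(a = a, beta = beta)
    }
  }
  a <- best$a
  w <- as.vector(t(X) %*% (a * yy))
  free_sv <- which(a > tol & a < C - tol)
  b <- if (length(free_sv)) {
    mean(yy[free_sv] - as.vector(X[free_sv, , drop = FALSE] %*% w))
  } else {
    # b is any value in the KKT interval: lower bounds come from
    # {y=+1, a=0} and {y=-1, a=C}, upper bounds from the complements
    g <- yy - as.vector(X %*% w)
    lowers <- g[(yy == 1 & a <= tol) | (yy == -1 & a >= C - tol)]
    uppers <- g[(yy == 1 & a >= C - tol) | (yy == -1 & a <= tol)]
    (max(lowers) + min(uppers)) / 2
  }
  list(w = w, b = b, alpha = a, levels = lv, objective = best_obj)
}
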