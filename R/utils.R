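## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

## Log-normal parameterised by arithmetic mean and coefficient of variation.
## CV = 0 degenerates to the constant `mean`.
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

## Multiplicative noise factors with unit mean and given CV.
noise_factors <- function(n, cv) rlnorm_cv(n, mean = 1, cv = cv)

## Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
## `offset` decouples the four generators so each is independently
## reproducible from the same cohort seed.
with_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}

## Row-wise two-sample Student (pooled-variance) t-test on a numeric matrix.
## Vectorised so a full protein table is screened in one pass; agreement with
## stats::t.test(var.equal = TRUE) is enforced in the test suite.
row_t_student <- function(x, grp1, grp2) {
  x1 <- x[, grp1, drop = FALSE]
  x2 <- x[, grp2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
  ## zero pooled variance: identical groups -> no evidence (t = 0, p = 1),
  ## otherwise the difference is exact relative to zero noise.
  degenerate <- se == 0 | !is.finite(se)
  if (any(degenerate)) {
    same <- degenerate & (m1 == m2)
    p[same] <- 1; tstat[same] <- 0
    p[degenerate & !same] <- 0
    tstat[degenerate & !same] <- sign(m1 - m2)[degenerate & !same] * Inf
  }
  list(statistic = tstat, p.value = p, mean1 = m1, mean2 = m2,
       df = n1 + n2 - 2)
}

## Two-sample Student t on vectors; returns NA p when a group has < 2 values.
two_group_t <- function(patient, control) {
  patient <- patient[is.finite(patient)]
  control <- control[is.finite(control)]
  if (length(patient) < 2 || length(control) < 2) {
    return(list(p.value = NA_real_, statistic = NA_real_))
  }
  if (stats::sd(patient) == 0 && stats::sd(control) == 0) {
    if (isTRUE(all.equal(mean(patient), mean(control)))) {
      return(list(p.value = 1, statistic = 0))
    }
    return(list(p.value = 0, statistic = sign(mean(patient) - mean(control)) * Inf))
  }
  ht <- stats::t.test(patient, control, var.equal = TRUE)
  list(p.value = ht$p.value, statistic = unname(ht$statistic))
}

cv_of <- function(x) stats::sd(x) / mean(x)
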