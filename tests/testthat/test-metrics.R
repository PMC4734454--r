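# Observation layer: rates, preferences, bouts, matrix statistics

# independent oracles -----------------------------------------------------

# run lengths by explicit scan (oracle for preference_bouts)
rle_oracle <- function(series) {
  bouts <- integer(0); run <- 0L
  for (v in c(as.logical(series), FALSE)) {
    if (v) run <- run + 1L
    else if (run > 0) { bouts <- c(bouts, run); run <- 0L }
  }
  bouts
}

# brute-force row-wise Pearson + Fisher-z pooling
rowwise_pearson_oracle <- function(A, B) {
  n <- nrow(A); zs <- numeric(0)
  for (i in seq_len(n)) {
    a <- A[i, -i]; b <- B[i, -i]
    if (sd(a) == 0 || sd(b) == 0) next
    zs <- c(zs, atanh(sum((a - mean(a)) * (b - mean(b))) /
                      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))))
  }
  tanh(mean(zs))
}

# exhaustive concordant/discordant pair counting (tau-b)
tau_b_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0) tx <- tx + 1
    if (sy == 0) ty <- ty + 1
    if (sx != 0 && sy != 0) { if (sx == sy) C <- C + 1 else D <- D + 1 }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

tau_rw_oracle <- function(Dm) {
  n <- nrow(Dm)
  taus <- sapply(seq_len(n), function(i) tau_b_oracle(Dm[i, -i], Dm[-i, i]))
  mean(taus, na.rm = TRUE)
}

# ------------------------------------------------------------------------

test_that("hourly rates divide minutes by the 42-hour interval", {
  m <- matrix(0, 3, 3); m[1, 2] <- 21
  r <- hourly_rates(m)
  expect_equal(r$dyadic[1, 2], 0.5)
  expect_equal(r$group_mean, mean(c(0.5, 0, 0)))
  expect_equal(hourly_rates(matrix(0, 3, 3))$group_mean, 0)
  # group mean of identical individual rates is that rate
  m <- matrix(4.2 * 42 / 2, 3, 3); diag(m) <- 0
  expect_equal(hourly_rates(m)$group_mean, 4.2)
  expect_error(hourly_rates(matrix(-1, 2, 2)), ">= 0")
})

test_that("preferred partners need strictly more than 10% of monthly grooming", {
  g <- c(B = 30, C = 15, D = 5)
  expect_equal(preferred_partners(g), c(B = TRUE, C = TRUE, D = FALSE))
  expect_false(any(preferred_partners(rep(0, 19))))
  expect_false(any(preferred_partners(rep(3, 19))))  # 1/19 < 10% each
  # at most 9 shares can strictly exceed 10%
  set.seed(11)
  for (k in 1:200)
    expect_lte(sum(preferred_partners(runif(19, 0, 10))), 9)
})

test_that("preference bouts match a run-length-encoding oracle", {
  s <- c(1, 1, 0, 0, 1, 1, 1, rep(0, 17))
  b <- preference_bouts(s, full_length = 24)
  expect_equal(b$bouts, c(2L, 3L))
  expect_equal(b$mean_bout, 2.5)
  expect_equal(b$total, 5L)
  expect_equal(preference_bouts(rep(TRUE, 24))$bouts, 24L)
  expect_equal(preference_bouts(rep(FALSE, 24))$total, 0L)
  expect_error(preference_bouts(rep(TRUE, 10), full_length = 24), "length")
  set.seed(12)
  for (k in 1:1000) {
    s <- runif(24) < runif(1)
    b <- preference_bouts(s)
    o <- rle_oracle(s)
    expect_equal(b$bouts, o)
    expect_equal(b$total, sum(o))
    expect_lte(b$total, 24)
    expect_equal(b$mean_bout, if (length(o)) mean(o) else 0)
  }
})

test_that("row-wise Pearson equals the brute-force oracle to 1e-12", {
  A <- matrix(rnorm(16), 4, 4)
  expect_equal(as.numeric(rowwise_pearson(A, A)), 1)
  expect_equal(as.numeric(rowwise_pearson(A, -A)), -1)
  set.seed(13)
  for (k in 1:100) {
    n <- sample(4:8, 1)
    A <- matrix(rnorm(n * n), n, n)
    B <- matrix(rnorm(n * n), n, n)
    expect_equal(as.numeric(rowwise_pearson(A, B)),
                 rowwise_pearson_oracle(A, B), tolerance = 1e-12)
  }
  # degenerate rows are skipped; all-degenerate input is flagged
  A <- matrix(1, 3, 3)
  expect_warning(v <- rowwise_pearson(A, A), "degenerate")
  expect_true(is.na(v))
})

test_that("row-wise Kendall reciprocity equals the exhaustive pair-count oracle", {
  # symmetric matrix with within-row variation -> 1
  set.seed(14)
  S <- matrix(rpois(25, 5), 5, 5); S <- S + t(S)
  expect_equal(as.numeric(tau_rw_reciprocity(S)), 1)
  # a matrix whose rows are exactly reversed in its transpose -> -1
  D <- matrix(0, 4, 4)
  D[1, -1] <- c(1, 2, 3); D[-1, 1] <- c(3, 2, 1)
  D[2, -2] <- c(1, 2, 3); D[-2, 2] <- c(3, 2, 1)
  D[3, -3] <- c(2, 1, 3); D[-3, 3] <- c(2, 3, 1)
  D[4, -4] <- c(3, 2, 1); D[-4, 4] <- c(1, 2, 3)
  expect_equal(as.numeric(tau_rw_reciprocity(D)), -1)
  for (k in 1:100) {
    n <- sample(4:7, 1)
    D <- matrix(sample(0:6, n * n, replace = TRUE), n, n)
    diag(D) <- 0
    expect_equal(as.numeric(tau_rw_reciprocity(D)), tau_rw_oracle(D))
    expect_equal(as.numeric(tau_rw_reciprocity(D)),
                 as.numeric(tau_rw_reciprocity(t(D))))
  }
  expect_warning(tau_rw_reciprocity(matrix(1, 3, 3)), "degenerate")
})

test_that("run summaries wire the statistics together consistently", {
  r <- cached_run("smoke_lps0", function() smoke_run(1, lhw = 720, lps = 0))
  s <- summarize_run(r)
  expect_equal(s$mean_bout_min, mean(r$bouts$duration))
  # grooming matrix conservation: logged bout minutes equal accumulated
  # interval minutes inside the recording window
  expect_equal(sum(r$groom_interval),
               sum(pmin(r$bouts$start + r$bouts$duration,
                        r$stab_minutes + r$record_minutes) -
                   pmax(r$bouts$start, r$stab_minutes)),
               tolerance = 1e-8)
  # recomputing the summary is deterministic
  expect_identical(s[], summarize_run(r)[])
})
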