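# Observation and statistical analysis ----------------------------------

#' Hourly grooming rates from accumulated minutes
#'
#' Converts dyadic grooming minutes per recording interval into average
#' hourly rates (minutes of grooming per hour).  For a single interval
#' matrix each entry is `minutes / (interval_minutes / 60)`; for a
#' 3-dimensional array of intervals the rates are averaged over the
#' intervals.
#'
#' @param minutes square matrix, or `n x n x k` array, of dyadic grooming
#'   minutes (actor rows, receiver columns).
#' @param interval_minutes duration of one recording interval (default
#'   2520 min = 42 h).
#' @return list with `dyadic` (rate matrix, min/h), `individual` (row
#'   sums: total rate each actor directs at others) and `group_mean` (the
#'   mean of the individual rates).
#' @export
hourly_rates <- function(minutes, interval_minutes = 2520) {
  if (any(minutes < 0, na.rm = TRUE)) stop("grooming minutes must be >= 0")
  hours <- interval_minutes / 60
  if (length(dim(minutes)) == 3) {
    dyadic <- apply(minutes, c(1, 2), mean) / hours
  } else {
    dyadic <- minutes / hours
  }
  indiv <- rowSums(dyadic, na.rm = TRUE)
  list(dyadic = dyadic, individual = indiv, group_mean = mean(indiv))
}

#' Preferred grooming partners of one actor in one month
#'
#' A partner is preferred when it received strictly more than
#' `threshold` (10 percent) of the actor's total grooming given that
#' month.  An actor that gave no grooming has no preferred partners.
#'
#' @param monthly_given numeric vector of grooming minutes the actor gave
#'   to each partner during one month.
#' @param threshold preference threshold as a fraction (default 0.10).
#' @return logical vector parallel to `monthly_given`.
#' @export
preferred_partners <- function(monthly_given, threshold = 0.10) {
  if (any(monthly_given < 0, na.rm = TRUE)) stop("grooming minutes must be >= 0")
  tot <- sum(monthly_given, na.rm = TRUE)
  if (tot <= 0) return(rep(FALSE, length(monthly_given)))
  out <- monthly_given / tot > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Monthly preference series for all dyads
#'
#' Applies [preferred_partners()] to every actor and month of a monthly
#' grooming array.
#'
#' @param groom_month `n x n x m` array of monthly grooming minutes.
#' @param threshold preference threshold (default 0.10).
#' @return `n x n x m` logical array; `[i, j, k]` is `TRUE` when `j` was a
#'   preferred partner of `i` in month `k`.  Diagonals are `FALSE`.
#' @export
preference_series <- function(groom_month, threshold = 0.10) {
  d <- dim(groom_month)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    m <- groom_month[, , k]
    diag(m) <- 0
    out[, , k] <- t(apply(m, 1, preferred_partners, threshold = threshold))
  }
  out
}

#' Preference-bout statistics of one dyad
#'
#' A preference bout is a maximal run of consecutive months during which
#' the partner stayed preferred.  Dyads with no bouts contribute a mean
#' bout duration of 0 (configurable downstream).
#'
#' @param series logical vector: the dyad's monthly preferred flags in
#'   time order.
#' @param full_length if non-`NULL`, error unless `length(series)` equals
#'   it (a guard for full-run statistics).
#' @return list with `bouts` (integer run lengths in months), `mean_bout`
#'   (0 when there are none) and `total` (sum of bout lengths).
#' @export
preference_bouts <- function(series, full_length = NULL) {
  if (!is.null(full_length) && length(series) != full_length)
    stop("series has length ", length(series), ", expected ", full_length)
  r <- rle(as.logical(series))
  bouts <- r$lengths[r$values]
  list(bouts = as.integer(bouts),
       mean_bout = if (length(bouts)) mean(bouts) else 0,
       total = as.integer(sum(bouts)))
}

#' Dyadic bout-duration and total-duration matrices
#'
#' Summarizes a monthly preference array into per-dyad mean bout
#' durations and total preference durations (months).
#'
#' @param pref `n x n x m` logical array from [preference_series()].
#' @return list of two `n x n` matrices, `mean_bout` and `total`
#'   (diagonals `NA`).
#' @export
preference_durations <- function(pref) {
  n <- dim(pref)[1]
  mb <- matrix(NA_real_, n, n); tot <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    b <- preference_bouts(pref[i, j, ])
    mb[i, j] <- b$mean_bout
    tot[i, j] <- b$total
  }
  list(mean_bout = mb, total = tot)
}

#' Fisher-z pooled mean of correlation coefficients
#'
#' Averages correlations on the z scale (`atanh`) and transforms back.
#' `NA`s are dropped; coefficients of exactly +-1 map to +-Inf on the z
#' scale and saturate the pooled value at +-1.
#'
#' @param r numeric vector of correlation coefficients.
#' @return pooled correlation.
#' @export
fisher_z_mean <- function(r) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  tanh(mean(atanh(r)))
}

#' Row-wise Pearson matrix correlation
#'
#' For each actor row, the Pearson correlation between the off-diagonal
#' entries of `A`'s row and `B`'s row; rows in which either vector has
#' zero variance are skipped.  Row coefficients are combined with a
#' Fisher-z mean.
#'
#' @param A,B square matrices of the same size (e.g. grooming rates and
#'   LIKE attitudes; actor rows, receiver columns, diagonal ignored).
#' @return the pooled correlation; attribute `"rows"` holds the per-row
#'   coefficients (`NA` for skipped rows).
#' @export
rowwise_pearson <- function(A, B) {
  stopifnot(is.matrix(A), all(dim(A) == dim(B)), nrow(A) == ncol(A))
  n <- nrow(A)
  rows <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- A[i, -i]; b <- B[i, -i]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) next
    rows[i] <- stats::cor(a, b)
  }
  if (all(is.na(rows))) {
    warning("all rows degenerate; row-wise correlation undefined")
    out <- NA_real_
  } else out <- fisher_z_mean(rows)
  attr(out, "rows") <- rows
  out
}

# Kendall tau-b between two vectors, computed from its definition by
# exhaustive concordant/discordant pair counting with tie corrections.
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

#' Row-wise Kendall tau reciprocity of a dyadic matrix
#'
#' The group-level reciprocity statistic: for each actor row `i`, the
#' Kendall tau (tau-b, i.e. tie-corrected) between the off-diagonal
#' entries of row `i` of `D` and row `i` of `t(D)` (what `i` directs at
#' each partner versus what each partner directs at `i`), averaged over
#' rows with variation.  A symmetric matrix with within-row variation
#' yields 1.
#'
#' @param D square matrix (e.g. total preference durations); diagonal
#'   ignored.
#' @return mean row-wise tau in `[-1, 1]`; attribute `"rows"` holds the
#'   per-row values.
#' @export
tau_rw_reciprocity <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  rows <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- D[i, -i]; b <- D[-i, i]
    keep <- !is.na(a) & !is.na(b)
    rows[i] <- kendall_tau_b(a[keep], b[keep])
  }
  if (all(is.na(rows))) {
    warning("all rows degenerate; tau_rw undefined")
    out <- NA_real_
  } else out <- mean(rows, na.rm = TRUE)
  attr(out, "rows") <- rows
  out
}
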