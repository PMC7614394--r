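#' Wilcoxon signed-rank test for paired depth measurements
#'
#' From-first-principles paired signed-rank test. Zero differences are
#' dropped (Wilcoxon's original convention); absolute differences are
#' ranked with average ranks for ties; `W+` and `W-` are the rank sums of
#' positive and negative differences. The normal approximation uses
#' `Z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)` with
#' the tie-correction term, and no continuity correction by default. The
#' exact method enumerates all `2^n` sign configurations of the observed
#' rank vector (n <= 20 enforced) and reports
#' `p = min(1, 2 min(P(W+ <= w), P(W+ >= w)))` for the two-tailed case.
#'
#' @param x Numeric vector: first measurement per pair (e.g. imaging
#'   depths), or the paired differences when `y` is `NULL`.
#' @param y Optional second measurement per pair (e.g. reference depths);
#'   differences are `x - y`.
#' @param two_tailed Two-tailed p-value (default `TRUE`); one-tailed
#'   reports the smaller tail.
#' @param method `"auto"` (exact for n <= 15, normal otherwise),
#'   `"exact"`, or `"normal"`.
#' @param continuity Apply a 0.5 continuity correction towards the mean in
#'   the normal approximation. Default `FALSE`.
#' @return An object of class `signed_rank_result`: `W_plus`, `W_minus`,
#'   `Z`, `p` , `n_effective`, `method` (`"exact"` or `"normal_approx"`),
#'   `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, two_tailed = TRUE,
                                 method = c("auto", "exact", "normal"),
                                 continuity = FALSE) {
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(W_plus = 0, W_minus = 0, Z = 0, p = 1,
                          n_effective = 0L, method = "degenerate",
                          degenerate = TRUE),
                     class = "signed_rank_result"))
  }
  r <- rank(abs(d))
  W_plus <- sum(r[d > 0])
  W_minus <- sum(r[d < 0])

  if (method == "auto") method <- if (n <= 15) "exact" else "normal"

  if (method == "exact") {
    if (n > 20) stop("exact enumeration limited to n <= 20")
    dist <- signed_rank_null_distribution(r)
    p_le <- sum(dist$prob[dist$w <= W_plus + 1e-9])
    p_ge <- sum(dist$prob[dist$w >= W_plus - 1e-9])
    p <- if (two_tailed) min(1, 2 * min(p_le, p_ge)) else min(p_le, p_ge)
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    Z <- if (sigma > 0) (W_plus - mu) / sigma else 0
    meth <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    num <- W_plus - mu
    if (continuity) num <- num - sign(num) * 0.5
    Z <- if (sigma > 0) num / sigma else 0
    p <- if (two_tailed) 2 * stats::pnorm(-abs(Z)) else stats::pnorm(-abs(Z))
    p <- min(1, p)
    meth <- "normal_approx"
  }

  structure(list(W_plus = W_plus, W_minus = W_minus, Z = Z, p = p,
                 n_effective = as.integer(n), method = meth,
                 degenerate = FALSE),
            class = "signed_rank_result")
}

#' Exact null distribution of the signed-rank statistic
#'
#' Under the null every difference is independently positive or negative
#' with probability 1/2, so `W+` is the sum of a uniformly random subset
#' of the observed rank vector. All `2^n` subsets are enumerated.
#'
#' @param ranks Rank vector of the absolute differences (average ranks
#'   for ties).
#' @return Data frame with columns `w` (distinct statistic values) and
#'   `prob`.
#' @export
signed_rank_null_distribution <- function(ranks) {
  n <- length(ranks)
  stopifnot(n >= 1, n <= 20)
  sums <- numeric(2^n)
  for (i in seq_len(n)) {
    block <- 2^(i - 1)
    idx <- which(bitwAnd(seq_len(2^n) - 1L, block) > 0)
    sums[idx] <- sums[idx] + ranks[i]
  }
  tab <- table(sums)
  data.frame(w = as.numeric(names(tab)),
             prob = as.numeric(tab) / 2^n)
}

#' Read a paired depth-measurement table
#'
#' CSV with one row per lesion and columns `lesion_id`, `power_w`,
#' `duration_s`, `depth_opus_mm`, `depth_reference_mm`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_paired_depths <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("lesion_id", "power_w", "duration_s",
              "depth_opus_mm", "depth_reference_mm")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("paired depth table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$lesion_id))
    stop("paired depth table must have one row per lesion")
  stopifnot(all(tab$depth_opus_mm > 0), all(tab$depth_reference_mm > 0))
  tab
}

#' Compare imaging and reference depths
#'
#' Runs the two-tailed signed-rank test on `depth_opus_mm` vs
#' `depth_reference_mm` of a paired table.
#'
#' @param table A data frame as returned by [read_paired_depths()].
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return A `signed_rank_result`.
#' @export
compare_depths <- function(table, ...) {
  wilcoxon_signed_rank(table$depth_opus_mm, table$depth_reference_mm, ...)
}
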