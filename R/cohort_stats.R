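# Cohort statistics: exact Mann-Whitney group comparison, Shapiro-Wilk
# normality screen, linear regression goodness of fit, Spearman
# correlation, and the treatment-response report.

#' Exact Mann-Whitney U test
#'
#' The U statistic is computed from mid-ranks. For combined sample size
#' n1 + n2 <= `exact_max` the two-sided p-value is obtained by full
#' enumeration of all C(n1+n2, n1) group assignments, defining
#' p = P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|) under the permutation
#' null (mid-ranks handle ties inside the enumeration). Larger samples
#' use the normal approximation with tie correction and continuity
#' correction. Asymptotic p-values at the group sizes typical of animal
#' studies (4-5 per arm) are unreliable, hence enumeration by default.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max largest n1 + n2 for which enumeration is used
#'   (default 20).
#' @return object of class `mw_test`: `u` (U of the first sample),
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney_exact <- function(x, y, exact_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                       # mid-ranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    idx <- combn(n, n1)
    rs <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(mu * (n + 1 - tie_term) / 6)
    z <- (abs(u_obs - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  structure(list(u = u_obs, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, p = %.5g (%s, n = %d vs %d)\n",
              x$u, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around the standard Shapiro-Wilk implementation, used as
#' a reported normality screen; group comparisons remain nonparametric
#' regardless of the outcome.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `w`, `p`, `n`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (var(x) == 0) stop("sample is constant; normality test undefined")
  sw <- shapiro.test(x)
  list(w = unname(sw$statistic), p = sw$p.value, n = length(x))
}

#' Ordinary least-squares line and goodness of fit
#'
#' @param x,y numeric vectors, n >= 3, `var(x) > 0`.
#' @return list with `slope`, `intercept`, `r2` (1 - SSres/SStot; defined
#'   as 0 when y is constant), `n`.
#' @export
linear_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete observations")
  if (var(x) == 0) stop("x has zero variance")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - intercept - slope * x)^2) / sst
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}

# all permutations of 1..n (n small), one per row
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    block <- (i - 1L) * nrow(p) + seq_len(nrow(p))
    out[block, 1L] <- i
    rest <- seq_len(n)[-i]
    out[block, -1L] <- matrix(rest[p], nrow(p))
  }
  out
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Mid-rank correlation; the two-sided p-value is by full permutation
#' enumeration for n <= `exact_max` (default 9) and by the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors, n >= 4, non-constant.
#' @param exact_max largest n for exact permutation p.
#' @return list with `rho`, `p`, `method`, `n`.
#' @export
spearman_r <- function(x, y, exact_max = 9L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete observations")
  if (var(x) == 0 || var(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_max) {
    P <- perms(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    rho_all <- as.numeric(matrix(ry_c[P], nrow(P)) %*% rx_c) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
    method <- "t_approx"
  }
  list(rho = rho, p = p, method = method, n = n)
}

#' Treatment-response report: group summaries, tests, effect directions
#'
#' For each endpoint marker (mean ADC, anatomic volume, cellular
#' density), computes per-arm means and ranges, the exact Mann-Whitney
#' two-sided p, and whether the observed effect direction matches the
#' expected treatment response (treated ADC higher, volume lower,
#' density lower).
#'
#' @param cohort a `cohort_table` (or data.frame) containing endpoint
#'   rows with columns `arm`, `adc_mean_mm2_s`, `vmri_mm3`,
#'   `density_cells_mm2`; `arm` must include `"treated"` and `"control"`.
#' @return data.frame with one row per marker: group means/min/max, `p`,
#'   `expected_direction`, `direction_ok`.
#' @export
treatment_report <- function(cohort) {
  df <- as.data.frame(cohort)
  df <- df[df$arm %in% c("treated", "control"), , drop = FALSE]
  if (!all(c("treated", "control") %in% df$arm))
    stop("cohort must contain both a treated and a control arm")
  markers <- data.frame(
    marker = c("adc_mean_mm2_s", "vmri_mm3", "density_cells_mm2"),
    expected = c("treated_higher", "treated_lower", "treated_lower"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    m <- markers$marker[i]
    tr <- df[[m]][df$arm == "treated"]
    ct <- df[[m]][df$arm == "control"]
    tr <- tr[!is.na(tr)]; ct <- ct[!is.na(ct)]
    if (!length(tr) || !length(ct))
      stop("marker ", m, " missing in one arm")
    test <- mann_whitney_exact(tr, ct)
    dir_ok <- if (mean(tr) == mean(ct)) NA
    else if (markers$expected[i] == "treated_higher") mean(tr) > mean(ct)
    else mean(tr) < mean(ct)
    data.frame(marker = m, n_treated = length(tr), n_control = length(ct),
               mean_treated = mean(tr), min_treated = min(tr),
               max_treated = max(tr), mean_control = mean(ct),
               min_control = min(ct), max_control = max(ct),
               u = test$u, p = test$p_two_sided,
               expected_direction = markers$expected[i],
               direction_ok = dir_ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
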