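# Permutation t-tests (two-sample and paired).

welch_t <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Two-sided permutation t-test
#'
#' Unpaired: group labels are permuted; paired: within-pair signs are
#' flipped. Whenever the number of distinct relabellings (or sign
#' patterns) is no larger than `n_perm`, the full set is enumerated and
#' the p-value is exact; otherwise `n_perm` random permutations are
#' drawn and p = (1 + #{|t*| >= |t_obs|}) / (n_perm + 1).
#'
#' @param group_a,group_b numeric vectors; in the paired case they must
#'   have equal length and `group_b` pairs with `group_a` elementwise.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed for the sampled case.
#' @param paired logical.
#' @param statistic "welch" (default) or "pooled"; the paired test uses
#'   the one-sample t on differences.
#' @return list of class `perm_test`: t_observed, p_two_sided, n_perm
#'   (permutations actually used), exact (logical), seed. When both
#'   groups have zero variance the statistic is undefined and both
#'   t_observed and p are NA.
#' @export
permutation_t_test <- function(group_a, group_b, n_perm = 9999L,
                               seed = 1L, paired = FALSE,
                               statistic = c("welch", "pooled")) {
  statistic <- match.arg(statistic)
  tfun <- if (statistic == "welch") welch_t else pooled_t
  res <- function(t_obs, p, used, exact) {
    structure(list(t_observed = t_obs, p_two_sided = p, n_perm = used,
                   exact = exact, seed = seed, statistic = statistic,
                   paired = paired),
              class = "perm_test")
  }
  if (paired) {
    if (length(group_a) != length(group_b)) {
      stop("paired test needs equal-length groups")
    }
    d <- group_a - group_b
    if (length(d) < 2) stop("need at least 2 pairs")
    if (stats::sd(d) == 0 && mean(d) == 0) return(res(NA_real_, NA_real_, 0L, TRUE))
    tstat <- function(dd) mean(dd) / (stats::sd(dd) / sqrt(length(dd)))
    t_obs <- tstat(d)
    n <- length(d)
    if (2^n <= n_perm) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      tt <- apply(signs, 1, function(s) tstat(d * s))
      tt[is.nan(tt)] <- 0
      p <- mean(abs(tt) >= abs(t_obs) - 1e-12)
      return(res(t_obs, p, length(tt), TRUE))
    }
    tt <- withr::with_seed(as.integer(seed %% 2147483647), {
      vapply(seq_len(n_perm), function(i) {
        tstat(d * sample(c(-1, 1), n, replace = TRUE))
      }, numeric(1))
    })
    p <- (1 + sum(abs(tt) >= abs(t_obs) - 1e-12, na.rm = TRUE)) / (n_perm + 1)
    return(res(t_obs, p, n_perm, FALSE))
  }
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("need at least 2 values per group")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # no variation anywhere: the statistic is genuinely undefined
    return(res(NA_real_, NA_real_, 0L, TRUE))
  }
  pool <- c(group_a, group_b)
  t_obs <- tfun(group_a, group_b)
  # zero-variance splits with differing means separate completely:
  # t = +/-Inf, kept; 0/0 splits (both groups constant and equal) carry
  # no evidence and count as 0
  clean <- function(tt) { tt[is.nan(tt)] <- 0; tt }
  n_comb <- choose(na + nb, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(na + nb, na)
    tt <- clean(apply(idx, 2, function(ix) tfun(pool[ix], pool[-ix])))
    p <- mean(abs(tt) >= abs(t_obs) - 1e-12)
    return(res(t_obs, p, length(tt), TRUE))
  }
  tt <- clean(withr::with_seed(as.integer(seed %% 2147483647), {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(na + nb, na)
      tfun(pool[ix], pool[-ix])
    }, numeric(1))
  }))
  p <- (1 + sum(abs(tt) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  res(t_obs, p, n_perm, FALSE)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Two-sided %spermutation t-test (%s)\n",
              if (x$paired) "paired " else "", x$statistic))
  cat(sprintf("  t = %.4f, p = %.4g (%s, %d permutations)\n",
              x$t_observed, x$p_two_sided,
              if (x$exact) "exact enumeration" else "sampled", x$n_perm))
  invisible(x)
}
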