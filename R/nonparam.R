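# Group-comparison machinery for repeated-measures designs: parametric
# (repeated-measures one-way ANOVA with Scheffe post hoc) and rank-based
# (Friedman with Steel-Dwass post hoc, Wilcoxon signed-rank). Data enter
# as a complete blocked matrix: rows = subjects (animals), columns =
# repeated treatments (doses or conditions).

as_blocked_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("blocked data must be numeric")
  if (anyNA(m) || any(!is.finite(m)))
    stop("blocked data must be complete and finite (no missing cells); ",
         "listwise deletion is the caller's decision")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 subjects and 2 treatments")
  m
}

new_test_result <- function(method, statistic, df, p_value,
                            degenerate = FALSE, notes = character()) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, degenerate = degenerate, notes = notes),
            class = "cordox_test")
}

#' @export
print.cordox_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 5),
      ", df = ", paste(format(x$df, digits = 5), collapse = ", "),
      ", p = ", format(x$p_value, digits = 4),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Repeated-measures one-way ANOVA
#'
#' Two-way additive decomposition (subjects x treatments) with the subject
#' effect removed: F = MS_treatment / MS_error on
#' (k - 1, (k - 1)(n - 1)) degrees of freedom. No sphericity correction is
#' applied (a deliberate fidelity choice; see the methods vignette).
#'
#' @param data numeric matrix or data frame, rows = subjects, columns =
#'   treatments; complete.
#' @return a `cordox_test` result.
#' @export
rm_anova_oneway <- function(data) {
  m <- as_blocked_matrix(data)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_treat <- ss_treat / df1
  ms_err <- ss_err / df2
  if (ss_treat <= 1e-12 * max(1, ss_tot))
    return(new_test_result("repeated-measures one-way ANOVA", 0, c(df1, df2), 1))
  if (ms_err <= 1e-12 * max(1, ss_tot))
    return(new_test_result("repeated-measures one-way ANOVA", Inf,
                           c(df1, df2), 0, degenerate = TRUE,
                           notes = "zero error variance"))
  f <- ms_treat / ms_err
  new_test_result("repeated-measures one-way ANOVA", f, c(df1, df2),
                  stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Scheffe post hoc contrasts after repeated-measures ANOVA
#'
#' For each unordered treatment pair, the contrast
#' F = n (mean_i - mean_j)^2 / (2 MS_error) is referred to the Scheffe
#' bound: significant when F exceeds (k - 1) F_{alpha; k-1, df_error}, with
#' p = P(F_{k-1, df_error} >= F / (k - 1)). Uses the same error term as
#' [rm_anova_oneway()].
#'
#' @param data blocked matrix (rows = subjects, columns = treatments).
#' @param alpha familywise significance level.
#' @return data frame with one row per unordered pair: `treatment_a`,
#'   `treatment_b`, `statistic` (contrast F), `p_value`, `significant`.
#' @export
scheffe_posthoc <- function(data, alpha = 0.05) {
  m <- as_blocked_matrix(data)
  n <- nrow(m); k <- ncol(m)
  labs <- colnames(m) %||% as.character(seq_len(k))
  grand <- mean(m)
  ss_tot <- sum((m - grand)^2)
  ss_treat <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  df2 <- (k - 1) * (n - 1)
  ms_err <- (ss_tot - ss_treat - ss_subj) / df2
  cm <- colMeans(m)
  pairs <- utils::combn(k, 2)
  out <- data.frame(treatment_a = labs[pairs[1, ]],
                    treatment_b = labs[pairs[2, ]],
                    statistic = NA_real_, p_value = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (ms_err <= 0) {
      delta <- cm[i1] - cm[i2]
      out$statistic[j] <- if (abs(delta) > 0) Inf else 0
      out$p_value[j] <- if (abs(delta) > 0) 0 else 1
    } else {
      f_con <- n * (cm[i1] - cm[i2])^2 / (2 * ms_err)
      out$statistic[j] <- f_con
      out$p_value[j] <- stats::pf(f_con / (k - 1), k - 1, df2,
                                  lower.tail = FALSE)
    }
    out$significant[j] <- out$p_value[j] < alpha
  }
  out
}

friedman_statistic <- function(r_mat) {
  # r_mat: within-block mid-ranks, n x k
  n <- nrow(r_mat); k <- ncol(r_mat)
  rj <- colSums(r_mat)
  q_raw <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  # tie correction: divide by 1 - sum(t^3 - t) / (n k (k^2 - 1))
  tie_term <- sum(apply(r_mat, 1, function(r) {
    t_ <- table(r); sum(t_^3 - t_)
  }))
  corr <- 1 - tie_term / (n * k * (k^2 - 1))
  if (corr <= 0) return(NA_real_)  # all blocks fully tied
  q_raw / corr
}

#' Friedman rank test for complete blocks
#'
#' Tie-corrected Friedman statistic on within-block mid-ranks, referred to
#' chi-square with k - 1 degrees of freedom. When the number of
#' within-block rank assignments (k!)^n is enumerable (<= `exact_limit`),
#' an exact permutation p value is also computed by full enumeration and
#' reported as `p_value`; the chi-square p is kept in `notes`.
#'
#' @param data blocked matrix (rows = subjects/blocks, columns = treatments).
#' @param exact_limit largest (k!)^n for which the exact permutation
#'   distribution is enumerated.
#' @return a `cordox_test` result with extra fields `p_chisq` and
#'   (when computed) `p_exact`.
#' @export
friedman_test <- function(data, exact_limit = 1e6) {
  m <- as_blocked_matrix(data)
  n <- nrow(m); k <- ncol(m)
  r_mat <- t(apply(m, 1, rank, ties.method = "average"))
  q <- friedman_statistic(r_mat)
  if (is.na(q)) {
    res <- new_test_result("Friedman rank test", 0, k - 1, 1,
                           degenerate = TRUE,
                           notes = "all blocks fully tied")
    res$p_chisq <- 1
    return(res)
  }
  p_chisq <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  res <- new_test_result("Friedman rank test", q, k - 1, p_chisq)
  res$p_chisq <- p_chisq
  n_assign <- factorial(k)^n
  if (n_assign <= exact_limit) {
    res$p_exact <- friedman_exact_p(r_mat, q)
    res$p_value <- res$p_exact
    res$notes <- sprintf(
      "exact permutation p over (k!)^n = %d assignments; chi-square p = %.6g",
      n_assign, p_chisq)
  }
  res
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  row <- 1
  for (pos in seq_len(k)) for (r in seq_len(nrow(sub))) {
    v <- integer(k)
    v[pos] <- k
    v[-pos] <- sub[r, ]
    out[row, ] <- v
    row <- row + 1
  }
  out
}

friedman_exact_p <- function(r_mat, q_obs) {
  n <- nrow(r_mat); k <- ncol(r_mat)
  perms <- all_permutations(k)
  np <- nrow(perms)
  # cumulative distribution of rank-sum vectors across blocks
  sums <- matrix(0, nrow = 1, ncol = k)
  ties_cum <- 0
  tie_of_block <- vapply(seq_len(n), function(i) {
    t_ <- table(r_mat[i, ]); sum(t_^3 - t_)
  }, 0)
  for (i in seq_len(n)) {
    block_rows <- perms
    for (j in seq_len(np)) block_rows[j, ] <- r_mat[i, perms[j, ]]
    m_old <- nrow(sums)
    sums <- sums[rep(seq_len(m_old), each = np), , drop = FALSE] +
      block_rows[rep(seq_len(np), times = m_old), , drop = FALSE]
    ties_cum <- ties_cum + tie_of_block[i]
  }
  q_raw_all <- 12 / (n * k * (k + 1)) * rowSums(sums^2) - 3 * n * (k + 1)
  corr <- 1 - ties_cum / (n * k * (k^2 - 1))
  q_all <- q_raw_all / corr
  mean(q_all >= q_obs - 1e-9)
}

#' Steel-Dwass all-pairs rank comparison
#'
#' For each unordered pair of groups, the two samples are jointly
#' mid-ranked and the standardized Wilcoxon rank-sum statistic (with
#' tie-corrected variance) is computed; sqrt(2) |z| is referred to the
#' studentized-range distribution with `k` groups and infinite degrees of
#' freedom (the standard large-sample form of the procedure).
#'
#' @param data blocked matrix whose columns are the groups, or a list of
#'   numeric vectors (groups may then differ in size).
#' @param alpha familywise significance level.
#' @return data frame with one row per unordered pair: `group_a`,
#'   `group_b`, `z` (standardized rank-sum), `statistic`
#'   (sqrt(2) |z|), `p_value`, `significant`, `degenerate`.
#' @export
steel_dwass_posthoc <- function(data, alpha = 0.05) {
  if (is.matrix(data) || is.data.frame(data)) {
    m <- as_blocked_matrix(data)
    groups <- lapply(seq_len(ncol(m)), function(j) m[, j])
    names(groups) <- colnames(m) %||% as.character(seq_len(ncol(m)))
  } else if (is.list(data)) {
    groups <- data
    if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
    stopifnot(all(vapply(groups, is.numeric, TRUE)))
  } else stop("data must be a matrix/data frame or a list of group vectors")
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = names(groups)[pairs[1, ]],
                    group_b = names(groups)[pairs[2, ]],
                    z = NA_real_, statistic = NA_real_, p_value = NA_real_,
                    significant = NA, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    x <- groups[[pairs[1, j]]]; y <- groups[[pairs[2, j]]]
    n1 <- length(x); n2 <- length(y); nn <- n1 + n2
    r <- rank(c(x, y), ties.method = "average")
    w <- sum(r[seq_len(n1)])
    ew <- n1 * (nn + 1) / 2
    t_ <- table(r)
    var_w <- n1 * n2 / 12 * ((nn + 1) - sum(t_^3 - t_) / (nn * (nn - 1)))
    if (var_w <= 0) {
      out$z[j] <- 0; out$statistic[j] <- 0; out$p_value[j] <- 1
      out$degenerate[j] <- TRUE; out$significant[j] <- FALSE
      next
    }
    z <- (w - ew) / sqrt(var_w)
    stat <- sqrt(2) * abs(z)
    p <- stats::ptukey(stat, nmeans = k, df = Inf, lower.tail = FALSE)
    out$z[j] <- z; out$statistic[j] <- stat; out$p_value[j] <- p
    out$significant[j] <- p < alpha
  }
  out
}

#' Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (and counted in `notes`). The statistic is W+, the sum of the mid-ranks
#' of positive differences among |differences|. For n <= `exact_max` the p
#' value enumerates the 2^n equally likely sign assignments exactly (via
#' the signed-rank distribution convolution, valid under ties); beyond
#' that, a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x paired differences, or first sample if `y` given.
#' @param y optional second sample (`x - y` is tested).
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @param exact_max largest n for which `"auto"` enumerates exactly.
#' @return a `cordox_test` result (statistic = W+, df = n used).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, method = c("auto", "exact", "approx"),
                                 exact_max = 25) {
  method <- match.arg(method)
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) stop("differences must be complete")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  notes <- if (n_zero > 0)
    sprintf("%d zero difference(s) dropped", n_zero) else character()
  if (n == 0)
    return(new_test_result("Wilcoxon signed-rank test", 0, 0, 1,
                           degenerate = TRUE,
                           notes = c(notes, "all differences zero")))
  r <- rank(abs(d), ties.method = "average")
  w_pos <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && n <= exact_max)
  if (use_exact) {
    p <- signed_rank_exact_p(r, w_pos)
    meth <- "Wilcoxon signed-rank test (exact)"
  } else {
    ew <- n * (n + 1) / 4
    t_ <- table(r)
    var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(t_^3 - t_) / 48
    if (var_w <= 0)
      return(new_test_result("Wilcoxon signed-rank test", w_pos, n, 1,
                             degenerate = TRUE, notes = notes))
    z <- (w_pos - ew - sign(w_pos - ew) * 0.5) / sqrt(var_w)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    meth <- "Wilcoxon signed-rank test (normal approximation)"
  }
  res <- new_test_result(meth, w_pos, n, p, notes = notes)
  res
}

# Exact two-sided p for W+ given the mid-ranks of |d|: full distribution of
# W+ over the 2^n sign assignments by convolution on a doubled-rank integer
# grid (mid-ranks are multiples of 1/2).
signed_rank_exact_p <- function(r, w_obs) {
  w2 <- as.integer(round(2 * r))  # doubled ranks, integers
  total <- sum(w2)
  counts <- numeric(total + 1)  # index = doubled W+ value + 1
  counts[1] <- 1
  for (w in w2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(w2)
  w2_obs <- round(2 * w_obs)
  p_ge <- sum(probs[(w2_obs + 1):(total + 1)])
  p_le <- sum(probs[seq_len(w2_obs + 1)])
  min(1, 2 * min(p_ge, p_le))
}
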