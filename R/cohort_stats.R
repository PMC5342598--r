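# Cohort statistics: incidence, profile distributions, a two-sided Fisher
# exact test computed by hypergeometric enumeration, and the two-tailed
# paired t-test.

#' Positivity incidence of a group
#'
#' @param labels Character vector of profile labels for one group
#'   (`"NEGATIVE"` vs anything else).
#' @param group Group name for reporting.
#' @return One-row data frame `group`, `n_positive`, `n_total`,
#'   `percent_positive`.
#' @export
#' @examples
#' incidence(c(rep("NKP44_1_DOMINANT", 21), rep("NEGATIVE", 2)), "spontaneous")
incidence <- function(labels, group = "group") {
  if (length(labels) == 0L) stop("empty group: ", group, call. = FALSE)
  n_pos <- sum(labels != "NEGATIVE")
  data.frame(group = group, n_positive = n_pos, n_total = length(labels),
             percent_positive = 100 * n_pos / length(labels),
             stringsAsFactors = FALSE)
}

#' Profile distribution among positive cases of a group
#'
#' Counts and percentages per profile label; the denominator is the number
#' of positive (non-`NEGATIVE`) cases, matching how profile figures are
#' reported (profiles only exist for receptor-positive samples).
#'
#' @param labels Character vector of profile labels for one group.
#' @param group Group name for reporting.
#' @return Data frame `group`, `label`, `count`, `percent` (percentages sum
#'   to 100 over the non-negative labels).
#' @export
profile_distribution <- function(labels, group = "group") {
  if (length(labels) == 0L) stop("empty group: ", group, call. = FALSE)
  pos <- labels[labels != "NEGATIVE"]
  if (length(pos) == 0L) {
    stop("group ", group, " has no positive cases (all NEGATIVE)",
         call. = FALSE)
  }
  tab <- table(pos)
  data.frame(group = group, label = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(pos),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by enumerating the hypergeometric
#' support with the table's margins fixed: p is the sum of point
#' probabilities of every table whose probability does not exceed the
#' observed table's (with a small relative tolerance for floating-point
#' ties). Point probabilities are evaluated from log binomial coefficients,
#' so large counts are handled stably. A table with a zero margin carries no
#' information and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filling the table by rows.
#' @param tie_rel_tol Relative tolerance used when comparing point
#'   probabilities to the observed one (default 1e-7).
#' @return A list of class `ncr_test`: `method`, `p_value`, `table`,
#'   `odds_ratio` (sample odds ratio, for orientation only).
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(6, 1, 5, 16), 2, byrow = TRUE))
fisher_exact_two_sided <- function(tab, tie_rel_tol = 1e-7) {
  if (is.vector(tab) && length(tab) == 4L) {
    tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  }
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(tab < 0) || any(!is.finite(tab)) || any(tab != round(tab))) {
    stop("contingency table must hold finite non-negative integers",
         call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  if (n == 0) stop("empty contingency table", call. = FALSE)
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("degenerate 2x2 table (zero margin); p = 1", call. = FALSE)
    p <- 1
  } else {
    # support of the (1,1) cell given margins
    lo <- max(0, c1 - (n - r1))
    hi <- min(r1, c1)
    k <- lo:hi
    logp <- lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)
    obs <- logp[k == a]
    p <- sum(exp(logp)[logp <= obs + log1p(tie_rel_tol)])
    p <- min(1, p)
  }
  structure(list(method = "FISHER_EXACT_TWO_SIDED",
                 statistic = NA_real_, p_value = p, table = tab,
                 odds_ratio = (a * d) / (b * c_)),
            class = "ncr_test")
}

#' Two-tailed paired t-test
#'
#' For paired measurements, tests whether the mean within-pair difference
#' `d = x - y` is zero: `t = mean(d) / (sd(d) / sqrt(n))` with the
#' (n-1)-denominator standard deviation, and a two-tailed p-value from the
#' Student t distribution with n-1 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 2 pairs).
#' @return A list of class `ncr_test`: `method`, `statistic` (t), `df`,
#'   `p_value`.
#' @export
paired_t_two_tail <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    stop("all within-pair differences are identical (zero variance)",
         call. = FALSE)
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  structure(list(method = "PAIRED_T_TWO_TAIL", statistic = t_stat,
                 df = n - 1, p_value = p),
            class = "ncr_test")
}

#' @export
print.ncr_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) {
    cat(sprintf("  t = %.4f, df = %d\n", x$statistic, x$df))
  }
  cat(sprintf("  p = %.5g\n", x$p_value))
  invisible(x)
}

#' Compare two groups' binary category counts with a Fisher exact test
#'
#' Builds the 2x2 table (rows = groups, columns = the two categories) from
#' two count pairs — e.g. positive/negative incidences, or
#' dominant/non-dominant profile counts — and runs
#' [fisher_exact_two_sided()].
#'
#' @param counts_a,counts_b Length-2 non-negative integer vectors, same
#'   category order.
#' @return List with `table` (2x2 matrix) and `test` (`ncr_test`).
#' @export
#' @examples
#' compare_groups(c(6, 1), c(5, 16)) # elective vs spontaneous NKp44 profiles
compare_groups <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L)
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("each group needs at least one count", call. = FALSE)
  }
  tab <- rbind(as.numeric(counts_a), as.numeric(counts_b))
  rownames(tab) <- c("A", "B")
  list(table = tab, test = fisher_exact_two_sided(tab))
}

# Counts for a label set restricted to two categories (used when building
# 2x2 comparisons from profile distributions).
label_counts <- function(labels, categories) {
  vapply(categories, function(l) sum(labels == l), numeric(1))
}
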