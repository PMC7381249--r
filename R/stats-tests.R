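#' 2x2 contingency tables
#'
#' Cell layout: rows are the phenotype/ratio grouping, columns smoker
#' yes/no —
#' \preformatted{        smoker  non-smoker
#'   group1     a        b
#'   group2     c        d}
#'
#' @param a,b,c,d nonnegative integer cell counts; total must be positive.
#' @return object of class `table2x2`.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  if (sum(cells) == 0) stop("table total must be > 0", call. = FALSE)
  structure(as.list(cells), class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(unlist(x), 2, 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"), c("yes", "no")))
  print(m)
  invisible(x)
}

#' Cross-product odds ratio of a 2x2 table
#'
#' `OR = (a*d) / (b*c)`; with `haldane = TRUE`, 0.5 is added to every cell
#' first (Haldane-Anscombe correction), which also rescues zero denominators.
#'
#' @param t a [table2x2()].
#' @param haldane add 0.5 to all cells.
#' @return a single number.
#' @examples
#' odds_ratio(table2x2(9, 4, 5, 11))  # 4.95
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  stopifnot(inherits(t, "table2x2"))
  k <- if (haldane) 0.5 else 0
  denom <- (t$b + k) * (t$c + k)
  if (denom == 0)
    stop("zero denominator (b*c = 0); use haldane = TRUE", call. = FALSE)
  (t$a + k) * (t$d + k) / denom
}

#' Woolf log-odds-ratio confidence interval
#'
#' @param t a [table2x2()].
#' @param conf confidence level.
#' @param haldane add 0.5 to all cells (required when any cell is 0).
#' @return numeric `c(lower, upper)` on the OR scale.
#' @export
odds_ratio_ci <- function(t, conf = 0.95, haldane = FALSE) {
  stopifnot(inherits(t, "table2x2"))
  k <- if (haldane) 0.5 else 0
  cells <- unlist(t) + k
  if (any(cells == 0)) stop("zero cell; use haldane = TRUE", call. = FALSE)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  unname(exp(c(lo - z * se, lo + z * se)))
}

new_test_result <- function(statistic, p, method, exact, n) {
  structure(list(statistic = statistic, p_two_sided = min(max(p, 0), 1),
                 method = method, exact = exact, n = n),
            class = "fx_test")
}

#' @export
print.fx_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, two-sided p = %g (%s, n = %s)\n",
              x$method, x$statistic, x$p_two_sided,
              if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "+")))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities, over all tables
#' with the observed margins, whose point probability does not exceed the
#' observed table's (with relative tolerance 1e-7 so equal-probability tables
#' are not lost to floating point).
#'
#' @param t a [table2x2()].
#' @return an `fx_test` result (statistic is the observed `a` cell).
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "table2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n)
    stop("all margins must be positive", call. = FALSE)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_test_result(statistic = a, p = p, method = "Fisher exact", exact = TRUE, n = n)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by evaluating the full null distribution of the rank sum
#' over all `choose(nx+ny, nx)` group labelings (computed by the standard
#' count recursion, equivalent to complete enumeration) when the combined
#' size is at most `exact_max_n` and there are no ties across samples;
#' otherwise a normal approximation with tie and continuity corrections. The
#' two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y non-empty numeric vectors (`NA` dropped).
#' @param exact_max_n largest combined sample size for the exact path.
#' @return an `fx_test`; `statistic` is U for the first sample.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && N <= exact_max_n) {
    # null counts of rank-sum W = U + nx(nx+1)/2 over all labelings
    counts <- mw_counts(nx, ny)           # counts[u+1] = #labelings with U = u
    total <- sum(counts)
    lower <- sum(counts[seq_len(U + 1)]) / total        # P(U <= u)
    upper <- sum(counts[(U + 1):length(counts)]) / total # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    return(new_test_result(U, p, "Mann-Whitney U (exact)", TRUE, c(nx, ny)))
  }
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(new_test_result(U, 1, "Mann-Whitney U (normal approx)",
                                          FALSE, c(nx, ny)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- 2 * stats::pnorm(-z)
  new_test_result(U, min(p, 1), "Mann-Whitney U (normal approx)", FALSE, c(nx, ny))
}

# Number of labelings with each U value in 0..nx*ny: classic partition
# recursion N(u; m, n) = N(u - n; m-1, n) + N(u; m, n-1), which aggregates
# the full C(nx+ny, nx) enumeration.
mw_counts <- function(nx, ny) {
  f <- vector("list", ny + 1)
  for (n in 0:ny) f[[n + 1]] <- c(1)  # m = 0 row: U = 0 only
  for (m in seq_len(nx)) {
    g <- vector("list", ny + 1)
    g[[1]] <- c(1)  # n = 0: U = 0 only
    for (n in seq_len(ny)) {
      a <- g[[n]]                      # N(u; m, n-1)
      b <- f[[n + 1]]                  # N(u; m-1, n), shift by n
      len <- m * n + 1
      av <- c(a, numeric(len - length(a)))
      bv <- c(numeric(n), b)
      bv <- c(bv, numeric(len - length(bv)))
      g[[n + 1]] <- av + bv
    }
    f <- g
  }
  f[[ny + 1]]
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. Exact two-sided p by evaluating the null
#' distribution of the positive-rank sum over all `2^n` sign assignments
#' (generating-function expansion, equivalent to complete enumeration) when
#' `n <= exact_max_n` and no `|differences|` are tied; otherwise a normal
#' approximation with tie and continuity corrections. Two-sided p doubles the
#' smaller tail, capped at 1.
#'
#' @param diffs numeric vector of paired differences (`NA` dropped).
#' @param exact_max_n largest n for the exact path.
#' @return an `fx_test`; `statistic` is V, the positive-rank sum. All-zero
#'   differences give p = 1 with n = 0.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max_n = 25) {
  diffs <- diffs[!is.na(diffs)]
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n == 0) {
    out <- new_test_result(0, 1, "Wilcoxon signed rank (all differences zero)",
                           TRUE, 0)
    return(out)
  }
  r <- rank(abs(diffs))
  V <- sum(r[diffs > 0])
  ties <- anyDuplicated(abs(diffs)) > 0
  if (!ties && n <= exact_max_n) {
    counts <- wsr_counts(n)             # counts[v+1] = #sign assignments with V = v
    total <- 2^n
    lower <- sum(counts[seq_len(V + 1)]) / total
    upper <- sum(counts[(V + 1):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    return(new_test_result(V, p, "Wilcoxon signed rank (exact)", TRUE, n))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(diffs))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(new_test_result(V, 1, "Wilcoxon signed rank (normal approx)",
                                          FALSE, n))
  z <- max((abs(V - mu) - 0.5), 0) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-z)
  new_test_result(V, min(p, 1), "Wilcoxon signed rank (normal approx)", FALSE, n)
}

# Null distribution of the positive-rank sum: expand prod_r (1 + x^r).
wsr_counts <- function(n) {
  counts <- 1
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), counts)
    counts <- c(counts, numeric(r)) + shifted
  }
  counts
}
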