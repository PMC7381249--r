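# Independent brute-force oracles, deliberately naive: literal enumeration
# only, no shared code with the implementation paths they check.

# Mann-Whitney: enumerate all C(nx+ny, nx) group labelings.
bf_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  labelings <- utils::combn(nx + ny, nx)
  us <- apply(labelings, 2, u_of)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# Wilcoxon signed rank: enumerate all 2^n sign assignments.
bf_wilcoxon_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  lower <- mean(vs <= v_obs)
  upper <- mean(vs >= v_obs)
  min(1, 2 * min(lower, upper))
}

# Fisher: enumerate the hypergeometric support directly from factorials.
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  tab_prob <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    if (min(bb, cc, dd) < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
          lfactorial(n) - lfactorial(aa) - lfactorial(bb) - lfactorial(cc) -
          lfactorial(dd))
  }
  support <- 0:min(r1, c1)
  probs <- vapply(support, tab_prob, numeric(1))
  probs <- probs[!is.na(probs)]
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small seeded expression matrix builder
rand_expr <- function(nf = 6, ns = 4, kind = "raw_intensity", seed = 1,
                      gen = function(n) round(runif(n, 10, 500), 3)) {
  set.seed(seed)
  m <- matrix(gen(nf * ns), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  expr_matrix(m, kind)
}

# paired-sample qPCR nicotine pipeline used by several tests: CT tables ->
# quantities -> RQ on control medians -> classified ratios for both conditions
qpcr_ratio_pipeline <- function(sim, panel = analyte_panel(),
                                hi = 1.5, lo = 2 / 3) {
  rq_ctrl <- relative_quantity_to_median(panel_dct_quantities(sim$ct_control, panel))
  med <- attr(rq_ctrl, "scope_medians")
  q_nic <- panel_dct_quantities(sim$ct_nicotine, panel)
  rq_nic <- expr_matrix(unclass(q_nic)[names(med), , drop = FALSE] / med, "rq")
  attr(rq_nic, "normalization_scope") <- "vs_cohort_median"
  list(control = classify_ratio(mrna_mir_ratio(rq_ctrl, panel), hi, lo),
       nicotine = classify_ratio(mrna_mir_ratio(rq_nic, panel), hi, lo),
       rq_control = rq_ctrl, rq_nicotine = rq_nic)
}
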