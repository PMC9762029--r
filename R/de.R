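# Statistical core: Seurat-convention fold change, a MAST-style two-part
# hurdle test, a tie-aware paired signed-rank test, and BH adjustment.

#' Log2 fold change between two groups of log-normalized values
#'
#' Seurat-convention fold change: the log-normalized values are mapped back to
#' normalized counts with `expm1`, averaged over *all* cells of each group
#' (zeros included), and compared with a pseudocount of 1:
#' `log2(mean(expm1(xa)) + 1) - log2(mean(expm1(xb)) + 1)`.
#'
#' @param xa,xb Non-empty numeric vectors of lognorm-layer values.
#' @return A single log2 fold change; antisymmetric in its arguments.
#' @export
#' @examples
#' fold_change(log1p(c(3, 3)), log1p(c(1, 1)))  # log2(4) - log2(2) = 1
fold_change <- function(xa, xb) {
  if (length(xa) == 0 || length(xb) == 0) {
    stop("fold_change requires non-empty groups", call. = FALSE)
  }
  log2(mean(expm1(xa)) + 1) - log2(mean(expm1(xb)) + 1)
}

# Vectorized two-part hurdle machinery ------------------------------------
#
# Detection part: G (likelihood-ratio) statistic on the 2x2 table of
# (value > 0) x group; available when the detection margin varies.
# Continuous part: Welch t on the positive values, converted to a 1-df
# deviance through the normal-quantile transform of its two-sided p;
# available when both groups have >= 2 positive values.
# Total: sum of available parts ~ chi-square with df = number of parts.
hurdle_core <- function(n_a, n_b, pos_a, pos_b, sum_a, sum_b, ss_a, ss_b) {
  n_tot <- n_a + n_b
  c1 <- pos_a + pos_b
  gterm <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  e11 <- n_a * c1 / n_tot
  e12 <- n_a * (n_tot - c1) / n_tot
  e21 <- n_b * c1 / n_tot
  e22 <- n_b * (n_tot - c1) / n_tot
  G <- 2 * (gterm(pos_a, e11) + gterm(n_a - pos_a, e12) +
              gterm(pos_b, e21) + gterm(n_b - pos_b, e22))
  # the detection margin is degenerate below 2: with 0 or 1 minority cells
  # the conditional table distribution collapses to (near) a point mass
  det_avail <- c1 >= 2 & n_tot - c1 >= 2

  cont_avail <- pos_a >= 2 & pos_b >= 2
  m_a <- ifelse(pos_a > 0, sum_a / pos_a, 0)
  m_b <- ifelse(pos_b > 0, sum_b / pos_b, 0)
  v_a <- ifelse(pos_a > 1, pmax(0, (ss_a - pos_a * m_a^2) / (pos_a - 1)), 0)
  v_b <- ifelse(pos_b > 1, pmax(0, (ss_b - pos_b * m_b^2) / (pos_b - 1)), 0)
  se2 <- v_a / pmax(pos_a, 1) + v_b / pmax(pos_b, 1)
  tstat <- ifelse(se2 > 0, (m_a - m_b) / sqrt(se2),
                  ifelse(m_a == m_b, 0, Inf))
  df_w <- ifelse(se2 > 0,
                 se2^2 / ((v_a / pmax(pos_a, 1))^2 / pmax(pos_a - 1, 1) +
                            (v_b / pmax(pos_b, 1))^2 / pmax(pos_b - 1, 1)),
                 1)
  p_t <- ifelse(is.finite(tstat),
                2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE),
                0)
  p_t <- pmin(1, p_t)
  dev_t <- stats::qchisq(p_t, df = 1, lower.tail = FALSE)

  stat <- ifelse(det_avail, G, 0) + ifelse(cont_avail, dev_t, 0)
  df <- as.numeric(det_avail) + as.numeric(cont_avail)
  ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)
}

#' Two-part hurdle test for single-cell differential expression
#'
#' MAST-style hurdle test on log-normalized values: a G (likelihood-ratio)
#' test on the 2x2 detection table of (value > 0) by group, plus a Welch
#' two-sample t test on the positive values converted to a 1-df deviance via
#' the normal-quantile transform of its two-sided p. The two deviances are
#' summed and referred to a chi-square distribution whose degrees of freedom
#' equal the number of available parts (the continuous part needs at least two
#' positive values per group; the detection part needs a non-degenerate
#' detection margin). When both groups are all-zero the test returns p = 1.
#'
#' @param xa,xb Non-empty numeric vectors of lognorm-layer values.
#' @return Two-sided p-value in \[0, 1\].
#' @export
#' @examples
#' hurdle_test(c(0, 0, 0), c(2.1, 1.7, 2.5))
hurdle_test <- function(xa, xb) {
  if (length(xa) == 0 || length(xb) == 0) {
    stop("hurdle_test requires non-empty groups", call. = FALSE)
  }
  hurdle_core(
    n_a = length(xa), n_b = length(xb),
    pos_a = sum(xa > 0), pos_b = sum(xb > 0),
    sum_a = sum(xa[xa > 0]), sum_b = sum(xb[xb > 0]),
    ss_a = sum(xa[xa > 0]^2), ss_b = sum(xb[xb > 0]^2)
  )
}

# Per-row positive-value summaries of a sparse lognorm submatrix.
row_group_stats <- function(X, idx) {
  Xs <- X[, idx, drop = FALSE]
  pos <- Matrix::rowSums(Xs > 0)
  s <- Matrix::rowSums(Xs)
  Xq <- Xs
  Xq@x <- Xq@x^2
  ss <- Matrix::rowSums(Xq)
  Xe <- Xs
  Xe@x <- expm1(Xe@x)
  list(n = length(idx), pos = pos, sum = s, ss = ss,
       sum_expm1 = Matrix::rowSums(Xe))
}

#' Genewise differential expression between two cell groups
#'
#' Runs [hurdle_test()] and [fold_change()] for every gene between two sets of
#' cells, vectorized over the sparse lognorm layer (no densification).
#'
#' @param ds An [sc_dataset()] with a lognorm layer.
#' @param cells_a,cells_b Barcode character vectors (or logical/integer column
#'   indexes) defining the two groups; group a is the "target".
#' @param adjust Apply BH adjustment across genes (adds a `q` column).
#' @return A tibble: `gene_id`, `log2fc` (a minus b), `p`, optionally `q`,
#'   `pct_a`, `pct_b` (fractions of cells with a nonzero value).
#' @export
de_test <- function(ds, cells_a, cells_b, adjust = TRUE) {
  X <- get_lognorm(ds, "de_test")
  to_idx <- function(v) {
    if (is.character(v)) match(v, colnames(X)) else seq_len(ncol(X))[v]
  }
  ia <- to_idx(cells_a)
  ib <- to_idx(cells_b)
  if (length(ia) == 0 || length(ib) == 0 || anyNA(ia) || anyNA(ib)) {
    stop("both cell groups must be non-empty and resolve to matrix columns",
         call. = FALSE)
  }
  a <- row_group_stats(X, ia)
  b <- row_group_stats(X, ib)
  p <- hurdle_core(a$n, b$n, a$pos, b$pos, a$sum, b$sum, a$ss, b$ss)
  log2fc <- log2(a$sum_expm1 / a$n + 1) - log2(b$sum_expm1 / b$n + 1)
  out <- tibble(
    gene_id = rownames(X),
    log2fc = as.numeric(log2fc),
    p = as.numeric(p),
    pct_a = as.numeric(a$pos / a$n),
    pct_b = as.numeric(b$pos / b$n)
  )
  if (adjust) out$q <- bh_adjust(out$p)
  out
}

# Paired signed-rank ------------------------------------------------------

# Exact tie-aware null distribution of 2*W+ by dynamic programming over the
# doubled midranks (integers even under ties).
signed_rank_exact_p <- function(r, w_obs) {
  w <- as.integer(round(2 * r))
  total <- sum(w)
  f <- numeric(total + 1)
  f[1] <- 1
  for (wi in w) {
    g <- f
    g[(wi + 1):(total + 1)] <- g[(wi + 1):(total + 1)] + f[1:(total + 1 - wi)]
    f <- g / 2
  }
  w2 <- as.integer(round(2 * w_obs))
  lower <- sum(f[1:(w2 + 1)])
  upper <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences, used for homoeolog
#' dominance calls where the two copies are measured in the same cells. Zero
#' differences are dropped. With at most 25 nonzero differences the null
#' distribution of the rank sum is enumerated exactly (tie-aware, via dynamic
#' programming over midranks); otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Equal-length numeric vectors of per-cell values over the same
#'   cells.
#' @return Two-sided p-value; 1 when all differences are zero.
#' @export
#' @examples
#' paired_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))  # 2/64
paired_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (paired per cell)", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    return(signed_rank_exact_p(r, W))
  }
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2)) / 2
  if (sigma == 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to input order. A thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
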