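#' Audic-Claverie two-library exact test
#'
#' Tests whether a gene's tag count differs between two libraries of sizes
#' `N1` and `N2`. Conditional on the count `x` observed in library 1, the
#' count in library 2 under the null of equal rates follows
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},}
#' a negative-binomial tail model. The two-sided p-value is
#' `min(1, 2 * min(P(Y <= y), P(Y >= y)))`. Tails are summed exactly in
#' log space (log-gamma terms, summed from the lower side); no normal
#' approximation is used, and the computation is overflow-free for
#' `x + y` up to about 1e6.
#'
#' @param x,y Tag counts in library 1 (control) and library 2 (treatment);
#'   vectors are recycled to a common length.
#' @param N1,N2 Total tag counts of the two libraries (positive).
#' @return Vector of two-sided p-values in `(0, 1]`.
#' @examples
#' audic_claverie_p(5, 5, 1e5, 1e5)       # symmetric case: 1
#' audic_claverie_p(0, 10, 1e5, 1e5)      # 2^(1 - 10)
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) {
    stop_input("library totals N1, N2 must be positive")
  }
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  N1 <- rep_len(as.numeric(N1), n); N2 <- rep_len(as.numeric(N2), n)
  assert_that(all(x >= 0) && all(y >= 0) && all(x <= N1) && all(y <= N2),
              "counts must satisfy 0 <= x <= N1, 0 <= y <= N2")

  key <- paste(x, y, N1, N2)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    ac_two_sided(x[i], y[i], N2[i] / N1[i])
  }, numeric(1))
  pu[match(key, key[uk])]
}

## log p(k | x) for k = 0..kmax under the conditional model with r = N2/N1
ac_log_terms <- function(x, kmax, r) {
  k <- 0:kmax
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

## P(Y >= y | x): summed upward from k = y; the term ratio
## (x+k+1)/(k+1) * r/(1+r) is < 1 for all k >= r*x, so for y above the
## conditional mean (x+1)*r the series converges geometrically
ac_upper_direct <- function(x, y, r) {
  lp <- y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  s <- 1; t <- 1; k <- y
  repeat {
    t <- t * ((x + k + 1) / (k + 1)) * (r / (1 + r))
    s <- s + t
    k <- k + 1
    if (t < s * 1e-18) break
  }
  exp(lp) * s
}

## each tail is summed from its own small side so neither ever comes from
## a 1 - (nearly 1) subtraction
ac_two_sided <- function(x, y, r) {
  if (y <= (x + 1) * r) {
    lt <- ac_log_terms(x, y, r)
    lower <- min(exp(logsumexp(lt)), 1)
    upper <- if (y == 0) 1 else
      max(1 - exp(logsumexp(lt[seq_len(y)])), 0)
  } else {
    upper <- min(ac_upper_direct(x, y, r), 1)
    lower <- max(1 - ac_upper_direct(x, y + 1, r), 0)
  }
  # extremely discordant counts underflow to 0; keep p in (0, 1]
  max(min(1, 2 * min(lower, upper)), .Machine$double.xmin)
}

#' Log2 expression ratio with a zero floor
#'
#' `log2(max(treat, floor) / max(ctrl, floor))` on the TPM scale. The
#' default floor used by [diff_expression()] is the TPM of a single tag in
#' the smaller library (`1e6 / min(N1, N2)`), which keeps genes observed
#' in only one library at large finite ratios rather than infinities.
#'
#' @param tpm_treat,tpm_ctrl Non-negative expression values (recycled).
#' @param zero_floor Positive floor substituted for values below it.
#' @return Vector of log2 ratios (treatment over control).
#' @export
log2_tpm_ratio <- function(tpm_treat, tpm_ctrl, zero_floor) {
  assert_that(all(tpm_treat >= 0) && all(tpm_ctrl >= 0),
              "expression values must be non-negative")
  assert_that(zero_floor > 0, "zero_floor must be positive")
  log2(pmax(tpm_treat, zero_floor) / pmax(tpm_ctrl, zero_floor))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output is order-preserving with the input,
#' elementwise no smaller than the input, and capped at 1.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @return Adjusted values (the smallest FDR at which each test would be
#'   called significant).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  assert_that(all(p_values > 0 & p_values <= 1),
              "p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the conjunction of an FDR ceiling and a minimum absolute log2
#' ratio; direction follows the sign of the ratio.
#'
#' @param results A data.frame/data.table with columns `fdr` and
#'   `log2ratio`.
#' @param fdr_max FDR ceiling (default 0.001).
#' @param min_abs_log2 Minimum `|log2ratio|` (default 1).
#' @return `results` with a `call` column in `{"up", "down", "ns"}`.
#' @export
call_degs <- function(results, fdr_max = 0.001, min_abs_log2 = 1) {
  results <- as.data.table(results)
  assert_that(all(c("fdr", "log2ratio") %in% names(results)),
              "results needs fdr and log2ratio columns")
  results[, call := ifelse(fdr <= fdr_max & log2ratio >= min_abs_log2, "up",
                    ifelse(fdr <= fdr_max & log2ratio <= -min_abs_log2,
                           "down", "ns"))]
  results[]
}

#' Two-library differential expression
#'
#' Runs the Audic-Claverie test gene by gene between a control and a
#' treated expression table, adjusts p-values by Benjamini-Hochberg, and
#' calls DEGs at the given thresholds. Ratios are computed on the TPM
#' scale; library totals default to total clean tags.
#'
#' @param ctrl,treat `expression_table` objects over the same gene
#'   universe (TPM filled in; [tpm_normalize()] is applied with the
#'   default denominator if not).
#' @param fdr_max,min_abs_log2 DEG thresholds (defaults 0.001 and 1).
#' @param zero_floor Floor for zero TPM; default `1e6 / min(N1, N2)`.
#' @param totals Which library total to use as `N1`/`N2`: `"clean"`
#'   (default) or `"unambiguous"`.
#' @return A `data.table` with columns `gene_id`, `x`, `y`, `tpm_ctrl`,
#'   `tpm_treat`, `log2ratio`, `p_value`, `fdr`, `call`; attributes `N1`,
#'   `N2` carry the totals used.
#' @export
diff_expression <- function(ctrl, treat, fdr_max = 0.001, min_abs_log2 = 1,
                            zero_floor = NULL,
                            totals = c("clean", "unambiguous")) {
  totals <- match.arg(totals)
  for (tb in list(ctrl, treat)) {
    assert_that(inherits(tb, "expression_table"),
                "ctrl and treat must be expression_table objects")
  }
  assert_that(identical(ctrl$expr$gene_id, treat$expr$gene_id),
              "expression tables must share one gene universe")
  if (is.na(ctrl$denominator)) ctrl <- tpm_normalize(ctrl)
  if (is.na(treat$denominator)) treat <- tpm_normalize(treat)
  N1 <- ctrl$totals[[totals]]
  N2 <- treat$totals[[totals]]
  floor_tpm <- zero_floor %||% (1e6 / min(N1, N2))

  res <- data.table(gene_id = ctrl$expr$gene_id,
                    x = ctrl$expr$count, y = treat$expr$count,
                    tpm_ctrl = ctrl$expr$tpm, tpm_treat = treat$expr$tpm)
  res[, log2ratio := log2_tpm_ratio(tpm_treat, tpm_ctrl, floor_tpm)]
  res[, p_value := audic_claverie_p(x, y, N1, N2)]
  res[, fdr := bh_fdr(p_value)]
  res <- call_degs(res, fdr_max, min_abs_log2)
  setattr(res, "N1", N1)
  setattr(res, "N2", N2)
  res[]
}

#' Intersect DEG calls from two comparisons
#'
#' @param comparison_a,comparison_b Results from [diff_expression()] (or
#'   any table with `gene_id` and `call`) over the same gene universe.
#' @return List with `common_up` and `common_down`: genes called in the
#'   same direction in both comparisons. Genes with opposite calls appear
#'   in neither set.
#' @export
common_degs <- function(comparison_a, comparison_b) {
  a <- as.data.table(comparison_a)
  b <- as.data.table(comparison_b)
  if (!setequal(a$gene_id, b$gene_id)) {
    stop_input("comparisons cover different gene universes")
  }
  up_a <- a$gene_id[a$call == "up"]; up_b <- b$gene_id[b$call == "up"]
  dn_a <- a$gene_id[a$call == "down"]; dn_b <- b$gene_id[b$call == "down"]
  list(common_up = sort(intersect(up_a, up_b)),
       common_down = sort(intersect(dn_a, dn_b)))
}
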