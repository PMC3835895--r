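#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing `m` or more DEGs annotated to a term under the
#' hypergeometric null,
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} \big/
#'   \binom{N}{n},}
#' where `N` is the number of annotated genes, `n` the number of DEGs among
#' them, `M` the genes annotated to the term, and `m` the DEGs annotated to
#' the term. Computed as the direct upper-tail sum of exact binomial
#' coefficients in log space.
#'
#' @param N,n,M,m Integer counts satisfying `0 <= m <= min(n, M)`,
#'   `M <= N`, `n <= N` (vectors are recycled).
#' @return Upper-tail p-values in `(0, 1]`; `m = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(6, 3, 3, 3)  # 1/20
#' @export
hypergeom_upper_tail <- function(N, n, M, m) {
  len <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, len); n <- rep_len(n, len)
  M <- rep_len(M, len); m <- rep_len(m, len)
  assert_that(all(M <= N) && all(n <= N) && all(m >= 0) &&
                all(m <= pmin(n, M)),
              "need 0 <= m <= min(n, M), M <= N, n <= N")
  vapply(seq_len(len), function(j) {
    i <- seq.int(m[j], min(n[j], M[j]))
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(exp(logsumexp(lt)), 1)
  }, numeric(1))
}

#' Term enrichment of a DEG set
#'
#' Tests each annotation term for over-representation among DEGs with the
#' exact hypergeometric upper tail, against a background restricted to
#' annotated genes (which defines `N`). Multiple-testing correction is
#' Bonferroni by default (GO-style "corrected P-value") or
#' Benjamini-Hochberg (`"bh"`, KEGG-style Q-value); terms annotating no
#' background gene are skipped.
#'
#' @param annotation Two-column table (`gene_id`, `term`), e.g. from
#'   [generate_annotations()].
#' @param deg_set Character vector of DEG identifiers.
#' @param background_set Optional gene universe; intersected with the
#'   annotated genes. Defaults to all annotated genes.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param alpha Significance threshold on the corrected value.
#' @return A `data.table` with columns `term`, `N`, `n`, `M`, `m`,
#'   `p_raw`, `p_corrected`, `significant`, sorted by `p_raw`.
#' @export
enrich_terms <- function(annotation, deg_set, background_set = NULL,
                         correction = c("bonferroni", "bh"), alpha = 0.05) {
  correction <- match.arg(correction)
  ann <- as.data.table(annotation)
  if (!all(c("gene_id", "term") %in% names(ann))) {
    setnames(ann, names(ann)[1:2], c("gene_id", "term"))
  }
  universe <- unique(ann$gene_id)
  if (!is.null(background_set)) {
    universe <- intersect(universe, background_set)
  }
  if (length(universe) == 0L) stop_input("empty annotated background")
  assert_that(all(deg_set %in% universe) || is.null(background_set) ||
                all(deg_set %in% background_set),
              "deg_set must be contained in background_set")
  degs <- intersect(deg_set, universe)

  ann <- unique(ann[gene_id %in% universe])
  N <- length(universe)
  n <- length(degs)
  per_term <- ann[, list(M = length(unique(gene_id)),
                         m = sum(unique(gene_id) %in% degs)), by = "term"]
  per_term <- per_term[M >= 1L]
  per_term[, `:=`(N = N, n = n)]
  per_term[, p_raw := hypergeom_upper_tail(N, n, M, m)]
  per_term[, p_corrected := if (correction == "bonferroni")
    pmin(p_raw * .N, 1) else bh_fdr(p_raw)]
  per_term[, significant := p_corrected <= alpha]
  setorder(per_term, p_raw, term)
  per_term[, list(term, N, n, M, m, p_raw, p_corrected, significant)]
}
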