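library(data.table)

# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct route available (plain-arithmetic recurrences, exhaustive
# enumeration, brute-force scans) without touching the package internals it
# checks.

## Audic-Claverie two-sided p by plain-space tail summation over the
## conditional distribution p(k | x) with r = N2/N1, using the term
## recurrence t_{k+1} = t_k * (x+k+1)/(k+1) * r/(1+r)
oracle_ac_p <- function(x, y, N1, N2) {
  r <- N2 / N1
  q <- r / (1 + r)
  terms <- numeric(0)
  t <- (1 / (1 + r))^(x + 1)
  k <- 0
  s <- 0
  repeat {
    terms[k + 1] <- t
    s <- s + t
    t <- t * ((x + k + 1) / (k + 1)) * q
    k <- k + 1
    # keep collecting far past the crossing point so a tiny upper tail is
    # still summed to full relative precision
    if (k > y && k > (x + 1) * r && t < 1e-40) break
  }
  lower <- sum(terms[seq_len(y + 1)])
  # P(Y >= y), summed directly so a small upper tail never comes from a
  # 1 - (nearly 1) subtraction
  upper <- if (y == 0) 1 else min(1, sum(terms[seq.int(y + 1, length(terms))]))
  min(1, 2 * min(lower, upper))
}

## hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, n, M, m) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= M)                  # genes 1..M carry the term
  mean(hits >= m)
}

## brute-force tag mapping: Hamming distance of every query against every
## reference tag, exact-match precedence, ambiguity on the candidate set
oracle_map_bruteforce <- function(query_tags, ref_tags, ref_genes) {
  L <- nchar(ref_tags[1])
  rmat <- do.call(rbind, strsplit(ref_tags, "", fixed = TRUE))
  vapply(query_tags, function(qt) {
    if (nchar(qt) != L) return("__invalid__")
    qv <- strsplit(qt, "", fixed = TRUE)[[1]]
    d <- rowSums(rmat != matrix(qv, nrow(rmat), L, byrow = TRUE))
    cand <- if (any(d == 0)) which(d == 0) else which(d == 1)
    if (length(cand) == 0) return("__unmapped__")
    genes <- unique(ref_genes[cand])
    if (length(genes) == 1) genes else "__ambiguous__"
  }, character(1))
}

## plain Smith-Waterman with match 2 / mismatch -3 / linear gap -4,
## tracking matches along the traceback of the best cell
oracle_smith_waterman <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (av[i] == bv[j]) 2 else -3
      H[i + 1, j + 1] <- max(0, H[i, j] + sc,
                             H[i, j + 1] - 4, H[i + 1, j] - 4)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

## deterministic random 21-mers starting with CATG
random_ref_tags <- function(n) {
  tails <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
  }, character(1))
  paste0("CATG", tails)
}

mutate_tag <- function(tag, n_sub) {
  v <- strsplit(tag, "", fixed = TRUE)[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

## a tag_library wrapped around arbitrary species counts
make_tag_library <- function(tags, counts, name = "test") {
  structure(list(name = name,
                 tags = data.table::data.table(tag = tags, count = counts),
                 total_raw = sum(counts), total_clean = sum(counts),
                 true_counts = NULL),
            class = "tag_library")
}

## a tag_index wrapped around explicit (tag, gene) assignments
make_tag_index <- function(tags, genes) {
  tab <- data.table::data.table(gene_id = genes, strand = "sense",
                                site_offset = 0L, tag = tags)
  structure(list(tags = tab, gene_ids = sort(unique(genes)),
                 unquantifiable = character(0),
                 gene_count = length(unique(genes)),
                 tag_count = length(unique(tags)),
                 strand_mode = "sense_only"),
            class = "tag_index")
}
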