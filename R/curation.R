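STOP_CODONS <- c("TAA", "TAG", "TGA")

## codon vector of one frame (offset 0..2) of a sequence
frame_codons <- function(seq, offset) {
  L <- nchar(seq)
  n_cod <- (L - offset) %/% 3L
  if (n_cod < 1L) return(character(0))
  starts <- offset + 1L + 3L * (seq_len(n_cod) - 1L)
  substring(seq, starts, starts + 2L)
}

## best ORF within one frame's codon vector; returns codon-index start,
## codon count (aa, stop excluded), and whether a stop terminates it
frame_best_orf <- function(codons, mode) {
  n <- length(codons)
  if (n == 0L) return(NULL)
  is_stop <- codons %in% STOP_CODONS
  if (mode == "stop_free") {
    # longest run of non-stop codons
    r <- rle(!is_stop)
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    best <- which(r$values)[which.max(r$lengths[r$values])]
    start <- ends[best] - r$lengths[best] + 1L
    return(list(start_codon = start, aa = r$lengths[best],
                stopped = (ends[best] < n)))
  }
  atg <- which(codons == "ATG")
  if (length(atg) == 0L) return(NULL)
  stop_idx <- which(is_stop)
  # index of first stop at or after each codon position
  nxt <- rep.int(NA_integer_, n)
  if (length(stop_idx) > 0L) {
    nxt[seq_len(max(stop_idx))] <-
      stop_idx[findInterval(seq_len(max(stop_idx)) - 1L, stop_idx) + 1L]
  }
  aa <- ifelse(is.na(nxt[atg]), n - atg + 1L, nxt[atg] - atg)
  best <- which.max(aa)  # leftmost ATG wins ties
  list(start_codon = atg[best], aa = as.integer(aa[best]),
       stopped = !is.na(nxt[atg[best]]))
}

#' Longest open reading frame across six frames
#'
#' Finds the longest ATG-initiated reading frame (standard genetic code)
#' over frames +1, +2, +3 of the sequence and -1, -2, -3 of its reverse
#' complement. An ORF normally runs ATG-to-stop; when no stop follows, it
#' extends to the last complete codon of the frame (open-ended). Ties are
#' broken by frame order (+1, +2, +3, -1, -2, -3) then by leftmost start.
#' `mode = "stop_free"` instead scores the longest stop-free codon
#' stretch, without requiring an ATG.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param mode `"atg_to_stop"` (default) or `"stop_free"`.
#' @return List of class `orf_call`: `frame` (one of `+1,+2,+3,-1,-2,-3`,
#'   `NA` if no ORF), `start`, `end` (0-based half-open nucleotide
#'   coordinates on the scanned strand; `end` includes the stop codon
#'   when present), `aa_length` (amino acids, stop excluded; 0 when no
#'   ORF exists), `stopped` (stop-terminated?).
#' @examples
#' longest_orf("ATGAAATAA")$aa_length  # 2 (Met-Lys)
#' @export
longest_orf <- function(sequence, mode = c("atg_to_stop", "stop_free")) {
  mode <- match.arg(mode)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rc <- if (nchar(sequence) > 0L) reverse_complement(sequence) else ""
  best <- NULL
  for (fi in seq_along(frames)) {
    offset <- (fi - 1L) %% 3L
    strand_seq <- if (fi <= 3L) sequence else rc
    hit <- frame_best_orf(frame_codons(strand_seq, offset), mode)
    if (is.null(hit)) next
    if (is.null(best) || hit$aa > best$aa_length) {
      start <- offset + 3L * (hit$start_codon - 1L)
      best <- list(frame = frames[fi], start = start,
                   end = start + 3L * (hit$aa + as.integer(hit$stopped)),
                   aa_length = hit$aa, stopped = hit$stopped)
    }
  }
  if (is.null(best)) {
    best <- list(frame = NA_character_, start = NA_integer_,
                 end = NA_integer_, aa_length = 0L, stopped = FALSE)
  }
  structure(best, class = "orf_call")
}

#' Length and ORF filters for gene-family candidates
#'
#' Applies the curation cutoffs used when screening detoxification-enzyme
#' candidates: sequences shorter than `min_len` nucleotides are removed
#' first; of the remainder, sequences whose longest six-frame ORF is
#' shorter than `min_orf_aa` amino acids are removed.
#'
#' @param unigenes Named character vector of sequences (or a
#'   `family_fixtures` / `unigene_sim` object).
#' @param min_len Minimum nucleotide length (default 400; a 300-bp variant
#'   is in use for P450 screens — pass `min_len = 300`).
#' @param min_orf_aa Minimum longest-ORF length in amino acids (default
#'   100).
#' @param orf_mode Passed to [longest_orf()].
#' @return A `data.table` with columns `gene_id`, `length_bp`,
#'   `longest_orf_aa`, `disposition` in
#'   `{"kept", "removed_short", "removed_short_orf"}`.
#' @export
filter_family_candidates <- function(unigenes, min_len = 400L,
                                     min_orf_aa = 100L,
                                     orf_mode = "atg_to_stop") {
  if (inherits(unigenes, "family_fixtures") ||
      inherits(unigenes, "unigene_sim")) {
    unigenes <- unigenes$sequences
  }
  assert_that(!is.null(names(unigenes)), "unigenes must be named")
  lens <- nchar(unigenes)
  orf_aa <- vapply(unigenes, function(s) longest_orf(s, orf_mode)$aa_length,
                   integer(1))
  data.table(
    gene_id = names(unigenes),
    length_bp = as.integer(lens),
    longest_orf_aa = orf_aa,
    disposition = ifelse(lens < min_len, "removed_short",
                  ifelse(orf_aa < min_orf_aa, "removed_short_orf", "kept")))
}

## local (Smith-Waterman) alignment of two sequences; returns score,
## identity over aligned columns, and coverage of the shorter sequence
align_identity <- function(a, b) {
  short_first <- nchar(a) <= nchar(b)
  p <- if (short_first) a else b
  s <- if (short_first) b else a
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  # linear gap cost (4 per gapped base) keeps the scoring scheme simple
  # enough to reproduce with a plain Smith-Waterman recurrence
  aln <- Biostrings::pairwiseAlignment(p, s, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 4)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  span <- Biostrings::width(Biostrings::pattern(aln))
  list(score = Biostrings::score(aln),
       identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
       coverage = span / nchar(p))
}

#' Collapse allelic variants by single-linkage clustering
#'
#' Computes exact local alignments between all pairs of kept sequences and
#' links two genes when identity over the aligned columns is at least
#' `min_identity` and the alignment covers at least `min_coverage` of the
#' shorter sequence — a numeric stand-in for manual same-BLAST-hit /
#' high-homology judgement. Each single-linkage cluster keeps its longest
#' member (ties broken by lexicographically smallest id) as the
#' representative.
#'
#' @param kept Named character vector of sequences that passed
#'   [filter_family_candidates()].
#' @param min_identity Minimum fractional identity (default 0.95).
#' @param min_coverage Minimum fraction of the shorter sequence covered by
#'   the local alignment (default 0.8).
#' @return List with `clusters` (data.table `gene_id`, `cluster_id`,
#'   `representative`, `is_representative`) and `representatives`
#'   (character vector of representative gene ids). Results are invariant
#'   to input order.
#' @export
cluster_allelic_variants <- function(kept, min_identity = 0.95,
                                     min_coverage = 0.8) {
  assert_that(!is.null(names(kept)) || length(kept) == 0L,
              "kept must be named")
  ids <- sort(names(kept))
  kept <- kept[ids]
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        al <- align_identity(kept[[i]], kept[[j]])
        if (al$identity >= min_identity && al$coverage >= min_coverage) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- data.table(gene_id = ids, length_bp = nchar(kept),
                         root = root)
  clusters[, representative :=
             gene_id[order(-length_bp, gene_id)][1L], by = "root"]
  setorder(clusters, representative, gene_id)
  reps <- unique(clusters$representative)
  clusters[, cluster_id := sprintf("CL%03d", match(representative, reps))]
  clusters[, is_representative := gene_id == representative]
  list(clusters = clusters[, list(gene_id, cluster_id, representative,
                                  is_representative)],
       representatives = reps)
}

#' Full curation of family candidates
#'
#' Runs the length filter, the ORF filter, and allelic-variant collapsing
#' in order, assigning each input gene exactly one disposition.
#'
#' @inheritParams filter_family_candidates
#' @inheritParams cluster_allelic_variants
#' @return A `data.table` with columns `gene_id`, `length_bp`,
#'   `longest_orf_aa`, `disposition` in `{"kept", "removed_short",
#'   "removed_short_orf", "removed_variant"}` and `cluster_id` (NA for
#'   genes removed before clustering).
#' @export
curate_families <- function(unigenes, min_len = 400L, min_orf_aa = 100L,
                            min_identity = 0.95, min_coverage = 0.8,
                            orf_mode = "atg_to_stop") {
  if (inherits(unigenes, "family_fixtures") ||
      inherits(unigenes, "unigene_sim")) {
    unigenes <- unigenes$sequences
  }
  rec <- filter_family_candidates(unigenes, min_len, min_orf_aa, orf_mode)
  rec[, cluster_id := NA_character_]
  kept_ids <- rec$gene_id[rec$disposition == "kept"]
  if (length(kept_ids) > 0L) {
    cl <- cluster_allelic_variants(unigenes[kept_ids], min_identity,
                                   min_coverage)
    mi <- match(rec$gene_id, cl$clusters$gene_id)
    hit <- !is.na(mi)
    rec[hit, cluster_id := cl$clusters$cluster_id[mi[hit]]]
    dropped <- cl$clusters$gene_id[!cl$clusters$is_representative]
    rec[gene_id %in% dropped, disposition := "removed_variant"]
  }
  rec[]
}
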