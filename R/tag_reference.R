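#' Extract CATG+17 reference tags from one sequence
#'
#' Scans a unigene for NlaIII recognition sites (`CATG`) and emits the
#' 21-mer tag (CATG plus the 17 downstream bases) for every site with at
#' least 17 downstream bases. Tags containing `N` are skipped. With
#' `strand_mode = "both"` the reverse complement is scanned too; antisense
#' coordinates are reported on the sense strand as the 0-based position of
#' the `C` of the reverse-complemented CATG.
#'
#' @param gene_id Gene identifier.
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param strand_mode `"sense_only"` (default) or `"both"`.
#' @return A `data.table` with columns `gene_id`, `strand` (`"sense"` /
#'   `"antisense"`), `site_offset` (0-based position of the C of CATG on
#'   the scanned strand), `tag`; ordered by strand then position. Empty
#'   for sequences without an eligible site.
#' @examples
#' extract_reference_tags("g1", "TTCATGAAAAAAAAAAAAAAAAAGG")
#' @export
extract_reference_tags <- function(gene_id, sequence,
                                   strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  one_strand <- function(seq, strand) {
    sites <- catg_sites(seq)
    sites <- sites[sites + TAG_LEN - 1L <= nchar(seq)]
    if (length(sites) == 0L) {
      return(data.table(gene_id = character(), strand = character(),
                        site_offset = integer(), tag = character()))
    }
    tags <- substring(seq, sites, sites + TAG_LEN - 1L)
    ok <- !grepl("N", tags, fixed = TRUE)
    data.table(gene_id = gene_id, strand = strand,
               site_offset = sites[ok] - 1L, tag = tags[ok])
  }
  out <- one_strand(sequence, "sense")
  if (strand_mode == "both" && nzchar(sequence)) {
    out <- rbindlist(list(out,
                          one_strand(reverse_complement(sequence),
                                     "antisense")))
  }
  out
}

#' Build the reference tag index for a transcriptome
#'
#' Indexes every CATG+17 tag of every unigene (all sites, not only the
#' 3'-most) for exact and one-mismatch lookup by [map_tags()]. Genes
#' without any eligible site are recorded as unquantifiable.
#'
#' @param unigenes Named character vector of sequences, a `unigene_sim`
#'   object, or a path to a FASTA file.
#' @param strand_mode `"sense_only"` (default) or `"both"`.
#' @return An object of class `tag_index`: list with `tags` (data.table
#'   `gene_id`, `strand`, `site_offset`, `tag`), `gene_ids`,
#'   `unquantifiable` (gene ids with zero tags), `gene_count`, `tag_count`
#'   (distinct 21-mers) and `strand_mode`.
#' @export
build_tag_index <- function(unigenes, strand_mode = c("sense_only", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(unigenes, "unigene_sim")) unigenes <- unigenes$sequences
  if (is.character(unigenes) && length(unigenes) == 1L &&
      is.null(names(unigenes)) && file.exists(unigenes)) {
    unigenes <- read_fasta(unigenes)
  }
  assert_that(!is.null(names(unigenes)) && all(nzchar(names(unigenes))),
              "unigenes must be named sequences")
  if (anyDuplicated(names(unigenes))) {
    stop_input("duplicate gene identifiers in unigene set")
  }
  tabs <- lapply(seq_along(unigenes), function(i) {
    extract_reference_tags(names(unigenes)[i], unigenes[[i]], strand_mode)
  })
  tags <- rbindlist(tabs)
  quantifiable <- unique(tags$gene_id)
  structure(list(tags = tags,
                 gene_ids = names(unigenes),
                 unquantifiable = setdiff(names(unigenes), quantifiable),
                 gene_count = length(unigenes),
                 tag_count = length(unique(tags$tag)),
                 strand_mode = strand_mode),
            class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf(paste0("tag_index: %d genes, %d sites, %d distinct 21-mers ",
                     "(%s), %d unquantifiable genes\n"),
              x$gene_count, nrow(x$tags), x$tag_count, x$strand_mode,
              length(x$unquantifiable)))
  invisible(x)
}

#' Write / read a reference tag index as TSV
#'
#' The on-disk form is a plain TSV (`gene_id`, `strand`, `site_offset_1based`,
#' `tag`) with one header comment line carrying the gene universe and
#' strand mode, so an index round-trips losslessly through text.
#'
#' @param index A `tag_index`.
#' @param path Output/input TSV path.
#' @return `write_tag_index` returns `path` invisibly; `read_tag_index`
#'   returns a `tag_index`.
#' @export
write_tag_index <- function(index, path) {
  writeLines(c(sprintf("##strand_mode=%s", index$strand_mode),
               sprintf("##genes=%s", paste(index$gene_ids, collapse = ","))),
             path)
  tab <- copy(index$tags)
  tab[, site_offset_1based := site_offset + 1L]
  data.table::fwrite(tab[, list(gene_id, strand, site_offset_1based, tag)],
                     path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_tag_index
#' @export
read_tag_index <- function(path) {
  hdr <- readLines(path, n = 2L)
  strand_mode <- sub("^##strand_mode=", "", hdr[1L])
  gene_ids <- strsplit(sub("^##genes=", "", hdr[2L]), ",", fixed = TRUE)[[1L]]
  tab <- data.table::fread(path, sep = "\t", skip = 2L, header = TRUE,
                           colClasses = list(character = c("gene_id",
                                                           "strand", "tag")))
  tags <- tab[, list(gene_id, strand,
                     site_offset = site_offset_1based - 1L, tag)]
  structure(list(tags = tags, gene_ids = gene_ids,
                 unquantifiable = setdiff(gene_ids, unique(tags$gene_id)),
                 gene_count = length(gene_ids),
                 tag_count = length(unique(tags$tag)),
                 strand_mode = strand_mode),
            class = "tag_index")
}

## all 3*L single-substitution neighbours of each input k-mer, as a long
## data.table (tag = original, nb = neighbour); vectorised position-wise
mismatch_neighbors <- function(tags) {
  L <- TAG_LEN
  out <- vector("list", 4L * L)
  k <- 1L
  for (p in seq_len(L)) {
    orig <- substr(tags, p, p)
    for (b in DNA_BASES) {
      sel <- orig != b
      if (!any(sel)) next
      out[[k]] <- data.table(tag = tags[sel],
                             nb = splice_at(tags[sel], p, b))
      k <- k + 1L
    }
  }
  rbindlist(out[seq_len(k - 1L)])
}
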