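#' Clean a raw tag library
#'
#' Applies the standard DGE cleaning rules: remove empty reads and reads
#' equal to the adapter sentinel (adapter-only reads), remove tag species
#' containing `N` (low-quality), and remove tag species with a total copy
#' number of exactly 1 (likely sequencing errors).
#'
#' @param raw A `tag_library` (from [simulate_tag_library()] or
#'   [read_tag_library()]).
#' @param adapter_sentinel Read sequence treated as adapter-only.
#' @return A `tag_library` with filtered `tags` and `total_clean` set to the
#'   sum of retained counts (`total_raw` is carried over unchanged).
#' @export
clean_tags <- function(raw, adapter_sentinel = tag_adapter_sentinel()) {
  assert_that(inherits(raw, "tag_library"), "raw must be a tag_library")
  tags <- raw$tags[nzchar(tag) & tag != adapter_sentinel]
  tags <- tags[!grepl("N", tag, fixed = TRUE)]
  tags <- tags[count != 1L]
  structure(list(name = raw$name, tags = tags,
                 total_raw = raw$total_raw,
                 total_clean = sum(tags$count),
                 true_counts = raw$true_counts),
            class = "tag_library")
}

#' Map clean tags to the reference with at most one mismatch
#'
#' Each clean tag species is looked up in the reference index, first for
#' exact 21-mer matches and, only when none exist, for matches at Hamming
#' distance 1 (exact-match precedence, so a sequencing error cannot steal
#' counts across close paralogs). If the candidate set lies in exactly one
#' gene the species' whole count accrues to that gene (unambiguous); if it
#' spans several genes it is ambiguous and contributes to no gene; with no
#' match within distance 1 it is unmapped. Species whose length is not
#' 21 nt are tallied separately as length-invalid.
#'
#' The distance-1 search uses a neighbourhood index precomputed from the
#' reference (all 3x21 single-substitution variants of every reference
#' 21-mer), equivalent to scanning the query's own neighbourhood.
#'
#' @param clean A cleaned `tag_library`.
#' @param index A `tag_index` from [build_tag_index()].
#' @return An `expression_table`: list with `expr` (data.table `gene_id`,
#'   `count`, `tpm`, one row per indexed gene), `totals` (named list
#'   `clean`, `mapped`, `unambiguous`, `ambiguous`, `unmapped`,
#'   `invalid_length`), `library` (name) and `denominator` (NA until
#'   [tpm_normalize()]).
#' @export
map_tags <- function(clean, index) {
  assert_that(inherits(clean, "tag_library"), "clean must be a tag_library")
  assert_that(inherits(index, "tag_index"), "index must be a tag_index")
  if (nrow(index$tags) == 0L) stop_input("reference index is empty")

  pairs <- unique(index$tags[, list(tag, gene_id)])
  ex_sets <- pairs[, list(n_genes = length(unique(gene_id)),
                          gene = gene_id[1L]), by = "tag"]
  nb <- mismatch_neighbors(ex_sets$tag)
  nb_long <- merge(nb, pairs, by = "tag", allow.cartesian = TRUE)
  nb_sets <- nb_long[, list(n_genes = length(unique(gene_id)),
                            gene = gene_id[1L]), by = "nb"]

  q <- copy(clean$tags)
  q[, valid := nchar(tag) == TAG_LEN]
  q[, `:=`(n_genes = NA_integer_, gene = NA_character_)]
  mi <- match(q$tag, ex_sets$tag)
  hit <- !is.na(mi) & q$valid
  q[hit, `:=`(n_genes = ex_sets$n_genes[mi[hit]],
              gene = ex_sets$gene[mi[hit]])]
  todo <- q$valid & is.na(q$n_genes)
  mj <- match(q$tag[todo], nb_sets$nb)
  q[which(todo)[!is.na(mj)],
    `:=`(n_genes = nb_sets$n_genes[mj[!is.na(mj)]],
         gene = nb_sets$gene[mj[!is.na(mj)]])]

  status <- ifelse(!q$valid, "invalid_length",
            ifelse(is.na(q$n_genes), "unmapped",
            ifelse(q$n_genes == 1L, "unambiguous", "ambiguous")))
  tot <- function(s) sum(q$count[status == s])
  totals <- list(clean = sum(q$count),
                 mapped = tot("unambiguous") + tot("ambiguous"),
                 unambiguous = tot("unambiguous"),
                 ambiguous = tot("ambiguous"),
                 unmapped = tot("unmapped"),
                 invalid_length = tot("invalid_length"))

  counts <- q[status == "unambiguous",
              list(count = sum(count)), by = "gene"]
  expr <- data.table(gene_id = index$gene_ids, count = 0L, tpm = NA_real_)
  mi <- match(counts$gene, expr$gene_id)
  expr[mi, count := as.integer(counts$count)]
  structure(list(expr = expr, totals = totals, library = clean$name,
                 denominator = NA_character_),
            class = "expression_table")
}

#' Normalize unambiguous tag counts to TPM
#'
#' `tpm(g) = count(g) / denominator_total * 1e6` (tags per million). The
#' denominator is the library's total clean tags by default (the stated
#' mapping universe); with `denominator = "unambiguous"` the TPM column
#' sums to exactly one million.
#'
#' @param table An `expression_table` from [map_tags()].
#' @param denominator `"clean"` (default) or `"unambiguous"`.
#' @return The `expression_table` with `tpm` filled in and `denominator`
#'   recorded.
#' @export
tpm_normalize <- function(table, denominator = c("clean", "unambiguous")) {
  denominator <- match.arg(denominator)
  assert_that(inherits(table, "expression_table"),
              "table must be an expression_table")
  denom <- table$totals[[denominator]]
  if (is.null(denom) || denom <= 0) {
    stop_input("TPM denominator total must be positive")
  }
  table$expr[, tpm := count / denom * 1e6]
  table$denominator <- denominator
  table
}

#' @export
print.expression_table <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("expression_table '%s': %d genes; clean %d, ",
                     "unambiguous %d (%.2f%%), ambiguous %d, unmapped %d\n"),
              x$library, nrow(x$expr), t$clean, t$unambiguous,
              100 * t$unambiguous / max(t$clean, 1L), t$ambiguous,
              t$unmapped))
  invisible(x)
}

#' Read / write tag libraries and expression tables as TSV
#'
#' Tag libraries are two-column TSVs (`tag`, `count`); expression tables
#' are `gene_id`, `count`, `tpm` with the accounting totals emitted as a
#' JSON sidecar by the CLI.
#'
#' @param path TSV path.
#' @param name Library label (defaults to the file name).
#' @param total_raw Raw read total; defaults to the sum of counts.
#' @return `read_tag_library` returns a `tag_library`.
#' @export
read_tag_library <- function(path, name = basename(path), total_raw = NULL) {
  tags <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = "tag"))
  assert_that(all(c("tag", "count") %in% names(tags)),
              "tag library TSV needs columns tag, count")
  structure(list(name = name, tags = tags[, list(tag, count)],
                 total_raw = total_raw %||% sum(tags$count),
                 total_clean = NA_integer_, true_counts = NULL),
            class = "tag_library")
}

#' @rdname read_tag_library
#' @param lib A `tag_library`.
#' @export
write_tag_library <- function(lib, path) {
  write_tsv(lib$tags, path)
}

#' @rdname read_tag_library
#' @param table An `expression_table`.
#' @export
write_expression_table <- function(table, path) {
  write_tsv(table$expr, path)
}
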