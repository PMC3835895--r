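#' @importFrom data.table data.table as.data.table := .N setkey setorder rbindlist fread fwrite copy setnames
#' @importFrom stats p.adjust rbinom rmultinom runif rlnorm setNames
#' @importFrom utils head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")
TAG_LEN <- 21L
ANCHOR <- "CATG"

# fixed non-tag sentinel standing in for an adapter-dimer ("empty") read
ADAPTER_SENTINEL <- "TCGGACTGTAGAACTCTGAAC"

#' Adapter-only read sentinel
#'
#' The synthetic generator emits adapter-only ("empty") reads as this fixed
#' 21-nt sentinel, and [clean_tags()] removes reads equal to it. It cannot
#' collide with an informative tag because it does not start with `CATG`.
#'
#' @return A single character string.
#' @export
tag_adapter_sentinel <- function() ADAPTER_SENTINEL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_input(msg)
  invisible(TRUE)
}

## numerically stable log(sum(exp(lx)))
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## random DNA of given lengths as a character vector (uniform base use)
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

## replace the substring [at, at+nchar(with)-1] (1-based) in each string
splice_at <- function(x, at, with) {
  paste0(substr(x, 1L, at - 1L), with, substr(x, at + nchar(with), nchar(x)))
}

## positions (1-based, start of match) of every occurrence of CATG
catg_sites <- function(seq) {
  hits <- gregexpr(ANCHOR, seq, fixed = TRUE)[[1]]
  hits <- as.integer(hits)
  hits[hits > 0L]
}

## rewrite a sequence so it contains no CATG on the given strand
destroy_catg <- function(seq) {
  repeat {
    sites <- catg_sites(seq)
    if (length(sites) == 0L) return(seq)
    # flip the G of each occurrence to a non-G base; loop guards against
    # new sites created by the replacement's upstream context
    for (s in sites) {
      seq <- splice_at(seq, s + 3L, sample(c("A", "C", "T"), 1L))
    }
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## read/write FASTA through Biostrings, returning plain named character
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

write_tsv <- function(dt, path) {
  data.table::fwrite(as.data.table(dt), path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, ...)
}
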