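#' Simulation configuration for synthetic DGE experiments
#'
#' Bundles every knob of the synthetic-data generator: transcriptome shape
#' (number of unigenes, length range, fraction of genes without a CATG
#' anchor site), tag-library sampling (library size, per-base substitution
#' error, contaminant reads), the differential-expression spike design
#' (number of up/down genes and the fold change applied in the treated
#' library), and the master seed from which all randomness flows.
#'
#' @param n_genes Number of unigenes to simulate.
#' @param length_range Integer vector `c(min_bp, max_bp)`; minimum 25 bp so
#'   every gene has room for one CATG+17 tag.
#' @param catg_free_fraction Fraction of genes constructed without any
#'   sense-strand CATG site (these are unquantifiable by the assay).
#' @param library_size Number of informative tag reads per library.
#' @param error_rate Per-base substitution probability applied independently
#'   to each of the 21 tag positions.
#' @param n_contaminant_reads Adapter-only plus N-containing reads appended
#'   to each library (split half and half, adapter reads get the extra one).
#' @param n_up,n_down Number of genes spiked up/down in the treated library.
#' @param fold_change Multiplier applied to spiked genes (up: `fold_change`,
#'   down: `1/fold_change`).
#' @param abundance_sdlog Log-normal sd of baseline per-gene abundances.
#' @param seed Integer master seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 50, library_size = 1e4, seed = 1)
#' @export
sim_config <- function(n_genes = 2000L,
                       length_range = c(300L, 2000L),
                       catg_free_fraction = 0.05,
                       library_size = 1e6,
                       error_rate = 0.01,
                       n_contaminant_reads = 1000L,
                       n_up = 100L,
                       n_down = 100L,
                       fold_change = 8,
                       abundance_sdlog = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              length_range = as.integer(length_range),
              catg_free_fraction = catg_free_fraction,
              library_size = as.integer(library_size),
              error_rate = error_rate,
              n_contaminant_reads = as.integer(n_contaminant_reads),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              fold_change = fold_change,
              abundance_sdlog = abundance_sdlog,
              seed = as.integer(seed))
  assert_that(cfg$n_genes >= 1L, "n_genes must be a positive integer")
  assert_that(length(cfg$length_range) == 2L &&
                cfg$length_range[1] <= cfg$length_range[2],
              "length_range must be c(min_bp, max_bp) with min <= max")
  assert_that(cfg$length_range[1] >= 25L,
              "length_range minimum is 25 bp (room for one CATG+17 tag)")
  assert_that(cfg$catg_free_fraction >= 0 && cfg$catg_free_fraction <= 1,
              "catg_free_fraction must be in [0, 1]")
  assert_that(cfg$error_rate >= 0 && cfg$error_rate < 1,
              "error_rate must be in [0, 1)")
  assert_that(cfg$library_size >= 1L, "library_size must be positive")
  assert_that(cfg$n_contaminant_reads >= 0L,
              "n_contaminant_reads must be non-negative")
  assert_that(cfg$fold_change > 0, "fold_change must be positive")
  assert_that(cfg$n_up + cfg$n_down <= cfg$n_genes,
              "more spiked genes than genes")
  assert_that(length(cfg$seed) == 1L && is.finite(cfg$seed),
              "seed must be a single integer")
  structure(cfg, class = "sim_config")
}

## 3'-most CATG site with >= 17 downstream bases; NA if none
last_taggable_site <- function(seq) {
  sites <- catg_sites(seq)
  sites <- sites[sites + TAG_LEN - 1L <= nchar(seq)]
  if (length(sites) == 0L) NA_integer_ else max(sites)
}

#' Generate a synthetic unigene set with ground truth
#'
#' Sequences use uniform base composition with all accidental CATG
#' occurrences rewritten out, then 1-3 CATG sites planted explicitly
#' (each with at least 17 downstream bases) in the genes meant to be
#' quantifiable. A fraction `catg_free_fraction` of genes is left with no
#' sense-strand CATG at all. Baseline abundances are log-normal;
#' differential-expression spikes (`n_up` genes at `fold_change`, `n_down`
#' at `1/fold_change`) are assigned only to quantifiable genes.
#'
#' @param config A [sim_config()].
#' @return A list of class `unigene_sim` with elements `sequences` (named
#'   character vector) and `truth` (a `data.table` with columns `gene_id`,
#'   `length_bp`, `catg_free`, `baseline_abundance`, `fold_change`,
#'   `de_label`).
#' @examples
#' sim <- generate_unigenes(sim_config(n_genes = 20, n_up = 2, n_down = 2,
#'                                     seed = 7))
#' table(sim$truth$de_label)
#' @export
generate_unigenes <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  withr::with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("UG%05d", seq_len(n))
    len_pool <- seq.int(config$length_range[1], config$length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
    n_free <- as.integer(round(n * config$catg_free_fraction))
    free <- logical(n)
    if (n_free > 0L) free[sample.int(n, n_free)] <- TRUE

    seqs <- vapply(seq_len(n), function(i) {
      s <- destroy_catg(random_dna(lens[i]))
      if (free[i]) return(s)
      k <- sample.int(3L, 1L)
      cand <- seq.int(1L, lens[i] - TAG_LEN + 1L)
      pos <- sort(cand[sample.int(length(cand), min(k, length(cand)))])
      # planted sites cannot overlap or interact; enforce >= 4 bp spacing
      keep <- c(TRUE, diff(pos) >= 4L)
      for (p in pos[keep]) s <- splice_at(s, p, ANCHOR)
      s
    }, character(1))
    names(seqs) <- gene_id

    truth <- data.table(
      gene_id = gene_id,
      length_bp = lens,
      catg_free = free,
      baseline_abundance = rlnorm(n, meanlog = 0,
                                  sdlog = config$abundance_sdlog),
      fold_change = 1,
      de_label = "null")
    quant <- which(!free)
    spike <- sample(quant, min(config$n_up + config$n_down, length(quant)))
    up <- head(spike, config$n_up)
    down <- spike[seq_along(spike) > config$n_up]
    truth[up, `:=`(fold_change = config$fold_change, de_label = "up")]
    truth[down, `:=`(fold_change = 1 / config$fold_change,
                     de_label = "down")]
    structure(list(sequences = seqs, truth = truth), class = "unigene_sim")
  })
}

#' @export
print.unigene_sim <- function(x, ...) {
  cat(sprintf("unigene_sim: %d genes (%d CATG-free), %d up / %d down spiked\n",
              length(x$sequences), sum(x$truth$catg_free),
              sum(x$truth$de_label == "up"),
              sum(x$truth$de_label == "down")))
  invisible(x)
}

## conditional on >= 1 substituted base, draw 21-position error masks by
## rejection; exact for the independent per-base model
sample_error_masks <- function(n_reads, error_rate) {
  mask <- matrix(rbinom(n_reads * TAG_LEN, 1L, error_rate) == 1L,
                 nrow = n_reads)
  repeat {
    bad <- which(rowSums(mask) == 0L)
    if (length(bad) == 0L) break
    mask[bad, ] <- matrix(rbinom(length(bad) * TAG_LEN, 1L,
                                 error_rate) == 1L, nrow = length(bad))
  }
  mask
}

substitute_bases <- function(orig) {
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(orig), replace = TRUE)
  out <- character(length(orig))
  for (b in DNA_BASES) {
    sel <- orig == b
    out[sel] <- alt[[b]][pick[sel]]
  }
  out
}

#' Simulate one raw tag library
#'
#' Draws `library_size` informative tag reads multinomially over
#' quantifiable genes with weight `baseline_abundance` (times `fold_change`
#' in the treated library). Each read is the gene's 3'-most CATG+17 tag
#' with independent per-base substitution at `error_rate`; CATG-free genes
#' get zero sampling weight. `n_contaminant_reads` adapter-only and
#' N-containing reads are appended, then identical read sequences are
#' aggregated into per-species counts.
#'
#' @param unigenes A `unigene_sim` object (or named character vector of
#'   sequences, in which case `truth` must be supplied).
#' @param truth Truth table; defaults to `unigenes$truth`.
#' @param treated Logical; apply the spiked fold changes?
#' @param config The [sim_config()] used for sampling parameters.
#' @param library_seed Seed for this library; defaults to
#'   `config$seed + 1L` (control) or `config$seed + 2L` (treated) so the
#'   two libraries of a pair are independent draws.
#' @param name Library label.
#' @return A `tag_library`: list with `name`, `tags` (data.table `tag`,
#'   `count`), `total_raw`, `total_clean` (NA until [clean_tags()]), and
#'   `true_counts`, the per-gene multinomial draws (the simulation ground
#'   truth before sequencing error).
#' @export
simulate_tag_library <- function(unigenes, truth = NULL, treated = FALSE,
                                 config, library_seed = NULL,
                                 name = if (treated) "treated" else "control") {
  if (inherits(unigenes, "unigene_sim")) {
    truth <- truth %||% unigenes$truth
    seqs <- unigenes$sequences
  } else {
    seqs <- unigenes
  }
  assert_that(!is.null(truth), "truth table required")
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  truth <- as.data.table(truth)
  assert_that(all(truth$gene_id %in% names(seqs)),
              "truth genes missing from sequences")
  seqs <- seqs[truth$gene_id]

  site <- vapply(seqs, last_taggable_site, integer(1))
  ref_tag <- ifelse(is.na(site), NA_character_,
                    substr(seqs, site, site + TAG_LEN - 1L))
  w <- truth$baseline_abundance * (if (treated) truth$fold_change else 1)
  w[is.na(site)] <- 0
  if (sum(w) <= 0) stop_input("all sampling weights are zero")

  seed <- library_seed %||% (config$seed + if (treated) 2L else 1L)
  withr::with_seed(as.integer(seed), {
    draws <- as.integer(rmultinom(1L, config$library_size, w))
    names(draws) <- truth$gene_id

    er <- config$error_rate
    p_any <- 1 - (1 - er)^TAG_LEN
    n_err <- if (er > 0) rbinom(length(draws), draws, p_any) else
      integer(length(draws))
    clean_part <- data.table(tag = ref_tag, count = draws - n_err)
    clean_part <- clean_part[count > 0L]

    err_part <- NULL
    E <- sum(n_err)
    if (E > 0L) {
      g_idx <- rep.int(seq_along(draws), n_err)
      chmat <- matrix(unlist(strsplit(ref_tag[g_idx], "", fixed = TRUE),
                             use.names = FALSE),
                      nrow = E, byrow = TRUE)
      mask <- sample_error_masks(E, er)
      hit <- which(mask)
      chmat[hit] <- substitute_bases(chmat[hit])
      reads <- do.call(paste0, as.data.frame(chmat, stringsAsFactors = FALSE))
      err_part <- data.table(tag = reads)[, list(count = .N), by = "tag"]
    }

    cont_part <- NULL
    nc <- config$n_contaminant_reads
    if (nc > 0L) {
      n_ad <- as.integer(ceiling(nc / 2))
      n_nn <- nc - n_ad
      parts <- list(data.table(tag = ADAPTER_SENTINEL, count = n_ad))
      if (n_nn > 0L) {
        src <- sample(which(!is.na(ref_tag)), n_nn, replace = TRUE)
        npos <- sample.int(TAG_LEN, n_nn, replace = TRUE)
        nn <- splice_at(ref_tag[src], npos, "N")
        parts <- c(parts, list(data.table(tag = nn)[, list(count = .N),
                                                    by = "tag"]))
      }
      cont_part <- rbindlist(parts)
    }

    tags <- rbindlist(list(clean_part, err_part, cont_part))
    tags <- tags[, list(count = sum(count)), by = "tag"]
    setorder(tags, -count, tag)
    structure(list(name = name, tags = tags,
                   total_raw = config$library_size + nc,
                   total_clean = NA_integer_,
                   true_counts = draws),
              class = "tag_library")
  })
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d tag species, %d raw reads%s\n",
              x$name, nrow(x$tags), x$total_raw,
              if (is.na(x$total_clean)) " (not cleaned)"
              else sprintf(", %d clean", x$total_clean)))
  invisible(x)
}

#' Generate a synthetic gene-to-term annotation map
#'
#' One designated term (the first, `TERM001`) is attached to true-DE genes
#' with probability `enriched_rate` and to null genes with probability
#' `background_rate`; every other term is attached uniformly at
#' `background_rate`, independent of DE status.
#'
#' @param truth Truth table from [generate_unigenes()] (columns `gene_id`,
#'   `de_label`).
#' @param n_terms Number of annotation terms.
#' @param enriched_rate,background_rate Attachment probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `data.table` with columns `gene_id`, `term`; the spiked term id
#'   is stored in attribute `enriched_term`.
#' @export
generate_annotations <- function(truth, n_terms = 20L, enriched_rate = 0.6,
                                 background_rate = 0.05, seed = 1L) {
  assert_that(enriched_rate >= 0 && enriched_rate <= 1 &&
                background_rate >= 0 && background_rate <= 1,
              "rates must be in [0, 1]")
  truth <- as.data.table(truth)
  terms <- sprintf("TERM%03d", seq_len(n_terms))
  withr::with_seed(as.integer(seed), {
    is_de <- truth$de_label != "null"
    out <- vector("list", n_terms)
    p1 <- ifelse(is_de, enriched_rate, background_rate)
    keep <- runif(nrow(truth)) < p1
    out[[1L]] <- data.table(gene_id = truth$gene_id[keep], term = terms[1L])
    for (j in seq_len(n_terms)[-1L]) {
      keep <- runif(nrow(truth)) < background_rate
      out[[j]] <- data.table(gene_id = truth$gene_id[keep], term = terms[j])
    }
    map <- rbindlist(out)
    setattr(map, "enriched_term", terms[1L])
    map[]
  })
}

#' Fixture unigenes exercising each curation filter branch
#'
#' Builds a small deterministic set of labelled sequences: `too_short`
#' (350 bp, fails the length filter), `short_orf` (900 bp, longest
#' six-frame ORF exactly 80 aa), `kept_member` (1203 bp, 400-aa ORF),
#' and a 99%-identical allelic-variant pair `variant_a`/`variant_b`
#' (variant_a longer, so it becomes the cluster representative).
#'
#' The ORF-bearing fixtures are built from codon blocks (TAA background,
#' GCC/GAA bodies) chosen so that no reading frame on either strand
#' contains an unintended ATG, making the longest-ORF length exact by
#' construction.
#'
#' @param seed Seed for the random filler sequence and variant mutation
#'   positions.
#' @return A list of class `family_fixtures` with `sequences` (named
#'   character) and `expected` (data.table `gene_id`,
#'   `expected_disposition`).
#' @export
generate_family_fixtures <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    too_short <- random_dna(350L)

    short_orf <- paste0(paste(rep("TAA", 49L), collapse = ""),
                        "ATG", paste(rep("GCC", 79L), collapse = ""), "TAA",
                        paste(rep("TAA", 170L), collapse = ""))

    kept <- paste0("ATG", paste(rep("GCC", 399L), collapse = ""), "TAA")

    va_body <- rep("GAA", 399L)
    variant_a <- paste0("ATG", paste(va_body, collapse = ""), "TAA",
                        paste(rep("TTC", 10L), collapse = ""))
    vb_body <- va_body
    mut <- sample.int(399L, 12L)
    vb_body[mut] <- "GAG"  # synonymous, never creates ATG or a stop
    variant_b <- paste0("ATG", paste(vb_body, collapse = ""), "TAA")

    seqs <- c(too_short = too_short, short_orf = short_orf,
              kept_member = kept, variant_a = variant_a,
              variant_b = variant_b)
    expected <- data.table(
      gene_id = names(seqs),
      expected_disposition = c("removed_short", "removed_short_orf",
                               "kept", "kept", "removed_variant"))
    structure(list(sequences = seqs, expected = expected),
              class = "family_fixtures")
  })
}

#' @importFrom data.table setattr
NULL
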