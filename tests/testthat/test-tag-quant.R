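tagA <- paste0("CATG", strrep("A", 17))
tagC <- paste0("CATG", strrep("C", 17))
tagG <- paste0("CATG", strrep("G", 17))

test_that("clean_tags applies each filtering rule", {
  lib <- make_tag_library(
    tags = c(tagA, tagC, sub("A$", "N", tagA), tag_adapter_sentinel(), ""),
    counts = c(5L, 1L, 50L, 400L, 30L))
  clean <- clean_tags(lib)
  # singleton species, N species, adapter-only and empty reads all removed
  expect_identical(clean$tags$tag, tagA)
  expect_identical(clean$tags$count, 5L)
  expect_identical(clean$total_clean, 5L)
  expect_identical(clean$total_raw, lib$total_raw)
})

test_that("map_tags follows distance, ambiguity and precedence rules", {
  # gene A owns tagA, gene B owns tagC; tagG is shared by A and B
  idx <- make_tag_index(c(tagA, tagC, tagG, tagG),
                        c("A", "B", "A", "B"))
  near_AC <- paste0("CATG", strrep("A", 8), "C", strrep("A", 8)) # d1 of tagA
  halfway <- paste0("CATG", strrep("A", 16), "C")                # d1 of tagA
  far <- paste0("CATG", strrep("T", 17))                         # d >= 2
  short <- "CATGAAA"
  lib <- make_tag_library(c(tagA, near_AC, tagG, far, short, halfway),
                          c(40L, 7L, 9L, 3L, 2L, 5L))
  et <- map_tags(lib, idx)
  expect_identical(et$expr[gene_id == "A"]$count, 40L + 7L + 5L)
  expect_identical(et$expr[gene_id == "B"]$count, 0L)
  expect_identical(et$totals$unambiguous, 52L)
  expect_identical(et$totals$ambiguous, 9L)   # tagG exact in two genes
  expect_identical(et$totals$unmapped, 3L)
  expect_identical(et$totals$invalid_length, 2L)
  expect_identical(et$totals$mapped,
                   et$totals$unambiguous + et$totals$ambiguous)
  expect_identical(et$totals$clean,
                   et$totals$mapped + et$totals$unmapped +
                     et$totals$invalid_length)
})

test_that("exact-match precedence beats a distance-1 cross match", {
  # query equals gene A's tag exactly and is at distance 1 from gene B's
  tagB <- paste0("CATG", strrep("A", 16), "T")
  idx <- make_tag_index(c(tagA, tagB), c("A", "B"))
  lib <- make_tag_library(tagA, 12L)
  et <- map_tags(lib, idx)
  expect_identical(et$expr[gene_id == "A"]$count, 12L)
  expect_identical(et$totals$ambiguous, 0L)
})

test_that("map_tags rejects an empty index", {
  idx <- make_tag_index(character(0), character(0))
  expect_error(map_tags(make_tag_library(tagA, 5L), idx), "empty")
})

test_that("tpm_normalize computes and conserves TPM", {
  idx <- make_tag_index(c(tagA, tagC), c("A", "B"))
  lib <- make_tag_library(c(tagA, tagC), c(50L, 150L))
  et <- map_tags(lib, idx)
  et$totals$clean <- 1e6   # emulate a large clean total
  tpm <- tpm_normalize(et, "clean")
  expect_equal(tpm$expr[gene_id == "A"]$tpm, 50)

  et2 <- map_tags(lib, idx)
  tpm2 <- tpm_normalize(et2, "unambiguous")
  expect_equal(sum(tpm2$expr$tpm), 1e6, tolerance = 1e-12)
  # one gene holding every unambiguous tag reaches 1e6 exactly
  solo <- tpm_normalize(map_tags(make_tag_library(tagA, 9L), idx),
                        "unambiguous")
  expect_equal(max(solo$expr$tpm), 1e6)

  bad <- map_tags(make_tag_library(paste0("CATG", strrep("T", 17)), 5L), idx)
  expect_error(tpm_normalize(bad, "unambiguous"), "positive")
})

test_that("indexed mapping agrees with the brute-force Hamming oracle", {
  withr::with_seed(101, {
    n_ref <- 400
    ref_tags <- unique(random_ref_tags(n_ref))
    ref_genes <- sprintf("G%03d", sample(120, length(ref_tags),
                                         replace = TRUE))
    idx <- make_tag_index(ref_tags, ref_genes)
    qs <- c(sample(ref_tags, 300, replace = TRUE),
            vapply(sample(ref_tags, 400, replace = TRUE), mutate_tag,
                   character(1), n_sub = 1),
            vapply(sample(ref_tags, 200, replace = TRUE), mutate_tag,
                   character(1), n_sub = 2),
            random_ref_tags(100))
    qs <- unique(qs)
    counts <- sample.int(50L, length(qs), replace = TRUE)
  })
  et <- map_tags(make_tag_library(qs, counts), idx)
  verdict <- oracle_map_bruteforce(qs, ref_tags, ref_genes)
  exp_counts <- tapply(counts[!startsWith(verdict, "__")],
                       verdict[!startsWith(verdict, "__")], sum)
  got <- setNames(et$expr$count, et$expr$gene_id)
  for (g in idx$gene_ids) {
    expect_identical(got[[g]],
                     as.integer(if (g %in% names(exp_counts))
                       exp_counts[[g]] else 0L))
  }
  expect_identical(et$totals$ambiguous,
                   sum(counts[verdict == "__ambiguous__"]))
  expect_identical(et$totals$unmapped,
                   sum(counts[verdict == "__unmapped__"]))
})

test_that("error-free simulation is recovered exactly by the pipeline", {
  cfg <- sim_config(n_genes = 120, library_size = 5e4, error_rate = 0,
                    n_contaminant_reads = 0, n_up = 8, n_down = 8,
                    catg_free_fraction = 0, seed = 31)
  sim <- generate_unigenes(cfg)
  lib <- simulate_tag_library(sim, treated = FALSE, config = cfg)
  idx <- build_tag_index(sim)
  et <- map_tags(clean_tags(lib), idx)

  # the 3'-most tag of each gene, and how many index entries carry it
  tag3 <- vapply(names(sim$sequences), function(g) {
    s <- sim$sequences[[g]]
    sites <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    sites <- sites[sites + 20 <= nchar(s)]
    substr(s, max(sites), max(sites) + 20)
  }, character(1))
  species <- table(tag3)  # genes sharing one sampled species
  owners <- tapply(idx$tags$gene_id, idx$tags$tag,
                   function(x) length(unique(x)))
  got <- setNames(et$expr$count, et$expr$gene_id)
  for (g in names(sim$sequences)) {
    tg <- tag3[[g]]
    draw <- lib$true_counts[[g]]
    if (species[[tg]] == 1 && owners[[tg]] == 1) {
      # uniquely owned species: exact recovery minus the singleton filter
      expect_identical(got[[g]], if (draw == 1L) 0L else draw)
    }
  }
})
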