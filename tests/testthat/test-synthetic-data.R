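test_that("sim_config validates its invariants", {
  expect_error(sim_config(length_range = c(10, 50)), "25 bp")
  expect_error(sim_config(catg_free_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(n_genes = 10, n_up = 8, n_down = 8), "spiked")
  expect_s3_class(sim_config(seed = 3), "sim_config")
})

test_that("generate_unigenes enforces CATG content, lengths, determinism", {
  cfg <- sim_config(n_genes = 100, catg_free_fraction = 0.1,
                    n_up = 5, n_down = 5, seed = 7)
  sim <- generate_unigenes(cfg)
  expect_length(sim$sequences, 100)
  n_free <- sum(!grepl("CATG", sim$sequences, fixed = TRUE))
  expect_identical(n_free, 10L)
  expect_identical(which(!grepl("CATG", sim$sequences, fixed = TRUE)),
                   which(sim$truth$catg_free))
  # every non-free gene has a CATG with >= 17 downstream bases
  for (s in sim$sequences[!sim$truth$catg_free]) {
    sites <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    expect_true(any(sites + 20 <= nchar(s)))
  }
  # fixed-seed determinism, byte for byte
  sim2 <- generate_unigenes(cfg)
  expect_identical(sim$sequences, sim2$sequences)
  expect_identical(sim$truth, sim2$truth)

  tiny <- generate_unigenes(sim_config(n_genes = 30, n_up = 2, n_down = 2,
                                       length_range = c(25, 25), seed = 1))
  expect_true(all(nchar(tiny$sequences) == 25))
})

test_that("truth table couples fold_change and de_label", {
  sim <- generate_unigenes(sim_config(n_genes = 200, n_up = 15, n_down = 15,
                                      fold_change = 8, seed = 2))
  tr <- sim$truth
  expect_true(all((tr$fold_change == 1) == (tr$de_label == "null")))
  expect_identical(sum(tr$de_label == "up"), 15L)
  expect_true(all(tr$fold_change[tr$de_label == "down"] == 1 / 8))
  expect_false(any(tr$catg_free & tr$de_label != "null"))
})

test_that("simulated libraries conserve counts and honour the error model", {
  cfg <- sim_config(n_genes = 80, library_size = 2e4, error_rate = 0,
                    n_contaminant_reads = 101, n_up = 5, n_down = 5,
                    seed = 9)
  sim <- generate_unigenes(cfg)
  lib <- simulate_tag_library(sim, treated = FALSE, config = cfg)
  idx <- build_tag_index(sim)

  expect_identical(sum(lib$true_counts), 20000L)
  expect_identical(lib$total_raw, 20101L)
  informative <- lib$tags[!grepl("N", tag, fixed = TRUE) &
                            tag != tag_adapter_sentinel()]
  expect_identical(sum(informative$count), 20000L)
  contaminant <- lib$tags[grepl("N", tag, fixed = TRUE) |
                            tag == tag_adapter_sentinel()]
  expect_identical(sum(contaminant$count), 101L)
  # error-free limit: every informative species is a verbatim reference tag
  expect_true(all(informative$tag %in% idx$tags$tag))

  lib2 <- simulate_tag_library(sim, treated = FALSE, config = cfg)
  expect_identical(lib$tags, lib2$tags)

  cfg_err <- sim_config(n_genes = 80, library_size = 2e4, error_rate = 0.05,
                        n_contaminant_reads = 0, n_up = 5, n_down = 5,
                        seed = 9)
  libe <- simulate_tag_library(sim, treated = FALSE, config = cfg_err)
  expect_identical(sum(libe$tags$count), 20000L)
  expect_gt(nrow(libe$tags), nrow(lib$tags))  # errors spread species out
})

test_that("multinomial sampling matches a binomial bound", {
  # one gene holds 1% of the weight; its draw should land within 3 sd
  truth <- data.table::data.table(
    gene_id = sprintf("G%02d", 1:50),
    catg_free = FALSE,
    baseline_abundance = c(1, rep(99 / 49, 49)),
    fold_change = 1, de_label = "null")
  # G-free tails guarantee the planted CATG is each gene's only site
  seqs <- withr::with_seed(4, setNames(
    paste0("CATG", vapply(1:50, function(i)
      paste(sample(c("A", "C", "T"), 30, replace = TRUE), collapse = ""),
      character(1))),
    truth$gene_id))
  cfg <- sim_config(n_genes = 50, library_size = 1e6, error_rate = 0,
                    n_contaminant_reads = 0, n_up = 0, n_down = 0, seed = 5)
  lib <- simulate_tag_library(seqs, truth = truth, treated = FALSE,
                              config = cfg, library_seed = 42)
  expected <- 1e4
  sd3 <- 3 * sqrt(1e6 * 0.01 * 0.99)
  expect_lt(abs(lib$true_counts[["G01"]] - expected), sd3)
})

test_that("annotations attach the designated term as configured", {
  sim <- generate_unigenes(sim_config(n_genes = 150, n_up = 10, n_down = 10,
                                      seed = 3))
  ann <- generate_annotations(sim$truth, n_terms = 5, enriched_rate = 1,
                              background_rate = 0, seed = 11)
  spiked <- attr(ann, "enriched_term")
  de_genes <- sim$truth$gene_id[sim$truth$de_label != "null"]
  expect_setequal(ann$gene_id[ann$term == spiked], de_genes)
  expect_identical(nrow(ann[ann$term != spiked]), 0L)

  ann2 <- generate_annotations(sim$truth, n_terms = 5, enriched_rate = 1,
                               background_rate = 0, seed = 11)
  expect_identical(as.data.frame(ann), as.data.frame(ann2))
})

test_that("enriched-term coverage follows the binomial bound", {
  sim <- generate_unigenes(sim_config(n_genes = 2000, n_up = 50,
                                      n_down = 50, seed = 8))
  ann <- generate_annotations(sim$truth, n_terms = 10, enriched_rate = 0.6,
                              background_rate = 0.05, seed = 21)
  spiked <- attr(ann, "enriched_term")
  de_genes <- sim$truth$gene_id[sim$truth$de_label != "null"]
  hits <- sum(ann$gene_id[ann$term == spiked] %in% de_genes)
  expect_lt(abs(hits - 0.6 * 100), 3 * sqrt(100 * 0.6 * 0.4))
})

test_that("family fixtures are constructed to their labels", {
  fx <- generate_family_fixtures(seed = 1)
  s <- fx$sequences
  expect_identical(nchar(s[["too_short"]]), 350L)
  expect_identical(longest_orf(s[["short_orf"]])$aa_length, 80L)
  expect_gte(longest_orf(s[["kept_member"]])$aa_length, 100L)
  # variant pair differs at < 5% of aligned positions
  av <- strsplit(s[["variant_a"]], "")[[1]]
  bv <- strsplit(s[["variant_b"]], "")[[1]]
  n <- min(length(av), length(bv))
  expect_lt(mean(av[1:n] != bv[1:n]), 0.05)
  expect_identical(fx$expected$expected_disposition,
                   c("removed_short", "removed_short_orf", "kept", "kept",
                     "removed_variant"))
  expect_identical(generate_family_fixtures(seed = 1)$sequences, s)
})
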