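gm <- function(...) {
  tibble::tibble(...)
}

simple_model <- tibble::tibble(
  chrom = "chr1",
  start = c(0, 150),
  end = c(2000, 300),
  name = "GENEA",
  type = c("gene", "exon")
)

test_that("a 1-bp exon overlap is exonic and carries the gene symbol", {
  re <- tibble::tibble(re_id = "re1", chrom = "chr1", start = 100, end = 200)
  out <- classify_re(re, simple_model)
  expect_equal(out$re_class, "exonic")
  expect_equal(out$gene_symbols, "GENEA")
})

test_that("exon proximity within the window is near_exon, by brute-force distance", {
  model <- gm(chrom = "chr1", start = c(0, 1150), end = c(5000, 1300),
              name = "GENEB", type = c("gene", "exon"))
  re <- tibble::tibble(re_id = "re1", chrom = "chr1", start = 100, end = 200)
  out <- classify_re(re, model, near_window = 1000)
  expect_equal(out$re_class, "near_exon") # gap 950 <= 1000
  expect_equal(out$re_class,
               brute_classify(100, 200, "chr1",
                              model[model$type == "exon", ],
                              model[model$type == "gene", ], 1000))
  out2 <- classify_re(re, model, near_window = 900)
  expect_equal(out2$re_class, "intronic") # gap 950 > 900, inside gene body
})

test_that("REs on chromosomes without genes are orphan, with a warning", {
  re <- tibble::tibble(re_id = "re1", chrom = "chrX", start = 10, end = 20)
  expect_warning(out <- classify_re(re, simple_model), "chrX")
  expect_equal(out$re_class, "orphan")
  expect_warning(out2 <- classify_re(re, simple_model[0, ]), "empty gene model")
  expect_equal(out2$re_class, "orphan")
})

test_that("classifier agrees with the quadratic brute-force scan on random intervals", {
  withr::local_seed(21)
  n_genes <- 15
  gstart <- sort(sample.int(200000, n_genes))
  model <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = gstart, end = gstart + 3000,
                   name = sprintf("G%02d", 1:n_genes), type = "gene"),
    tibble::tibble(chrom = "chr1", start = gstart + 200, end = gstart + 600,
                   name = sprintf("G%02d", 1:n_genes), type = "exon")
  )
  res <- tibble::tibble(
    re_id = sprintf("re%03d", 1:200),
    chrom = "chr1",
    start = sample.int(220000, 200)
  )
  res$end <- res$start + sample(50:400, 200, replace = TRUE)
  out <- classify_re(res, model, near_window = 800)
  expected <- vapply(seq_len(nrow(res)), function(i) {
    brute_classify(res$start[i], res$end[i], "chr1",
                   model[model$type == "exon", ],
                   model[model$type == "gene", ], 800)
  }, character(1))
  expect_equal(out$re_class, expected)
})

test_that("repeat overlap respects the half-open convention and sorts names", {
  reps <- tibble::tibble(chrom = "chr1", start = c(100, 150, 300),
                         end = c(200, 250, 400),
                         name = c("GA-rich", "(AATGGAATGG)n", "MER1A"))
  res <- tibble::tibble(re_id = c("a", "b", "c"), chrom = "chr1",
                        start = c(180, 200, 0), end = c(220, 300, 100))
  out <- overlap_repeats(res, reps)
  expect_equal(out$repeat_names[1], "(AATGGAATGG)n,GA-rich")
  expect_equal(out$repeat_names[2], "(AATGGAATGG)n") # [200,250) only
  expect_equal(out$repeat_names[3], "") # end == start of first repeat: no hit
  # permutation invariance of the repeat input order
  out2 <- overlap_repeats(res, reps[c(3, 1, 2), ])
  expect_equal(out$repeat_names, out2$repeat_names)
})

test_that("motility overlap reports listed genes of significant exonic REs by direction", {
  calls <- tibble::tibble(
    re_class = c("exonic", "exonic", "intronic", "exonic", "exonic"),
    gene_symbols = c("TEKT2", "ATP1A4,WDR66", "TEKT2", "", "DDX4"),
    direction = c("down", "down", "down", "down", "ns")
  )
  out <- motility_overlap(calls, c("TEKT2", "ATP1A4", "DDX4"))
  expect_equal(out$gene, c("ATP1A4", "TEKT2"))
  expect_equal(out$direction, c("down", "down"))
  # the list can also come from a one-symbol-per-line file
  path <- system.file("extdata", "motility_genes_example.txt",
                      package = "crossbackr")
  out_file <- motility_overlap(calls, path)
  expect_equal(out_file$gene, c("ATP1A4", "TEKT2", "WDR66"))
  expect_warning(empty <- motility_overlap(calls, character(0)), "empty gene list")
  expect_equal(nrow(empty), 0)
})

test_that("simulated annotation covers all classes, several repeats, and re-classifies identically", {
  sim <- simulate_re_annotation(60, seed = 5)
  ann <- sim$annotation
  expect_setequal(unique(ann$re_class),
                  c("exonic", "near_exon", "intronic", "orphan"))
  reps <- unique(unlist(strsplit(ann$repeat_names[ann$repeat_names != ""], ",")))
  expect_gte(length(reps), 3)
  # round-trip: classifying the emitted coordinates reproduces stored classes
  re_done <- classify_re(ann[, c("re_id", "chrom", "start", "end")],
                         sim$gene_model, near_window = 1000)
  expect_equal(re_done$re_class, ann$re_class)
  # exonic REs always carry a gene symbol
  expect_true(all(ann$gene_symbols[ann$re_class == "exonic"] != ""))
  # empty repeat model leaves repeat names empty
  sim2 <- simulate_re_annotation(12, repeat_model = tibble::tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    name = character(0)), seed = 5)
  expect_true(all(sim2$annotation$repeat_names == ""))
})
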