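#' Simulate RE annotation over a toy genome
#'
#' Places `n_features` RNA elements on a synthetic genome so that all four
#' RE classes (exonic, near-exon, intronic, orphan) are represented, and a
#' subset of orphan REs fall on repeat intervals covering at least three
#' distinct repeat names. The emitted classes and repeat names are computed
#' by [classify_re()] and [overlap_repeats()] on the emitted coordinates,
#' so annotation and classifier agree by construction.
#'
#' The default toy genome tiles genes of 10 kb (two 500-bp exons, at the
#' gene start and 8 kb in) every 30 kb along one chromosome, with repeat
#' intervals in the intergenic gaps named after repeats observed in sperm
#' RNA (`"(AATGGAATGG)n"`, `"GA-rich"`, `"(TTTC)n"`, `"MER1A"`).
#'
#' @param n_features Number of REs; ids match the expression simulators
#'   (`re_00001`, ...).
#' @param gene_model Optional gene model tibble (`chrom`, `start`, `end`,
#'   `name`, `type`); pass a zero-row tibble to force all-orphan output
#'   (warns). Built automatically when `NULL`.
#' @param repeat_model Optional repeat tibble (`chrom`, `start`, `end`,
#'   `name`); zero-row means no repeat names. Built automatically when
#'   `NULL`.
#' @param class_fractions Named target fractions per RE class.
#' @param near_window Near-exon window (bp) used for classification.
#' @param seed Integer seed (coordinate jitter).
#' @return A list with `annotation` (tibble: `re_id`, `chrom`, `start`,
#'   `end`, `strand`, `re_class`, `gene_symbols`, `repeat_names`),
#'   `gene_model`, and `repeat_model`.
#' @examples
#' ann <- simulate_re_annotation(20, seed = 1)
#' table(ann$annotation$re_class)
#' @export
simulate_re_annotation <- function(n_features, gene_model = NULL,
                                   repeat_model = NULL,
                                   class_fractions = c(exonic = 0.40,
                                                       near_exon = 0.15,
                                                       intronic = 0.25,
                                                       orphan = 0.20),
                                   near_window = 1000, seed = 1) {
  assert_count(n_features, "n_features", min = 1)
  stopifnot(all(sort(names(class_fractions)) == sort(RE_CLASSES)))
  if (near_window > 3000) {
    abort("the toy genome supports near_window <= 3000 bp")
  }
  withr::local_seed(seed)

  n_genes <- max(3L, ceiling(n_features / 4))
  gene_span <- 30000L
  gs <- (seq_len(n_genes) - 1L) * gene_span
  if (is.null(gene_model)) {
    gene_model <- bind_rows(
      tibble(chrom = "chr1", start = gs, end = gs + 10000L,
             name = sprintf("GENE%03d", seq_len(n_genes)), type = "gene"),
      tibble(chrom = "chr1", start = gs, end = gs + 500L,
             name = sprintf("GENE%03d", seq_len(n_genes)), type = "exon"),
      tibble(chrom = "chr1", start = gs + 8000L, end = gs + 8500L,
             name = sprintf("GENE%03d", seq_len(n_genes)), type = "exon")
    )
  }
  repeat_names_pool <- c("(AATGGAATGG)n", "GA-rich", "(TTTC)n", "MER1A")
  if (is.null(repeat_model)) {
    repeat_model <- tibble(
      chrom = "chr1",
      start = gs + 15000L,
      end = gs + 15500L,
      name = repeat_names_pool[(seq_len(n_genes) - 1L) %% length(repeat_names_pool) + 1L]
    )
  }

  # class counts: floor the fractions, hand out the remainder, then make
  # sure every class appears when there is room for it
  counts <- floor(class_fractions * n_features)
  while (sum(counts) < n_features) {
    i <- which.max(class_fractions * n_features - counts)
    counts[i] <- counts[i] + 1
  }
  if (n_features >= length(RE_CLASSES)) {
    for (cl in names(counts)) {
      if (counts[cl] == 0) {
        counts[cl] <- 1
        counts[which.max(counts)] <- counts[which.max(counts)] - 1
      }
    }
  }
  classes <- rep(names(counts), counts)

  slot <- (seq_len(n_features) - 1L) %% n_genes + 1L
  g0 <- gs[slot]
  jitter <- sample.int(80, n_features, replace = TRUE)
  width <- 100L
  start <- integer(n_features)
  # two thirds of orphan REs (a contiguous block, so consecutive gene slots
  # and hence cycling repeat names) sit on repeat intervals; the rest are
  # plain intergenic
  orphan_idx <- which(classes == "orphan")
  on_repeat <- logical(n_features)
  on_repeat[orphan_idx[seq_len(ceiling(2 * length(orphan_idx) / 3))]] <- TRUE
  for (i in seq_len(n_features)) {
    start[i] <- g0[i] + switch(classes[i],
      exonic    = 100L,            # inside exon 1
      near_exon = 620L,            # 120 bp past exon 1, inside the gene body
      intronic  = 4000L,           # mid-intron, > near_window from both exons
      orphan    = if (on_repeat[i]) 15100L else 20000L
    ) + jitter[i]
  }

  ann <- tibble(
    re_id = sprintf("re_%05d", seq_len(n_features)),
    chrom = "chr1",
    start = start,
    end = start + width,
    strand = "."
  )
  ann <- classify_re(ann, gene_model, near_window = near_window)
  ann <- overlap_repeats(ann, repeat_model)
  list(annotation = ann, gene_model = gene_model, repeat_model = repeat_model)
}
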