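#' Classify RNA elements by overlap with a gene model
#'
#' Assigns each RNA element (RE) one of four classes by interval overlap,
#' with deterministic priority: `exonic` if the RE overlaps at least 1 bp
#' of any exon; else `near_exon` if its gap to the nearest exon is at most
#' `near_window` bp; else `intronic` if it lies within a gene body; else
#' `orphan` (intergenic). Strand is ignored: sperm RNA is extensively
#' fragmented and no strand rule is defensible for these elements. All
#' coordinates are 0-based half-open (BED convention).
#'
#' @param res Tibble of REs with columns `chrom`, `start`, `end` (and
#'   typically `re_id`).
#' @param gene_model Tibble with columns `chrom`, `start`, `end`, `name`
#'   (gene symbol), `type` (`"gene"` for gene bodies, `"exon"` for exons).
#' @param near_window Maximum exon gap (bp) for the `near_exon` class.
#' @return `res` with columns `re_class` and `gene_symbols`
#'   (comma-separated, sorted; `""` when none). Exonic REs always carry at
#'   least one symbol. REs on chromosomes absent from the gene model are
#'   `orphan`, with a warning.
#' @examples
#' gm <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(1000, 300),
#'                      name = "GENE1", type = c("gene", "exon"))
#' classify_re(tibble::tibble(re_id = "re1", chrom = "chr1",
#'                            start = 150, end = 250), gm)
#' @export
classify_re <- function(res, gene_model, near_window = 1000) {
  check_intervals(res, "res")
  check_intervals(gene_model, "gene_model", allow_empty = TRUE)
  n <- nrow(res)
  re_class <- rep("orphan", n)
  symbols <- vector("list", n)
  for (i in seq_len(n)) symbols[[i]] <- character(0)

  if (nrow(gene_model) > 0) {
    missing_chrom <- setdiff(unique(res$chrom), unique(gene_model$chrom))
    if (length(missing_chrom)) {
      warn(sprintf("chromosome(s) absent from gene model, REs set to orphan: %s",
                   paste(missing_chrom, collapse = ", ")))
    }
    exons <- gene_model[gene_model$type == "exon", , drop = FALSE]
    genes <- gene_model[gene_model$type == "gene", , drop = FALSE]

    for (ch in intersect(unique(res$chrom), unique(gene_model$chrom))) {
      idx <- which(res$chrom == ch)
      ir <- IRanges::IRanges(res$start[idx] + 1L, res$end[idx])
      ex <- exons[exons$chrom == ch, , drop = FALSE]
      gn <- genes[genes$chrom == ch, , drop = FALSE]
      ir_ex <- IRanges::IRanges(ex$start + 1L, ex$end)
      ir_gn <- IRanges::IRanges(gn$start + 1L, gn$end)

      ov_ex <- IRanges::findOverlaps(ir, ir_ex, minoverlap = 1L)
      ov_gn <- IRanges::findOverlaps(ir, ir_gn, minoverlap = 1L)

      is_ex <- logical(length(idx))
      if (length(ir_ex)) {
        is_ex[unique(S4Vectors::queryHits(ov_ex))] <- TRUE
        gap <- rep(NA_real_, length(idx))
        near <- IRanges::distanceToNearest(ir, ir_ex)
        gap[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
        is_near <- !is_ex & !is.na(gap) & gap > 0 & gap <= near_window
      } else {
        is_near <- logical(length(idx))
      }
      is_gn <- logical(length(idx))
      if (length(ir_gn)) is_gn[unique(S4Vectors::queryHits(ov_gn))] <- TRUE

      cls <- ifelse(is_ex, "exonic",
                    ifelse(is_near, "near_exon",
                           ifelse(is_gn, "intronic", "orphan")))
      re_class[idx] <- cls

      # symbols: exons and gene bodies overlapped; for near_exon REs, the
      # nearest exon's gene
      for (k in seq_along(idx)) {
        sy <- character(0)
        if (length(ir_ex)) {
          hit_ex <- S4Vectors::subjectHits(ov_ex)[S4Vectors::queryHits(ov_ex) == k]
          sy <- c(sy, ex$name[hit_ex])
        }
        if (length(ir_gn)) {
          hit_gn <- S4Vectors::subjectHits(ov_gn)[S4Vectors::queryHits(ov_gn) == k]
          sy <- c(sy, gn$name[hit_gn])
        }
        if (cls[k] == "near_exon" && length(ir_ex)) {
          hit_nr <- S4Vectors::subjectHits(near)[S4Vectors::queryHits(near) == k]
          sy <- c(sy, ex$name[hit_nr])
        }
        symbols[[idx[k]]] <- sort(unique(sy))
      }
    }
  } else {
    warn("empty gene model: all REs classified as orphan")
  }

  res$re_class <- re_class
  res$gene_symbols <- map_chr(symbols, paste, collapse = ",")
  res
}

#' Attach overlapping repeat names to RNA elements
#'
#' Reports, per RE, the names of all repeat intervals it overlaps by at
#' least 1 bp (half-open coordinates: abutting intervals do not overlap).
#' Names are sorted and deduplicated, so the result does not depend on the
#' input order of the repeat intervals.
#'
#' @param res Tibble of REs (`chrom`, `start`, `end`).
#' @param repeats Tibble of RepeatMasker-style intervals (`chrom`, `start`,
#'   `end`, `name`), e.g. name `"(AATGGAATGG)n"` or `"GA-rich"`.
#' @return `res` with a `repeat_names` column (comma-separated; `""` when
#'   none).
#' @export
overlap_repeats <- function(res, repeats) {
  check_intervals(res, "res")
  check_intervals(repeats, "repeats", allow_empty = TRUE)
  out <- rep("", nrow(res))
  if (nrow(repeats) > 0) {
    for (ch in intersect(unique(res$chrom), unique(repeats$chrom))) {
      idx <- which(res$chrom == ch)
      rp <- repeats[repeats$chrom == ch, , drop = FALSE]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(res$start[idx] + 1L, res$end[idx]),
        IRanges::IRanges(rp$start + 1L, rp$end),
        minoverlap = 1L
      )
      hits <- split(rp$name[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov))
      for (q in names(hits)) {
        out[idx[as.integer(q)]] <- paste(sort(unique(hits[[q]])), collapse = ",")
      }
    }
  }
  res$repeat_names <- out
  res
}

#' Overlap significant exonic REs with a sperm-motility gene list
#'
#' Intersects the gene symbols of significant exonic REs with a supplied
#' gene list (one HGNC symbol per line), partitioned by the direction of
#' the expression change. REs without gene symbols never contribute.
#'
#' @param annotated_calls Tibble with columns `re_class`, `gene_symbols`
#'   (comma-separated) and `direction` (`"up"`/`"down"`/`"ns"`), e.g. a
#'   join of differential calls with [classify_re()] output.
#' @param gene_list Either a path to a one-symbol-per-line file or a
#'   character vector of symbols.
#' @return Tibble with columns `gene` and `direction`, one row per
#'   (gene, direction) pair observed; empty (with a warning) when the gene
#'   list is empty.
#' @export
motility_overlap <- function(annotated_calls, gene_list) {
  if (is.character(gene_list) && length(gene_list) == 1 && file.exists(gene_list)) {
    gene_list <- readr::read_lines(gene_list)
  }
  gene_list <- setdiff(trimws(gene_list), "")
  if (!length(gene_list)) {
    warn("empty gene list: no motility overlap possible")
    return(tibble(gene = character(0), direction = character(0)))
  }
  annotated_calls |>
    filter(.data$re_class == "exonic", .data$direction %in% c("up", "down"),
           .data$gene_symbols != "") |>
    mutate(gene = strsplit(.data$gene_symbols, ",", fixed = TRUE)) |>
    tidyr::unnest("gene") |>
    filter(.data$gene %in% gene_list) |>
    distinct(.data$gene, .data$direction) |>
    arrange(.data$gene, .data$direction)
}

check_intervals <- function(x, name, allow_empty = FALSE) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("`%s` must have columns chrom/start/end", name))
  }
  if (!allow_empty && nrow(x) == 0) abort(sprintf("`%s` has no intervals", name))
  if (nrow(x) && any(x$start >= x$end)) {
    abort(sprintf("`%s` has intervals with start >= end (0-based half-open required)", name))
  }
  invisible(x)
}
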