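## On-disk artifacts. Everything is TSV (diff-friendly, bit-exact); "NA" is
## legal only in covariate columns, never in expression cells. Genomic
## coordinates are 0-based half-open throughout.

SAMPLE_SHEET_REQUIRED <- c("sample_id", "subject_id", "arm", "visit", "condition")

#' Read and validate a sample sheet
#'
#' Reads a TSV sample sheet and enforces the study-design contract: known
#' arm/visit/condition levels, unique sample ids, rate columns in
#' \[0, 1\], and — the key invariant — that every row's condition equals
#' the one implied by its arm and visit (see [arm_visit_condition()]).
#' Samples failing QC are retained (for reporting) but flagged via
#' `qc_pass`; modeling functions drop them.
#'
#' @param path TSV file with at least columns `sample_id`, `subject_id`,
#'   `arm`, `visit`, `condition`.
#' @return A tibble of validated sample records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.size(path) > 0) abort(sprintf("empty sample sheet: %s", path))
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(sheet) == 0) abort(sprintf("sample sheet has a header but no rows: %s", path))
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  missing <- setdiff(SAMPLE_SHEET_REQUIRED, names(sheet))
  if (length(missing)) {
    abort(sprintf("sample sheet lacks required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_row <- function(what, rows) {
    abort(sprintf("sample sheet row %s: %s", paste(rows, collapse = ","), what))
  }
  if (anyDuplicated(sheet$sample_id)) {
    bad_row("duplicate sample_id", which(duplicated(sheet$sample_id)))
  }
  if (any(!sheet$arm %in% ARMS)) {
    bad_row(sprintf("unknown arm '%s'", sheet$arm[!sheet$arm %in% ARMS][1]),
            which(!sheet$arm %in% ARMS)[1])
  }
  if (any(!sheet$visit %in% VISITS)) {
    bad_row(sprintf("unknown visit '%s'", sheet$visit[!sheet$visit %in% VISITS][1]),
            which(!sheet$visit %in% VISITS)[1])
  }
  if (any(!sheet$condition %in% CONDITIONS)) {
    bad_row(sprintf("unknown condition '%s'",
                    sheet$condition[!sheet$condition %in% CONDITIONS][1]),
            which(!sheet$condition %in% CONDITIONS)[1])
  }
  expected <- arm_visit_condition(sheet$arm, sheet$visit)
  if (any(mismatch <- sheet$condition != expected)) {
    i <- which(mismatch)[1]
    bad_row(sprintf("condition '%s' contradicts arm %s x visit %s (expected '%s')",
                    sheet$condition[i], sheet$arm[i], sheet$visit[i], expected[i]), i)
  }
  for (col in intersect(c("duplication_rate", "alignment_rate"), names(sheet))) {
    v <- sheet[[col]]
    if (any(ok <- !is.na(v) & (v < 0 | v > 1))) {
      bad_row(sprintf("%s outside [0, 1]", col), which(ok)[1])
    }
  }
  if (!"qc_pass" %in% names(sheet)) sheet$qc_pass <- TRUE
  sheet
}

#' Write a sample sheet as TSV
#' @param sheet Sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a rectangular TSV whose first column holds feature ids and whose
#' remaining columns are samples. Every expression cell must parse as a
#' finite, nonnegative number (scientific notation is fine); violations are
#' reported with their (feature, sample) coordinates.
#'
#' @param path TSV file.
#' @param unit `"RPKM"` (long RNAs) or `"RPM"` (small RNAs); stored as the
#'   matrix `unit` attribute.
#' @return Numeric matrix, features x samples, with dimnames.
#' @export
read_expression_matrix <- function(path, unit = c("RPKM", "RPM")) {
  unit <- match.arg(unit)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(readr::problems(tab)) > 0 || ncol(tab) < 2 || nrow(tab) == 0) {
    abort(sprintf("matrix file is not rectangular TSV: %s", path))
  }
  feature_ids <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "invalid expression cell at feature '%s', sample '%s' (value '%s'): must be a finite nonnegative number",
      feature_ids[bad[1, 1]], colnames(body)[bad[1, 2]], body[bad[1, 1], bad[1, 2]]
    ))
  }
  dimnames(vals) <- list(feature_ids, colnames(body))
  attr(vals, "unit") <- unit
  vals
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with dimnames (features x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- bind_cols(tibble(feature_id = rownames(mat)),
                  as_tibble(as.data.frame(mat)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read RE annotation from BED6+2
#'
#' BED columns: chrom, start, end, name, score, strand, plus RE class and
#' comma-separated repeat names (`"."` for none). Coordinates are 0-based
#' half-open; intervals may overlap (REs can share loci).
#'
#' @param path BED6+2 file (no header).
#' @return Tibble with `re_id`, `chrom`, `start`, `end`, `strand`,
#'   `re_class`, `repeat_names`.
#' @export
read_bed_annotation <- function(path) {
  bed <- readr::read_tsv(
    path, progress = FALSE,
    col_names = c("chrom", "start", "end", "re_id", "score", "strand",
                  "re_class", "repeat_names"),
    col_types = "ciiccccc"
  )
  if (any(bed$start >= bed$end)) {
    abort(sprintf("BED interval with start >= end at line %d",
                  which(bed$start >= bed$end)[1]))
  }
  if (any(!bed$re_class %in% RE_CLASSES)) {
    abort("BED annotation has an unknown RE class")
  }
  bed |>
    mutate(repeat_names = if_else(.data$repeat_names == ".", "", .data$repeat_names)) |>
    select("re_id", "chrom", "start", "end", "strand", "re_class", "repeat_names")
}

#' Write RE annotation as BED6+2
#' @param ann Annotation tibble ([simulate_re_annotation()] /
#'   [classify_re()] output with `repeat_names`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_annotation <- function(ann, path) {
  out <- tibble(
    chrom = ann$chrom, start = ann$start, end = ann$end, name = ann$re_id,
    score = 0L, strand = ann$strand %||% ".",
    re_class = ann$re_class,
    repeat_names = if_else(ann$repeat_names == "", ".", ann$repeat_names)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write result tables plus a run manifest
#'
#' Writes one TSV per named table and a `manifest.json` capturing the
#' configuration, its hash, the seed, and package/R versions, so a run can
#' be audited and reproduced.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config List recorded (and hashed) in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisible character vector of files written.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NA) {
  stopifnot(is.list(tables), length(tables) == 0 || !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    config = config,
    config_hash = rlang::hash(config),
    seed = seed,
    tables = names(tables),
    package_version = as.character(packageVersion("crossbackr")),
    r_version = as.character(getRversion())
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a run manifest
#' @param out_dir Directory containing `manifest.json`.
#' @return The manifest as a list.
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"), simplifyVector = TRUE)
}
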