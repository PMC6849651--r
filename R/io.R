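# Plain-CSV interchange: count matrices, probe annotations, sample sheets and
# results tables, each validated on the way in. Missing values are written as
# the literal "NA"; every writer emits a "#" comment line with the package
# version (and seed when one applies), which the readers skip.

probe_classes <- c("endogenous", "housekeeping", "positive", "negative")

read_csv_quiet <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), class = "bcrpanel_io_error")
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA")
}

#' Write a results table as CSV with a provenance header
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, seed = NULL) {
  if (!is.data.frame(x)) abort("write_table: `x` must be a data frame")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# bcrpanel %s%s",
                    as.character(utils::packageVersion("bcrpanel")),
                    if (is.null(seed)) "" else sprintf("; seed=%d", as.integer(seed)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(x), con, sep = ",", row.names = FALSE,
                     qmethod = "double", na = "NA")
  invisible(path)
}

#' Read a raw count matrix and its probe annotation
#'
#' @param path CSV of counts: first column `probe`, one column per sample.
#' @param annotation_path CSV with columns `probe`, `gene`, `class`,
#'   `spike_fM`.
#' @return A list with `counts` (wide tibble, stage `"raw"`) and `probes`.
#' @export
read_counts <- function(path, annotation_path) {
  counts <- read_csv_quiet(path)
  probes <- read_probe_annotation(annotation_path)
  validate_count_matrix(counts, stage = "raw")
  missing_ann <- setdiff(counts$probe, probes$probe)
  if (length(missing_ann))
    abort(sprintf("probe(s) absent from annotation: %s",
                  paste(missing_ann, collapse = ", ")),
          class = "bcrpanel_validation_error")
  missing_cnt <- setdiff(probes$probe, counts$probe)
  if (length(missing_cnt))
    abort(sprintf("annotated probe(s) absent from counts: %s",
                  paste(missing_cnt, collapse = ", ")),
          class = "bcrpanel_validation_error")
  attr(counts, "stage") <- "raw"
  list(counts = counts, probes = probes)
}

#' Read and validate a probe annotation table
#'
#' @param path CSV with columns `probe`, `gene`, `class`, `spike_fM`.
#' @return A validated tibble.
#' @export
read_probe_annotation <- function(path) {
  ann <- read_csv_quiet(path)
  validate_probe_annotation(ann, context = path)
  ann
}

#' Read and validate a cohort sample sheet
#'
#' @param path CSV with columns `sample`, `patient`, `tissue`, `outcome`,
#'   `lane`.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_csv_quiet(path)
  validate_sample_sheet(sheet)
  sheet
}

validate_count_matrix <- function(counts, stage = "raw") {
  if (!is.data.frame(counts) || names(counts)[1] != "probe")
    abort("count table must have `probe` as its first column",
          class = "bcrpanel_validation_error")
  if (anyDuplicated(counts$probe))
    abort(sprintf("duplicate probe id(s): %s",
                  paste(unique(counts$probe[duplicated(counts$probe)]), collapse = ", ")),
          class = "bcrpanel_validation_error")
  if (anyDuplicated(names(counts)))
    abort("duplicate sample id(s) in count table",
          class = "bcrpanel_validation_error")
  vals <- counts[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    abort(sprintf("non-numeric counts in column(s): %s",
                  paste(names(vals)[!num], collapse = ", ")),
          class = "bcrpanel_validation_error")
  m <- as.matrix(vals)
  if (anyNA(m) || any(!is.finite(m)))
    abort("counts must be finite and non-missing",
          class = "bcrpanel_validation_error")
  if (any(m < 0))
    abort("counts must be non-negative", class = "bcrpanel_validation_error")
  if (stage == "raw" && any(m != floor(m)))
    abort("raw counts must be integers", class = "bcrpanel_validation_error")
  invisible(counts)
}

validate_probe_annotation <- function(ann, context = "probe annotation") {
  need <- c("probe", "gene", "class", "spike_fM")
  if (!is.data.frame(ann) || !all(need %in% names(ann)))
    abort(sprintf("%s must have columns %s", context, paste(need, collapse = ", ")),
          class = "bcrpanel_validation_error")
  if (anyDuplicated(ann$probe))
    abort(sprintf("%s: duplicate probe id(s)", context),
          class = "bcrpanel_validation_error")
  bad <- setdiff(unique(ann$class), probe_classes)
  if (length(bad))
    abort(sprintf("%s: unknown probe class(es): %s (allowed: %s)",
                  context, paste(bad, collapse = ", "),
                  paste(probe_classes, collapse = ", ")),
          class = "bcrpanel_validation_error")
  pos <- ann$class == "positive"
  if (any(pos) && anyNA(ann$spike_fM[pos]))
    abort(sprintf("%s: positive controls need spike_fM concentrations", context),
          class = "bcrpanel_validation_error")
  invisible(ann)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample", "patient", "tissue", "outcome", "lane")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet)))
    abort(sprintf("sample sheet must have columns %s", paste(need, collapse = ", ")),
          class = "bcrpanel_validation_error")
  if (anyDuplicated(sheet$sample))
    abort("duplicate sample id(s) in sample sheet",
          class = "bcrpanel_validation_error")
  bad_tissue <- setdiff(unique(sheet$tissue), c("tumor", "normal"))
  if (length(bad_tissue))
    abort(sprintf("unknown tissue label(s): %s", paste(bad_tissue, collapse = ", ")),
          class = "bcrpanel_validation_error")
  bad_out <- setdiff(unique(sheet$outcome), c("BCR", "nonBCR"))
  if (length(bad_out))
    abort(sprintf("unknown outcome label(s): %s", paste(bad_out, collapse = ", ")),
          class = "bcrpanel_validation_error")
  dup <- duplicated(sheet[, c("patient", "tissue")])
  if (any(dup)) {
    d <- sheet[dup, , drop = FALSE]
    abort(sprintf("duplicate (patient, tissue) pair(s): %s",
                  paste(sprintf("%s/%s", d$patient, d$tissue), collapse = ", ")),
          class = "bcrpanel_validation_error")
  }
  invisible(sheet)
}

#' Write a synthetic cohort as a CSV fixture set
#'
#' Writes `counts.csv`, `probes.csv`, `samples.csv`, `qpcr.csv`, `ihc.csv`,
#' `truth.csv` and `erg_state.csv` into `dir`, round-trippable with
#' [read_cohort()].
#'
#' @param cohort A `bcr_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "bcr_cohort"))
    abort("write_cohort: `cohort` must be a bcr_cohort")
  if (is.null(cohort$counts) || ncol(cohort$counts) <= 1L || nrow(cohort$counts) == 0L)
    abort("write_cohort: empty cohort", class = "bcrpanel_validation_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    abort(sprintf("cannot create directory %s", dir), class = "bcrpanel_io_error")
  seed <- cohort$params$seed
  write_table(cohort$counts, file.path(dir, "counts.csv"), seed = seed)
  write_table(cohort$probes, file.path(dir, "probes.csv"), seed = seed)
  write_table(cohort$samples, file.path(dir, "samples.csv"), seed = seed)
  write_table(cohort$qpcr, file.path(dir, "qpcr.csv"), seed = seed)
  write_table(cohort$ihc, file.path(dir, "ihc.csv"), seed = seed)
  write_table(cohort$truth, file.path(dir, "truth.csv"), seed = seed)
  write_table(cohort$erg_state, file.path(dir, "erg_state.csv"), seed = seed)
  invisible(dir)
}

#' Read a cohort fixture set written by [write_cohort()]
#'
#' @param dir Directory containing the fixture CSVs.
#' @return A list of class `bcr_cohort` (without simulation parameters).
#' @export
read_cohort <- function(dir) {
  cp <- read_counts(file.path(dir, "counts.csv"), file.path(dir, "probes.csv"))
  samples <- read_sample_sheet(file.path(dir, "samples.csv"))
  out <- list(
    counts = cp$counts, probes = cp$probes, samples = samples,
    truth = read_csv_quiet(file.path(dir, "truth.csv")),
    erg_state = read_csv_quiet(file.path(dir, "erg_state.csv")),
    qpcr = read_csv_quiet(file.path(dir, "qpcr.csv")),
    ihc = read_csv_quiet(file.path(dir, "ihc.csv")),
    params = NULL
  )
  structure(out, class = "bcr_cohort")
}
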