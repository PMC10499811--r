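#' NPX matrix container
#'
#' The central data container of the pipeline: a samples x assays matrix of
#' NPX values (Normalized Protein eXpression, a log2-scale relative
#' abundance unit), together with one lower limit of detection (LOD) per
#' assay and one batch (measurement round) label per sample. Assay
#' identifiers combine the protein symbol with the panel name so that
#' replicate assays of the same protein measured on different panels remain
#' distinct columns.
#'
#' @param values numeric matrix, samples in rows and assays in columns, with
#'   unique row and column names. `NA` entries are allowed.
#' @param lod numeric vector of per-assay LODs on the NPX (log2) scale,
#'   named by assay or in column order; all values must be finite.
#' @param batch character/factor vector of per-sample batch labels, named by
#'   sample or in row order. Defaults to a single batch.
#' @param panel optional character vector of per-assay panel names.
#' @return an object of class `npx_matrix` with elements `values`, `lod`,
#'   `batch` and `panel`.
#' @export
npx_matrix <- function(values, lod, batch = NULL, panel = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stopf("`values` must have sample row names and assay column names")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(character(0), character(0))
  if (anyDuplicated(rownames(values)))
    stopf("duplicated sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicated assay ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  lod <- align_named(lod, colnames(values), "lod", "assay")
  if (any(!is.finite(lod))) stopf("every assay needs one finite LOD value")
  if (is.null(batch)) batch <- rep("batch1", nrow(values))
  batch <- align_named(as.character(batch), rownames(values), "batch", "sample")
  if (!is.null(panel)) panel <- align_named(as.character(panel), colnames(values),
                                            "panel", "assay")
  structure(list(values = values, lod = lod, batch = batch, panel = panel),
            class = "npx_matrix")
}

align_named <- function(x, ids, what, dim_name) {
  if (length(x) != length(ids))
    stopf("`%s` must have one value per %s (%d != %d)",
          what, dim_name, length(x), length(ids))
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stopf("`%s` missing entries for: %s", what, paste(missing, collapse = ", "))
    x <- x[ids]
  } else {
    names(x) <- ids
  }
  x
}

#' @exportS3Method base::print
print.npx_matrix <- function(x, ...) {
  cat(sprintf("npx_matrix: %d samples x %d assays, %d batch(es)\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch))))
  cat(sprintf("  NPX range: [%.2f, %.2f], %.1f%% missing\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' @rdname npx_matrix
#' @param x an `npx_matrix`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname npx_matrix
#' @export
assay_ids <- function(x) colnames(x$values)

#' Subset an NPX matrix
#'
#' @param x an `npx_matrix`.
#' @param i,j sample / assay indices (logical, integer or names).
#' @param ... unused.
#' @param drop ignored; subsetting always returns an `npx_matrix`.
#' @export
`[.npx_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  npx_matrix(v, lod = x$lod[colnames(v)], batch = x$batch[rownames(v)],
             panel = if (!is.null(x$panel)) x$panel[colnames(v)])
}

npx_long_columns <- c("sample_id", "assay_id", "panel", "npx", "lod", "batch")

#' Read a long-format NPX table
#'
#' Reads the long (one row per sample x assay measurement) CSV/TSV layout in
#' which PEA results are commonly exported and pivots it into an
#' [npx_matrix]. Required columns: `sample_id`, `assay_id`, `panel`, `npx`,
#' `lod`, `batch` (alternative column names can be mapped via `aliases`).
#' Duplicate (sample, assay) rows are an error; combinations absent from the
#' file become `NA`.
#'
#' @param path file path.
#' @param sep field separator; guessed from the extension by default
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param aliases named character vector mapping required column names to
#'   the names used in the file, e.g. `c(sample_id = "SampleID")`.
#' @return an [npx_matrix].
#' @export
read_npx_long <- function(path, sep = NULL, aliases = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (std in names(aliases)) {
    if (!aliases[[std]] %in% names(df))
      stopf("aliased column '%s' (for '%s') not found in %s",
            aliases[[std]], std, path)
    names(df)[names(df) == aliases[[std]]] <- std
  }
  missing <- setdiff(npx_long_columns, names(df))
  if (length(missing))
    stopf("format error: %s lacks required column(s): %s",
          path, paste(missing, collapse = ", "))
  if (!is.numeric(df$npx)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$npx))) & !is.na(df$npx))
    if (length(bad))
      stopf("parse error: non-numeric NPX at row(s) %s",
            paste(utils::head(bad, 5), collapse = ", "))
    df$npx <- as.numeric(df$npx)
  }
  if (!is.numeric(df$lod)) df$lod <- as.numeric(df$lod)
  pivot_npx_long(df)
}

pivot_npx_long <- function(df) {
  key <- paste(df$sample_id, df$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stopf("duplicated (sample, assay) row: (%s, %s)", d$sample_id, d$assay_id)
  }
  samples <- unique(df$sample_id)
  assays <- unique(df$assay_id)
  m <- matrix(NA_real_, length(samples), length(assays),
              dimnames = list(samples, assays))
  m[cbind(match(df$sample_id, samples), match(df$assay_id, assays))] <- df$npx

  first <- !duplicated(df$assay_id)
  lod <- df$lod[first]
  names(lod) <- df$assay_id[first]
  chk <- tapply(df$lod, df$assay_id, function(v) length(unique(v[!is.na(v)])))
  if (any(chk > 1))
    stopf("assay(s) with conflicting LOD values: %s",
          paste(names(chk)[chk > 1], collapse = ", "))
  panel <- df$panel[first]
  names(panel) <- df$assay_id[first]

  firsts <- !duplicated(df$sample_id)
  batch <- as.character(df$batch[firsts])
  names(batch) <- df$sample_id[firsts]
  chkb <- tapply(df$batch, df$sample_id, function(v) length(unique(v)))
  if (any(chkb > 1))
    stopf("sample(s) assigned to more than one batch: %s",
          paste(names(chkb)[chkb > 1], collapse = ", "))

  npx_matrix(m, lod = lod, batch = batch, panel = panel)
}

#' Write an NPX matrix in long format
#'
#' Inverse of [read_npx_long()]; `NA` cells are not written, so a
#' read/write round trip reproduces the input up to row order.
#'
#' @param m an [npx_matrix].
#' @param path output file path; extension selects the separator as in
#'   [read_npx_long()].
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(m, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  long <- npx_to_long(m)
  utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

npx_to_long <- function(m) {
  idx <- which(!is.na(m$values), arr.ind = TRUE)
  s <- rownames(m$values)[idx[, 1]]
  a <- colnames(m$values)[idx[, 2]]
  data.frame(
    sample_id = s,
    assay_id = a,
    panel = if (!is.null(m$panel)) unname(m$panel[a]) else "panel1",
    npx = m$values[idx],
    lod = unname(m$lod[a]),
    batch = unname(m$batch[s]),
    stringsAsFactors = FALSE
  )
}

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata contract: a `sample_id` column, a
#' non-missing `diagnosis` for every analyzed (non-bridge) sample, `age` in
#' years > 0 and `sex` coded M/F. Optional columns (`cohort`,
#' `parkinson_medication`, `abeta42`, `ttau`, `ptau`, `mmse`, `updrs3`,
#' `dlb_stage`, `braak_asyn`, `is_bridge`) are passed through.
#'
#' @param meta a data.frame of per-sample metadata.
#' @param m optional [npx_matrix]; if given, every sample of `m` must be
#'   present in `meta`.
#' @return `meta`, with `diagnosis` and `sex` as character, invisibly
#'   checked.
#' @export
validate_metadata <- function(meta, m = NULL) {
  req <- c("sample_id", "diagnosis", "age", "sex")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stopf("metadata lacks required column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stopf("duplicated sample_id in metadata")
  meta$diagnosis <- as.character(meta$diagnosis)
  meta$sex <- as.character(meta$sex)
  analyzed <- if ("is_bridge" %in% names(meta)) !meta$is_bridge else
    rep(TRUE, nrow(meta))
  if (any(is.na(meta$diagnosis[analyzed])))
    stopf("diagnosis missing for analyzed sample(s)")
  if (any(!is.na(meta$age) & meta$age <= 0)) stopf("age must be > 0")
  if (!all(meta$sex[!is.na(meta$sex)] %in% c("M", "F")))
    stopf("sex must be coded M/F")
  if (!is.null(m)) {
    absent <- setdiff(sample_ids(m), meta$sample_id)
    if (length(absent))
      stopf("samples missing from metadata: %s",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  meta
}
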