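#' Per-trial voxel-pattern container
#'
#' Holds one activation pattern (a voxel vector over a fixed region of
#' interest) per trial, keyed by subject, phase (encoding/test), run and
#' stimulus id, together with the aligned trial metadata. The analysis
#' modules (RSA, encoding-retrieval similarity) consume this container; it
#' can be filled by the synthetic generator, read from disk, or extracted
#' from per-trial NIfTI maps with [extract_patterns()].
#'
#' @param patterns Numeric matrix, one row per trial.
#' @param meta Data frame aligned to the rows, with at least columns
#'   subject, phase, run, stimulus; typically also delay, set, item_type,
#'   emotion.
#' @return An object of class `pattern_store`.
#' @export
pattern_store <- function(patterns, meta) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != nrow(meta))
    stop("pattern_store: patterns and meta must have the same number of rows",
         call. = FALSE)
  req <- c("subject", "phase", "run", "stimulus")
  if (!all(req %in% names(meta)))
    stop("pattern_store: meta needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  key <- paste(meta$subject, meta$phase, meta$run, meta$stimulus, sep = "|")
  if (anyDuplicated(key))
    stop("pattern_store: duplicate (subject, phase, run, stimulus) keys",
         call. = FALSE)
  rownames(meta) <- NULL
  rownames(patterns) <- key
  structure(list(patterns = patterns, meta = meta), class = "pattern_store")
}

#' @export
print.pattern_store <- function(x, ...) {
  cat("pattern_store:", nrow(x$patterns), "trials x", ncol(x$patterns),
      "voxels;", length(unique(x$meta$subject)), "subject(s);",
      "phases:", paste(unique(x$meta$phase), collapse = "/"), "\n")
  invisible(x)
}

#' Subset a pattern store by metadata
#'
#' @param store A [pattern_store()].
#' @param ... Named filters matched against metadata columns, e.g.
#'   `subject = "sub001"`, `phase = "test"`, `emotion = "neutral"`.
#' @return A `pattern_store` restricted to the matching trials.
#' @export
subset_store <- function(store, ...) {
  stopifnot(inherits(store, "pattern_store"))
  filters <- list(...)
  keep <- rep(TRUE, nrow(store$meta))
  for (nm in names(filters)) {
    if (!nm %in% names(store$meta))
      stop("subset_store: no metadata column '", nm, "'", call. = FALSE)
    keep <- keep & store$meta[[nm]] %in% filters[[nm]]
  }
  pattern_store(store$patterns[keep, , drop = FALSE],
                store$meta[keep, , drop = FALSE])
}

#' Retrieve one pattern vector
#'
#' @param store A [pattern_store()].
#' @param subject,phase,run,stimulus Key components.
#' @return The voxel vector for that trial.
#' @export
get_pattern <- function(store, subject, phase, run, stimulus) {
  key <- paste(subject, phase, run, stimulus, sep = "|")
  hit <- match(key, rownames(store$patterns))
  if (is.na(hit))
    stop("get_pattern: no pattern for key ", key, call. = FALSE)
  store$patterns[hit, ]
}

#' Write a pattern store as per-subject TSV archives plus a JSON manifest
#'
#' One `<subject>.tsv` per subject (trials x voxels, keyed rows) and a
#' `manifest.json` recording subjects, files, voxel count and per-trial keys.
#'
#' @param store A [pattern_store()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pattern_store <- function(store, dir) {
  stopifnot(inherits(store, "pattern_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- unique(store$meta$subject)
  files <- character(0)
  for (s in subjects) {
    idx <- store$meta$subject == s
    f <- file.path(dir, paste0(s, ".tsv"))
    utils::write.table(
      data.frame(key = rownames(store$patterns)[idx],
                 store$patterns[idx, , drop = FALSE],
                 check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(format = "memsem-pattern-store/1",
                   n_voxels = ncol(store$patterns),
                   subjects = as.list(stats::setNames(files, subjects)),
                   meta_file = "meta.tsv")
  write_tsv(store$meta, file.path(dir, "meta.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a pattern store written by [write_pattern_store()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A [pattern_store()].
#' @export
read_pattern_store <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- read_tsv(file.path(dir, manifest$meta_file))
  mats <- lapply(unlist(manifest$subjects), function(f) {
    d <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$key
    m
  })
  pats <- do.call(rbind, mats)
  key <- paste(meta$subject, meta$phase, meta$run, meta$stimulus, sep = "|")
  pattern_store(pats[key, , drop = FALSE], meta)
}
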