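#' Encoding-phase pattern of an item
#'
#' Returns either the voxel-wise mean across all encoding runs (variant
#' "mean_encoding", the default indicator of encoding-related activation)
#' or a single run's pattern (variant "run1"/"run2"/"run3").
#'
#' @param store A [pattern_store()].
#' @param subject Subject id.
#' @param stimulus Stimulus id of the encoded (old) item.
#' @param variant "mean_encoding" or "runK".
#' @return Voxel vector.
#' @export
encoding_pattern <- function(store, subject, stimulus,
                             variant = "mean_encoding") {
  stopifnot(inherits(store, "pattern_store"))
  idx <- store$meta$subject == subject & store$meta$phase == "encoding" &
    store$meta$stimulus == stimulus
  if (!any(idx))
    stop("encoding_pattern: no encoding patterns for ", subject, "/",
         stimulus, call. = FALSE)
  if (variant == "mean_encoding")
    return(colMeans(store$patterns[idx, , drop = FALSE]))
  run <- suppressWarnings(as.integer(sub("^run", "", variant)))
  if (is.na(run))
    stop("encoding_pattern: unknown variant '", variant, "'", call. = FALSE)
  hit <- idx & store$meta$run == run
  if (!any(hit))
    stop("encoding_pattern: ", subject, "/", stimulus,
         " has no pattern in run ", run, call. = FALSE)
  store$patterns[which(hit)[1], ]
}

.fisher_r <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(c(r = NA_real_, z = NA_real_))
  r <- stats::cor(a, b)
  c(r = r, z = atanh(r))
}

#' Trial-specific encoding-retrieval similarity (ERS)
#'
#' For every old item: Pearson correlation between its encoding pattern
#' (see [encoding_pattern()]) and its test-phase pattern, Fisher
#' z-transformed. Records with undefined (zero-variance) or non-finite z
#' (r = +-1, possible only in noise-free synthetic data) are flagged
#' invalid. Optionally restricts to correctly recognized items (excluding
#' misses) given a response table.
#'
#' @param store A [pattern_store()].
#' @param variant Encoding-pattern variant, see [encoding_pattern()].
#' @param roi Label stored in the output (default "roi").
#' @param responses Optional response table; if supplied with
#'   `correct_only = TRUE`, old items not endorsed 'old' are excluded.
#' @param correct_only Exclude misses (requires `responses`).
#' @return Data frame of class `ers_records`: subject, delay, set, stimulus,
#'   emotion, roi, variant, r, z, valid.
#' @export
compute_ers <- function(store, variant = "mean_encoding", roi = "roi",
                        responses = NULL, correct_only = FALSE) {
  stopifnot(inherits(store, "pattern_store"))
  test_old <- store$meta[store$meta$phase == "test" &
                           store$meta$item_type == "old", , drop = FALSE]
  if (correct_only) {
    if (is.null(responses))
      stop("compute_ers: correct_only requires a response table", call. = FALSE)
    hits <- responses[responses$item_type == "old" &
                        collapse_response(responses$response) == "old",
                      c("subject", "set")]
    keep <- paste(test_old$subject, test_old$set) %in%
      paste(hits$subject, hits$set)
    test_old <- test_old[keep, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(test_old)), function(i) {
    tr <- test_old[i, ]
    enc <- encoding_pattern(store, tr$subject, tr$stimulus, variant)
    tst <- get_pattern(store, tr$subject, "test", tr$run, tr$stimulus)
    rz <- .fisher_r(enc, tst)
    data.frame(subject = tr$subject, delay = tr$delay, set = tr$set,
               stimulus = tr$stimulus, emotion = tr$emotion, roi = roi,
               variant = variant, r = rz[["r"]], z = rz[["z"]],
               valid = is.finite(rz[["z"]]))
  })
  out <- do.call(rbind, rows)
  n_bad <- sum(!out$valid)
  if (n_bad > 0)
    warning("compute_ers: ", n_bad, " record(s) with undefined or infinite z")
  rownames(out) <- NULL
  class(out) <- c("ers_records", class(out))
  out
}

#' Lure-based gist reinstatement
#'
#' Similarity (Fisher z of Pearson r) between a related lure's test-phase
#' pattern and the corresponding old item's encoding pattern — an index of
#' reinstatement of the semantic or perceptual gist of the original memory.
#'
#' @param store A [pattern_store()].
#' @param lure_type "semantic" or "perceptual".
#' @param variant Encoding-pattern variant.
#' @param roi Label stored in the output.
#' @return Data frame: subject, delay, set, emotion, lure_type, roi, r, z,
#'   valid.
#' @export
compute_gist_reinstatement <- function(store, lure_type,
                                       variant = "mean_encoding",
                                       roi = "roi") {
  stopifnot(inherits(store, "pattern_store"),
            lure_type %in% c("semantic", "perceptual"))
  lure_trials <- store$meta[store$meta$phase == "test" &
                              store$meta$item_type == lure_type, ,
                            drop = FALSE]
  rows <- lapply(seq_len(nrow(lure_trials)), function(i) {
    tr <- lure_trials[i, ]
    enc <- encoding_pattern(store, tr$subject, paste0(tr$set, "_old"), variant)
    tst <- get_pattern(store, tr$subject, "test", tr$run, tr$stimulus)
    rz <- .fisher_r(enc, tst)
    data.frame(subject = tr$subject, delay = tr$delay, set = tr$set,
               emotion = tr$emotion, lure_type = lure_type, roi = roi,
               r = rz[["r"]], z = rz[["z"]], valid = is.finite(rz[["z"]]))
  })
  out <- do.call(rbind, rows)
  n_bad <- sum(!out$valid)
  if (n_bad > 0)
    warning("compute_gist_reinstatement: ", n_bad,
            " record(s) with undefined or infinite z")
  rownames(out) <- NULL
  out
}
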