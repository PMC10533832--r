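#' Build a representational similarity matrix for one emotion category
#'
#' Correlates (Pearson's r) every test-phase activation pattern of the given
#' emotion with every other, yielding an n x n symmetric RSM with trials
#' ordered by item type (old, semantic, perceptual, unrelated) and then by
#' stimulus-set id. The diagonal is set to NA and is excluded from all
#' downstream statistics. Zero-variance pattern vectors make their pairs
#' undefined; those trials are flagged and their cells set to NA.
#'
#' @param store A [pattern_store()] (one subject).
#' @param emotion "neutral" or "negative".
#' @param phase Phase to use, default "test".
#' @return An object of class `rsm`: list(mat, meta, emotion).
#' @export
build_rsm <- function(store, emotion, phase = "test") {
  stopifnot(inherits(store, "pattern_store"))
  sub <- subset_store(store, phase = phase, emotion = emotion)
  if (length(unique(sub$meta$subject)) != 1L)
    stop("build_rsm: store must contain exactly one subject", call. = FALSE)
  if (ncol(sub$patterns) < 2)
    stop("build_rsm: need at least 2 voxels", call. = FALSE)
  ord <- order(match(sub$meta$item_type, .item_types), sub$meta$set)
  meta <- sub$meta[ord, , drop = FALSE]
  pats <- sub$patterns[ord, , drop = FALSE]
  sds <- apply(pats, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  mat <- suppressWarnings(stats::cor(t(pats)))
  mat[degenerate, ] <- NA_real_
  mat[, degenerate] <- NA_real_
  diag(mat) <- NA_real_
  dimnames(mat) <- list(meta$stimulus, meta$stimulus)
  rownames(meta) <- NULL
  structure(list(mat = mat, meta = meta, emotion = emotion,
                 flagged = meta$stimulus[degenerate]),
            class = "rsm")
}

#' @export
print.rsm <- function(x, ...) {
  cat("rsm:", nrow(x$mat), "x", ncol(x$mat), "trials, emotion:", x$emotion,
      if (isTRUE(attr(x, "run_bias_corrected"))) "(run-bias corrected)", "\n")
  invisible(x)
}

#' Correct run-proximity bias in an RSM
#'
#' Pattern correlations are inflated for trial pairs close in time (same
#' scanner run). For each unordered run combination (within-run pairs and
#' every between-run pair) the mean similarity over the off-diagonal cells
#' of that combination is computed and subtracted from each of its cells,
#' so per-combination cell means of the corrected matrix are zero. The
#' operation is idempotent. A combination with no off-diagonal pairs is
#' skipped with a warning.
#'
#' @param rsm An [build_rsm()] result.
#' @return The corrected `rsm`, with attribute `run_bias_corrected = TRUE`
#'   and the subtracted per-combination means in `run_combination_means`.
#' @export
correct_run_bias <- function(rsm) {
  stopifnot(inherits(rsm, "rsm"))
  runs <- rsm$meta$run
  n <- nrow(rsm$mat)
  combo <- outer(runs, runs, function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "-"))
  off <- upper.tri(combo) | lower.tri(combo)
  mat <- rsm$mat
  means <- list()
  for (cb in sort(unique(combo[off]))) {
    cells <- combo == cb & off
    vals <- mat[cells]
    if (all(is.na(vals))) {
      warning("correct_run_bias: run combination ", cb,
              " has no valid off-diagonal pairs; skipped")
      next
    }
    m <- mean(vals, na.rm = TRUE)
    mat[cells] <- mat[cells] - m
    means[[cb]] <- m
  }
  rsm$mat <- mat
  attr(rsm, "run_bias_corrected") <- TRUE
  attr(rsm, "run_combination_means") <- unlist(means)
  rsm
}

#' Conceptual model RSM
#'
#' Binary a-priori similarity hypotheses over the four stimulus categories
#' at test:
#' \itemize{
#'   \item model 1 — 'old items are distinct from all lures': 1 for
#'     old-old pairs, 0 elsewhere;
#'   \item model 2 — 'old and semantically related items are similar': 1
#'     within the old + semantic-lure block, 0 elsewhere;
#'   \item model 3 — 'old and perceptually related items are similar': 1
#'     within the old + perceptual-lure block, 0 elsewhere.
#' }
#' The "similar" cluster is treated as a full block (including lure-lure
#' pairs), the standard categorical model-RSM convention; set
#' `lure_lure = FALSE` to restrict model 2/3 similarity to old-lure pairs
#' only.
#'
#' @param model_id 1, 2 or 3.
#' @param meta Trial metadata with `item_type`, in RSM row order.
#' @param lure_lure Include lure-lure pairs of the similar cluster
#'   (default TRUE).
#' @return An object of class `model_rsm`: list(mat, model_id, meta).
#' @export
model_rsm <- function(model_id, meta, lure_lure = TRUE) {
  if (!model_id %in% 1:3)
    stop("model_rsm: model_id must be 1, 2 or 3", call. = FALSE)
  it <- meta$item_type
  cluster <- switch(as.character(model_id), "1" = "old",
                    "2" = c("old", "semantic"), "3" = c("old", "perceptual"))
  inc <- it %in% cluster
  mat <- outer(inc, inc, "&")
  if (!lure_lure && model_id > 1) {
    lure <- it %in% setdiff(cluster, "old")
    mat[outer(lure, lure, "&")] <- FALSE
  }
  mat <- mat * 1
  diag(mat) <- NA_real_
  dimnames(mat) <- list(meta$stimulus, meta$stimulus)
  structure(list(mat = mat, model_id = model_id, meta = meta),
            class = "model_rsm")
}

#' Fit conceptual models to a neural RSM
#'
#' Spearman rank correlation between the neural RSM and each model RSM over
#' the lower-triangle off-diagonal cells (ties get average ranks), followed
#' by the Fisher z transformation (atanh). Cells that are NA in the neural
#' matrix (flagged trials) are excluded pairwise.
#'
#' @param rsm A (typically run-bias corrected) [build_rsm()] result.
#' @param models List of [model_rsm()] objects (default: models 1-3 built
#'   from the RSM's own metadata).
#' @return Data frame of class `model_fit`: model, rho, z, n_cells, emotion.
#' @export
fit_models <- function(rsm, models = NULL) {
  stopifnot(inherits(rsm, "rsm"))
  if (is.null(models))
    models <- lapply(1:3, model_rsm, meta = rsm$meta)
  lt <- lower.tri(rsm$mat)
  neural <- rsm$mat[lt]
  out <- do.call(rbind, lapply(models, function(m) {
    if (!identical(m$meta$stimulus, rsm$meta$stimulus))
      stop("fit_models: model and neural RSM trial orderings differ",
           call. = FALSE)
    mv <- m$mat[lt]
    ok <- !is.na(neural) & !is.na(mv)
    if (stats::sd(mv[ok]) == 0 || stats::sd(neural[ok]) == 0)
      stop("fit_models: constant model or neural values; rho undefined",
           call. = FALSE)
    rho <- stats::cor(neural[ok], mv[ok], method = "spearman")
    data.frame(model = m$model_id, rho = rho, z = atanh(rho),
               n_cells = sum(ok))
  }))
  out$emotion <- rsm$emotion
  class(out) <- c("model_fit", class(out))
  out
}

#' Model fits for every subject and emotion in a store
#'
#' Convenience wrapper running [build_rsm()], [correct_run_bias()] and
#' [fit_models()] per subject x emotion, producing the table the RSA group
#' ANOVAs consume.
#'
#' @param store A multi-subject [pattern_store()].
#' @param models Model ids to fit (default 1:3).
#' @param correct Apply run-proximity bias correction (default TRUE).
#' @return Data frame: subject, delay, emotion, model, rho, z.
#' @export
fit_models_all <- function(store, models = 1:3, correct = TRUE) {
  stopifnot(inherits(store, "pattern_store"))
  subjects <- unique(store$meta$subject)
  emotions <- intersect(.emotions, unique(store$meta$emotion))
  rows <- list()
  for (s in subjects) {
    ss <- subset_store(store, subject = s)
    delay <- ss$meta$delay[1]
    for (e in emotions) {
      r <- build_rsm(ss, emotion = e)
      if (correct) r <- correct_run_bias(r)
      f <- fit_models(r, lapply(models, model_rsm, meta = r$meta))
      rows[[paste(s, e)]] <- data.frame(subject = s, delay = delay,
                                        emotion = e, model = f$model,
                                        rho = f$rho, z = f$z)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
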