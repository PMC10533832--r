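# Canonical factor levels used throughout the package.
.item_types <- c("old", "semantic", "perceptual", "unrelated")
.lure_types <- c("semantic", "perceptual", "unrelated")
.responses  <- c("definitely_new", "rather_new", "rather_old", "definitely_old",
                 "missing")
.emotions   <- c("neutral", "negative")
.delays     <- c("1d", "28d")

#' Design configuration for the synthetic study
#'
#' Describes a two-group (1d vs. 28d retention delay) delayed-recognition
#' design: each subject encodes `n_sets_per_emotion` stimulus sets per emotion
#' category (neutral, negative), each set consisting of one studied picture
#' and three lures (semantically related, perceptually related, unrelated).
#' Every old item appears once in each encoding run; all four items of every
#' set appear exactly once across the test runs.
#'
#' @param n_subjects_per_group Subjects per delay group (study value 26).
#' @param n_sets_per_emotion Stimulus sets per emotion category (study value 30).
#' @param n_encoding_runs Number of encoding runs (study value 3).
#' @param n_test_runs Number of recognition-test runs (study value 3).
#' @param n_voxels Voxels in the simulated region of interest.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_subjects_per_group = 26L,
                          n_sets_per_emotion = 30L,
                          n_encoding_runs = 3L,
                          n_test_runs = 3L,
                          n_voxels = 200L,
                          seed = 1L) {
  counts <- c(n_subjects_per_group = n_subjects_per_group,
              n_sets_per_emotion = n_sets_per_emotion,
              n_encoding_runs = n_encoding_runs,
              n_test_runs = n_test_runs,
              n_voxels = n_voxels)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("design_config: all counts must be integers >= 1", call. = FALSE)
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_sets_per_emotion = as.integer(n_sets_per_emotion),
                 n_encoding_runs = as.integer(n_encoding_runs),
                 n_test_runs = as.integer(n_test_runs),
                 n_voxels = as.integer(n_voxels),
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Behavioral response-probability parameters
#'
#' `p_endorse` is a data frame with columns `delay`, `emotion`, `item_type`
#' and `p` giving, per cell, the probability that an item is endorsed as
#' 'old' (pooling both confidence levels). `p_confident` has the same keys
#' with column `p` giving the probability that a response (old or new) is
#' given with high confidence ('definitely'). `p_miss` is the probability of
#' a missing response on any trial.
#'
#' The defaults emulate the published group-level pattern: near-ceiling hits
#' after 1 day dropping by 28 days (more so for neutral items), and a
#' delay-dependent rise in false alarms that is largest for semantically
#' related lures and amplified for negative material.
#'
#' @param p_endorse Data frame (delay, emotion, item_type, p) or NULL for
#'   defaults.
#' @param p_confident Same shape, probability of a 'definitely' response.
#' @param p_miss Probability of a missing response.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_endorse = NULL, p_confident = NULL,
                            p_miss = 0.0095) {
  if (is.null(p_endorse)) p_endorse <- default_endorsement()
  req <- c("delay", "emotion", "item_type", "p")
  if (!all(req %in% names(p_endorse)))
    stop("p_endorse needs columns delay, emotion, item_type, p", call. = FALSE)
  if (is.null(p_confident)) {
    p_confident <- p_endorse
    p_confident$p <- 0.5
  }
  probs <- c(p_endorse$p, p_confident$p, p_miss)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("behavior_params: probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(p_endorse = p_endorse, p_confident = p_confident,
                 p_miss = p_miss),
            class = "behavior_params")
}

#' Default endorsement probabilities
#'
#' The stated world behind the generator: one 'old'-endorsement probability
#' per delay x emotion x item type, chosen to reproduce the published
#' qualitative and approximate quantitative pattern (hit means near 92% at
#' 1d and 70/81% neutral/negative at 28d; a 28d false-alarm mix dominated by
#' semantic lures).
#'
#' @return Data frame with columns delay, emotion, item_type, p.
#' @export
default_endorsement <- function() {
  g <- expand.grid(delay = .delays, emotion = .emotions,
                   item_type = .item_types,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- c(
    old_1d_neutral = 0.92,  old_28d_neutral = 0.70,
    old_1d_negative = 0.92, old_28d_negative = 0.81,
    semantic_1d_neutral = 0.12,  semantic_28d_neutral = 0.22,
    semantic_1d_negative = 0.14, semantic_28d_negative = 0.34,
    perceptual_1d_neutral = 0.08,  perceptual_28d_neutral = 0.12,
    perceptual_1d_negative = 0.08, perceptual_28d_negative = 0.12,
    unrelated_1d_neutral = 0.04,  unrelated_28d_neutral = 0.10,
    unrelated_1d_negative = 0.04, unrelated_28d_negative = 0.10)
  g$p <- p[paste(g$item_type, g$delay, g$emotion, sep = "_")]
  rownames(g) <- NULL
  g
}

#' Voxel-pattern composition parameters
#'
#' Every simulated activation pattern is a weighted sum of independent
#' unit-variance voxel vectors: an item-specific component, components shared
#' between an old item and its semantic or perceptual lure (the gist the
#' conceptual models probe), a component common to all old items at test
#' (recognition signal), an additive run-level offset (the artifact the
#' run-proximity bias correction removes) and i.i.d. Gaussian noise. The
#' encoding pattern of an item carries its test-signal components scaled by
#' `w_reinstate`, which is what encoding-retrieval similarity detects.
#'
#' @param sd_noise Noise standard deviation per voxel.
#' @param w_item Weight of the item-specific component.
#' @param w_semantic Weight shared between an old item and its semantic lure.
#' @param w_perceptual Weight shared between an old item and its perceptual lure.
#' @param w_old_common Weight shared among all old items at test.
#' @param run_offset_sd SD of the additive common vector per run.
#' @param w_reinstate Coupling between an item's encoding and test patterns.
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(sd_noise = 1, w_item = 1, w_semantic = 0.5,
                           w_perceptual = 0.5, w_old_common = 0.5,
                           run_offset_sd = 0.5, w_reinstate = 0.5) {
  w <- c(sd_noise, w_item, w_semantic, w_perceptual, w_old_common,
         run_offset_sd, w_reinstate)
  if (any(!is.finite(w)) || any(w < 0))
    stop("pattern_params: all weights must be finite and >= 0", call. = FALSE)
  structure(list(sd_noise = sd_noise, w_item = w_item, w_semantic = w_semantic,
                 w_perceptual = w_perceptual, w_old_common = w_old_common,
                 run_offset_sd = run_offset_sd, w_reinstate = w_reinstate),
            class = "pattern_params")
}

#' Relatedness-rating parameters
#'
#' Mean 0-10 rating per lure type x dimension; defaults are the published
#' group means (semantic dimension: semantic 9.20, perceptual 2.30, unrelated
#' 1.72; perceptual dimension: 5.50, 6.09, 1.74). Ratings are drawn from a
#' normal around the mean, truncated to [0, 10] and rounded to integers.
#'
#' @param means Data frame (lure_type, dimension, mean) or NULL for defaults.
#' @param sd Latent rating SD before truncation/rounding.
#' @return An object of class `rating_params`.
#' @export
rating_params <- function(means = NULL, sd = 1.5) {
  if (is.null(means)) {
    means <- expand.grid(lure_type = .lure_types,
                         dimension = c("semantic", "perceptual"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    m <- c(semantic_semantic = 9.20, perceptual_semantic = 2.30,
           unrelated_semantic = 1.72,
           semantic_perceptual = 5.50, perceptual_perceptual = 6.09,
           unrelated_perceptual = 1.74)
    means$mean <- m[paste(means$lure_type, means$dimension, sep = "_")]
  }
  if (!all(c("lure_type", "dimension", "mean") %in% names(means)))
    stop("rating means need columns lure_type, dimension, mean", call. = FALSE)
  if (any(means$mean < 0 | means$mean > 10))
    stop("rating means must lie in [0, 10]", call. = FALSE)
  if (sd < 0) stop("rating sd must be >= 0", call. = FALSE)
  rownames(means) <- NULL
  structure(list(means = means, sd = sd), class = "rating_params")
}

#' Generate encoding and test trial tables
#'
#' Builds per-subject trial tables for the two delay groups. Encoding: every
#' old item once per encoding run, order randomized within run. Test: all
#' four items of every stimulus set (old, semantic, perceptual, unrelated)
#' exactly once, randomly assigned to test runs with per-run counts balanced
#' within one trial, order randomized within run.
#'
#' @param config A [design_config()].
#' @return A list of class `msm_design` with data frames `encoding` and
#'   `test` (columns: subject, delay, run, trial, set, stimulus, item_type,
#'   emotion) and the config as attribute.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  set.seed(config$seed)
  n_items <- 2L * config$n_sets_per_emotion
  sets <- c(sprintf("neu%02d", seq_len(config$n_sets_per_emotion)),
            sprintf("neg%02d", seq_len(config$n_sets_per_emotion)))
  emo  <- rep(.emotions, each = config$n_sets_per_emotion)
  subjects <- sprintf("sub%03d", seq_len(2L * config$n_subjects_per_group))
  delay <- rep(.delays, each = config$n_subjects_per_group)

  enc_list <- vector("list", length(subjects))
  test_list <- vector("list", length(subjects))
  n_test <- 4L * n_items
  for (i in seq_along(subjects)) {
    # encoding: each item once per run, shuffled within run
    enc <- do.call(rbind, lapply(seq_len(config$n_encoding_runs), function(r) {
      ord <- sample.int(n_items)
      data.frame(subject = subjects[i], delay = delay[i], run = r,
                 trial = seq_len(n_items), set = sets[ord],
                 stimulus = paste0(sets[ord], "_old"),
                 item_type = "old", emotion = emo[ord],
                 stringsAsFactors = FALSE)
    }))
    # test: balanced random run assignment of the 4 x n_items trials
    base_runs <- rep(seq_len(config$n_test_runs),
                     length.out = n_test)
    runs <- sample(base_runs)
    tt <- data.frame(subject = subjects[i], delay = delay[i], run = runs,
                     set = rep(sets, times = 4L),
                     item_type = rep(.item_types, each = n_items),
                     emotion = rep(emo, times = 4L),
                     stringsAsFactors = FALSE)
    tt$stimulus <- paste0(tt$set, "_", tt$item_type)
    tt <- tt[order(tt$run, sample.int(nrow(tt))), ]
    tt$trial <- stats::ave(seq_len(nrow(tt)), tt$run, FUN = seq_along)
    rownames(tt) <- NULL
    enc_list[[i]] <- enc
    test_list[[i]] <- tt[, c("subject", "delay", "run", "trial", "set",
                             "stimulus", "item_type", "emotion")]
  }
  out <- list(encoding = do.call(rbind, enc_list),
              test = do.call(rbind, test_list))
  rownames(out$encoding) <- rownames(out$test) <- NULL
  attr(out, "config") <- config
  class(out) <- "msm_design"
  out
}

#' @export
print.msm_design <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("msm_design:", length(unique(x$test$subject)), "subjects,",
      cfg$n_sets_per_emotion, "sets/emotion,",
      nrow(x$encoding), "encoding +", nrow(x$test), "test trials\n")
  invisible(x)
}

#' Simulate recognition responses
#'
#' Draws, independently per test trial, a response on the four-point scale
#' ('definitely new', 'rather new', 'rather old', 'definitely old') or
#' 'missing'. The probability of an 'old' endorsement comes from
#' `params$p_endorse` for the trial's delay x emotion x item type; the split
#' between 'rather' and 'definitely' from `params$p_confident`. Response
#' times are drawn lognormal (median ~1.3 s) as plumbing for the
#' response-time control analyses.
#'
#' @param design A `msm_design`.
#' @param params A [behavior_params()].
#' @param seed Integer seed.
#' @return The test table with columns `response` and `rt` added
#'   (a `ResponseTable`).
#' @export
simulate_responses <- function(design, params = behavior_params(), seed = 1L) {
  stopifnot(inherits(design, "msm_design"), inherits(params, "behavior_params"))
  set.seed(seed)
  tt <- design$test
  key <- paste(tt$delay, tt$emotion, tt$item_type)
  pe <- params$p_endorse
  pc <- params$p_confident
  pe_map <- stats::setNames(pe$p, paste(pe$delay, pe$emotion, pe$item_type))
  pc_map <- stats::setNames(pc$p, paste(pc$delay, pc$emotion, pc$item_type))
  if (any(!key %in% names(pe_map)))
    stop("simulate_responses: p_endorse is missing keys: ",
         paste(unique(key[!key %in% names(pe_map)]), collapse = ", "),
         call. = FALSE)
  n <- nrow(tt)
  old <- stats::runif(n) < pe_map[key]
  conf <- stats::runif(n) < pc_map[key]
  resp <- ifelse(old,
                 ifelse(conf, "definitely_old", "rather_old"),
                 ifelse(conf, "definitely_new", "rather_new"))
  resp[stats::runif(n) < params$p_miss] <- "missing"
  tt$response <- resp
  tt$rt <- round(stats::rlnorm(n, meanlog = log(1.3), sdlog = 0.35), 3)
  tt$rt[tt$response == "missing"] <- NA_real_
  tt
}

#' Simulate voxel-pattern stores
#'
#' Generates per-trial activation patterns for every subject in the design
#' according to the shared-component model described in [pattern_params()].
#' All latent component vectors are drawn independently per subject; run
#' offsets are drawn independently per subject x phase x run.
#'
#' @param design A `msm_design`.
#' @param params A [pattern_params()].
#' @param seed Integer seed.
#' @return A [pattern_store] containing encoding- and test-phase patterns.
#' @export
simulate_patterns <- function(design, params = pattern_params(), seed = 1L) {
  stopifnot(inherits(design, "msm_design"), inherits(params, "pattern_params"))
  cfg <- attr(design, "config")
  v <- cfg$n_voxels
  if (v < 10) stop("simulate_patterns: n_voxels must be >= 10", call. = FALSE)
  set.seed(seed)
  enc <- design$encoding
  tt <- design$test
  subjects <- unique(tt$subject)
  metas <- vector("list", length(subjects))
  mats <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    te <- enc[enc$subject == s, ]
    tx <- tt[tt$subject == s, ]
    stims <- unique(tx$stimulus)
    sets <- unique(tx$set)
    u_item <- matrix(stats::rnorm(length(stims) * v), nrow = length(stims),
                     dimnames = list(stims, NULL))
    u_sem  <- matrix(stats::rnorm(length(sets) * v), nrow = length(sets),
                     dimnames = list(sets, NULL))
    u_perc <- matrix(stats::rnorm(length(sets) * v), nrow = length(sets),
                     dimnames = list(sets, NULL))
    u_old  <- stats::rnorm(v)
    enc_runs <- sort(unique(te$run))
    test_runs <- sort(unique(tx$run))
    off_enc <- matrix(stats::rnorm(length(enc_runs) * v),
                      nrow = length(enc_runs),
                      dimnames = list(enc_runs, NULL))
    off_test <- matrix(stats::rnorm(length(test_runs) * v),
                       nrow = length(test_runs),
                       dimnames = list(test_runs, NULL))

    # Encoding signal: the item's reinstatable trace (item + gist components),
    # scaled by the encoding-test coupling; the old-common component is a
    # test-phase recognition signal and does not appear at encoding.
    trace <- params$w_item * u_item[te$stimulus, , drop = FALSE] +
      params$w_semantic * u_sem[te$set, , drop = FALSE] +
      params$w_perceptual * u_perc[te$set, , drop = FALSE]
    pat_e <- params$w_reinstate * trace +
      params$run_offset_sd * off_enc[as.character(te$run), , drop = FALSE] +
      matrix(stats::rnorm(nrow(te) * v, sd = params$sd_noise), nrow(te), v)

    pat_t <- params$w_item * u_item[tx$stimulus, , drop = FALSE]
    m_sem <- tx$item_type %in% c("old", "semantic")
    m_perc <- tx$item_type %in% c("old", "perceptual")
    m_old <- tx$item_type == "old"
    pat_t[m_sem, ] <- pat_t[m_sem, ] +
      params$w_semantic * u_sem[tx$set[m_sem], , drop = FALSE]
    pat_t[m_perc, ] <- pat_t[m_perc, ] +
      params$w_perceptual * u_perc[tx$set[m_perc], , drop = FALSE]
    pat_t[m_old, ] <- pat_t[m_old, ] +
      rep(params$w_old_common * u_old, each = sum(m_old))
    pat_t <- pat_t +
      params$run_offset_sd * off_test[as.character(tx$run), , drop = FALSE] +
      matrix(stats::rnorm(nrow(tx) * v, sd = params$sd_noise), nrow(tx), v)
    meta <- rbind(cbind(te[, c("subject", "delay", "run", "set", "stimulus",
                               "item_type", "emotion")], phase = "encoding"),
                  cbind(tx[, c("subject", "delay", "run", "set", "stimulus",
                               "item_type", "emotion")], phase = "test"))
    metas[[si]] <- meta
    mats[[si]] <- rbind(pat_e, pat_t)
  }
  pattern_store(do.call(rbind, mats), do.call(rbind, metas))
}

#' Simulate Day-3 relatedness ratings
#'
#' For every subject, stimulus set and lure type, draws integer ratings of
#' semantic and perceptual relatedness between the lure and its old item on
#' the 0 ('not related') to 10 ('very related') scale: truncated normal
#' around the configured mean, rounded.
#'
#' @param design A `msm_design`.
#' @param params A [rating_params()].
#' @param seed Integer seed.
#' @return Data frame: subject, delay, set, emotion, lure_type, dimension,
#'   rating.
#' @export
simulate_relatedness <- function(design, params = rating_params(), seed = 1L) {
  stopifnot(inherits(design, "msm_design"), inherits(params, "rating_params"))
  set.seed(seed)
  tt <- unique(design$test[design$test$item_type != "old",
                           c("subject", "delay", "set", "emotion", "item_type")])
  out <- merge(cbind(tt, dummy = 1),
               cbind(data.frame(dimension = c("semantic", "perceptual")),
                     dummy = 1), by = "dummy")
  out$dummy <- NULL
  names(out)[names(out) == "item_type"] <- "lure_type"
  m <- params$means
  mu <- stats::setNames(m$mean, paste(m$lure_type, m$dimension))
  out_mu <- mu[paste(out$lure_type, out$dimension)]
  raw <- stats::rnorm(nrow(out), mean = out_mu, sd = params$sd)
  out$rating <- as.integer(round(pmin(10, pmax(0, raw))))
  out <- out[order(out$subject, out$set, out$lure_type, out$dimension), ]
  rownames(out) <- NULL
  out
}

#' Simulate patterns with delay-group-specific parameters
#'
#' The study's premise is that representational structure differs between
#' the 1d and 28d groups (e.g. elevated semantic-gist sharing after 28 days).
#' This wrapper simulates each delay group's subjects under its own
#' [pattern_params()] and combines the results.
#'
#' @param design A `msm_design`.
#' @param params_1d,params_28d [pattern_params()] for each delay group.
#' @param seed Integer seed (the 28d group uses `seed + 1`).
#' @return A combined [pattern_store()].
#' @export
simulate_patterns_grouped <- function(design, params_1d, params_28d,
                                      seed = 1L) {
  stopifnot(inherits(design, "msm_design"))
  split_design <- function(d) {
    out <- list(encoding = design$encoding[design$encoding$delay == d, ],
                test = design$test[design$test$delay == d, ])
    attr(out, "config") <- attr(design, "config")
    class(out) <- "msm_design"
    out
  }
  combine_stores(
    simulate_patterns(split_design("1d"), params_1d, seed = seed),
    simulate_patterns(split_design("28d"), params_28d, seed = seed + 1L))
}

#' Combine pattern stores over disjoint trials
#'
#' @param ... [pattern_store()] objects with identical voxel counts.
#' @return A single combined `pattern_store`.
#' @export
combine_stores <- function(...) {
  stores <- list(...)
  stopifnot(all(vapply(stores, inherits, TRUE, "pattern_store")))
  nv <- vapply(stores, function(s) ncol(s$patterns), 1L)
  if (length(unique(nv)) != 1)
    stop("combine_stores: voxel counts differ", call. = FALSE)
  metas <- lapply(stores, `[[`, "meta")
  cols <- Reduce(intersect, lapply(metas, names))
  pattern_store(do.call(rbind, lapply(stores, `[[`, "patterns")),
                do.call(rbind, lapply(metas, `[`, cols)))
}
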