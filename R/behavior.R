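#' Collapse a four-point recognition response to old/new/missing
#'
#' 'rather old' and 'definitely old' count as an 'old' endorsement; the two
#' 'new' levels as 'new'. The primary hit/false-alarm analyses are binary,
#' with confidence entering only through [weight_by_confidence()].
#'
#' @param response Character vector of responses
#'   (definitely_new/rather_new/rather_old/definitely_old/missing).
#' @return Character vector in {old, new, missing}.
#' @export
collapse_response <- function(response) {
  out <- rep(NA_character_, length(response))
  out[response %in% c("rather_old", "definitely_old")] <- "old"
  out[response %in% c("rather_new", "definitely_new")] <- "new"
  out[response == "missing"] <- "missing"
  if (anyNA(out))
    stop("collapse_response: unknown response level(s): ",
         paste(unique(response[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

.check_responses <- function(responses) {
  req <- c("subject", "delay", "emotion", "item_type", "set", "response")
  if (!all(req %in% names(responses)))
    stop("ResponseTable needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  invisible(responses)
}

#' Score recognition performance
#'
#' Hit rate per subject x emotion (percentage of old items endorsed 'old')
#' and false-alarm rate per subject x emotion x lure type. Missing responses
#' are excluded from the denominators; a cell with no valid trials gets an
#' NA rate and is listed in the `flagged` attribute.
#'
#' @param responses A response table (see [simulate_responses()]).
#' @return List of class `recognition_summary` with data frames `hits`
#'   (subject, delay, emotion, n_valid, hit_rate) and `false_alarms`
#'   (subject, delay, emotion, lure_type, n_valid, fa_rate), rates in
#'   percent.
#' @export
score_recognition <- function(responses) {
  .check_responses(responses)
  responses$coll <- collapse_response(responses$response)
  rate_cell <- function(d) {
    valid <- d$coll != "missing"
    n <- sum(valid)
    data.frame(n_valid = n,
               rate = if (n == 0) NA_real_ else 100 * sum(d$coll[valid] == "old") / n)
  }
  split_rate <- function(d, by) {
    parts <- split(d, d[by], drop = TRUE)
    out <- do.call(rbind, lapply(parts, function(p)
      cbind(p[1, by, drop = FALSE], rate_cell(p))))
    rownames(out) <- NULL
    out[do.call(order, out[by]), , drop = FALSE]
  }
  hits <- split_rate(responses[responses$item_type == "old", ],
                     c("subject", "delay", "emotion"))
  names(hits)[names(hits) == "rate"] <- "hit_rate"
  fas <- responses[responses$item_type != "old", ]
  fas$lure_type <- fas$item_type
  fas <- split_rate(fas, c("subject", "delay", "emotion", "lure_type"))
  names(fas)[names(fas) == "rate"] <- "fa_rate"
  flagged <- rbind(
    if (any(is.na(hits$hit_rate))) hits[is.na(hits$hit_rate), 1:3],
    if (any(is.na(fas$fa_rate))) fas[is.na(fas$fa_rate), 1:4])
  out <- list(hits = hits, false_alarms = fas)
  attr(out, "flagged") <- flagged
  class(out) <- "recognition_summary"
  out
}

#' @export
print.recognition_summary <- function(x, ...) {
  cat("recognition_summary:", nrow(x$hits), "subject x emotion hit cells;",
      nrow(x$false_alarms), "FA cells\n")
  cat("mean hit rate:", round(mean(x$hits$hit_rate, na.rm = TRUE), 2), "%\n")
  invisible(x)
}

#' Confidence-weighted false-alarm scores
#'
#' Each false alarm contributes its confidence weight (1 for 'rather old',
#' 2 for 'definitely old'); the per-cell sum is normalized by the valid
#' trial count and scaled by 100. With exclusively low-confidence
#' endorsements this equals the unweighted FA rate.
#'
#' @param responses A response table.
#' @return Data frame subject, delay, emotion, lure_type, n_valid,
#'   weighted_fa.
#' @export
weight_by_confidence <- function(responses) {
  .check_responses(responses)
  lures <- responses[responses$item_type != "old", ]
  lures$w <- ifelse(lures$response == "rather_old", 1,
                    ifelse(lures$response == "definitely_old", 2, 0))
  lures$valid <- lures$response != "missing"
  by <- c("subject", "delay", "emotion", "item_type")
  parts <- split(lures, lures[by], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    n <- sum(p$valid)
    cbind(p[1, by, drop = FALSE],
          data.frame(n_valid = n,
                     weighted_fa = if (n == 0) NA_real_
                     else 100 * sum(p$w[p$valid]) / n))
  }))
  names(out)[names(out) == "item_type"] <- "lure_type"
  rownames(out) <- NULL
  out[do.call(order, out[c("subject", "delay", "emotion", "lure_type")]), ]
}

#' Classify one stimulus set's memory specificity
#'
#' Applies the four-category rule to the responses given to a set's old
#' item, semantic lure and perceptual lure:
#' \itemize{
#'   \item detailed — old endorsed 'old', both lures rejected;
#'   \item semantically_transformed — semantic lure endorsed, perceptual lure
#'     rejected, irrespective of the response to the old item;
#'   \item perceptually_transformed — perceptual lure endorsed, semantic lure
#'     rejected, irrespective of the response to the old item;
#'   \item forgotten — old missed and both lures rejected;
#'   \item missing — any of the three responses missing;
#'   \item uncategorized — both lures endorsed (no rule applies).
#' }
#' The six labels partition all 8 non-missing response combinations plus the
#' missing cases.
#'
#' @param old_resp,sem_resp,perc_resp Response vectors (four-point scale or
#'   already collapsed old/new/missing), recycled to common length.
#' @return Factor with the six category levels.
#' @export
categorize_set <- function(old_resp, sem_resp, perc_resp) {
  norm <- function(x) ifelse(x %in% c("old", "new", "missing"), x,
                             collapse_response(x))
  o <- norm(old_resp); s <- norm(sem_resp); p <- norm(perc_resp)
  lab <- rep("uncategorized", length(o))
  lab[o == "old" & s == "new" & p == "new"] <- "detailed"
  lab[s == "old" & p == "new"] <- "semantically_transformed"
  lab[p == "old" & s == "new"] <- "perceptually_transformed"
  lab[o == "new" & s == "new" & p == "new"] <- "forgotten"
  lab[o == "missing" | s == "missing" | p == "missing"] <- "missing"
  factor(lab, levels = c("detailed", "semantically_transformed",
                         "perceptually_transformed", "forgotten",
                         "uncategorized", "missing"))
}

#' Per-subject specificity-category counts
#'
#' Classifies every stimulus set with [categorize_set()] and tabulates the
#' six labels per subject x emotion. Counts always sum to the number of sets
#' per emotion.
#'
#' @param responses A response table.
#' @return List with `counts` (wide: subject, delay, emotion, one column per
#'   label) and `sets` (long: one row per subject x set with its label).
#' @export
categorize_all <- function(responses) {
  .check_responses(responses)
  wide <- stats::reshape(
    responses[, c("subject", "delay", "emotion", "set", "item_type", "response")],
    idvar = c("subject", "delay", "emotion", "set"),
    timevar = "item_type", direction = "wide")
  names(wide) <- sub("^response\\.", "", names(wide))
  miss <- setdiff(c("old", "semantic", "perceptual"), names(wide))
  if (length(miss))
    stop("categorize_all: response table lacks item types: ",
         paste(miss, collapse = ", "), call. = FALSE)
  wide$category <- categorize_set(wide$old, wide$semantic, wide$perceptual)
  sets <- wide[, c("subject", "delay", "emotion", "set", "category")]
  sets <- sets[order(sets$subject, sets$set), ]
  rownames(sets) <- NULL
  tab <- as.data.frame.matrix(
    table(interaction(sets$subject, sets$delay, sets$emotion, sep = "\r",
                      drop = TRUE),
          sets$category))
  keyparts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  counts <- data.frame(subject = keyparts[, 1], delay = keyparts[, 2],
                       emotion = keyparts[, 3], tab, row.names = NULL,
                       check.names = FALSE)
  counts <- counts[order(counts$subject, counts$emotion), ]
  rownames(counts) <- NULL
  list(counts = counts, sets = sets)
}

#' Build the model-ready lure-trial feature table
#'
#' Joins the Day-3 relatedness ratings onto the lure trials, codes the binary
#' false-alarm outcome, centers the semantic and perceptual relatedness
#' ratings within subject (group-mean centering, required for unbiased
#' cross-level interaction estimates) and adds the dichotomized perceptual
#' relatedness level (low: rating <= 5, high: > 5). Lure trials with a
#' missing response or missing rating are dropped; the number dropped is
#' recorded in the `dropped` attribute.
#'
#' @param responses A response table.
#' @param ratings Relatedness ratings as from [simulate_relatedness()]
#'   (subject, set, lure_type, dimension, rating).
#' @return Data frame: subject, delay, emotion, set, lure_type, fa (0/1),
#'   sem_rating, perc_rating, sem_centered, perc_centered, perc_level.
#' @export
build_trial_features <- function(responses, ratings) {
  .check_responses(responses)
  lures <- responses[responses$item_type != "old", ]
  lures$lure_type <- lures$item_type
  wide_r <- stats::reshape(
    ratings[, c("subject", "set", "lure_type", "dimension", "rating")],
    idvar = c("subject", "set", "lure_type"), timevar = "dimension",
    direction = "wide")
  names(wide_r) <- sub("^rating\\.semantic$", "sem_rating",
                       sub("^rating\\.perceptual$", "perc_rating",
                           names(wide_r)))
  out <- merge(lures[, c("subject", "delay", "emotion", "set", "lure_type",
                         "response")],
               wide_r, by = c("subject", "set", "lure_type"), all.x = TRUE)
  n0 <- nrow(out)
  out <- out[out$response != "missing" &
               !is.na(out$sem_rating) & !is.na(out$perc_rating), ]
  dropped <- n0 - nrow(out)
  if (dropped > 0)
    message("build_trial_features: dropped ", dropped,
            " lure trial(s) with missing response or rating")
  out$fa <- as.integer(collapse_response(out$response) == "old")
  out$sem_centered <- out$sem_rating -
    stats::ave(out$sem_rating, out$subject, FUN = mean)
  out$perc_centered <- out$perc_rating -
    stats::ave(out$perc_rating, out$subject, FUN = mean)
  out$perc_level <- factor(ifelse(out$perc_rating <= 5, "low", "high"),
                           levels = c("low", "high"))
  out <- out[order(out$subject, out$set, out$lure_type),
             c("subject", "delay", "emotion", "set", "lure_type", "fa",
               "sem_rating", "perc_rating", "sem_centered", "perc_centered",
               "perc_level")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
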