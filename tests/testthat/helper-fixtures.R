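# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so frozen oracle values stay valid.

tiny_config <- function(seed = 1L, subjects = 2L, sets = 4L, voxels = 40L) {
  design_config(n_subjects_per_group = subjects, n_sets_per_emotion = sets,
                n_voxels = voxels, seed = seed)
}

tiny_design <- function(...) generate_design(tiny_config(...))

# A hand-rolled response table: one subject, one emotion, explicit responses.
manual_responses <- function(subject = "s1", delay = "1d",
                             emotion = "neutral", old, sem, perc,
                             unrel = NULL) {
  n <- length(old)
  if (is.null(unrel)) unrel <- rep("definitely_new", n)
  data.frame(
    subject = subject, delay = delay, emotion = emotion,
    set = rep(sprintf("set%02d", seq_len(n)), 4),
    item_type = rep(c("old", "semantic", "perceptual", "unrelated"), each = n),
    response = c(old, sem, perc, unrel),
    stringsAsFactors = FALSE)
}

# Deterministic dataset for the ANOVA oracle cross-checks. The same code
# (same seed) generated the values frozen from the pingouin reference run.
anova_fixture_mixed <- function() {
  set.seed(42)
  n <- 10
  df <- expand.grid(subject = sprintf("s%02d", 1:(2 * n)),
                    emotion = c("neutral", "negative"),
                    lure = c("sem", "perc", "unrel"),
                    stringsAsFactors = FALSE)
  df$delay <- ifelse(as.integer(sub("s", "", df$subject)) <= n, "1d", "28d")
  df$y <- rnorm(nrow(df)) + 0.5 * (df$lure == "sem") +
    0.3 * (df$delay == "28d") +
    0.4 * (df$lure == "sem") * (df$delay == "28d") +
    0.2 * (df$emotion == "negative")
  df$y <- df$y + rep(rnorm(2 * n), times = 6) *
    ifelse(df$lure == "sem", 1.5, 0.5)
  df
}

anova_fixture_within <- function() {
  set.seed(9)
  n <- 12
  df <- expand.grid(subject = sprintf("s%02d", 1:n), lure = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df)) +
    rep(rnorm(n), 3) * ifelse(df$lure == "a", 1.6, 0.4)
  df
}
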