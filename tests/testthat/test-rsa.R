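# A minimal single-subject store with hand-chosen patterns.
hand_store <- function(pats, item_type, set, run = rep(1, nrow(pats)),
                       emotion = "neutral") {
  meta <- data.frame(subject = "s1", delay = "1d", phase = "test", run = run,
                     set = set, item_type = item_type,
                     stimulus = paste0(set, "_", item_type),
                     emotion = emotion, stringsAsFactors = FALSE)
  pattern_store(pats, meta)
}

test_that("build_rsm reproduces hand-computed Pearson correlations", {
  pats <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1), c(1, 0, 2))
  st <- hand_store(pats, item_type = c("old", "semantic", "perceptual",
                                       "unrelated"),
                   set = c("a", "a", "a", "a"))
  r <- build_rsm(st, "neutral")
  # identical up to scaling -> r = 1; reversal -> r = -1
  expect_equal(r$mat["a_old", "a_semantic"], 1)
  expect_equal(r$mat["a_old", "a_perceptual"], -1)
  # closed-form Pearson for the remaining pairs
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  expect_equal(r$mat["a_old", "a_unrelated"], pearson(c(1, 2, 3), c(1, 0, 2)))
  expect_equal(r$mat["a_perceptual", "a_unrelated"],
               pearson(c(3, 2, 1), c(1, 0, 2)))
  # symmetry, NA diagonal, ordering by item type
  expect_true(isSymmetric(unname(r$mat)))
  expect_true(all(is.na(diag(r$mat))))
  expect_equal(r$meta$item_type, c("old", "semantic", "perceptual",
                                   "unrelated"))
  # zero-variance vector flagged, its pairs NA
  st2 <- hand_store(rbind(c(1, 2, 3), c(5, 5, 5), c(0, 1, 0)),
                    item_type = c("old", "semantic", "perceptual"),
                    set = c("a", "a", "a"))
  r2 <- build_rsm(st2, "neutral")
  expect_equal(r2$flagged, "a_semantic")
  expect_true(all(is.na(r2$mat["a_semantic", ])))
  expect_false(is.na(r2$mat["a_old", "a_perceptual"]))
})

test_that("RSM is invariant to per-trial affine rescaling", {
  set.seed(4)
  pats <- matrix(rnorm(5 * 30), 5)
  st <- hand_store(pats, item_type = c("old", "old", "semantic", "perceptual",
                                       "unrelated"),
                   set = c("a", "b", "a", "a", "a"))
  scaled <- pats * c(2, 0.5, 3, 10, 1) + c(1, -2, 0, 5, 3)
  st2 <- hand_store(scaled, item_type = c("old", "old", "semantic",
                                          "perceptual", "unrelated"),
                    set = c("a", "b", "a", "a", "a"))
  expect_equal(build_rsm(st, "neutral")$mat, build_rsm(st2, "neutral")$mat)
})

test_that("run-bias correction zeroes per-combination means and is idempotent", {
  set.seed(8)
  d <- tiny_design(seed = 8, subjects = 1, sets = 6, voxels = 50)
  st <- simulate_patterns(d, pattern_params(run_offset_sd = 2), seed = 9)
  r <- build_rsm(subset_store(st, subject = "sub001"), "neutral")
  runs <- r$meta$run
  combo <- outer(runs, runs, function(a, b) paste(pmin(a, b), pmax(a, b)))
  off <- lower.tri(combo)
  within_between_gap <- function(m) {
    same <- outer(runs, runs, "==")
    mean(m[off & same], na.rm = TRUE) - mean(m[off & !same], na.rm = TRUE)
  }
  expect_gt(within_between_gap(r$mat), 0)   # planted offsets inflate within-run
  rc <- correct_run_bias(r)
  for (cb in unique(combo[off]))
    expect_lt(abs(mean(rc$mat[off & combo == cb])), 1e-12)
  expect_lt(abs(within_between_gap(rc$mat)), 1e-12)
  # idempotence
  rcc <- correct_run_bias(rc)
  expect_equal(rcc$mat, rc$mat, tolerance = 1e-12)
  # constant-combination case: all cells of a combination -> exactly 0
  pats <- rbind(c(1, 2, 3, 1), c(2, 4, 6, 2), c(0, 1, 0, 1), c(1, 1, 0, 0))
  stc <- hand_store(pats, item_type = c("old", "semantic", "perceptual",
                                        "unrelated"),
                    set = rep("a", 4), run = c(1, 1, 2, 2))
  rcst <- correct_run_bias(build_rsm(stc, "neutral"))
  expect_equal(rcst$mat["a_old", "a_semantic"], 0)  # single within-run-1 pair
})

test_that("model RSMs have the prescribed block structure", {
  sets <- sprintf("s%02d", 1:30)
  meta <- data.frame(
    item_type = rep(c("old", "semantic", "perceptual", "unrelated"),
                    each = 30),
    set = rep(sets, 4), stringsAsFactors = FALSE)
  meta$stimulus <- paste0(meta$set, "_", meta$item_type)
  m1 <- model_rsm(1, meta); m2 <- model_rsm(2, meta); m3 <- model_rsm(3, meta)
  ut <- upper.tri(m1$mat)
  expect_equal(sum(m1$mat[ut]), 30 * 29 / 2)        # 435
  expect_equal(sum(m2$mat[ut]), 60 * 59 / 2)        # 1770
  expect_equal(sum(m3$mat[ut]), 60 * 59 / 2)
  # old-unrelated cells are 0 in every model
  for (m in list(m1, m2, m3))
    expect_true(all(m$mat[meta$item_type == "old",
                          meta$item_type == "unrelated"] == 0))
  # without lure-lure cells the semantic block shrinks by choose(30, 2)
  m2b <- model_rsm(2, meta, lure_lure = FALSE)
  expect_equal(sum(m2b$mat[ut]), 435 + 900)
  expect_error(model_rsm(4, meta), "model_id")
})

test_that("fit_models matches a rank-correlation oracle and handles ties", {
  set.seed(15)
  sets <- c("a", "b", "c")
  meta <- data.frame(item_type = rep(c("old", "semantic", "perceptual",
                                       "unrelated"), each = 3),
                     set = rep(sets, 4), stringsAsFactors = FALSE)
  meta$stimulus <- paste0(meta$set, "_", meta$item_type)
  # neural matrix = model 1 matrix + small monotone jitter on distinct values
  m1 <- model_rsm(1, meta)
  neural <- m1$mat
  lt <- lower.tri(neural)
  neural[lt] <- neural[lt] + runif(sum(lt), 0, 0.4)
  neural[upper.tri(neural)] <- t(neural)[upper.tri(neural)]
  rsm <- structure(list(mat = neural, meta = meta, emotion = "neutral"),
                   class = "rsm")
  # oracle: Spearman as Pearson on average ranks (independent route)
  oracle_rho <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  m2 <- model_rsm(2, meta)
  nv <- neural[lt]
  f <- fit_models(rsm, list(m1, m2))
  expect_equal(f$rho[1], oracle_rho(nv, m1$mat[lt]), tolerance = 1e-12)
  expect_equal(f$rho[2], oracle_rho(nv, m2$mat[lt]), tolerance = 1e-12)
  expect_equal(f$z, atanh(f$rho), tolerance = 1e-12)
  # the jittered model-1 structure is recovered as the best-fitting model
  expect_gt(f$rho[1], f$rho[2])
  # rho ~ 0 for iid noise at larger n
  set.seed(16)
  sets2 <- sprintf("s%02d", 1:20)
  meta2 <- data.frame(item_type = rep(c("old", "semantic", "perceptual",
                                        "unrelated"), each = 20),
                      set = rep(sets2, 4), stringsAsFactors = FALSE)
  meta2$stimulus <- paste0(meta2$set, "_", meta2$item_type)
  noise <- matrix(rnorm(80 * 80), 80)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- NA
  rsm2 <- structure(list(mat = noise, meta = meta2, emotion = "neutral"),
                    class = "rsm")
  f3 <- fit_models(rsm2, list(model_rsm(1, meta2)))
  # permutation null SD for point-biserial-style rank correlation ~ 1/sqrt(n)
  expect_lt(abs(f3$rho), 4 / sqrt(sum(lower.tri(noise))))
  # rho = 0 -> z = 0
  expect_equal(atanh(0), 0)
  # constant neural matrix -> error
  cm <- noise; cm[] <- 1; diag(cm) <- NA
  rsm3 <- structure(list(mat = cm, meta = meta2, emotion = "neutral"),
                    class = "rsm")
  expect_error(fit_models(rsm3, list(model_rsm(1, meta2))), "constant")
})

test_that("fit is invariant to simultaneous row/column permutation", {
  set.seed(23)
  d <- tiny_design(seed = 23, subjects = 1, sets = 5, voxels = 40)
  st <- simulate_patterns(d, pattern_params(), seed = 24)
  r <- build_rsm(subset_store(st, subject = "sub001"), "negative")
  f <- fit_models(r)
  perm <- sample(nrow(r$mat))
  rp <- r
  rp$mat <- r$mat[perm, perm]
  rp$meta <- r$meta[perm, ]
  fp <- fit_models(rp, lapply(1:3, model_rsm, meta = rp$meta))
  expect_equal(fp$rho, f$rho, tolerance = 1e-12)
})
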