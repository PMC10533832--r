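#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA for designs with one between-subjects
#' factor (optional) and any number of crossed within-subject factors, one
#' observation per subject x within-cell. Within-subject effects are tested
#' via orthonormal contrast transforms of the subject x cell matrix; for each
#' within effect the Mauchly sphericity test and the Greenhouse-Geisser
#' epsilon are computed from the pooled within-group covariance of the
#' transformed variables, and corrected degrees of freedom and p-values are
#' reported. Partial eta squared is accompanied by a confidence interval
#' from noncentral-F inversion.
#'
#' The `p` column follows the usual reporting convention: Greenhouse-Geisser
#' corrected whenever Mauchly's test is significant at .05 (only possible
#' for effects with more than 1 numerator df), uncorrected otherwise.
#'
#' @param data Long data frame.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject id column.
#' @param between Name of the between-subjects factor column, or NULL.
#' @param within Character vector of within-subject factor columns.
#' @param conf Confidence level for the partial eta squared CI.
#' @return Data frame of class `anova_result`: effect, df1, df2, F,
#'   p_uncorrected, epsilon, df1_gg, df2_gg, p_gg, mauchly_p, gg_applied, p,
#'   eta_p2, eta_p2_lo, eta_p2_hi, ss_effect, ss_error.
#' @export
mixed_anova <- function(data, dv, subject, between = NULL, within,
                        conf = 0.95) {
  for (col in c(dv, subject, between, within))
    if (!col %in% names(data))
      stop("mixed_anova: no column '", col, "'", call. = FALSE)
  if (length(between) > 1)
    stop("mixed_anova: at most one between-subjects factor is supported",
         call. = FALSE)
  data <- as.data.frame(data)
  y <- data[[dv]]
  if (!is.numeric(y) || anyNA(y))
    stop("mixed_anova: dv must be numeric with no missing values",
         call. = FALSE)
  subj <- as.character(data[[subject]])
  wlev <- lapply(within, function(w) {
    v <- data[[w]]
    if (is.factor(v)) levels(droplevels(v)) else sort(unique(as.character(v)))
  })
  names(wlev) <- within
  cells <- do.call(expand.grid,
                   c(wlev, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  row_key <- do.call(paste, c(lapply(within, function(w)
    as.character(data[[w]])), sep = "\r"))
  if (!all(row_key %in% cell_key))
    stop("mixed_anova: inconsistent within-factor levels", call. = FALSE)

  subjects <- unique(subj)
  p <- length(cell_key)
  Y <- matrix(NA_real_, length(subjects), p,
              dimnames = list(subjects, cell_key))
  for (i in seq_len(nrow(data))) {
    if (!is.na(Y[subj[i], row_key[i]]))
      stop("mixed_anova: more than one value for subject ", subj[i],
           " in cell ", gsub("\r", "/", row_key[i]),
           " - aggregate first", call. = FALSE)
    Y[subj[i], row_key[i]] <- y[i]
  }
  if (anyNA(Y)) {
    bad <- which(is.na(Y), arr.ind = TRUE)[1, ]
    stop("mixed_anova: missing cell for subject ", subjects[bad[1]],
         " in cell ", gsub("\r", "/", cell_key[bad[2]]), call. = FALSE)
  }
  if (is.null(between)) {
    g <- factor(rep("all", length(subjects)))
  } else {
    gmap <- unique(data.frame(s = subj, g = as.character(data[[between]])))
    if (anyDuplicated(gmap$s))
      stop("mixed_anova: between factor varies within subject", call. = FALSE)
    g <- factor(gmap$g[match(subjects, gmap$s)])
  }
  N <- length(subjects); G <- nlevels(g)
  if (N - G < 1)
    stop("mixed_anova: no error degrees of freedom", call. = FALSE)

  # orthonormal basis per factor: unit direction and poly contrasts
  unit <- lapply(wlev, function(l) matrix(1 / sqrt(length(l)), length(l), 1))
  ctr <- lapply(wlev, function(l)
    if (length(l) >= 2) stats::contr.poly(length(l)) else NULL)

  gmeans <- apply(Y, 2, function(col) tapply(col, g, mean))
  if (G == 1) gmeans <- matrix(gmeans, nrow = 1)
  res <- list()

  sst_scale <- sum((Y - mean(Y))^2)
  eff_row <- function(effect, sse, dfe, ssh, dfh, Z = NULL) {
    if (sse < 1e-12 * max(sst_scale, 1)) {
      warning("mixed_anova: effect '", effect,
              "' has (near-)zero error variance; F undefined")
      sse <- NaN
    }
    Fv <- (ssh / dfh) / (sse / dfe)
    p_unc <- stats::pf(Fv, dfh, dfe, lower.tail = FALSE)
    eps <- 1; mau <- NA_real_
    if (!is.null(Z) && ncol(Z) >= 2) {
      Gm <- Z - apply(Z, 2, function(col) stats::ave(col, g))
      S <- crossprod(Gm) / (N - G)
      d <- ncol(S)
      eps <- sum(diag(S))^2 / (d * sum(S^2))
      dt <- determinant(S, logarithm = TRUE)
      if (dt$sign > 0 && sum(diag(S)) > 0) {
        logW <- as.numeric(dt$modulus) - d * log(sum(diag(S)) / d)
        f <- (N - G) - (2 * d^2 + d + 2) / (6 * d)
        mau <- stats::pchisq(-f * logW, d * (d + 1) / 2 - 1,
                             lower.tail = FALSE)
      }
    }
    df1g <- eps * dfh; df2g <- eps * dfe
    p_gg <- stats::pf(Fv, df1g, df2g, lower.tail = FALSE)
    applied <- is.finite(mau) && mau < 0.05
    eta <- ssh / (ssh + sse)
    ci <- .eta_ci(Fv, dfh, dfe, conf)
    data.frame(effect = effect, df1 = dfh, df2 = dfe, F = Fv,
               p_uncorrected = p_unc, epsilon = eps, df1_gg = df1g,
               df2_gg = df2g, p_gg = p_gg, mauchly_p = mau,
               gg_applied = applied, p = if (applied) p_gg else p_unc,
               eta_p2 = eta, eta_p2_lo = ci[1], eta_p2_hi = ci[2],
               ss_effect = ssh, ss_error = sse)
  }

  # between-subjects stratum: subject totals projected on the unit direction
  u_all <- Reduce(kronecker, rev(unit))
  z0 <- drop(Y %*% u_all)
  z0g <- tapply(z0, g, mean); z0bar <- mean(z0)
  ng <- as.integer(table(g))
  ss_sub <- sum((z0 - z0g[g])^2)
  if (!is.null(between)) {
    ss_b <- sum(ng * (z0g - z0bar)^2)
    res[[between]] <- eff_row(between, ss_sub, N - G, ss_b, G - 1)
  }

  # within strata: every nonempty subset of within factors
  subsets <- unlist(lapply(seq_along(within), function(k)
    utils::combn(seq_along(within), k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    mats <- lapply(seq_along(within), function(j)
      if (j %in% S) ctr[[j]] else unit[[j]])
    if (any(vapply(mats, is.null, TRUE))) next  # single-level factor in S
    M <- Reduce(kronecker, rev(mats))
    Z <- Y %*% M
    d <- ncol(Z)
    Zg <- apply(Z, 2, function(col) tapply(col, g, mean))
    if (G == 1) Zg <- matrix(Zg, nrow = 1)
    zbar <- colMeans(Z)
    E <- crossprod(Z - apply(Z, 2, function(col) stats::ave(col, g)))
    sse <- sum(diag(as.matrix(E))); dfe <- (N - G) * d
    nameS <- paste(within[S], collapse = ":")
    res[[nameS]] <- eff_row(nameS, sse, dfe, N * sum(zbar^2), d, Z)
    if (!is.null(between)) {
      ssh <- sum(ng * rowSums((Zg - rep(zbar, each = G))^2))
      res[[paste(between, nameS, sep = ":")]] <-
        eff_row(paste(between, nameS, sep = ":"), sse, dfe, ssh,
                (G - 1) * d, Z)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("anova_result", class(out))
  out
}

# CI for partial eta squared by inverting the noncentral-F distribution.
.eta_ci <- function(Fv, df1, df2, conf = 0.95) {
  if (!is.finite(Fv)) return(c(NA_real_, NA_real_))
  a <- (1 - conf) / 2
  bound <- function(target) {
    if (stats::pf(Fv, df1, df2, ncp = 0) < target) return(0)
    hi <- 10
    while (stats::pf(Fv, df1, df2, ncp = hi) > target && hi < 1e7) hi <- hi * 2
    stats::uniroot(function(l) stats::pf(Fv, df1, df2, ncp = l) - target,
                   c(0, hi), tol = 1e-8)$root
  }
  lam <- c(bound(1 - a), bound(a))
  lam / (lam + df1 + df2 + 1)
}

#' Sidak adjustment for multiple comparisons
#'
#' Adjusted p = 1 - (1 - p)^m for a family of m comparisons; monotone in
#' both p and m.
#'
#' @param p Raw p-value(s).
#' @param m Family size (default: number of p-values supplied).
#' @return Adjusted p-value(s), capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("sidak_adjust: m must be >= 1", call. = FALSE)
  pmin(1, 1 - (1 - p)^m)
}

#' Sidak-corrected post-hoc contrasts on cell means
#'
#' Runs a family of planned contrasts on subject-level cell data and applies
#' the Sidak correction over the family. Supported contrast types:
#' \itemize{
#'   \item `paired` — within-subject difference of two cells (optionally in
#'     one group only);
#'   \item `two_sample` — between-group difference of one cell (pooled
#'     variance t);
#'   \item `interaction` — contrast between contrasts: the between-group
#'     difference of a within-subject cell difference.
#' }
#' Cells are addressed as the `sep`-joined levels of the within columns.
#' Cohen's d is the paired difference mean over its SD (paired) or the group
#' difference over the pooled SD (two-sample and interaction).
#'
#' @param data Long data frame (one value per subject x cell).
#' @param dv,subject,between,within As in [mixed_anova()].
#' @param contrasts List of specs, each
#'   `list(name=, type=, cells=c(a,b), groups=c(g1,g2))` (`groups` optional
#'   for `paired`, `cells` of length 1 for `two_sample`).
#' @param sep Separator used to address cells of crossed within factors.
#' @return Data frame of class `contrast_result`: contrast, type, estimate,
#'   t, df, p, p_sidak, d.
#' @export
sidak_posthoc <- function(data, dv, subject, contrasts, between = NULL,
                          within, sep = ".") {
  if (length(contrasts) < 1)
    stop("sidak_posthoc: need at least one contrast", call. = FALSE)
  data <- as.data.frame(data)
  cell <- do.call(paste, c(lapply(within, function(w)
    as.character(data[[w]])), list(sep = sep)))
  subj <- as.character(data[[subject]])
  grp <- if (is.null(between)) rep("all", nrow(data))
         else as.character(data[[between]])
  y <- data[[dv]]
  cell_of <- function(cl) {
    idx <- cell == cl
    if (!any(idx)) stop("sidak_posthoc: unknown cell '", cl, "'",
                        call. = FALSE)
    idx
  }
  sub_vals <- function(idx, subjects) y[idx][match(subjects, subj[idx])]
  two_sample_t <- function(x1, x2) {
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
      (n1 + n2 - 2)
    est <- mean(x1) - mean(x2)
    tv <- est / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(estimate = est, t = tv, df = n1 + n2 - 2,
         p = 2 * stats::pt(abs(tv), n1 + n2 - 2, lower.tail = FALSE),
         d = est / sqrt(sp2))
  }
  one <- function(ct) {
    type <- ct$type
    if (type == "paired") {
      keep <- if (!is.null(ct$groups)) grp %in% ct$groups else TRUE
      i1 <- cell_of(ct$cells[1]) & keep; i2 <- cell_of(ct$cells[2]) & keep
      ss <- intersect(subj[i1], subj[i2])
      dvec <- sub_vals(i1, ss) - sub_vals(i2, ss)
      est <- mean(dvec); sdd <- stats::sd(dvec)
      tv <- est / (sdd / sqrt(length(dvec)))
      list(estimate = est, t = tv, df = length(dvec) - 1,
           p = 2 * stats::pt(abs(tv), length(dvec) - 1, lower.tail = FALSE),
           d = est / sdd)
    } else if (type == "two_sample") {
      idx <- if (is.null(ct$cells)) rep(TRUE, length(y)) else
        Reduce(`|`, lapply(ct$cells, cell_of))
      agg <- tapply(y[idx], subj[idx], mean)
      gg <- grp[idx][match(names(agg), subj[idx])]
      two_sample_t(agg[gg == ct$groups[1]], agg[gg == ct$groups[2]])
    } else if (type == "interaction") {
      i1 <- cell_of(ct$cells[1]); i2 <- cell_of(ct$cells[2])
      ss <- intersect(subj[i1], subj[i2])
      dvec <- sub_vals(i1, ss) - sub_vals(i2, ss)
      gg <- grp[i1][match(ss, subj[i1])]
      two_sample_t(dvec[gg == ct$groups[1]], dvec[gg == ct$groups[2]])
    } else stop("sidak_posthoc: unknown contrast type '", type, "'",
                call. = FALSE)
  }
  rows <- lapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    r <- one(ct)
    data.frame(contrast = if (!is.null(ct$name)) ct$name else paste0("c", i),
               type = ct$type, estimate = r$estimate, t = r$t, df = r$df,
               p = r$p, d = r$d)
  })
  out <- do.call(rbind, rows)
  out$p_sidak <- sidak_adjust(out$p, m = length(contrasts))
  out <- out[, c("contrast", "type", "estimate", "t", "df", "p", "p_sidak",
                 "d")]
  class(out) <- c("contrast_result", class(out))
  out
}

#' Mixed-model specification
#'
#' Declarative model spec consumed by [fit_mixed_model()]: outcome, fixed
#' part (right-hand-side formula string, e.g.
#' `"delay * emotion * sem_centered"`), random-intercept grouping factors
#' (typically participants and stimuli or stimulus sets) and the family.
#'
#' @param outcome Outcome column name.
#' @param fixed Fixed-effects RHS as a string.
#' @param random Character vector of random-intercept grouping columns.
#' @param family "gaussian" or "binomial" (logit link).
#' @return Object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(outcome, fixed, random,
                             family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 family = family), class = "mixed_model_spec")
}

#' Fit a linear or generalized linear mixed model
#'
#' Thin wrapper around lme4 enforcing the study's fitting conventions:
#' gaussian LMMs with REML (lme4's nloptwrap optimizer), binomial-logit
#' GLMMs with maximum likelihood and the bobyqa optimizer. Fixed effects are
#' reported with Wald z tests (binomial) or t statistics (gaussian; p from a
#' residual-df approximation, see the methods vignette for why Satterthwaite
#' is not used here). Non-convergence is flagged, never silent.
#'
#' @param spec A [mixed_model_spec()].
#' @param data Data frame containing all referenced columns.
#' @return List of class `mixed_model_fit`: `model` (the merMod),
#'   `coefficients` (term, estimate, se, statistic, df, p), `converged`,
#'   `family`, `messages`.
#' @export
fit_mixed_model <- function(spec, data) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  miss <- setdiff(spec$random, names(data))
  if (length(miss))
    stop("fit_mixed_model: grouping factor(s) not in data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste(
    spec$outcome, "~", spec$fixed, "+",
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")))
  msgs <- character(0)
  fit <- withCallingHandlers({
    if (spec$family == "binomial") {
      lme4::glmer(fml, data = data, family = stats::binomial("logit"),
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    } else {
      lme4::lmer(fml, data = data, REML = TRUE)
    }
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- any(grepl("singular|boundary", c(conv_msgs, msgs),
                        ignore.case = TRUE))
  converged <- !any(grepl("converge", c(conv_msgs, msgs),
                          ignore.case = TRUE))
  cf <- as.data.frame(summary(fit)$coefficients)
  est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
  stat <- est / se
  if (spec$family == "binomial") {
    df <- rep(NA_real_, length(stat))
    p <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  } else {
    df <- rep(stats::nobs(fit) - length(est), length(stat))
    p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  }
  coefs <- data.frame(term = rownames(cf), estimate = est, se = se,
                      statistic = stat, df = df, p = p, row.names = NULL)
  structure(list(model = fit, coefficients = coefs, converged = converged,
                 singular = singular, family = spec$family, messages = msgs),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("mixed_model_fit (", x$family, "), converged: ", x$converged, "\n",
      sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Mean +- k SD outlier-inclusion mask
#'
#' TRUE where a value lies within k standard deviations of the mean of the
#' supplied values (mean and SD computed on all values); the study's extreme
#' outlier rule uses k = 3. With SD = 0 every value is included.
#'
#' @param values Numeric vector (length >= 3).
#' @param k SD multiplier (default 3; Inf keeps everything).
#' @return Logical inclusion mask.
#' @export
exclude_outliers <- function(values, k = 3) {
  if (length(values) < 3)
    stop("exclude_outliers: need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}
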