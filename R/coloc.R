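# Two-channel cluster colocalization and the associated statistics:
# per-channel matched fractions, paired pre/post t tests with Holm
# adjustment, one-way ANOVA with Tukey HSD, and plain Welch/Student t.

#' Match clusters between two channels
#'
#' A cluster is colocalized either when it shares at least one voxel with
#' any cluster of the other channel (`criterion = "overlap"`, default,
#' tolerance-free) or when the nearest other-channel centroid lies within
#' `tolerance` (`criterion = "centroid"`). A cluster matching several
#' partners counts as matched once, so fractions stay in `[0, 1]`.
#'
#' @param a,b segmentation results for the two channels, as returned by
#'   [segment_clusters()] (lists with `labels` and `clusters`), measured on
#'   grids with identical shape and spacing.
#' @param criterion `"overlap"` or `"centroid"`.
#' @param tolerance centroid-distance tolerance, um (centroid criterion).
#' @return a `match_result` list: `n_a`, `n_b`, `n_a_matched`,
#'   `n_b_matched`, `fraction_a`, `fraction_b`, `criterion`, `tolerance`.
#' @export
match_clusters <- function(a, b, criterion = c("overlap", "centroid"),
                           tolerance = 0.25) {
  criterion <- match.arg(criterion)
  la <- a$labels; lb <- b$labels
  stopifnot(inherits(la, "label_volume"), inherits(lb, "label_volume"))
  if (!identical(dim(la$labels), dim(lb$labels)) ||
      max(abs(la$spacing - lb$spacing)) > 1e-12) {
    stop("input error: channels must share grid shape and spacing")
  }
  ca <- a$clusters$clusters; cb <- b$clusters$clusters
  n_a <- nrow(ca); n_b <- nrow(cb)
  if (criterion == "overlap") {
    both <- la$labels > 0L & lb$labels > 0L
    ma <- unique(la$labels[both])
    mb <- unique(lb$labels[both])
    n_am <- length(ma); n_bm <- length(mb)
  } else {
    if (n_a && n_b) {
      pa <- as.matrix(ca[, c("x", "y", "z")])
      pb <- as.matrix(cb[, c("x", "y", "z")])
      d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
      d2[d2 < 0] <- 0
      n_am <- sum(apply(d2, 1, min) <= tolerance^2)
      n_bm <- sum(apply(d2, 2, min) <= tolerance^2)
    } else {
      n_am <- 0L; n_bm <- 0L
    }
  }
  structure(list(n_a = n_a, n_b = n_b,
                 n_a_matched = n_am, n_b_matched = n_bm,
                 fraction_a = if (n_a) n_am / n_a else NA_real_,
                 fraction_b = if (n_b) n_bm / n_b else NA_real_,
                 criterion = criterion,
                 tolerance = if (criterion == "centroid") tolerance else NA_real_),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> (%s) A: %d/%d matched (%.3f), B: %d/%d matched (%.3f)\n",
              x$criterion, x$n_a_matched, x$n_a, x$fraction_a,
              x$n_b_matched, x$n_b, x$fraction_b))
  invisible(x)
}

#' Paired pre/post tests with Holm-Bonferroni correction
#'
#' Runs a two-sided paired t test for every (pre, post) pair of per-cell
#' counts and adjusts the family of p-values by Holm's step-down rule
#' (sort raw p ascending, multiply p_(i) by m - i + 1, enforce monotone
#' non-decreasing, cap at 1).
#'
#' @param family a list of pairs, each `list(pre = , post = )` with per-cell
#'   values of equal length >= 2.
#' @param labels optional names for the pairs.
#' @return data.frame with `comparison`, `n`, `t`, `df`, `p_raw`, `p_adj`,
#'   `family_size`.
#' @export
paired_prepost_test <- function(family, labels = NULL) {
  if (!length(family)) stop("input error: empty family")
  if (!is.null(names(family)) && is.null(labels)) labels <- names(family)
  labels <- labels %||% paste0("pair", seq_along(family))
  rows <- lapply(seq_along(family), function(i) {
    pre <- family[[i]]$pre; post <- family[[i]]$post
    if (length(pre) != length(post)) stop("input error: pre/post length mismatch in pair ", i)
    if (length(pre) < 2) stop("input error: need >= 2 cells per pair")
    d <- post - pre
    if (sd(d) == 0) stop("degenerate-input error: zero-variance differences in pair ", i)
    tt <- t.test(post, pre, paired = TRUE)
    data.frame(comparison = labels[i], n = length(pre),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw, method = "holm")
  out$family_size <- nrow(out)
  out
}

#' One-way group comparison: ANOVA with Tukey's HSD
#'
#' @param values numeric vector of per-experiment means.
#' @param group factor/character of condition labels; every group needs at
#'   least 2 values.
#' @return list with `anova` (data.frame `F`, `df_between`, `df_within`,
#'   `p`) and `tukey` (data.frame `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj` from the studentized-range distribution).
#' @export
group_comparison <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("input error: need >= 2 groups")
  if (any(table(group) < 2)) stop("input error: every group needs >= 2 values")
  dat <- data.frame(y = values, g = group)
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(anova = data.frame(F = an[1, "F value"],
                          df_between = an[1, "Df"], df_within = an[2, "Df"],
                          p = an[1, "Pr(>F)"]),
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Two-sample t test (Student or Welch)
#'
#' @param x,y numeric samples, each with >= 2 values and positive variance.
#' @param welch use Welch's degrees-of-freedom correction (default) or the
#'   pooled-variance Student form.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_or_student_t <- function(x, y, welch = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("input error: need >= 2 values per sample")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate-input error: zero-variance sample")
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
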