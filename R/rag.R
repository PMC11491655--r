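#' Retinal age gap per subject
#'
#' The gap of each record is `predicted age - chronological age`; a
#' subject's RAG is the mean of their two eye-level gaps (the two eyes of
#' one subject are not independent, so all downstream statistics operate
#' at the subject level).
#'
#' @param head a trained [head_model()].
#' @param cohort a `fedgap_cohort`.
#' @param subjects optional character vector restricting to a subset of
#'   subject ids.
#' @return data.frame with columns `subject_id`, `age`, `group`, `rag`.
#' @export
compute_rag <- function(head, cohort, subjects = NULL) {
  stopifnot(inherits(head, "fedgap_head"), inherits(cohort, "fedgap_cohort"))
  meta <- cohort$meta
  keep <- if (is.null(subjects)) seq_len(nrow(meta)) else
    which(meta$subject_id %in% subjects)
  if (length(keep) == 0L) stop_param("no records selected")
  validate_record_pairs(meta[keep, , drop = FALSE])
  gap <- predict_head(head, cohort$features[keep, , drop = FALSE]) -
    meta$age[keep]
  agg <- stats::aggregate(gap,
                          by = list(subject_id = meta$subject_id[keep]),
                          FUN = mean)
  first <- keep[!duplicated(meta$subject_id[keep])]
  info <- data.frame(subject_id = meta$subject_id[first],
                     age = meta$age[first],
                     group = meta$group[first],
                     stringsAsFactors = FALSE)
  out <- merge(info, agg, by = "subject_id", sort = TRUE)
  names(out)[names(out) == "x"] <- "rag"
  out
}

#' Histogram-ratio importance weights for age-distribution adaptation
#'
#' RAG comparisons are only meaningful if the target group is evaluated
#' under the age distribution the model was trained on. Each target
#' subject receives the weight `train bin proportion / target bin
#' proportion` on a shared age-bin grid; target subjects in bins without
#' training support get weight 0. Weights are renormalized to mean 1.
#'
#' @param train_ages ages of the training subjects (years).
#' @param target_ages ages of the target-group subjects (years).
#' @param bin_width bin width in years (default 5).
#' @return numeric vector of weights, one per target subject.
#' @export
age_weights <- function(train_ages, target_ages, bin_width = 5) {
  if (length(train_ages) == 0L || length(target_ages) == 0L) {
    stop_param("both age sets must be non-empty")
  }
  check_scalar(bin_width, "bin_width", min = 1e-12)
  lo <- floor(min(train_ages, target_ages) / bin_width) * bin_width
  hi <- ceiling(max(train_ages, target_ages) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  btr <- findInterval(train_ages, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  btg <- findInterval(target_ages, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  p_tr <- tabulate(btr, nb) / length(train_ages)
  p_tg <- tabulate(btg, nb) / length(target_ages)
  ratio <- ifelse(p_tg > 0, p_tr / p_tg, 0)
  w <- ratio[btg]
  if (sum(w) == 0) {
    stop_param("no overlap between the training and target age supports")
  }
  w / mean(w)
}

#' One-tailed weighted bootstrap group test
#'
#' Tests whether the disease group's mean RAG exceeds the healthy group's.
#' Each of `B` replicates resamples both groups with replacement at the
#' subject level, with selection probability proportional to the
#' importance weights; the replicate statistic is
#' `mean(disease) - mean(healthy)`. The one-tailed p-value is
#' `(1 + #{replicates <= 0}) / (B + 1)` (the add-one estimator never
#' returns an exact zero). The p-value is invariant to a common positive
#' rescaling of the weights.
#'
#' @param rag_disease,rag_healthy per-subject RAG values.
#' @param weights_disease,weights_healthy optional non-negative importance
#'   weights (default uniform).
#' @param B number of bootstrap replicates (>= 1000).
#' @param seed integer seed.
#' @return object of class `rag_test`: list with `p_value`, `observed`
#'   (weighted mean difference), `replicates`, group means, `B` and `seed`.
#' @export
bootstrap_group_test <- function(rag_disease, rag_healthy,
                                 weights_disease = NULL,
                                 weights_healthy = NULL,
                                 B = 10000, seed = 1) {
  nd <- length(rag_disease)
  nh <- length(rag_healthy)
  if (nd < 2L || nh < 2L) {
    stop_param("each group needs at least 2 subjects (got %d and %d)",
               nd, nh)
  }
  check_scalar(B, "B", min = 1000, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  wd <- if (is.null(weights_disease)) rep(1, nd) else weights_disease
  wh <- if (is.null(weights_healthy)) rep(1, nh) else weights_healthy
  for (w in list(wd, wh)) {
    if (any(!is.finite(w)) || any(w < 0) || sum(w) == 0) {
      stop_param("weights must be finite, non-negative, not all zero")
    }
  }
  wmean <- function(x, w) sum(x * w) / sum(w)
  with_seed(derive_seed(seed, "bootstrap"), {
    id <- sample.int(nd, nd * B, replace = TRUE, prob = wd)
    ih <- sample.int(nh, nh * B, replace = TRUE, prob = wh)
    md <- colMeans(matrix(rag_disease[id], nd, B))
    mh <- colMeans(matrix(rag_healthy[ih], nh, B))
    reps <- md - mh
    structure(list(
      p_value = (1 + sum(reps <= 0)) / (B + 1),
      observed = wmean(rag_disease, wd) - wmean(rag_healthy, wh),
      mean_disease = wmean(rag_disease, wd),
      mean_healthy = wmean(rag_healthy, wh),
      replicates = reps, B = as.integer(B), seed = as.integer(seed)),
      class = "rag_test")
  })
}

#' @export
print.rag_test <- function(x, ...) {
  cat(sprintf(
    "Weighted bootstrap RAG test: disease %.2f y vs healthy %.2f y\n",
    x$mean_disease, x$mean_healthy))
  cat(sprintf("  one-tailed p = %.4g (B = %d)\n", x$p_value, x$B))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 15) # 5 dataset sizes x 3 training strategies
#' bonferroni_alpha(0.05, 6)  # 3 strategies x 2 evaluation datasets
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  check_scalar(alpha, "alpha", min = 0, max = 1)
  check_scalar(m, "m", min = 1, integer = TRUE)
  alpha / m
}

#' Compare training strategies across Monte-Carlo iterations
#'
#' The primary pairwise comparison is the classic two-sided two-sample
#' t-test (pooled variance) between the strategies' per-iteration MAE
#' samples — the standard test between two models' Monte-Carlo results.
#' Because within an iteration the strategies are trained on identical
#' data, the paired t-test on the per-iteration differences is reported
#' alongside (`t_paired`, `p_paired`); it is far more sensitive and flags
#' even year-fraction systematic offsets. Degenerate zero-variance cases
#' report t = 0, p = 1. A one-way ANOVA across strategies is included, and
#' per-strategy summaries are formatted as `"mean +/- sd"`.
#'
#' @param mae_table data.frame with columns `iteration`, `strategy`, `mae`.
#' @return list with `summary` (per-strategy mean, sd, label), `pairwise`
#'   (data.frame with `t`, `p_value` for the two-sample test and
#'   `t_paired`, `p_paired`) and `anova` (F and p).
#' @export
compare_strategies <- function(mae_table) {
  need <- c("iteration", "strategy", "mae")
  if (!all(need %in% names(mae_table))) {
    stop_param("mae_table must have columns %s", paste(need, collapse = ", "))
  }
  strategies <- unique(mae_table$strategy)
  iters <- sort(unique(mae_table$iteration))
  wide <- sapply(strategies, function(s) {
    sub <- mae_table[mae_table$strategy == s, ]
    if (!setequal(sub$iteration, iters) || anyDuplicated(sub$iteration)) {
      stop_param("strategy '%s' is missing iterations or has duplicates", s)
    }
    sub$mae[match(iters, sub$iteration)]
  })
  wide <- matrix(wide, nrow = length(iters),
                 dimnames = list(NULL, strategies))
  if (nrow(wide) < 2L) stop_param("need at least 2 iterations per strategy")
  summary <- data.frame(
    strategy = strategies,
    mean = colMeans(wide),
    sd = apply(wide, 2L, stats::sd),
    row.names = NULL)
  summary$label <- sprintf("%.2f ± %.2f", summary$mean, summary$sd)
  pairs <- utils::combn(strategies, 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    x <- wide[, p[1L]]
    y <- wide[, p[2L]]
    d <- x - y
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      t_stat <- 0
      p_val <- 1
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      t_stat <- unname(tt$statistic)
      p_val <- tt$p.value
    }
    if (all(d == 0)) {
      t_pair <- 0
      p_pair <- 1
    } else {
      tp <- tryCatch(stats::t.test(d), error = function(e) NULL)
      if (is.null(tp)) {
        # (numerically) constant nonzero difference: infinitely strong
        # paired evidence
        t_pair <- sign(mean(d)) * Inf
        p_pair <- 0
      } else {
        t_pair <- unname(tp$statistic)
        p_pair <- tp$p.value
      }
    }
    data.frame(a = p[1L], b = p[2L], mean_diff = mean(d),
               t = t_stat, p_value = p_val,
               t_paired = t_pair, p_paired = p_pair,
               stringsAsFactors = FALSE)
  }))
  long <- data.frame(
    mae = as.numeric(wide),
    strategy = factor(rep(strategies, each = nrow(wide))))
  fit <- stats::aov(mae ~ strategy, data = long)
  tab <- summary(fit)[[1L]]
  anova <- list(F = tab[["F value"]][1L], p_value = tab[["Pr(>F)"]][1L])
  if (!is.finite(anova$F)) {
    anova$F <- 0
    anova$p_value <- 1
  }
  list(summary = summary, pairwise = pairwise, anova = anova)
}
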