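# Dynamic brush assay scoring and generic group comparison.

#' Score the dynamic brush assay for one mouse
#'
#' Responses to stroking are scored 0-3 per trial (0 = no movement or very
#' fast lift, 1 = sustained lifting of 2 s or more, 2 = lateral
#' kicking/flinching, 3 = licking of the stimulated paw), collected in
#' 3-minute periods repeated three times. The allodynia score is the mean
#' over periods of the highest score per period; a mouse is called allodynic
#' when the score exceeds 1.5.
#'
#' @param period_scores list of integer vectors, one per period (3 periods
#'   expected), each value in \{0, 1, 2, 3\}
#' @param mouse_id optional label
#' @param n_periods required period count, default 3
#' @return list of class `behavior_score`: `mouse_id`, `period_max`,
#'   `allodynia_score`, `allodynic`
#' @export
score_dynamic_brush <- function(period_scores, mouse_id = NA_character_,
                                n_periods = 3) {
  if (length(period_scores) != n_periods) {
    stop("expected ", n_periods, " periods, got ", length(period_scores))
  }
  for (p in seq_along(period_scores)) {
    sc <- period_scores[[p]]
    if (length(sc) < 1) stop("period ", p, " has no scores")
    if (any(is.na(sc)) || any(sc != round(sc)) || any(sc < 0) || any(sc > 3)) {
      stop("period ", p, ": scores must be integers in {0, 1, 2, 3}")
    }
  }
  period_max <- vapply(period_scores, max, 0)
  score <- mean(period_max)
  structure(list(mouse_id = mouse_id, period_max = period_max,
                 allodynia_score = score, allodynic = score > 1.5),
            class = "behavior_score")
}

#' Score a long-format behavior table
#'
#' @param df data.frame with columns `mouse_id`, `period`, `score`
#' @return data.frame, one row per mouse: `mouse_id`, `allodynia_score`,
#'   `allodynic`
#' @export
score_behavior_table <- function(df) {
  stopifnot(all(c("mouse_id", "period", "score") %in% names(df)))
  out <- lapply(split(df, df$mouse_id), function(d) {
    periods <- split(d$score, d$period)
    r <- score_dynamic_brush(periods, mouse_id = d$mouse_id[1],
                             n_periods = length(periods))
    data.frame(mouse_id = r$mouse_id, allodynia_score = r$allodynia_score,
               allodynic = r$allodynic)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two groups of scalar measurements
#'
#' Either a two-sided Wilcoxon rank-sum test or a percentile bootstrap CI
#' of the mean difference (a - b). Fully tied degenerate input returns
#' p = 1 with a warning.
#'
#' @param values_a,values_b numeric vectors (at least 3 each)
#' @param method `"rank_sum"` or `"bootstrap_mean_diff"`
#' @param n_boot bootstrap iterations, default 10000
#' @param seed integer seed (needed for the bootstrap)
#' @param conf confidence level for the bootstrap CI
#' @param alternative passed to [stats::wilcox.test()]
#' @return list: `method`, `statistic`, `p` (rank-sum) or `ci` and
#'   `mean_diff` (bootstrap)
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("rank_sum", "bootstrap_mean_diff"),
                           n_boot = 10000, seed = NULL, conf = 0.95,
                           alternative = "two.sided") {
  method <- match.arg(method)
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("need at least 3 values per group")
  }
  if (method == "rank_sum") {
    if (length(unique(c(values_a, values_b))) == 1) {
      warning("all values tied: p set to 1")
      return(list(method = method, statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    list(method = method, statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    if (is.null(seed)) stop("seed is required for the bootstrap")
    md <- mean(values_a) - mean(values_b)
    boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
      mean(sample(values_a, replace = TRUE)) -
        mean(sample(values_b, replace = TRUE))
    }, 0))
    qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    list(method = method, mean_diff = md, ci = qs, conf = conf)
  }
}
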