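#' Build a drivers x sessions x kind error table
#'
#' @param counts Tibble with columns `driver`, `session`, `kind`, `count`
#'   (one row per driver/session/kind; missing combinations are zero).
#'   Sessions are labelled `"1"`..`"5"` and `"recall"`.
#' @return A 3-way integer array of class `error_table`, indexed
#'   `[driver, session, kind]`.
#' @export
build_error_table <- function(counts) {
  drivers <- unique(counts$driver)
  sess <- unique(as.character(counts$session))
  train <- sort(as.integer(sess[sess != "recall"]))
  sessions <- c(as.character(train), if ("recall" %in% sess) "recall")
  kinds <- error_kinds()
  arr <- array(0L, dim = c(length(drivers), length(sessions), length(kinds)),
               dimnames = list(driver = as.character(drivers),
                               session = sessions, kind = kinds))
  for (r in seq_len(nrow(counts))) {
    arr[as.character(counts$driver[r]), as.character(counts$session[r]),
        as.character(counts$kind[r])] <- as.integer(counts$count[r])
  }
  structure(arr, class = c("error_table", "array"))
}

#' Per-driver-session totals of an error table
#'
#' @param table An `error_table`.
#' @return Matrix drivers x sessions of total error counts.
#' @export
error_totals <- function(table) {
  apply(unclass(table), c(1, 2), sum)
}

#' Session means and standard errors
#'
#' Mean per-driver error count and its standard error for every session,
#' per kind and for the total over kinds (the per-session summary behind
#' the study's learning-curve figures).
#'
#' @param table An `error_table`.
#' @return Tibble with columns `measure`, `session`, `mean`, `se`, `n`.
#' @export
session_summary <- function(table) {
  arr <- unclass(table)
  sessions <- dimnames(arr)$session
  out <- list()
  for (k in dimnames(arr)$kind) {
    m <- arr[, , k, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(sessions))
    out[[k]] <- tibble(
      measure = k, session = sessions,
      mean = unname(colMeans(m)),
      se = unname(apply(m, 2, stats::sd)) / sqrt(nrow(m)),
      n = nrow(m)
    )
  }
  tot <- error_totals(table)
  out$total <- tibble(
    measure = "total", session = sessions,
    mean = unname(colMeans(tot)),
    se = unname(apply(tot, 2, stats::sd)) / sqrt(nrow(tot)),
    n = nrow(tot)
  )
  dplyr::bind_rows(out)
}

#' Analyse a simulated (or compiled) training study
#'
#' Reproduces the study's statistical surface: for each error kind and for
#' the per-driver totals, a Friedman test across the training sessions,
#' and the three pairwise Wilcoxon signed-rank contrasts — last training
#' session vs first, recall vs last, and recall vs first. When the table
#' has no recall session the recall contrasts are skipped with a note.
#' No multiple-testing correction is applied (raw two-sided p at
#' alpha = 0.05); this is recorded in the result's metadata attribute.
#'
#' @param table An `error_table`.
#' @param exact Passed to [friedman_test()] (only usable for tiny tables).
#' @return Tibble with one row per test: `measure`, `test`, `contrast`,
#'   `statistic`, `z`, `df`, `n`, `p_value`, `method`, `degenerate`.
#'   Attribute `alpha` records the nominal level, `p_adjust` the (absent)
#'   correction.
#' @export
analyze_study <- function(table, exact = FALSE) {
  arr <- unclass(table)
  sessions <- dimnames(arr)$session
  train <- sessions[sessions != "recall"]
  if (length(train) < 2) stop("need >= 2 training sessions", call. = FALSE)
  has_recall <- "recall" %in% sessions
  s1 <- train[1]; s_last <- train[length(train)]

  measures <- c(dimnames(arr)$kind, "total")
  slice <- function(measure, session) {
    if (measure == "total") rowSums(arr[, session, , drop = FALSE])
    else arr[, session, measure]
  }
  rows <- list()
  add <- function(measure, test, contrast, res) {
    rows[[length(rows) + 1]] <<- tibble(
      measure = measure, test = test, contrast = contrast,
      statistic = res$statistic, z = res$z, df = res$df, n = res$n,
      p_value = res$p_value, method = res$method, degenerate = res$degenerate
    )
  }
  for (ms in measures) {
    mat <- sapply(train, function(ss) slice(ms, ss))
    add(ms, "friedman", paste0("sessions ", s1, "-", s_last),
        friedman_test(mat, exact = exact))
    add(ms, "wilcoxon", paste0("session ", s_last, " vs ", s1),
        wilcoxon_paired_test(slice(ms, s_last), slice(ms, s1)))
    if (has_recall) {
      add(ms, "wilcoxon", paste0("recall vs session ", s_last),
          wilcoxon_paired_test(slice(ms, "recall"), slice(ms, s_last)))
      add(ms, "wilcoxon", paste0("recall vs session ", s1),
          wilcoxon_paired_test(slice(ms, "recall"), slice(ms, s1)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- 0.05
  attr(out, "p_adjust") <- "none (raw two-sided p-values)"
  if (!has_recall) attr(out, "note") <- "no recall session: recall contrasts skipped"
  out
}

#' Plot per-session mean error counts
#'
#' Learning-curve panels (one per error kind, or the totals curve), showing
#' the mean per-driver count per session with +/- 1 SE bars.
#'
#' @param table An `error_table`.
#' @param total_only Plot only the totals curve.
#' @return A ggplot object.
#' @export
plot_session_means <- function(table, total_only = FALSE) {
  sm <- session_summary(table)
  if (total_only) sm <- sm[sm$measure == "total", ]
  else sm <- sm[sm$measure != "total", ]
  sm$session <- factor(sm$session, levels = unique(sm$session))
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$session, y = .data$mean,
                                        group = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "Session", y = "Mean errors per driver") +
    ggplot2::theme_minimal()
  if (!total_only) p <- p + ggplot2::facet_wrap(~measure, scales = "free_y")
  p
}
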