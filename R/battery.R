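#' Aggregate repetition scores to one score per participant and test
#'
#' Averages the valid repetition scores on the condition's combination
#' scale: geometric mean in native units for contrast and orientation
#' (log-spaced quantities), arithmetic mean for spatial frequency, plain
#' arithmetic mean for any other test name or for scores on an already-log
#' working scale (`scale = "arithmetic"`). Participants with no valid
#' score for a test are dropped for that test.
#'
#' @param table Long-format score tibble with columns `participant`,
#'   `method`, `test`, `repetition`, `score`, `valid`.
#' @param scale `"per_condition"` (default; geometric for
#'   contrast/orientation, arithmetic for spatial frequency) or
#'   `"arithmetic"` for all tests.
#' @return Tibble with `participant`, `method`, `test`, `score`,
#'   `n_valid`, `flagged` (fewer repetitions than available).
#' @export
aggregate_scores <- function(table, scale = c("per_condition", "arithmetic")) {
  scale <- match.arg(scale)
  need <- c("participant", "method", "test", "repetition", "score", "valid")
  if (!all(need %in% names(table))) {
    stop("score table lacks column(s): ",
         paste(setdiff(need, names(table)), collapse = ", "))
  }
  table |>
    dplyr::group_by(.data$participant, .data$method, .data$test) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_valid = sum(.data$valid & !is.na(.data$score)),
      score = combine_scale(.data$score[.data$valid & !is.na(.data$score)],
                            .data$test[1], scale),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_valid > 0) |>
    dplyr::mutate(flagged = .data$n_valid < .data$n_total) |>
    dplyr::select("participant", "method", "test", "score", "n_valid",
                  "flagged")
}

combine_scale <- function(x, test, scale) {
  if (length(x) == 0) return(NA_real_)
  geometric <- scale == "per_condition" &&
    test %in% c("contrast", "orientation") && all(x > 0)
  if (geometric) exp(mean(log(x))) else mean(x)
}

#' Run the full correlation battery on a score table
#'
#' Reproduces the reliability/correlation analysis: (1) per method and
#' test, ICC(3,1) test-retest between the two repetitions, after modified
#' z-score outlier removal on the pair; (2) within each method, Spearman
#' correlations between every pair of tests on repetition-averaged scores;
#' (3) the same between methods for each test. Every pairwise analysis
#' applies [zdiff_outliers()] symmetrically (an outlying pair is removed
#' from both vectors) before the coefficient. Cohen's 0.1/0.3/0.5 bands
#' label each coefficient; p values are unadjusted.
#'
#' @param table Long-format score tibble (see [aggregate_scores()]).
#' @param scale Aggregation scale, passed to [aggregate_scores()].
#' @param min_n Minimum complete pairs; analyses below it are skipped with
#'   a reason.
#' @return Tibble of reports: `analysis` (`"test_retest"`,
#'   `"between_tests"`, `"between_methods"`), `pair`, `statistic`
#'   (`"icc31"` or `"spearman"`), `coefficient`, `p`, `n`,
#'   `interpretation`, `n_excluded`, `skipped_reason`.
#' @examples
#' st <- simulate_score_table(20, seed = 2)
#' correlation_battery(st)
#' @export
correlation_battery <- function(table, scale = "per_condition", min_n = 3) {
  methods <- unique(table$method)
  tests <- unique(table$test)
  reports <- list()

  # (1) test-retest ICC between repetitions
  reps <- sort(unique(table$repetition))
  if (length(reps) >= 2) {
    wide <- table |>
      dplyr::filter(.data$valid, .data$repetition %in% reps[1:2]) |>
      dplyr::select("participant", "method", "test", "repetition", "score") |>
      tidyr::pivot_wider(names_from = "repetition", values_from = "score",
                         names_prefix = "rep")
    for (m in methods) for (t in tests) {
      sub <- wide[wide$method == m & wide$test == t, ]
      reports[[length(reports) + 1L]] <- pairwise_report(
        sub[[paste0("rep", reps[1])]], sub[[paste0("rep", reps[2])]],
        analysis = "test_retest", pair = paste(m, t, sep = ":"),
        statistic = "icc31", min_n = min_n
      )
    }
  }

  # repetition-averaged scores for the correlation analyses
  agg <- aggregate_scores(table, scale = scale)
  agg_wide <- tidyr::pivot_wider(
    agg[, c("participant", "method", "test", "score")],
    names_from = c("method", "test"), values_from = "score"
  )

  # (2) between tests within method
  if (length(tests) >= 2) {
    for (m in methods) {
      pairs <- utils::combn(tests, 2, simplify = FALSE)
      for (pr in pairs) {
        a <- agg_wide[[paste(m, pr[1], sep = "_")]]
        b <- agg_wide[[paste(m, pr[2], sep = "_")]]
        reports[[length(reports) + 1L]] <- pairwise_report(
          a, b, analysis = "between_tests",
          pair = paste0(m, ":", pr[1], " vs ", pr[2]),
          statistic = "spearman", min_n = min_n
        )
      }
    }
  }

  # (3) between methods per test
  if (length(methods) >= 2) {
    mpairs <- utils::combn(methods, 2, simplify = FALSE)
    for (mp in mpairs) for (t in tests) {
      a <- agg_wide[[paste(mp[1], t, sep = "_")]]
      b <- agg_wide[[paste(mp[2], t, sep = "_")]]
      reports[[length(reports) + 1L]] <- pairwise_report(
        a, b, analysis = "between_methods",
        pair = paste0(t, ": ", mp[1], " vs ", mp[2]),
        statistic = "spearman", min_n = min_n
      )
    }
  }

  dplyr::bind_rows(reports)
}

pairwise_report <- function(a, b, analysis, pair, statistic, min_n) {
  skel <- tibble::tibble(
    analysis = analysis, pair = pair, statistic = statistic,
    coefficient = NA_real_, p = NA_real_, n = NA_integer_,
    interpretation = NA_character_, n_excluded = NA_integer_,
    skipped_reason = NA_character_
  )
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_n) {
    skel$skipped_reason <- sprintf("only %d complete pairs", sum(ok))
    return(skel)
  }
  a2 <- a[ok]; b2 <- b[ok]
  out <- withCallingHandlers(
    zdiff_outliers(a2, b2),
    warning = function(w) invokeRestart("muffleWarning")
  )
  keep <- !out$outlier
  if (sum(keep) < min_n) {
    skel$skipped_reason <- sprintf("only %d pairs after outlier removal", sum(keep))
    return(skel)
  }
  res <- tryCatch(
    if (statistic == "icc31") {
      r <- icc31(a2[keep], b2[keep])
      tibble::tibble(coefficient = r$r, p = r$p, n = r$n)
    } else {
      r <- spearman_cor(a2[keep], b2[keep])
      tibble::tibble(coefficient = r$rho, p = r$p, n = r$n)
    },
    error = function(e) NULL
  )
  if (is.null(res)) {
    skel$skipped_reason <- "statistic undefined on these scores"
    return(skel)
  }
  skel$coefficient <- res$coefficient
  skel$p <- res$p
  skel$n <- res$n
  skel$interpretation <- cohen_label(res$coefficient)
  skel$n_excluded <- sum(out$outlier)
  skel
}
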