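# Min-max scaling of metric summaries across algorithms, aggregation into
# task / scenario / overall scores, failure handling and ranking.
#
# The score table is tidy: one row per (algorithm, scenario, metric) with
# the metric's summary value and a failure flag. Metrics map to tasks as
# correlation -> S_correlation, similarity -> S_similarity (SIMIC),
# sip -> S_enrichment.

#' Min-max scale metric values across algorithms within one scenario
#'
#' Non-failed values are mapped by `(Y - min) / (max - min)` computed over
#' the non-failed algorithms only, so the best gets 1 and the worst 0.
#' Failed algorithms score 0 regardless of any value. If all non-failed
#' values are equal the scale is degenerate and all of them receive 0.5.
#'
#' @param values numeric metric summaries, one per algorithm.
#' @param failed logical failure flags, same length.
#' @return Scaled values in `[0, 1]`.
#' @export
minmax_scale <- function(values, failed = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(failed))
  if (all(failed)) stop("all algorithms failed in this scenario")
  ok <- !failed
  y <- values[ok]
  if (anyNA(y)) stop("missing metric value on a non-failed algorithm")
  rng <- range(y)
  out <- numeric(length(values))
  out[ok] <- if (rng[1] == rng[2]) 0.5 else (y - rng[1]) / (rng[2] - rng[1])
  out
}

#' Compute task and scenario scores from raw metric summaries
#'
#' Scales every metric across algorithms within each scenario
#' ([minmax_scale()]), maps metrics to task scores (`S_correlation`,
#' `S_similarity`, `S_enrichment`) and averages the three into
#' `S_scenario`. Failed (algorithm, scenario) pairs score 0 on every task.
#'
#' @param table data.frame with columns `algorithm`, `scenario`, `metric`
#'   (one of `"correlation"`, `"similarity"`, `"sip"`), `value`, and
#'   optionally `failed`.
#' @return data.frame with one row per (algorithm, scenario): the three
#'   task scores, `S_scenario` and `failed`.
#' @export
task_and_scenario_scores <- function(table) {
  needed <- c("algorithm", "scenario", "metric", "value")
  if (!all(needed %in% names(table)))
    stop("score table needs columns: ", paste(needed, collapse = ", "))
  if (is.null(table$failed)) table$failed <- FALSE
  metrics <- c(correlation = "S_correlation", similarity = "S_similarity",
               sip = "S_enrichment")
  if (!all(table$metric %in% names(metrics)))
    stop("unknown metric: ",
         paste(setdiff(unique(table$metric), names(metrics)), collapse = ", "))
  # failure is per (algorithm, scenario): any flagged metric fails the pair
  fail_key <- unique(table[table$failed, c("algorithm", "scenario")])
  out <- list()
  for (sc in unique(table$scenario)) {
    sub <- table[table$scenario == sc, , drop = FALSE]
    algs <- sort(unique(sub$algorithm))
    failed <- algs %in% fail_key$algorithm[fail_key$scenario == sc]
    scores <- matrix(NA_real_, nrow = length(algs), ncol = 3,
                     dimnames = list(algs, unname(metrics)))
    for (met in names(metrics)) {
      rows <- sub[sub$metric == met, , drop = FALSE]
      vals <- rows$value[match(algs, rows$algorithm)]
      if (any(is.na(vals) & !failed))
        stop("metric '", met, "' missing for non-failed algorithm(s) in ",
             "scenario '", sc, "': ",
             paste(algs[is.na(vals) & !failed], collapse = ", "))
      scores[, metrics[[met]]] <- minmax_scale(ifelse(failed, 0, vals), failed)
    }
    out[[sc]] <- data.frame(algorithm = algs, scenario = sc, scores,
                            S_scenario = rowMeans(scores), failed = failed,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overall scores and rankings
#'
#' `S_overall` is the median `S_scenario` across all scenarios (failures
#' having contributed 0). Algorithms are ranked by descending score both
#' overall and per scenario; ties share the better rank.
#'
#' @param scored output of [task_and_scenario_scores()].
#' @return List with `overall` (algorithm, `S_overall`, `rank`) sorted by
#'   rank, and `per_scenario` (adds `rank` to each scenario row).
#' @export
overall_and_rank <- function(scored) {
  if (nrow(scored) == 0L) stop("empty score table")
  s <- vapply(split(scored$S_scenario, scored$algorithm), stats::median,
              numeric(1))
  overall <- data.frame(algorithm = names(s), S_overall = unname(s))
  overall$rank <- rank(-overall$S_overall, ties.method = "min")
  overall <- overall[order(overall$rank, overall$algorithm), ]
  rownames(overall) <- NULL
  per_scenario <- do.call(rbind, lapply(split(scored, scored$scenario),
    function(sub) {
      sub$rank <- rank(-sub$S_scenario, ties.method = "min")
      sub[order(sub$rank, sub$algorithm), ]
    }))
  rownames(per_scenario) <- NULL
  list(overall = overall, per_scenario = per_scenario)
}
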