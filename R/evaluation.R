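#' Proximal-credit classification accuracy
#'
#' The study's accuracy statistic: `(n_correct + 0.5 * n_similar) /
#' n_total`, where `n_correct` counts exact matches and `n_similar` counts
#' proximal predictions -- misclassifications whose layer-composition
#' difference from the truth equals the minimal inter-class difference of
#' the design (see [is_proximal()]). The confusion matrix counts raw
#' predictions (rows = truth, columns = prediction); proximal credit
#' affects only the scalar accuracy.
#'
#' @param predictions,truths Equal-length vectors of construct labels, all
#'   members of `design$classes`.
#' @param design A [study_design()].
#' @return An object of class `lss_evaluation`: list with `n_correct`,
#'   `n_similar`, `n_total`, `accuracy`, `confusion`.
#' @export
#' @examples
#' d <- study_design("depth")
#' classification_accuracy("11000000", "00110000", d)$accuracy # 0.5
classification_accuracy <- function(predictions, truths, design) {
  stopifnot(inherits(design, "lss_study_design"))
  if (length(predictions) == 0L || length(predictions) != length(truths)) {
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(predictions %in% design$classes) ||
      !all(truths %in% design$classes)) {
    stop("labels must belong to the study's class set", call. = FALSE)
  }
  n_total <- length(predictions)
  n_correct <- sum(predictions == truths)
  n_similar <- sum(mapply(function(p, t) is_proximal(p, t, design),
                          predictions, truths))
  confusion <- table(
    factor(truths, levels = design$classes),
    factor(predictions, levels = design$classes),
    dnn = c("truth", "prediction")
  )
  structure(
    list(n_correct = n_correct, n_similar = n_similar, n_total = n_total,
         accuracy = (n_correct + 0.5 * n_similar) / n_total,
         confusion = unclass(confusion)),
    class = "lss_evaluation"
  )
}

#' @export
print.lss_evaluation <- function(x, ...) {
  cat(sprintf(
    "<lss_evaluation> accuracy %.4f (%d correct + 0.5 x %d proximal of %d)\n",
    x$accuracy, x$n_correct, x$n_similar, x$n_total))
  invisible(x)
}

#' Evaluate trained replicates on their held-out spectra
#'
#' Convenience wrapper: applies [classification_accuracy()] to the
#' held-out predictions of each replicate from [train_replicates()].
#'
#' @param replicates List of `lss_trained_replicate`.
#' @param design The [study_design()].
#' @return List of `lss_evaluation`, one per replicate.
#' @export
evaluate_replicates <- function(replicates, design) {
  lapply(replicates, function(r) {
    classification_accuracy(r$test_predictions, r$test_truth, design)
  })
}

#' Summarize replicate accuracies with low-accuracy exclusion
#'
#' Replicates whose accuracy falls below the exclusion threshold (default:
#' chance level, one over the number of classes) are treated as failed
#' training runs and excluded, with the reason recorded; the mean and
#' sample (n-1) standard deviation are computed over the survivors.
#'
#' @param replicate_results List of `lss_evaluation` (or numeric vector of
#'   accuracies).
#' @param n_classes Number of classes, used for the default threshold.
#' @param exclusion_threshold Accuracy below which a replicate is
#'   excluded; default `1 / n_classes`.
#' @return List with `mean`, `sd`, `accuracies` (survivors), `excluded`
#'   (data.frame of replicate index, accuracy, reason), `n_used`, and
#'   `single_replicate` flag (sd reported as 0 when only one survivor).
#' @export
summarize_replicates <- function(replicate_results, n_classes = NULL,
                                 exclusion_threshold = NULL) {
  acc <- if (is.numeric(replicate_results)) replicate_results else
    vapply(replicate_results, function(r) r$accuracy, numeric(1))
  if (length(acc) == 0L) stop("need at least one replicate", call. = FALSE)
  if (is.null(exclusion_threshold)) {
    if (is.null(n_classes)) {
      stop("give n_classes or an explicit exclusion_threshold", call. = FALSE)
    }
    exclusion_threshold <- 1 / n_classes
  }
  drop <- which(acc < exclusion_threshold)
  excluded <- data.frame(
    replicate = drop,
    accuracy = acc[drop],
    reason = if (length(drop)) sprintf(
      "accuracy %.4f below exclusion threshold %.4f",
      acc[drop], exclusion_threshold) else character(0),
    stringsAsFactors = FALSE
  )
  keep <- setdiff(seq_along(acc), drop)
  if (length(keep) == 0L) {
    stop("all replicates fell below the exclusion threshold", call. = FALSE)
  }
  surv <- acc[keep]
  list(
    mean = mean(surv),
    sd = if (length(surv) > 1L) stats::sd(surv) else 0,
    accuracies = surv,
    excluded = excluded,
    n_used = length(surv),
    single_replicate = length(surv) == 1L
  )
}

#' Rank single fibers and fiber pairs by mean accuracy
#'
#' Sorts fiber specifications (e.g. `"R5"`, `"R1R5"`) by descending mean
#' replicate accuracy; ties break by lower standard deviation, then
#' lexicographically. Also reports the two-fiber-minus-single-fiber gap:
#' the difference between the average mean accuracy of the pair specs and
#' that of the single specs present in the input.
#'
#' @param summaries Named list of [summarize_replicates()] results (names
#'   are fiber specs), or a data.frame with columns `fiber_spec`, `mean`,
#'   `sd`.
#' @return An object of class `lss_fiber_ranking`: data.frame
#'   (`fiber_spec`, `mean_accuracy`, `sd_accuracy`, `n_fibers`) sorted as
#'   above, with attribute `pair_minus_single_gap`.
#' @export
rank_fiber_combinations <- function(summaries) {
  if (is.data.frame(summaries)) {
    df <- data.frame(fiber_spec = summaries$fiber_spec,
                     mean_accuracy = summaries$mean,
                     sd_accuracy = summaries$sd,
                     stringsAsFactors = FALSE)
  } else {
    if (length(summaries) == 0L || is.null(names(summaries))) {
      stop("summaries must be a non-empty named list or data.frame",
           call. = FALSE)
    }
    df <- data.frame(
      fiber_spec = names(summaries),
      mean_accuracy = vapply(summaries, function(s) s$mean, numeric(1)),
      sd_accuracy = vapply(summaries, function(s) s$sd, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!all(grepl("^R[1-5](R[1-5])?$", df$fiber_spec))) {
    stop("fiber specs must look like 'R3' or 'R1R5'", call. = FALSE)
  }
  df$n_fibers <- ifelse(nchar(df$fiber_spec) == 2L, 1L, 2L)
  ord <- order(-df$mean_accuracy, df$sd_accuracy, df$fiber_spec)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  singles <- df$mean_accuracy[df$n_fibers == 1L]
  pairs <- df$mean_accuracy[df$n_fibers == 2L]
  gap <- if (length(singles) && length(pairs)) mean(pairs) - mean(singles)
         else NA_real_
  structure(df, class = c("lss_fiber_ranking", "data.frame"),
            pair_minus_single_gap = gap)
}

#' @export
print.lss_fiber_ranking <- function(x, ...) {
  cat("<lss_fiber_ranking>\n")
  print.data.frame(x, digits = 4)
  gap <- attr(x, "pair_minus_single_gap")
  if (!is.na(gap)) {
    cat(sprintf("two-fiber minus single-fiber mean accuracy: %+.4f\n", gap))
  }
  invisible(x)
}

#' Split a fiber spec string into fiber ids
#'
#' @param spec A spec like `"R3"` or `"R1R5"`.
#' @return Character vector of 1 or 2 fiber ids.
#' @export
parse_fiber_spec <- function(spec) {
  if (!grepl("^R[1-5](R[1-5])?$", spec)) {
    stop("malformed fiber spec: ", spec, call. = FALSE)
  }
  regmatches(spec, gregexpr("R[1-5]", spec))[[1]]
}
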