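#' Round half away from zero
#'
#' Commercial rounding at `digits` decimals (0.125 -> 0.13), used for the
#' reported mean score change; base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

arm_group <- function(arm) {
  ifelse(arm == "control", "control", "experimental")
}

check_records <- function(records) {
  need <- c("patient_id", "arm", "score_pre", "score_post")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Total score of a patient selection
#'
#' Sums elasticity scores over the patients of one or more arms at one
#' timepoint. Alternatively, a length-5 per-score count histogram (patients
#' at scores 1..5) can be passed directly, in which case the total is
#' `sum(counts * 1:5)`.
#'
#' @param records a `patient_records` data.frame, or a length-5 numeric
#'   vector of patient counts at scores 1..5.
#' @param arms character vector of arm names to include; NULL (default)
#'   keeps all arms. `"experimental"` / `"control"` select by pooled group.
#' @param timepoint `"pre"` or `"post"` (ignored for histogram input).
#' @return integer total score.
#' @examples
#' group_total(c(3, 6, 5, 25, 14))   # 200
#' group_total(c(2, 1, 2, 27, 21))   # 223
#' @export
group_total <- function(records, arms = NULL, timepoint = c("pre", "post")) {
  if (is.numeric(records) && is.null(dim(records))) {
    if (length(records) != 5L || any(records < 0)) {
      stop("a histogram must be 5 non-negative counts at scores 1..5",
           call. = FALSE)
    }
    return(as.integer(sum(records * 1:5)))
  }
  check_records(records)
  timepoint <- match.arg(timepoint)
  sel <- select_arms(records, arms)
  if (nrow(sel) == 0L) stop("no patients match the arm selection",
                            call. = FALSE)
  as.integer(sum(sel[[paste0("score_", timepoint)]]))
}

select_arms <- function(records, arms) {
  if (is.null(arms)) return(records)
  records[records$arm %in% arms | arm_group(records$arm) %in% arms, ,
          drop = FALSE]
}

#' Mean per-patient score change
#'
#' `(sum of post scores - sum of pre scores) / n`, rounded half away from
#' zero to 2 decimals — the per-patient average increase reported for each
#' treatment group. `mean_change()` computes it from paired patient records;
#' `mean_change_from_totals()` from reported group totals and group size.
#'
#' @param records a `patient_records` data.frame with paired scores.
#' @param arms arm/group selection as in [group_total()].
#' @return mean change, rounded to 2 decimals.
#' @examples
#' mean_change_from_totals(200, 223, 53)  # 0.43
#' mean_change_from_totals(217, 224, 55)  # 0.13
#' @export
mean_change <- function(records, arms = NULL) {
  check_records(records)
  sel <- select_arms(records, arms)
  if (nrow(sel) == 0L) stop("no patients match the arm selection",
                            call. = FALSE)
  if (anyNA(sel$score_pre) || anyNA(sel$score_post)) {
    stop("every patient needs both a pre and a post score", call. = FALSE)
  }
  round_half_up((sum(sel$score_post) - sum(sel$score_pre)) / nrow(sel), 2L)
}

#' @rdname mean_change
#' @param total_pre,total_post group score totals before / after treatment.
#' @param n number of patients in the group.
#' @export
mean_change_from_totals <- function(total_pre, total_post, n) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  round_half_up((total_post - total_pre) / n, 2L)
}

#' Confusion table and its accuracy
#'
#' `confusion_table()` holds the four counts of a binary confusion matrix;
#' `accuracy()` is the fraction of correctly classified units,
#' `(TP + TN) / (TP + TN + FP + FN)`, computed on exact integer counts. The
#' same formula serves pixel-level segmentation agreement and score-level
#' agreement; [score_confusion()] builds the binarized score-level table
#' (a predicted score counts as correct iff it equals the reference score).
#'
#' @param TP,FP,FN,TN non-negative integer counts; their total must be >= 1
#'   for `accuracy()`.
#' @return `confusion_table()`: a named integer vector of class
#'   `confusion_table`; `accuracy()`: a fraction in \[0, 1\].
#' @examples
#' accuracy(confusion_table(TP = 49, FP = 1, FN = 1, TN = 49))  # 0.98
#' @export
confusion_table <- function(TP, FP, FN, TN) {
  x <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(x < 0) || any(x != round(x)) || anyNA(x)) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(x), names = names(x), class = "confusion_table")
}

#' @rdname confusion_table
#' @param ct a `confusion_table`.
#' @export
accuracy <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- sum(ct)
  if (total < 1L) stop("confusion table is empty", call. = FALSE)
  (ct[["TP"]] + ct[["TN"]]) / total
}

#' @rdname confusion_table
#' @param predicted,reference integer score vectors of equal length.
#' @export
score_confusion <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(predicted) >= 1L)
  hits <- sum(predicted == reference)
  confusion_table(TP = hits, FP = length(predicted) - hits, FN = 0L, TN = 0L)
}

#' Compare per-patient score change across groups
#'
#' One-way analysis of variance of the per-patient change (post - pre)
#' across treatment groups, the standard pairwise group comparison; a
#' difference is flagged significant at p < 0.05.
#'
#' @param records a `patient_records` data.frame.
#' @param by `"group"` pools the experimental arms against control (default);
#'   `"arm"` compares the individual arms.
#' @return list with `means` (named per-group mean change), `F`, `df`
#'   (numerator, denominator), `p_value`, `significant`, and the underlying
#'   `stats::aov` fit.
#' @export
compare_groups <- function(records, by = c("group", "arm")) {
  check_records(records)
  by <- match.arg(by)
  g <- factor(if (by == "group") arm_group(records$arm) else records$arm)
  if (nlevels(g) < 2L) stop("need at least 2 groups to compare",
                            call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs at least 2 patients",
                               call. = FALSE)
  change <- records$score_post - records$score_pre
  fit <- stats::aov(change ~ g)
  an <- summary(fit)[[1]]
  means <- tapply(change, g, mean)
  list(means = stats::setNames(as.numeric(means), names(means)),
       F = an[1, "F value"],
       df = c(an[1, "Df"], an[2, "Df"]),
       p_value = an[1, "Pr(>F)"],
       significant = an[1, "Pr(>F)"] < 0.05,
       fit = fit)
}

#' Cohort summary with consistency audit
#'
#' Assembles the headline numbers per pooled group (experimental arms
#' together, control): group size, total score before and after treatment,
#' mean per-patient change, and the pre/post score histograms. When printed
#' (externally reported) totals are supplied — e.g. via the metadata of
#' [default_cohort_spec()] — the audit compares each against the
#' histogram-derived total and flags any group where the two disagree.
#'
#' @param records a `patient_records` data.frame.
#' @param printed_totals optional named list, per group, of
#'   `c(pre = ..., post = ...)` reported totals to audit.
#' @return a `cohort_summary`: list with `groups` (data.frame: group, n,
#'   total_pre, total_post, mean_change), `histograms`, and `audit`
#'   (data.frame: group, timepoint, printed, derived, flag).
#' @examples
#' rec <- generate_cohort(default_cohort_spec(), rng_seed = 1)
#' s <- summarize_cohort(rec, default_cohort_spec()$printed_totals)
#' s$groups
#' any(s$audit$flag)  # TRUE: experimental pre counts sum to 212, not 217
#' @export
summarize_cohort <- function(records, printed_totals = NULL) {
  check_records(records)
  grp <- arm_group(records$arm)
  groups <- sort(unique(grp))
  rows <- do.call(rbind, lapply(groups, function(g) {
    sel <- records[grp == g, ]
    data.frame(group = g, n = nrow(sel),
               total_pre = sum(sel$score_pre),
               total_post = sum(sel$score_post),
               mean_change = mean_change(sel))
  }))
  hists <- lapply(stats::setNames(groups, groups), function(g) {
    sel <- records[grp == g, ]
    list(pre = tabulate(sel$score_pre, 5L), post = tabulate(sel$score_post, 5L))
  })
  audit <- NULL
  if (!is.null(printed_totals)) {
    audit <- do.call(rbind, lapply(names(printed_totals), function(g) {
      derived <- if (g %in% rows$group) {
        c(pre = rows$total_pre[rows$group == g],
          post = rows$total_post[rows$group == g])
      } else c(pre = NA_integer_, post = NA_integer_)
      data.frame(group = g, timepoint = c("pre", "post"),
                 printed = as.integer(printed_totals[[g]][c("pre", "post")]),
                 derived = as.integer(derived),
                 flag = as.integer(printed_totals[[g]][c("pre", "post")]) !=
                   as.integer(derived))
    }))
  }
  structure(list(groups = rows, histograms = hists, audit = audit),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$audit) && any(x$audit$flag, na.rm = TRUE)) {
    bad <- x$audit[which(x$audit$flag), ]
    for (k in seq_len(nrow(bad))) {
      cat(sprintf("  ! %s %s: printed total %d differs from histogram-derived %d\n",
                  bad$group[k], bad$timepoint[k], bad$printed[k],
                  bad$derived[k]))
    }
  }
  invisible(x)
}
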