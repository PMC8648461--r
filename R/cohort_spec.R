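#' Specify per-arm pre/post score distributions for a synthetic cohort
#'
#' A `cohort_spec` lists, for every treatment arm, how many patients score
#' 1..5 before and after drug administration. Optional printed group totals
#' (as reported in a source table or narrative) can be attached; the cohort
#' summary audits them against the histogram-derived totals and flags any
#' discrepancy.
#'
#' @param arms named list; each element is a list with integer vectors
#'   `pre` and `post` of length 5 (patient counts at scores 1..5). Pre and
#'   post counts of an arm must sum to the same number of patients. Valid arm
#'   names are `experimental_crispr`, `experimental_shrna`, `control`.
#' @param printed_totals optional named list mapping a group
#'   (`experimental` = both experimental arms pooled, or `control`) to
#'   `c(pre = ..., post = ...)` reported totals.
#' @return an object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(arms, printed_totals = NULL) {
  valid <- c("experimental_crispr", "experimental_shrna", "control")
  if (is.null(names(arms)) || !all(names(arms) %in% valid)) {
    stop("arm names must be among: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(arms)) {
    a <- arms[[nm]]
    for (tp in c("pre", "post")) {
      v <- a[[tp]]
      if (length(v) != 5L || any(v < 0) || any(v != round(v))) {
        stop(sprintf("arm '%s' %s counts must be 5 non-negative integers",
                     nm, tp), call. = FALSE)
      }
    }
    if (sum(a$pre) != sum(a$post)) {
      stop(sprintf("arm '%s': pre counts sum to %d but post to %d (same patients are scored twice)",
                   nm, sum(a$pre), sum(a$post)), call. = FALSE)
    }
    if (sum(a$pre) == 0L) stop(sprintf("arm '%s' has no patients", nm),
                               call. = FALSE)
  }
  structure(list(arms = lapply(arms, function(a)
    list(pre = as.integer(a$pre), post = as.integer(a$post))),
    printed_totals = printed_totals), class = "cohort_spec")
}

#' Default cohort: the reported score distributions
#'
#' The score histograms of the three arms as printed in the source study:
#' 25 CRISPR-nanoparticle patients (pre 1/2/3/12/7, post 0/1/2/13/9),
#' 30 shRNA-nanoparticle patients (pre 1/3/4/14/8, post 1/2/3/15/9), and
#' 53 saline controls (pre 3/6/5/25/14, post 2/1/2/27/21), together with
#' the narrative group totals (experimental 217 -> 224, control 200 -> 223)
#' attached as printed metadata for the consistency audit.
#'
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function() {
  cohort_spec(
    arms = list(
      experimental_crispr = list(pre = c(1, 2, 3, 12, 7),
                                 post = c(0, 1, 2, 13, 9)),
      experimental_shrna = list(pre = c(1, 3, 4, 14, 8),
                                post = c(1, 2, 3, 15, 9)),
      control = list(pre = c(3, 6, 5, 25, 14),
                     post = c(2, 1, 2, 27, 21))),
    printed_totals = list(
      experimental = c(pre = 217, post = 224),
      control = c(pre = 200, post = 223)))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  for (nm in names(x$arms)) {
    a <- x$arms[[nm]]
    cat(sprintf("  %-20s n=%-3d pre %s | post %s\n", nm, sum(a$pre),
                paste(a$pre, collapse = "/"), paste(a$post, collapse = "/")))
  }
  invisible(x)
}

# Random pre->post matching with marginals fixed to the spec histograms and
# no patient dropping by more than 1 point. Rows (pre scores) are processed
# from most to least constrained (5 -> 1); a Hall-type count condition is
# checked first, and the constraint is dropped with a warning if infeasible.
pair_scores <- function(pre, post) {
  feasible <- all(vapply(2:5, function(t)
    sum(pre[t:5]) <= sum(post[(t - 1):5]), logical(1)))
  min_post <- if (feasible) function(i) max(1L, i - 1L) else function(i) 1L
  if (!feasible) {
    warning("pre/post histograms admit no matching with score drops <= 1; ",
            "falling back to unconstrained random matching", call. = FALSE)
  }
  cap <- as.integer(post)
  out <- vector("list", 5L)
  for (i in 5:1) {
    cols <- min_post(i):5
    pool <- rep(cols, cap[cols])
    take <- pool[sample.int(length(pool), pre[i])]
    out[[i]] <- sort(take)
    for (j in cols) cap[j] <- cap[j] - sum(take == j)
  }
  data.frame(score_pre = rep(1:5, times = pre),
             score_post = unlist(out))
}

#' Generate a longitudinal synthetic cohort
#'
#' Emits one record per patient with paired pre/post elasticity scores whose
#' per-arm, per-timepoint histograms equal the spec's counts exactly. The
#' pre-to-post pairing within an arm is a seeded random matching constrained
#' so that no patient's score decreases by more than 1 point. Optionally
#' materializes a synthetic elastogram per (patient, timepoint) via
#' [composition_for_score()] and [generate_elastogram()], with per-image
#' child seeds derived from `rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param rng_seed integer seed for the whole cohort.
#' @param images if TRUE, attach an `images` attribute: a named list of
#'   [elastogram()]s keyed `"<patient_id>_<timepoint>"`.
#' @param height,width,noise_sd image parameters when `images = TRUE`.
#' @return a data.frame of class `patient_records` with columns
#'   `patient_id`, `arm`, `score_pre`, `score_post`.
#' @examples
#' rec <- generate_cohort(default_cohort_spec(), rng_seed = 1)
#' table(rec$arm)
#' @export
generate_cohort <- function(spec, rng_seed = 1L, images = FALSE,
                            height = 64L, width = 64L, noise_sd = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- with_seed(rng_seed, {
    do.call(rbind, lapply(names(spec$arms), function(nm) {
      a <- spec$arms[[nm]]
      pairs <- pair_scores(a$pre, a$post)
      pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]  # shuffle ids
      data.frame(patient_id = sprintf("%s_%03d", nm, seq_len(nrow(pairs))),
                 arm = nm, score_pre = pairs$score_pre,
                 score_post = pairs$score_post, row.names = NULL)
    }))
  })
  class(records) <- c("patient_records", "data.frame")
  if (images) {
    imgs <- list()
    for (k in seq_len(nrow(records))) {
      for (tp in c("pre", "post")) {
        s <- records[[paste0("score_", tp)]][k]
        cs <- child_seed(rng_seed, 2L * k + (tp == "post"))
        comp <- composition_for_score(s, rng_seed = cs)
        imgs[[paste0(records$patient_id[k], "_", tp)]] <-
          generate_elastogram(comp, height, width, noise_sd, rng_seed = cs,
                              patient_id = records$patient_id[k],
                              timepoint = tp)
      }
    }
    attr(records, "images") <- imgs
  }
  records
}

#' Read / write patient score tables
#'
#' Scores travel as long-format CSV with header
#' `patient_id,arm,timepoint,score` (RFC 4180, UTF-8). `write_scores_csv()`
#' pivots the wide per-patient records to long form; `read_scores_csv()`
#' reads the long form back into paired records.
#'
#' @param records a `patient_records` data.frame (see [generate_cohort()]).
#' @param path CSV file path.
#' @return `read_scores_csv()` returns a `patient_records` data.frame;
#'   `write_scores_csv()` returns `path` invisibly.
#' @export
write_scores_csv <- function(records, path) {
  long <- rbind(
    data.frame(patient_id = records$patient_id, arm = records$arm,
               timepoint = "pre", score = records$score_pre),
    data.frame(patient_id = records$patient_id, arm = records$arm,
               timepoint = "post", score = records$score_post))
  long <- long[order(long$patient_id, long$timepoint, decreasing = c(FALSE, TRUE),
                     method = "radix"), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("patient_id", "arm", "timepoint", "score")
  if (!all(need %in% names(long))) {
    stop("scores CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pre <- long[long$timepoint == "pre", ]
  post <- long[long$timepoint == "post", ]
  m <- merge(pre[, c("patient_id", "arm", "score")],
             post[, c("patient_id", "score")], by = "patient_id",
             suffixes = c("_pre", "_post"))
  if (nrow(m) != nrow(pre) || nrow(m) != nrow(post)) {
    stop("every patient needs exactly one pre and one post score",
         call. = FALSE)
  }
  names(m) <- c("patient_id", "arm", "score_pre", "score_post")
  if (!all(unlist(m[, c("score_pre", "score_post")]) %in% 1:5)) {
    stop("scores must lie in 1..5", call. = FALSE)
  }
  class(m) <- c("patient_records", "data.frame")
  m
}
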