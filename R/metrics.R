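#' @title Benchmark metrics
#' @description Per-rank confusion accounting in the style of the standard
#'   k-mer classifier benchmarks: sensitivity counts correct assignments
#'   against all reads whose truth is known at the rank (so unclassified
#'   reads count against it), precision counts correct assignments against
#'   all assignments made (unclassified reads excluded), and F1 is their
#'   harmonic mean.
#' @name metrics
NULL

#' Construct per-rank confusion counts
#'
#' @param correct Reads with the taxon correctly assigned.
#' @param incorrect Reads with an incorrect taxon assigned.
#' @param unclassified Reads with known truth left unassigned.
#' @param rank Optional rank annotation.
#' @return Object of class \code{confusion_counts} with
#'   \code{total_known = correct + incorrect + unclassified}.
#' @export
confusion_counts <- function(correct, incorrect, unclassified,
                             rank = NA_character_) {
    stopifnot(correct >= 0, incorrect >= 0, unclassified >= 0)
    structure(list(rank = rank, correct = correct, incorrect = incorrect,
                   unclassified = unclassified,
                   total_known = correct + incorrect + unclassified),
              class = "confusion_counts")
}

#' Tally assignments against per-read truth at one rank
#'
#' Reads whose truth at the rank is the unknown sentinel are excluded
#' entirely. The remaining reads split three ways: assigned with matching
#' taxon (correct), assigned with a different taxon (incorrect), and
#' unassigned (unclassified).
#'
#' @param assignments Data frame with columns \code{read_id},
#'   \code{taxon}, \code{assigned}, and (if present) \code{rank}, in which
#'   case only rows at \code{rank} are used. One row per read at the rank.
#' @param truth Data frame with \code{read_id} plus one column per rank
#'   holding each read's true lineage.
#' @param rank One of \code{\link{lineage_ranks}()}.
#' @return A \code{\link{confusion_counts}} object.
#' @export
tally <- function(assignments, truth, rank) {
    if (!rank %in% lineage_ranks())
        stop("rank must be one of: ", paste(lineage_ranks(), collapse = ", "))
    a <- assignments
    if ("rank" %in% names(a)) a <- a[!is.na(a$rank) & a$rank == rank, ]
    unknown <- setdiff(unique(a$read_id), truth$read_id)
    if (length(unknown) > 0)
        stop("assignment for read(s) missing from truth: ",
             paste(head(unknown, 3), collapse = ", "))
    true_taxon <- truth[[rank]][match(a$read_id, truth$read_id)]
    known <- true_taxon != lineage_sentinel()
    a <- a[known, ]
    true_taxon <- true_taxon[known]
    assigned <- a$assigned & !is.na(a$taxon)
    correct <- sum(assigned & a$taxon == true_taxon)
    incorrect <- sum(assigned & a$taxon != true_taxon)
    unclassified <- sum(!assigned)
    cc <- confusion_counts(correct, incorrect, unclassified, rank)
    stopifnot(cc$correct + cc$incorrect + cc$unclassified ==
                  cc$total_known)
    cc
}

#' Sensitivity, precision, and F1 from confusion counts
#'
#' Sensitivity is \code{correct / total_known}; precision is
#' \code{correct / (correct + incorrect)}. Cases with an empty denominator
#' are reported as \code{NA} (undefined), never silently zero.
#'
#' @param cc A \code{\link{confusion_counts}} object.
#' @return List with \code{sensitivity}, \code{precision}, \code{f1}.
#' @export
compute_metrics <- function(cc) {
    sens <- if (cc$total_known > 0) cc$correct / cc$total_known
            else NA_real_
    prec <- if (cc$correct + cc$incorrect > 0)
        cc$correct / (cc$correct + cc$incorrect) else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
        2 * sens * prec / (sens + prec) else NA_real_
    list(sensitivity = sens, precision = prec, f1 = f1)
}

#' Format a proportion as a percentage
#'
#' Two decimal places, round-half-even.
#'
#' @param x Proportion(s) in \code{[0, 1]}.
#' @return Numeric percentage(s).
#' @export
format_pct <- function(x) round(100 * x, 2)

#' Evaluate an assignment table against truth across ranks
#'
#' @param assignments Long assignment data frame (see \code{\link{tally}}).
#' @param truth Per-read truth lineage data frame.
#' @param ranks Ranks to evaluate (default all six).
#' @return Data frame with one row per rank: counts plus sensitivity,
#'   precision, F1.
#' @export
evaluate_assignments <- function(assignments, truth,
                                 ranks = lineage_ranks()) {
    rows <- lapply(ranks, function(r) {
        cc <- tally(assignments, truth, r)
        m <- compute_metrics(cc)
        data.frame(rank = r, correct = cc$correct,
                   incorrect = cc$incorrect,
                   unclassified = cc$unclassified,
                   total_known = cc$total_known,
                   sensitivity = m$sensitivity, precision = m$precision,
                   f1 = m$f1, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
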