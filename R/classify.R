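#' @title End-to-end read classification
#' @description Each read's best-scoring genome fixes a candidate lineage;
#'   at every rank the calibration model converts the raw score and read
#'   length into an assignment probability, which is gated by the
#'   probability cutoff. In hybrid mode a first-pass exact k-mer
#'   classifier's assignments are kept verbatim and only its unclassified
#'   reads take the model-based assignments.
#' @name classify
NULL

#' Classifier configuration
#'
#' @param k Model order.
#' @param cutoff Assignment probability cutoff in \code{[0, 1]}
#'   (default 0.25; 0 disables thresholding so the top-scoring genome is
#'   always assigned).
#' @param delta Model pseudocount.
#' @param workers Parallel workers for scoring.
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(k = 10L, cutoff = 0.25, delta = 1,
                              workers = 1L) {
    stopifnot(cutoff >= 0, cutoff <= 1)
    structure(list(k = as.integer(k), cutoff = cutoff, delta = delta,
                   workers = as.integer(workers)),
              class = "classifier_config")
}

validate_score_models <- function(score_models, k) {
    for (r in lineage_ranks()) {
        m <- score_models[[r]]
        if (is.null(m) || !inherits(m, "score_model"))
            stop("missing score model for rank '", r, "' at order ", k)
        if (!is.na(m$order) && m$order != k)
            stop("score model for rank '", r, "' has order ", m$order,
                 ", classifier order is ", k)
    }
    invisible(TRUE)
}

#' Classify reads against a genome set
#'
#' The best-scoring genome per read (ties broken to the ascending genome
#' id) supplies the candidate taxon at every rank; each rank's probability
#' comes from that rank's calibration model applied to the raw score and
#' read length, and the rank is assigned iff the probability reaches the
#' cutoff and the lineage at that rank is not the unknown sentinel.
#' Unscorable reads are reported unassigned at all ranks.
#'
#' @param reads Record data frame of reads.
#' @param genome_paths Genome FASTA paths or named in-memory genomes.
#' @param lineage_map Lineage map covering every genome.
#' @param score_models Named list of \code{score_model}s, one per rank in
#'   \code{\link{lineage_ranks}()}, at the classifier's order.
#' @param config A \code{\link{classifier_config}}.
#' @return Assignment data frame: one row per read and rank with columns
#'   \code{read_id}, \code{rank}, \code{taxon}, \code{probability},
#'   \code{assigned}, \code{raw_score}, \code{genome_id}.
#' @export
classify_reads <- function(reads, genome_paths, lineage_map, score_models,
                           config = classifier_config()) {
    validate_score_models(score_models, config$k)
    tab <- score_reads_against_genomes(reads, genome_paths, config$k,
                                       delta = config$delta,
                                       workers = config$workers)
    missing <- setdiff(unique(tab$genome_id), lineage_map$genome_id)
    if (length(missing) > 0)
        stop("scored genome(s) missing from lineage map: ",
             paste(missing, collapse = ", "))
    best <- top_hits(tab, 1L)
    ranks <- lineage_ranks()
    parts <- vector("list", length(ranks))
    for (ri in seq_along(ranks)) {
        r <- ranks[ri]
        taxon <- lineage_map[[r]][match(best$genome_id,
                                        lineage_map$genome_id)]
        p <- predict_probability(score_models[[r]], best$raw_score,
                                 best$read_length)
        parts[[ri]] <- data.frame(
            read_id = best$read_id, rank = r, taxon = taxon,
            probability = p,
            assigned = p >= config$cutoff & taxon != lineage_sentinel(),
            raw_score = best$raw_score, genome_id = best$genome_id,
            stringsAsFactors = FALSE)
    }
    unscorable <- attr(tab, "unscorable")
    if (length(unscorable) > 0)
        parts[[length(parts) + 1L]] <- data.frame(
            read_id = rep(unscorable, each = length(ranks)),
            rank = rep(ranks, times = length(unscorable)),
            taxon = NA_character_, probability = NA_real_,
            assigned = FALSE, raw_score = NA_real_,
            genome_id = NA_character_, stringsAsFactors = FALSE)
    out <- do.call(rbind, parts)
    out <- out[order(match(out$read_id, reads$id),
                     match(out$rank, ranks)), ]
    rownames(out) <- NULL
    out
}

#' Merge first-pass classifications with model-based reassignments
#'
#' Reads the first pass classified (status \code{C}) keep their taxon
#' verbatim, with the probability marked not applicable; unclassified reads
#' (status \code{U}) take the second pass's per-rank assignments. The
#' output covers the union of read ids exactly once per read; a second-pass
#' assignment for a read the first pass already classified is an error.
#'
#' @param first_pass Data frame from \code{\link{parse_kraken_output}}.
#' @param second_pass Assignment data frame from
#'   \code{\link{classify_reads}} covering (a subset of) the status-U
#'   reads.
#' @return Assignment-style data frame with an extra \code{source} column
#'   (\code{"first"} or \code{"second"}); first-pass rows carry \code{NA}
#'   rank and probability.
#' @export
hybrid_merge <- function(first_pass, second_pass) {
    c_ids <- first_pass$read_id[first_pass$status == "C"]
    u_ids <- first_pass$read_id[first_pass$status == "U"]
    clash <- intersect(unique(second_pass$read_id), c_ids)
    if (length(clash) > 0)
        stop("second-pass assignment for read(s) already classified by ",
             "the first pass: ", paste(head(clash, 3), collapse = ", "))
    first_rows <- data.frame(
        read_id = c_ids,
        rank = rep(NA_character_, length(c_ids)),
        taxon = first_pass$taxon[match(c_ids, first_pass$read_id)],
        probability = rep(NA_real_, length(c_ids)),
        assigned = rep(TRUE, length(c_ids)),
        source = rep("first", length(c_ids)),
        stringsAsFactors = FALSE)
    sec <- second_pass[, c("read_id", "rank", "taxon", "probability",
                           "assigned")]
    sec$source <- rep("second", nrow(sec))
    uncovered <- setdiff(u_ids, unique(sec$read_id))
    unass <- if (length(uncovered) > 0) data.frame(
        read_id = uncovered, rank = NA_character_, taxon = NA_character_,
        probability = NA_real_, assigned = FALSE, source = "first",
        stringsAsFactors = FALSE) else NULL
    out <- rbind(first_rows, sec, unass)
    rownames(out) <- NULL
    out
}

#' Per-rank view of a hybrid assignment table
#'
#' First-pass rows carry a single taxon with no rank; for rank-level
#' benchmarking that taxon is taken at face value as the read's assignment
#' at the requested rank, while second-pass rows contribute their matching
#' rank rows.
#'
#' @param merged Output of \code{\link{hybrid_merge}}.
#' @param rank One of \code{\link{lineage_ranks}()}.
#' @return Data frame with \code{read_id}, \code{taxon}, \code{assigned}.
#' @export
hybrid_rank_assignments <- function(merged, rank) {
    first <- merged[merged$source == "first", ]
    second <- merged[merged$source == "second" & merged$rank == rank, ]
    out <- rbind(first[, c("read_id", "taxon", "assigned")],
                 second[, c("read_id", "taxon", "assigned")])
    rownames(out) <- NULL
    out
}
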