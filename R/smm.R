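#' @title Standard Markov models of genomes and read scoring
#' @description A genome is modeled by a fixed-order Markov chain: an
#'   initial k-mer distribution plus per-context transition probabilities,
#'   both pseudocount-smoothed so every probability is finite. A read's raw
#'   score is its total natural-log likelihood under the model, evaluated on
#'   both strands with the maximum retained. Models are built on the fly;
#'   nothing is persisted.
#' @name smm
NULL

validate_order <- function(k) {
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 14 || k != round(k))
        stop("model order k must be an integer in 1..14")
    if (k < 10 || k > 12)
        warning("model order ", k, " is outside the validated range 10-12",
                call. = FALSE)
    as.integer(k)
}

as_record_seqs <- function(genome) {
    if (is.data.frame(genome)) toupper(genome$seq)
    else toupper(as.character(genome))
}

#' Build a fixed-order Markov model of one genome
#'
#' Transition and initial count tables are initialized to the pseudocount
#' \code{delta} in every cell before counting, so the model is proper even
#' for unseen contexts; a genome shorter than \code{k + 1} yields the pure
#' pseudocount (uniform) model. Counts accumulate over all records of the
#' genome jointly (chromosome plus plasmids are one model), but no context
#' window spans a record boundary, and windows containing non-ACGT bases are
#' skipped.
#'
#' @param genome Record data frame (see \code{\link{read_fasta}}) or a
#'   character vector of sequences; all records together form one genome.
#' @param k Model order (validated range 10-12; 1-14 accepted).
#' @param delta Pseudocount added to every count cell; default 1 (Laplace).
#' @param genome_id Identifier carried on the model.
#' @return An object of class \code{smm_model} holding natural-log initial
#'   and transition probability tables.
#' @export
build_model <- function(genome, k, delta = 1, genome_id = "genome") {
    k <- validate_order(k)
    seqs <- as_record_seqs(genome)
    if (length(seqs) == 0) stop("genome has no records")
    tabs <- cpp_build_smm(seqs, k, delta)
    structure(list(genome_id = genome_id, k = k, delta = delta,
                   initial_log = tabs$initial_log,
                   transition_log = tabs$transition_log),
              class = "smm_model")
}

#' @export
print.smm_model <- function(x, ...) {
    cat("Order-", x$k, " Markov model of '", x$genome_id, "' (pseudocount ",
        x$delta, ", ", 4^x$k, " contexts)\n", sep = "")
    invisible(x)
}

#' Transition probabilities of a model for one context
#'
#' @param model An \code{smm_model}.
#' @param context A k-mer over ACGT.
#' @return Named numeric vector of \code{P(x | context)} for x in A,C,G,T.
#' @export
model_transition_probs <- function(model, context) {
    if (nchar(context) != model$k) stop("context must be a k-mer")
    idx <- encode_kmer(context)
    p <- exp(model$transition_log[(4L * idx + 1L):(4L * idx + 4L)])
    setNames(p, c("A", "C", "G", "T"))
}

encode_kmer <- function(kmer) {
    b <- match(strsplit(toupper(kmer), "")[[1]], c("A", "C", "G", "T")) - 1L
    if (anyNA(b)) stop("ambiguous base in k-mer")
    sum(b * 4^(rev(seq_along(b)) - 1))
}

#' Score a read against a Markov model
#'
#' The raw score is \code{log P(first k-mer) + sum log P(x | context)} over
#' every window of \code{k + 1} consecutive unambiguous bases, evaluated on
#' the forward and reverse-complement strands with the maximum returned.
#' A read with no run of \code{k + 1} unambiguous bases is unscorable and
#' yields \code{NA}.
#'
#' @param model An \code{smm_model}.
#' @param read A single sequence string or one-row record data frame.
#' @return Total natural-log likelihood (always <= 0), or \code{NA} if the
#'   read is unscorable.
#' @export
score_read <- function(model, read) {
    seq <- if (is.data.frame(read)) read$seq[1] else as.character(read)[1]
    cpp_score_read(model$initial_log, model$transition_log, model$k,
                   toupper(seq))
}

genome_id_from_path <- function(path) {
    sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
}

load_genomes <- function(genome_paths) {
    if (is.list(genome_paths) && !is.null(names(genome_paths)))
        return(lapply(genome_paths, as_record_seqs))
    ids <- names(genome_paths)
    if (is.null(ids)) ids <- vapply(genome_paths, genome_id_from_path, "")
    out <- lapply(genome_paths, function(p) {
        if (!file.exists(p)) stop("cannot read genome file: ", p)
        toupper(read_fasta(p)$seq)
    })
    names(out) <- ids
    out
}

#' Score reads against a set of genomes
#'
#' Reads are indexed in memory once; each worker streams its share of the
#' genomes through a single reusable model buffer that is reset as each
#' genome is modeled, so peak model memory does not grow with the number of
#' genomes. Results are keyed by (read, genome) and are identical for any
#' worker count.
#'
#' @param reads Record data frame of reads.
#' @param genome_paths Character vector of FASTA paths (optionally named by
#'   genome id; default id is the file name without extension), or a named
#'   list of in-memory genomes (each a record data frame or character
#'   vector).
#' @param k Model order.
#' @param delta Pseudocount.
#' @param workers Number of parallel workers (forked; results identical for
#'   any value).
#' @return A score table: data frame with columns \code{read_id},
#'   \code{genome_id}, \code{raw_score}, \code{read_length}, sorted within
#'   each read by decreasing score (ties by ascending genome id). Unscorable
#'   reads are excluded; their ids are kept in the \code{"unscorable"}
#'   attribute.
#' @export
score_reads_against_genomes <- function(reads, genome_paths, k, delta = 1,
                                        workers = 1L) {
    k <- validate_order(k)
    genomes <- load_genomes(genome_paths)
    if (length(genomes) < 1) stop("need at least one genome")
    seqs <- toupper(reads$seq)

    score_chunk <- function(idx)
        cpp_score_genomes(seqs, unname(genomes[idx]), k, delta)
    chunks <- split(seq_along(genomes),
                    rep_len(seq_len(max(1L, min(workers, length(genomes)))),
                            length(genomes)))
    mats <- if (length(chunks) > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(chunks, score_chunk, mc.cores = length(chunks))
    } else {
        lapply(chunks, score_chunk)
    }
    scores <- matrix(NA_real_, nrow = length(seqs), ncol = length(genomes))
    for (i in seq_along(chunks)) scores[, chunks[[i]]] <- mats[[i]]
    colnames(scores) <- names(genomes)

    unscorable <- reads$id[apply(is.na(scores), 1L, all)]
    if (length(unscorable) > 0)
        message(length(unscorable), " read(s) shorter than k+1 unambiguous ",
                "bases are unscorable and were excluded")
    keep <- !(reads$id %in% unscorable)
    if (!any(keep)) {
        warning("no scorable reads")
        tab <- data.frame(read_id = character(), genome_id = character(),
                          raw_score = numeric(), read_length = integer(),
                          stringsAsFactors = FALSE)
        attr(tab, "unscorable") <- unscorable
        return(tab)
    }
    tab <- data.frame(
        read_id = rep(reads$id[keep], times = length(genomes)),
        genome_id = rep(names(genomes), each = sum(keep)),
        raw_score = as.vector(scores[keep, , drop = FALSE]),
        read_length = rep(nchar(reads$seq[keep]), times = length(genomes)),
        stringsAsFactors = FALSE)
    tab <- tab[order(match(tab$read_id, reads$id), -tab$raw_score,
                     tab$genome_id), ]
    rownames(tab) <- NULL
    attr(tab, "unscorable") <- unscorable
    tab
}

#' Keep the top-scoring hits per read
#'
#' @param table Score table from \code{\link{score_reads_against_genomes}}.
#' @param n Number of hits to keep per read (default 50, the calibration
#'   training setting).
#' @return The score table restricted to the first \code{min(n, hits)}
#'   entries of each read, order preserved.
#' @export
top_hits <- function(table, n = 50L) {
    if (n < 1) stop("n must be >= 1")
    keep <- unlist(lapply(split(seq_len(nrow(table)), table$read_id),
                          function(ix) ix[seq_len(min(n, length(ix)))]),
                   use.names = FALSE)
    out <- table[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "unscorable") <- attr(table, "unscorable")
    out
}
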