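#' @title Calibration training sets
#' @description Labeled datasets for score calibration are built by
#'   sampling fragments of random length from the retained compositional
#'   clusters of each genome, scoring every fragment against the whole
#'   genome set, keeping the top hits, and labeling each (fragment, genome)
#'   pair by whether the genome's taxon at the target rank matches the
#'   fragment's source.
#' @name trainset
NULL

#' Training-set configuration
#'
#' Defaults are the production settings: fragments of 30-500 bp, datasets
#' of 250,000 fragments, ten datasets, top-50 hits retained per fragment.
#' Tests use far smaller values via the same knobs.
#'
#' @param min_len,max_len Fragment length range in bp.
#' @param reads_per_dataset Fragments per dataset.
#' @param n_datasets Number of datasets.
#' @param top_n Hits kept per fragment.
#' @param seed Optional integer seed recorded in the manifest.
#' @return A list of class \code{training_config}.
#' @export
training_config <- function(min_len = 30L, max_len = 500L,
                            reads_per_dataset = 250000L, n_datasets = 10L,
                            top_n = 50L, seed = NULL) {
    stopifnot(min_len > 0, min_len <= max_len, reads_per_dataset >= 0,
              n_datasets >= 1, top_n >= 1)
    structure(list(min_len = as.integer(min_len),
                   max_len = as.integer(max_len),
                   reads_per_dataset = as.integer(reads_per_dataset),
                   n_datasets = as.integer(n_datasets),
                   top_n = as.integer(top_n), seed = seed),
              class = "training_config")
}

#' Sample labeled fragments from retained clusters
#'
#' For each fragment a genome is chosen uniformly, a fragment length is
#' drawn uniformly from the configured range, a cluster is chosen with
#' probability proportional to its total length among clusters holding a
#' member segment long enough, a member segment proportionally to the
#' number of admissible start positions, and the start uniformly within the
#' segment, so fragments never span segment boundaries. Fragments
#' containing ambiguous bases are resampled a bounded number of times.
#'
#' @param clusters_by_genome Named list (by genome id); each entry a list
#'   with \code{seq} (the genome sequence) and \code{clusters} (retained
#'   clusters from \code{\link{filter_clusters}}).
#' @param lineage_map Lineage map data frame covering every genome.
#' @param config A \code{\link{training_config}}.
#' @param n_fragments Number of fragments (default
#'   \code{config$reads_per_dataset}).
#' @return Record-style data frame with columns \code{id}, \code{desc},
#'   \code{seq} plus \code{source_genome}.
#' @export
sample_fragments <- function(clusters_by_genome, lineage_map,
                             config = training_config(),
                             n_fragments = config$reads_per_dataset) {
    missing <- setdiff(names(clusters_by_genome), lineage_map$genome_id)
    if (length(missing) > 0)
        stop("genome(s) missing from lineage map: ",
             paste(missing, collapse = ", "))
    eligible <- vapply(clusters_by_genome, function(g)
        any(vapply(g$clusters, function(cl)
            any(vapply(cl$members, function(s)
                s$end - s$start >= config$min_len, logical(1))),
            logical(1))), logical(1))
    if (any(!eligible))
        warning("genome(s) with no segment of at least min_len skipped: ",
                paste(names(clusters_by_genome)[!eligible], collapse = ", "))
    pool <- names(clusters_by_genome)[eligible]
    if (length(pool) == 0 || n_fragments == 0)
        return(cbind(new_seq_records(), source_genome = character()))

    ids <- character(n_fragments)
    seqs <- character(n_fragments)
    src <- character(n_fragments)
    gids <- sample(pool, n_fragments, replace = TRUE)
    for (i in seq_len(n_fragments)) {
        g <- clusters_by_genome[[gids[i]]]
        frag <- NA_character_
        for (try in 1:20) {
            len <- sample(config$min_len:config$max_len, 1L)
            ok_cl <- which(vapply(g$clusters, function(cl)
                any(vapply(cl$members, function(s)
                    s$end - s$start >= len, logical(1))), logical(1)))
            if (length(ok_cl) == 0) next
            w <- vapply(g$clusters[ok_cl], `[[`, numeric(1), "total_length")
            cl <- g$clusters[[ok_cl[sample.int(length(ok_cl), 1L,
                                               prob = w)]]]
            segs <- Filter(function(s) s$end - s$start >= len, cl$members)
            nstart <- vapply(segs, function(s)
                s$end - s$start - len + 1L, 0L)
            s <- segs[[sample.int(length(segs), 1L, prob = nstart)]]
            a <- s$start + sample.int(s$end - s$start - len + 1L, 1L) - 1L
            cand <- substr(g$seq, a + 1L, a + len)
            if (!grepl("[^ACGT]", cand)) { frag <- cand; break }
        }
        if (is.na(frag)) next
        ids[i] <- sprintf("f%07d", i)
        seqs[i] <- frag
        src[i] <- gids[i]
    }
    keep <- nzchar(ids)
    out <- new_seq_records(ids[keep], "", seqs[keep])
    out$source_genome <- src[keep]
    out
}

#' Build a labeled training dataset at one rank and order
#'
#' Every fragment is scored against all genomes, the top hits retained, and
#' each retained (fragment, genome) pair becomes one example labeled by
#' whether the hit genome's taxon at \code{rank} equals the fragment
#' source's taxon at that rank. Pairs where either lineage carries the
#' sentinel at that rank are excluded.
#'
#' @param fragments Fragment data frame from \code{\link{sample_fragments}}.
#' @param genome_paths Genome FASTA paths or named in-memory genomes (see
#'   \code{\link{score_reads_against_genomes}}).
#' @param lineage_map Lineage map covering every scored genome and source.
#' @param rank One of \code{\link{lineage_ranks}()}.
#' @param k Model order.
#' @param config A \code{\link{training_config}}.
#' @param workers Parallel workers for scoring.
#' @return Data frame with columns \code{raw_score}, \code{read_length},
#'   \code{label}, \code{rank}, \code{order} (plus \code{fragment_id},
#'   \code{genome_id}).
#' @export
build_training_dataset <- function(fragments, genome_paths, lineage_map,
                                   rank, k, config = training_config(),
                                   workers = 1L) {
    if (!rank %in% lineage_ranks())
        stop("rank must be one of: ", paste(lineage_ranks(), collapse = ", "))
    tab <- score_reads_against_genomes(fragments, genome_paths, k,
                                       workers = workers)
    tab <- top_hits(tab, config$top_n)
    missing <- setdiff(unique(tab$genome_id), lineage_map$genome_id)
    if (length(missing) > 0)
        stop("scored genome(s) missing from lineage map: ",
             paste(missing, collapse = ", "))
    taxon_of <- setNames(lineage_map[[rank]], lineage_map$genome_id)
    src_taxon <- taxon_of[fragments$source_genome[
        match(tab$read_id, fragments$id)]]
    hit_taxon <- taxon_of[tab$genome_id]
    keep <- src_taxon != lineage_sentinel() & hit_taxon != lineage_sentinel()
    data.frame(fragment_id = tab$read_id[keep],
               genome_id = tab$genome_id[keep],
               raw_score = tab$raw_score[keep],
               read_length = tab$read_length[keep],
               label = unname(hit_taxon[keep] == src_taxon[keep]),
               rank = rank, order = as.integer(k),
               stringsAsFactors = FALSE)
}

#' Persist and reload a training dataset
#'
#' The dataset is a TSV of the example columns; a JSON manifest records the
#' seed and configuration for reproducibility.
#'
#' @param dataset Training dataset data frame.
#' @param path Output TSV path.
#' @param config The \code{\link{training_config}} used.
#' @param manifest_path Manifest path (default: \code{path} with
#'   \code{.manifest.json} appended).
#' @return Invisibly, \code{path}; \code{read_training_dataset} returns the
#'   parsed data frame.
#' @export
write_training_dataset <- function(dataset, path, config = NULL,
                                   manifest_path = paste0(path,
                                                          ".manifest.json")) {
    write.table(dataset, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(config))
        jsonlite::write_json(unclass(config), manifest_path,
                             auto_unbox = TRUE, null = "null")
    invisible(path)
}

#' @rdname write_training_dataset
#' @export
read_training_dataset <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    tab$label <- as.logical(tab$label)
    tab
}
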