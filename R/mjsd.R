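#' @title MJSD segmentation and clustering
#' @description Genomes are recursively segmented at the position of maximal
#'   Markovian Jensen-Shannon divergence (MJSD) between the two resulting
#'   subsequences, provided the split is statistically significant; the
#'   resulting compositionally homogeneous segments are then agglomeratively
#'   clustered. Divergence along a genome is computed with an incremental
#'   (reverse-calculation) entropy update so every nucleotide position is
#'   evaluated at linear cost.
#' @name mjsd
NULL

#' Segmentation and clustering configuration
#'
#' @param m Context order of the divergence statistic (default 2).
#' @param alpha_segment Significance level for accepting a split
#'   (default 0.05).
#' @param p_cluster Significance threshold below which two clusters are kept
#'   apart (default 1e-5).
#' @param min_segment_len Minimum segment length in bp; candidate splits are
#'   restricted so both sides respect it (default 5000, chosen so order-2
#'   context profiles are estimated from roughly a thousand or more
#'   observations per context row).
#' @param min_cluster_frac Clusters whose total length is strictly less than
#'   this fraction of the genome are discarded (default 1e-5, i.e. 0.001
#'   percent).
#' @return A list of class \code{segmentation_config}.
#' @export
segmentation_config <- function(m = 2L, alpha_segment = 0.05,
                                p_cluster = 1e-5, min_segment_len = 5000L,
                                min_cluster_frac = 1e-5) {
    stopifnot(m >= 0, m <= 8, alpha_segment >= 0, alpha_segment < 1,
              p_cluster > 0, p_cluster < 1, min_segment_len >= 1,
              min_cluster_frac >= 0)
    structure(list(m = as.integer(m), alpha_segment = alpha_segment,
                   p_cluster = p_cluster,
                   min_segment_len = as.integer(min_segment_len),
                   min_cluster_frac = min_cluster_frac),
              class = "segmentation_config")
}

#' Order-m context counts of a genome interval
#'
#' Counts every (m+1)-mer window whose emitted base lies in
#' \code{[start, end)} (0-based half-open); the m-base context may extend
#' before \code{start} but never before the sequence origin, which makes
#' profiles exactly additive across adjacent intervals. Windows containing
#' non-ACGT bases are skipped.
#'
#' @param seq A sequence string.
#' @param m Context order.
#' @param start,end 0-based half-open interval (defaults: whole sequence).
#' @return A \code{count_profile}: list with \code{m}, integer count matrix
#'   \code{counts} (4^m contexts x 4 next bases), and \code{total}.
#' @export
count_contexts <- function(seq, m, start = 0L, end = nchar(seq)) {
    counts <- cpp_count_contexts(toupper(seq), as.integer(m),
                                 as.integer(start), as.integer(end))
    new_count_profile(m, counts)
}

new_count_profile <- function(m, counts) {
    structure(list(m = as.integer(m), counts = counts,
                   total = sum(counts)), class = "count_profile")
}

#' Combine or subtract count profiles
#'
#' @param a,b \code{count_profile} objects of the same order.
#' @return A \code{count_profile} with cellwise summed (or subtracted)
#'   counts.
#' @export
profile_add <- function(a, b) {
    if (a$m != b$m) stop("profiles have different context orders")
    new_count_profile(a$m, a$counts + b$counts)
}

#' @rdname profile_add
#' @export
profile_subtract <- function(a, b) {
    if (a$m != b$m) stop("profiles have different context orders")
    out <- a$counts - b$counts
    if (any(out < 0)) stop("subtraction yields negative counts")
    new_count_profile(a$m, out)
}

#' Markov entropy of a count profile
#'
#' \code{H = -sum_w P(w) sum_x P(x|w) log2 P(x|w)} with maximum-likelihood
#' probabilities taken directly from the raw counts (no pseudocounts), in
#' bits per symbol; bounded by \code{[0, 2]} for a nucleotide alphabet.
#'
#' @param profile A \code{count_profile} with positive total.
#' @return Entropy in bits per symbol.
#' @export
markov_entropy <- function(profile) {
    if (profile$total <= 0) stop("empty profile")
    c <- profile$counts
    nw <- rowSums(c)
    s1 <- sum(ifelse(c > 0, c * log2(c), 0))
    s2 <- sum(ifelse(nw > 0, nw * log2(nw), 0))
    (s2 - s1) / profile$total
}

#' Markovian Jensen-Shannon divergence between two profiles
#'
#' \code{D = H(left + right) - wL * H(left) - wR * H(right)} with weights
#' equal to the profiles' count-total proportions; non-negative by the
#' concavity of entropy, and zero iff the empirical conditional
#' distributions coincide on every observed context.
#'
#' @param left,right \code{count_profile} objects of the same order, both
#'   with positive totals.
#' @return Divergence in bits per symbol.
#' @export
mjsd <- function(left, right) {
    if (left$m != right$m) stop("profiles have different context orders")
    if (left$total <= 0 || right$total <= 0) stop("empty profile")
    n <- left$total + right$total
    d <- markov_entropy(profile_add(left, right)) -
        (left$total / n) * markov_entropy(left) -
        (right$total / n) * markov_entropy(right)
    max(d, 0)
}

#' Analytic significance of an observed divergence
#'
#' The scaled statistic \code{x = 2 n ln(2) D} is referred to a chi-square
#' distribution with \code{3 * 4^m} degrees of freedom (the free parameters
#' separating two order-m Markov chains). When the divergence is the maximum
#' over \code{n_candidates} candidate split positions, a maximum-statistic
#' correction \code{p = 1 - F(x)^n_candidates} is applied under an
#' independence approximation, which is conservative for the strongly
#' correlated sliding-split statistics.
#'
#' @param D Divergence in bits per symbol.
#' @param n Total symbol (window) count the divergence was computed from.
#' @param m Context order.
#' @param n_candidates Number of candidate split positions examined.
#' @return p-value in \code{[0, 1]}.
#' @export
split_significance <- function(D, n, m, n_candidates = 1L) {
    if (!is.finite(n) || n < 0) stop("invalid n")
    if (n == 0 || D <= 0) return(1)
    x <- 2 * n * log(2) * D
    p1 <- pchisq(x, df = 3 * 4^m, lower.tail = FALSE)
    if (p1 >= 1) return(1)
    -expm1(n_candidates * log1p(-p1))
}

#' Monte-Carlo significance of the best split of an interval
#'
#' Permutation reference for \code{\link{split_significance}}: the interval
#' is shuffled \code{B} times, the maximal divergence recomputed for each
#' replicate, and the observed maximum referred to that null.
#'
#' @param seq Sequence string.
#' @param m Context order.
#' @param lo,hi 0-based half-open interval.
#' @param min_segment_len Minimum flank length for candidate splits.
#' @param B Number of shuffle replicates.
#' @return p-value \code{(1 + #{D* >= D}) / (B + 1)}.
#' @export
mc_split_significance <- function(seq, m, lo = 0L, hi = nchar(seq),
                                  min_segment_len = 100L, B = 100L) {
    obs <- best_split(seq, m, lo, hi, min_segment_len)
    if (!is.finite(obs$D)) return(1)
    chars <- strsplit(toupper(seq), "")[[1]]
    exceed <- 0L
    for (b in seq_len(B)) {
        perm <- paste(sample(chars[(lo + 1):hi]), collapse = "")
        d <- best_split(perm, m, 0L, hi - lo, min_segment_len)$D
        if (d >= obs$D) exceed <- exceed + 1L
    }
    (1 + exceed) / (B + 1)
}

#' Divergence at every admissible split of an interval
#'
#' Slides the split one nucleotide at a time, moving exactly one context
#' window between the left and right profiles per step and adjusting the
#' entropy sums incrementally, so the whole curve costs time linear in the
#' interval length.
#'
#' @inheritParams mc_split_significance
#' @return List with \code{positions}, \code{D} (bits per symbol at each
#'   position), \code{n_total}, \code{n_candidates}.
#' @export
mjsd_curve <- function(seq, m, lo = 0L, hi = nchar(seq),
                       min_segment_len = 100L) {
    cpp_mjsd_curve(toupper(seq), as.integer(m), as.integer(lo),
                   as.integer(hi), as.integer(min_segment_len))
}

#' Best split position of an interval
#'
#' @inheritParams mc_split_significance
#' @return List with \code{D}, \code{split} (0-based position; \code{NA} if
#'   the interval admits no split), \code{p_value}, \code{n_total},
#'   \code{n_candidates}. Ties in \code{D} break to the smallest position.
#' @export
best_split <- function(seq, m, lo = 0L, hi = nchar(seq),
                       min_segment_len = 100L) {
    curve <- mjsd_curve(seq, m, lo, hi, min_segment_len)
    if (curve$n_candidates == 0)
        return(list(D = 0, split = NA_integer_, p_value = 1,
                    n_total = 0, n_candidates = 0))
    i <- which.max(curve$D)
    list(D = curve$D[i], split = curve$positions[i],
         p_value = split_significance(curve$D[i], curve$n_total, m,
                                      curve$n_candidates),
         n_total = curve$n_total, n_candidates = curve$n_candidates)
}

#' Recursively segment a genome
#'
#' Binary recursion: the interval is split at its maximal-divergence
#' position whenever the associated p-value falls below
#' \code{alpha_segment}, and both halves are segmented in turn. The returned
#' segments tile \code{[0, L)} exactly, in coordinate order.
#'
#' @param seq Genome sequence string.
#' @param config A \code{\link{segmentation_config}}.
#' @return Object of class \code{mjsd_segments}: list of segments, each a
#'   list with \code{start}, \code{end}, \code{profile}; attributes
#'   \code{genome_length} and \code{m}.
#' @export
segment_genome <- function(seq, config = segmentation_config()) {
    seq <- toupper(seq)
    L <- nchar(seq)
    bounds <- list()
    stack <- list(c(0L, L))
    while (length(stack) > 0) {
        iv <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        lo <- iv[1]; hi <- iv[2]
        split <- NULL
        if (hi - lo >= 2L * config$min_segment_len &&
            config$alpha_segment > 0) {
            bs <- best_split(seq, config$m, lo, hi, config$min_segment_len)
            if (!is.na(bs$split) && bs$p_value < config$alpha_segment)
                split <- bs$split
        }
        if (is.null(split)) {
            bounds[[length(bounds) + 1L]] <- c(lo, hi)
        } else {
            # push right first so left is processed next (coordinate order)
            stack[[length(stack) + 1L]] <- c(split, hi)
            stack[[length(stack) + 1L]] <- c(lo, split)
        }
    }
    bounds <- bounds[order(vapply(bounds, `[`, 0L, 1L))]
    segs <- lapply(bounds, function(b)
        list(start = b[1], end = b[2],
             profile = count_contexts(seq, config$m, b[1], b[2])))
    structure(segs, class = "mjsd_segments", genome_length = L,
              m = config$m)
}

#' @export
print.mjsd_segments <- function(x, ...) {
    cat(length(x), "segment(s) tiling a", attr(x, "genome_length"),
        "bp genome (order", attr(x, "m"), "profiles)\n")
    invisible(x)
}

cluster_pair_pvalue <- function(a, b, m) {
    D <- mjsd(a$profile, b$profile)
    split_significance(D, a$profile$total + b$profile$total, m,
                       n_candidates = 1L)
}

#' Agglomeratively cluster segments by compositional similarity
#'
#' Starting from one cluster per segment, the pair with the largest
#' divergence p-value (computed on the clusters' summed profiles) is merged
#' repeatedly while that p-value exceeds \code{p_cluster}; merging stops
#' when every remaining pair differs significantly. Ties break to the pair
#' with the smallest member start coordinates.
#'
#' @param segments An \code{mjsd_segments} object.
#' @param config A \code{\link{segmentation_config}}.
#' @return List of clusters, each a list with \code{members} (list of
#'   segments), \code{profile} (summed), \code{total_length}.
#' @export
cluster_segments <- function(segments, config = segmentation_config()) {
    if (length(segments) < 1) stop("need at least one segment")
    m <- attr(segments, "m")
    cl <- lapply(segments, function(s)
        list(members = list(s), profile = s$profile,
             total_length = s$end - s$start, min_start = s$start))
    repeat {
        n <- length(cl)
        if (n < 2) break
        best <- NULL
        for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
            p <- cluster_pair_pvalue(cl[[i]], cl[[j]], m)
            key <- c(-p, min(cl[[i]]$min_start, cl[[j]]$min_start),
                     max(cl[[i]]$min_start, cl[[j]]$min_start))
            if (is.null(best) ||
                key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2]) ||
                (key[1] == best$key[1] && key[2] == best$key[2] &&
                 key[3] < best$key[3]))
                best <- list(i = i, j = j, p = p, key = key)
        }
        if (best$p <= config$p_cluster) break
        a <- cl[[best$i]]; b <- cl[[best$j]]
        merged <- list(members = c(a$members, b$members),
                       profile = profile_add(a$profile, b$profile),
                       total_length = a$total_length + b$total_length,
                       min_start = min(a$min_start, b$min_start))
        cl <- cl[-c(best$i, best$j)]
        cl[[length(cl) + 1L]] <- merged
    }
    cl <- cl[order(vapply(cl, `[[`, numeric(1), "min_start"))]
    lapply(cl, function(x) x[c("members", "profile", "total_length")])
}

#' Discard clusters that are tiny relative to the genome
#'
#' Clusters with total length strictly less than
#' \code{min_cluster_frac * genome_length} are removed; an optional
#' predicate (e.g. a contaminant screen) can reject further clusters.
#'
#' @param clusters List of clusters from \code{\link{cluster_segments}}.
#' @param genome_length Genome length in bp.
#' @param config A \code{\link{segmentation_config}}.
#' @param keep_fn Optional predicate \code{function(cluster) TRUE/FALSE};
#'   default keeps everything.
#' @return The retained clusters.
#' @export
filter_clusters <- function(clusters, genome_length,
                            config = segmentation_config(),
                            keep_fn = NULL) {
    if (genome_length <= 0) stop("genome_length must be > 0")
    # strict "less than" rule; the relative epsilon keeps lengths exactly
    # at the threshold from being lost to floating-point representation
    thr <- config$min_cluster_frac * genome_length * (1 - 1e-12)
    keep <- vapply(clusters, function(cl) cl$total_length >= thr,
                   logical(1))
    out <- clusters[keep]
    if (!is.null(keep_fn))
        out <- out[vapply(out, function(cl) isTRUE(keep_fn(cl)), logical(1))]
    out
}

#' Write segments and clusters as BED, plus a cluster summary TSV
#'
#' BED rows are 0-based half-open with the cluster index as the name
#' column.
#'
#' @param segments An \code{mjsd_segments} object.
#' @param clusters Cluster list covering those segments.
#' @param retained Cluster list after \code{\link{filter_clusters}}.
#' @param chrom Chromosome/record name for the BED rows.
#' @param bed_path,summary_path Output paths.
#' @return Invisibly, \code{bed_path}.
#' @export
write_cluster_bed <- function(segments, clusters, retained, chrom,
                              bed_path, summary_path) {
    rows <- list()
    for (ci in seq_along(clusters))
        for (s in clusters[[ci]]$members)
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = chrom, start = s$start, end = s$end,
                           name = paste0("cluster_", ci))
    bed <- do.call(rbind, rows)
    bed <- bed[order(bed$start), ]
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    kept_sig <- vapply(retained, function(cl)
        paste(vapply(cl$members, function(s)
            paste0(s$start, "-", s$end), ""), collapse = ","), "")
    summ <- data.frame(
        cluster_id = seq_along(clusters),
        n_segments = vapply(clusters, function(cl) length(cl$members), 0L),
        total_length = vapply(clusters, `[[`, numeric(1), "total_length"),
        retained = as.integer(vapply(clusters, function(cl)
            paste(vapply(cl$members, function(s)
                paste0(s$start, "-", s$end), ""), collapse = ",") %in%
                kept_sig, logical(1))))
    write.table(summ, summary_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(bed_path)
}
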