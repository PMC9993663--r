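# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's computational path: sequence
# counting is done with substring operations, likelihoods with plain
# per-position probability products, entropies by direct evaluation of the
# defining sum.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

all_words <- function(len) {
    if (len == 0) return("")
    g <- expand.grid(rep(list(c("A", "C", "G", "T")), len),
                     stringsAsFactors = FALSE)
    sort(apply(g[, rev(seq_len(len)), drop = FALSE], 1, paste,
               collapse = ""))
}

# window-level context counting by substring extraction (emitted base at
# 0-based position x in [start, end), context the m preceding bases)
oracle_count_contexts <- function(seq, m, start = 0, end = nchar(seq)) {
    counts <- matrix(0L, 4^m, 4)
    ch <- strsplit(seq, "")[[1]]
    bases <- c("A", "C", "G", "T")
    for (x in seq(max(start, m), end - 1)) {
        win <- ch[(x - m + 1):(x + 1)]
        if (any(!win %in% bases)) next
        b <- match(win[m + 1], bases)
        w <- 1L
        if (m > 0) {
            digits <- match(win[1:m], bases) - 1L
            w <- sum(digits * 4^(rev(seq_len(m)) - 1)) + 1L
        }
        counts[w, b] <- counts[w, b] + 1L
    }
    counts
}

# direct evaluation of H = -sum_w P(w) sum_x P(x|w) log2 P(x|w)
oracle_entropy <- function(counts) {
    N <- sum(counts)
    H <- 0
    for (w in seq_len(nrow(counts))) {
        nw <- sum(counts[w, ])
        if (nw == 0) next
        pw <- nw / N
        for (x in 1:4) {
            pxw <- counts[w, x] / nw
            if (pxw > 0) H <- H - pw * pxw * log2(pxw)
        }
    }
    H
}

# brute-force read log-likelihood: word tables built by substring counting,
# probability accumulated in log space term by term, both strands, max
oracle_score_read <- function(gseqs, k, delta, read) {
    count_words <- function(len) {
        tab <- setNames(rep(delta, 4^len), all_words(len))
        for (s in gseqs) {
            if (nchar(s) < len) next
            for (i in 1:(nchar(s) - len + 1)) {
                w <- substr(s, i, i + len - 1)
                if (!grepl("[^ACGT]", w)) tab[w] <- tab[w] + 1
            }
        }
        tab
    }
    km <- count_words(k)
    k1 <- count_words(k + 1)
    one_strand <- function(s) {
        ch <- strsplit(s, "")[[1]]
        valid <- ch %in% c("A", "C", "G", "T")
        logp <- 0
        any_win <- FALSE
        seen_init <- FALSE
        run <- 0
        for (i in seq_along(ch)) {
            if (!valid[i]) { run <- 0; next }
            run <- run + 1
            if (run >= k + 1) {
                w <- substr(s, i - k, i - 1)
                ctx_tot <- sum(k1[paste0(w, c("A", "C", "G", "T"))])
                logp <- logp + log(k1[paste0(w, ch[i])] / ctx_tot)
                any_win <- TRUE
            }
            if (run == k && !seen_init) {
                logp <- logp + log(km[substr(s, i - k + 1, i)] / sum(km))
                seen_init <- TRUE
            }
        }
        if (!any_win) NA_real_ else unname(logp)
    }
    f <- one_strand(read)
    r <- one_strand(revcomp_str(read))
    if (is.na(f) && is.na(r)) return(NA_real_)
    max(f, r, na.rm = TRUE)
}

# wrap truth intervals of a mosaic genome as an mjsd_segments object
segments_from_intervals <- function(seq, intervals, m) {
    structure(lapply(seq_len(nrow(intervals)), function(i)
        list(start = intervals$start[i], end = intervals$end[i],
             profile = count_contexts(seq, m, intervals$start[i],
                                      intervals$end[i]))),
        class = "mjsd_segments", genome_length = nchar(seq), m = as.integer(m))
}

# clusters_by_genome entry with a single whole-sequence cluster (for
# fragment-sampling tests that do not need real segmentation)
whole_seq_cluster <- function(seq) {
    list(seq = seq,
         clusters = list(list(
             members = list(list(start = 0L, end = nchar(seq))),
             total_length = nchar(seq))))
}

quiet_build_model <- function(...) suppressWarnings(build_model(...))

quiet_scores <- function(...)
    suppressMessages(suppressWarnings(score_reads_against_genomes(...)))
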