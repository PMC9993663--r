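#' @title Synthetic mosaic genomes and shotgun reads
#' @description Fixture generator: parameterized Markov sources, mosaic
#'   genomes assembled from blocks of different sources (host backbone plus
#'   compositionally divergent islands), a toy six-rank taxonomy, and
#'   shotgun reads with substitution errors. Everything any other module
#'   needs for testing is generated in code; no download is required.
#' @name synth
NULL

#' Draw a random Markov source
#'
#' Each transition row is a mixture \code{(1 - d) * uniform + d * g} of the
#' uniform distribution and a row-specific random (Dirichlet-like) draw,
#' optionally tilted toward a target GC content. \code{divergence = 0}
#' yields the exactly uniform matrix regardless of the random stream, so
#' any two such sources are identical; larger values give larger expected
#' divergence between independently drawn sources.
#'
#' @param m_gen Order of the generating chain (default 2; deliberately
#'   independent of the scoring order so tests never assume model-true
#'   data).
#' @param gc_bias Target GC proportion of the row tilt (default 0.5, no
#'   tilt).
#' @param divergence Mixing knob in \code{[0, 1]}.
#' @param label Source label.
#' @return A \code{markov_source}: list with \code{m_gen}, row-stochastic
#'   \code{matrix} (4^m_gen x 4), \code{label}.
#' @export
make_source <- function(m_gen = 2L, gc_bias = 0.5, divergence = 0.5,
                        label = "source") {
    stopifnot(divergence >= 0, divergence <= 1, gc_bias > 0, gc_bias < 1)
    nctx <- 4L^m_gen
    bias <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2,
              (1 - gc_bias) / 2)
    rows <- matrix(0, nctx, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    for (w in seq_len(nctx)) {
        g <- rgamma(4L, shape = 0.8)
        g <- g / sum(g)
        raw <- ((1 - divergence) * 0.25 + divergence * g) * bias
        rows[w, ] <- raw / sum(raw)
    }
    structure(list(m_gen = as.integer(m_gen), matrix = rows, label = label),
              class = "markov_source")
}

sample_chain <- function(source, len) {
    m <- source$m_gen
    P <- source$matrix
    cum <- P %*% upper.tri(diag(4), diag = TRUE)  # row-wise cumsum
    nctx <- nrow(P)
    drop_mod <- if (m > 0) 4L^(m - 1L) else 1L
    ctx <- sample.int(nctx, 1L) - 1L
    u <- runif(len)
    out <- integer(len)
    for (i in seq_len(len)) {
        b <- 1L + sum(u[i] > cum[ctx + 1L, 1:3])
        out[i] <- b
        ctx <- if (m > 0) (ctx %% drop_mod) * 4L + (b - 1L) else 0L
    }
    paste(c("A", "C", "G", "T")[out], collapse = "")
}

#' Generate a mosaic genome from a block specification
#'
#' @param spec List with \code{genome_id} and \code{blocks}, a list of
#'   \code{list(source = <markov_source>, length = <bp>)} entries laid down
#'   in order.
#' @return List with \code{record} (one-row record data frame) and
#'   \code{truth} (data frame of 0-based half-open component intervals with
#'   the source labels).
#' @export
generate_mosaic_genome <- function(spec) {
    stopifnot(length(spec$blocks) >= 1)
    pieces <- character(length(spec$blocks))
    starts <- integer(length(spec$blocks))
    pos <- 0L
    for (i in seq_along(spec$blocks)) {
        blk <- spec$blocks[[i]]
        stopifnot(blk$length >= 1)
        pieces[i] <- sample_chain(blk$source, blk$length)
        starts[i] <- pos
        pos <- pos + blk$length
    }
    truth <- data.frame(
        start = starts,
        end = starts + vapply(spec$blocks, function(b)
            as.integer(b$length), 0L),
        label = vapply(spec$blocks, function(b) b$source$label, ""))
    list(record = new_seq_records(spec$genome_id, "",
                                  paste(pieces, collapse = "")),
         truth = truth)
}

revcomp_chr <- function(s) {
    chartr("ACGTN", "TGCAN",
           vapply(s, function(x)
               paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

#' Simulate shotgun reads with substitution errors
#'
#' Reads are drawn with start positions uniform along each genome, genomes
#' chosen with probability proportional to their length, strand uniform,
#' and each base substituted with probability \code{error_rate} to a
#' uniformly chosen different base. Qualities, when written as FASTQ, are a
#' constant placeholder.
#'
#' @param genomes Named list of genome sequence strings (or record data
#'   frames).
#' @param n_reads Number of reads.
#' @param read_length A single length or a \code{c(min, max)} range sampled
#'   uniformly.
#' @param error_rate Per-base substitution probability in \code{[0, 1)}.
#' @return List with \code{reads} (record data frame) and \code{truth}
#'   (data frame: \code{read_id}, \code{genome_id}, \code{start} (0-based),
#'   \code{strand}).
#' @export
simulate_reads <- function(genomes, n_reads, read_length = 100L,
                           error_rate = 0) {
    stopifnot(error_rate >= 0, error_rate < 1)
    seqs <- vapply(genomes, function(g)
        if (is.data.frame(g)) g$seq[1] else as.character(g)[1], "")
    lens <- nchar(seqs)
    maxread <- max(read_length)
    if (any(lens <= maxread))
        stop("every genome must be longer than the maximum read length")
    gid <- sample(names(seqs), n_reads, replace = TRUE, prob = lens)
    rl <- if (length(read_length) == 2L)
        sample(read_length[1]:read_length[2], n_reads, replace = TRUE)
    else rep(as.integer(read_length), n_reads)
    start <- vapply(seq_len(n_reads), function(i)
        sample.int(lens[gid[i]] - rl[i] + 1L, 1L) - 1L, 0L)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    frag <- substring(seqs[gid], start + 1L, start + rl)
    frag[strand == "-"] <- revcomp_chr(frag[strand == "-"])
    if (error_rate > 0) {
        frag <- vapply(frag, function(s) {
            ch <- strsplit(s, "")[[1]]
            hit <- which(runif(length(ch)) < error_rate)
            for (i in hit)
                ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
            paste(ch, collapse = "")
        }, "", USE.NAMES = FALSE)
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    list(reads = new_seq_records(ids, "", frag),
         truth = data.frame(read_id = ids, genome_id = unname(gid),
                            start = start, strand = strand,
                            stringsAsFactors = FALSE))
}

#' Stationary GC content of a Markov source
#'
#' Power-iterates the induced context chain to its stationary distribution
#' and returns the expected G+C emission probability.
#'
#' @param source A \code{markov_source}.
#' @return Stationary GC proportion.
#' @export
source_stationary_gc <- function(source) {
    m <- source$m_gen
    P <- source$matrix
    nctx <- nrow(P)
    if (m == 0) return(P[1, "C"] + P[1, "G"])
    drop_mod <- 4L^(m - 1L)
    Tm <- matrix(0, nctx, nctx)
    for (w in seq_len(nctx)) for (b in 1:4) {
        w2 <- ((w - 1L) %% drop_mod) * 4L + (b - 1L) + 1L
        Tm[w, w2] <- Tm[w, w2] + P[w, b]
    }
    pi <- rep(1 / nctx, nctx)
    for (it in 1:500) {
        nxt <- as.vector(pi %*% Tm)
        if (max(abs(nxt - pi)) < 1e-13) { pi <- nxt; break }
        pi <- nxt
    }
    sum(pi * (P[, "C"] + P[, "G"]))
}

#' Simulate a small labeled community
#'
#' Convenience wrapper: draws \code{n_genomes} well-separated sources,
#' generates one single-source genome per taxon, and builds a toy lineage
#' map in which every genome carries its own taxon at every rank (a panel
#' of distantly related organisms, so both label classes are present in
#' calibration training data at every rank).
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Length of each genome in bp.
#' @param divergence Source divergence knob.
#' @param m_gen Generating chain order.
#' @return List with \code{genomes} (named list of sequence strings),
#'   \code{records}, \code{lineage_map}, \code{sources}.
#' @export
simulate_community <- function(n_genomes = 4L, genome_length = 60000L,
                               divergence = 0.8, m_gen = 2L) {
    sources <- lapply(seq_len(n_genomes), function(i)
        make_source(m_gen = m_gen, divergence = divergence,
                    label = sprintf("G%02d", i)))
    ids <- sprintf("G%02d", seq_len(n_genomes))
    genomes <- setNames(vector("list", n_genomes), ids)
    for (i in seq_len(n_genomes))
        genomes[[i]] <- generate_mosaic_genome(list(
            genome_id = ids[i],
            blocks = list(list(source = sources[[i]],
                               length = genome_length))))$record$seq
    lineage <- data.frame(
        genome_id = ids, phylum = paste0("Phy", seq_len(n_genomes)),
        class = paste0("Cla", seq_len(n_genomes)),
        order = paste0("Ord", seq_len(n_genomes)),
        family = paste0("Fam", seq_len(n_genomes)),
        genus = paste0("Gen", seq_len(n_genomes)),
        species = paste0("Spe", seq_len(n_genomes)),
        stringsAsFactors = FALSE)
    records <- do.call(rbind, lapply(ids, function(id)
        new_seq_records(id, "", genomes[[id]])))
    list(genomes = genomes, records = records, lineage_map = lineage,
         sources = sources)
}
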