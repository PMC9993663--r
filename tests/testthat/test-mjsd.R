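test_that("context counting matches hand counts and the substring oracle", {
    p <- count_contexts("AAAA", 1)
    expect_equal(p$counts[1, 1], 3L)
    expect_equal(p$total, 3L)

    pN <- count_contexts("AANAA", 1)
    expect_equal(pN$total, 2L)  # windows touching N are skipped

    set.seed(31)
    for (m in 0:2) {
        s <- rand_dna(300)
        expect_identical(count_contexts(s, m)$counts,
                         oracle_count_contexts(s, m))
        a <- count_contexts(s, m, 0, 150)
        b <- count_contexts(s, m, 150, 300)
        expect_identical(profile_add(a, b)$counts,
                         count_contexts(s, m)$counts)
    }
    expect_error(count_contexts("ACG", 2, 0, 2), "shorter")
    expect_error(profile_add(count_contexts("ACGT", 0),
                             count_contexts("ACGT", 1)), "orders")
})

test_that("profile self-addition doubles every cell", {
    p <- count_contexts("ACGTACGT", 0)
    expect_identical(profile_add(p, p)$counts, p$counts * 2L)
})

test_that("Markov entropy hits its limits and the formula oracle", {
    expect_equal(markov_entropy(count_contexts(strrep("A", 50), 0)), 0)
    expect_equal(markov_entropy(count_contexts(strrep("ACGT", 25), 0)), 2,
                 tolerance = 1e-12)
    s <- strrep("ACGT", 5)
    expect_equal(markov_entropy(count_contexts(s, 2)),
                 oracle_entropy(oracle_count_contexts(s, 2)),
                 tolerance = 1e-12)
    set.seed(32)
    for (m in 0:2) {
        s <- rand_dna(500)
        p <- count_contexts(s, m)
        H <- markov_entropy(p)
        expect_equal(H, oracle_entropy(p$counts), tolerance = 1e-12)
        expect_gte(H, 0); expect_lte(H, 2)
    }
    expect_error(markov_entropy(count_contexts("NNNNN", 0)), "empty")
})

test_that("MJSD is zero on identical profiles, symmetric, non-negative", {
    p <- count_contexts(rand_dna(200), 1)
    expect_equal(mjsd(p, p), 0)
    # hand case: all-A versus all-C at order 0 diverge by exactly 1 bit
    a <- count_contexts(strrep("A", 100), 0)
    c <- count_contexts(strrep("C", 100), 0)
    expect_equal(mjsd(a, c), 1, tolerance = 1e-12)
    set.seed(33)
    for (i in 1:25) {
        m <- sample(0:2, 1)
        x <- count_contexts(rand_dna(sample(50:400, 1)), m)
        y <- count_contexts(rand_dna(sample(50:400, 1)), m)
        expect_equal(mjsd(x, y), mjsd(y, x))
        expect_gte(mjsd(x, y), 0)
    }
})

test_that("best split lands on a planted order-0 boundary", {
    s <- paste0(strrep("A", 500), strrep("C", 500))
    bs <- best_split(s, 0, min_segment_len = 100)
    expect_equal(bs$split, 500L)
    expect_equal(bs$D, 1, tolerance = 1e-9)
    expect_lt(bs$p_value, 1e-10)
    # brute-force argmax agrees
    fresh <- vapply(100:899, function(pos)
        mjsd(count_contexts(s, 0, 0, pos),
             count_contexts(s, 0, pos, 1000)), 0)
    expect_equal(bs$split, (100:899)[which.max(fresh)])
})

test_that("incremental divergence equals fresh recomputation everywhere", {
    set.seed(34)
    for (i in 1:6) {
        m <- sample(0:2, 1)
        s <- rand_dna(sample(500:2000, 1))
        cur <- mjsd_curve(s, m, min_segment_len = 50)
        fresh <- vapply(cur$positions, function(pos)
            mjsd(count_contexts(s, m, 0, pos),
                 count_contexts(s, m, pos, nchar(s))), 0)
        expect_lt(max(abs(cur$D - fresh)), 1e-9)
    }
})

test_that("intervals too short for two flanks yield a no-split result", {
    bs <- best_split(rand_dna(150), 0, min_segment_len = 100)
    expect_true(is.na(bs$split))
    expect_equal(bs$p_value, 1)
})

test_that("split significance is 1 at D = 0 and decreases in D", {
    expect_equal(split_significance(0, 1000, 2), 1)
    d <- seq(0.001, 0.05, by = 0.001)
    p <- vapply(d, split_significance, 0, n = 5000, m = 1,
                n_candidates = 100)
    expect_true(all(diff(p) <= 0))
    expect_error(split_significance(0.1, NA, 1), "invalid n")
})

test_that("analytic significance is conservative on homogeneous nulls and
           agrees with Monte Carlo on a strong planted split", {
    set.seed(35)
    rej <- 0L
    for (i in 1:40) {
        s <- rand_dna(4000)
        if (best_split(s, 1, min_segment_len = 300)$p_value < 0.05)
            rej <- rej + 1L
    }
    # the independence max-correction over-corrects, so observed type-I
    # stays at or below the nominal level
    expect_lte(rej / 40, 0.05)

    two <- paste0(strrep("A", 2000), strrep("C", 2000))
    expect_lt(best_split(two, 0, min_segment_len = 300)$p_value, 1e-6)
    expect_lte(mc_split_significance(two, 0, min_segment_len = 300, B = 49),
               0.02)
})

test_that("segmentation tiles the genome and conserves profiles exactly", {
    set.seed(36)
    a <- make_source(divergence = 0.9, label = "A")
    b <- make_source(divergence = 0.9, label = "B")
    g <- generate_mosaic_genome(list(genome_id = "g", blocks = list(
        list(source = a, length = 8000), list(source = b, length = 8000),
        list(source = a, length = 8000))))
    cfg <- segmentation_config(min_segment_len = 2000)
    segs <- segment_genome(g$record$seq, cfg)
    starts <- vapply(segs, `[[`, numeric(1), "start")
    ends <- vapply(segs, `[[`, numeric(1), "end")
    expect_equal(starts[1], 0)
    expect_equal(ends[length(segs)], 24000)
    expect_equal(starts[-1], ends[-length(segs)])  # no gaps or overlaps
    total <- Reduce(profile_add, lapply(segs, `[[`, "profile"))
    expect_identical(total$counts, count_contexts(g$record$seq, 2)$counts)
    expect_gte(length(segs), 2)
})

test_that("a zero split level never segments; homogeneous genomes stay
           whole at a stringent level", {
    set.seed(37)
    src <- make_source(divergence = 0.8)
    g <- generate_mosaic_genome(list(genome_id = "h", blocks = list(
        list(source = src, length = 20000))))$record$seq
    expect_length(segment_genome(g, segmentation_config(alpha_segment = 0,
                                                        min_segment_len = 2000)), 1L)
    ones <- sum(vapply(1:10, function(i) {
        gi <- generate_mosaic_genome(list(genome_id = "h", blocks = list(
            list(source = src, length = 15000))))$record$seq
        length(segment_genome(gi, segmentation_config(
            alpha_segment = 1e-6, min_segment_len = 2000))) == 1L
    }, logical(1)))
    expect_gte(ones / 10, 0.9)
})

test_that("alternating-source segments cluster into the two sources", {
    set.seed(38)
    a <- make_source(divergence = 0.9, label = "A")
    b <- make_source(divergence = 0.9, label = "B")
    g <- generate_mosaic_genome(list(genome_id = "alt",
        blocks = lapply(1:6, function(i)
            list(source = if (i %% 2) a else b, length = 10000))))
    segs <- segments_from_intervals(g$record$seq, g$truth, 2)
    cl <- cluster_segments(segs, segmentation_config())
    expect_length(cl, 2L)
    starts <- lapply(cl, function(c_)
        sort(vapply(c_$members, `[[`, numeric(1), "start")))
    expect_setequal(starts, list(c(0, 20000, 40000), c(10000, 30000, 50000)))
    # summed profile equals the exact member sum
    for (c_ in cl)
        expect_identical(c_$profile$counts,
                         Reduce(profile_add,
                                lapply(c_$members, `[[`, "profile"))$counts)
})

test_that("single segments and degenerate thresholds collapse clustering", {
    set.seed(39)
    s <- rand_dna(3000)
    segs <- segments_from_intervals(
        s, data.frame(start = 0L, end = 3000L), 2)
    expect_length(cluster_segments(segs, segmentation_config()), 1L)

    # weakly different halves merge when the keep-apart threshold vanishes
    segs2 <- segments_from_intervals(
        s, data.frame(start = c(0L, 1500L), end = c(1500L, 3000L)), 2)
    expect_length(cluster_segments(
        segs2, segmentation_config(p_cluster = 1e-300)), 1L)
})

test_that("tiny clusters are discarded by the strict size rule", {
    mk <- function(len) list(members = list(list(start = 0, end = len)),
                             profile = NULL, total_length = len)
    cfg <- segmentation_config()  # min_cluster_frac 1e-5
    cl <- list(mk(40), mk(50), mk(60))
    kept <- filter_clusters(cl, 5e6, cfg)  # threshold = 50 bp
    expect_equal(vapply(kept, `[[`, numeric(1), "total_length"), c(50, 60))
    # the optional predicate hook can reject further clusters
    kept2 <- filter_clusters(cl, 5e6, cfg,
                             keep_fn = function(c_) c_$total_length > 55)
    expect_equal(vapply(kept2, `[[`, numeric(1), "total_length"), 60)
    expect_error(filter_clusters(cl, 0, cfg), "> 0")
})
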