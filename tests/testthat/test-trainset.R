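test_that("fragment lengths stay inside the configured range", {
    set.seed(41)
    cbg <- list(G1 = whole_seq_cluster(rand_dna(5000)))
    lm <- data.frame(genome_id = "G1", phylum = "P", class = "C",
                     order = "O", family = "F", genus = "G", species = "S")
    cfg <- training_config(reads_per_dataset = 400)
    frags <- sample_fragments(cbg, lm, cfg)
    expect_equal(nrow(frags), 400L)
    expect_true(all(nchar(frags$seq) >= 30 & nchar(frags$seq) <= 500))
    expect_true(all(frags$source_genome == "G1"))

    expect_equal(nrow(sample_fragments(cbg, lm, cfg, n_fragments = 0)), 0L)
})

test_that("clusters are sampled proportionally to their total length", {
    set.seed(42)
    seq <- rand_dna(12000)
    cbg <- list(G1 = list(seq = seq, clusters = list(
        list(members = list(list(start = 0L, end = 6000L)),
             total_length = 6000L),
        list(members = list(list(start = 6000L, end = 9000L)),
             total_length = 3000L))))
    lm <- data.frame(genome_id = "G1", phylum = "P", class = "C",
                     order = "O", family = "F", genus = "G", species = "S")
    cfg <- training_config(min_len = 100, max_len = 100,
                           reads_per_dataset = 10000)
    frags <- sample_fragments(cbg, lm, cfg)
    # recover which cluster each fragment came from by its start offset
    starts <- vapply(frags$seq, function(f)
        as.integer(regexpr(f, seq, fixed = TRUE)), 0L)
    from_first <- sum(starts <= 5901)
    chi <- chisq.test(c(from_first, nrow(frags) - from_first),
                      p = c(2 / 3, 1 / 3))
    expect_gt(chi$p.value, 0.001)
})

test_that("fragments never span segment boundaries and avoid N runs", {
    set.seed(43)
    left <- rand_dna(1000)
    right <- rand_dna(1000)
    seq <- paste0(left, strrep("N", 50), right)
    cbg <- list(G1 = list(seq = seq, clusters = list(
        list(members = list(list(start = 0L, end = 1000L),
                            list(start = 1050L, end = 2050L)),
             total_length = 2000L))))
    lm <- data.frame(genome_id = "G1", phylum = "P", class = "C",
                     order = "O", family = "F", genus = "G", species = "S")
    frags <- sample_fragments(cbg, lm,
                              training_config(reads_per_dataset = 300))
    expect_false(any(grepl("N", frags$seq)))
    inside <- vapply(frags$seq, function(f)
        grepl(f, left, fixed = TRUE) || grepl(f, right, fixed = TRUE),
        logical(1))
    expect_true(all(inside))
})

test_that("genomes with no segment long enough are skipped with warning", {
    cbg <- list(G1 = whole_seq_cluster(rand_dna(2000)),
                G2 = list(seq = rand_dna(100), clusters = list(
                    list(members = list(list(start = 0L, end = 20L)),
                         total_length = 20L))))
    lm <- data.frame(genome_id = c("G1", "G2"), phylum = "P", class = "C",
                     order = "O", family = "F", genus = "G",
                     species = c("S1", "S2"))
    expect_warning(
        frags <- sample_fragments(cbg, lm,
                                  training_config(reads_per_dataset = 50)),
        "skipped.*G2")
    expect_true(all(frags$source_genome == "G1"))
})

test_that("training datasets carry one labeled example per retained hit", {
    set.seed(44)
    comm <- simulate_community(n_genomes = 3, genome_length = 8000,
                               divergence = 0.9)
    cbg <- lapply(comm$genomes, whole_seq_cluster)
    cfg <- training_config(reads_per_dataset = 60, top_n = 50)
    frags <- sample_fragments(cbg, comm$lineage_map, cfg)
    ds <- suppressWarnings(suppressMessages(build_training_dataset(
        frags, comm$genomes, comm$lineage_map, "genus", 6, cfg)))
    # 3 genomes < top_n: every fragment contributes 3 examples
    expect_equal(nrow(ds), 3L * nrow(frags))
    expect_setequal(unique(ds$rank), "genus")
    expect_equal(unique(ds$order), 6L)
    expect_true(all(ds$read_length >= 30 & ds$read_length <= 500))
    # well-separated sources: the top-scoring hit is almost always correct
    top1 <- ds[!duplicated(ds$fragment_id), ]
    expect_gte(mean(top1$label), 0.9)

    cfg2 <- training_config(reads_per_dataset = 60, top_n = 2)
    ds2 <- suppressWarnings(suppressMessages(build_training_dataset(
        frags, comm$genomes, comm$lineage_map, "genus", 6, cfg2)))
    expect_equal(nrow(ds2), 2L * nrow(frags))

    expect_error(build_training_dataset(frags, comm$genomes,
                                        comm$lineage_map, "kingdom", 6,
                                        cfg),
                 "rank must be")
})

test_that("sentinel lineages are excluded from training pairs", {
    set.seed(45)
    comm <- simulate_community(n_genomes = 3, genome_length = 8000,
                               divergence = 0.9)
    comm$lineage_map$species[2] <- lineage_sentinel()
    cbg <- lapply(comm$genomes, whole_seq_cluster)
    cfg <- training_config(reads_per_dataset = 60, top_n = 50)
    frags <- sample_fragments(cbg, comm$lineage_map, cfg)
    ds <- suppressWarnings(suppressMessages(build_training_dataset(
        frags, comm$genomes, comm$lineage_map, "species", 6, cfg)))
    g2 <- comm$lineage_map$genome_id[2]
    expect_false(any(ds$genome_id == g2))
    expect_false(any(frags$source_genome[match(ds$fragment_id,
                                               frags$id)] == g2))
})

test_that("fragment sampling and labeling are deterministic under a seed", {
    comm <- local({ set.seed(46)
        simulate_community(n_genomes = 2, genome_length = 6000) })
    cbg <- lapply(comm$genomes, whole_seq_cluster)
    cfg <- training_config(reads_per_dataset = 40, top_n = 50)
    run <- function() {
        set.seed(47)
        frags <- sample_fragments(cbg, comm$lineage_map, cfg)
        suppressWarnings(suppressMessages(build_training_dataset(
            frags, comm$genomes, comm$lineage_map, "genus", 6, cfg)))
    }
    expect_identical(run(), run())
})

test_that("more unrelated genomes dilute the true-label fraction", {
    set.seed(48)
    big <- simulate_community(n_genomes = 8, genome_length = 6000,
                              divergence = 0.8)
    small_ids <- big$lineage_map$genome_id[1:2]
    cbg <- lapply(big$genomes[small_ids], whole_seq_cluster)
    cfg <- training_config(reads_per_dataset = 50, top_n = 50)
    frags <- sample_fragments(cbg, big$lineage_map, cfg)
    frac_of <- function(genomes) {
        ds <- suppressWarnings(suppressMessages(build_training_dataset(
            frags, genomes, big$lineage_map, "genus", 6, cfg)))
        mean(ds$label)
    }
    expect_gt(frac_of(big$genomes[small_ids]), frac_of(big$genomes))
})

test_that("training datasets round-trip through TSV with a manifest", {
    ds <- data.frame(fragment_id = "f1", genome_id = "G1",
                     raw_score = -123.456, read_length = 100L,
                     label = TRUE, rank = "genus", order = 10L)
    path <- withr::local_tempfile(fileext = ".tsv")
    cfg <- training_config(reads_per_dataset = 10, seed = 7L)
    write_training_dataset(ds, path, config = cfg)
    back <- read_training_dataset(path)
    expect_equal(back$raw_score, ds$raw_score)
    expect_identical(back$label, TRUE)
    manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
    expect_equal(manifest$seed, 7L)
    expect_equal(manifest$reads_per_dataset, 10L)
})
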