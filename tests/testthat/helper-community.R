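# Shared end-to-end community fixture: 4 well-separated genomes, reads,
# calibration models at order 10, and classification at cutoff 0. Built
# once per session and reused by the pipeline-level tests.
e2e_fixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        set.seed(101)
        comm <- simulate_community(n_genomes = 4, genome_length = 60000,
                                   divergence = 0.8)
        sim <- simulate_reads(comm$genomes, n_reads = 2000,
                              read_length = 100, error_rate = 0)
        cfg <- segmentation_config()
        cbg <- lapply(comm$genomes, function(s) {
            segs <- segment_genome(s, cfg)
            list(seq = s,
                 clusters = filter_clusters(cluster_segments(segs, cfg),
                                            nchar(s), cfg))
        })
        tcfg <- training_config(reads_per_dataset = 5000, top_n = 50)
        frags <- sample_fragments(cbg, comm$lineage_map, tcfg)
        models <- setNames(lapply(lineage_ranks(), function(r) {
            ds <- build_training_dataset(frags, comm$genomes,
                                         comm$lineage_map, r, 10, tcfg)
            fit_logistic(ds, penalty = "l2", C = 1, tol = 1e-7,
                         rank = r, order = 10)
        }), lineage_ranks())
        truth <- cbind(
            read_id = sim$truth$read_id,
            comm$lineage_map[match(sim$truth$genome_id,
                                   comm$lineage_map$genome_id),
                             lineage_ranks()])
        rownames(truth) <- NULL
        assignments <- suppressMessages(classify_reads(
            sim$reads, comm$genomes, comm$lineage_map, models,
            classifier_config(k = 10, cutoff = 0)))
        cache <<- list(comm = comm, sim = sim, models = models,
                       truth = truth, assignments = assignments)
        cache
    }
})
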