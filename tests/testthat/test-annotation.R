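make_gff <- function(lines) {
    path <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", lines), path)
    path
}

test_that("GFF3 gene models are parsed with exon/intron structure", {
    path <- make_gff(c(
        "chr1\tsrc\tgene\t101\t1100\t.\t+\t.\tID=g1",
        "chr1\tsrc\tmRNA\t101\t1100\t.\t+\t.\tID=g1.t1;Parent=g1",
        "chr1\tsrc\texon\t101\t400\t.\t+\t.\tID=g1.t1.e1;Parent=g1.t1",
        "chr1\tsrc\texon\t601\t1100\t.\t+\t.\tID=g1.t1.e2;Parent=g1.t1"))
    m <- read_gene_models(path)
    expect_equal(nrow(m), 1L)
    expect_equal(m$start, 100L)          # 0-based half-open
    expect_equal(m$end, 1100L)
    expect_equal(m$type, "mRNA")
    expect_equal(m$n_exons, 2L)
    expect_equal(m$mean_intron_length, 200)
    expect_equal(m$mean_exon_length, (300 + 500) / 2)
})

test_that("protein_coding_gene is normalised and longest transcript kept", {
    path <- make_gff(c(
        "chr1\tsrc\tprotein_coding_gene\t1\t2000\t.\t+\t.\tID=g1",
        "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=g1.t1;Parent=g1",
        "chr1\tsrc\texon\t1\t900\t.\t+\t.\tID=e1;Parent=g1.t1",
        "chr1\tsrc\tmRNA\t1\t2000\t.\t+\t.\tID=g1.t2;Parent=g1",
        "chr1\tsrc\texon\t1\t2000\t.\t+\t.\tID=e2;Parent=g1.t2"))
    m <- read_gene_models(path)
    expect_equal(nrow(m), 1L)
    expect_equal(m$n_exons, 1L)
    expect_equal(m$mean_exon_length, 2000)
})

test_that("malformed parentage and out-of-bounds coordinates are errors", {
    orphan <- make_gff(c(
        "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
        "chr1\tsrc\texon\t1\t500\t.\t+\t.\tID=e1;Parent=missing"))
    expect_error(read_gene_models(orphan), "Parent")

    oob <- make_gff("chr1\tsrc\tgene\t1\t9000\t.\t+\t.\tID=g1")
    expect_error(read_gene_models(oob, seqlengths = c(chr1 = 5000L)),
                 "outside scaffold bounds.*g1")
})

test_that("a gene split between two windows is counted in both", {
    path <- make_gff(c(
        "chr1\tsrc\tgene\t2001\t8000\t.\t+\t.\tID=g1",
        "chr1\tsrc\tmRNA\t2001\t8000\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\tsrc\texon\t2001\t8000\t.\t+\t.\tID=e1;Parent=t1"))
    m <- read_gene_models(path)
    grid <- window_grid(c(chr1 = 10000L), window_size = 5000)
    tr <- gene_density_tracks(m, grid)
    expect_equal(tr$mRNA_annotations, c(1, 1))
    expect_equal(tr$gene_length, c(6000, 6000))
})

test_that("empty annotation yields all-zero tracks", {
    grid <- window_grid(c(chr1 = 10000L), window_size = 5000)
    empty <- data.frame(id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character(), type = character())
    tr <- gene_density_tracks(empty, grid)
    expect_true(all(vapply(tr, function(v) all(v == 0), logical(1))))
    expect_equal(length(tr$mRNA_annotations), 2L)
})

test_that("gene density tracks match a brute-force interval scan", {
    set.seed(13)
    sim <- simulate_genome(list(chrA = list(segment_spec(
        "seg", 2e5, gc = 0.4, genes_per_10kb = 3))), seed = 13)
    grid <- window_grid(sim$assembly, 5000)
    tr <- gene_density_tracks(sim$genes, grid)
    o <- o_gene_tracks(sim$genes, grid)
    expect_equal(tr$mRNA_annotations, o$count)
    expect_equal(tr$gene_length, o$mean_len)
    # conservation: total window counts >= gene count, equality iff none split
    n_split <- sum(sim$genes$start %/% 5000 != (sim$genes$end - 1) %/% 5000)
    expect_equal(sum(tr$mRNA_annotations), nrow(sim$genes) + n_split)
})

test_that("bedgraph re-binning is a length-weighted mean with implicit zeros", {
    grid <- window_grid(c(chr1 = 10000L), window_size = 5000)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                 score = 3.5)
    expect_equal(rebin_bedgraph(gr, grid), c(3.5, 3.5))

    # half a window at 2, the rest uncovered -> mean 1
    gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2500),
                                  score = 2)
    expect_equal(rebin_bedgraph(gr2, grid), c(1, 0))

    # sum aggregator allocates interval totals proportionally
    expect_equal(rebin_bedgraph(gr2, grid, aggregator = "sum"), c(2, 0))
    gr3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000),
                                  score = 10)
    expect_equal(rebin_bedgraph(gr3, grid, aggregator = "sum"), c(5, 5))
})

test_that("re-binning matches a per-base expansion oracle on random tracks", {
    set.seed(29)
    grid <- window_grid(c(chr1 = 20000L), window_size = 5000)
    for (rep in 1:5) {
        n_iv <- sample(3:10, 1)
        starts <- sort(sample.int(19000, n_iv))
        ends <- pmin(starts + sample.int(3000, n_iv), 20000)
        keep <- !duplicated(starts)
        gr <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(starts[keep] + 1, ends[keep]),
            score = round(runif(sum(keep)), 3))
        gr <- GenomicRanges::reduce(gr, with.revmap = FALSE)
        gr$score <- round(runif(length(gr)), 3)
        per_base <- numeric(20000)
        for (i in seq_along(gr)) {
            idx <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
            per_base[idx] <- gr$score[i]
        }
        oracle <- vapply(seq_len(nrow(grid)), function(w) {
            mean(per_base[(grid$start[w] + 1):grid$end[w]])
        }, numeric(1))
        expect_equal(rebin_bedgraph(gr, grid), oracle, tolerance = 1e-12)
    }
})

test_that("intervals beyond the scaffold end are clipped with a warning", {
    grid <- window_grid(c(chr1 = 6000L), window_size = 5000)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 9000),
                                 score = 2)
    expect_warning(v <- rebin_bedgraph(gr, grid), "clipping")
    expect_equal(v, c(0, 2))
})

test_that("bedgraph write/rebin round-trips grid-aligned tracks", {
    set.seed(41)
    grid <- window_grid(c(chr1 = 23000L), window_size = 5000)
    vals <- round(runif(nrow(grid)) * 10, 4)
    path <- tempfile(fileext = ".bedgraph")
    write_bedgraph(vals, grid, path, name = "test")
    expect_equal(rebin_bedgraph(path, grid), vals, tolerance = 1e-9)
    # idempotence: write the rebinned track and rebin again
    path2 <- tempfile(fileext = ".bedgraph")
    write_bedgraph(rebin_bedgraph(path, grid), grid, path2)
    expect_equal(rebin_bedgraph(path2, grid), vals, tolerance = 1e-9)
})

test_that("homopolymeric amino acid runs are found at the length threshold", {
    prot <- c(p1 = "MAAAAAAAK", p2 = "MAAAAAAK", p3 = "QQQQQQQQLLLLLLL")
    runs <- find_haars(prot)
    expect_equal(nrow(runs), 3L)
    r1 <- runs[runs$protein == "p1", ]
    expect_equal(r1$residue, "A")
    expect_equal(r1$start, 2L)
    expect_equal(r1$length, 7L)
    expect_false("p2" %in% runs$protein)   # run of 6+1 boundary: 7 required
    expect_setequal(runs$residue[runs$protein == "p3"], c("Q", "L"))
    expect_equal(runs$length[runs$protein == "p3" & runs$residue == "Q"], 8L)

    # from a FASTA file
    path <- tempfile(fileext = ".fasta")
    writeLines(c(">p1", "MSSSSSSSSM"), path)
    expect_equal(find_haars(path)$length, 8L)
})
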