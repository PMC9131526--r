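test_that("base composition features match hand-computed values", {
    expect_equal(gc_percentage("ATGC"), 50, ignore_attr = TRUE)
    expect_equal(gc_percentage("AAAA"), 0, ignore_attr = TRUE)
    expect_equal(gc_percentage("GGGCCA"), 100 * 5 / 6, ignore_attr = TRUE)
    expect_equal(gc_percentage("NNNN"), 0, ignore_attr = TRUE)
    # N excluded from the denominator
    expect_equal(gc_percentage("GCNN"), 100, ignore_attr = TRUE)

    expect_equal(gc_skew("GGGC"), 0.5, ignore_attr = TRUE)
    expect_equal(gc_skew("GGCC"), 0, ignore_attr = TRUE)
    expect_equal(gc_skew("AATT"), 0, ignore_attr = TRUE)
    expect_equal(at_skew("AAAT"), 0.5, ignore_attr = TRUE)

    expect_equal(n_percentage("NNAA"), 50, ignore_attr = TRUE)
    expect_equal(n_percentage("ACGT"), 0, ignore_attr = TRUE)
    expect_equal(n_percentage("NNNN"), 100, ignore_attr = TRUE)
})

test_that("dinucleotide and codon frequencies use overlapping scans", {
    expect_equal(cpg_frequency("CGCG"), 100 * 2 / 3, ignore_attr = TRUE)
    expect_equal(cpg_frequency("AAAA"), 0, ignore_attr = TRUE)
    expect_equal(cpg_frequency("C"), 0, ignore_attr = TRUE)

    expect_equal(stop_codon_frequency("TAATAG"), 0.5, ignore_attr = TRUE)
    expect_equal(stop_codon_frequency("CCCCCC"), 0, ignore_attr = TRUE)
    expect_equal(stop_codon_frequency("TA"), 0, ignore_attr = TRUE)
    # overlapping occurrences: TAATAA has TAA at 1 and 4 -> 2/4
    expect_equal(stop_codon_frequency("TAATAA"), 0.5, ignore_attr = TRUE)
})

test_that("motif frequency counts overlaps and reverse complements", {
    expect_equal(motif_frequency("TTTAGGGTTTAGGG", "TTTAGGG", FALSE),
                 100 * 2 / 14, ignore_attr = TRUE)
    expect_equal(motif_frequency("CCCTAAA", "TTTAGGG", TRUE),
                 100 * 1 / 7, ignore_attr = TRUE)
    expect_equal(motif_frequency("CCCTAAA", "TTTAGGG", FALSE), 0,
                 ignore_attr = TRUE)
    # palindromic motif is not double counted
    expect_equal(motif_frequency("ACGT", "ACGT", TRUE), 100 / 4,
                 ignore_attr = TRUE)
    expect_error(motif_frequency("ACGT", "A"), "length >= 2")
})

test_that("k-mer deviation is zero for a single-window genome and symmetric for mirrored windows", {
    asm <- Biostrings::DNAStringSet(c(chr1 = random_dna(4000)))
    grid <- window_grid(asm, window_size = 5000)
    prof <- genome_kmer_profile(asm, 3)
    win <- window_sequences(asm, grid)
    expect_equal(kmer_deviation(win, 3, prof), 0, ignore_attr = TRUE,
                 tolerance = 1e-12)

    asm2 <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000),
                                       chr2 = strrep("T", 1000)))
    g2 <- window_grid(asm2, window_size = 1000)
    p2 <- genome_kmer_profile(asm2, 3)
    dev <- kmer_deviation(window_sequences(asm2, g2), 3, p2)
    expect_equal(dev[1], dev[2], ignore_attr = TRUE)
    expect_gt(dev[1], 0)

    expect_equal(kmer_deviation("NN", 3, prof), 0, ignore_attr = TRUE)
    expect_error(kmer_deviation("ACGT", 3, rep(1, 10)), "4\\^k")
})

test_that("low-complexity masking flags homopolymers but not random sequence", {
    expect_equal(low_complexity_fraction(strrep("A", 5000)), 1)
    set.seed(21)
    expect_lt(low_complexity_fraction(random_dna(5000)), 0.05)
    half <- paste0(strrep("A", 2500), random_dna(2500))
    expect_equal(low_complexity_fraction(half), 0.5, tolerance = 0.1)
})

test_that("tandem repeat masking covers perfect repeats of any unit", {
    expect_equal(tandem_repeat_fraction("ACACACAC"), 1)
    expect_equal(tandem_repeat_fraction("ACGTACGTACGT"), 1)
    # the repeated half masks, the random-looking half mostly does not
    s <- paste0(strrep("ACGGTC", 20), "GCATCGAAGCTACGGATCGC")
    expect_gte(tandem_repeat_fraction(s), 120 / 140)
})

test_that("features are case-insensitive", {
    set.seed(9)
    s <- random_dna(800, gc = 0.4)
    lower <- tolower(s)
    expect_equal(gc_percentage(s), gc_percentage(lower), ignore_attr = TRUE)
    expect_equal(cpg_frequency(s), cpg_frequency(lower), ignore_attr = TRUE)
    expect_equal(motif_frequency(s, "TTTAGGG"), motif_frequency(lower, "tttaggg"),
                 ignore_attr = TRUE)
    expect_equal(tandem_repeat_fraction(s), tandem_repeat_fraction(lower))
    expect_equal(low_complexity_fraction(s), low_complexity_fraction(lower))
})

test_that("mappability depth reflects copy number", {
    set.seed(31)
    unique_part <- random_dna(60000, gc = 0.4)
    dup <- random_dna(20000, gc = 0.4)
    asm <- Biostrings::DNAStringSet(c(
        chr1 = paste0(unique_part, dup, random_dna(20000, gc = 0.4), dup)))
    grid <- window_grid(asm, window_size = 5000)
    depth <- mappability_depth(asm, grid, fragment_length = 150, fold = 10)
    expect_true(all(depth >= 0 & depth <= 10))
    # interior unique windows reach full fold coverage
    expect_gte(min(depth[3:10]), 9.5)
    # windows wholly inside either copy of the duplicated segment halve
    first_copy <- which(grid$start >= 60000 & grid$end <= 80000)
    second_copy <- which(grid$start >= 100000 & grid$end <= 120000)
    expect_equal(mean(depth[first_copy]), 5, tolerance = 0.05)
    expect_equal(mean(depth[second_copy]), 5, tolerance = 0.05)
})

test_that("scaffolds shorter than the fragment length contribute no depth", {
    asm <- Biostrings::DNAStringSet(c(tiny = "ACGTACGT"))
    grid <- window_grid(asm, window_size = 5000)
    expect_equal(mappability_depth(asm, grid), 0, ignore_attr = TRUE)
})

test_that("every sequence feature matches its naive oracle on random windows", {
    set.seed(77)
    prof3 <- NULL
    for (i in 1:25) {
        len <- sample(200:2000, 1)
        s <- random_dna(len, gc = runif(1, 0.2, 0.7),
                        n_frac = sample(c(0, 0.02), 1))
        expect_equal(gc_percentage(s), o_gc_percentage(s),
                     ignore_attr = TRUE, tolerance = 1e-12)
        expect_equal(gc_skew(s), o_gc_skew(s), ignore_attr = TRUE,
                     tolerance = 1e-12)
        expect_equal(at_skew(s), o_at_skew(s), ignore_attr = TRUE,
                     tolerance = 1e-12)
        expect_equal(cpg_frequency(s), o_cpg_frequency(s),
                     ignore_attr = TRUE, tolerance = 1e-12)
        expect_equal(stop_codon_frequency(s), o_stop_codon_frequency(s),
                     ignore_attr = TRUE, tolerance = 1e-12)
        expect_equal(motif_frequency(s, "TTTAGGG"),
                     o_motif_frequency(s, "TTTAGGG"),
                     ignore_attr = TRUE, tolerance = 1e-12)
        expect_equal(tandem_repeat_fraction(s), o_tandem_fraction(s),
                     tolerance = 1e-12)
        expect_equal(low_complexity_fraction(s), o_low_complexity(s),
                     tolerance = 1e-12)
    }
})

test_that("the sequence feature driver assembles the full default track set", {
    p <- preset_fixture()
    expect_setequal(
        p$fm$feature_names,
        c("gc_percentage", "at_skew", "gc_skew", "cpg_percentage",
          "stop_codon_freq", "telomere_freq", "cag_freq",
          "kmer_deviation_kmer_size_3", "kmer_deviation_kmer_size_4",
          "N_percentage", "low_complexity_fraction",
          "tandem_repeat_fraction", "mappability_depth"))
    expect_equal(nrow(p$fm$raw), nrow(p$grid))
    expect_true(all(is.finite(p$fm$raw)))
    expect_true(all(p$fm$raw[, "mappability_depth"] <= 10 + 1e-9))
    expect_true(all(abs(p$fm$raw[, "gc_skew"]) <= 1))
})
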