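test_that("one-sided KS statistics behave at the extremes", {
    r <- ks_test_1sided(c(10, 11, 12), c(1, 2, 3))
    expect_equal(r$D_plus, 1)
    expect_equal(r$D_minus, 0)
    expect_lt(r$p_plus, 0.06)
    expect_equal(ks_call(r$p_plus, r$p_minus, 0.06), "higher")

    set.seed(83)
    x <- rnorm(100)
    r2 <- ks_test_1sided(x, x + 1e-9 * seq_along(x))
    expect_lt(r2$D_plus, 0.05)
    expect_gt(r2$p_plus, 0.9)
    expect_equal(ks_call(r2$p_plus, r2$p_minus, 1e-20), "none")
})

test_that("exact one-sided KS p-values match exhaustive permutation enumeration", {
    set.seed(89)
    for (rep in 1:8) {
        m <- sample(3:5, 1); n <- sample(3:5, 1)
        v <- sample(1000, m + n) / 7   # tie-free
        x <- v[1:m]; y <- v[-(1:m)]
        r <- ks_test_1sided(x, y)
        expect_true(r$exact)
        o <- o_ks_enumeration(x, y)
        expect_equal(r$D_plus, o$D_plus, tolerance = 1e-12)
        expect_equal(r$D_minus, o$D_minus, tolerance = 1e-12)
        expect_equal(r$p_plus, o$p_plus, tolerance = 1e-12)
        expect_equal(r$p_minus, o$p_minus, tolerance = 1e-12)
    }
})

test_that("KS results are invariant under strictly monotone transforms", {
    set.seed(97)
    x <- rnorm(30); y <- rnorm(40, 0.5)
    a <- ks_test_1sided(x, y, exact = FALSE)
    b <- ks_test_1sided(exp(x), exp(y), exact = FALSE)
    expect_equal(a[c("D_plus", "D_minus", "p_plus", "p_minus")],
                 b[c("D_plus", "D_minus", "p_plus", "p_minus")],
                 tolerance = 1e-12)
})

test_that("cluster characterisation calls higher/lower/dispersed features", {
    set.seed(101)
    grid <- window_grid(c(chr1 = 400000L), window_size = 1000)
    labels <- rep(c(0L, 1L), each = 200)
    hi <- c(rnorm(200, 10), rnorm(200, 0))       # higher in cluster 0
    lo <- c(rnorm(200, 0), rnorm(200, 10))       # lower in cluster 0
    disp <- c(rnorm(200, 0, 8), rnorm(200, 0, 0.5)) # dispersed in cluster 0
    flat <- rnorm(400)
    fm <- feature_matrix(list(hi = hi, lo = lo, disp = disp, flat = flat),
                         grid)
    ks <- characterise_clusters(fm, labels, alpha = 1e-10)
    row <- function(k, f) ks[ks$cluster == k & ks$feature == f, ]
    expect_equal(row(0, "hi")$call, "higher")
    expect_equal(row(0, "lo")$call, "lower")
    expect_equal(row(0, "disp")$call, "dispersed")
    expect_equal(row(0, "flat")$call, "none")
    expect_equal(row(1, "hi")$call, "lower")
    expect_gt(row(0, "hi")$mean_scaled, row(1, "hi")$mean_scaled)
    expect_true(all(ks$D_plus >= 0 & ks$D_plus <= 1))

    # unclassified windows join the "rest" sample but never form a row
    labels2 <- labels; labels2[1:50] <- -1L
    ks2 <- characterise_clusters(fm, labels2, alpha = 1e-10)
    expect_setequal(unique(ks2$cluster), c(0, 1))

    expect_error(characterise_clusters(fm, rep(0L, 400)), "two clusters")
})

test_that("tiny clusters are reported with call 'none' and a warning", {
    grid <- window_grid(c(chr1 = 10000L), window_size = 1000)
    fm <- feature_matrix(list(x = c(100, 1:9)), grid)
    labels <- c(5L, rep(0L, 9))
    expect_warning(ks <- characterise_clusters(fm, labels, alpha = 0.5),
                   "fewer than 2")
    expect_equal(ks$call[ks$cluster == 5], "none")
})

test_that("heatmap tables carry values and icons and round-trip through TSV", {
    ks <- data.frame(cluster = rep(0:1, each = 3),
                     feature = rep(c("f1", "f2", "f3"), 2),
                     D_plus = 0.5, D_minus = 0.1, p_plus = 1e-30,
                     p_minus = 1, call = c("higher", "lower", "none",
                                           "dispersed", "none", "higher"),
                     mean_scaled = round(runif(6), 3))
    hm <- heatmap_table(ks)
    expect_equal(dim(hm$values), c(2L, 3L))
    expect_equal(hm$icons["0", "f1"], "^")
    expect_equal(hm$icons["0", "f2"], "v")
    expect_equal(hm$icons["1", "f1"], "-")
    expect_equal(hm$icons["0", "f3"], "")

    path <- tempfile(fileext = ".tsv")
    write_heatmap_tsv(hm, path)
    back <- read_heatmap_tsv(path)
    expect_equal(back$values, hm$values)
    expect_equal(back$icons, hm$icons)
})

test_that("junction counts are conserved and direct counts match", {
    grid <- window_grid(c(chr1 = 4000L), window_size = 1000)
    jt <- junction_enrichment(c(0L, 0L, 1L, 1L), grid)
    get <- function(a, b) jt$observed[jt$cluster_a == a & jt$cluster_b == b]
    expect_equal(get(0, 0), 1L)
    expect_equal(get(0, 1), 1L)
    expect_equal(get(1, 1), 1L)
    expect_equal(sum(jt$observed), 3L)

    # conservation on random labels across several scaffolds
    set.seed(103)
    lens <- c(a = 40000L, b = 25000L, c = 1000L)
    g2 <- window_grid(lens, window_size = 1000)
    labels <- sample(c(-1L, 0L, 1L, 2L), nrow(g2), replace = TRUE)
    jt2 <- junction_enrichment(labels, g2)
    expect_equal(sum(jt2$observed),
                 sum(tapply(labels, g2$scaffold, length) - 1))
    # BH is monotone: sorting by p sorts by q
    expect_false(is.unsorted(jt2$q[order(jt2$p)]))
    expect_true(all(jt2$q >= jt2$p - 1e-12))
})

test_that("alternating labels enrich the cross-cluster junction", {
    grid <- window_grid(c(chr1 = 200000L), window_size = 1000)
    labels <- rep(c(0L, 1L), 100)
    jt <- junction_enrichment(labels, grid)
    ab <- jt[jt$cluster_a == 0 & jt$cluster_b == 1, ]
    expect_equal(ab$observed, 199L)
    expect_lt(ab$q, 1e-10)
    expect_gt(ab$odds_ratio, 1)
    # and matches the hypergeometric closed form of the same 2x2 table
    e <- round(199 * 2 * 0.5 * 0.5)
    tab <- matrix(c(199L, 0L, e, 199L - e), nrow = 2)
    expect_equal(ab$p, o_fisher_p(tab), tolerance = 1e-9)
})

test_that("junction p-values match the exact-test oracle on toy strings", {
    set.seed(107)
    for (rep in 1:10) {
        n_win <- sample(20:60, 1)
        grid <- window_grid(setNames(n_win * 1000L, "chr1"),
                            window_size = 1000)
        labels <- sample(0:2, n_win, replace = TRUE)
        jt <- junction_enrichment(labels, grid)
        N <- n_win - 1
        freq <- table(labels) / n_win
        for (r in seq_len(nrow(jt))) {
            i <- jt$cluster_a[r]; j <- jt$cluster_b[r]
            pe <- if (i == j) freq[[as.character(i)]]^2 else
                2 * freq[[as.character(i)]] * freq[[as.character(j)]]
            tab <- matrix(c(jt$observed[r], N - jt$observed[r],
                            round(N * pe), N - round(N * pe)), nrow = 2)
            expect_equal(jt$p[r], o_fisher_p(tab), tolerance = 1e-9)
        }
    }
})

test_that("uniformly shuffled labels rarely reach nominal significance", {
    set.seed(109)
    grid <- window_grid(c(chr1 = 300000L), window_size = 1000)
    pvals <- c()
    for (rep in 1:10) {
        labels <- sample(rep(0:2, each = 100))
        jt <- junction_enrichment(labels, grid)
        pvals <- c(pvals, jt$p)
    }
    expect_lte(mean(pvals < 0.05), 0.05 + 0.04)
})

test_that("interval-cluster overlap counts every touched cluster once", {
    grid <- window_grid(c(chr1 = 10000L), window_size = 1000)
    labels <- c(rep(0L, 5), rep(1L, 5))
    iv <- data.frame(scaffold = "chr1",
                     start = c(1200L, 4500L, 9100L),
                     end = c(1400L, 5600L, 9900L))
    ov <- overlap_clusters(iv, labels, grid)
    expect_equal(ov$counts$n, c(2L, 2L))
    expect_equal(unname(ov$overlaps[1, ]), c(TRUE, FALSE))   # inside cluster 0
    expect_equal(unname(ov$overlaps[2, ]), c(TRUE, TRUE))    # spans both
    expect_equal(unname(ov$overlaps[3, ]), c(FALSE, TRUE))

    # brute force on random fixtures
    set.seed(113)
    for (rep in 1:5) {
        labels <- sample(c(-1L, 0L, 1L, 2L), 10, replace = TRUE)
        st <- sample(0:9500, 6)
        iv <- data.frame(scaffold = "chr1", start = st,
                         end = pmin(st + sample(100:3000, 6), 10000L))
        ov <- overlap_clusters(iv, labels, grid)
        for (i in seq_len(6)) {
            touched <- unique(labels[
                grid$start < iv$end[i] & grid$end > iv$start[i]])
            for (k in colnames(ov$overlaps)) {
                expect_equal(ov$overlaps[i, k],
                             as.integer(k) %in% touched,
                             ignore_attr = TRUE)
            }
        }
    }
})

test_that("subtelomeric windows are those within the distance of either end", {
    grid <- window_grid(c(chr1 = 1000000L), window_size = 5000)
    part <- split_subtelomeric(grid, distance = 200000)
    expect_equal(sum(part == "subtelomeric"), 80L)
    expect_equal(which(part == "subtelomeric"), c(1:40, 161:200))

    short <- window_grid(c(mini = 300000L), window_size = 5000)
    expect_true(all(split_subtelomeric(short, 200000) == "subtelomeric"))
})

test_that("cluster BED covers every window exactly once and collapses runs", {
    grid <- window_grid(c(a = 5000L, b = 3000L), window_size = 1000)
    labels <- c(0L, 0L, 1L, 1L, -1L, 2L, 2L, 2L)
    path <- tempfile(fileext = ".bed")
    write_cluster_bed(labels, grid, path)
    bed <- read.delim(path, header = FALSE)
    expect_equal(nrow(bed), 8L)
    expect_equal(bed$V2, grid$start)
    expect_equal(bed$V3, grid$end)
    expect_equal(bed$V4[5], "unclassified")
    expect_equal(sum(bed$V3 - bed$V2), 8000)

    path2 <- tempfile(fileext = ".bed")
    write_cluster_bed(labels, grid, path2, collapse = TRUE)
    bed2 <- read.delim(path2, header = FALSE)
    expect_equal(nrow(bed2), 4L)
    expect_equal(sum(bed2$V3 - bed2$V2), 8000)
    expect_equal(bed2$V4, c("cluster_0", "cluster_1", "unclassified",
                            "cluster_2"))
})
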