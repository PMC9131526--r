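## Statistical characterisation of window clusters: per-feature one-sided
## two-sample Kolmogorov-Smirnov tests with higher/lower/dispersed calls,
## heatmap tables, cluster-junction enrichment (Fisher + BH), interval
## overlap and subtelomere partitioning.

#' One-sided two-sample Kolmogorov-Smirnov test, both directions
#'
#' Computes `D_plus = max(F_rest - F_x)` (evidence that `x` is
#' stochastically *higher* than `y`) and `D_minus = max(F_x - F_rest)`
#' (lower), with one-sided p-values. P-values are asymptotic
#' (`exp(-2 D^2 mn / (m+n))`) by default; for small tie-free samples an
#' exact p-value is computed by counting lattice paths.
#'
#' @param x Numeric sample (e.g. feature values of one cluster).
#' @param y Numeric reference sample (the rest of the windows).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact computation;
#'   default `NULL` uses exact when `m * n <= 10000` and there are no ties
#'   across the pooled sample.
#' @return List with `D_plus`, `D_minus`, `p_plus`, `p_minus`, `exact`.
#' @export
ks_test_1sided <- function(x, y, exact = NULL) {
    x <- as.numeric(x); y <- as.numeric(y)
    m <- length(x); n <- length(y)
    stopifnot(m > 0, n > 0)
    pts <- sort(unique(c(x, y)))
    Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
    Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
    D_plus <- max(0, max(Fy - Fx))   # x shifted high => its ECDF lags
    D_minus <- max(0, max(Fx - Fy))
    ties <- anyDuplicated(c(x, y)) > 0
    if (is.null(exact)) exact <- (as.double(m) * n <= 10000) && !ties
    if (exact && ties) {
        warning("ties present; falling back to asymptotic p-values")
        exact <- FALSE
    }
    if (exact) {
        p_plus <- ks_exact_p_1sided(m, n, D_plus)
        p_minus <- ks_exact_p_1sided(m, n, D_minus)
    } else {
        mn <- m * n / (m + n)
        p_plus <- min(1, exp(-2 * mn * D_plus^2))
        p_minus <- min(1, exp(-2 * mn * D_minus^2))
    }
    list(D_plus = D_plus, D_minus = D_minus,
         p_plus = p_plus, p_minus = p_minus, exact = exact)
}

## Exact one-sided two-sample KS p-value for tie-free samples:
## P(max_t (F_y - F_x) >= d) under exchangeability, by counting monotone
## lattice paths from (0,0) to (m,n) that never reach j/n - i/m >= d.
ks_exact_p_1sided <- function(m, n, d) {
    if (d <= 0) return(1)
    eps <- 1e-12
    A <- matrix(0, nrow = m + 1, ncol = n + 1)
    A[1, 1] <- 1
    for (i in 0:m) {
        for (j in 0:n) {
            if (i == 0 && j == 0) next
            if (j / n - i / m >= d - eps) { A[i + 1, j + 1] <- 0; next }
            acc <- 0
            if (i > 0) acc <- acc + A[i, j + 1]
            if (j > 0) acc <- acc + A[i + 1, j]
            A[i + 1, j + 1] <- acc
        }
    }
    1 - A[m + 1, n + 1] / choose(m + n, m)
}

ks_call <- function(p_plus, p_minus, alpha) {
    if (p_plus <= alpha && p_minus <= alpha) return("dispersed")
    if (p_plus <= alpha) return("higher")
    if (p_minus <= alpha) return("lower")
    "none"
}

call_icon <- c(higher = "^", lower = "v", dispersed = "-", none = "")

#' Characterise clusters by per-feature KS tests
#'
#' For every (cluster, feature) pair, compares the distribution of the
#' feature in the cluster's windows against all other windows (unclassified
#' windows are part of the "rest" but never form a cluster row) with
#' one-sided KS tests in both directions. A feature is called `higher` in a
#' cluster when `p_plus <= alpha` only, `lower` when `p_minus <= alpha`
#' only, and `dispersed` when both directions are significant.
#'
#' @param fm A `feature_matrix`.
#' @param labels Integer cluster labels (`-1` = unclassified), grid order.
#' @param alpha Significance level for the calls (default `1e-20`, the
#'   level used for the heatmap icons).
#' @return data.frame with one row per cluster x feature: `cluster`,
#'   `feature`, `D_plus`, `D_minus`, `p_plus`, `p_minus`, `call`,
#'   `mean_scaled`.
#' @export
characterise_clusters <- function(fm, labels, alpha = 1e-20) {
    stopifnot(length(labels) == nrow(fm$raw))
    clusters <- sort(unique(labels[labels >= 0]))
    if (length(clusters) < 2) {
        stop("need at least two clusters to characterise")
    }
    rows <- list()
    for (k in clusters) {
        in_k <- labels == k
        degenerate <- sum(in_k) < 2
        if (degenerate) {
            warning("cluster ", k, " has fewer than 2 windows; calls set ",
                    "to 'none'")
        }
        for (f in fm$feature_names) {
            x <- fm$raw[in_k, f]
            y <- fm$raw[!in_k, f]
            ks <- ks_test_1sided(x, y, exact = FALSE)
            rows[[length(rows) + 1]] <- data.frame(
                cluster = k, feature = f,
                D_plus = ks$D_plus, D_minus = ks$D_minus,
                p_plus = ks$p_plus, p_minus = ks$p_minus,
                call = if (degenerate) "none"
                       else ks_call(ks$p_plus, ks$p_minus, alpha),
                mean_scaled = mean(fm$scaled[in_k, f]),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Cluster x feature heatmap table
#'
#' Reshapes a [characterise_clusters()] result into a cluster x feature
#' matrix of mean scaled values plus a matching matrix of significance
#' icons (`^` higher, `v` lower, `-` dispersed, empty = none).
#'
#' @param ks A data.frame from [characterise_clusters()].
#' @return List with matrices `values` and `icons` (rows = clusters,
#'   columns = features) of class `cluster_heatmap`.
#' @export
heatmap_table <- function(ks) {
    clusters <- sort(unique(ks$cluster))
    feats <- unique(ks$feature)
    values <- matrix(NA_real_, length(clusters), length(feats),
                     dimnames = list(as.character(clusters), feats))
    icons <- matrix("", length(clusters), length(feats),
                    dimnames = dimnames(values))
    for (r in seq_len(nrow(ks))) {
        i <- as.character(ks$cluster[r]); j <- ks$feature[r]
        values[i, j] <- ks$mean_scaled[r]
        icons[i, j] <- call_icon[[ks$call[r]]]
    }
    structure(list(values = values, icons = icons),
              class = "cluster_heatmap")
}

#' Write / read a heatmap table as long TSV
#' @param hm A `cluster_heatmap` (or the TSV path for the reader).
#' @param path Output TSV path.
#' @return The path (writer) or a `cluster_heatmap` (reader).
#' @export
write_heatmap_tsv <- function(hm, path) {
    df <- expand.grid(cluster = rownames(hm$values),
                      feature = colnames(hm$values),
                      stringsAsFactors = FALSE)
    df$mean_scaled <- hm$values[cbind(df$cluster, df$feature)]
    df$icon <- hm$icons[cbind(df$cluster, df$feature)]
    df$mean_scaled <- format_num(df$mean_scaled)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_heatmap_tsv
#' @export
read_heatmap_tsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     na.strings = NULL, colClasses = c(
                         cluster = "character", feature = "character",
                         mean_scaled = "numeric", icon = "character"))
    clusters <- unique(df$cluster)
    feats <- unique(df$feature)
    values <- matrix(NA_real_, length(clusters), length(feats),
                     dimnames = list(clusters, feats))
    icons <- matrix("", length(clusters), length(feats),
                    dimnames = dimnames(values))
    values[cbind(df$cluster, df$feature)] <- df$mean_scaled
    icons[cbind(df$cluster, df$feature)] <- df$icon
    structure(list(values = values, icons = icons),
              class = "cluster_heatmap")
}

#' Cluster junction enrichment
#'
#' Counts junctions between consecutive windows within each scaffold (the
#' unordered label pair of each adjacency, self-pairs included, unclassified
#' windows participating as label `-1`) and tests each pair for enrichment
#' against the expectation under the marginal label frequencies with
#' Fisher's exact test, Benjamini-Hochberg corrected across pairs.
#'
#' @param labels Integer cluster labels, grid order.
#' @param grid The matching `window_grid`.
#' @return data.frame with one row per unordered label pair: `cluster_a`,
#'   `cluster_b`, `observed`, `expected`, `odds_ratio`, `p`, `q`.
#' @export
junction_enrichment <- function(labels, grid) {
    stopifnot(length(labels) == nrow(grid))
    scaf <- factor(grid$scaffold, levels = unique(grid$scaffold))
    a <- labels[-length(labels)]
    b <- labels[-1]
    same <- scaf[-length(labels)] == scaf[-1]
    a <- a[same]; b <- b[same]
    if (length(a) == 0) {
        return(data.frame(cluster_a = integer(), cluster_b = integer(),
                          observed = integer(), expected = numeric(),
                          odds_ratio = numeric(), p = numeric(),
                          q = numeric()))
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi)
    N <- length(a)
    freq <- table(labels) / length(labels)
    labs <- as.integer(names(freq))
    pairs <- expand.grid(i = labs, j = labs)
    pairs <- pairs[pairs$i <= pairs$j, ]
    obs <- table(factor(key, levels = paste(pairs$i, pairs$j)))
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
        i <- pairs$i[r]; j <- pairs$j[r]
        p_exp <- if (i == j) freq[[as.character(i)]]^2
                 else 2 * freq[[as.character(i)]] * freq[[as.character(j)]]
        e <- N * p_exp
        o <- as.integer(obs[[paste(i, j)]])
        tab <- matrix(c(o, N - o, round(e), N - round(e)), nrow = 2)
        ft <- stats::fisher.test(tab)
        data.frame(cluster_a = i, cluster_b = j, observed = o, expected = e,
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out[order(out$p), , drop = FALSE]
}

#' Count annotated intervals overlapping each cluster
#'
#' An interval (gene, repeat, ...) overlaps cluster `k` when it overlaps at
#' least one window labelled `k`; an interval spanning a cluster boundary is
#' counted for every cluster it touches.
#'
#' @param intervals A `GRanges`, or a data.frame with `scaffold`, `start`,
#'   `end` (0-based half-open).
#' @param labels Integer cluster labels, grid order.
#' @param grid The matching `window_grid`.
#' @return List with `counts` (data.frame `cluster`, `n`) and `overlaps`
#'   (logical intervals x clusters matrix).
#' @export
overlap_clusters <- function(intervals, labels, grid) {
    if (is.data.frame(intervals)) {
        intervals <- GenomicRanges::GRanges(
            intervals$scaffold,
            IRanges::IRanges(intervals$start + 1L, intervals$end))
    }
    win <- grid_granges(grid)
    hits <- GenomicRanges::findOverlaps(intervals, win)
    q <- S4Vectors::queryHits(hits)
    lab <- labels[S4Vectors::subjectHits(hits)]
    clusters <- sort(unique(labels[labels >= 0]))
    ov <- matrix(FALSE, length(intervals), length(clusters),
                 dimnames = list(NULL, as.character(clusters)))
    for (k in clusters) {
        ov[unique(q[lab == k]), as.character(k)] <- TRUE
    }
    list(counts = data.frame(cluster = clusters, n = colSums(ov)),
         overlaps = ov)
}

#' Partition windows into subtelomeric and internal
#'
#' A window is subtelomeric when it lies within `distance` bp of either
#' scaffold end (`start < distance` or `end > scaffold_length - distance`).
#' Scaffolds shorter than twice the distance are entirely subtelomeric.
#'
#' @param grid A `window_grid`.
#' @param distance Distance from the scaffold end in bp (default 200000).
#' @return Factor of `"subtelomeric"` / `"internal"`, grid order.
#' @export
split_subtelomeric <- function(grid, distance = 200000) {
    lens <- attr(grid, "seqlengths")[grid$scaffold]
    sub <- grid$start < distance | grid$end > lens - distance
    factor(ifelse(sub, "subtelomeric", "internal"),
           levels = c("subtelomeric", "internal"))
}

#' Write per-window cluster labels as BED
#'
#' Emits one line per window (`scaffold start end cluster_<k>`,
#' unclassified windows as `unclassified`), optionally collapsing runs of
#' consecutive same-label windows into single intervals.
#'
#' @param labels Integer cluster labels, grid order.
#' @param grid The matching `window_grid`.
#' @param path Output BED path.
#' @param collapse Merge consecutive same-label windows (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(labels, grid, path, collapse = FALSE) {
    stopifnot(length(labels) == nrow(grid))
    name <- ifelse(labels >= 0, sprintf("cluster_%d", labels),
                   "unclassified")
    df <- data.frame(scaffold = grid$scaffold, start = grid$start,
                     end = grid$end, name = name, stringsAsFactors = FALSE)
    if (collapse) {
        run <- cumsum(c(TRUE, df$scaffold[-1] != df$scaffold[-nrow(df)] |
                              df$name[-1] != df$name[-nrow(df)]))
        df <- data.frame(
            scaffold = tapply(df$scaffold, run, `[`, 1),
            start = as.integer(tapply(df$start, run, min)),
            end = as.integer(tapply(df$end, run, max)),
            name = tapply(df$name, run, `[`, 1),
            stringsAsFactors = FALSE)
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
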