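## UMAP embedding + HDBSCAN clustering of scaled windows, parameter sweep
## and quality metrics. The embedding/clustering algorithms themselves run
## in the umap-learn and scikit-learn libraries through a bundled Python
## worker; everything around them (contracts, metrics, selection policy)
## lives here.

find_python <- function() {
    py <- getOption("genarch.python", "")
    if (!nzchar(py)) py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) {
        stop("no python interpreter found; install python with numpy, ",
             "umap-learn and scikit-learn, or set options(genarch.python=)")
    }
    unname(py)
}

run_python_worker <- function(mode, input_matrix, jobs, out) {
    script <- system.file("python", "embed_cluster.py", package = "genarch")
    if (!nzchar(script)) stop("bundled python worker not found")
    jobs_file <- tempfile(fileext = ".json")
    on.exit(unlink(jobs_file))
    jsonlite::write_json(jobs, jobs_file, auto_unbox = TRUE, digits = NA)
    res <- suppressWarnings(system2(
        find_python(), c(script, "--mode", mode, "--input", input_matrix,
                         "--jobs", jobs_file, "--out", out),
        stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0) {
        stop("python worker failed (mode=", mode, "):\n",
             paste(utils::tail(res, 15), collapse = "\n"))
    }
    invisible(out)
}

write_matrix_tmp <- function(m) {
    path <- tempfile(fileext = ".tsv")
    write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

#' Clustering parameters
#'
#' Bundles the two key parameters of the window clustering: the UMAP
#' `n_neighbours` (`n`; low values fragment the data into many small groups,
#' high values pull it into few large ones) and the HDBSCAN
#' `min_cluster_size` (`c`), plus the UMAP `min_dist` and the random seed.
#'
#' @param n UMAP number of neighbours (>= 2).
#' @param c HDBSCAN minimum cluster size (>= 2).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param seed Random seed recorded in all outputs (default 42).
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(n = 5, c = 50, min_dist = 0.1, seed = 42) {
    stopifnot(n >= 2, c >= 2, min_dist >= 0)
    structure(list(n = as.integer(n), c = as.integer(c),
                   min_dist = as.numeric(min_dist), seed = as.integer(seed)),
              class = "clustering_params")
}

#' Embed scaled windows in two dimensions with UMAP
#'
#' @param fm A `feature_matrix` (the scaled view is embedded).
#' @param params A [clustering_params()].
#' @return A windows x 2 numeric matrix of embedding coordinates;
#'   deterministic for a fixed seed.
#' @export
embed_windows <- function(fm, params = clustering_params()) {
    n_win <- nrow(fm$scaled)
    if (n_win <= params$n) {
        stop("need more than n = ", params$n, " windows to embed ",
             "(have ", n_win, "); use a smaller n")
    }
    mat_file <- write_matrix_tmp(fm$scaled)
    on.exit(unlink(mat_file))
    out <- tempfile(fileext = ".tsv")
    on.exit(unlink(out), add = TRUE)
    run_python_worker("embed", mat_file,
                      list(n = params$n, min_dist = params$min_dist,
                           seed = params$seed), out)
    emb <- as.matrix(read.delim(out, header = FALSE))
    dimnames(emb) <- list(NULL, c("x", "y"))
    if (nrow(emb) != n_win || any(!is.finite(emb))) {
        stop("embedding failed: bad worker output")
    }
    emb
}

#' Cluster an embedding with HDBSCAN
#'
#' @param embedding A windows x 2 coordinate matrix from [embed_windows()].
#' @param params A [clustering_params()]; only `c` (minimum cluster size)
#'   is used.
#' @return Integer vector of per-window cluster labels; `-1` marks
#'   unclassified (noise) windows. Every cluster has at least `c` members.
#' @export
cluster_embedding <- function(embedding, params = clustering_params()) {
    stopifnot(is.matrix(embedding), ncol(embedding) == 2,
              all(is.finite(embedding)))
    mat_file <- write_matrix_tmp(embedding)
    on.exit(unlink(mat_file))
    out <- tempfile(fileext = ".tsv")
    on.exit(unlink(out), add = TRUE)
    run_python_worker("cluster", mat_file,
                      list(min_cluster_size = params$c), out)
    labels <- scan(out, what = integer(), quiet = TRUE)
    stopifnot(length(labels) == nrow(embedding))
    labels
}

## --- clustering quality metrics (computed on classified windows only) ----

metric_input <- function(x, labels) {
    keep <- labels >= 0
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
    list(x = x, labels = labels, k = length(unique(labels)))
}

#' Clustering quality metrics
#'
#' Silhouette score, Davies-Bouldin index and Calinski-Harabasz score of a
#' labelling, computed over classified windows (label >= 0) only. With
#' fewer than two clusters all three are `NA`.
#'
#' @param x Point coordinates (the 2-D embedding by default in the
#'   pipeline).
#' @param labels Integer cluster labels, `-1` = unclassified.
#' @return Named list `silhouette`, `davies_bouldin`, `calinski_harabasz`.
#' @export
clustering_metrics <- function(x, labels) {
    mi <- metric_input(as.matrix(x), labels)
    if (mi$k < 2 || nrow(mi$x) < 3) {
        return(list(silhouette = NA_real_, davies_bouldin = NA_real_,
                    calinski_harabasz = NA_real_))
    }
    list(silhouette = silhouette_score(mi$x, mi$labels),
         davies_bouldin = davies_bouldin_index(mi$x, mi$labels),
         calinski_harabasz = calinski_harabasz_score(mi$x, mi$labels))
}

#' @rdname clustering_metrics
#' @export
silhouette_score <- function(x, labels) {
    x <- as.matrix(x)
    d <- as.matrix(stats::dist(x))
    labs <- unique(labels)
    if (length(labs) < 2) return(NA_real_)
    n <- nrow(x)
    sil <- numeric(n)
    idx <- split(seq_len(n), labels)
    for (i in seq_len(n)) {
        own <- labels[i]
        own_idx <- setdiff(idx[[as.character(own)]], i)
        if (length(own_idx) == 0) { sil[i] <- 0; next }
        a <- mean(d[i, own_idx])
        b <- min(vapply(labs[labs != own], function(l) {
            mean(d[i, idx[[as.character(l)]]])
        }, numeric(1)))
        sil[i] <- (b - a) / max(a, b)
    }
    mean(sil)
}

#' @rdname clustering_metrics
#' @export
davies_bouldin_index <- function(x, labels) {
    x <- as.matrix(x)
    labs <- sort(unique(labels))
    k <- length(labs)
    if (k < 2) return(NA_real_)
    cent <- t(vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                     numeric(ncol(x))))
    s <- vapply(seq_along(labs), function(i) {
        pts <- x[labels == labs[i], , drop = FALSE]
        mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
    }, numeric(1))
    db <- vapply(seq_len(k), function(i) {
        max(vapply(setdiff(seq_len(k), i), function(j) {
            (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
        }, numeric(1)))
    }, numeric(1))
    mean(db)
}

#' @rdname clustering_metrics
#' @export
calinski_harabasz_score <- function(x, labels) {
    x <- as.matrix(x)
    labs <- sort(unique(labels))
    k <- length(labs)
    n <- nrow(x)
    if (k < 2 || n <= k) return(NA_real_)
    grand <- colMeans(x)
    B <- 0; W <- 0
    for (l in labs) {
        pts <- x[labels == l, , drop = FALSE]
        cl <- colMeans(pts)
        B <- B + nrow(pts) * sum((cl - grand)^2)
        W <- W + sum(sweep(pts, 2, cl)^2)
    }
    (B / (k - 1)) / (W / (n - k))
}

summarise_labels <- function(labels) {
    list(n_clusters = length(unique(labels[labels >= 0])),
         pct_unclassified = 100 * mean(labels == -1))
}

#' Sweep clustering parameters
#'
#' Runs UMAP + HDBSCAN for every combination of `n_values` (UMAP neighbours)
#' and `c_values` (HDBSCAN minimum cluster size), computing per combination
#' the number of clusters, the percentage of unclassified windows and the
#' silhouette / Davies-Bouldin / Calinski-Harabasz metrics on the embedding
#' coordinates of classified windows. One UMAP embedding is computed per
#' `n` and reused across `c` values.
#'
#' @param fm A `feature_matrix`.
#' @param n_values UMAP neighbour counts (default `c(5, 10, 15, 20)`).
#' @param c_values HDBSCAN minimum cluster sizes
#'   (default `c(50, 100, 200, 500)`).
#' @param min_dist,seed Shared UMAP parameters, see [clustering_params()].
#' @return A data.frame with one row per `(n, c)` combination; the
#'   embeddings and labels of every combination are attached as the
#'   `"results"` attribute (a list keyed `"n_c"`).
#' @export
sweep_clusterings <- function(fm, n_values = c(5, 10, 15, 20),
                              c_values = c(50, 100, 200, 500),
                              min_dist = 0.1, seed = 42) {
    stopifnot(length(n_values) > 0, length(c_values) > 0)
    n_values <- as.integer(n_values)
    c_values <- as.integer(c_values)
    n_win <- nrow(fm$scaled)
    if (any(n_values >= n_win)) {
        stop("n_values must be smaller than the number of windows")
    }
    mat_file <- write_matrix_tmp(fm$scaled)
    on.exit(unlink(mat_file))
    out <- tempfile(fileext = ".tsv")
    on.exit(unlink(out), add = TRUE)
    jobs <- lapply(n_values, function(n) {
        list(n = n, min_dist = min_dist, seed = seed, c = as.list(c_values))
    })
    run_python_worker("sweep", mat_file, jobs, out)
    long <- read.delim(out)
    rows <- list()
    results <- list()
    for (n in n_values) {
        for (cc in c_values) {
            sel <- long$n == n & long$c == cc
            sub <- long[sel, ][order(long$row[sel]), ]
            emb <- cbind(x = sub$x, y = sub$y)
            labels <- sub$label
            met <- clustering_metrics(emb, labels)
            s <- summarise_labels(labels)
            rows[[length(rows) + 1]] <- data.frame(
                n = n, c = cc, n_clusters = s$n_clusters,
                pct_unclassified = s$pct_unclassified,
                silhouette = met$silhouette,
                davies_bouldin = met$davies_bouldin,
                calinski_harabasz = met$calinski_harabasz)
            results[[sprintf("%d_%d", n, cc)]] <-
                list(n = n, c = cc, embedding = emb, labels = labels)
        }
    }
    tab <- do.call(rbind, rows)
    attr(tab, "results") <- results
    attr(tab, "params") <- list(min_dist = min_dist, seed = seed)
    tab
}

#' Select clustering parameters from a sweep table
#'
#' Advisory, deterministic ranking of sweep results: keep combinations with
#' at least two clusters, then sort by percentage of unclassified windows
#' (ascending), silhouette (descending) and number of clusters
#' (descending); ties are broken by smaller `n`, then smaller `c`. A final
#' run should still set `(n, c)` explicitly after inspecting the sweep.
#'
#' @param sweep A table from [sweep_clusterings()].
#' @return A [clustering_params()] for the top-ranked combination.
#' @export
select_params <- function(sweep) {
    valid <- sweep[sweep$n_clusters >= 2, , drop = FALSE]
    if (nrow(valid) == 0) {
        stop("no parameter combination produced >= 2 clusters")
    }
    sil <- ifelse(is.na(valid$silhouette), -Inf, valid$silhouette)
    o <- order(valid$pct_unclassified, -sil, -valid$n_clusters,
               valid$n, valid$c)
    top <- valid[o[1], ]
    p <- attr(sweep, "params")
    clustering_params(n = top$n, c = top$c,
                      min_dist = if (is.null(p)) 0.1 else p$min_dist,
                      seed = if (is.null(p)) 42 else p$seed)
}
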