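## End-to-end pipeline drivers: configuration, extraction, sweep, final
## clustering run with tables, BED and static figures.

#' Pipeline configuration
#'
#' Collects every tunable of a run. The resolved configuration is written
#' as JSON next to the outputs of each stage, together with its hash and
#' seed, so a run can be reproduced exactly.
#'
#' @param window_size Window size in bp (default 5000).
#' @param telomere_motif Telomeric motif (default `TTTAGGG`).
#' @param include_cag Include the CAG motif track (default `TRUE`).
#' @param kmer_sizes K-mer deviation sizes (default `c(3, 4)`).
#' @param fragment_length,fold Mappability surrogate parameters.
#' @param exclude Feature names to exclude from the matrix.
#' @param n_values,c_values Sweep grids for UMAP neighbours and HDBSCAN
#'   minimum cluster size.
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param alpha KS significance level for cluster calls (default 1e-20).
#' @param seed Random seed (default 42).
#' @return A `run_config` list.
#' @export
run_config <- function(window_size = 5000, telomere_motif = "TTTAGGG",
                       include_cag = TRUE, kmer_sizes = c(3, 4),
                       fragment_length = 150, fold = 10,
                       exclude = character(),
                       n_values = c(5, 10, 15, 20),
                       c_values = c(50, 100, 200, 500),
                       min_dist = 0.1, alpha = 1e-20, seed = 42) {
    structure(list(window_size = as.integer(window_size),
                   telomere_motif = telomere_motif,
                   include_cag = include_cag,
                   kmer_sizes = as.integer(kmer_sizes),
                   fragment_length = as.integer(fragment_length),
                   fold = as.integer(fold), exclude = exclude,
                   n_values = as.integer(n_values),
                   c_values = as.integer(c_values),
                   min_dist = as.numeric(min_dist),
                   alpha = as.numeric(alpha), seed = as.integer(seed)),
              class = "run_config")
}

config_json <- function(config) {
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
}

config_hash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(config_json(config), tmp)
    unname(tools::md5sum(tmp))
}

#' Read / write a run configuration as JSON
#' @param config A `run_config` (writer) or path (reader).
#' @param path Output path.
#' @return The path (writer) / a `run_config` (reader).
#' @export
write_config <- function(config, path) {
    writeLines(config_json(config), path)
    invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(run_config, vals)
}

stage_log <- function(stage, t0) {
    message(sprintf("[genarch] %-28s %8.1f s", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Extract all feature tracks and build the feature matrix
#'
#' Runs the window partition, the sequence feature set, optionally the
#' gene-annotation feature set and the re-binning of external bedgraph
#' tracks, and merges everything into a `feature_matrix`. When `outdir` is
#' given, per-feature bedgraphs, the matrix TSV and the resolved
#' configuration are written there.
#'
#' @param fasta Path to the assembly FASTA, or a `DNAStringSet`.
#' @param gff3 Optional path to a GFF3 gene annotation.
#' @param tracks Optional named character vector (or list) of bedgraph
#'   paths to re-bin onto the grid.
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return A `feature_matrix`.
#' @export
run_extract <- function(fasta, gff3 = NULL, tracks = NULL,
                        config = run_config(), outdir = NULL) {
    t0 <- as.numeric(Sys.time())
    assembly <- if (is.character(fasta)) read_assembly(fasta) else fasta
    grid <- window_grid(assembly, config$window_size)
    stage_log("windows", t0)
    all_tracks <- seq_feature_tracks(
        assembly, grid, telomere_motif = config$telomere_motif,
        include_cag = config$include_cag, kmer_sizes = config$kmer_sizes,
        fragment_length = config$fragment_length, fold = config$fold)
    stage_log("seq features", t0)
    if (!is.null(gff3)) {
        models <- read_gene_models(gff3, attr(grid, "seqlengths"))
        all_tracks <- c(all_tracks, gene_density_tracks(models, grid))
        stage_log("gene features", t0)
    }
    if (!is.null(tracks) && length(tracks) > 0) {
        if (is.null(names(tracks))) {
            names(tracks) <- tools::file_path_sans_ext(basename(
                unlist(tracks)))
        }
        for (nm in names(tracks)) {
            all_tracks[[nm]] <- rebin_bedgraph(tracks[[nm]], grid)
        }
        stage_log("external tracks", t0)
    }
    fm <- feature_matrix(all_tracks, grid, exclude = config$exclude)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (f in fm$feature_names) {
            write_bedgraph(fm$raw[, f], grid,
                           file.path(outdir, paste0(f, ".bedgraph")), f)
        }
        write_feature_tsv(fm, file.path(outdir, "feature_matrix.tsv"))
        write_config(config, file.path(outdir, "config.json"))
        stage_log("outputs written", t0)
    }
    fm
}

#' Sweep clustering parameters and recommend a combination
#'
#' @param fm A `feature_matrix` (or path to a matrix TSV).
#' @param config A [run_config()] providing the sweep grids and seed.
#' @param outdir Optional output directory for the sweep TSV and
#'   recommendation.
#' @return The sweep table (see [sweep_clusterings()]) with the
#'   recommendation attached as attribute `"recommended"`.
#' @export
run_sweep <- function(fm, config = run_config(), outdir = NULL) {
    if (is.character(fm)) fm <- read_feature_tsv(fm)
    tab <- sweep_clusterings(fm, n_values = config$n_values,
                             c_values = config$c_values,
                             min_dist = config$min_dist,
                             seed = config$seed)
    rec <- tryCatch(select_params(tab), error = function(e) NULL)
    attr(tab, "recommended") <- rec
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        out <- tab
        attributes(out) <- attributes(out)[c("names", "row.names", "class")]
        write.table(out, file.path(outdir, "sweep.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        if (!is.null(rec)) {
            writeLines(jsonlite::toJSON(unclass(rec), auto_unbox = TRUE),
                       file.path(outdir, "recommended_params.json"))
        }
        write_config(config, file.path(outdir, "config.json"))
    }
    tab
}

#' Run the final clustering and characterisation
#'
#' Embeds and clusters the windows at an explicit `(n, c)`, characterises
#' the clusters (KS tests, heatmap table, junction enrichment) and, when
#' `outdir` is given, writes the cluster BED, the KS / junction / heatmap
#' TSVs, the resolved configuration and static figures (embedding scatter,
#' chromosome cluster paint, feature heatmap).
#'
#' @param fm A `feature_matrix` (or path to a matrix TSV).
#' @param n UMAP number of neighbours.
#' @param c HDBSCAN minimum cluster size.
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return List with `params`, `embedding`, `labels`, `metrics`,
#'   `n_clusters`, `pct_unclassified`, `ks`, `heatmap`, `junctions`.
#' @export
run_cluster <- function(fm, n, c, config = run_config(), outdir = NULL) {
    if (is.character(fm)) fm <- read_feature_tsv(fm)
    params <- clustering_params(n = n, c = c, min_dist = config$min_dist,
                                seed = config$seed)
    emb <- embed_windows(fm, params)
    labels <- cluster_embedding(emb, params)
    met <- clustering_metrics(emb, labels)
    s <- summarise_labels(labels)
    ks <- if (s$n_clusters >= 2) {
        characterise_clusters(fm, labels, alpha = config$alpha)
    } else NULL
    hm <- if (!is.null(ks)) heatmap_table(ks) else NULL
    jt <- junction_enrichment(labels, fm$grid)
    res <- list(params = params, embedding = emb, labels = labels,
                metrics = met, n_clusters = s$n_clusters,
                pct_unclassified = s$pct_unclassified,
                ks = ks, heatmap = hm, junctions = jt)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_cluster_bed(labels, fm$grid,
                          file.path(outdir, "clusters.bed"))
        if (!is.null(ks)) {
            ks_out <- ks
            for (col in c("D_plus", "D_minus", "p_plus", "p_minus",
                          "mean_scaled")) {
                ks_out[[col]] <- format_num(ks_out[[col]])
            }
            write.table(ks_out, file.path(outdir, "ks_tests.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write_heatmap_tsv(hm, file.path(outdir, "heatmap.tsv"))
        }
        jt_out <- jt
        for (col in c("expected", "odds_ratio", "p", "q")) {
            jt_out[[col]] <- format_num(jt_out[[col]])
        }
        write.table(jt_out, file.path(outdir, "junctions.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        emb_out <- data.frame(fm$grid$scaffold, fm$grid$start,
                              fm$grid$end, format_num(emb[, 1]),
                              format_num(emb[, 2]), labels)
        colnames(emb_out) <- c("scaffold", "start", "end", "x", "y",
                               "label")
        write.table(emb_out, file.path(outdir, "embedding.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write_config(config, file.path(outdir, "config.json"))
        writeLines(sprintf("config_hash\t%s\nseed\t%d",
                           config_hash(config), config$seed),
                   file.path(outdir, "run_info.tsv"))
        try(write_figures(res, fm, outdir), silent = TRUE)
    }
    res
}

cluster_palette <- function(labels) {
    labs <- sort(unique(labels))
    cols <- grDevices::hcl.colors(max(2, sum(labs >= 0)), "Dark 3")
    stats::setNames(c(if (any(labs == -1)) "grey70",
                      cols[seq_len(sum(labs >= 0))]),
                    as.character(labs))
}

write_figures <- function(res, fm, outdir) {
    labels <- factor(res$labels)
    pal <- cluster_palette(res$labels)
    df <- data.frame(x = res$embedding[, 1], y = res$embedding[, 2],
                     cluster = labels)
    p1 <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                           colour = cluster)) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::scale_colour_manual(values = pal) +
        ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = "cluster") +
        ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(outdir, "embedding.png"), p1,
                    width = 6, height = 5, dpi = 150)
    g <- fm$grid
    df2 <- data.frame(scaffold = g$scaffold, start = g$start, end = g$end,
                      cluster = labels)
    p2 <- ggplot2::ggplot(df2) +
        ggplot2::geom_rect(ggplot2::aes(xmin = start / 1e6,
                                        xmax = end / 1e6,
                                        ymin = 0, ymax = 1,
                                        fill = cluster)) +
        ggplot2::facet_grid(rows = ggplot2::vars(scaffold)) +
        ggplot2::scale_fill_manual(values = pal) +
        ggplot2::labs(x = "position (Mb)", y = NULL, fill = "cluster") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.y = ggplot2::element_blank())
    ggplot2::ggsave(file.path(outdir, "chromosome_paint.png"), p2,
                    width = 8, height = 1 + length(unique(g$scaffold)),
                    dpi = 150)
    if (!is.null(res$heatmap)) {
        hm <- res$heatmap
        df3 <- expand.grid(cluster = rownames(hm$values),
                           feature = colnames(hm$values),
                           stringsAsFactors = FALSE)
        df3$value <- hm$values[cbind(df3$cluster, df3$feature)]
        df3$icon <- hm$icons[cbind(df3$cluster, df3$feature)]
        p3 <- ggplot2::ggplot(df3, ggplot2::aes(x = feature,
                                                y = cluster)) +
            ggplot2::geom_tile(ggplot2::aes(fill = value)) +
            ggplot2::geom_text(ggplot2::aes(label = icon),
                               size = 3) +
            ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                          high = "red", midpoint = 0.5) +
            ggplot2::labs(x = NULL, y = "cluster",
                          fill = "mean scaled") +
            ggplot2::theme_minimal() +
            ggplot2::theme(axis.text.x = ggplot2::element_text(
                angle = 45, hjust = 1))
        ggplot2::ggsave(file.path(outdir, "heatmap.png"), p3,
                        width = 2 + 0.4 * ncol(hm$values),
                        height = 1.5 + 0.4 * nrow(hm$values), dpi = 150)
    }
    invisible(outdir)
}
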