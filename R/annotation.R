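## Gene-annotation-derived feature tracks and external track re-binning.

#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 gene/transcript/exon hierarchy into one gene model per
#' transcript-bearing gene, keeping the longest transcript where a gene has
#' several. Feature type `protein_coding_gene` is normalised to `gene`;
#' gene models are typed `mRNA`, `tRNA`, `rRNA` or `pseudogene` from their
#' transcript's type. Genes without transcript children are treated as
#' single-exon models of type `mRNA` (or their own type for
#' tRNA/rRNA/pseudogene records placed at gene level).
#'
#' @param path Path to a GFF3 file.
#' @param seqlengths Optional named scaffold lengths; when given, any feature
#'   extending beyond its scaffold raises an error naming the feature.
#' @return A data.frame with one row per gene: `id`, `scaffold`, `start`,
#'   `end` (0-based half-open), `strand`, `type`, `n_exons`, `gene_length`,
#'   `mean_exon_length`, `mean_intron_length`, plus list columns
#'   `exon_starts` / `exon_ends`.
#' @export
read_gene_models <- function(path, seqlengths = NULL) {
    gff <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gff$type)
    type[type == "protein_coding_gene"] <- "gene"
    id <- as.character(gff$ID)
    parent <- vapply(gff$Parent, function(p) {
        if (length(p) == 0) NA_character_ else as.character(p)[1]
    }, character(1))

    tx_types <- c("mRNA", "tRNA", "rRNA", "pseudogene", "transcript")
    is_gene <- type %in% c("gene", "tRNA_gene", "rRNA_gene", "pseudogene")
    is_tx <- type %in% tx_types & !is.na(parent)
    is_exon <- type == "exon"
    if (any(is_exon & is.na(parent))) {
        stop("exon without Parent in ", path)
    }
    if (any(is_exon)) {
        known <- c(id[is_tx], id[is_gene])
        orphan <- setdiff(parent[is_exon], known)
        if (length(orphan) > 0) {
            stop("exon Parent(s) not found: ", paste(orphan, collapse = ", "))
        }
    }

    gene_idx <- which(is_gene)
    if (length(gene_idx) == 0) stop("no gene features found in ", path)
    models <- lapply(gene_idx, function(i) {
        gid <- id[i]
        tx <- which(is_tx & parent == gid)
        ttype <- "mRNA"
        if (type[i] %in% c("tRNA_gene")) ttype <- "tRNA"
        if (type[i] %in% c("rRNA_gene")) ttype <- "rRNA"
        if (type[i] == "pseudogene") ttype <- "pseudogene"
        if (length(tx) > 0) {
            tx <- tx[which.max(GenomicRanges::width(gff)[tx])]
            if (type[tx] %in% c("mRNA", "tRNA", "rRNA", "pseudogene")) {
                ttype <- type[tx]
            }
            ex <- which(is_exon & parent == id[tx])
        } else {
            ex <- which(is_exon & parent == gid)
        }
        if (length(ex) == 0) {
            ex_start <- GenomicRanges::start(gff)[i] - 1L
            ex_end <- GenomicRanges::end(gff)[i]
        } else {
            o <- order(GenomicRanges::start(gff)[ex])
            ex_start <- GenomicRanges::start(gff)[ex][o] - 1L
            ex_end <- GenomicRanges::end(gff)[ex][o]
        }
        list(id = gid,
             scaffold = as.character(GenomicRanges::seqnames(gff))[i],
             start = GenomicRanges::start(gff)[i] - 1L,
             end = GenomicRanges::end(gff)[i],
             strand = as.character(GenomicRanges::strand(gff))[i],
             type = ttype, exon_starts = ex_start, exon_ends = ex_end)
    })
    out <- data.frame(
        id = vapply(models, `[[`, character(1), "id"),
        scaffold = vapply(models, `[[`, character(1), "scaffold"),
        start = vapply(models, `[[`, integer(1), "start"),
        end = vapply(models, `[[`, integer(1), "end"),
        strand = vapply(models, `[[`, character(1), "strand"),
        type = vapply(models, `[[`, character(1), "type"),
        stringsAsFactors = FALSE)
    out$exon_starts <- lapply(models, `[[`, "exon_starts")
    out$exon_ends <- lapply(models, `[[`, "exon_ends")
    out$n_exons <- vapply(out$exon_starts, length, integer(1))
    out$gene_length <- out$end - out$start
    out$mean_exon_length <- vapply(seq_len(nrow(out)), function(i) {
        mean(out$exon_ends[[i]] - out$exon_starts[[i]])
    }, numeric(1))
    out$mean_intron_length <- vapply(seq_len(nrow(out)), function(i) {
        s <- out$exon_starts[[i]]; e <- out$exon_ends[[i]]
        if (length(s) < 2) return(0)
        mean(s[-1] - e[-length(e)])
    }, numeric(1))
    if (!is.null(seqlengths)) {
        bad <- which(!(out$scaffold %in% names(seqlengths)) |
                     out$end > seqlengths[out$scaffold] | out$start < 0)
        if (length(bad) > 0) {
            stop("feature(s) outside scaffold bounds: ",
                 paste(out$id[bad], collapse = ", "))
        }
    }
    out
}

models_granges <- function(models) {
    GenomicRanges::GRanges(models$scaffold,
                           IRanges::IRanges(models$start + 1L, models$end))
}

#' Gene-annotation feature tracks
#'
#' Computes the annotation-derived feature set on a window grid: per-type
#' gene density counts (`mRNA_annotations`, `tRNA_annotations`,
#' `rRNA_annotations`, `pseudogene_annotations`) and per-window means over
#' the overlapping genes (`gene_length`, `exon_count`,
#' `gene_average_exon_length`, `gene_average_intron_length`). A gene
#' overlapping several windows is counted in each of them; windows with no
#' genes get 0 everywhere.
#'
#' @param models Gene models from [read_gene_models()].
#' @param grid A `window_grid`.
#' @return Named list of numeric vectors, grid order.
#' @export
gene_density_tracks <- function(models, grid) {
    n <- nrow(grid)
    zero <- numeric(n)
    tracks <- list(mRNA_annotations = zero, tRNA_annotations = zero,
                   rRNA_annotations = zero, pseudogene_annotations = zero,
                   gene_length = zero, exon_count = zero,
                   gene_average_exon_length = zero,
                   gene_average_intron_length = zero)
    if (nrow(models) == 0) return(tracks)
    extra <- setdiff(unique(models$scaffold), names(attr(grid, "seqlengths")))
    if (length(extra) > 0) {
        stop("gene models on scaffolds absent from grid: ",
             paste(extra, collapse = ", "))
    }
    hits <- GenomicRanges::findOverlaps(models_granges(models),
                                        grid_granges(grid))
    g <- S4Vectors::queryHits(hits)
    w <- S4Vectors::subjectHits(hits)
    count_type <- function(t) {
        sel <- models$type[g] == t
        as.numeric(tabulate(w[sel], nbins = n))
    }
    tracks$mRNA_annotations <- count_type("mRNA")
    tracks$tRNA_annotations <- count_type("tRNA")
    tracks$rRNA_annotations <- count_type("rRNA")
    tracks$pseudogene_annotations <- count_type("pseudogene")
    mean_by_window <- function(vals) {
        s <- tapply(vals[g], w, mean)
        out <- zero
        out[as.integer(names(s))] <- as.numeric(s)
        out
    }
    tracks$gene_length <- mean_by_window(models$gene_length)
    tracks$exon_count <- mean_by_window(models$n_exons)
    tracks$gene_average_exon_length <- mean_by_window(models$mean_exon_length)
    tracks$gene_average_intron_length <-
        mean_by_window(models$mean_intron_length)
    tracks
}

#' Re-bin a bedgraph track onto a window grid
#'
#' Maps arbitrary per-interval numeric tracks (precomputed repeat densities,
#' ChIP log-ratios, ...) onto the window grid. The default aggregator is the
#' length-weighted mean over the window, with uncovered bases contributing 0;
#' `"sum"` allocates each interval's value to windows proportionally to
#' overlap, for count-like tracks. Intervals extending past the scaffold end
#' are clipped with a warning.
#'
#' @param x Path to a bedgraph file, or a `GRanges` with a `score` column.
#' @param grid A `window_grid`.
#' @param aggregator `"mean"` (length-weighted, default) or `"sum"`.
#' @return Numeric vector, one value per window.
#' @export
rebin_bedgraph <- function(x, grid, aggregator = c("mean", "sum")) {
    aggregator <- match.arg(aggregator)
    if (is.character(x)) {
        x <- rtracklayer::import(x, format = "bedGraph")
    }
    stopifnot(methods::is(x, "GRanges"), !is.null(x$score))
    lens <- attr(grid, "seqlengths")
    keep <- as.character(GenomicRanges::seqnames(x)) %in% names(lens)
    if (!all(keep)) {
        warning("dropping ", sum(!keep), " interval(s) on scaffolds absent ",
                "from the grid")
        x <- x[keep]
    }
    ends <- lens[as.character(GenomicRanges::seqnames(x))]
    if (any(GenomicRanges::end(x) > ends)) {
        warning("clipping interval(s) beyond scaffold end")
        GenomicRanges::end(x) <- pmin(GenomicRanges::end(x), ends)
        x <- x[GenomicRanges::width(x) > 0]
    }
    win <- grid_granges(grid)
    hits <- GenomicRanges::findOverlaps(x, win)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(x[q], win[s]))
    out <- numeric(nrow(grid))
    if (length(q) > 0) {
        val <- if (aggregator == "mean") x$score[q] * ov
               else x$score[q] * ov / GenomicRanges::width(x)[q]
        acc <- tapply(val, s, sum)
        out[as.integer(names(acc))] <- as.numeric(acc)
    }
    if (aggregator == "mean") out <- out / window_lengths(grid)
    out
}

#' Find homopolymeric amino acid repeats (HAARs) in proteins
#'
#' Maximal single-residue runs of at least `min_run` residues, by default for
#' alanine, serine, glutamine, leucine and asparagine.
#'
#' @param proteins An `AAStringSet`, a named character vector of protein
#'   sequences, or a path to a protein FASTA file.
#' @param residues Residues to scan (single letters).
#' @param min_run Minimum run length (default 7).
#' @return data.frame with one row per run: `protein`, `residue`, `start`
#'   (1-based), `length`.
#' @export
find_haars <- function(proteins, residues = c("A", "S", "Q", "L", "N"),
                       min_run = 7) {
    if (is.character(proteins) && length(proteins) == 1 &&
        file.exists(proteins)) {
        proteins <- Biostrings::readAAStringSet(proteins)
    }
    ids <- names(proteins)
    seqs <- toupper(as.character(proteins))
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    out <- list()
    for (r in residues) {
        pat <- sprintf("%s{%d,}", r, as.integer(min_run))
        m <- gregexpr(pat, seqs)
        for (i in seq_along(seqs)) {
            st <- m[[i]]
            if (st[1] == -1) next
            out[[length(out) + 1]] <- data.frame(
                protein = ids[i], residue = r, start = as.integer(st),
                length = attr(st, "match.length"), stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0) {
        return(data.frame(protein = character(), residue = character(),
                          start = integer(), length = integer()))
    }
    res <- do.call(rbind, out)
    res[order(match(res$protein, ids), res$start), , drop = FALSE]
}
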