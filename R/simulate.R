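## Synthetic genomes with planted architecture: contrasting segments
## (GC-rich telomere-adjacent motif arrays, duplicated gene-family arrays,
## AT-rich gene-dense cores, repeat bands, gene deserts) with truth labels,
## so every pipeline stage is testable without external data.

with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Specify one planted genome segment
#'
#' @param label Truth label of the segment (e.g. `"core"`).
#' @param length Segment length in bp.
#' @param gc Target GC fraction of the i.i.d. background sequence
#'   (0 < gc < 1).
#' @param motif Optional motif planted as tandem arrays (e.g. the telomeric
#'   repeat `TTTAGGG`).
#' @param motif_copies Total motif copies across the arrays.
#' @param n_motif_arrays Number of arrays the copies are split into.
#' @param dup_unit,dup_copies Optional tandem duplication: a `dup_unit` bp
#'   sequence repeated `dup_copies` times verbatim (low sequence
#'   uniqueness, emulating multigene-family arrays).
#' @param genes_per_10kb Gene density (genes per 10 kb; 0 = none).
#' @param gene_mean_length Mean planted gene length in bp.
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(label, length, gc = 0.5, motif = NULL,
                         motif_copies = 0, n_motif_arrays = 4,
                         dup_unit = 0, dup_copies = 0,
                         genes_per_10kb = 0, gene_mean_length = 1500) {
    stopifnot(length > 0, gc > 0, gc < 1)
    if (dup_unit > 0 && dup_unit * dup_copies > length) {
        stop("duplication array does not fit in segment '", label, "'")
    }
    structure(list(label = label, length = as.integer(length), gc = gc,
                   motif = motif, motif_copies = as.integer(motif_copies),
                   n_motif_arrays = as.integer(n_motif_arrays),
                   dup_unit = as.integer(dup_unit),
                   dup_copies = as.integer(dup_copies),
                   genes_per_10kb = genes_per_10kb,
                   gene_mean_length = gene_mean_length),
              class = "segment_spec")
}

random_bases <- function(n, gc) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

rc_chr <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Replace seg[at..] with `ins`, in place (both character vectors of bases).
splice_in <- function(seg, ins, at) {
    seg[at:(at + length(ins) - 1L)] <- ins
    seg
}

build_segment <- function(spec) {
    seg <- random_bases(spec$length, spec$gc)
    if (!is.null(spec$motif) && spec$motif_copies > 0) {
        n_arr <- max(1L, spec$n_motif_arrays)
        per <- diff(round(seq(0, spec$motif_copies, length.out = n_arr + 1)))
        slot <- spec$length %/% n_arr
        for (i in seq_len(n_arr)) {
            if (per[i] == 0) next
            arr <- strrep(spec$motif, per[i])
            if (stats::runif(1) < 0.5) arr <- rc_chr(arr)
            arr <- strsplit(arr, "")[[1]]
            if (length(arr) > slot) {
                stop("motif array longer than its slot in segment '",
                     spec$label, "'")
            }
            at <- (i - 1L) * slot +
                sample.int(slot - length(arr) + 1L, 1)
            seg <- splice_in(seg, arr, at)
        }
    }
    if (spec$dup_unit > 0 && spec$dup_copies > 0) {
        unit <- random_bases(spec$dup_unit, spec$gc)
        arr <- rep(unit, spec$dup_copies)
        at <- sample.int(spec$length - length(arr) + 1L, 1)
        seg <- splice_in(seg, arr, at)
    }
    seg
}

place_genes <- function(spec, offset, scaffold, counter) {
    n_genes <- round(spec$length * spec$genes_per_10kb / 1e4)
    if (n_genes < 1) return(NULL)
    slot <- spec$length / n_genes
    if (spec$gene_mean_length >= 0.9 * slot) {
        stop("genes of mean length ", spec$gene_mean_length,
             " do not fit at density ", spec$genes_per_10kb,
             " per 10 kb in segment '", spec$label, "'")
    }
    rows <- list()
    for (i in seq_len(n_genes)) {
        len <- round(stats::rnorm(1, spec$gene_mean_length,
                                  0.2 * spec$gene_mean_length))
        len <- max(300L, min(as.integer(len), as.integer(0.9 * slot)))
        slack <- floor(slot) - len
        g_start <- offset + as.integer((i - 1) * slot) +
            (if (slack > 0) sample.int(slack, 1) else 1L) - 1L
        n_ex <- sample.int(4L, 1)
        # introns of 100-300 bp between exons, exons share the rest
        introns <- if (n_ex > 1) sample(100:300, n_ex - 1, replace = TRUE)
                   else integer(0)
        ex_total <- len - sum(introns)
        if (ex_total < n_ex * 50) { n_ex <- 1L; introns <- integer(0)
                                    ex_total <- len }
        cuts <- sort(sample.int(ex_total - 1, n_ex - 1))
        ex_len <- diff(c(0, cuts, ex_total))
        ex_start <- g_start + cumsum(c(0, utils::head(ex_len, -1) +
                                            introns))
        rows[[i]] <- data.frame(
            id = sprintf("gene%05d", counter + i),
            scaffold = scaffold, start = g_start, end = g_start + len,
            strand = sample(c("+", "-"), 1), type = "mRNA",
            stringsAsFactors = FALSE)
        rows[[i]]$exon_starts <- list(as.integer(ex_start))
        rows[[i]]$exon_ends <- list(as.integer(ex_start + ex_len))
    }
    do.call(rbind, rows)
}

#' Simulate a genome with planted architecture
#'
#' Per chromosome, the segments are concatenated in order; each segment's
#' background is drawn i.i.d. at its target GC, motif arrays and tandem
#' duplications are spliced in verbatim, and genes are placed uniformly at
#' the stated density with 1-4 exons. Every base carries its segment's
#' truth label.
#'
#' @param plans Named list of chromosomes, each a list of
#'   [segment_spec()]s.
#' @param seed Random seed; the same seed reproduces the genome exactly.
#' @return A `simulated_genome` list: `assembly` (`DNAStringSet`), `genes`
#'   (data.frame as in [read_gene_models()]), `truth` (data.frame
#'   `scaffold`, `start`, `end`, `label`, 0-based half-open) and `seed`.
#' @export
simulate_genome <- function(plans, seed = 42) {
    stopifnot(length(plans) > 0)
    if (is.null(names(plans)) || any(!nzchar(names(plans)))) {
        names(plans) <- sprintf("chr%d", seq_along(plans))
    }
    with_seed(seed, {
        seqs <- character(length(plans))
        truth <- list()
        genes <- list()
        counter <- 0L
        for (ci in seq_along(plans)) {
            chrom <- names(plans)[ci]
            offset <- 0L
            parts <- character(length(plans[[ci]]))
            for (si in seq_along(plans[[ci]])) {
                spec <- plans[[ci]][[si]]
                stopifnot(methods::is(spec, "segment_spec"))
                parts[si] <- paste(build_segment(spec), collapse = "")
                truth[[length(truth) + 1]] <- data.frame(
                    scaffold = chrom, start = offset,
                    end = offset + spec$length, label = spec$label,
                    stringsAsFactors = FALSE)
                if (spec$genes_per_10kb > 0) {
                    g <- place_genes(spec, offset, chrom, counter)
                    if (!is.null(g)) {
                        counter <- counter + nrow(g)
                        genes[[length(genes) + 1]] <- g
                    }
                }
                offset <- offset + spec$length
            }
            seqs[ci] <- paste(parts, collapse = "")
        }
        assembly <- Biostrings::DNAStringSet(seqs)
        names(assembly) <- names(plans)
        genes <- if (length(genes) > 0) do.call(rbind, genes) else
            data.frame(id = character(), scaffold = character(),
                       start = integer(), end = integer(),
                       strand = character(), type = character())
        if (nrow(genes) > 0) {
            genes$n_exons <- vapply(genes$exon_starts, length, integer(1))
            genes$gene_length <- genes$end - genes$start
            genes$mean_exon_length <- vapply(seq_len(nrow(genes)),
                function(i) mean(genes$exon_ends[[i]] -
                                 genes$exon_starts[[i]]), numeric(1))
            genes$mean_intron_length <- vapply(seq_len(nrow(genes)),
                function(i) {
                    s <- genes$exon_starts[[i]]; e <- genes$exon_ends[[i]]
                    if (length(s) < 2) 0 else mean(s[-1] - e[-length(e)])
                }, numeric(1))
        }
        structure(list(assembly = assembly, genes = genes,
                       truth = do.call(rbind, truth), seed = seed),
                  class = "simulated_genome")
    })
}

#' @export
print.simulated_genome <- function(x, ...) {
    cat(sprintf("simulated_genome: %d chromosome(s), %s bp, %d gene(s), seed %d\n",
                length(x$assembly),
                format(sum(Biostrings::width(x$assembly)), big.mark = ","),
                nrow(x$genes), x$seed))
    invisible(x)
}

#' Parasite-like genome preset
#'
#' Three chromosomes (1.2, 1.0 and 0.8 Mb) with the architecture typical of
#' *Plasmodium*-like parasite genomes: GC-richer telomere-adjacent repeat
#' arrays built from the telomeric motif (TARE-like, 50 kb per end),
#' flanking tandem-duplicated gene-family arrays with low sequence
#' uniqueness (100 kb per end, a 10 kb unit in 6 copies), and an AT-rich,
#' gene-dense conserved core in between. Truth labels: `tare`, `family`,
#' `core`.
#'
#' @return A plans list for [simulate_genome()].
#' @export
parasite_preset <- function() {
    one_chrom <- function(len) {
        tare <- function() segment_spec(
            "tare", 5e4, gc = 0.30, motif = "TTTAGGG",
            motif_copies = 2000, n_motif_arrays = 8)
        family <- function() segment_spec(
            "family", 1e5, gc = 0.22, dup_unit = 1.6e4, dup_copies = 6,
            genes_per_10kb = 3, gene_mean_length = 1500)
        core <- segment_spec("core", len - 3e5, gc = 0.19,
                             genes_per_10kb = 2, gene_mean_length = 2200)
        list(tare(), family(), core, family(), tare())
    }
    list(chr1 = one_chrom(1.2e6), chr2 = one_chrom(1.0e6),
         chr3 = one_chrom(0.8e6))
}

#' Write a simulated genome to disk
#'
#' Writes the assembly FASTA, the gene annotation GFF3 (gene/mRNA/exon
#' hierarchy) and the truth BED (`scaffold start end label`).
#'
#' @param sim A `simulated_genome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "genome.fasta")
    gff <- file.path(dir, "genes.gff3")
    bed <- file.path(dir, "truth.bed")
    Biostrings::writeXStringSet(sim$assembly, fasta)
    export_gene_gff3(sim$genes, gff)
    write.table(sim$truth, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(c(fasta = fasta, gff3 = gff, truth = bed))
}

export_gene_gff3 <- function(genes, path) {
    if (nrow(genes) == 0) {
        rtracklayer::export(GenomicRanges::GRanges(), path, format = "gff3")
        return(invisible(path))
    }
    rows <- list()
    for (i in seq_len(nrow(genes))) {
        gid <- genes$id[i]
        tid <- paste0(gid, ".1")
        ex_s <- genes$exon_starts[[i]]
        ex_e <- genes$exon_ends[[i]]
        rows[[length(rows) + 1]] <- data.frame(
            scaffold = genes$scaffold[i],
            start = c(genes$start[i], genes$start[i], ex_s) + 1L,
            end = c(genes$end[i], genes$end[i], ex_e),
            strand = genes$strand[i],
            type = c("gene", "mRNA", rep("exon", length(ex_s))),
            ID = c(gid, tid, paste0(tid, ".exon", seq_along(ex_s))),
            Parent = c(NA, gid, rep(tid, length(ex_s))),
            stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$scaffold,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gr$type <- df$type
    gr$ID <- df$ID
    gr$Parent <- IRanges::CharacterList(lapply(df$Parent, function(p) {
        if (is.na(p)) character(0) else p
    }))
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Majority truth label per window
#'
#' @param truth Truth intervals (`scaffold`, `start`, `end`, `label`,
#'   0-based half-open), e.g. from [simulate_genome()].
#' @param grid A `window_grid`.
#' @return Character vector of per-window majority labels.
#' @export
window_truth <- function(truth, grid) {
    tr <- GenomicRanges::GRanges(truth$scaffold,
                                 IRanges::IRanges(truth$start + 1L,
                                                  truth$end))
    win <- grid_granges(grid)
    hits <- GenomicRanges::findOverlaps(tr, win)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(tr[q], win[s]))
    out <- rep(NA_character_, nrow(grid))
    best <- rep(0L, nrow(grid))
    for (r in seq_along(q)) {
        if (ov[r] > best[s[r]]) {
            best[s[r]] <- ov[r]
            out[s[r]] <- truth$label[q[r]]
        }
    }
    if (any(is.na(out))) stop("truth intervals do not cover the grid")
    out
}

#' Score recovery of planted architecture
#'
#' Compares a clustering of windows against the planted truth labels with
#' the adjusted Rand index. Unclassified windows (`-1`) participate as
#' their own class.
#'
#' @param labels Integer cluster labels, grid order.
#' @param truth Truth intervals (see [window_truth()]).
#' @param grid A `window_grid`.
#' @return List with `ari` and the `confusion` table
#'   (truth x cluster).
#' @export
score_recovery <- function(labels, truth, grid) {
    tw <- window_truth(truth, grid)
    list(ari = mclust::adjustedRandIndex(labels, tw),
         confusion = table(truth = tw, cluster = labels))
}
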