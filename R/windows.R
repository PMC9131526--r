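#' Read a genome assembly from FASTA
#'
#' Reads a (plain or gzip-compressed) FASTA file into a
#' [Biostrings::DNAStringSet]. Sequences are normalised to uppercase;
#' characters outside `A/C/G/T/N` (IUPAC ambiguity codes, gaps, stray
#' letters) are mapped to `N` with a warning. All downstream features treat
#' sequence case-insensitively, so the normalisation is lossless for them.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A `DNAStringSet`, one entry per record, file order preserved.
#' @export
read_assembly <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("not readable as FASTA: ", path,
                                             " (", conditionMessage(e), ")"))
    if (length(raw) == 0) stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids)) {
        stop("duplicate sequence id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    chars <- toupper(as.character(raw))
    bad <- gsub("[ACGTN]", "", chars)
    if (any(nzchar(bad))) {
        offenders <- ids[nzchar(bad)]
        warning("non-ACGTN characters mapped to N in record(s): ",
                paste(offenders, collapse = ", "))
        chars <- gsub("[^ACGTN]", "N", chars)
    }
    if (any(!nzchar(chars))) {
        stop("zero-length sequence record: ", ids[!nzchar(chars)][1])
    }
    out <- Biostrings::DNAStringSet(chars)
    names(out) <- ids
    out
}

#' Partition an assembly into a fixed-size window grid
#'
#' Every scaffold is cut into contiguous, non-overlapping windows of
#' `window_size` bp in 0-based half-open coordinates. The trailing window of
#' each scaffold is retained even when shorter than `window_size`, so window
#' lengths sum exactly to scaffold lengths and each scaffold contributes
#' `ceiling(length / window_size)` windows. Scaffolds shorter than a window
#' yield a single short window.
#'
#' @param x A `DNAStringSet` (from [read_assembly()]) or a named integer
#'   vector of scaffold lengths.
#' @param window_size Window size in bp (default 5000).
#' @return A `window_grid`: a data.frame with columns `scaffold`, `start`,
#'   `end` (0-based half-open), carrying the window size and scaffold lengths
#'   as attributes.
#' @examples
#' window_grid(c(chr1 = 12000L), window_size = 5000)
#' @export
window_grid <- function(x, window_size = 5000) {
    if (!is.numeric(window_size) || length(window_size) != 1 ||
        is.na(window_size) || window_size < 1) {
        stop("window_size must be a single integer >= 1")
    }
    window_size <- as.integer(window_size)
    if (methods::is(x, "DNAStringSet") || methods::is(x, "XStringSet")) {
        lens <- stats::setNames(Biostrings::width(x), names(x))
    } else {
        lens <- x
    }
    if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
        stop("scaffold lengths must be named")
    }
    lens <- stats::setNames(as.integer(lens), names(lens))
    if (any(lens < 1)) stop("scaffold lengths must be positive")
    n_win <- as.integer(ceiling(lens / window_size))
    scaffold <- rep(names(lens), n_win)
    start <- unlist(lapply(n_win, function(k) (seq_len(k) - 1L) * window_size),
                    use.names = FALSE)
    end <- pmin(start + window_size, rep(lens, n_win))
    grid <- data.frame(scaffold = scaffold, start = start, end = end,
                       stringsAsFactors = FALSE)
    attr(grid, "window_size") <- window_size
    attr(grid, "seqlengths") <- lens
    class(grid) <- c("window_grid", "data.frame")
    grid
}

#' @export
print.window_grid <- function(x, ...) {
    cat(sprintf("window_grid: %d windows of %d bp over %d scaffold(s) (%s bp)\n",
                nrow(x), attr(x, "window_size"),
                length(attr(x, "seqlengths")),
                format(sum(attr(x, "seqlengths")), big.mark = ",")))
    invisible(x)
}

#' Window lengths of a grid
#' @param grid A `window_grid`.
#' @return Integer vector of window lengths (`end - start`).
#' @export
window_lengths <- function(grid) grid$end - grid$start

#' Convert a window grid to GRanges
#' @param grid A `window_grid`.
#' @return A [GenomicRanges::GRanges] with one range per window (1-based).
#' @export
grid_granges <- function(grid) {
    gr <- GenomicRanges::GRanges(
        seqnames = grid$scaffold,
        ranges = IRanges::IRanges(start = grid$start + 1L, end = grid$end))
    GenomeInfoDb::seqlengths(gr) <- attr(grid, "seqlengths")[
        GenomeInfoDb::seqlevels(gr)]
    gr
}

#' Extract per-window sequences
#' @param assembly A `DNAStringSet`.
#' @param grid A `window_grid` built from the same assembly.
#' @return A `DNAStringSet` of window sequences, grid order.
#' @export
window_sequences <- function(assembly, grid) {
    lens <- attr(grid, "seqlengths")
    if (!all(names(lens) %in% names(assembly))) {
        stop("grid scaffolds missing from assembly: ",
             paste(setdiff(names(lens), names(assembly)), collapse = ", "))
    }
    per_scaf <- split(IRanges::IRanges(start = grid$start + 1L, end = grid$end),
                      factor(grid$scaffold, levels = names(lens)))
    views <- Biostrings::extractAt(assembly[names(lens)],
                                   unname(as(per_scaf, "IRangesList")))
    out <- unlist(views, use.names = FALSE)
    names(out) <- sprintf("%s:%d-%d", grid$scaffold, grid$start, grid$end)
    out
}

#' Map window indices to genomic positions and back
#'
#' `window_of()` returns the grid row index containing each (scaffold,
#' position) pair; positions are 0-based.
#'
#' @param grid A `window_grid`.
#' @param scaffold Character vector of scaffold ids.
#' @param pos Integer vector of 0-based positions.
#' @return Integer vector of window indices (1-based row numbers).
#' @export
window_of <- function(grid, scaffold, pos) {
    w <- attr(grid, "window_size")
    lens <- attr(grid, "seqlengths")
    if (any(!scaffold %in% names(lens))) stop("unknown scaffold")
    if (any(pos < 0 | pos >= lens[scaffold])) stop("position out of range")
    n_win <- ceiling(lens / w)
    offset <- c(0, cumsum(n_win))[match(scaffold, names(lens))]
    as.integer(offset + pos %/% w + 1L)
}
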