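## Per-window sequence features. All functions are vectorised over windows,
## case-insensitive, and count a motif / k-mer / codon only when it lies
## wholly inside the window: features are computed per window sequence, so a
## match broken by a window border is counted in neither window.

as_window_set <- function(x) {
    if (methods::is(x, "DNAStringSet")) return(x)
    if (methods::is(x, "XString")) return(Biostrings::DNAStringSet(x))
    if (is.character(x)) {
        x <- toupper(x)
        if (any(grepl("[^ACGTN]", x))) x <- gsub("[^ACGTN]", "N", x)
        return(Biostrings::DNAStringSet(x))
    }
    stop("expected a DNAStringSet or character vector of window sequences")
}

base_counts <- function(x) {
    x <- as_window_set(x)
    af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
    # columns A, C, G, T, other; "other" is N after read_assembly normalisation
    af
}

#' Feature track constructor
#'
#' A feature track is one named per-window numeric signal (a bedgraph in
#' memory): a numeric vector in window-grid order with `name` and `units`
#' attributes.
#'
#' @param name Feature identifier, e.g. `"gc_percentage"`.
#' @param values Numeric vector, one value per window.
#' @param units Free-text units (`"%"`, `"fraction"`, `"fold"`, ...).
#' @return A `feature_track` numeric vector.
#' @export
feature_track <- function(name, values, units = "") {
    stopifnot(is.character(name), length(name) == 1, is.numeric(values))
    values <- as.numeric(values)
    if (any(!is.finite(values))) stop("feature track '", name,
                                      "' contains non-finite values")
    structure(values, feature_name = name, units = units,
              class = c("feature_track", "numeric"))
}

#' @export
print.feature_track <- function(x, ...) {
    cat(sprintf("feature_track '%s' (%s): %d windows\n",
                attr(x, "feature_name"), attr(x, "units"), length(x)))
    print(utils::head(as.numeric(x)))
    invisible(x)
}

#' GC percentage per window
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. All-N windows return 0 (and are effectively flagged by
#' [n_percentage()] = 100).
#'
#' @param x Window sequences (`DNAStringSet` or character vector).
#' @return Numeric vector, percent.
#' @export
gc_percentage <- function(x) {
    af <- base_counts(x)
    eff <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- af[, "C"] + af[, "G"]
    ifelse(eff > 0, 100 * gc / eff, 0)
}

#' GC and AT skew per window
#'
#' `gc_skew = (G - C) / (G + C)` and `at_skew = (A - T) / (A + T)`;
#' 0 when the denominator is 0.
#'
#' @inheritParams gc_percentage
#' @return Numeric vector in `[-1, 1]`.
#' @export
gc_skew <- function(x) {
    af <- base_counts(x)
    d <- af[, "G"] + af[, "C"]
    ifelse(d > 0, (af[, "G"] - af[, "C"]) / d, 0)
}

#' @rdname gc_skew
#' @export
at_skew <- function(x) {
    af <- base_counts(x)
    d <- af[, "A"] + af[, "T"]
    ifelse(d > 0, (af[, "A"] - af[, "T"]) / d, 0)
}

#' N percentage per window
#' @inheritParams gc_percentage
#' @return Numeric vector, percent of window length.
#' @export
n_percentage <- function(x) {
    x <- as_window_set(x)
    af <- base_counts(x)
    len <- Biostrings::width(x)
    ifelse(len > 0, 100 * af[, "other"] / len, 0)
}

#' CpG dinucleotide frequency per window
#'
#' Overlapping occurrences of `CG` per dinucleotide position:
#' `100 * count / (effective_length - 1)` where the effective length is the
#' number of A/C/G/T bases. Windows with effective length < 2 return 0.
#'
#' @inheritParams gc_percentage
#' @return Numeric vector, percent of dinucleotide positions.
#' @export
cpg_frequency <- function(x) {
    x <- as_window_set(x)
    n <- Biostrings::vcountPattern("CG", x)
    eff <- rowSums(base_counts(x)[, c("A", "C", "G", "T"), drop = FALSE])
    ifelse(eff >= 2, 100 * n / (eff - 1), 0)
}

#' Stop codon frequency per window
#'
#' Overlapping occurrences of `TAA`, `TAG`, `TGA` on the forward strand in
#' any frame, divided by the number of codon positions
#' (`effective_length - 2`). Windows with effective length < 3 return 0.
#'
#' @inheritParams gc_percentage
#' @return Numeric vector, count per position.
#' @export
stop_codon_frequency <- function(x) {
    x <- as_window_set(x)
    n <- Biostrings::vcountPattern("TAA", x) +
        Biostrings::vcountPattern("TAG", x) +
        Biostrings::vcountPattern("TGA", x)
    eff <- rowSums(base_counts(x)[, c("A", "C", "G", "T"), drop = FALSE])
    ifelse(eff >= 3, n / (eff - 2), 0)
}

#' Motif frequency per window
#'
#' Overlapping occurrences of a motif (optionally plus its reverse
#' complement), wholly inside the window, per 100 bp of effective length.
#' The default motif is the plant/apicomplexan telomeric repeat `TTTAGGG`.
#'
#' @inheritParams gc_percentage
#' @param motif Nucleotide motif over `A/C/G/T`, length >= 2.
#' @param count_reverse_complement Also count the reverse complement
#'   (default `TRUE`).
#' @return Numeric vector, matches per 100 bp.
#' @export
motif_frequency <- function(x, motif = "TTTAGGG",
                            count_reverse_complement = TRUE) {
    stopifnot(is.character(motif), length(motif) == 1)
    motif <- toupper(motif)
    if (nchar(motif) < 2 || grepl("[^ACGT]", motif)) {
        stop("motif must be length >= 2 over A/C/G/T")
    }
    x <- as_window_set(x)
    n <- Biostrings::vcountPattern(motif, x)
    if (count_reverse_complement) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        if (rc != motif) n <- n + Biostrings::vcountPattern(rc, x)
    }
    eff <- rowSums(base_counts(x)[, c("A", "C", "G", "T"), drop = FALSE])
    ifelse(eff > 0, 100 * n / eff, 0)
}

#' Genome-wide k-mer frequency profile
#'
#' Counts forward-strand k-mers over whole scaffolds (k-mers containing N are
#' skipped by construction) and normalises to a frequency vector over all
#' `4^k` k-mers.
#'
#' @param assembly A `DNAStringSet`.
#' @param k K-mer size (3 or 4 in the default feature set).
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
genome_kmer_profile <- function(assembly, k) {
    stopifnot(k >= 1)
    counts <- colSums(Biostrings::oligonucleotideFrequency(
        as_window_set(assembly), width = k))
    tot <- sum(counts)
    if (tot == 0) stop("assembly has no informative ", k, "-mers")
    counts / tot
}

#' K-mer deviation per window
#'
#' Euclidean distance between the window's normalised k-mer frequency vector
#' and a genome-wide profile from [genome_kmer_profile()]. K-mers containing
#' N are skipped; windows with fewer than k informative bases (no countable
#' k-mers) return 0.
#'
#' @inheritParams gc_percentage
#' @param k K-mer size.
#' @param genome_profile Genome-wide k-mer frequency vector (sums to 1).
#' @return Numeric vector, dimensionless distance.
#' @export
kmer_deviation <- function(x, k, genome_profile) {
    x <- as_window_set(x)
    if (length(genome_profile) != 4^k) {
        stop("genome_profile must have length 4^k")
    }
    if (abs(sum(genome_profile) - 1) > 1e-6) {
        stop("genome_profile must sum to 1")
    }
    counts <- Biostrings::oligonucleotideFrequency(x, width = k)
    tot <- rowSums(counts)
    freq <- counts / ifelse(tot > 0, tot, 1)
    dev <- sqrt(rowSums(sweep(freq, 2, as.numeric(genome_profile))^2))
    ifelse(tot > 0, dev, 0)
}

#' Low-complexity fraction per window
#'
#' Fraction of the window masked by a DUST-style triplet-count score: scan
#' windows of `scan` bp (stepped every `step` bp, plus a right-aligned tail)
#' are scored `10 * sum(c*(c-1)/2) / (T-1)` over their triplet counts and
#' masked whole when the score exceeds `threshold`. This is a bespoke
#' deterministic masker, not a Dustmasker reimplementation, and is named
#' accordingly in outputs.
#'
#' @inheritParams gc_percentage
#' @param scan Scan window size in bp (default 64).
#' @param step Scan step in bp (default 16).
#' @param threshold Score threshold (default 20).
#' @return Numeric vector, fraction of bases masked in `[0, 1]`.
#' @export
low_complexity_fraction <- function(x, scan = 64, step = 16, threshold = 20) {
    x <- as_window_set(x)
    .low_complexity_fraction_cpp(as.character(x), as.integer(scan),
                                 as.integer(step), as.numeric(threshold))
}

#' Tandem repeat fraction per window
#'
#' Fraction of the window covered by maximal perfect tandem runs: positions
#' where `seq[i] == seq[i - u]` sustained so the repeated region spans at
#' least `2u` bases, for any unit size `u` in `1..max_unit`; overlapping runs
#' are merged. A bespoke deterministic surrogate for tandem-repeat masking
#' (perfect repeats only).
#'
#' @inheritParams gc_percentage
#' @param max_unit Largest repeat unit considered (default 12).
#' @return Numeric vector, fraction in `[0, 1]`.
#' @export
tandem_repeat_fraction <- function(x, max_unit = 12) {
    x <- as_window_set(x)
    .tandem_repeat_fraction_cpp(as.character(x), as.integer(max_unit))
}

#' Mappability depth per window
#'
#' Deterministic surrogate for simulated-read mapping coverage: error-free
#' fragments of `fragment_length` bp are tiled every
#' `fragment_length / fold` bp across the assembly; each fragment contributes
#' weight `1 / m` over the bases it covers, where `m` is the number of exact
#' full-length match loci of the fragment in the assembly (both strands).
#' The window value is the mean per-base depth. Unique sequence approaches
#' `fold`; a segment present in `m` copies approaches `fold / m`. Fragments
#' containing N are skipped; scaffolds shorter than `fragment_length`
#' contribute no fragments and their windows are 0.
#'
#' @param assembly A `DNAStringSet`.
#' @param grid A `window_grid` on the same assembly.
#' @param fragment_length Fragment length in bp (default 150).
#' @param fold Tiling fold-coverage, the maximum attainable depth
#'   (default 10).
#' @return Numeric vector in `[0, fold]`, one value per window.
#' @export
mappability_depth <- function(assembly, grid, fragment_length = 150,
                              fold = 10) {
    assembly <- as_window_set(assembly)
    lens <- attr(grid, "seqlengths")
    stopifnot(all(names(lens) %in% names(assembly)))
    depth <- .mappability_depth_cpp(as.character(assembly[names(lens)]),
                                    as.integer(fragment_length),
                                    as.integer(fold))
    names(depth) <- names(lens)
    out <- numeric(nrow(grid))
    for (s in names(lens)) {
        idx <- which(grid$scaffold == s)
        cs <- c(0, cumsum(depth[[s]]))
        out[idx] <- (cs[grid$end[idx] + 1L] - cs[grid$start[idx] + 1L]) /
            (grid$end[idx] - grid$start[idx])
    }
    out
}

## Units used for bedgraph headers and documentation.
feature_units <- c(
    gc_percentage = "%", at_skew = "ratio", gc_skew = "ratio",
    cpg_percentage = "% of dinucleotide positions",
    stop_codon_freq = "count per position",
    telomere_freq = "count per 100 bp", cag_freq = "count per 100 bp",
    kmer_deviation_kmer_size_3 = "distance",
    kmer_deviation_kmer_size_4 = "distance",
    N_percentage = "%", low_complexity_fraction = "fraction",
    tandem_repeat_fraction = "fraction", mappability_depth = "fold")

#' Compute the sequence-derived feature set for a window grid
#'
#' Runs every sequence-only feature over the windows of `grid`:
#' GC percentage, AT/GC skew, CpG frequency, stop codon frequency, telomeric
#' and CAG motif frequencies, k-mer deviation (k = 3, 4 by default), N
#' percentage, low-complexity fraction, tandem repeat fraction and
#' mappability depth.
#'
#' @param assembly A `DNAStringSet` from [read_assembly()].
#' @param grid A `window_grid` on the same assembly.
#' @param telomere_motif Telomeric repeat motif (lineage-specific; default
#'   `TTTAGGG`, reverse complement counted).
#' @param include_cag Include the CAG-repeat motif frequency track
#'   (default `TRUE`).
#' @param kmer_sizes K-mer sizes for the deviation tracks (default `c(3, 4)`).
#' @param fragment_length,fold Mappability surrogate parameters, see
#'   [mappability_depth()].
#' @param mappability Set `FALSE` to skip the (relatively costly)
#'   mappability track.
#' @return Named list of numeric vectors, one per feature, grid order.
#' @export
seq_feature_tracks <- function(assembly, grid, telomere_motif = "TTTAGGG",
                               include_cag = TRUE, kmer_sizes = c(3, 4),
                               fragment_length = 150, fold = 10,
                               mappability = TRUE) {
    win <- window_sequences(assembly, grid)
    tracks <- list(
        gc_percentage = gc_percentage(win),
        at_skew = at_skew(win),
        gc_skew = gc_skew(win),
        cpg_percentage = cpg_frequency(win),
        stop_codon_freq = stop_codon_frequency(win),
        telomere_freq = motif_frequency(win, telomere_motif, TRUE))
    if (include_cag) {
        tracks$cag_freq <- motif_frequency(win, "CAG", TRUE)
    }
    for (k in kmer_sizes) {
        prof <- genome_kmer_profile(assembly, k)
        tracks[[sprintf("kmer_deviation_kmer_size_%d", k)]] <-
            kmer_deviation(win, k, prof)
    }
    tracks$N_percentage <- n_percentage(win)
    tracks$low_complexity_fraction <- low_complexity_fraction(win)
    tracks$tandem_repeat_fraction <- tandem_repeat_fraction(win)
    if (mappability) {
        tracks$mappability_depth <- mappability_depth(
            assembly, grid, fragment_length, fold)
    }
    tracks
}
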