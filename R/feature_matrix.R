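## The windows x features matrix: merging, min-max scaling, window merging,
## TSV and bedgraph interchange.

minmax_scale <- function(m) {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    span <- hi - lo
    scaled <- sweep(m, 2, lo)
    scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), "/")
    scaled[, span == 0] <- 0 # constant columns map to all-0
    scaled
}

#' Merge feature tracks into a feature matrix
#'
#' Combines per-window tracks into a windows x features matrix with a raw
#' and a min-max-scaled view (each feature independently scaled to
#' `[0, 1]`; constant features map to all-0).
#'
#' @param tracks Named list of numeric vectors (or `feature_track`s), each
#'   of grid length. Column order follows input order.
#' @param grid The `window_grid` the tracks were computed on.
#' @param exclude Character vector of feature names to drop (e.g. a default
#'   motif track irrelevant to the genome at hand).
#' @return A `feature_matrix`: list with `grid`, `feature_names`, `raw` and
#'   `scaled` matrices.
#' @export
feature_matrix <- function(tracks, grid, exclude = character()) {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
        nm <- vapply(tracks, function(t) {
            a <- attr(t, "feature_name"); if (is.null(a)) "" else a
        }, character(1))
        if (any(!nzchar(nm))) stop("tracks must be named")
        names(tracks) <- nm
    }
    if (anyDuplicated(names(tracks))) {
        stop("duplicate feature names: ",
             paste(unique(names(tracks)[duplicated(names(tracks))]),
                   collapse = ", "))
    }
    tracks <- tracks[setdiff(names(tracks), exclude)]
    if (length(tracks) == 0) stop("no tracks left after exclusion")
    bad <- names(tracks)[vapply(tracks, length, integer(1)) != nrow(grid)]
    if (length(bad) > 0) {
        stop("track length != number of windows: ",
             paste(bad, collapse = ", "))
    }
    raw <- do.call(cbind, lapply(tracks, as.numeric))
    colnames(raw) <- names(tracks)
    if (any(!is.finite(raw))) stop("non-finite feature values")
    structure(list(grid = grid, feature_names = names(tracks),
                   raw = raw, scaled = minmax_scale(raw)),
              class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
    cat(sprintf("feature_matrix: %d windows x %d features\n",
                nrow(x$raw), ncol(x$raw)))
    cat("features:", paste(x$feature_names, collapse = ", "), "\n")
    invisible(x)
}

#' Merge windows of a feature matrix into coarser bins
#'
#' Groups runs of `factor` consecutive same-scaffold windows (the trailing
#' short group of each scaffold is kept), averages raw feature values with
#' window-length weights, and re-scales. Used to move from fine to coarse
#' resolution (e.g. 5 kb to 50 kb windows) without re-extracting features.
#'
#' @param fm A `feature_matrix`.
#' @param factor Integer >= 2, number of windows per merged bin.
#' @return A `feature_matrix` on the coarser grid.
#' @export
merge_windows <- function(fm, factor) {
    if (!is.numeric(factor) || length(factor) != 1 || factor < 2) {
        stop("factor must be a single integer >= 2")
    }
    factor <- as.integer(factor)
    grid <- fm$grid
    scaf <- factor(grid$scaffold, levels = unique(grid$scaffold))
    within <- unlist(lapply(table(scaf), seq_len), use.names = FALSE)
    group <- paste(as.integer(scaf), (within - 1L) %/% factor)
    group <- factor(group, levels = unique(group))
    w <- window_lengths(grid)
    raw <- apply(fm$raw, 2, function(v) {
        as.numeric(tapply(v * w, group, sum) / tapply(w, group, sum))
    })
    new_grid <- data.frame(
        scaffold = as.character(tapply(grid$scaffold, group, `[`, 1)),
        start = as.integer(tapply(grid$start, group, min)),
        end = as.integer(tapply(grid$end, group, max)),
        stringsAsFactors = FALSE)
    attr(new_grid, "window_size") <- attr(grid, "window_size") * factor
    attr(new_grid, "seqlengths") <- attr(grid, "seqlengths")
    class(new_grid) <- class(grid)
    tracks <- lapply(seq_len(ncol(raw)), function(j) raw[, j])
    names(tracks) <- fm$feature_names
    feature_matrix(tracks, new_grid)
}

format_num <- function(v) {
    # full double precision, so TSV round-trips are lossless
    out <- formatC(v, format = "g", digits = 17)
    trimws(out)
}

#' Write / read a feature matrix as TSV
#'
#' The interchange format of the pipeline: columns `scaffold`, `start`,
#' `end`, then one column of raw values per feature. Values are written at
#' full double precision and round-trip losslessly.
#'
#' @param fm A `feature_matrix`.
#' @param path Output (input) TSV path.
#' @return `write_feature_tsv` returns `path` invisibly; `read_feature_tsv`
#'   returns a `feature_matrix`.
#' @export
write_feature_tsv <- function(fm, path) {
    df <- data.frame(scaffold = fm$grid$scaffold, start = fm$grid$start,
                     end = fm$grid$end, stringsAsFactors = FALSE)
    for (f in fm$feature_names) df[[f]] <- format_num(fm$raw[, f])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_feature_tsv
#' @param seqlengths Optional named scaffold lengths; when omitted, each
#'   scaffold's length is taken as the end of its last window.
#' @export
read_feature_tsv <- function(path, seqlengths = NULL) {
    df <- tryCatch(read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE),
                   error = function(e) stop("malformed TSV ", path, ": ",
                                            conditionMessage(e)))
    need <- c("scaffold", "start", "end")
    if (!all(need %in% colnames(df))) {
        stop("missing column(s) in ", path, ": ",
             paste(setdiff(need, colnames(df)), collapse = ", "))
    }
    feats <- setdiff(colnames(df), need)
    if (length(feats) == 0) stop("no feature columns in ", path)
    for (f in feats) {
        v <- suppressWarnings(as.numeric(df[[f]]))
        if (any(is.na(v))) {
            stop("non-numeric value in column '", f, "' of ", path,
                 " (line ", which(is.na(v))[1] + 1L, ")")
        }
        df[[f]] <- v
    }
    if (is.null(seqlengths)) {
        seqlengths <- tapply(df$end, df$scaffold, max)
        seqlengths <- stats::setNames(as.integer(seqlengths),
                                      names(seqlengths))
    }
    seqlengths <- seqlengths[unique(df$scaffold)]
    grid <- data.frame(scaffold = df$scaffold, start = as.integer(df$start),
                       end = as.integer(df$end), stringsAsFactors = FALSE)
    attr(grid, "window_size") <- as.integer(max(grid$end - grid$start))
    attr(grid, "seqlengths") <- seqlengths
    class(grid) <- c("window_grid", "data.frame")
    feature_matrix(as.list(df[feats]), grid)
}

#' Write one feature track as a bedgraph file
#'
#' Lines are `scaffold<TAB>start<TAB>end<TAB>value` in 0-based half-open
#' coordinates, window order, preceded by a track-name comment header.
#'
#' @param values Numeric vector, one value per window.
#' @param grid A `window_grid`.
#' @param path Output path.
#' @param name Track name for the header.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, grid, path, name = "track") {
    stopifnot(length(values) == nrow(grid))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    writeLines(sprintf("%s\t%d\t%d\t%s", grid$scaffold, grid$start, grid$end,
                       format_num(as.numeric(values))), con)
    invisible(path)
}
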