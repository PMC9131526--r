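## Independently coded naive oracles used across the suite. These scan
## sequences position by position (no Biostrings, no vectorised tricks) so
## they share no code path with the implementation.

random_dna <- function(n, gc = 0.5, n_frac = 0) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(p), n, replace = TRUE, prob = p)
    if (n_frac > 0) {
        k <- rbinom(1, n, n_frac)
        if (k > 0) s[sample.int(n, k)] <- "N"
    }
    paste(s, collapse = "")
}

o_chars <- function(s) strsplit(toupper(s), "")[[1]]

o_count_base <- function(s, b) sum(o_chars(s) == b)

o_eff_len <- function(s) sum(o_chars(s) %in% c("A", "C", "G", "T"))

o_gc_percentage <- function(s) {
    eff <- o_eff_len(s)
    if (eff == 0) return(0)
    100 * (o_count_base(s, "G") + o_count_base(s, "C")) / eff
}

o_gc_skew <- function(s) {
    g <- o_count_base(s, "G"); c <- o_count_base(s, "C")
    if (g + c == 0) 0 else (g - c) / (g + c)
}

o_at_skew <- function(s) {
    a <- o_count_base(s, "A"); t <- o_count_base(s, "T")
    if (a + t == 0) 0 else (a - t) / (a + t)
}

o_n_percentage <- function(s) {
    ch <- o_chars(s)
    if (length(ch) == 0) return(0)
    100 * sum(!(ch %in% c("A", "C", "G", "T"))) / length(ch)
}

## overlapping substring count, position by position
o_substr_count <- function(s, pat) {
    s <- toupper(s); pat <- toupper(pat)
    L <- nchar(s); k <- nchar(pat)
    if (L < k) return(0L)
    n <- 0L
    for (i in seq_len(L - k + 1)) {
        if (substr(s, i, i + k - 1) == pat) n <- n + 1L
    }
    n
}

o_cpg_frequency <- function(s) {
    eff <- o_eff_len(s)
    if (eff < 2) return(0)
    100 * o_substr_count(s, "CG") / (eff - 1)
}

o_stop_codon_frequency <- function(s) {
    eff <- o_eff_len(s)
    if (eff < 3) return(0)
    (o_substr_count(s, "TAA") + o_substr_count(s, "TAG") +
        o_substr_count(s, "TGA")) / (eff - 2)
}

o_revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[o_chars(s)]), collapse = "")
}

o_motif_frequency <- function(s, motif, rc = TRUE) {
    n <- o_substr_count(s, motif)
    if (rc && o_revcomp(motif) != toupper(motif)) {
        n <- n + o_substr_count(s, o_revcomp(motif))
    }
    eff <- o_eff_len(s)
    if (eff == 0) 0 else 100 * n / eff
}

## dictionary-count k-mer frequency vector over the 4^k k-mers
o_kmer_freq <- function(s, k) {
    bases <- c("A", "C", "G", "T")
    kmers <- bases
    if (k > 1) for (i in 2:k) kmers <- as.vector(outer(kmers, bases, paste0))
    kmers <- sort(kmers)
    counts <- setNames(numeric(length(kmers)), kmers)
    s <- toupper(s)
    L <- nchar(s)
    if (L >= k) {
        for (i in seq_len(L - k + 1)) {
            sub <- substr(s, i, i + k - 1)
            if (!grepl("[^ACGT]", sub)) counts[sub] <- counts[sub] + 1
        }
    }
    counts
}

o_kmer_deviation <- function(s, k, profile) {
    counts <- o_kmer_freq(s, k)
    tot <- sum(counts)
    if (tot == 0) return(0)
    sqrt(sum((counts / tot - profile[names(counts)])^2))
}

o_low_complexity <- function(s, scan = 64, step = 16, threshold = 20) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < 3) return(0)
    starts <- seq(1, max(1, L - scan + 1), by = step)
    if (max(starts) + scan - 1 < L) starts <- c(starts, max(1, L - scan + 1))
    masked <- rep(FALSE, L)
    for (st in unique(starts)) {
        en <- min(L, st + scan - 1)
        trips <- substring(s, st:(en - 2), (st + 2):en)
        trips <- trips[!grepl("[^ACGT]", trips)]
        if (length(trips) < 2) next
        cc <- table(trips)
        score <- 10 * sum(cc * (cc - 1) / 2) / (length(trips) - 1)
        if (score > threshold) masked[st:en] <- TRUE
    }
    sum(masked) / L
}

o_tandem_fraction <- function(s, max_unit = 12) {
    ch <- o_chars(s)
    L <- length(ch)
    if (L == 0) return(0)
    masked <- rep(FALSE, L)
    acgt <- ch %in% c("A", "C", "G", "T")
    for (u in 1:max_unit) {
        if (2 * u > L) break
        # match[i] is TRUE when positions i+u and i hold the same real base
        match <- acgt[(u + 1):L] & acgt[1:(L - u)] &
            ch[(u + 1):L] == ch[1:(L - u)]
        r <- rle(match)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (k in which(r$values & r$lengths >= u)) {
            # run over positions (starts[k]+u)..(ends[k]+u) in the sequence
            masked[starts[k]:(ends[k] + u)] <- TRUE
        }
    }
    sum(masked) / L
}

## exhaustive one-sided two-sample KS enumeration: all C(m+n, m) ways to
## assign the pooled values to the two groups
o_ks_enumeration <- function(x, y) {
    pool <- c(x, y)
    m <- length(x); n <- length(y)
    d_stats <- function(a, b) {
        pts <- sort(unique(pool))
        Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
        Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
        c(dp = max(0, max(Fb - Fa)), dm = max(0, max(Fa - Fb)))
    }
    obs <- d_stats(x, y)
    combos <- combn(m + n, m)
    perm <- apply(combos, 2, function(idx) d_stats(pool[idx], pool[-idx]))
    eps <- 1e-12
    list(D_plus = obs[["dp"]], D_minus = obs[["dm"]],
         p_plus = mean(perm["dp", ] >= obs[["dp"]] - eps),
         p_minus = mean(perm["dm", ] >= obs[["dm"]] - eps))
}

## Fisher 2x2 one-sided-free p by summing hypergeometric point probabilities
o_fisher_p <- function(tab) {
    m <- tab[1, 1] + tab[2, 1]
    n <- tab[1, 2] + tab[2, 2]
    k <- tab[1, 1] + tab[1, 2]
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## adjusted Rand index from the contingency-table closed form
o_ari <- function(a, b) {
    tab <- table(a, b)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    exp_idx <- sum_a * sum_b / n2
    max_idx <- (sum_a + sum_b) / 2
    if (max_idx == exp_idx) return(0)
    (sum_ij - exp_idx) / (max_idx - exp_idx)
}

## naive per-point clustering metrics (explicit loops)
o_davies_bouldin <- function(x, labels) {
    labs <- sort(unique(labels))
    k <- length(labs)
    cent <- lapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]))
    disp <- sapply(seq_len(k), function(i) {
        pts <- x[labels == labs[i], , drop = FALSE]
        mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
    })
    total <- 0
    for (i in seq_len(k)) {
        best <- -Inf
        for (j in seq_len(k)) {
            if (i == j) next
            r <- (disp[i] + disp[j]) /
                sqrt(sum((cent[[i]] - cent[[j]])^2))
            if (r > best) best <- r
        }
        total <- total + best
    }
    total / k
}

o_calinski_harabasz <- function(x, labels) {
    labs <- sort(unique(labels))
    k <- length(labs)
    n <- nrow(x)
    grand <- colMeans(x)
    B <- 0; W <- 0
    for (l in labs) {
        pts <- x[labels == l, , drop = FALSE]
        ce <- colMeans(pts)
        B <- B + nrow(pts) * sum((ce - grand)^2)
        for (r in seq_len(nrow(pts))) W <- W + sum((pts[r, ] - ce)^2)
    }
    (B / (k - 1)) / (W / (n - k))
}

## brute-force per-window gene overlap means/counts (quadratic scan)
o_gene_tracks <- function(models, grid) {
    n <- nrow(grid)
    out <- list(count = numeric(n), mean_len = numeric(n))
    for (w in seq_len(n)) {
        hit <- which(models$scaffold == grid$scaffold[w] &
                     models$start < grid$end[w] &
                     models$end > grid$start[w])
        out$count[w] <- length(hit)
        out$mean_len[w] <- if (length(hit) > 0)
            mean(models$end[hit] - models$start[hit]) else 0
    }
    out
}
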