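## Shared fixtures, computed lazily once per test run and cached. The
## planted-architecture preset run is the expensive one (feature extraction
## plus a full parameter sweep); several test files reuse it.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixture_cache)) {
        assign(name, builder(), envir = .fixture_cache)
    }
    get(name, envir = .fixture_cache)
}

preset_fixture <- function() {
    fixture("preset", function() {
        sim <- simulate_genome(parasite_preset(), seed = 42)
        grid <- window_grid(sim$assembly, 5000)
        fm <- suppressMessages(run_extract(sim$assembly,
                                           config = run_config(seed = 42)))
        list(sim = sim, grid = grid, fm = fm,
             truth_windows = window_truth(sim$truth, grid))
    })
}

preset_sweep_fixture <- function() {
    fixture("preset_sweep", function() {
        p <- preset_fixture()
        sweep_clusterings(p$fm, seed = 42)
    })
}

small_sim <- function() {
    fixture("small_sim", function() {
        sim <- simulate_genome(list(chr1 = list(
            segment_spec("left", 1e5, gc = 0.25, genes_per_10kb = 2),
            segment_spec("right", 1e5, gc = 0.45, motif = "TTTAGGG",
                         motif_copies = 600, n_motif_arrays = 4))),
            seed = 77)
        dir <- tempfile("smallsim")
        paths <- write_simulation(sim, dir)
        list(sim = sim, paths = paths)
    })
}

## small two-population feature matrix with an obvious block structure
two_block_fm <- function(n_per = 100, seed = 1) {
    set.seed(seed)
    grid <- window_grid(c(chrA = 2L * n_per * 1000L), window_size = 1000)
    block <- rep(c(0, 1), each = n_per)
    tracks <- list(
        f1 = block * 10 + rnorm(2 * n_per, sd = 0.1),
        f2 = (1 - block) * 5 + rnorm(2 * n_per, sd = 0.1),
        f3 = rnorm(2 * n_per, sd = 0.1))
    list(fm = feature_matrix(tracks, grid), block = block, grid = grid)
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
    con <- file(path, "w")
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        writeLines(seqs[[nm]], con)
    }
    close(con)
    path
}
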