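# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The standard quadrant world: 20x20 lattice, 200 genes, rank 3, 30%
# dropout (generator defaults).
quadrant_fixture <- function(seed = 1) {
  cached(paste0("quad", seed), {
    sim <- generate_synthetic_st(seed = seed)
    list(sim = sim, data = normalize_cpm(sim$data))
  })
}

# A small world for cheaper unit tests: 12x12, 100 genes.
small_fixture <- function(seed = 1) {
  cached(paste0("small", seed), {
    sim <- generate_synthetic_st(rows = 12, cols = 12, n_genes = 100,
                                 seed = seed)
    list(sim = sim, data = normalize_cpm(sim$data))
  })
}

# Tiny deterministic STData: 4 spots x 3 genes on a 2x2 grid.
tiny_stdata <- function() {
  counts <- matrix(c(1, 1, 2,
                     3, 0, 1,
                     0, 2, 2,
                     5, 5, 0), nrow = 4, byrow = TRUE)
  STData(counts, data.frame(x = c(1, 2, 1, 2), y = c(1, 1, 2, 2)),
         gene_ids = c("gA", "gB", "MT-1"),
         spot_ids = paste0("s", 1:4))
}

# Manually assemble a SpatialGraph (for oracle comparisons).
manual_graph <- function(M, edges, weights, layout = "square4") {
  structure(list(edges = edges, weights = weights, M = M, layout = layout),
            class = "SpatialGraph")
}
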