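# Shared fixtures, all built in code.

path_graph <- function(n) {
  ids <- LETTERS[seq_len(n)]
  edges <- cbind(ids[-n], ids[-1])
  graph_from_edgelist(ids, edges, warn_isolated = FALSE)
}

# nr x nc grid with rook adjacency, ids g<row>_<col>
grid_rook_graph <- function(nr, nc) {
  ids <- as.vector(outer(seq_len(nr), seq_len(nc),
                         function(r, c) sprintf("g%d_%d", r, c)))
  cell <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  edges <- NULL
  for (k in seq_len(nrow(cell))) {
    r <- cell$row[k]; c <- cell$col[k]
    if (c < nc) edges <- rbind(edges, c(sprintf("g%d_%d", r, c),
                                        sprintf("g%d_%d", r, c + 1)))
    if (r < nr) edges <- rbind(edges, c(sprintf("g%d_%d", r, c),
                                        sprintf("g%d_%d", r + 1, c)))
  }
  graph_from_edgelist(ids, edges, warn_isolated = FALSE)
}

# GeoJSON FeatureCollection of unit squares at the given (col, row) offsets
write_squares_geojson <- function(origins, ids, path) {
  feat <- lapply(seq_along(ids), function(k) {
    x <- origins[k, 1]; y <- origins[k, 2]
    ring <- list(c(x, y), c(x + 1, y), c(x + 1, y + 1), c(x, y + 1), c(x, y))
    list(type = "Feature",
         properties = list(id = ids[k]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# k x k grid of unit squares as GeoJSON; returns the file path
grid_geojson <- function(k, path = tempfile(fileext = ".geojson")) {
  origins <- as.matrix(expand.grid(x = seq_len(k) - 1, y = seq_len(k) - 1))
  ids <- sprintf("sq%d", seq_len(k * k))
  write_squares_geojson(origins, ids, path)
}

# tiny stratified counts table: `n` regions, two strata (one sex, two ages)
tiny_counts <- function(n = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%d", seq_len(n))
  df <- expand.grid(region_id = ids, sex = "f", age_band = c("young", "old"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$population <- sample(500:2000, nrow(df), replace = TRUE)
  df$deaths <- rpois(nrow(df), df$population * 0.01)
  stratified_counts(df, region_ids = ids)
}

# brute-force Moran's I by the O(n^2) double sum
moran_bruteforce <- function(W, x) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# all permutations of seq_len(n) (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# random connected graph on n nodes: random tree plus extra random edges
random_connected_graph <- function(n, extra = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("v%d", seq_len(n))
  W <- matrix(0, n, n)
  for (i in seq.int(2L, n)) {
    j <- sample.int(i - 1L, 1L)
    W[i, j] <- W[j, i] <- 1
  }
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 1
  }
  region_graph(ids, W, warn_isolated = FALSE)
}

# small synthetic config for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  synthetic_config(n_regions = 40, pop_meanlog = log(50000), seed = seed, ...)
}

short_mcmc <- function(seed = 1, n = 4000, burn = 1000) {
  mcmc_config(n_iterations = n, burn_in = burn, seed = seed)
}
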