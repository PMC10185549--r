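# Small shared fixtures, built in code at test time.

protocol_ti <- c(200, 500, 700, 1000, 2000, 3000, 4000)

# compact imaging geometry for fast map tests (same ring layout, coarser grid)
small_layout <- function(n = 4, grid = 96L, n_slices = 1L) {
  phantom_layout(n, grid = grid, fov_mm = 200, n_slices = n_slices)
}

# a handful of phantoms with well-spread relaxation parameters
small_truth <- function(n = 4) {
  tibble::tibble(
    id = seq_len(n),
    a = 1,
    b = seq(1.6, 2, length.out = n),
    T1_ms = seq(600, 2200, length.out = n)
  ) |>
    dplyr::mutate(T0_ms = T1_ms * log(b))
}

# session-level cache for expensive shared computations
.t1ept_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .t1ept_cache)) {
    assign(key, force(expr), envir = .t1ept_cache)
  }
  get(key, envir = .t1ept_cache)
}
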