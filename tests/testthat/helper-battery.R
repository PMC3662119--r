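# Shared phantom battery: 50 phantoms at default image size and noise with
# uniformly distributed true densities, generated once per test session and
# reused by the segmentation, density and acceptance tests.

.battery_cache <- new.env(parent = emptyenv())

phantom_battery <- function(n_seeds = 50L) {
  key <- sprintf("battery_%d", n_seeds)
  if (!is.null(.battery_cache[[key]])) return(.battery_cache[[key]])
  truths <- withr::with_seed(2024L, runif(n_seeds))
  battery <- lapply(seq_len(n_seeds), function(i) {
    ph <- generate_phantom(phantom_spec(seed = i, true_density = truths[i]))
    masks <- build_envelope(ph$image)
    dens <- compute_density(ph$image, masks)
    list(phantom = ph, masks = masks, density = dens)
  })
  .battery_cache[[key]] <- battery
  battery
}

# Build a gray_histogram directly from bin counts (levels 0..length-1).
hist_from_counts <- function(counts) {
  counts <- as.integer(counts)
  structure(
    list(levels = seq_along(counts) - 1L,
         mids = as.numeric(seq_along(counts) - 1L),
         counts = counts, total = sum(counts)),
    class = "gray_histogram"
  )
}

# Drop incidental attributes (dimnames, provenance flags) before mask
# comparisons.
strip_mask <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}
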