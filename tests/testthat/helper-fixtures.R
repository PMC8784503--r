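# Shared fixtures: all synthetic, built in code.

# Small-FOV phantom spec for unit tests (clinical voxel/slice sizes kept).
small_spec <- function(...) {
  phantom_spec(matrix_size = c(72, 72), n_slices = 30, ...)
}

# Validation-size phantom (cardiac-centred FOV crop of the full matrix).
accept_spec <- function(...) {
  phantom_spec(matrix_size = c(96, 96), n_slices = 36, ...)
}

run_phantom <- function(spec, ...) {
  ph <- generate_phantom(spec)
  process_scan(ph$pet, ph$ct, ...)
}

# annulus test slice: value `hot` on inner_r <= r <= outer_r, `bg` elsewhere
annulus_slice <- function(n = 32, center = c(n + 1, n + 1) / 2,
                          inner_r = 8, outer_r = 12, hot = 10, bg = 0) {
  xs <- seq_len(n)
  r <- sqrt(outer((xs - center[1])^2, (xs - center[2])^2, "+"))
  s <- matrix(bg, n, n)
  s[r >= inner_r & r <= outer_r] <- hot
  s
}

# synthetic polar map with prescribed per-cell values
make_polar_map <- function(values, n_cap, n_rings) {
  stopifnot(nrow(values) == 360, ncol(values) == n_cap + n_rings)
  ring_zone <- as.character(cut((seq_len(n_rings) - 0.5) / n_rings,
                                c(0, 1 / 3, 2 / 3, 1),
                                labels = c("apical", "mid", "basal")))
  zone <- c(rep("apex", n_cap), ring_zone)
  segment <- matrix(0L, 360, ncol(values))
  for (m in seq_len(ncol(values)))
    segment[, m] <- cardpet:::aha_segment_id(0:359, rep(zone[m], 360))
  structure(list(values = values, valid = !is.na(values) & values >= 0,
                 n_cap = n_cap, n_rings = n_rings, ring_zone = ring_zone,
                 segment = segment, angles = 0:359,
                 provenance = list(apex_first = TRUE, slices_used = NULL,
                                   truncated_slices = 0L,
                                   manual_masks = integer(),
                                   centers = NULL)),
            class = "polar_map")
}

# segment table with prescribed means (counts default equal)
make_segments <- function(means, maxes = means, counts = rep(100L, 17)) {
  out <- data.frame(segment = 1:17, name = cardpet:::AHA_SEGMENT_NAMES,
                    suv_mean = means, suv_max = maxes,
                    n_cells = as.integer(counts), stringsAsFactors = FALSE)
  class(out) <- c("aha_segments", "data.frame")
  out
}
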