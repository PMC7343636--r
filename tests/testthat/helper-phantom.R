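# Compact phantom configuration for unit tests: two small spheroids with a
# handful of cells in a 16 x 96 x 96 volume. The full-size default
# configuration is exercised by the acceptance tests.
small_phantom_config <- function(...) {
  defaults <- list(volume_shape = c(18, 112, 112),
                   n_spheroids = 2,
                   spheroid_radius_um = 20,
                   necrotic_core_fraction = 0.4,
                   n_cells_per_spheroid = 3,
                   n_keratinocytes = 300)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_config, args)
}

ref_norm <- function() normalization_reference()

# warp a 2D image through the package's slice-wise transform
warp2d_helper <- function(img, t) {
  apply_transform(array(img, c(1, nrow(img), ncol(img))), t)[1, , ]
}

# brute-force flood fill used as the connected-components oracle
flood_fill_labels <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  manh <- rowSums(abs(offs))
  keep <- manh > 0 & switch(as.character(connectivity),
                            "6" = manh <= 1, "18" = manh <= 2,
                            "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || labels[z, y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    labels[z, y, x] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        p <- cur + offs[k, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
          labels[p[1], p[2], p[3]] <- nxt
          queue <- rbind(queue, p)
        }
      }
    }
  }
  labels
}

# canonical relabeling by first occurrence in column-major scan order,
# so labelings can be compared independently of numbering
canonical_labels <- function(labels) {
  v <- as.integer(labels)
  first <- v[v != 0L]
  remap <- integer(max(v, 0L))
  nxt <- 0L
  for (lab in first) {
    if (remap[lab] == 0L) { nxt <- nxt + 1L; remap[lab] <- nxt }
  }
  out <- v
  out[v != 0L] <- remap[v[v != 0L]]
  array(out, dim(labels))
}

# exhaustive-search Otsu oracle: all cuts between sorted distinct values,
# minimizing the weighted intra-class variance; returns every minimizing
# foreground mask (ties allowed)
otsu_oracle_masks <- function(v) {
  vals <- sort(unique(as.numeric(v)))
  stopifnot(length(vals) >= 2)
  cuts <- vals[-length(vals)]
  wvar <- vapply(cuts, function(cut) {
    a <- v[v <= cut]; b <- v[v > cut]
    va <- if (length(a) > 1) stats::var(a) * (length(a) - 1) / length(a) else 0
    vb <- if (length(b) > 1) stats::var(b) * (length(b) - 1) / length(b) else 0
    (length(a) * va + length(b) * vb) / length(v)
  }, numeric(1))
  best <- which(wvar <= min(wvar) + 1e-12)
  lapply(cuts[best], function(cut) v > cut)
}

table1_summaries <- function() {
  list(
    rfp_cells = list(control = group_summary("control", 74, 87, 62),
                     treated = group_summary("treated", 69, 48, 46),
                     printed_g = 0.703),
    rfp_total = list(control = group_summary("control", 74, 69, 75),
                     treated = group_summary("treated", 69, 37, 57),
                     printed_g = 0.4773),
    gfp_cells = list(control = group_summary("control", 49, 101, 38),
                     treated = group_summary("treated", 47, 89, 36),
                     printed_g = 0.3251))
}
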