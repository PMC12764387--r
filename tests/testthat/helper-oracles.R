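# Independent numeric FWHM oracle: locate the two half-maximum crossings
# of a densely sampled pulse by direct scan + linear interpolation,
# without using the package's compute_fwhm().
numeric_fwhm_oracle <- function(y, t) {
  ipk <- which.max(y)
  half <- y[ipk] / 2
  below_l <- which(y[seq_len(ipk)] < half)
  below_r <- which(y[ipk:length(y)] < half) + ipk - 1
  l <- below_l[length(below_l)]
  r <- below_r[1]
  tl <- t[l] + (half - y[l]) / (y[l + 1] - y[l]) * (t[l + 1] - t[l])
  tr <- t[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) * (t[r] - t[r - 1])
  tr - tl
}

# absolute angular difference in degrees, wrapped to [0, 180]
ang_diff_deg <- function(a, b) {
  d <- abs(((a - b + pi) %% (2 * pi)) - pi)
  d * 180 / pi
}

# 90-degree counter-clockwise rotation of a matrix
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# build a trace_set directly from a matrix of raw traces
make_trace_set <- function(time_ms, raw, frame_rate = 20) {
  ids <- sprintf("roi_%02d", seq_len(ncol(raw)))
  colnames(raw) <- ids
  structure(list(time_ms = time_ms, raw = raw, roi_ids = ids,
                 frame_rate = frame_rate),
            class = "trace_set")
}

# flow_sequence wrapper around explicit (u, v) fields for summary tests
make_flow_sequence <- function(us, vs, pixel_size = 1, frame_rate = 1) {
  fields <- Map(function(u, v)
    structure(list(u = u, v = v, iterations = 0L), class = "flow_field"),
    us, vs)
  structure(list(fields = fields,
                 mask = matrix(TRUE, nrow(us[[1]]), ncol(us[[1]])),
                 pixel_size = pixel_size, frame_rate = frame_rate),
            class = "flow_sequence")
}
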