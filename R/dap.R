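#' Dimension-adaptive average pooling
#'
#' Maps a feature map of arbitrary channel count C and time length T to a
#' fixed (out_channel_bins x out_time_bins) grid by bin-averaging: output
#' cell (i, j) (0-based) is the arithmetic mean of input rows
#' `[floor(i*C/Cb), floor((i+1)*C/Cb))` and columns
#' `[floor(j*T/Tb), floor((j+1)*T/Tb))`. When `Cb <= C` and `Tb <= T`
#' every bin is non-empty and every input element belongs to exactly one
#' cell. When a bin count exceeds the input size, an empty bin replicates
#' the element at its start boundary (its end is clamped to start + 1),
#' so the output shape depends only on the bin specification, never on
#' the input shape.
#'
#' @param feature_map numeric matrix (C x T), both dimensions >= 1.
#' @param out_time_bins,out_channel_bins positive integers Tb and Cb.
#' @return Numeric matrix of shape (out_channel_bins x out_time_bins).
#' @export
#' @examples
#' dap_pool(matrix(1:7, 1, 7), out_time_bins = 2, out_channel_bins = 1)
dap_pool <- function(feature_map, out_time_bins, out_channel_bins) {
  stopifnot(is.matrix(feature_map))
  Cn <- nrow(feature_map); Tn <- ncol(feature_map)
  if (Cn < 1 || Tn < 1) stop("feature map must be at least 1 x 1", call. = FALSE)
  # sum over each bin, then divide by the bin-size product: this keeps
  # constants exactly constant (a weighted dot product would not)
  Rb <- dap_bin_matrix(Cn, out_channel_bins)
  Cb <- dap_bin_matrix(Tn, out_time_bins)
  R1 <- (Rb > 0) * 1
  C1 <- (Cb > 0) * 1
  (R1 %*% feature_map %*% t(C1)) / outer(rowSums(R1), rowSums(C1))
}

#' Averaging matrix for one pooling axis
#'
#' Row b of the returned (bins x size) matrix holds weight 1/(e-s) over
#' the half-open index range [s, e) given by the floor-boundary rule,
#' with empty bins clamped to a single replicated element.
#'
#' @keywords internal
dap_bin_matrix <- function(size, bins) {
  bins <- as.integer(bins)
  if (bins < 1) stop("bin count must be >= 1", call. = FALSE)
  A <- matrix(0, bins, size)
  for (b in seq_len(bins)) {
    s <- floor((b - 1) * size / bins)
    e <- floor(b * size / bins)
    if (e <= s) e <- s + 1          # replication when bins > size
    A[b, (s + 1):e] <- 1 / (e - s)
  }
  A
}

#' Bin specification for the dimension-adaptive pooling layer
#'
#' @param out_time_bins number of output time bins (default 8).
#' @param out_channel_bins number of output channel bins (default 6).
#' @return A `dap_spec` object.
#' @export
dap_spec <- function(out_time_bins = 8L, out_channel_bins = 6L) {
  out_time_bins <- as.integer(out_time_bins)
  out_channel_bins <- as.integer(out_channel_bins)
  if (out_time_bins < 1 || out_channel_bins < 1) {
    stop("bin counts must be >= 1", call. = FALSE)
  }
  structure(list(out_time_bins = out_time_bins,
                 out_channel_bins = out_channel_bins),
            class = "dap_spec")
}
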