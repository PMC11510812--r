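# Energy-spatial block extraction and re-assembly.
#
# Training samples are small (energy x height x width) blocks cut from the
# spectral image stacks on a regular stride grid with configurable overlap.
# Extraction adds flush-to-border blocks when the stride grid does not reach
# the far edge, so every voxel is covered and the prediction can be
# re-assembled by uniform averaging of overlapping blocks.

#' Block specification
#'
#' @param block_shape `c(energy, height, width)` block size in voxels.
#' @param overlap Overlap fraction per axis in `[0, 1)`; scalar or length-3.
#'   The stride per axis is `max(1, round(size * (1 - overlap)))`.
#' @return A `block_spec` list with `block_shape`, `overlap`, `stride`.
#' @export
block_spec <- function(block_shape = c(4L, 16L, 16L), overlap = 0.75) {
  block_shape <- as.integer(block_shape)
  overlap <- rep(as.numeric(overlap), length.out = 3)
  stopifnot(length(block_shape) == 3, all(block_shape >= 1),
            all(overlap >= 0), all(overlap < 1))
  stride <- pmax(1L, as.integer(round(block_shape * (1 - overlap))))
  structure(list(block_shape = block_shape, overlap = overlap,
                 stride = stride),
            class = "block_spec")
}

# start offsets along one axis: stride grid plus a flush-to-border block
.block_origins_axis <- function(size, block, stride) {
  if (block > size) {
    stop("block_too_large: block exceeds the stack along one axis",
         call. = FALSE)
  }
  o <- seq.int(1L, size - block + 1L, by = stride)
  if (o[length(o)] != size - block + 1L) {
    o <- c(o, size - block + 1L)
  }
  o
}

#' Grid of block origins for a stack shape
#'
#' @param dims Stack dimensions `c(E, H, W)`.
#' @param spec A [block_spec()].
#' @return Integer matrix (n x 3) of 1-based origins (energy, row, col).
#' @export
block_origins <- function(dims, spec) {
  stopifnot(inherits(spec, "block_spec"))
  axes <- lapply(1:3, function(k) {
    .block_origins_axis(dims[k], spec$block_shape[k], spec$stride[k])
  })
  as.matrix(expand.grid(e = axes[[1]], r = axes[[2]], c = axes[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Extract overlapping blocks from a stack
#'
#' @param stack A [spectral_image_stack()] or a bare E x H x W array.
#' @param spec A [block_spec()].
#' @return List with `blocks` (array `block_shape` x n) and `origins`
#'   (n x 3 matrix of 1-based corner indices).
#' @export
extract_blocks <- function(stack, spec) {
  arr <- if (is.array(stack)) stack else stack$pixels
  d <- dim(arr)
  org <- block_origins(d, spec)
  bs <- spec$block_shape
  n <- nrow(org)
  blocks <- array(0, dim = c(bs, n))
  for (i in seq_len(n)) {
    blocks[, , , i] <- arr[org[i, 1] + seq_len(bs[1]) - 1L,
                           org[i, 2] + seq_len(bs[2]) - 1L,
                           org[i, 3] + seq_len(bs[3]) - 1L]
  }
  list(blocks = blocks, origins = org, spec = spec, dims = d)
}

#' Re-assemble blocks into a stack by uniform averaging
#'
#' Every voxel receives the mean of all block values that cover it;
#' `assemble_blocks(extract_blocks(x, spec))` reproduces `x` exactly.
#'
#' @param blocks Array `block_shape` x n (e.g. network predictions).
#' @param origins n x 3 matrix of 1-based origins.
#' @param dims Target stack dimensions `c(E, H, W)`.
#' @return Array (E x H x W).
#' @export
assemble_blocks <- function(blocks, origins, dims) {
  bs <- dim(blocks)[1:3]
  n <- dim(blocks)[4]
  stopifnot(nrow(origins) == n)
  acc <- array(0, dim = dims)
  cnt <- array(0, dim = dims)
  for (i in seq_len(n)) {
    ei <- origins[i, 1] + seq_len(bs[1]) - 1L
    ri <- origins[i, 2] + seq_len(bs[2]) - 1L
    ci <- origins[i, 3] + seq_len(bs[3]) - 1L
    acc[ei, ri, ci] <- acc[ei, ri, ci] + blocks[, , , i]
    cnt[ei, ri, ci] <- cnt[ei, ri, ci] + 1
  }
  if (any(cnt == 0)) {
    stop("uncovered_voxel: blocks do not cover the full stack", call. = FALSE)
  }
  acc / cnt
}

#' Stride rule helper for arbitrary dimensionality
#'
#' Exposes the stride computation (`max(1, round(size * (1 - overlap)))`) for
#' block shapes of any rank, e.g. the 4-way blocks used with volumetric data.
#'
#' @param block_shape Integer sizes per axis.
#' @param overlap Overlap fractions per axis (recycled).
#' @return Integer strides per axis.
#' @export
block_strides <- function(block_shape, overlap) {
  overlap <- rep(as.numeric(overlap), length.out = length(block_shape))
  stopifnot(all(overlap >= 0), all(overlap < 1))
  pmax(1L, as.integer(round(block_shape * (1 - overlap))))
}
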