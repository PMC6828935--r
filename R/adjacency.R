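## Adjacency codes ------------------------------------------------------------
##
## An adjacency a(x, y) is an ordered pair of signed block labels with
## a(x, y) identified with a(-y, -x) (reading the chromosome from the other
## end).  The label 0 is the telomere cap used by RGRPT; at most one side of
## an adjacency may be a cap.  Adjacencies are stored as a single integer
## code so that whole candidate sets are plain integer vectors and set
## algebra stays vectorised.

.ADJ_MAX_LABEL <- 20000L
.ADJ_BASE <- 40001L # one more than the span of shifted labels

.adj_enc_raw <- function(x, y) {
  (x + .ADJ_MAX_LABEL) * .ADJ_BASE + (y + .ADJ_MAX_LABEL)
}

#' Canonical adjacency code
#'
#' Encodes the adjacency `a(x, y)` as a single integer such that
#' `canonical_adjacency(x, y) == canonical_adjacency(-y, -x)`.  Block
#' labels are non-zero signed integers; `0` denotes a telomere cap and may
#' occupy at most one side.
#'
#' @param x,y signed integer block labels (vectorised); `0` is the cap.
#' @return integer vector of canonical adjacency codes.
#' @examples
#' canonical_adjacency(2, 3) == canonical_adjacency(-3, -2)
#' canonical_adjacency(0, 1) == canonical_adjacency(-1, 0)
#' @export
canonical_adjacency <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (any(x == 0L & y == 0L))
    stop("invalid adjacency: both sides are telomere caps")
  if (any(abs(x) > .ADJ_MAX_LABEL) || any(abs(y) > .ADJ_MAX_LABEL))
    stop("block labels above ", .ADJ_MAX_LABEL, " are not supported")
  pmin(.adj_enc_raw(x, y), .adj_enc_raw(-y, -x))
}

#' Decode adjacency codes
#'
#' @param code integer vector of canonical adjacency codes.
#' @return two-column integer matrix with columns `left` and `right`
#'   (the stored canonical orientation).
#' @export
decode_adjacency <- function(code) {
  left <- code %/% .ADJ_BASE - .ADJ_MAX_LABEL
  right <- code %% .ADJ_BASE - .ADJ_MAX_LABEL
  cbind(left = as.integer(left), right = as.integer(right))
}

#' Human-readable adjacency labels
#'
#' @param code integer vector of adjacency codes.
#' @return character vector like `"a(1,-3)"`.
#' @export
format_adjacency <- function(code) {
  m <- decode_adjacency(code)
  sprintf("a(%d,%d)", m[, 1L], m[, 2L])
}

## Both oriented readings of each code: rows = 2 * length(code),
## columns p (left), q (right), code.  The two readings are always distinct
## because a(x, -x) cannot occur (labels are unique within a genome).
.adj_orientations <- function(code) {
  m <- decode_adjacency(code)
  cbind(p = c(m[, 1L], -m[, 2L]),
        q = c(m[, 2L], -m[, 1L]),
        code = c(code, code))
}

#' Do two adjacencies share a block?
#'
#' True when the two adjacencies share at least one block by absolute
#' label.  Telomere caps (0) never count as shared.
#'
#' @param a1,a2 canonical adjacency codes (scalars).
#' @return logical.
#' @export
blocks_overlap <- function(a1, a2) {
  m1 <- abs(decode_adjacency(a1))
  m2 <- abs(decode_adjacency(a2))
  l1 <- m1[m1 != 0L]
  l2 <- m2[m2 != 0L]
  any(l1 %in% l2)
}

## Absolute non-cap labels of a set of codes, as a list parallel to codes.
.adj_block_labels <- function(codes) {
  m <- abs(decode_adjacency(codes))
  lapply(seq_along(codes), function(i) {
    v <- m[i, ]
    v[v != 0L]
  })
}
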